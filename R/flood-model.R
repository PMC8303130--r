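#' Configuration for the flood / mental-health network
#'
#' The packaged model links flooding of a household to probable depression
#' through the loss of sentimental items, a recognized secondary stressor:
#' `Flood -> LOSI -> PPD`, with `PPD -> Lsever` and `PPD -> Msever` as the
#' two (possibly overlapping) depression-severity outcomes. All nodes are
#' binary with states `present`/`absent`.
#'
#' The elicited evidence arrives as *marginal* prevalences, not conditional
#' tables: 20.1% of households flooded, 62% losing sentimental items, 18.6%
#' prevalence of probable depression, 48.3% less severe and 21.1% more
#' severe depression. [build_flood_network()] turns these marginals into
#' conditionals (see its help for the calibration rule).
#'
#' @param marginals Named numeric vector of target marginal probabilities of
#'   the `present` state for every node.
#' @param arcs Arc set as a data frame (`parent`, `child`); must be acyclic
#'   with at most one parent per node.
#' @param risk_ratio Requested exposed-vs-unexposed probability ratio used to
#'   complete the conditionals (see [build_flood_network()]).
#' @return A list of class `flood_config`.
#' @export
flood_config <- function(marginals = c(Flood = 0.201, LOSI = 0.62,
                                       PPD = 0.186, Lsever = 0.483,
                                       Msever = 0.211),
                         arcs = NULL,
                         risk_ratio = 2) {
  if (is.null(arcs)) {
    arcs <- tibble::tibble(
      parent = c("Flood", "LOSI", "PPD", "PPD"),
      child = c("LOSI", "PPD", "Lsever", "Msever")
    )
  }
  if (any(marginals < 0 | marginals > 1)) {
    rlang::abort("marginal probabilities must lie in [0, 1]",
                 class = "floodbn_input_error")
  }
  if (risk_ratio <= 0) {
    rlang::abort("risk_ratio must be positive",
                 class = "floodbn_input_error")
  }
  structure(list(marginals = marginals, arcs = normalize_arcs(arcs),
                 risk_ratio = risk_ratio),
            class = "flood_config")
}

#' Build the flood / mental-health Bayesian network
#'
#' Constructs a binary network over the configured nodes whose marginal
#' distribution of every node reproduces its elicited prevalence exactly.
#'
#' Because the elicited inputs are marginals, the conditional tables are
#' underdetermined: for a child with target marginal `m` and a single parent
#' with marginal `p`, any pair `(q1, q0)` with `p*q1 + (1-p)*q0 = m` matches.
#' The residual degree of freedom is fixed by the exposed-vs-unexposed risk
#' ratio `r = q1/q0` (default 2: the outcome is twice as likely when the
#' parent condition is present). When the requested ratio is infeasible —
#' `r*q0` would exceed 1, which happens for LOSI under the default marginals
#' — it is clamped to the largest feasible ratio `(1-p)/(m-p)` with a
#' message; the marginal constraint is honored exactly either way.
#'
#' The change-in-utility (CU) and change-in-QALY (CQALY) quantities drawn
#' downstream of the severity nodes are deterministic arithmetic on the
#' network's posteriors and the utility table; they are computed by
#' [change_in_utility()] and [compute_cqaly()], not stored as CPTs.
#'
#' @param cfg A [flood_config()].
#' @return A valid `bn` network whose per-node `present` marginals equal
#'   `cfg$marginals` to machine precision.
#' @examples
#' net <- build_flood_network()
#' query_posterior(net, "PPD") # P(PPD = present) = 0.186
#' @export
build_flood_network <- function(cfg = flood_config()) {
  if (!inherits(cfg, "flood_config")) cfg <- do.call(flood_config, cfg)
  nodes <- names(cfg$marginals)
  required <- c("Flood", "LOSI", "PPD", "Lsever", "Msever")
  missing_nodes <- setdiff(required, nodes)
  if (length(missing_nodes) > 0L) {
    rlang::abort(sprintf("config is missing node(s): %s",
                         paste(missing_nodes, collapse = ", ")),
                 class = "floodbn_input_error")
  }
  states <- c("present", "absent")
  variables <- stats::setNames(rep(list(states), length(nodes)), nodes)
  skel <- bn_structure(variables, cfg$arcs)
  order <- topological_sort(skel)
  if (is.null(order)) {
    rlang::abort("the configured arc set contains a cycle",
                 class = "floodbn_input_error")
  }

  cpts <- list()
  for (nm in order) {
    parents <- bn_parents(skel, nm)
    m <- cfg$marginals[[nm]]
    if (length(parents) == 0L) {
      cpts[[nm]] <- cpt(nm, character(), states, c(m, 1 - m))
    } else if (length(parents) == 1L) {
      p <- cfg$marginals[[parents]]
      r <- cfg$risk_ratio
      if (m > p) {
        r_max <- (1 - p) / (m - p)
        if (r > r_max) {
          message(sprintf(
            "node '%s': risk ratio %.3g infeasible for marginal %.3g given parent marginal %.3g; clamped to %.6g",
            nm, r, m, p, r_max))
          r <- r_max
        }
      }
      q0 <- m / (p * r + 1 - p)
      q1 <- r * q0
      cpts[[nm]] <- cpt(nm, parents, states,
                        rbind(c(q1, 1 - q1), c(q0, 1 - q0)),
                        parent_states = variables)
    } else {
      rlang::abort(sprintf(
        "node '%s' has %d parents; marginal calibration by a single risk ratio needs at most one parent",
        nm, length(parents)), class = "floodbn_input_error")
    }
  }
  bn_network(variables, cfg$arcs, cpts[nodes])
}

#' Health-state utility table
#'
#' The three depression-related health states and their preference weights
#' (QALY utilities on a 0-1 scale): remission 0.85, less severe depression
#' (`Lsever`) 0.60, more severe depression (`Msever`) 0.42, each backed by a
#' Beta(alpha, beta) distribution encoding elicitation uncertainty
#' (Be(923, 163), Be(182, 122) and Be(54, 75) respectively — each stated
#' mean agrees with its Beta mean to within 0.005). The change in utility
#' (CU) of a state is the remission utility minus the state utility, so one
#' year spent in a state instead of remission forgoes CU quality-adjusted
#' life years.
#'
#' @param states Character vector of health-state labels; must include the
#'   reference state.
#' @param utility Numeric utilities in `[0, 1]`, same length as `states`.
#' @param alpha,beta Positive Beta hyperparameters per state.
#' @param reference Label of the reference (full-recovery) state.
#' @param horizon Monitoring horizon in years over which a utility change
#'   accrues (default 1).
#' @return A tibble of class `utility_table` with columns `state`, `utility`,
#'   `alpha`, `beta` and `cu`, plus attributes `reference` and `horizon`.
#' @examples
#' utility_table()
#' @export
utility_table <- function(states = c("Remission", "Lsever", "Msever"),
                          utility = c(0.85, 0.60, 0.42),
                          alpha = c(923, 182, 54),
                          beta = c(163, 122, 75),
                          reference = "Remission",
                          horizon = 1) {
  if (!reference %in% states) {
    rlang::abort("the reference state must be one of the states",
                 class = "floodbn_input_error")
  }
  if (any(alpha <= 0) || any(beta <= 0)) {
    rlang::abort("Beta hyperparameters must be positive",
                 class = "floodbn_input_error")
  }
  if (any(utility < 0 | utility > 1)) {
    rlang::abort("utilities must lie in [0, 1]",
                 class = "floodbn_input_error")
  }
  drift <- abs(alpha / (alpha + beta) - utility)
  if (any(drift > 0.005)) {
    rlang::abort(sprintf(
      "stated utility of '%s' differs from its Beta mean by %.4f (> 0.005)",
      states[which.max(drift)], max(drift)),
      class = "floodbn_input_error")
  }
  ref_u <- utility[match(reference, states)]
  cu <- ref_u - utility
  if (any(cu < 0)) {
    rlang::abort("no state may have higher utility than the reference state",
                 class = "floodbn_input_error")
  }
  out <- tibble::tibble(state = states, utility = utility,
                        alpha = alpha, beta = beta, cu = cu)
  structure(out, class = c("utility_table", class(out)),
            reference = reference, horizon = as.numeric(horizon))
}

#' Change in utility of a health state
#'
#' Utility forgone per year in a health state relative to the reference
#' state (remission): `CU = u_reference - u_state`. For the packaged table
#' this is 0.25 for less severe and 0.43 for more severe depression, and 0
#' for remission itself.
#'
#' @param utilities A [utility_table()].
#' @param state Health-state label.
#' @return The change in utility (dimensionless, full precision).
#' @export
change_in_utility <- function(utilities, state) {
  i <- match(state, utilities$state)
  if (is.na(i)) {
    rlang::abort(sprintf("unknown health state '%s'", state),
                 class = "floodbn_input_error")
  }
  utilities$cu[i]
}

#' Mean of a Beta distribution
#'
#' @param alpha,beta Positive shape parameters.
#' @return `alpha / (alpha + beta)`.
#' @examples
#' beta_mean(923, 163) # ~0.85, the remission utility
#' @export
beta_mean <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    rlang::abort("Beta parameters must be positive",
                 class = "floodbn_input_error")
  }
  alpha / (alpha + beta)
}

#' Change in QALY attributable to loss of sentimental items
#'
#' The default pathway reading: the QALY loss in a depression-severity state
#' caused by losing sentimental items in a flood is the probability of being
#' in that state *and* having lost sentimental items, among the flooded,
#' times the state's change in utility, over the monitoring horizon:
#'
#' `CQALY_s = P(s = present, LOSI = present | Flood = present) * CU_s * horizon`
#'
#' This is one defensible reading of the model's CQALY node; published
#' analyses may state CQALY values directly, and those are accepted as
#' authoritative inputs via `override` (or via a value-form
#' [intervention_scenario()]) rather than recomputed.
#'
#' @param net A valid `bn` with `LOSI` and `Flood` nodes.
#' @param utilities A [utility_table()].
#' @param state A depression-severity state name (not the reference state).
#' @param override Optional named numeric vector of externally supplied
#'   CQALY values; when it names `state`, that value is returned unchanged.
#' @return The change in QALY (years).
#' @export
compute_cqaly <- function(net, utilities, state, override = NULL) {
  if (!is.null(override) && state %in% names(override)) {
    return(override[[state]])
  }
  if (identical(state, attr(utilities, "reference"))) {
    rlang::abort("the reference state has no change in QALY by definition",
                 class = "floodbn_input_error")
  }
  if (!state %in% names(net$variables)) {
    rlang::abort(sprintf("'%s' is not a node of the network", state),
                 class = "floodbn_input_error")
  }
  post <- query_posterior(net, c(state, "LOSI"), c(Flood = "present"))
  path_p <- post$prob[post[[state]] == "present" & post$LOSI == "present"]
  path_p * change_in_utility(utilities, state) * attr(utilities, "horizon")
}

#' Define a before/after intervention scenario
#'
#' Pairs the model state without an intervention ("before") against the
#' state with it ("after"), for one intervention such as a flood
#' early-warning system. Each side is either a named numeric vector of
#' per-state CQALY values (the value form, used when the CQALY outcomes are
#' supplied directly) or a `bn` network (the model form, in which case
#' CQALYs are computed by [compute_cqaly()] at evaluation time). Both sides
#' must use the same form.
#'
#' @param before,after Named numeric CQALY vectors, or `bn` networks.
#' @param label Free-text scenario label.
#' @param threshold Willingness-to-pay threshold in pounds per QALY
#'   (default 20000, the lower bound of the conventional NICE range).
#' @return A list of class `intervention_scenario`.
#' @examples
#' scenario_ews() # the packaged early-warning-system scenario
#' @export
intervention_scenario <- function(before, after, label = "intervention",
                                  threshold = 20000) {
  if (threshold <= 0) {
    rlang::abort("threshold must be positive", class = "floodbn_input_error")
  }
  value_form <- function(x) is.numeric(x) && !is.null(names(x))
  model_form <- function(x) inherits(x, "bn")
  if (value_form(before) && value_form(after)) {
    if (!setequal(names(before), names(after))) {
      rlang::abort("before and after must cover the same health states",
                   class = "floodbn_input_error")
    }
    form <- "value"
  } else if (model_form(before) && model_form(after)) {
    form <- "model"
  } else {
    rlang::abort(
      "before and after must both be named CQALY vectors or both be networks",
      class = "floodbn_input_error")
  }
  structure(list(label = label, before = before, after = after,
                 threshold = threshold, form = form),
            class = "intervention_scenario")
}

#' The packaged early-warning-system scenario
#'
#' The published evaluation of a flood early-warning system operated by the
#' local environment agency: without the intervention the changes in QALY
#' are 0.055 (more severe) and 0.062 (less severe depression); with it,
#' 0.033 and 0.038. These four CQALY values are carried as stated inputs.
#'
#' @param threshold Pounds per QALY (default 20000).
#' @return An [intervention_scenario()].
#' @export
scenario_ews <- function(threshold = 20000) {
  read_scenario(system.file("extdata", "scenario_ews.json",
                            package = "floodbn"),
                threshold = threshold)
}

round_gbp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Evaluate the cost-effectiveness of an intervention
#'
#' For every health state, the incremental QALY gain of the intervention is
#' the before-minus-after change in QALY, and its monetary value is that
#' gain times the willingness-to-pay threshold. At the packaged scenario and
#' the lower NICE threshold of 20,000 pounds per QALY this reproduces gains
#' of 0.022 QALY (440 pounds) for more severe and 0.024 QALY (480 pounds)
#' for less severe depression.
#'
#' @param scn An [intervention_scenario()].
#' @param utilities A [utility_table()]; used to compute CQALYs when the
#'   scenario is in model (network) form.
#' @return A tibble of class `ce_result` with columns `state`,
#'   `cqaly_before`, `cqaly_after`, `delta_qaly` and `monetary_value`
#'   (pounds, full precision; the print method rounds to the nearest pound,
#'   half away from zero), plus attributes `threshold` and `label`.
#' @examples
#' evaluate_intervention(scenario_ews())
#' @export
evaluate_intervention <- function(scn, utilities = utility_table()) {
  stopifnot(inherits(scn, "intervention_scenario"))
  if (scn$form == "value") {
    states <- names(scn$before)
    before <- as.numeric(scn$before[states])
    after <- as.numeric(scn$after[states])
  } else {
    states <- setdiff(utilities$state, attr(utilities, "reference"))
    before <- vapply(states, function(s) {
      compute_cqaly(scn$before, utilities, s)
    }, numeric(1))
    after <- vapply(states, function(s) {
      compute_cqaly(scn$after, utilities, s)
    }, numeric(1))
  }
  delta <- before - after
  out <- tibble::tibble(
    state = states,
    cqaly_before = before,
    cqaly_after = after,
    delta_qaly = delta,
    monetary_value = delta * scn$threshold
  )
  structure(out, class = c("ce_result", class(out)),
            threshold = scn$threshold, label = scn$label)
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<cost-effectiveness: %s at £%s/QALY>\n",
              attr(x, "label"),
              format(attr(x, "threshold"), big.mark = ",")))
  shown <- tibble::as_tibble(x)
  shown$monetary_value <- round_gbp(shown$monetary_value)
  print(shown)
  invisible(x)
}
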