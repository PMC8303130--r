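#' Probabilistic sensitivity analysis over utility uncertainty
#'
#' Propagates the elicitation uncertainty in the health-state utilities
#' through the cost-effectiveness evaluation by Monte Carlo: each draw
#' samples every state's utility from its Beta distribution, recomputes the
#' change in utility (CU) of each state against the drawn reference utility,
#' rescales the scenario's QALY changes proportionally to
#' `CU_draw / CU_mean`, where `CU_mean` is the Beta-implied mean CU (the
#' change in QALY is linear in CU, so the scaling is exact for model-form
#' scenarios and a stated modeling assumption for value-form ones, and the
#' PSA mean converges to the deterministic result as the Beta variances
#' vanish), and re-values the intervention at the threshold.
#'
#' Draws are state-major — all `n` draws for the first state, then the next
#' — from a single seeded generator, so results are bit-reproducible.
#'
#' The summary includes a per-person expected value of perfect information
#' (EVPI) for the two-option decision {intervene, do nothing}, where the net
#' benefit of intervening in a draw is its total monetary value minus
#' `cost`, and doing nothing has net benefit 0.
#'
#' @param scn An [intervention_scenario()].
#' @param utilities A [utility_table()].
#' @param n Number of Monte Carlo draws (at least 1).
#' @param seed Integer seed for the utility draws.
#' @param cost Up-front cost of the intervention in pounds per person
#'   (default 0), entering only the EVPI net-benefit comparison.
#' @return A `psa_result` object: list with `n`, `seed`, `threshold`,
#'   `cost`, `evpi` (pounds per person), `utility_draws` (tibble: draw,
#'   state, utility), `outcomes` (tibble: draw, state, cu, delta_qaly,
#'   monetary_value) and `summary` (per-state mean and 2.5/97.5 percentiles
#'   of delta_qaly and monetary_value).
#' @examples
#' psa <- run_psa(scenario_ews(), utility_table(), n = 500, seed = 42)
#' tidy(psa)
#' @export
run_psa <- function(scn, utilities, n = 10000, seed = 1L, cost = 0) {
  stopifnot(inherits(scn, "intervention_scenario"),
            inherits(utilities, "utility_table"))
  if (n < 1) {
    rlang::abort("n must be at least 1", class = "floodbn_input_error")
  }
  det <- evaluate_intervention(scn, utilities)
  ref <- attr(utilities, "reference")

  u_draws <- withr::with_seed(seed, {
    vapply(seq_len(nrow(utilities)), function(i) {
      stats::rbeta(n, utilities$alpha[i], utilities$beta[i])
    }, numeric(n))
  })
  u_draws <- matrix(u_draws, nrow = n,
                    dimnames = list(NULL, utilities$state))

  states <- det$state
  # center the multiplicative perturbation on the Beta-implied mean CU so
  # the PSA mean converges to the deterministic result as variance vanishes
  bmeans <- stats::setNames(beta_mean(utilities$alpha, utilities$beta),
                            utilities$state)
  cu_mean <- bmeans[ref] - bmeans[states]
  cu_draw <- u_draws[, ref] - u_draws[, states, drop = FALSE]
  # 0/0 scaling guard: a state with zero mean CU contributes no QALY change
  scale <- sweep(cu_draw, 2, cu_mean, `/`)
  zero_cu <- cu_mean == 0
  if (any(zero_cu)) {
    warning("state(s) with zero mean change in utility contribute 0 (0/0 treated as 0)",
            call. = FALSE)
    scale[, zero_cu] <- 0
  }
  delta <- sweep(scale, 2, det$delta_qaly, `*`)
  money <- delta * scn$threshold

  nb <- cbind(intervene = rowSums(money) - cost, do_nothing = 0)
  ev <- evpi(nb)

  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  summary <- purrr::map_dfr(seq_along(states), function(j) {
    tibble::tibble(
      state = states[j],
      mean_delta_qaly = mean(delta[, j]),
      delta_qaly_lo = q(delta[, j], 0.025),
      delta_qaly_hi = q(delta[, j], 0.975),
      mean_monetary_value = mean(money[, j]),
      monetary_value_lo = q(money[, j], 0.025),
      monetary_value_hi = q(money[, j], 0.975)
    )
  })

  utility_draws <- tibble::tibble(
    draw = rep(seq_len(n), times = ncol(u_draws)),
    state = rep(colnames(u_draws), each = n),
    utility = as.vector(u_draws)
  )
  outcomes <- tibble::tibble(
    draw = rep(seq_len(n), times = length(states)),
    state = rep(states, each = n),
    cu = as.vector(cu_draw),
    delta_qaly = as.vector(delta),
    monetary_value = as.vector(money)
  )

  structure(
    list(n = n, seed = seed, threshold = scn$threshold, cost = cost,
         evpi = ev, utility_draws = utility_draws, outcomes = outcomes,
         summary = summary),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<PSA: %d draws (seed %d), threshold £%s/QALY; EVPI £%.2f/person>\n",
    x$n, x$seed, format(x$threshold, big.mark = ","), x$evpi))
  print(x$summary)
  invisible(x)
}

#' Expected value of perfect information
#'
#' The per-person value of resolving all parameter uncertainty before
#' choosing between decision options: the expectation over draws of the
#' best achievable net benefit, minus the net benefit of the single best
#' option chosen under current information,
#' `E[max_d NB_d] - max_d E[NB_d]`. With a common set of draws across
#' options the estimate is nonnegative by construction.
#'
#' @param nb A numeric matrix or data frame of net benefits with one row per
#'   draw and one column per decision option (at least two options, at least
#'   one draw, no missing values).
#' @return EVPI in the net-benefit units (pounds per person).
#' @examples
#' evpi(cbind(a = c(1, 0), b = c(0, 1))) # 0.5
#' @export
evpi <- function(nb) {
  nb <- as.matrix(nb)
  if (!is.numeric(nb) || anyNA(nb)) {
    rlang::abort("nb must be a complete numeric table",
                 class = "floodbn_input_error")
  }
  if (ncol(nb) < 2L || nrow(nb) < 1L) {
    rlang::abort("nb needs at least 2 decision options and 1 draw",
                 class = "floodbn_input_error")
  }
  mean(apply(nb, 1, max)) - max(colMeans(nb))
}
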