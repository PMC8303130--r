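# Internal factor algebra for variable elimination.
#
# A factor is a nonnegative table over a subset of variables ("scope"),
# stored as a numeric array with one dimension per scope variable (declared
# state order). Scalar factors (empty scope) carry a single number.

new_factor <- function(scope, states, values) {
  if (length(scope) == 0L) {
    values <- as.numeric(values)
  }
  list(scope = scope, states = states, values = values)
}

factor_from_cpt <- function(net, v) {
  tab <- net$cpts[[v]]
  scope <- c(v, tab$parents)
  new_factor(scope, net$variables[scope], tab$values)
}

# Broadcast f's value array onto the union scope (scope_u, states_u), with
# dimensions permuted into scope_u order.
factor_expand <- function(f, scope_u, states_u) {
  if (length(f$scope) == 0L) {
    return(array(f$values, dim = lengths(states_u)))
  }
  miss <- setdiff(scope_u, f$scope)
  arr <- f$values
  scope_now <- f$scope
  if (length(miss) > 0L) {
    extra <- prod(lengths(states_u[miss]))
    arr <- array(rep(as.vector(arr), extra),
                 dim = c(lengths(f$states), lengths(states_u[miss])))
    scope_now <- c(f$scope, miss)
  }
  arr <- array(arr, dim = lengths(states_u[scope_now]))
  aperm(arr, match(scope_u, scope_now))
}

factor_product <- function(f, g) {
  if (length(f$scope) == 0L && length(g$scope) == 0L) {
    return(new_factor(character(), list(), f$values * g$values))
  }
  scope_u <- union(f$scope, g$scope)
  states_u <- c(f$states, g$states)[scope_u]
  vals <- factor_expand(f, scope_u, states_u) *
    factor_expand(g, scope_u, states_u)
  new_factor(scope_u, states_u, array(vals, dim = lengths(states_u)))
}

factor_marginalize <- function(f, v) {
  keep <- setdiff(f$scope, v)
  if (length(keep) == 0L) {
    return(new_factor(character(), list(), sum(f$values)))
  }
  vals <- apply(f$values, match(keep, f$scope), sum)
  new_factor(keep, f$states[keep], array(vals, dim = lengths(f$states[keep])))
}

# Condition on var = state: slice, drop that dimension.
factor_reduce <- function(f, v, state) {
  if (!v %in% f$scope) return(f)
  i <- match(state, f$states[[v]])
  idx <- rep(list(TRUE), length(f$scope)) # TRUE selects a whole dimension
  idx[[match(v, f$scope)]] <- i
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- setdiff(f$scope, v)
  if (length(keep) == 0L) {
    return(new_factor(character(), list(), as.numeric(vals)))
  }
  new_factor(keep, f$states[keep],
             array(as.vector(vals), dim = lengths(f$states[keep])))
}

# Min-degree elimination ordering over the moralized interaction graph of
# the current factor scopes; deterministic tie-break by declared order.
min_degree_order <- function(scopes, elim) {
  order <- character(0)
  scopes <- lapply(scopes, function(s) s)
  remaining <- elim
  while (length(remaining) > 0L) {
    deg <- vapply(remaining, function(v) {
      nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s,
                                        logical(1))]))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- remaining[which.min(deg)] # which.min keeps first => declared order
    order <- c(order, v)
    touched <- vapply(scopes, function(s) v %in% s, logical(1))
    merged <- setdiff(unique(unlist(scopes[touched])), v)
    scopes <- c(scopes[!touched], list(merged))
    remaining <- setdiff(remaining, v)
  }
  order
}

#' Exact posterior query by variable elimination
#'
#' Computes `P(targets | evidence)` exactly, summing out all other variables
#' factor by factor. Evidence is absorbed by slicing every factor, the
#' remaining variables are eliminated (min-degree ordering by default), and
#' the result is normalized; the normalizing constant is the probability of
#' the evidence itself.
#'
#' A target that is also an evidence variable yields a point mass on the
#' observed state. Evidence with probability zero is an error (class
#' `floodbn_inconsistent_evidence`) rather than a NaN-filled table.
#'
#' @param net A valid `bn` object.
#' @param targets Character vector of query variables (nonempty).
#' @param evidence Named character vector of observed states; may be empty.
#' @param elim_order Optional explicit elimination order (a permutation of
#'   the non-target, non-evidence variables); the posterior does not depend
#'   on it, only performance does.
#' @return A `bn_posterior` object: a tibble with one column per target
#'   variable and a `prob` column summing to 1, plus attributes
#'   `evidence_probability`, `targets` and `evidence`. Rows cover all joint
#'   target states, first target varying slowest.
#' @examples
#' net <- single_node_network("PPD", p_present = 0.186)
#' query_posterior(net, "PPD")
#' @export
query_posterior <- function(net, targets, evidence = character(),
                            elim_order = NULL) {
  vars <- names(net$variables)
  if (length(targets) == 0L) {
    rlang::abort("at least one target variable is required",
                 class = "floodbn_input_error")
  }
  bad <- setdiff(c(targets, names(evidence)), vars)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("unknown variable(s): %s", paste(bad, collapse = ", ")),
                 class = "floodbn_input_error")
  }
  for (nm in names(evidence)) {
    if (!evidence[[nm]] %in% net$variables[[nm]]) {
      rlang::abort(
        sprintf("'%s' is not a state of variable '%s'", evidence[[nm]], nm),
        class = "floodbn_input_error")
    }
  }

  factors <- lapply(vars, function(v) factor_from_cpt(net, v))
  for (nm in names(evidence)) {
    factors <- lapply(factors, factor_reduce, v = nm, state = evidence[[nm]])
  }

  elim <- setdiff(vars, c(targets, names(evidence)))
  if (is.null(elim_order)) {
    elim_order <- min_degree_order(lapply(factors, `[[`, "scope"), elim)
  } else {
    if (!setequal(elim_order, elim)) {
      rlang::abort("elim_order must be a permutation of the non-target, non-evidence variables",
                   class = "floodbn_input_error")
    }
  }

  for (v in elim_order) {
    has_v <- vapply(factors, function(f) v %in% f$scope, logical(1))
    if (!any(has_v)) next
    prod_f <- Reduce(factor_product, factors[has_v])
    factors <- c(factors[!has_v], list(factor_marginalize(prod_f, v)))
  }
  final <- Reduce(factor_product, factors)
  # deterministic scope order: declared variable order
  if (length(final$scope) > 1L) {
    ord <- match(intersect(vars, final$scope), final$scope)
    final <- new_factor(final$scope[ord], final$states[ord],
                        aperm(final$values, ord))
  }

  z <- sum(final$values)
  if (z <= 0) {
    rlang::abort("the evidence has probability zero under this network",
                 class = "floodbn_inconsistent_evidence")
  }

  # grid over all targets in request order; evidence targets are point masses
  tstates <- stats::setNames(net$variables[targets], targets)
  grid <- do.call(expand.grid,
                  c(rev(unname(tstates)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(targets)), drop = FALSE]
  names(grid) <- targets

  prob <- rep(1, nrow(grid))
  if (length(final$scope) > 0L) {
    idx <- do.call(cbind, lapply(final$scope, function(v) {
      match(grid[[v]], final$states[[v]])
    }))
    prob <- as.numeric(final$values[idx]) / z
  }
  for (nm in intersect(targets, names(evidence))) {
    prob <- prob * as.numeric(grid[[nm]] == evidence[[nm]])
  }
  prob <- prob / sum(prob)

  out <- tibble::as_tibble(grid)
  out$prob <- prob
  structure(out,
            class = c("bn_posterior", class(out)),
            evidence_probability = z,
            targets = targets,
            evidence = evidence)
}

#' @export
print.bn_posterior <- function(x, ...) {
  ev <- attr(x, "evidence")
  cat(sprintf("<posterior over %s%s; P(evidence) = %.6g>\n",
              paste(attr(x, "targets"), collapse = ", "),
              if (length(ev)) paste0(" | ", paste(names(ev), ev, sep = "=",
                                                  collapse = ", "))
              else "",
              attr(x, "evidence_probability")))
  NextMethod()
}

#' Evidence back-propagation onto root causes
#'
#' Propagates outcome evidence backwards through the network and reports, for
#' every root (parentless) node, its prior, its posterior given the evidence
#' and the induced probability shift. The shift of a root is the maximum over
#' its states of the absolute prior-to-posterior change; roots are ranked by
#' shift (largest first, ties broken by variable name), identifying which
#' causal factors the observed outcome most implicates.
#'
#' @param net A valid `bn` object.
#' @param evidence Nonempty named character vector of observed states.
#' @return A tibble with columns `root`, `state`, `prior`, `posterior` and
#'   `shift` (one shift value per root, repeated across its states), sorted
#'   by decreasing shift.
#' @examples
#' net <- build_flood_network()
#' backpropagate_to_roots(net, c(Msever = "present"))
#' @export
backpropagate_to_roots <- function(net, evidence) {
  if (length(evidence) == 0L) {
    rlang::abort("evidence must be nonempty", class = "floodbn_input_error")
  }
  roots <- bn_roots(net)
  rows <- purrr::map_dfr(roots, function(r) {
    pri <- query_posterior(net, r)
    post <- query_posterior(net, r, evidence)
    tibble::tibble(
      root = r,
      state = pri[[r]],
      prior = as.numeric(pri$prob),
      posterior = as.numeric(post$prob[match(pri[[r]], post[[r]])])
    )
  })
  rows <- dplyr::mutate(dplyr::group_by(rows, .data$root),
                        shift = max(abs(.data$posterior - .data$prior)))
  rows <- dplyr::ungroup(rows)
  dplyr::arrange(rows, dplyr::desc(.data$shift), .data$root)
}
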