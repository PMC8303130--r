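#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for floodbn result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per state, per node family, per target configuration) and `glance()` a
#' one-row summary.
#'
#' @param x A floodbn result object.
#' @param ... Unused.
#' @return A tibble.
#' @name floodbn_tidiers
NULL

#' @rdname floodbn_tidiers
#' @export
tidy.ce_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname floodbn_tidiers
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"),
    threshold = attr(x, "threshold"),
    total_delta_qaly = sum(x$delta_qaly),
    total_monetary_value = sum(x$monetary_value)
  )
}

#' @rdname floodbn_tidiers
#' @export
tidy.psa_result <- function(x, ...) x$summary

#' @rdname floodbn_tidiers
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(n = x$n, seed = x$seed, threshold = x$threshold,
                 cost = x$cost, evpi = x$evpi)
}

#' @rdname floodbn_tidiers
#' @export
tidy.bn_score <- function(x, ...) x$families

#' @rdname floodbn_tidiers
#' @export
glance.bn_score <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, penalty = x$penalty, total = x$total)
}

#' @rdname floodbn_tidiers
#' @export
tidy.bn_posterior <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "bn_posterior")
  out
}

#' @rdname floodbn_tidiers
#' @export
glance.bn_posterior <- function(x, ...) {
  tibble::tibble(
    targets = paste(attr(x, "targets"), collapse = ","),
    evidence = paste(names(attr(x, "evidence")), attr(x, "evidence"),
                     sep = "=", collapse = ","),
    evidence_probability = attr(x, "evidence_probability")
  )
}

#' @rdname floodbn_tidiers
#' @export
tidy.bn <- function(x, ...) x$arcs

#' @rdname floodbn_tidiers
#' @export
glance.bn <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variables),
    n_arcs = nrow(x$arcs),
    n_roots = length(bn_roots(x)),
    n_parameters = sum(vapply(names(x$variables), function(nm) {
      card <- length(x$variables[[nm]])
      (card - 1) * prod(lengths(x$variables[bn_parents(x, nm)]))
    }, numeric(1)))
  )
}

#' Plot methods for floodbn results
#'
#' `autoplot()` methods return ggplot objects: a per-state bar chart of
#' monetary value for cost-effectiveness results, the distribution of the
#' monetized QALY gain per state for PSA results, and a bar chart of the
#' posterior for query results.
#'
#' @param object A floodbn result object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name floodbn_autoplot
NULL

#' @rdname floodbn_autoplot
#' @export
autoplot.ce_result <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$state,
                                    y = .data$monetary_value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "Monetary value of QALY gain (£)",
      title = attr(object, "label"),
      subtitle = sprintf("threshold £%s per QALY",
                         format(attr(object, "threshold"), big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @rdname floodbn_autoplot
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$outcomes,
                  ggplot2::aes(x = .data$monetary_value,
                               fill = .data$state)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.7,
                            position = "identity") +
    ggplot2::labs(x = "Monetary value of QALY gain (£)", y = "Draws",
                  title = sprintf("PSA over utility uncertainty (%d draws)",
                                  object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname floodbn_autoplot
#' @export
autoplot.bn_posterior <- function(object, ...) {
  dat <- tidy.bn_posterior(object)
  targets <- attr(object, "targets")
  dat$configuration <- do.call(paste, c(dat[targets], list(sep = ", ")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$configuration,
                                    y = .data$prob)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = paste(targets, collapse = ", "),
                  y = "Posterior probability") +
    ggplot2::theme_minimal()
}
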