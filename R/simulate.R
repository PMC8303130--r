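#' Forward (ancestral) sampling of survey-style records
#'
#' Draws complete individual-level records from a network by sampling each
#' variable after its parents in topological order, each from the CPT row
#' selected by the already-sampled parent states. This is the generator
#' behind the package's synthetic survey data: flood-and-mental-health
#' cohorts statistically matching the elicited prevalences, standing in for
#' undeposited national survey records.
#'
#' @param net A valid `bn` network.
#' @param n Number of records (`n = 0` yields an empty table with the right
#'   columns).
#' @param seed Optional integer seed; given the same seed the output is
#'   identical between calls and the session RNG state is left untouched.
#' @param columns Optional subset of variables to keep, in network order
#'   (e.g. to drop latent nodes); sampling always uses the full network.
#' @return A tibble of character state labels, one row per individual,
#'   columns in the network's declared variable order (restricted to
#'   `columns` if given).
#' @examples
#' forward_sample(build_flood_network(), n = 5, seed = 1)
#' @export
forward_sample <- function(net, n, seed = NULL, columns = NULL) {
  report <- validate_network(net)
  if (nrow(report) > 0L) {
    rlang::abort(c("cannot sample from an invalid network",
                   stats::setNames(report$message, rep("x", nrow(report)))),
                 class = "floodbn_invalid_network")
  }
  if (n < 0) {
    rlang::abort("n must be nonnegative", class = "floodbn_input_error")
  }
  vars <- names(net$variables)
  keep <- if (is.null(columns)) vars else {
    bad <- setdiff(columns, vars)
    if (length(bad) > 0L) {
      rlang::abort(sprintf("unknown column(s): %s", paste(bad, collapse = ", ")),
                   class = "floodbn_input_error")
    }
    vars[vars %in% columns]
  }
  if (n == 0L) {
    out <- stats::setNames(rep(list(character(0)), length(keep)), keep)
    return(tibble::as_tibble(out))
  }

  draw <- function() {
    sampled <- list()
    for (nm in topological_sort(net)) {
      tab <- net$cpts[[nm]]
      states <- net$variables[[nm]]
      card <- length(states)
      mat <- matrix(tab$values, nrow = card)
      cum_t <- t(apply(mat, 2, cumsum)) # config x state
      if (length(tab$parents) == 0L) {
        cfg <- rep(1L, n)
      } else {
        # column-major config index: first parent varies fastest in `mat`
        cfg <- rep(1L, n)
        stride <- 1L
        for (pa in tab$parents) {
          pidx <- match(sampled[[pa]], net$variables[[pa]])
          cfg <- cfg + (pidx - 1L) * stride
          stride <- stride * length(net$variables[[pa]])
        }
      }
      u <- stats::runif(n)
      sidx <- pmin(rowSums(u > cum_t[cfg, , drop = FALSE]) + 1L, card)
      sampled[[nm]] <- states[sidx]
    }
    sampled
  }
  sampled <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::as_tibble(sampled[keep])
}

#' Synthetic flood-and-mental-health survey fixture
#'
#' Builds the packaged flood network and forward-samples `n` individual
#' records over its observable nodes (Flood, LOSI, PPD, Lsever, Msever),
#' returning both the records and the generating network so that learning
#' routines can be tested for parameter recovery against known ground truth.
#'
#' @param n Number of records (at least 1).
#' @param seed Integer seed.
#' @return A list with elements `records` (tibble) and `network` (`bn`).
#' @examples
#' fx <- make_survey_fixture(n = 1000, seed = 1)
#' head(fx$records)
#' @export
make_survey_fixture <- function(n, seed = 1L) {
  if (n < 1) {
    rlang::abort("n must be at least 1", class = "floodbn_input_error")
  }
  net <- suppressMessages(build_flood_network())
  records <- forward_sample(net, n = n, seed = seed,
                            columns = c("Flood", "LOSI", "PPD",
                                        "Lsever", "Msever"))
  list(records = records, network = net)
}
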