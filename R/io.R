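#' Write a network to its JSON interchange format
#'
#' The on-disk dialect is a single versioned JSON document with keys
#' `format_version`, `variables` (name + ordered states), `arcs`
#' (parent/child pairs) and `cpts` (per child: parents and rows keyed by the
#' joint parent configuration, states joined with `|`, the empty key for
#' roots; probability vectors in child-state order). Rows appear in
#' lexicographic parent-configuration order and numbers are written at full
#' precision, so load-save-load round-trips are value-identical.
#'
#' @param net A valid `bn` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bn <- function(net, path) {
  doc <- list(
    format_version = "1.0",
    variables = lapply(names(net$variables), function(nm) {
      list(name = nm, states = as.list(net$variables[[nm]]))
    }),
    arcs = purrr::pmap(net$arcs, function(parent, child) {
      list(parent = parent, child = child)
    }),
    cpts = lapply(names(net$variables), function(nm) {
      tab <- net$cpts[[nm]]
      cfg <- parent_grid(net$variables[tab$parents])
      card <- length(net$variables[[nm]])
      rows <- list()
      for (i in seq_len(max(nrow(cfg), 1L))) {
        key <- paste(unlist(cfg[i, , drop = FALSE]), collapse = "|")
        idx <- c(list(seq_len(card)),
                 as.list(unlist(cfg[i, , drop = FALSE])))
        rows[[key]] <- do.call(`[`, c(list(tab$values), unname(idx)))
      }
      list(child = nm, parents = as.list(tab$parents), rows = rows)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a network from its JSON interchange format
#'
#' The loader is a validation gate: CPT rows whose sums are off by at most
#' `1e-6` (elicited tables are often printed to few significant figures) are
#' renormalized with a warning; anything worse, or any structural violation,
#' is rejected with the itemized [validate_network()] report.
#'
#' @param path Path to a network JSON file (see [write_bn()]).
#' @return A valid `bn` network.
#' @export
read_bn <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  variables <- stats::setNames(
    lapply(doc$variables, function(v) unlist(v$states)),
    vapply(doc$variables, function(v) v$name, character(1)))
  arcs <- if (length(doc$arcs) == 0L) NULL else {
    tibble::tibble(
      parent = vapply(doc$arcs, function(a) a$parent, character(1)),
      child = vapply(doc$arcs, function(a) a$child, character(1)))
  }
  cpts <- stats::setNames(
    lapply(doc$cpts, function(entry) {
      child <- entry$child
      parents <- as.character(unlist(entry$parents))
      cfg <- parent_grid(variables[parents])
      keys <- if (nrow(cfg) == 0L) "" else {
        apply(cfg, 1, paste, collapse = "|")
      }
      probs <- matrix(0, nrow = max(nrow(cfg), 1L),
                      ncol = length(variables[[child]]))
      for (i in seq_along(keys)) {
        row <- if (keys[i] == "") unlist(entry$rows[[1L]]) else {
          unlist(entry$rows[[keys[i]]])
        }
        if (is.null(row)) {
          rlang::abort(sprintf(
            "CPT of '%s' is missing the row for parent configuration '%s'",
            child, keys[i]), class = "floodbn_input_error")
        }
        s <- sum(row)
        if (abs(s - 1) > 1e-9 && abs(s - 1) <= 1e-6) {
          warning(sprintf(
            "CPT row '%s' of '%s' sums to %.8f; renormalized",
            keys[i], child, s), call. = FALSE)
          row <- row / s
        }
        probs[i, ] <- row
      }
      cpt(child, parents, variables[[child]], probs,
          parent_states = variables)
    }),
    vapply(doc$cpts, function(entry) entry$child, character(1)))
  bn_network(variables, arcs, cpts[names(variables)])
}

#' The packaged flood network fixture
#'
#' Loads `flood_network.json` shipped with the package: the default flood /
#' mental-health network produced by [build_flood_network()] with the
#' elicited marginals and the default calibration.
#'
#' @return A valid `bn` network.
#' @export
flood_network_fixture <- function() {
  read_bn(system.file("extdata", "flood_network.json", package = "floodbn"))
}

#' Read and write utility tables as JSON
#'
#' @param path File path.
#' @return `read_utility_table()` returns a [utility_table()];
#'   `write_utility_table()` returns `path` invisibly.
#' @export
read_utility_table <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  st <- doc$states
  utility_table(
    states = vapply(st, function(s) s$state, character(1)),
    utility = vapply(st, function(s) s$utility, numeric(1)),
    alpha = vapply(st, function(s) s$alpha, numeric(1)),
    beta = vapply(st, function(s) s$beta, numeric(1)),
    reference = doc$reference,
    horizon = doc$horizon
  )
}

#' @rdname read_utility_table
#' @param utilities A [utility_table()].
#' @export
write_utility_table <- function(utilities, path) {
  doc <- list(
    reference = attr(utilities, "reference"),
    horizon = attr(utilities, "horizon"),
    states = purrr::pmap(
      utilities[, c("state", "utility", "alpha", "beta")],
      function(state, utility, alpha, beta) {
        list(state = state, utility = utility, alpha = alpha, beta = beta)
      })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an intervention scenario from JSON
#'
#' A scenario file holds `label`, optional `threshold`, and `before`/`after`
#' objects mapping health states to CQALY values.
#'
#' @param path File path.
#' @param threshold Optional threshold override (pounds per QALY).
#' @return An [intervention_scenario()].
#' @export
read_scenario <- function(path, threshold = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  thr <- threshold %||% doc$threshold %||% 20000
  intervention_scenario(
    before = unlist(doc$before),
    after = unlist(doc$after),
    label = doc$label %||% "intervention",
    threshold = thr
  )
}

#' Run the evaluation pipeline end to end
#'
#' Loads a scenario (and optionally a utility table), evaluates the
#' intervention, optionally runs the probabilistic sensitivity analysis, and
#' writes a TSV evaluation report, a JSON PSA summary and a provenance log
#' (input file MD5 hashes, seed, threshold, and an echo of every input
#' value) into the output directory. Any stage failure propagates as an
#' error after removing partial outputs.
#'
#' @param scenario Path to a scenario JSON file.
#' @param out_dir Output directory (created if needed).
#' @param utilities Optional path to a utility-table JSON file; default the
#'   packaged table.
#' @param threshold Optional threshold override (pounds per QALY).
#' @param psa_n Number of PSA draws; 0 (default) skips the PSA stage.
#' @param seed Integer seed for the PSA stage.
#' @return Invisibly, a list with the `ce_result`, the `psa_result` (or
#'   `NULL`) and the paths written.
#' @export
run_pipeline <- function(scenario, out_dir, utilities = NULL,
                         threshold = NULL, psa_n = 0, seed = 1L) {
  if (!file.exists(scenario)) {
    rlang::abort(sprintf("[scenario] file not found: %s", scenario),
                 class = "floodbn_input_error")
  }
  if (!is.null(utilities) && !file.exists(utilities)) {
    rlang::abort(sprintf("[utilities] file not found: %s", utilities),
                 class = "floodbn_input_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(evaluation = file.path(out_dir, "evaluation.tsv"),
             psa = file.path(out_dir, "psa_summary.json"),
             log = file.path(out_dir, "run_log.txt"))
  on_failure <- function(e, stage) {
    unlink(paths[file.exists(paths)])
    rlang::abort(sprintf("[%s] %s", stage, conditionMessage(e)),
                 class = "floodbn_pipeline_error", parent = e)
  }

  scn <- tryCatch(read_scenario(scenario, threshold = threshold),
                  error = function(e) on_failure(e, "scenario"))
  util <- tryCatch(
    if (is.null(utilities)) utility_table() else read_utility_table(utilities),
    error = function(e) on_failure(e, "utilities"))

  ce <- tryCatch(evaluate_intervention(scn, util),
                 error = function(e) on_failure(e, "evaluate"))
  report <- tibble::as_tibble(ce)
  report$monetary_value_gbp <- round_gbp(report$monetary_value)
  utils::write.table(report, paths[["evaluation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  psa <- NULL
  if (psa_n > 0) {
    psa <- tryCatch(run_psa(scn, util, n = psa_n, seed = seed),
                    error = function(e) on_failure(e, "psa"))
    jsonlite::write_json(
      list(n = psa$n, seed = psa$seed, threshold = psa$threshold,
           cost = psa$cost, evpi = psa$evpi, summary = psa$summary),
      paths[["psa"]], auto_unbox = TRUE, digits = I(17), dataframe = "rows")
  }

  hash <- tools::md5sum(c(scenario, utilities))
  log_lines <- c(
    sprintf("scenario: %s (md5 %s)", scenario, hash[[scenario]]),
    if (!is.null(utilities)) {
      sprintf("utilities: %s (md5 %s)", utilities, hash[[utilities]])
    } else "utilities: packaged default",
    sprintf("threshold: %s", scn$threshold),
    sprintf("seed: %d", seed),
    sprintf("psa_n: %d", psa_n),
    "",
    "utility table:",
    utils::capture.output(print(tibble::as_tibble(util))),
    "",
    sprintf("scenario '%s' before: %s", scn$label,
            paste(names(scn$before), scn$before, sep = "=", collapse = ", ")),
    sprintf("scenario '%s' after:  %s", scn$label,
            paste(names(scn$after), scn$after, sep = "=", collapse = ", ")),
    "",
    "evaluation:",
    utils::capture.output(print(report))
  )
  writeLines(log_lines, paths[["log"]])

  out_paths <- paths[c(TRUE, psa_n > 0, TRUE)]
  invisible(list(evaluation = ce, psa = psa, paths = out_paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
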