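#' Construct a discrete Bayesian network
#'
#' A Bayesian network is the pair of a directed acyclic graph over categorical
#' variables and one conditional probability table (CPT) per variable; together
#' they define the joint distribution as the product of per-node conditionals.
#'
#' @param variables Named list mapping each variable name to its ordered
#'   character vector of state labels (at least two, unique).
#' @param arcs A data frame with columns `parent` and `child` (one row per
#'   directed arc), or `NULL` for an empty graph.
#' @param cpts Named list with one CPT per variable, as built by [cpt()]. May
#'   be `NULL` to create a structure-only skeleton (see [bn_structure()]).
#' @param check If `TRUE` (default) the network is validated and construction
#'   fails with an itemized report when any invariant is violated.
#'
#' @return An object of class `bn`: a list with elements `variables`, `arcs`
#'   (tibble) and `cpts`.
#' @seealso [validate_network()], [cpt()], [joint_probability()]
#' @examples
#' net <- bn_network(
#'   variables = list(Flood = c("present", "absent")),
#'   arcs = NULL,
#'   cpts = list(Flood = cpt("Flood", character(), c("present", "absent"),
#'                           matrix(c(0.201, 0.799), nrow = 1)))
#' )
#' joint_probability(net, c(Flood = "present"))
#' @export
bn_network <- function(variables, arcs = NULL, cpts = NULL, check = TRUE) {
  arcs <- normalize_arcs(arcs)
  net <- structure(
    list(variables = variables, arcs = arcs, cpts = cpts),
    class = "bn"
  )
  if (check) {
    report <- validate_network(net)
    if (nrow(report) > 0L) {
      rlang::abort(
        c("Invalid Bayesian network.",
          stats::setNames(report$message, rep("x", nrow(report)))),
        class = "floodbn_invalid_network"
      )
    }
  }
  net
}

#' Construct a DAG structure without parameters
#'
#' A structure-only skeleton used by the learning functions: the graph and the
#' variable state spaces, with no CPTs attached. [fit_cpts()] turns a
#' structure plus data into a full [bn_network()].
#'
#' @inheritParams bn_network
#' @return An object of classes `bn_structure` and `bn`.
#' @export
bn_structure <- function(variables, arcs = NULL, check = TRUE) {
  arcs <- normalize_arcs(arcs)
  net <- structure(
    list(variables = variables, arcs = arcs, cpts = NULL),
    class = c("bn_structure", "bn")
  )
  if (check) {
    report <- validate_network(net)
    report <- report[report$type != "missing_cpt", , drop = FALSE]
    if (nrow(report) > 0L) {
      rlang::abort(
        c("Invalid DAG structure.",
          stats::setNames(report$message, rep("x", nrow(report)))),
        class = "floodbn_invalid_network"
      )
    }
  }
  net
}

normalize_arcs <- function(arcs) {
  if (is.null(arcs) || (is.data.frame(arcs) && nrow(arcs) == 0L)) {
    return(tibble::tibble(parent = character(), child = character()))
  }
  arcs <- tibble::as_tibble(arcs)
  stopifnot(all(c("parent", "child") %in% names(arcs)))
  tibble::tibble(parent = as.character(arcs$parent),
                 child = as.character(arcs$child))
}

#' Build a conditional probability table
#'
#' Stores P(child | parents) as a numeric array with the child dimension
#' first, then one dimension per parent in declared order. Rows (joint parent
#' configurations) are laid out lexicographically: the first parent varies
#' slowest, each parent's states in declared order.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (may be empty for roots).
#' @param states Ordered state labels of the child.
#' @param probs For a root: a probability vector over child states. Otherwise
#'   a matrix with one row per joint parent configuration (lexicographic
#'   order, see above) and one column per child state, or an array already in
#'   CPT layout.
#' @param parent_states Named list of state labels for each parent; required
#'   when `parents` is nonempty and `probs` is a matrix.
#' @return A `bn_cpt` object.
#' @export
cpt <- function(child, parents, states, probs, parent_states = NULL) {
  card <- length(states)
  if (length(parents) == 0L) {
    values <- array(as.numeric(probs), dim = card,
                    dimnames = stats::setNames(list(states), child))
  } else if (is.array(probs) && length(dim(probs)) == length(parents) + 1L &&
             identical(names(dimnames(probs)), c(child, parents))) {
    # already in CPT layout (child dimension first), e.g. from fit_cpts
    dn <- c(list(states), parent_states[parents])
    names(dn) <- c(child, parents)
    values <- array(as.numeric(probs), dim = lengths(dn), dimnames = dn)
  } else {
    stopifnot(!is.null(parent_states))
    pstates <- parent_states[parents]
    ncfg <- prod(lengths(pstates))
    probs <- matrix(as.numeric(probs), nrow = ncfg, ncol = card)
    # rows are lexicographic (first parent slowest) => after transposing to
    # child-first layout, the child index is fastest, then the LAST parent,
    # matching R's column-major array order with dims (child, p1, ..., pk)
    # only if we fill parents fastest-last; build by explicit permutation.
    dn <- c(list(states), pstates)
    names(dn) <- c(child, parents)
    values <- array(0, dim = lengths(dn), dimnames = dn)
    cfg <- parent_grid(pstates)
    for (i in seq_len(nrow(cfg))) {
      idx <- c(list(seq_len(card)), as.list(unlist(cfg[i, , drop = FALSE])))
      values <- do.call(`[<-`, c(list(values), idx, list(probs[i, ])))
    }
  }
  structure(list(child = child, parents = parents, values = values),
            class = "bn_cpt")
}

# Joint parent configurations in lexicographic order: first parent varies
# slowest, each parent's states in declared order.
parent_grid <- function(parent_states) {
  if (length(parent_states) == 0L) {
    return(data.frame(row.names = 1L))
  }
  g <- do.call(expand.grid,
               c(rev(unname(parent_states)),
                 list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  g <- g[, rev(seq_along(parent_states)), drop = FALSE]
  names(g) <- names(parent_states)
  g
}

#' Per-configuration view of a CPT
#'
#' @param x A `bn_cpt`.
#' @param variables Named list of state labels (used for parent state order).
#' @return A tibble with one row per joint parent configuration (lexicographic
#'   order) and one probability column per child state, prefixed `p_`.
#' @export
cpt_table <- function(x, variables) {
  pstates <- variables[x$parents]
  cfg <- parent_grid(pstates)
  card <- length(variables[[x$child]])
  out <- matrix(0, nrow = max(nrow(cfg), 1L), ncol = card)
  for (i in seq_len(nrow(out))) {
    idx <- c(list(seq_len(card)), as.list(unlist(cfg[i, , drop = FALSE])))
    out[i, ] <- do.call(`[`, c(list(x$values), idx))
  }
  colnames(out) <- paste0("p_", variables[[x$child]])
  dplyr::bind_cols(tibble::as_tibble(cfg), tibble::as_tibble(out))
}

bn_parents <- function(net, v) net$arcs$parent[net$arcs$child == v]
bn_children <- function(net, v) net$arcs$child[net$arcs$parent == v]

#' Root nodes (no parents) of a network
#' @param net A `bn` object.
#' @return Character vector of root variable names, in declared order.
#' @export
bn_roots <- function(net) {
  setdiff(names(net$variables), unique(net$arcs$child))
}

#' Topological order of a network's variables
#'
#' Kahn's algorithm with deterministic tie-breaking by declared variable
#' order. Returns `NULL` when the graph has a directed cycle.
#'
#' @param net A `bn` object (CPTs not required).
#' @return Character vector of variable names, parents before children, or
#'   `NULL` if the arcs contain a cycle.
#' @export
topological_sort <- function(net) {
  vars <- names(net$variables)
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (ch in net$arcs$child) {
    if (ch %in% vars) indeg[ch] <- indeg[ch] + 1L
  }
  order <- character(0)
  ready <- vars[indeg == 0L]
  while (length(ready) > 0L) {
    v <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, v)
    for (ch in bn_children(net, v)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        ready <- vars[vars %in% c(ready, ch)] # keep declared order
      }
    }
  }
  if (length(order) < length(vars)) NULL else order
}

#' Validate a Bayesian network
#'
#' Checks every structural and parametric invariant: unique, nonempty state
#' spaces; arcs referencing declared variables only; no self-loops, duplicate
#' arcs or directed cycles; one CPT per variable whose parent list equals the
#' graph's parent set; every CPT row a probability vector summing to 1 within
#' `1e-9` with entries in `[0, 1]`.
#'
#' Violations are data, not exceptions: the return value is a tibble with one
#' row per violation, empty if and only if the network is valid.
#'
#' @param net A `bn` object.
#' @return A tibble with columns `type`, `where` and `message`.
#' @examples
#' bad <- bn_network(
#'   variables = list(A = c("yes", "no")),
#'   cpts = list(A = cpt("A", character(), c("yes", "no"), c(0.5, 0.4))),
#'   check = FALSE
#' )
#' validate_network(bad)
#' @export
validate_network <- function(net) {
  v <- list()
  add <- function(type, where, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(type = type, where = where,
                                           message = message)
  }
  vars <- names(net$variables)
  if (is.null(vars) || anyDuplicated(vars)) {
    add("duplicate_variable", "variables", "variable names must be unique")
  }
  for (nm in vars) {
    st <- net$variables[[nm]]
    if (length(st) < 2L) {
      add("arity", nm, sprintf("variable '%s' needs at least 2 states", nm))
    }
    if (anyDuplicated(st)) {
      add("duplicate_state", nm,
          sprintf("variable '%s' has duplicate state labels", nm))
    }
  }
  undeclared <- setdiff(unique(c(net$arcs$parent, net$arcs$child)), vars)
  for (nm in undeclared) {
    add("undeclared_variable", nm,
        sprintf("arc references undeclared variable '%s'", nm))
  }
  self <- net$arcs$parent == net$arcs$child
  if (any(self)) {
    for (nm in unique(net$arcs$parent[self])) {
      add("self_loop", nm, sprintf("self-loop on '%s'", nm))
    }
  }
  if (anyDuplicated(paste(net$arcs$parent, net$arcs$child, sep = "\r"))) {
    add("duplicate_arc", "arcs", "duplicate arcs are not allowed")
  }
  if (length(undeclared) == 0L && is.null(topological_sort(net))) {
    add("cycle", "arcs", "the arc set contains a directed cycle")
  }
  if (!is.null(net$cpts)) {
    for (nm in vars) {
      tab <- net$cpts[[nm]]
      if (is.null(tab)) {
        add("missing_cpt", nm, sprintf("no CPT for variable '%s'", nm))
        next
      }
      expected <- sort(bn_parents(net, nm))
      if (!identical(sort(tab$parents), expected)) {
        add("parent_mismatch", nm,
            sprintf("CPT parents of '%s' (%s) do not match the graph (%s)",
                    nm, paste(tab$parents, collapse = ","),
                    paste(expected, collapse = ",")))
        next
      }
      vals <- tab$values
      if (any(vals < 0 | vals > 1, na.rm = TRUE) || anyNA(vals)) {
        add("range", nm,
            sprintf("CPT of '%s' has entries outside [0, 1]", nm))
      }
      card <- length(net$variables[[nm]])
      if (length(vals) %% card == 0L) {
        sums <- colSums(matrix(vals, nrow = card))
        bad <- which(abs(sums - 1) > 1e-9)
        for (i in bad) {
          add("normalization", nm,
              sprintf("CPT row %d of '%s' sums to %.9g, not 1", i, nm, sums[i]))
        }
      } else {
        add("shape", nm, sprintf("CPT of '%s' has the wrong shape", nm))
      }
    }
  } else {
    for (nm in vars) add("missing_cpt", nm, sprintf("no CPT for '%s'", nm))
  }
  if (length(v) == 0L) {
    tibble::tibble(type = character(), where = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' @export
print.bn <- function(x, ...) {
  kind <- if (is.null(x$cpts)) "DAG structure" else "Bayesian network"
  cat(sprintf("<%s: %d variables, %d arcs>\n", kind,
              length(x$variables), nrow(x$arcs)))
  for (nm in names(x$variables)) {
    pa <- bn_parents(x, nm)
    cat(sprintf("  %s [%s]%s\n", nm, paste(x$variables[[nm]], collapse = ", "),
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorized joint: the product over variables of the CPT
#' entry selected by the assignment.
#'
#' @param net A valid `bn` object.
#' @param assignment Named character vector mapping every variable to one of
#'   its states.
#' @return A single probability in `[0, 1]`.
#' @examples
#' net <- single_node_network("Flood", p_present = 0.201)
#' joint_probability(net, c(Flood = "present"))
#' @export
joint_probability <- function(net, assignment) {
  vars <- names(net$variables)
  missing <- setdiff(vars, names(assignment))
  if (length(missing) > 0L) {
    rlang::abort(
      sprintf("assignment is missing variable(s): %s",
              paste(missing, collapse = ", ")),
      class = "floodbn_input_error")
  }
  unknown <- setdiff(names(assignment), vars)
  if (length(unknown) > 0L) {
    rlang::abort(
      sprintf("assignment names undeclared variable(s): %s",
              paste(unknown, collapse = ", ")),
      class = "floodbn_input_error")
  }
  p <- 1
  for (nm in vars) {
    st <- assignment[[nm]]
    if (!st %in% net$variables[[nm]]) {
      rlang::abort(sprintf("'%s' is not a state of variable '%s'", st, nm),
                   class = "floodbn_input_error")
    }
    tab <- net$cpts[[nm]]
    idx <- as.list(assignment[c(nm, tab$parents)])
    p <- p * do.call(`[`, c(list(tab$values), unname(idx)))
  }
  unname(p)
}

#' Enumerate the full joint distribution
#'
#' Brute-force expansion of the joint over all full assignments; the oracle
#' against which variable-elimination inference is tested. Refuses state
#' spaces larger than `cap` cells.
#'
#' @param net A valid `bn` object.
#' @param cap Maximum number of joint cells (default `2^20`).
#' @return A tibble with one character column per variable (first declared
#'   variable varying slowest) and a `prob` column; `sum(prob)` is 1 within
#'   `1e-9` for a valid network.
#' @export
enumerate_joint <- function(net, cap = 2^20) {
  vars <- names(net$variables)
  size <- prod(lengths(net$variables))
  if (size > cap) {
    rlang::abort(
      sprintf("joint state space has %.3g cells, above the cap of %.3g",
              size, cap),
      class = "floodbn_size_error")
  }
  grid <- do.call(expand.grid,
                  c(rev(unname(net$variables)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(vars)), drop = FALSE]
  names(grid) <- vars
  # vectorized product of CPT lookups across all rows
  p <- rep(1, nrow(grid))
  for (nm in vars) {
    tab <- net$cpts[[nm]]
    fam <- c(nm, tab$parents)
    idx <- mapply(function(col, states) match(grid[[col]], states),
                  fam, net$variables[fam], SIMPLIFY = FALSE)
    p <- p * tab$values[do.call(cbind, idx)]
  }
  out <- tibble::as_tibble(grid)
  out$prob <- as.numeric(p)
  out
}

#' One-node binary helper network
#'
#' Convenience constructor used throughout examples and tests: a single
#' binary variable with states `present`/`absent` and prior
#' `P(present) = p_present`.
#'
#' @param name Variable name.
#' @param p_present Prior probability of the `present` state.
#' @return A `bn` object.
#' @export
single_node_network <- function(name, p_present) {
  states <- c("present", "absent")
  bn_network(
    variables = stats::setNames(list(states), name),
    cpts = stats::setNames(
      list(cpt(name, character(), states, c(p_present, 1 - p_present))),
      name
    )
  )
}
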