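#' Fit conditional probability tables from complete records
#'
#' Maximum a posteriori CPT estimation with a symmetric Dirichlet prior:
#' every entry is `(count + pseudocount) / (config total + pseudocount *
#' child cardinality)`. With `pseudocount = 0` this is the maximum-likelihood
#' estimate; parent configurations never observed then fall back to a uniform
#' distribution with a warning.
#'
#' @param structure A `bn_structure` (or any `bn`; its CPTs are ignored).
#' @param data A data frame of complete categorical records, one row per
#'   individual, with a column for every structure variable. Every value must
#'   be a declared state.
#' @param pseudocount Nonnegative Dirichlet smoothing constant (Laplace
#'   smoothing at 1; exact relative frequencies at 0).
#' @return A fully parameterized `bn` network.
#' @examples
#' net <- build_flood_network()
#' records <- forward_sample(net, n = 2000, seed = 1)
#' refit <- fit_cpts(bn_structure(net$variables, net$arcs), records)
#' @export
fit_cpts <- function(structure, data, pseudocount = 0) {
  if (pseudocount < 0) {
    rlang::abort("pseudocount must be nonnegative",
                 class = "floodbn_input_error")
  }
  vars <- names(structure$variables)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("data is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "floodbn_input_error")
  }
  for (nm in vars) {
    bad <- which(!data[[nm]] %in% structure$variables[[nm]])
    if (length(bad) > 0L) {
      rlang::abort(
        sprintf("row %d, column '%s': '%s' is not a declared state",
                bad[1L], nm, data[[nm]][bad[1L]]),
        class = "floodbn_input_error")
    }
  }
  cpts <- lapply(vars, function(nm) {
    parents <- bn_parents(structure, nm)
    fam <- c(nm, parents)
    counts <- table(lapply(stats::setNames(fam, fam), function(col) {
      factor(data[[col]], levels = structure$variables[[col]])
    }))
    counts <- array(as.numeric(counts), dim = dim(counts),
                    dimnames = stats::setNames(structure$variables[fam], fam))
    card <- length(structure$variables[[nm]])
    mat <- matrix(counts, nrow = card)
    tot <- colSums(mat)
    theta <- sweep(mat + pseudocount, 2, tot + pseudocount * card, `/`)
    empty <- tot + pseudocount * card == 0
    if (any(empty)) {
      warning(sprintf(
        "variable '%s': %d unobserved parent configuration(s) set to uniform",
        nm, sum(empty)), call. = FALSE)
      theta[, empty] <- 1 / card
    }
    cpt(nm, parents, structure$variables[[nm]],
        array(theta, dim = dim(counts), dimnames = dimnames(counts)),
        parent_states = structure$variables)
  })
  bn_network(structure$variables, structure$arcs,
             stats::setNames(cpts, vars))
}

# Per-family BIC contribution: maximized log-likelihood of the child given
# its parents, minus half the family's free-parameter count times ln N.
family_bic <- function(child, parents, data, variables) {
  fam <- c(child, parents)
  counts <- table(lapply(stats::setNames(fam, fam), function(col) {
    factor(data[[col]], levels = variables[[col]])
  }))
  card <- length(variables[[child]])
  mat <- matrix(as.numeric(counts), nrow = card)
  tot <- colSums(mat)
  theta <- sweep(mat, 2, pmax(tot, 1), `/`)
  ll <- sum(mat[mat > 0] * log(theta[mat > 0]))
  k <- (card - 1) * prod(lengths(variables[parents]))
  penalty <- -(k / 2) * log(nrow(data))
  c(loglik = ll, penalty = penalty)
}

#' BIC score of a network structure
#'
#' The Bayesian information criterion used by the search-and-score structure
#' learner: the maximized log-likelihood of the data under the structure
#' (CPTs at their maximum-likelihood values) minus `(k/2) ln(N)`, where `k`
#' is the number of free CPT parameters and `N` the number of records.
#' Larger is better. The score decomposes over node families, which is what
#' makes local hill-climbing moves cheap.
#'
#' @param net A `bn` or `bn_structure`.
#' @param data A nonempty data frame of complete records.
#' @return A `bn_score` object: list with `loglik`, `penalty`, `total`
#'   (= loglik + penalty) and a per-node `families` tibble.
#' @export
bic_score <- function(net, data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    rlang::abort("data must be a nonempty data frame",
                 class = "floodbn_input_error")
  }
  vars <- names(net$variables)
  fams <- purrr::map_dfr(vars, function(nm) {
    fb <- family_bic(nm, bn_parents(net, nm), data, net$variables)
    tibble::tibble(variable = nm, loglik = fb[["loglik"]],
                   penalty = fb[["penalty"]],
                   total = fb[["loglik"]] + fb[["penalty"]])
  })
  structure(
    list(loglik = sum(fams$loglik), penalty = sum(fams$penalty),
         total = sum(fams$total), families = fams),
    class = "bn_score")
}

#' @export
print.bn_score <- function(x, ...) {
  cat(sprintf("<BIC score: total %.4f (loglik %.4f, penalty %.4f)>\n",
              x$total, x$loglik, x$penalty))
  invisible(x)
}

#' Greedy hill-climbing structure search
#'
#' Search-and-score structure learning over the space of DAGs: starting from
#' the empty graph, repeatedly apply the single arc addition, deletion or
#' reversal that most improves the BIC score, stopping when no move improves
#' it. Acyclicity is preserved at every step and ties between equally scoring
#' moves are broken lexicographically on the move description, so the result
#' is deterministic.
#'
#' @param data A data frame of complete categorical records with at least two
#'   columns.
#' @param max_parents Maximum in-degree allowed per node (default `Inf`).
#' @param seed Integer seed, fixed for reproducibility of the run (the search
#'   itself is deterministic; the seed is part of the run's provenance).
#' @param variables Optional named list of state labels per column; defaults
#'   to the sorted unique values observed in `data`.
#' @return A list with elements `structure` (a `bn_structure`) and `score`
#'   (its `bn_score`).
#' @export
hill_climb_structure <- function(data, max_parents = Inf, seed = 1L,
                                 variables = NULL) {
  if (max_parents < 0) {
    rlang::abort("max_parents must be nonnegative",
                 class = "floodbn_input_error")
  }
  if (!is.data.frame(data) || ncol(data) < 2L || nrow(data) == 0L) {
    rlang::abort("data must have at least 2 columns and 1 row",
                 class = "floodbn_input_error")
  }
  set.seed(seed)
  if (is.null(variables)) {
    variables <- lapply(data, function(col) sort(unique(as.character(col))))
  }
  vars <- names(variables)

  fam_cache <- new.env(parent = emptyenv())
  fam_score <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(fam_cache[[key]])) {
      fb <- family_bic(child, parents, data, variables)
      fam_cache[[key]] <- fb[["loglik"]] + fb[["penalty"]]
    }
    fam_cache[[key]]
  }

  arcs <- tibble::tibble(parent = character(), child = character())
  parents_of <- function(arcs, v) arcs$parent[arcs$child == v]
  creates_cycle <- function(arcs, from, to) {
    # would adding from -> to close a cycle? i.e. is `from` reachable from `to`
    frontier <- to
    seen <- character(0)
    while (length(frontier) > 0L) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      if (v == from) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      frontier <- c(frontier, arcs$child[arcs$parent == v])
    }
    FALSE
  }

  add_arc <- function(a, p, ch) {
    dplyr::bind_rows(a, tibble::tibble(parent = p, child = ch))
  }
  drop_arc <- function(a, p, ch) {
    a[!(a$parent == p & a$child == ch), , drop = FALSE]
  }

  repeat {
    moves <- list()
    for (p in vars) for (ch in setdiff(vars, p)) {
      present <- any(arcs$parent == p & arcs$child == ch)
      if (!present) {
        if (length(parents_of(arcs, ch)) >= max_parents) next
        if (creates_cycle(arcs, p, ch)) next
        delta <- fam_score(ch, c(parents_of(arcs, ch), p)) -
          fam_score(ch, parents_of(arcs, ch))
        moves[[length(moves) + 1L]] <-
          list(desc = sprintf("add %s->%s", p, ch), delta = delta,
               op = "add", p = p, ch = ch)
      } else {
        delta <- fam_score(ch, setdiff(parents_of(arcs, ch), p)) -
          fam_score(ch, parents_of(arcs, ch))
        moves[[length(moves) + 1L]] <-
          list(desc = sprintf("delete %s->%s", p, ch), delta = delta,
               op = "delete", p = p, ch = ch)
        # reversal: delete p->ch, add ch->p
        without <- drop_arc(arcs, p, ch)
        if (!creates_cycle(without, ch, p) &&
            length(parents_of(without, p)) < max_parents) {
          delta_rev <-
            (fam_score(ch, setdiff(parents_of(arcs, ch), p)) -
               fam_score(ch, parents_of(arcs, ch))) +
            (fam_score(p, c(parents_of(arcs, p), ch)) -
               fam_score(p, parents_of(arcs, p)))
          moves[[length(moves) + 1L]] <-
            list(desc = sprintf("reverse %s->%s", p, ch), delta = delta_rev,
                 op = "reverse", p = p, ch = ch)
        }
      }
    }
    if (length(moves) == 0L) break
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    best <- max(deltas)
    if (best <= 1e-12) break
    cand <- which(deltas >= best - 1e-12)
    descs <- vapply(moves[cand], `[[`, character(1), "desc")
    pick <- moves[[cand[order(descs)[1L]]]]
    arcs <- switch(pick$op,
      add = add_arc(arcs, pick$p, pick$ch),
      delete = drop_arc(arcs, pick$p, pick$ch),
      reverse = add_arc(drop_arc(arcs, pick$p, pick$ch), pick$ch, pick$p)
    )
  }

  struct <- bn_structure(variables, arcs)
  list(structure = struct, score = bic_score(struct, data))
}

# ---- exact big-integer arithmetic (signed, base-1e7 limbs) ----------------
# Needed because labeled-DAG counts overflow double precision from p = 10.

big_norm <- function(limbs) {
  base <- 1e7
  carry <- 0
  for (i in seq_along(limbs)) {
    limbs[i] <- limbs[i] + carry
    carry <- floor(limbs[i] / base)
    limbs[i] <- limbs[i] - carry * base
  }
  while (carry > 0) {
    limbs <- c(limbs, carry %% base)
    carry <- floor(carry / base)
  }
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) {
    limbs <- limbs[-length(limbs)]
  }
  limbs
}

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% 1e7)
    x <- floor(x / 1e7)
    if (x == 0) break
  }
  list(sign = 1, limbs = limbs)
}

big_cmp_abs <- function(a, b) {
  if (length(a$limbs) != length(b$limbs)) {
    return(sign(length(a$limbs) - length(b$limbs)))
  }
  for (i in rev(seq_along(a$limbs))) {
    if (a$limbs[i] != b$limbs[i]) return(sign(a$limbs[i] - b$limbs[i]))
  }
  0
}

big_add_abs <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

big_sub_abs <- function(a, b) { # |a| >= |b|
  base <- 1e7
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  d <- a - b
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + base
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_add <- function(a, b) {
  if (a$sign == b$sign) {
    return(list(sign = a$sign, limbs = big_add_abs(a$limbs, b$limbs)))
  }
  cmp <- big_cmp_abs(a, b)
  if (cmp == 0) return(list(sign = 1, limbs = 0))
  if (cmp > 0) list(sign = a$sign, limbs = big_sub_abs(a$limbs, b$limbs))
  else list(sign = b$sign, limbs = big_sub_abs(b$limbs, a$limbs))
}

big_mul <- function(a, b) {
  # limbs < 1e7, so each product < 1e14 and the accumulated sum stays below
  # length(a) * 1e14 < 2^53 for the sizes count_dags needs (p <= 20 gives
  # at most ~11 limbs); a single carry pass at the end is exact
  out <- numeric(length(a$limbs) + length(b$limbs))
  for (i in seq_along(a$limbs)) {
    if (a$limbs[i] == 0) next
    seg <- seq_along(b$limbs) + i - 1L
    out[seg] <- out[seg] + a$limbs[i] * b$limbs
  }
  list(sign = a$sign * b$sign, limbs = big_norm(out))
}

big_pow2 <- function(e) {
  out <- big_from_num(1)
  chunk <- big_from_num(2^30)
  while (e >= 30) {
    out <- big_mul(out, chunk)
    e <- e - 30
  }
  big_mul(out, big_from_num(2^e))
}

big_to_string <- function(a) {
  digs <- sprintf("%07.0f", rev(a$limbs))
  s <- sub("^0+", "", paste(digs, collapse = ""))
  if (s == "") s <- "0"
  if (a$sign < 0) s <- paste0("-", s)
  s
}

big_to_number <- function(a) {
  x <- 0
  for (l in rev(a$limbs)) x <- x * 1e7 + l
  a$sign * x
}

#' Count labeled directed acyclic graphs
#'
#' The number of distinct DAGs on `p` labeled nodes, `a(p)`, via the
#' classical alternating-sum recurrence
#' `a(p) = sum_{k=1..p} (-1)^(k+1) choose(p, k) 2^(k(p-k)) a(p-k)`,
#' with `a(0) = 1`. This is the structure-space size that makes exhaustive
#' DAG search infeasible and motivates greedy search-and-score learning.
#'
#' Computed in exact integer arithmetic; returned as a numeric when the
#' count is exactly representable in a double (`p <= 9`), otherwise as a
#' decimal digit string.
#'
#' @param p Positive integer number of nodes, at most 20.
#' @return The exact DAG count (numeric, or character for large `p`).
#' @examples
#' count_dags(3) # 25
#' count_dags(4) # 543
#' @export
count_dags <- function(p) {
  if (length(p) != 1L || is.na(p) || p != floor(p) || p <= 0) {
    rlang::abort("p must be a positive integer",
                 class = "floodbn_input_error")
  }
  if (p > 20) {
    rlang::abort("p must be at most 20", class = "floodbn_input_error")
  }
  a <- vector("list", p + 1L)
  a[[1L]] <- big_from_num(1) # a(0)
  for (n in seq_len(p)) {
    acc <- list(sign = 1, limbs = 0)
    for (k in seq_len(n)) {
      term <- big_mul(big_from_num(choose(n, k)), big_pow2(k * (n - k)))
      term <- big_mul(term, a[[n - k + 1L]])
      term$sign <- term$sign * (-1)^(k + 1)
      acc <- big_add(acc, term)
    }
    a[[n + 1L]] <- acc
  }
  res <- a[[p + 1L]]
  num <- big_to_number(res)
  if (num <= 2^53) num else big_to_string(res)
}
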