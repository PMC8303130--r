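# Test fixtures built in code: random binary networks, small hand-built
# networks, and brute-force oracles independent of the implementation paths
# they check.

# Random binary network on p nodes: arcs only i -> j for i < j (acyclic by
# construction), arc probability arc_p, CPT rows drawn uniformly.
random_binary_network <- function(p, seed, arc_p = 0.4) {
  set.seed(seed)
  vars <- stats::setNames(rep(list(c("a", "b")), p), paste0("V", seq_len(p)))
  arcs <- NULL
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j && stats::runif(1) < arc_p) {
        arcs <- rbind(arcs, data.frame(parent = paste0("V", i),
                                       child = paste0("V", j)))
      }
    }
  }
  skel <- bn_structure(vars, arcs)
  cpts <- lapply(names(vars), function(nm) {
    pa <- skel$arcs$parent[skel$arcs$child == nm]
    ncfg <- max(1L, 2L^length(pa))
    rows <- t(vapply(seq_len(ncfg), function(i) {
      x <- stats::runif(2)
      x / sum(x)
    }, numeric(2)))
    if (length(pa) == 0L) {
      cpt(nm, character(), vars[[nm]], rows[1L, ])
    } else {
      cpt(nm, pa, vars[[nm]], rows, parent_states = vars)
    }
  })
  bn_network(vars, arcs, stats::setNames(cpts, names(vars)))
}

# Two-node network A -> B with the given probabilities (states yes/no).
two_node_network <- function(p_a = 0.3, p_b_given_a = 0.9,
                             p_b_given_not_a = 0.2) {
  vars <- list(A = c("yes", "no"), B = c("yes", "no"))
  bn_network(
    vars,
    arcs = data.frame(parent = "A", child = "B"),
    cpts = list(
      A = cpt("A", character(), vars$A, c(p_a, 1 - p_a)),
      B = cpt("B", "A", vars$B,
              rbind(c(p_b_given_a, 1 - p_b_given_a),
                    c(p_b_given_not_a, 1 - p_b_given_not_a)),
              parent_states = vars)
    )
  )
}

# Oracle: condition the brute-force joint table on evidence and marginalize
# onto the targets. Deliberately built on enumerate_joint + base aggregation,
# not on the variable-elimination path it is used to check.
oracle_posterior <- function(net, targets, evidence = character()) {
  joint <- enumerate_joint(net)
  keep <- rep(TRUE, nrow(joint))
  for (nm in names(evidence)) {
    keep <- keep & joint[[nm]] == evidence[[nm]]
  }
  sub <- joint[keep, , drop = FALSE]
  z <- sum(sub$prob)
  agg <- stats::aggregate(sub$prob,
                          by = lapply(targets, function(t) sub[[t]]),
                          FUN = sum)
  names(agg) <- c(targets, "prob")
  agg$prob <- agg$prob / z
  list(table = agg, evidence_probability = z)
}

match_oracle_prob <- function(post, oracle_tab, targets) {
  vapply(seq_len(nrow(post)), function(k) {
    keep <- rep(TRUE, nrow(oracle_tab))
    for (t in targets) keep <- keep & oracle_tab[[t]] == post[[t]][k]
    oracle_tab$prob[keep]
  }, numeric(1))
}

# Oracle: count DAGs on p labeled nodes by enumerating all 2^(p(p-1))
# directed graphs without self-loops and keeping the acyclic ones.
brute_force_dag_count <- function(p) {
  pairs <- expand.grid(from = seq_len(p), to = seq_len(p))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  m <- nrow(pairs)
  is_acyclic <- function(adj) {
    indeg <- colSums(adj)
    alive <- rep(TRUE, p)
    repeat {
      src <- which(alive & indeg == 0)
      if (length(src) == 0L) break
      for (s in src) {
        alive[s] <- FALSE
        indeg <- indeg - adj[s, ]
      }
    }
    !any(alive)
  }
  count <- 0L
  for (mask in 0:(2^m - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    adj <- matrix(0L, p, p)
    adj[cbind(pairs$from[bits], pairs$to[bits])] <- 1L
    if (is_acyclic(adj)) count <- count + 1L
  }
  count
}

flood_net_quiet <- function() suppressMessages(build_flood_network())
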