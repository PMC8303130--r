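test_that("fit_cpts reproduces hand counts", {
  skel <- bn_structure(list(X = c("present", "absent")))
  data <- data.frame(X = rep(c("present", "absent"), each = 3))
  net <- fit_cpts(skel, data, pseudocount = 0)
  expect_equal(as.numeric(net$cpts$X$values), c(0.5, 0.5))

  # all-constant column collapses to a point mass without smoothing
  const <- data.frame(X = rep("present", 10))
  net <- fit_cpts(skel, const, pseudocount = 0)
  expect_equal(as.numeric(net$cpts$X$values), c(1, 0))

  # Laplace smoothing pulls the point mass off the boundary
  net1 <- fit_cpts(skel, const, pseudocount = 1)
  expect_equal(as.numeric(net1$cpts$X$values), c(11 / 12, 1 / 12))
})

test_that("fit_cpts names the offending row and column for bad states", {
  skel <- bn_structure(list(X = c("present", "absent")))
  data <- data.frame(X = c("present", "sometimes"))
  err <- expect_error(fit_cpts(skel, data), class = "floodbn_input_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "'X'")
})

test_that("unobserved parent configurations fall back to uniform", {
  vars <- list(A = c("x", "y"), B = c("x", "y"))
  skel <- bn_structure(vars, data.frame(parent = "A", child = "B"))
  data <- data.frame(A = c("x", "x"), B = c("x", "y")) # A=y never seen
  expect_warning(net <- fit_cpts(skel, data, pseudocount = 0),
                 "unobserved parent configuration")
  expect_equal(as.numeric(net$cpts$B$values["x", "y"]), 0.5)
})

test_that("BIC matches its closed form on one binary node", {
  skel <- bn_structure(list(X = c("absent", "present")))
  data <- data.frame(X = c(rep("present", 3), "absent"))
  score <- bic_score(skel, data)
  expect_equal(score$loglik, 3 * log(0.75) + log(0.25), tolerance = 1e-12)
  expect_equal(score$penalty, -(1 / 2) * log(4), tolerance = 1e-12)
  expect_equal(score$total, score$loglik + score$penalty)
})

test_that("BIC is a sufficient-statistic: row permutations do not matter", {
  net <- two_node_network()
  records <- forward_sample(net, 400, seed = 8)
  skel <- bn_structure(net$variables, net$arcs)
  s1 <- bic_score(skel, records)
  s2 <- bic_score(skel, records[sample(nrow(records)), , drop = FALSE])
  expect_identical(s1$total, s2$total)
})

test_that("BIC decomposes over node families", {
  net <- random_binary_network(5, seed = 21)
  records <- forward_sample(net, 300, seed = 22)
  score <- bic_score(net, records)
  expect_equal(score$total, sum(score$families$total))
  expect_true(all(score$families$penalty <= 0))
})

test_that("the penalty rejects an arc between independent columns", {
  set.seed(40)
  n <- 10000
  data <- data.frame(A = sample(c("x", "y"), n, TRUE),
                     B = sample(c("x", "y"), n, TRUE))
  vars <- list(A = c("x", "y"), B = c("x", "y"))
  empty <- bic_score(bn_structure(vars), data)$total
  one_arc <- bic_score(
    bn_structure(vars, data.frame(parent = "A", child = "B")), data)$total
  expect_gt(empty, one_arc)
})

test_that("hill climbing returns the empty graph on independent data", {
  set.seed(7)
  n <- 5000
  data <- data.frame(A = sample(c("x", "y"), n, TRUE),
                     B = sample(c("x", "y"), n, TRUE),
                     C = sample(c("x", "y"), n, TRUE))
  hc <- hill_climb_structure(data, seed = 7)
  expect_identical(nrow(hc$structure$arcs), 0L)
  # exhaustive check: every single-arc graph scores below the empty graph
  vars <- lapply(data, function(col) sort(unique(col)))
  empty_score <- bic_score(bn_structure(vars), data)$total
  for (p in names(vars)) for (ch in setdiff(names(vars), p)) {
    s <- bic_score(bn_structure(vars, data.frame(parent = p, child = ch)),
                   data)$total
    expect_lt(s, empty_score)
  }
})

test_that("hill climbing finds the single arc of a dependent pair", {
  net <- two_node_network(p_a = 0.5, p_b_given_a = 0.9, p_b_given_not_a = 0.1)
  records <- forward_sample(net, 20000, seed = 3)
  hc <- hill_climb_structure(records, seed = 3)
  expect_identical(nrow(hc$structure$arcs), 1L)
  # Markov equivalence: both orientations score identically, and both beat
  # the empty graph (exhaustive 3-graph oracle)
  vars <- lapply(records, function(col) sort(unique(col)))
  s_empty <- bic_score(bn_structure(vars), records)$total
  s_ab <- bic_score(bn_structure(vars, data.frame(parent = "A", child = "B")),
                    records)$total
  s_ba <- bic_score(bn_structure(vars, data.frame(parent = "B", child = "A")),
                    records)$total
  expect_equal(s_ab, s_ba, tolerance = 1e-9)
  expect_gt(s_ab, s_empty)
  expect_gte(hc$score$total, s_ab - 1e-9)
})

test_that("hill climbing is deterministic and validates its inputs", {
  net <- two_node_network()
  records <- forward_sample(net, 1000, seed = 5)
  a <- hill_climb_structure(records, seed = 1)
  b <- hill_climb_structure(records, seed = 1)
  expect_identical(a$structure$arcs, b$structure$arcs)
  expect_identical(a$score$total, b$score$total)
  expect_error(hill_climb_structure(records, max_parents = -1),
               class = "floodbn_input_error")
  expect_error(bic_score(net, data.frame()), class = "floodbn_input_error")
})

test_that("DAG counts match brute-force enumeration and grow strictly", {
  for (p in 1:4) {
    expect_identical(count_dags(p), as.numeric(brute_force_dag_count(p)))
  }
  counts <- vapply(1:8, count_dags, numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(count_dags(0), class = "floodbn_input_error")
  expect_error(count_dags(-3), class = "floodbn_input_error")
  expect_error(count_dags(21), class = "floodbn_input_error")
})

test_that("large DAG counts stay exact beyond double precision", {
  expect_identical(count_dags(13), "18676600744432035186664816926721")
  expect_identical(count_dags(9), 1213442454842881)
})
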