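test_that("validation reports violations as data and passes valid networks", {
  ok <- single_node_network("Flood", 0.201)
  expect_identical(nrow(validate_network(ok)), 0L)

  # smallest possible cycle
  vars <- list(A = c("x", "y"), B = c("x", "y"))
  cyc <- bn_network(vars,
                    arcs = data.frame(parent = c("A", "B"),
                                      child = c("B", "A")),
                    cpts = NULL, check = FALSE)
  report <- validate_network(cyc)
  expect_identical(sum(report$type == "cycle"), 1L)

  # unnormalized row
  bad <- bn_network(
    list(A = c("x", "y")),
    cpts = list(A = cpt("A", character(), c("x", "y"), c(0.5, 0.4))),
    check = FALSE)
  report <- validate_network(bad)
  expect_identical(sum(report$type == "normalization"), 1L)

  # undeclared variable, self loop, duplicate arc
  messy <- bn_network(
    vars,
    arcs = data.frame(parent = c("A", "A", "A", "C"),
                      child = c("B", "B", "A", "B")),
    cpts = NULL, check = FALSE)
  report <- validate_network(messy)
  expect_true(all(c("undeclared_variable", "self_loop", "duplicate_arc")
                  %in% report$type))
})

test_that("constructor refuses invalid networks with an itemized report", {
  expect_error(
    bn_network(list(A = c("x", "y")),
               cpts = list(A = cpt("A", character(), c("x", "y"),
                                   c(0.5, 0.4)))),
    class = "floodbn_invalid_network")
})

test_that("joint probability multiplies out the factorization", {
  net <- single_node_network("Flood", 0.201)
  expect_equal(joint_probability(net, c(Flood = "present")), 0.201)
  expect_equal(joint_probability(net, c(Flood = "absent")), 0.799)

  expect_error(joint_probability(net, c(Other = "present")),
               class = "floodbn_input_error")
  expect_error(joint_probability(net, c(Flood = "soggy")),
               class = "floodbn_input_error")
})

test_that("3-node chain joint equals the hand-multiplied table", {
  # chain A -> B -> C with arbitrary entries; oracle multiplies the three
  # local terms cell by cell, independent of the cpt array plumbing
  vars <- list(A = c("1", "0"), B = c("1", "0"), C = c("1", "0"))
  pa <- 0.37
  pb <- c(`1` = 0.81, `0` = 0.24) # P(B=1 | A)
  pc_ <- c(`1` = 0.55, `0` = 0.06) # P(C=1 | B)
  net <- bn_network(
    vars,
    arcs = data.frame(parent = c("A", "B"), child = c("B", "C")),
    cpts = list(
      A = cpt("A", character(), vars$A, c(pa, 1 - pa)),
      B = cpt("B", "A", vars$B, rbind(c(pb[["1"]], 1 - pb[["1"]]),
                                      c(pb[["0"]], 1 - pb[["0"]])),
              parent_states = vars),
      C = cpt("C", "B", vars$C, rbind(c(pc_[["1"]], 1 - pc_[["1"]]),
                                      c(pc_[["0"]], 1 - pc_[["0"]])),
              parent_states = vars)
    ))
  for (a in c("1", "0")) for (b in c("1", "0")) for (cc in c("1", "0")) {
    expected <- (if (a == "1") pa else 1 - pa) *
      (if (b == "1") pb[[a]] else 1 - pb[[a]]) *
      (if (cc == "1") pc_[[b]] else 1 - pc_[[b]])
    expect_equal(joint_probability(net, c(A = a, B = b, C = cc)), expected)
  }
})

test_that("the joint normalizes to 1 across random networks", {
  for (seed in 1:10) {
    net <- random_binary_network(p = sample(2:8, 1), seed = seed)
    joint <- enumerate_joint(net)
    expect_equal(sum(joint$prob), 1, tolerance = 1e-9)
  }
})

test_that("joint probability ignores CPT storage order", {
  net <- flood_net_quiet()
  shuffled <- net
  shuffled$cpts <- shuffled$cpts[rev(names(shuffled$cpts))]
  assignment <- c(Flood = "present", LOSI = "present", PPD = "absent",
                  Lsever = "present", Msever = "absent")
  expect_identical(joint_probability(net, assignment),
                   joint_probability(shuffled, assignment))
})

test_that("enumerate_joint matches the stated small cases and the cap", {
  one <- single_node_network("LOSI", 0.62)
  joint <- enumerate_joint(one)
  expect_equal(joint$prob, c(0.62, 0.38))

  coins <- bn_network(
    list(H1 = c("h", "t"), H2 = c("h", "t")),
    cpts = list(H1 = cpt("H1", character(), c("h", "t"), c(0.5, 0.5)),
                H2 = cpt("H2", character(), c("h", "t"), c(0.5, 0.5))))
  expect_equal(enumerate_joint(coins)$prob, rep(0.25, 4))

  expect_equal(sum(enumerate_joint(flood_net_quiet())$prob), 1,
               tolerance = 1e-9)

  expect_error(enumerate_joint(coins, cap = 2), class = "floodbn_size_error")
})

test_that("topological sort orders parents first and detects cycles", {
  net <- flood_net_quiet()
  ord <- topological_sort(net)
  expect_true(which(ord == "Flood") < which(ord == "LOSI"))
  expect_true(which(ord == "PPD") < which(ord == "Msever"))

  cyc <- bn_network(list(A = c("x", "y"), B = c("x", "y")),
                    arcs = data.frame(parent = c("A", "B"),
                                      child = c("B", "A")),
                    check = FALSE)
  expect_null(topological_sort(cyc))
})
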