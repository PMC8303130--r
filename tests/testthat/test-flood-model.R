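elicited <- c(Flood = 0.201, LOSI = 0.62, PPD = 0.186,
              Lsever = 0.483, Msever = 0.211)

test_that("the built network honors every elicited marginal exactly", {
  net <- flood_net_quiet()
  for (nm in names(elicited)) {
    post <- query_posterior(net, nm)
    expect_equal(post$prob[post[[nm]] == "present"], elicited[[nm]],
                 tolerance = 1e-9)
  }
})

test_that("the packaged fixture file carries the same calibration", {
  net <- flood_network_fixture()
  expect_identical(nrow(validate_network(net)), 0L)
  for (nm in names(elicited)) {
    post <- query_posterior(net, nm)
    expect_equal(post$prob[post[[nm]] == "present"], elicited[[nm]],
                 tolerance = 1e-9)
  }
})

test_that("an infeasible risk ratio is clamped, not silently violated", {
  expect_message(build_flood_network(), "clamped")
  # a feasible ratio goes through silently and is honored
  net <- build_flood_network(flood_config(risk_ratio = 1.5))
  cpt_losi <- cpt_table(net$cpts$LOSI, net$variables)
  q1 <- cpt_losi$p_present[cpt_losi$Flood == "present"]
  q0 <- cpt_losi$p_present[cpt_losi$Flood == "absent"]
  expect_equal(q1 / q0, 1.5, tolerance = 1e-9)
  post <- query_posterior(net, "LOSI")
  expect_equal(post$prob[post$LOSI == "present"], 0.62, tolerance = 1e-12)
})

test_that("configs are validated", {
  expect_error(flood_config(marginals = c(Flood = 1.2, LOSI = 0.5,
                                          PPD = 0.2, Lsever = 0.4,
                                          Msever = 0.2)),
               class = "floodbn_input_error")
  expect_error(flood_config(risk_ratio = 0), class = "floodbn_input_error")
  cyc <- flood_config(arcs = data.frame(parent = c("Flood", "LOSI"),
                                        child = c("LOSI", "Flood")))
  expect_error(build_flood_network(cyc), class = "floodbn_invalid_network")
  two_parents <- flood_config(arcs = data.frame(
    parent = c("Flood", "LOSI", "Flood", "PPD", "PPD"),
    child = c("LOSI", "PPD", "PPD", "Lsever", "Msever")))
  expect_error(build_flood_network(two_parents),
               class = "floodbn_input_error")
})

test_that("change in utility matches the published table", {
  u <- utility_table()
  expect_equal(change_in_utility(u, "Lsever"), 0.25)
  expect_equal(change_in_utility(u, "Msever"), 0.43)
  expect_equal(change_in_utility(u, "Remission"), 0)
  expect_error(change_in_utility(u, "Euphoric"),
               class = "floodbn_input_error")
})

test_that("utility tables enforce their consistency rules", {
  expect_error(utility_table(alpha = c(923, 182, -1)),
               class = "floodbn_input_error")
  # a stated mean drifting >0.005 from its Beta mean is rejected
  expect_error(utility_table(utility = c(0.85, 0.65, 0.42)),
               class = "floodbn_input_error")
  # a state better than the reference is rejected
  expect_error(
    utility_table(states = c("Remission", "Better"),
                  utility = c(0.85, 0.95),
                  alpha = c(923, 95), beta = c(163, 5)),
    class = "floodbn_input_error")
})

test_that("Beta means reproduce the published utility means", {
  expect_equal(round(beta_mean(923, 163), 2), 0.85)
  expect_equal(round(beta_mean(182, 122), 2), 0.60)
  expect_equal(round(beta_mean(54, 75), 2), 0.42)
  expect_equal(beta_mean(1, 1), 0.5)
  expect_error(beta_mean(0, 1), class = "floodbn_input_error")
  expect_error(beta_mean(2, -1), class = "floodbn_input_error")
})

test_that("compute_cqaly follows the pathway formula", {
  u <- utility_table()
  # toy: Flood -> LOSI -> S, with P(LOSI=1|Flood=1)=1, P(S=1|LOSI=1)=0.5
  # so P(S=1, LOSI=1 | Flood=1) = 0.5 by hand
  vars <- list(Flood = c("present", "absent"),
               LOSI = c("present", "absent"),
               Msever = c("present", "absent"))
  toy <- bn_network(
    vars,
    arcs = data.frame(parent = c("Flood", "LOSI"),
                      child = c("LOSI", "Msever")),
    cpts = list(
      Flood = cpt("Flood", character(), vars$Flood, c(0.4, 0.6)),
      LOSI = cpt("LOSI", "Flood", vars$LOSI,
                 rbind(c(1, 0), c(0.3, 0.7)), parent_states = vars),
      Msever = cpt("Msever", "LOSI", vars$Msever,
                   rbind(c(0.5, 0.5), c(0.1, 0.9)), parent_states = vars)
    ))
  expect_equal(compute_cqaly(toy, u, "Msever"), 0.5 * 0.43 * 1,
               tolerance = 1e-12)

  # zero change in utility gives zero CQALY on any network
  u0 <- utility_table(states = c("Remission", "Msever"),
                      utility = c(0.85, 0.85),
                      alpha = c(923, 923), beta = c(163, 163))
  expect_equal(compute_cqaly(toy, u0, "Msever"), 0)

  expect_error(compute_cqaly(toy, u, "Remission"),
               class = "floodbn_input_error")
})

test_that("the pathway probability agrees with the enumeration oracle", {
  net <- flood_net_quiet()
  u <- utility_table()
  joint <- enumerate_joint(net)
  for (state in c("Lsever", "Msever")) {
    ok <- joint[[state]] == "present" & joint$LOSI == "present"
    flooded <- joint$Flood == "present"
    oracle_p <- sum(joint$prob[ok & flooded]) / sum(joint$prob[flooded])
    expect_equal(compute_cqaly(net, u, state),
                 oracle_p * change_in_utility(u, state),
                 tolerance = 1e-9)
  }
})

test_that("CQALY overrides pass printed values through untouched", {
  net <- flood_net_quiet()
  u <- utility_table()
  expect_identical(compute_cqaly(net, u, "Msever",
                                 override = c(Msever = 0.055)), 0.055)
})

test_that("the early-warning scenario reproduces the published valuation", {
  ce <- evaluate_intervention(scenario_ews(), utility_table())
  expect_equal(ce$delta_qaly[ce$state == "Msever"], 0.022, tolerance = 1e-12)
  expect_equal(ce$delta_qaly[ce$state == "Lsever"], 0.024, tolerance = 1e-12)
  expect_equal(ce$monetary_value[ce$state == "Msever"], 440,
               tolerance = 1e-9)
  expect_equal(ce$monetary_value[ce$state == "Lsever"], 480,
               tolerance = 1e-9)
  expect_equal(ce$delta_qaly, ce$cqaly_before - ce$cqaly_after,
               tolerance = 1e-12)
})

test_that("monetary value is linear in threshold and in the QALY gain", {
  before <- c(Msever = 0.055, Lsever = 0.062)
  after <- c(Msever = 0.033, Lsever = 0.038)
  base <- evaluate_intervention(
    intervention_scenario(before, after, threshold = 20000))
  for (thr in c(10000, 30000, 50000)) {
    scaled <- evaluate_intervention(
      intervention_scenario(before, after, threshold = thr))
    expect_equal(scaled$monetary_value,
                 base$monetary_value * thr / 20000, tolerance = 1e-9)
  }
  at30 <- evaluate_intervention(
    intervention_scenario(before, after, threshold = 30000))
  expect_equal(at30$monetary_value[at30$state == "Msever"], 660,
               tolerance = 1e-9)
  expect_equal(at30$monetary_value[at30$state == "Lsever"], 720,
               tolerance = 1e-9)

  doubled <- evaluate_intervention(
    intervention_scenario(before * 2, after * 2, threshold = 20000))
  expect_equal(doubled$monetary_value, base$monetary_value * 2,
               tolerance = 1e-9)
})

test_that("a null intervention is worth nothing", {
  vals <- c(Msever = 0.05, Lsever = 0.06)
  ce <- evaluate_intervention(intervention_scenario(vals, vals))
  expect_equal(ce$delta_qaly, c(0, 0))
  expect_equal(ce$monetary_value, c(0, 0))
})

test_that("scenario forms must match and thresholds must be positive", {
  net <- flood_net_quiet()
  expect_error(intervention_scenario(c(Msever = 0.05), net),
               class = "floodbn_input_error")
  expect_error(intervention_scenario(c(Msever = 0.05), c(Lsever = 0.03)),
               class = "floodbn_input_error")
  expect_error(intervention_scenario(c(Msever = 0.05), c(Msever = 0.03),
                                     threshold = -1),
               class = "floodbn_input_error")
})

test_that("model-form scenarios are evaluated through the network", {
  u <- utility_table()
  before_net <- flood_net_quiet()
  # intervention: halve the chance of losing sentimental items when flooded
  cfg <- flood_config(marginals = c(Flood = 0.201, LOSI = 0.31,
                                    PPD = 0.12, Lsever = 0.30,
                                    Msever = 0.13))
  after_net <- build_flood_network(cfg)
  scn <- intervention_scenario(before_net, after_net, label = "mitigation")
  ce <- evaluate_intervention(scn, u)
  expect_identical(sort(ce$state), c("Lsever", "Msever"))
  expect_equal(ce$cqaly_before,
               vapply(ce$state, function(s) compute_cqaly(before_net, u, s),
                      numeric(1)),
               ignore_attr = TRUE)
  expect_true(all(ce$delta_qaly > 0))
})
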