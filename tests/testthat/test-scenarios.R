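test_that("freezing retains 40% of Q, 10% of NQ, and books killed biomass as recyclable", {
  st <- population_state(q = 1e6, nq = 1e6)
  frozen <- apply_freezing(st)
  expect_equal(frozen$q, 4e5)
  expect_equal(frozen$nq, 1e5)
  expect_equal(frozen$recyclable, 0.6e6 + 0.9e6)

  expect_equal(unlist(apply_freezing(st, 1, 1)), unlist(st))

  dead <- apply_freezing(st, 0, 0)
  expect_equal(dead$q, 0)
  expect_equal(dead$nq, 0)
  expect_equal(dead$recyclable, 2e6)

  expect_error(apply_freezing(st, 1.2, 0.1), "\\[0, 1\\]")
})

test_that("culture initialisation splits biomass by composition and seeds the complex pool", {
  p <- qnq_params()
  total <- od_to_biomass(0.8)

  mixed <- initialize_culture(qnq_scenario("mixed", "simple"), p)
  expect_equal(mixed$q, 0.75 * total)
  expect_equal(mixed$nq, 0.25 * total)
  expect_equal(mixed$resource, 0)
  expect_equal(mixed$recyclable, 0)

  qmono <- initialize_culture(qnq_scenario("Q", "simple"), p)
  expect_equal(qmono$nq, 0)
  expect_equal(qmono$q, total)

  cx <- initialize_culture(qnq_scenario("NQ", "complex"), p)
  expect_equal(cx$recyclable, p$residual_seed_frac * p$fresh_resource)

  expect_error(qnq_scenario("QQ", "simple"), "arg")
})

test_that("sampling and transfer implement the 275/550/200 ul geometry", {
  scen <- qnq_scenario("mixed", "simple")
  st <- population_state(q = 3e6, nq = 1e6, recyclable = 5e5)
  plated <- sample_and_transfer(st, scen, fresh_resource = 3.2e7)

  # cells of 0.1 ml of culture end up in the well: factor 0.5 on the
  # per-well-equivalent biomass, Q:NQ ratio preserved
  expect_equal(plated$q, 1.5e6)
  expect_equal(plated$nq, 0.5e6)
  expect_equal(plated$q / plated$nq, st$q / st$nq)
  expect_equal(plated$recyclable, 0)
  expect_equal(plated$resource, 3.2e7)

  # a starved culture at 2e8 cells/ml carries 4e7 cells per 200 ul
  # well-equivalent and plates 2e7 cells
  dense <- population_state(nq = 4e7)
  expect_equal(sample_and_transfer(dense, scen, 3.2e7)$nq, 2e7)

  expect_error(sample_and_transfer(st, scen, 0), "positive")
})

test_that("with no death, no transition and flat lags all weekly assays are identical", {
  p <- qnq_params(d_q = 0, d_nq = 0, tau = 0, residual_seed_frac = 0,
                  lag_q_slope = 0, lag_nq_slope = 0)
  scen <- qnq_scenario("mixed", "complex", freezing = FALSE,
                       starvation_weeks = 3)
  assays <- run_long_starvation(scen, p)
  for (w in 2:3) {
    expect_equal(assays[[w]]$biomass, assays[[1]]$biomass, tolerance = 1e-9)
    expect_equal(assays[[w]]$od, assays[[1]]$od, tolerance = 1e-9)
  }
})

test_that("weekly assay series is deterministic and respects mass bounds", {
  p <- qnq_params()
  scen <- qnq_scenario("mixed", "simple", starvation_weeks = 2)
  a1 <- run_long_starvation(scen, p)
  a2 <- run_long_starvation(scen, p)
  expect_identical(a1, a2)

  for (assay in a1) {
    start <- attr(assay, "starting_state")
    expect_true(all(assay$biomass <=
                      start$q + start$nq + p$fresh_resource + 1))
    expect_true(all(diff(assay$biomass) > -1))
  }
})

test_that("early-regrowth Q advantage grows with starvation and recycling helps NQ", {
  p <- qnq_params()
  q_s <- run_long_starvation(qnq_scenario("Q", "simple",
                                          starvation_weeks = 4), p)
  nq_s <- run_long_starvation(qnq_scenario("NQ", "simple",
                                           starvation_weeks = 4), p)
  ratio <- vapply(1:4, function(w) {
    biomass_at(q_s[[w]], 2) / biomass_at(nq_s[[w]], 2)
  }, numeric(1))
  expect_true(all(diff(ratio) >= 0))

  nq_c <- run_long_starvation(qnq_scenario("NQ", "complex",
                                           starvation_weeks = 4), p)
  expect_gt(biomass_at(nq_c[[4]], 10), biomass_at(nq_s[[4]], 10))
})

test_that("mixed cultures stay between the monocultures in the simple environment", {
  p <- qnq_params()
  scens <- lapply(c("Q", "NQ", "mixed"), qnq_scenario,
                  environment = "simple", starvation_weeks = 2)
  runs <- lapply(scens, run_long_starvation, params = p)
  for (w in 1:2) {
    hi <- pmax(runs[[1]][[w]]$biomass, runs[[2]][[w]]$biomass)
    lo <- pmin(runs[[1]][[w]]$biomass, runs[[2]][[w]]$biomass)
    mix <- runs[[3]][[w]]$biomass
    expect_true(all(mix <= hi * (1 + 1e-9) + 1))
    expect_true(all(mix >= lo * (1 - 1e-9) - 1))
  }
})

test_that("short starvation favours NQ early and all compositions share the plateau", {
  p <- qnq_params()
  aq <- run_short_starvation(short_starvation_scenario("Q"), p)
  an <- run_short_starvation(short_starvation_scenario("NQ"), p)
  am <- run_short_starvation(short_starvation_scenario("mixed"), p)

  expect_gt(biomass_at(an, 3), biomass_at(aq, 3))
  expect_true(all(biomass_at(am, 3) <= biomass_at(an, 3) &
                    biomass_at(am, 3) >= biomass_at(aq, 3)))

  plateau <- od_to_biomass(0.4) + p$fresh_resource
  for (a in list(aq, an, am)) {
    expect_equal(final_biomass(a), plateau, tolerance = 0.01)
  }
})

test_that("equal short-starvation lags make the Q and NQ monocultures symmetric", {
  p <- qnq_params(lag_q_short = 1, lag_nq_short = 1)
  aq <- run_short_starvation(short_starvation_scenario("Q"), p)
  an <- run_short_starvation(short_starvation_scenario("NQ"), p)
  expect_equal(aq$biomass, an$biomass, tolerance = 1e-9)
})
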