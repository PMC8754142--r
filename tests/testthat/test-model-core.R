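test_that("growth-phase derivatives follow Monod growth and near-depletion differentiation", {
  p <- qnq_params()

  # resource exhausted: growth stops, differentiation runs at sigma_max
  d0 <- growth_rhs(population_state(q = 0, nq = 1e6, resource = 0), p)
  expect_equal(d0[["nq"]], -p$sigma_max * 1e6)
  expect_equal(d0[["q"]], p$sigma_max * 1e6)
  expect_equal(d0[["resource"]], 0)
  expect_equal(d0[["recyclable"]], 0)

  # saturated growth: division at v_max, differentiation negligible
  dsat <- growth_rhs(population_state(nq = 1e6, resource = 1e12), p)
  expect_equal(dsat[["nq"]], p$v_max * 1e6, tolerance = 1e-4)
  expect_lt(dsat[["q"]], p$sigma_max * 1e6 * 1e-4)

  expect_error(growth_rhs(c(q = -1, nq = 0, resource = 0, recyclable = 0), p),
               "non-negative")
})

test_that("growth to resource exhaustion conserves cell-equivalents", {
  p <- qnq_params()
  traj <- integrate_phase(population_state(nq = 1e5, resource = 3.2e7), p,
                          qnq_phase("growth_differentiation"), duration = 48,
                          output_step = 1)
  total <- traj$q + traj$nq + traj$resource + traj$recyclable
  expect_equal(total, rep(1e5 + 3.2e7, length(total)), tolerance = 1e-7)
  last <- traj[nrow(traj), ]
  expect_lt(last$resource / (1e5 + 3.2e7), 1e-6)
  expect_equal(last$q + last$nq, 1e5 + 3.2e7, tolerance = 1e-6)
})

test_that("starvation derivatives encode death, transition and gated recycling", {
  p <- qnq_params()
  st <- population_state(q = 1e6, nq = 2e6, recyclable = 5e5)

  dsimple <- starvation_rhs(st, p, qnq_phase("starvation", "simple"))
  expect_equal(dsimple[["q"]], -(p$d_q + p$tau) * 1e6)
  # simple environment: the recyclable pool is inert, no growth, no return
  expect_equal(dsimple[["nq"]], -p$d_nq * 2e6 + p$tau * 1e6)
  expect_equal(dsimple[["recyclable"]], 0)

  dcomplex <- starvation_rhs(st, p, qnq_phase("starvation", "complex"))
  uptake <- p$v_max * 5e5 / (p$k_m + 5e5) * 2e6
  expect_equal(dcomplex[["nq"]], -p$d_nq * 2e6 + p$tau * 1e6 + uptake)
  expect_equal(dcomplex[["recyclable"]],
               p$epsilon * (p$d_q * 1e6 + p$d_nq * 2e6) - uptake)

  # frozen dynamics when every rate is zero
  p0 <- qnq_params(v_max = 0, d_q = 0, d_nq = 0, tau = 0, sigma_max = 0)
  expect_equal(unname(starvation_rhs(st, p0, qnq_phase("starvation"))),
               rep(0, 4))

  expect_error(starvation_rhs(st, p, qnq_phase("growth_differentiation")),
               "starvation")
})

test_that("pure-Q starvation matches the exponential closed form from the 87% calibration", {
  p <- qnq_params(tau = 0, epsilon = 0)
  traj <- integrate_phase(population_state(q = 1e6), p,
                          qnq_phase("starvation"), duration = 28 * 24,
                          output_step = 24)
  expect_equal(traj$q, 1e6 * exp(-p$d_q * traj$time), tolerance = 1e-6)
  expect_equal(traj$q[nrow(traj)] / 1e6, 0.87, tolerance = 1e-6)
})

test_that("NQ survives starvation at least as well in the complex as in the simple environment", {
  p <- qnq_params(tau = 0)
  st <- population_state(nq = 1e6, recyclable = 6.4e5)
  horizon <- 7 * 24

  simple <- integrate_phase(st, p, qnq_phase("starvation", "simple"),
                            horizon, output_step = 12)
  complexe <- integrate_phase(st, p, qnq_phase("starvation", "complex"),
                              horizon, output_step = 12)
  expect_true(all(complexe$nq >= simple$nq - 1e-6))

  # cross-check both endpoints with a fine-grid Euler oracle
  for (env in c("simple", "complex")) {
    ph <- qnq_phase("starvation", env)
    oracle <- euler_integrate(function(t, y) starvation_rhs(y, p, ph),
                              c(q = 0, nq = 1e6, resource = 0,
                                recyclable = 6.4e5),
                              0, horizon, n_steps = 168000)
    got <- if (env == "simple") simple else complexe
    expect_equal(got$nq[nrow(got)], oracle[["nq"]], tolerance = 1e-3)
  }
})

test_that("lag schedule is linear in starvation weeks and matches the reported endpoints", {
  p <- qnq_params()
  expect_equal(lag_schedule(p, 0), c(q = 1.5, nq = 2.2))
  expect_equal(lag_schedule(p, 6), c(q = 1.6, nq = 9.4))

  pflat <- qnq_params(lag_q_slope = 0, lag_nq_slope = 0)
  expect_equal(lag_schedule(pflat, 5), c(q = 1.5, nq = 2.2))

  # negative slopes clamp at zero rather than going negative
  pneg <- qnq_params(lag_nq_slope = -1)
  expect_equal(lag_schedule(pneg, 5)[["nq"]], 0)
  expect_error(lag_schedule(p, -1), "non-negative")
})

test_that("regrowth derivatives gate each subpopulation by its own lag", {
  p <- qnq_params()
  lags <- c(q = 2, nq = 4)
  y <- regrowth_state(q_dormant = 1e6, nq_dormant = 1e6, active = 0,
                      resource = 3.2e7)

  expect_equal(unname(regrowth_rhs(y, p, t_elapsed = 1, lags)), rep(0, 5))

  d2 <- regrowth_rhs(y, p, t_elapsed = 2, lags)
  expect_equal(d2[["q_dormant"]], -p$wake_rate * 1e6)
  expect_equal(d2[["nq_dormant"]], 0)
  expect_equal(d2[["active"]], p$wake_rate * 1e6)

  d5 <- regrowth_rhs(regrowth_state(1e6, 1e6, 1e5, 3.2e7), p, 5, lags)
  expect_equal(d5[["nq_dormant"]], -p$wake_rate * 1e6)
  mu <- p$v_max * 3.2e7 / (p$k_m + 3.2e7)
  expect_equal(d5[["active"]], p$wake_rate * 2e6 + mu * 1e5)
  expect_equal(d5[["resource"]], -mu * 1e5)

  # no resource: biomass cannot increase whatever the lags say
  dry <- regrowth_rhs(regrowth_state(1e6, 1e6, 1e6, 0), p, 10, lags)
  expect_equal(dry[["active"]] + dry[["q_dormant"]] + dry[["nq_dormant"]], 0)
  expect_equal(dry[["resource"]], 0)

  expect_error(regrowth_rhs(y, p, -1, lags), "non-negative")
})

test_that("regrowth of an unlagged NQ culture is near-exponential and plateaus at initial + resource", {
  p <- qnq_params()
  n0 <- 1e5
  r0 <- 3.2e7
  traj <- integrate_phase(population_state(nq = n0, resource = r0), p,
                          qnq_phase("regrowth", lags = c(q = 0, nq = 0)),
                          duration = 40, output_step = 0.5)
  biomass <- traj$q + traj$nq
  # plateau: all resource converted (yield = 1)
  expect_equal(biomass[nrow(traj)], n0 + r0, tolerance = 1e-6)
  # early phase: exponential at the Monod-saturated rate after the brief
  # waking transient (resource still near r0 while biomass << r0)
  early <- traj[traj$time >= 2 & traj$time <= 6, ]
  rates <- diff(log(early$q + early$nq)) / diff(early$time)
  mu0 <- p$v_max * r0 / (p$k_m + r0)
  expect_equal(rates, rep(mu0, length(rates)), tolerance = 0.01)
})

test_that("trajectories keep states non-negative across random parameters and phases", {
  set.seed(42)
  for (i in 1:8) {
    d_q <- runif(1, 0, 5e-3)
    p <- qnq_params(v_max = runif(1, 0.1, 0.6), d_q = d_q,
                    d_nq = d_q + runif(1, 0, 1e-2),
                    tau = runif(1, 0, 5e-3), epsilon = runif(1),
                    sigma_max = runif(1, 0, 0.3))
    st <- population_state(q = runif(1, 0, 1e7), nq = runif(1, 1, 1e7),
                           resource = runif(1, 0, 4e7),
                           recyclable = runif(1, 0, 1e6))
    for (ph in list(qnq_phase("growth_differentiation"),
                    qnq_phase("starvation", sample(c("simple", "complex"),
                                                   1)),
                    qnq_phase("regrowth",
                              lags = c(q = runif(1, 0, 4),
                                       nq = runif(1, 0, 4))))) {
      traj <- integrate_phase(st, p, ph, duration = 36, output_step = 2)
      expect_true(all(traj$q >= 0 & traj$nq >= 0 & traj$resource >= 0 &
                        traj$recyclable >= 0))
    }
  }
})

test_that("cell-equivalents are conserved with perfect recycling and unit yield", {
  p <- qnq_params(epsilon = 1, yield = 1)
  st <- population_state(q = 5e6, nq = 5e6, resource = 1e7,
                         recyclable = 1e6)
  for (ph in list(qnq_phase("growth_differentiation"),
                  qnq_phase("starvation", "complex"),
                  qnq_phase("regrowth", lags = c(q = 1, nq = 3)))) {
    traj <- integrate_phase(st, p, ph, duration = 48, output_step = 4)
    total <- traj$q + traj$nq + traj$resource + traj$recyclable
    expect_equal(total, rep(total[1], length(total)), tolerance = 1e-7)
  }
})

test_that("without recycling, viable biomass never increases during starvation", {
  p <- qnq_params(epsilon = 0)
  traj <- integrate_phase(population_state(q = 1e6, nq = 1e6), p,
                          qnq_phase("starvation", "complex"),
                          duration = 7 * 24, output_step = 4)
  viable <- traj$q + traj$nq
  expect_true(all(diff(viable) <= 1e-6))
})

test_that("integrator output resolution and tolerance do not change the dynamics", {
  p <- qnq_params()
  st <- population_state(q = 2e6, nq = 2e6, recyclable = 6.4e5)
  ph <- qnq_phase("starvation", "complex")

  coarse <- integrate_phase(st, p, ph, duration = 48, output_step = 4)
  fine <- integrate_phase(st, p, ph, duration = 48, output_step = 2)
  shared <- fine[fine$time %in% coarse$time, ]
  expect_equal(shared$nq, coarse$nq, tolerance = 1e-7)

  loose <- integrate_phase(st, p, ph, 48, 4, rtol = 1e-8)
  tight <- integrate_phase(st, p, ph, 48, 4, rtol = 1e-9)
  b1 <- loose$q[nrow(loose)] + loose$nq[nrow(loose)]
  b2 <- tight$q[nrow(tight)] + tight$nq[nrow(tight)]
  expect_lt(abs(b1 - b2) / b2, 1e-3)
})

test_that("a zero-duration phase returns the initial state only", {
  st <- population_state(q = 1e5, nq = 2e5, resource = 3e5)
  traj <- integrate_phase(st, qnq_params(), qnq_phase("starvation"),
                          duration = 0)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$q, 1e5)
  expect_equal(traj$nq, 2e5)
  expect_equal(traj$resource, 3e5)
})

test_that("state and phase constructors reject invalid input", {
  expect_error(population_state(q = -1), "non-negative")
  expect_error(population_state(q = NaN), "finite")
  expect_error(qnq_phase("starvation", lags = c(q = 1)), "q and nq")
  expect_error(qnq_params(epsilon = 1.5), "epsilon")
  expect_error(qnq_params(d_q = 0.01, d_nq = 0.001), "d_q <= d_nq")
})
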