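# Independent fixed-step integrators used as oracles against the production
# lsoda path, plus small fixture builders shared across test files.

# classic RK4 with n_steps equal steps; rhs is function(t, y) -> dy/dt
rk4_integrate <- function(rhs, y0, t0, t1, n_steps) {
  h <- (t1 - t0) / n_steps
  y <- y0
  for (i in seq_len(n_steps)) {
    t <- t0 + (i - 1) * h
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# RK4 for the regrowth phase: integrates segment-wise between the lag times
# with the gates frozen per segment (the same discontinuity convention as the
# production solver: a gate switches on exactly at its lag).
rk4_regrowth <- function(y0, params, lags, t1, step) {
  bounds <- sort(unique(c(0, lags[lags > 0 & lags < t1], t1)))
  y <- y0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]
    b <- bounds[i + 1L]
    mid <- (a + b) / 2
    frozen <- c(q = if (mid >= lags[["q"]]) 0 else 1e9,
                nq = if (mid >= lags[["nq"]]) 0 else 1e9)
    rhs <- function(t, y) regrowth_rhs(pmax(y, 0), params, t, frozen)
    y <- rk4_integrate(rhs, y, a, b, max(1L, ceiling((b - a) / step)))
  }
  y
}

# forward-Euler on a fine grid: a second, cruder independent scheme for
# qualitative comparisons
euler_integrate <- function(rhs, y0, t0, t1, n_steps) {
  h <- (t1 - t0) / n_steps
  y <- y0
  for (i in seq_len(n_steps)) {
    y <- y + h * rhs(t0 + (i - 1) * h, y)
    y <- pmax(y, 0)
  }
  y
}

make_regrowth_vec <- function(state, active = 0) {
  c(q_dormant = state$q, nq_dormant = state$nq, active = active,
    resource = state$resource, recyclable = state$recyclable)
}

final_biomass <- function(assay) assay$biomass[nrow(assay)]

biomass_at <- function(assay, t) assay$biomass[abs(assay$time_h - t) < 1e-9]
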