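#' Population state of a starving yeast culture
#'
#' One instant of the model state. All quantities share the cell-equivalent
#' currency (cells per 200 ul well-equivalent): `resource` and `recyclable`
#' count the number of new cells each nutrient pool can yield at `yield = 1`,
#' so that `q + nq + resource + recyclable` is a conserved bookkeeping total
#' when recycling is perfect.
#'
#' @param q viable quiescent biomass (cells).
#' @param nq viable nonquiescent biomass (cells).
#' @param resource limiting nutrient of the fresh medium (cell-equivalents).
#' @param recyclable nutrient pool released by dead cells or present in spent
#'   medium (cell-equivalents).
#' @return An object of class `qnq_state`.
#' @examples
#' population_state(q = 1e6, nq = 1e6, resource = 3.2e7)
#' @export
population_state <- function(q = 0, nq = 0, resource = 0, recyclable = 0) {
  vals <- c(q = q, nq = nq, resource = resource, recyclable = recyclable)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals))) {
    stop("state components must be single finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("state components must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "qnq_state")
}

#' @export
print.qnq_state <- function(x, ...) {
  cat(sprintf(
    "Q/NQ state: q = %.4g, nq = %.4g, resource = %.4g, recyclable = %.4g\n",
    x$q, x$nq, x$resource, x$recyclable))
  invisible(x)
}

state_vec <- function(state) {
  if (inherits(state, "qnq_state")) {
    c(q = state$q, nq = state$nq, resource = state$resource,
      recyclable = state$recyclable)
  } else if (is.numeric(state) &&
             all(c("q", "nq", "resource", "recyclable") %in% names(state))) {
    state[c("q", "nq", "resource", "recyclable")]
  } else {
    stop("expected a qnq_state or a named numeric vector with components ",
         "q, nq, resource, recyclable", call. = FALSE)
  }
}

assert_state_nonneg <- function(y) {
  if (any(!is.finite(y))) stop("state contains non-finite values",
                               call. = FALSE)
  if (any(y < 0)) stop("state components must be non-negative", call. = FALSE)
  invisible(y)
}

#' Dynamical phase descriptor
#'
#' Labels which regime of the model applies and carries the phase-specific
#' context: the starvation environment (`"simple"`, sterile water, where the
#' recyclable pool is inert; or `"complex"`, spent medium, where it is both
#' fed by dead cells and consumed by NQ cells) and, for regrowth, either the
#' number of starvation weeks used by [lag_schedule()] or explicit lags.
#'
#' @param label one of `"growth_differentiation"`, `"starvation"`,
#'   `"regrowth"`.
#' @param environment `"simple"` or `"complex"` (used in starvation).
#' @param starvation_weeks weeks of starvation preceding regrowth (sets lags
#'   through [lag_schedule()] unless `lags` is given).
#' @param lags optional named vector `c(q =, nq =)` of growth-onset lags in
#'   hours, overriding the schedule (used by the short-starvation protocol).
#' @return An object of class `qnq_phase`.
#' @export
qnq_phase <- function(label = c("growth_differentiation", "starvation",
                                "regrowth"),
                      environment = c("simple", "complex"),
                      starvation_weeks = 0, lags = NULL) {
  label <- match.arg(label)
  environment <- match.arg(environment)
  if (!is.numeric(starvation_weeks) || starvation_weeks < 0) {
    stop("'starvation_weeks' must be non-negative", call. = FALSE)
  }
  if (!is.null(lags)) {
    if (!is.numeric(lags) || !all(c("q", "nq") %in% names(lags)) ||
        any(lags[c("q", "nq")] < 0)) {
      stop("'lags' must be a named non-negative vector with elements q and nq",
           call. = FALSE)
    }
    lags <- lags[c("q", "nq")]
  }
  structure(list(label = label, environment = environment,
                 starvation_weeks = starvation_weeks, lags = lags),
            class = "qnq_phase")
}

monod <- function(resource, p) p$v_max * resource / (p$k_m + resource)

# unvalidated kernels shared by the exported rhs functions and the solver
# (the solver validates parameters once, not per step)
.growth_rhs <- function(y, p) {
  growth <- monod(y[["resource"]], p) * y[["nq"]]
  sigma <- p$sigma_max * p$k_diff / (p$k_diff + y[["resource"]])
  c(q = sigma * y[["nq"]],
    nq = growth - sigma * y[["nq"]],
    resource = -growth / p$yield,
    recyclable = 0)
}

.starvation_rhs <- function(y, p, complex_env) {
  eps_eff <- if (complex_env) p$epsilon else 0
  u <- y[["recyclable"]]
  uptake_rate <- if (complex_env) p$v_max * u / (p$k_m + u) else 0
  growth <- uptake_rate * y[["nq"]]
  death <- p$d_q * y[["q"]] + p$d_nq * y[["nq"]]
  c(q = -(p$d_q + p$tau) * y[["q"]],
    nq = -p$d_nq * y[["nq"]] + p$tau * y[["q"]] + growth,
    resource = 0,
    recyclable = eps_eff * death - growth / p$yield)
}

.regrowth_rhs <- function(y, p, t_elapsed, lags) {
  g_q <- lag_gate(t_elapsed, lags[["q"]], p)
  g_nq <- lag_gate(t_elapsed, lags[["nq"]], p)
  wake_q <- g_q * p$wake_rate * y[["q_dormant"]]
  wake_nq <- g_nq * p$wake_rate * y[["nq_dormant"]]
  growth <- monod(y[["resource"]], p) * y[["active"]]
  c(q_dormant = -wake_q,
    nq_dormant = -wake_nq,
    active = wake_q + wake_nq + growth,
    resource = -growth / p$yield,
    recyclable = 0)
}

#' Right-hand side of the growth/differentiation phase
#'
#' Batch growth on the limiting resource with Monod kinetics. Differentiation
#' of NQ cells into quiescence proceeds at rate
#' `sigma_max * k_diff / (k_diff + R)`: negligible while the resource is
#' plentiful and maximal near depletion, so quiescence entry begins as
#' nutrients run out and is not instantaneous. No cells die in this phase and
#' the recyclable pool is untouched.
#'
#' @param state a [population_state()] (or named numeric vector).
#' @param params a [qnq_params()] object.
#' @return Named numeric derivative (per hour) with components `q`, `nq`,
#'   `resource`, `recyclable`.
#' @export
growth_rhs <- function(state, params) {
  y <- assert_state_nonneg(state_vec(state))
  .growth_rhs(y, validate_params(params))
}

#' Right-hand side of the starvation phase
#'
#' Q cells neither divide nor feed: they die at rate `d_q` and convert to NQ
#' at rate `tau`. NQ cells die at rate `d_nq` and, in the complex environment
#' only, divide on the recyclable pool with Monod kinetics; a fraction
#' `epsilon` of all dead biomass is returned to that pool. In the simple
#' environment (sterile water) the recyclable pool is inert: dead biomass is
#' not reusable there because the medium cannot supply the remaining
#' nutrients needed for growth. The fresh-medium resource is absent during
#' starvation.
#'
#' @inheritParams growth_rhs
#' @param phase a [qnq_phase()] with label `"starvation"`; its `environment`
#'   selects whether recycling operates.
#' @return Named numeric derivative (per hour), as in [growth_rhs()].
#' @export
starvation_rhs <- function(state, params, phase) {
  if (!inherits(phase, "qnq_phase") || phase$label != "starvation") {
    stop("'phase' must be a qnq_phase with label \"starvation\"",
         call. = FALSE)
  }
  y <- assert_state_nonneg(state_vec(state))
  .starvation_rhs(y, validate_params(params),
                  phase$environment == "complex")
}

#' Growth-onset lags after a given starvation length
#'
#' The lag of each subpopulation grows linearly with starvation time:
#' `lag = lag0 + slope * weeks`, clamped at zero. Defaults interpolate the
#' reported monoculture lags: Q from 1.5 h at week 0 to 1.6 h at week 6, NQ
#' from 2.2 h to 9.4 h.
#'
#' @param params a [qnq_params()] object.
#' @param starvation_weeks non-negative number of weeks starved.
#' @return Named numeric vector `c(q =, nq =)` of lags in hours.
#' @examples
#' lag_schedule(qnq_params(), 6)  # c(q = 1.6, nq = 9.4)
#' @export
lag_schedule <- function(params, starvation_weeks) {
  p <- validate_params(params)
  if (!is.numeric(starvation_weeks) || any(starvation_weeks < 0)) {
    stop("'starvation_weeks' must be non-negative", call. = FALSE)
  }
  c(q = pmax(0, p$lag_q0 + p$lag_q_slope * starvation_weeks),
    nq = pmax(0, p$lag_nq0 + p$lag_nq_slope * starvation_weeks))
}

#' Regrowth state with explicit dormant and active pools
#'
#' During regrowth on fresh medium each subpopulation stays dormant until its
#' lag has passed and then joins a common actively dividing pool, so the
#' integration state separates dormant Q, dormant NQ, and active cells.
#' [integrate_phase()] builds this from a [population_state()] (all cells
#' dormant, none active) and maps trajectories back to `q` and `nq` with
#' `nq = nq_dormant + active`.
#'
#' @param q_dormant,nq_dormant dormant (still lagged) Q and NQ biomass.
#' @param active actively dividing biomass (cells).
#' @param resource fresh-medium resource (cell-equivalents).
#' @param recyclable carried-over recyclable pool (inert during regrowth).
#' @return An object of class `qnq_regrowth_state`.
#' @export
regrowth_state <- function(q_dormant = 0, nq_dormant = 0, active = 0,
                           resource = 0, recyclable = 0) {
  vals <- c(q_dormant = q_dormant, nq_dormant = nq_dormant, active = active,
            resource = resource, recyclable = recyclable)
  if (!is.numeric(vals) || length(vals) != 5L || any(!is.finite(vals)) ||
      any(vals < 0)) {
    stop("regrowth state components must be single non-negative numbers",
         call. = FALSE)
  }
  structure(as.list(vals), class = "qnq_regrowth_state")
}

regrowth_vec <- function(state) {
  nms <- c("q_dormant", "nq_dormant", "active", "resource", "recyclable")
  if (inherits(state, "qnq_regrowth_state")) {
    unlist(state[nms])
  } else if (is.numeric(state) && all(nms %in% names(state))) {
    state[nms]
  } else {
    stop("expected a qnq_regrowth_state or a named numeric vector with ",
         "components ", paste(nms, collapse = ", "), call. = FALSE)
  }
}

lag_gate <- function(t, lag, params) {
  if (params$lag_gate == "hard") as.numeric(t >= lag)
  else plogis((t - lag) / params$gate_width)
}

#' Right-hand side of the regrowth phase
#'
#' Standard Monod kinetics on fresh medium, with starvation-dependent lags:
#' each dormant subpopulation starts waking into the actively dividing pool
#' at rate `wake_rate` once `t_elapsed` exceeds its own lag; active cells
#' divide at `v_max * R / (k_m + R)` and consume the resource. There is no
#' death over the 24 h regrowth window and the recyclable pool is inert.
#'
#' @param state a [regrowth_state()] (or named numeric vector).
#' @inheritParams growth_rhs
#' @param t_elapsed time (h) since transfer to fresh medium; must be >= 0.
#' @param lags named vector `c(q =, nq =)` of growth-onset lags in hours, as
#'   produced by [lag_schedule()].
#' @return Named numeric derivative (per hour) with the components of
#'   [regrowth_state()].
#' @export
regrowth_rhs <- function(state, params, t_elapsed, lags) {
  if (!is.numeric(t_elapsed) || length(t_elapsed) != 1L || t_elapsed < 0) {
    stop("'t_elapsed' must be a single non-negative time in hours",
         call. = FALSE)
  }
  if (!all(c("q", "nq") %in% names(lags)) || any(lags[c("q", "nq")] < 0)) {
    stop("'lags' must be a named non-negative vector with elements q and nq",
         call. = FALSE)
  }
  y <- regrowth_vec(state)
  assert_state_nonneg(y)
  .regrowth_rhs(y, validate_params(params), t_elapsed, lags)
}

#' Integrate one model phase
#'
#' Solves the phase dynamics from `state0` over `duration` hours with the
#' adaptive stiff-capable `lsoda` solver, reporting the state on a uniform
#' output grid. For regrowth with the hard lag gate, integration is split at
#' the lag times so the solver never steps across a discontinuity. Small
#' negative undershoots (below `atol` in magnitude) are clipped to zero;
#' larger ones, or non-finite states, raise an integration error naming the
#' phase.
#'
#' @param state0 a [population_state()] at the start of the phase.
#' @inheritParams growth_rhs
#' @param phase a [qnq_phase()].
#' @param duration phase length in hours (0 returns the initial state only).
#' @param output_step output grid spacing in hours; the final time is always
#'   included.
#' @param rtol,atol relative and absolute solver tolerances (absolute
#'   tolerance in cells).
#' @return A data frame of class `qnq_trajectory` with columns `time`, `q`,
#'   `nq`, `resource`, `recyclable` and, for regrowth, the underlying
#'   `q_dormant`, `nq_dormant`, `active` pools (`q = q_dormant`,
#'   `nq = nq_dormant + active`).
#' @examples
#' traj <- integrate_phase(population_state(q = 1e6),
#'                         qnq_params(tau = 0),
#'                         qnq_phase("starvation"), duration = 168,
#'                         output_step = 24)
#' tail(traj, 1)$q / 1e6  # one-week survival fraction of pure Q
#' @export
integrate_phase <- function(state0, params, phase, duration,
                            output_step = 0.5, rtol = 1e-8, atol = 1e-2) {
  p <- validate_params(params)
  if (!inherits(phase, "qnq_phase")) stop("'phase' must be a qnq_phase",
                                          call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0) {
    stop("'duration' must be a single non-negative number of hours",
         call. = FALSE)
  }
  y0 <- assert_state_nonneg(state_vec(state0))

  times <- seq(0, duration, by = output_step)
  if (abs(times[length(times)] - duration) > 1e-12) times <- c(times, duration)

  if (duration == 0) {
    out <- data.frame(time = 0, q = y0[["q"]], nq = y0[["nq"]],
                      resource = y0[["resource"]],
                      recyclable = y0[["recyclable"]])
    return(finish_trajectory(out, phase))
  }

  if (phase$label == "regrowth") {
    lags <- phase$lags
    if (is.null(lags)) lags <- lag_schedule(p, phase$starvation_weeks)
    z0 <- c(q_dormant = y0[["q"]], nq_dormant = y0[["nq"]], active = 0,
            resource = y0[["resource"]], recyclable = y0[["recyclable"]])
    func <- function(t, y, parms) {
      list(.regrowth_rhs(pmax(y, 0), p, max(t, 0), lags))
    }
    breaks <- if (p$lag_gate == "hard") {
      sort(unique(lags[lags > 0 & lags < duration]))
    } else numeric(0)
    raw <- integrate_segmented(z0, func, times, breaks, rtol, atol, phase)
    raw <- clip_undershoot(raw, atol, phase)
    out <- data.frame(time = raw[, "time"],
                      q = raw[, "q_dormant"],
                      nq = raw[, "nq_dormant"] + raw[, "active"],
                      resource = raw[, "resource"],
                      recyclable = raw[, "recyclable"],
                      q_dormant = raw[, "q_dormant"],
                      nq_dormant = raw[, "nq_dormant"],
                      active = raw[, "active"])
    return(finish_trajectory(out, phase))
  }

  func <- if (phase$label == "starvation") {
    complex_env <- phase$environment == "complex"
    function(t, y, parms) list(.starvation_rhs(pmax(y, 0), p, complex_env))
  } else {
    function(t, y, parms) list(.growth_rhs(pmax(y, 0), p))
  }
  raw <- integrate_segmented(y0, func, times, numeric(0), rtol, atol, phase)
  raw <- clip_undershoot(raw, atol, phase)
  out <- as.data.frame(raw[, c("time", "q", "nq", "resource", "recyclable")])
  finish_trajectory(out, phase)
}

# run lsoda piecewise so that hard-gate discontinuities fall on segment
# boundaries; returns a matrix with a `time` column at the requested times
integrate_segmented <- function(y0, func, times, breaks, rtol, atol, phase) {
  bounds <- sort(unique(c(times[1], breaks, times[length(times)])))
  rows <- list()
  y <- y0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]
    b <- bounds[i + 1L]
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    sol <- tryCatch(
      deSolve::ode(y = y, times = seg_times, func = func, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) stop("integration failed in phase '",
                                 phase$label, "': ", conditionMessage(w),
                                 call. = FALSE),
      error = function(e) stop("integration failed in phase '",
                               phase$label, "': ", conditionMessage(e),
                               call. = FALSE)
    )
    sol <- unclass(sol)
    if (any(!is.finite(sol))) {
      stop("integration produced non-finite state in phase '", phase$label,
           "'", call. = FALSE)
    }
    rows[[i]] <- sol[if (i == 1L) TRUE else -1L, , drop = FALSE]
    y <- sol[nrow(sol), -1L]
    names(y) <- names(y0)
  }
  out <- do.call(rbind, rows)
  out[out[, "time"] %in% times, , drop = FALSE]
}

clip_undershoot <- function(raw, atol, phase) {
  states <- raw[, -1L, drop = FALSE]
  if (any(states < -atol)) {
    stop("integration undershoot below -atol in phase '", phase$label, "'",
         call. = FALSE)
  }
  raw[, -1L] <- pmax(states, 0)
  raw
}

finish_trajectory <- function(df, phase) {
  attr(df, "phase") <- phase
  class(df) <- c("qnq_trajectory", "data.frame")
  df
}

#' Extract the final state of a trajectory
#'
#' @param trajectory a `qnq_trajectory` from [integrate_phase()].
#' @return A [population_state()] at the last time point.
#' @export
final_state <- function(trajectory) {
  last <- trajectory[nrow(trajectory), ]
  population_state(q = last$q, nq = last$nq, resource = last$resource,
                   recyclable = last$recyclable)
}
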