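#' Calibrate an exponential death rate from a surviving fraction
#'
#' Solves `exp(-d * duration) = surviving_fraction` for the death rate `d`.
#' The model's default death rates come from the 4-week colony-forming
#' viabilities of starved cells: 87% for Q and 3% for NQ, giving about
#' 0.005/day and 0.125/day respectively.
#'
#' @param surviving_fraction fraction of cells still viable, in `(0, 1]`.
#' @param duration starvation length in days.
#' @return Death rate per day. Divide by 24 for the per-hour rate used in
#'   [qnq_params()].
#' @examples
#' calibrate_death_rate(0.87, 28)  # Q cells
#' calibrate_death_rate(0.03, 28)  # NQ cells
#' @export
calibrate_death_rate <- function(surviving_fraction, duration) {
  if (!is.numeric(surviving_fraction) || any(surviving_fraction <= 0) ||
      any(surviving_fraction > 1)) {
    stop("'surviving_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(duration) || any(duration <= 0)) {
    stop("'duration' must be positive", call. = FALSE)
  }
  -log(surviving_fraction) / duration
}

#' Differential-evolution global minimiser
#'
#' A classic rand/1/bin differential-evolution optimiser over box
#' constraints: each generation builds, for every population member, a
#' mutant `x_r1 + f * (x_r2 - x_r3)` from three distinct other members,
#' recombines it coordinate-wise with probability `cr` (always inheriting at
#' least one mutant coordinate), clips to the bounds, and keeps the better
#' of parent and trial. Used by [fit_parameters()] to calibrate model
#' parameters against plate data.
#'
#' @param fn objective function of a numeric parameter vector; must return a
#'   finite scalar (use a large finite penalty for failures).
#' @param lower,upper numeric bounds, equal length.
#' @param control list of optimiser settings: `np` population size (default
#'   `10 * length(lower)`), `f` differential weight (0.8), `cr` crossover
#'   probability (0.9), `maxiter` generations (200), `stall` generations
#'   without relative improvement `reltol` (1e-8) that trigger early stopping
#'   (30), `seed` RNG seed for reproducibility, `trace` print progress.
#' @return List with `par`, `value`, `trace` (best objective per generation,
#'   non-increasing), `n_evaluations`, `converged`, `seed`.
#' @examples
#' de_optimize(function(x) sum((x - 3)^2), lower = c(-10, -10),
#'             upper = c(10, 10), control = list(seed = 1, maxiter = 50))
#' @export
de_optimize <- function(fn, lower, upper, control = list()) {
  d <- length(lower)
  if (length(upper) != d || d < 1L) {
    stop("'lower' and 'upper' must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower)) {
    stop("bounds must be finite with upper > lower", call. = FALSE)
  }
  ctl <- modifyList(list(np = 10L * d, f = 0.8, cr = 0.9, maxiter = 200L,
                         stall = 30L, reltol = 1e-8, seed = NULL,
                         trace = FALSE), control)
  if (ctl$np < 4L) stop("population size 'np' must be at least 4",
                        call. = FALSE)
  if (!is.null(ctl$seed)) set.seed(ctl$seed)

  pop <- matrix(runif(ctl$np * d, rep(lower, each = ctl$np),
                      rep(upper, each = ctl$np)), nrow = ctl$np)
  fit <- apply(pop, 1L, fn)
  if (any(!is.finite(fit))) {
    stop("objective returned a non-finite value; return a large finite ",
         "penalty instead", call. = FALSE)
  }
  n_eval <- ctl$np
  trace <- numeric(ctl$maxiter)
  converged <- FALSE
  last_gen <- 0L
  stall_ref <- min(fit)

  for (gen in seq_len(ctl$maxiter)) {
    for (i in seq_len(ctl$np)) {
      r <- sample(seq_len(ctl$np)[-i], 3L)
      mutant <- pop[r[1L], ] + ctl$f * (pop[r[2L], ] - pop[r[3L], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- runif(d) < ctl$cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      f_trial <- fn(trial)
      n_eval <- n_eval + 1L
      if (is.finite(f_trial) && f_trial <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
    trace[gen] <- min(fit)
    last_gen <- gen
    if (ctl$trace) {
      message(sprintf("DE generation %d: best objective %.6g", gen,
                      trace[gen]))
    }
    if (gen >= ctl$stall) {
      ref <- if (gen == ctl$stall) stall_ref else trace[gen - ctl$stall]
      if (ref - trace[gen] <= ctl$reltol * max(abs(ref), 1e-300)) {
        converged <- TRUE
        break
      }
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], trace = trace[seq_len(last_gen)],
       n_evaluations = n_eval, converged = converged, seed = ctl$seed)
}

#' Fit model parameters to plate-reader data
#'
#' Calibrates a chosen set of free parameters by minimising the sum of
#' squared residuals between simulated and observed biomass over every
#' culture, week, replicate, and time point, with [de_optimize()]. The
#' simulation path is exactly the one of the scenarios module:
#' [run_long_starvation()] for data with weeks >= 1 and
#' [run_short_starvation()] for week-0 (short-protocol) data, one scenario
#' per culture type and environment present in the data. Residuals are
#' computed on biomass (cells) by default, matching the converted-biomass
#' analyses; set `residual_space = "od"` for OD-space residuals. Simulation
#' failures inside the objective are penalised with a large finite value.
#'
#' @param data a plate-series data frame (see [generate_plate_dataset()])
#'   with columns `culture_type`, `environment`, `replicate`, `week`,
#'   `time_h`, and `od` or `biomass`.
#' @param free named list of `c(lower, upper)` bounds, one per free
#'   parameter; names must be numeric scalar fields of [qnq_params()].
#' @param fixed a [qnq_params()] holding every non-free parameter.
#' @param scenario_template a [qnq_scenario()] supplying protocol geometry
#'   (freezing flag, OD, transfer volumes); composition, environment and
#'   weeks are taken from the data.
#' @param control optimiser control list, see [de_optimize()].
#' @param residual_space `"biomass"` (default) or `"od"`.
#' @return An object of class `qnq_fit`: list with `best_params` (full
#'   parameter set with fitted values substituted), `par`, `objective`,
#'   `n_evaluations`, `converged`, `bounds`, `trace`, `seed`.
#' @export
fit_parameters <- function(data, free, fixed = qnq_params(),
                           scenario_template = qnq_scenario(),
                           control = list(),
                           residual_space = c("biomass", "od")) {
  residual_space <- match.arg(residual_space)
  if (!length(free)) stop("the free-parameter set must be non-empty",
                          call. = FALSE)
  if (is.null(names(free)) || any(!nzchar(names(free)))) {
    stop("'free' must be a named list of c(lower, upper) bounds",
         call. = FALSE)
  }
  bad <- names(free)[!vapply(free, function(b)
    is.numeric(b) && length(b) == 2L && all(is.finite(b)) && b[2] > b[1],
    logical(1))]
  if (length(bad)) stop("invalid bounds for: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  fixed <- validate_params(fixed)
  unknown <- setdiff(names(free), names(unclass(fixed)))
  if (length(unknown)) stop("unknown parameter(s) in 'free': ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data)
  need <- c("culture_type", "environment", "replicate", "week", "time_h")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(data$biomass)) {
    if (is.null(data$od)) stop("data needs an 'od' or 'biomass' column",
                               call. = FALSE)
    data$biomass <- od_to_biomass(data$od)
  }
  obs_col <- if (residual_space == "biomass") "biomass" else "od"
  if (obs_col == "od" && is.null(data$od)) {
    stop("OD-space residuals need an 'od' column", call. = FALSE)
  }

  groups <- split(data, interaction(data$culture_type, data$environment,
                                    drop = TRUE))
  specs <- lapply(groups, function(g) {
    weeks <- sort(unique(g$week))
    long <- any(weeks >= 1)
    scen <- scenario_template
    scen$composition <- as.character(g$culture_type[1])
    scen$environment <- as.character(g$environment[1])
    scen$starvation_weeks <- max(weeks)
    if (!long) {
      scen$freezing <- FALSE
      scen$initial_od <- 0.4
    }
    list(scenario = scen, long = long, obs = g)
  })

  penalty <- 1e30
  free_names <- names(free)
  n_fail <- 0L

  objective <- function(theta) {
    p <- unclass(fixed)
    p[free_names] <- theta
    p <- tryCatch(validate_params(structure(p, class = "qnq_params")),
                  error = function(e) NULL)
    if (is.null(p)) return(penalty)
    total <- 0
    for (sp in specs) {
      sims <- tryCatch({
        if (sp$long) run_long_starvation(sp$scenario, p)
        else list(run_short_starvation(sp$scenario, p))
      }, error = function(e) NULL)
      if (is.null(sims)) {
        n_fail <<- n_fail + 1L
        return(penalty)
      }
      for (k in seq_along(sims)) {
        assay <- sims[[k]]
        wk <- attr(assay, "week")
        obs <- sp$obs[sp$obs$week == wk, ]
        if (!nrow(obs)) next
        idx <- match(round(obs$time_h, 6), round(assay$time_h, 6))
        if (anyNA(idx)) {
          stop("observed time points not on the simulated grid",
               call. = FALSE)
        }
        sim_vals <- if (obs_col == "biomass") assay$biomass[idx]
                    else assay$od[idx]
        total <- total + sum((sim_vals - obs[[obs_col]])^2)
      }
    }
    total
  }

  lower <- vapply(free, `[`, numeric(1), 1L)
  upper <- vapply(free, `[`, numeric(1), 2L)
  res <- de_optimize(objective, lower, upper, control)
  if (n_fail > 0L) {
    message("fit_parameters: ", n_fail,
            " objective evaluation(s) failed and were penalised")
  }

  best <- unclass(fixed)
  best[free_names] <- res$par
  best <- validate_params(structure(best, class = "qnq_params"))
  structure(list(best_params = best,
                 par = setNames(res$par, free_names),
                 objective = res$value,
                 n_evaluations = res$n_evaluations,
                 converged = res$converged,
                 bounds = free,
                 trace = res$trace,
                 seed = res$seed,
                 residual_space = residual_space),
            class = "qnq_fit")
}

#' @export
print.qnq_fit <- function(x, ...) {
  cat("Q/NQ model fit (differential evolution)\n")
  cat("  fitted parameters:\n")
  for (nm in names(x$par)) {
    cat(sprintf("    %s = %.6g  (bounds %.4g .. %.4g)\n", nm, x$par[[nm]],
                x$bounds[[nm]][1], x$bounds[[nm]][2]))
  }
  cat(sprintf("  objective (sum sq. residuals, %s space): %.6g\n",
              x$residual_space, x$objective))
  cat(sprintf("  evaluations: %d; converged: %s; seed: %s\n",
              x$n_evaluations, x$converged,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Serialise a fit result to JSON
#'
#' Writes the fitted values, bounds, objective, optimiser trace and seed so
#' a fit can be archived next to the data it was computed from.
#'
#' @param fit a `qnq_fit` from [fit_parameters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "qnq_fit"))
  out <- list(par = as.list(fit$par),
              bounds = fit$bounds,
              objective = fit$objective,
              n_evaluations = fit$n_evaluations,
              converged = fit$converged,
              trace = fit$trace,
              seed = fit$seed,
              residual_space = fit$residual_space,
              best_params = unclass(fit$best_params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
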