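#' Default pipeline configuration
#'
#' A complete, runnable configuration for [run_pipeline()]: the full study
#' design with default model parameters and noise, analysis time points at
#' 2 h, 10 h and 24 h of regrowth (early regrowth, the time at which slow
#' cultures catch up, and the plateau), and no fitting stage.
#'
#' @param seed integer seed controlling every random draw of the run.
#' @return A named list understood by [validate_config()] and
#'   [run_pipeline()]. Fields: `seed`; `params` (named overrides for
#'   [qnq_params()]); `scenarios` (arguments of [qnq_default_scenarios()]);
#'   `noise` (arguments of [noise_model()], seed excluded); `data_file`
#'   (optional CSV to analyse instead of generating); `analysis_times`
#'   (regrowth hours at which biomass is compared across cultures);
#'   `lag_delta_od` (threshold of the lag rule); `fit` (optional list with
#'   `free` bounds and `control` for [fit_parameters()]).
#' @export
qnq_default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       params = list(),
       scenarios = list(include_short = TRUE, starvation_weeks = 6,
                        n_replicates = 5),
       noise = list(sigma_add = 0.005, sigma_mult = 0.01,
                    replicate_effect_sd = 0.25),
       data_file = NULL,
       analysis_times = c(2, 10, 24),
       lag_delta_od = 0.01,
       fit = NULL)
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [qnq_default_config()] values.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file must be a mapping", call. = FALSE)
  cfg <- modifyList(qnq_default_config(), user)
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns a character vector of blocking issues, each naming the offending
#' field; an empty vector means the configuration is executable. A negative
#' lag slope is allowed (lags are clamped at zero) but raises a warning.
#'
#' @param config a configuration list as from [qnq_default_config()].
#' @return Character vector of issues (empty if valid).
#' @examples
#' validate_config(qnq_default_config())          # character(0)
#' validate_config(list(seed = 1, params = list(epsilon = 1.5)))
#' @export
validate_config <- function(config) {
  issues <- character(0)
  config <- modifyList(qnq_default_config(), config)
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      !is.finite(config$seed) || config$seed != round(config$seed)) {
    issues <- c(issues, "seed: must be a single integer")
  }
  p <- tryCatch(do.call(qnq_params, config$params), error = function(e) e)
  if (inherits(p, "error")) {
    issues <- c(issues, paste0("params: ", conditionMessage(p)))
  } else {
    for (nm in c("lag_q_slope", "lag_nq_slope")) {
      if (p[[nm]] < 0) {
        warning("params$", nm, " is negative; lags are clamped at 0 and ",
                "will not decrease below it", call. = FALSE)
      }
    }
  }
  sc <- tryCatch(do.call(qnq_default_scenarios, config$scenarios),
                 error = function(e) e)
  if (inherits(sc, "error")) {
    issues <- c(issues, paste0("scenarios: ", conditionMessage(sc)))
  }
  nz <- tryCatch(do.call(noise_model, c(config$noise, list(seed = 1L))),
                 error = function(e) e)
  if (inherits(nz, "error")) {
    issues <- c(issues, paste0("noise: ", conditionMessage(nz)))
  }
  if (!is.null(config$data_file) && !file.exists(config$data_file)) {
    issues <- c(issues, paste0("data_file: file not found: ",
                               config$data_file))
  }
  if (!is.numeric(config$analysis_times) || !length(config$analysis_times) ||
      any(config$analysis_times < 0)) {
    issues <- c(issues, "analysis_times: must be non-negative hours")
  }
  if (!is.numeric(config$lag_delta_od) || config$lag_delta_od <= 0) {
    issues <- c(issues, "lag_delta_od: must be a positive OD increment")
  }
  if (!is.null(config$fit)) {
    if (!is.list(config$fit) || is.null(config$fit$free) ||
        !length(config$fit$free)) {
      issues <- c(issues, "fit: needs a non-empty 'free' bounds list")
    }
  }
  issues
}

#' Lag-length table of a plate series
#'
#' Estimates the lag of every well curve by the OD-increment threshold rule
#' and by the maximum-growth-rate rule.
#'
#' @param data a plate-series data frame (columns `culture_type`,
#'   `environment`, `replicate`, `week`, `time_h`, `od`).
#' @param delta_od OD increment of the threshold rule.
#' @return Data frame with one row per curve: `culture_type`, `environment`,
#'   `replicate`, `week`, `lag_threshold`, `lag_max_growth` (`NA` where the
#'   estimate is undefined).
#' @export
lag_table <- function(data, delta_od = 0.01) {
  data <- as.data.frame(data)
  keys <- interaction(data$culture_type, data$environment, data$replicate,
                      data$week, drop = TRUE)
  rows <- lapply(split(data, keys), function(d) {
    d <- d[order(d$time_h), ]
    curve <- growth_curve(d$time_h, od = d$od)
    data.frame(culture_type = d$culture_type[1],
               environment = d$environment[1],
               replicate = d$replicate[1], week = d$week[1],
               lag_threshold = lag_threshold(curve, delta_od),
               lag_max_growth = lag_max_growth(curve))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$environment, out$culture_type, out$week, out$replicate), ]
}

biomass_at_times <- function(data, times) {
  data <- data[data$time_h %in% times, ]
  data$biomass <- od_to_biomass(data$od)
  data
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a plate dataset, runs the growth-curve analytics
#' (lag tables, relative biomass against the mixed reference, complex/simple
#' environment ratios), the group statistics (one-way ANOVA with Tukey HSD
#' on biomass at the configured regrowth time points, and Q-vs-NQ lag
#' t tests per week), and optionally a parameter fit, writing every table as
#' CSV plus a JSON run summary and a plain-text log into `output_dir`. Every
#' output is deterministic given the configuration seed.
#'
#' @param config configuration list, see [qnq_default_config()].
#' @param output_dir directory for the report bundle (created if needed).
#' @return Invisibly, a list with the output paths and the in-memory tables.
#' @export
run_pipeline <- function(config = qnq_default_config(),
                         output_dir = tempfile("qnq_run_")) {
  config <- modifyList(qnq_default_config(), config)
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  config_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  params <- do.call(qnq_params, config$params)

  # stage: data
  if (!is.null(config$data_file)) {
    note("stage data: reading ", config$data_file)
    plate <- read_plate_csv(config$data_file)
  } else {
    note("stage data: generating synthetic plate dataset (seed ",
         config$seed, ")")
    noise <- do.call(noise_model, c(config$noise, list(seed = config$seed)))
    scenarios <- do.call(qnq_default_scenarios, config$scenarios)
    plate <- generate_plate_dataset(params, scenarios, noise)
    n_trunc <- attr(plate, "metadata")$n_truncated
    if (n_trunc > 0) note("stage data: ", n_trunc,
                          " noise-truncated OD readings")
  }
  paths <- list(plate = file.path(output_dir, "plate.csv"))
  write_plate_csv(plate, paths$plate)

  # stage: lag estimates
  note("stage curves: lag estimation")
  lags <- lag_table(plate, delta_od = config$lag_delta_od)
  n_sentinel <- sum(is.na(lags$lag_threshold))
  if (n_sentinel > 0) note("stage curves: ", n_sentinel,
                           " curve(s) never reached the OD threshold")
  paths$lags <- file.path(output_dir, "lags.csv")
  utils::write.csv(lags, paths$lags, row.names = FALSE)

  # stage: relative biomass vs the mixed reference
  note("stage curves: relative biomass vs mixed reference")
  rel_rows <- list()
  for (env in unique(plate$environment)) {
    for (wk in unique(plate$week[plate$environment == env])) {
      sub <- plate[plate$environment == env & plate$week == wk, ]
      if (!any(sub$culture_type == "mixed")) next
      rel <- relative_biomass_vs_mixed(sub)
      rel_rows[[length(rel_rows) + 1L]] <- rel
    }
  }
  rel_mixed <- do.call(rbind, rel_rows)
  paths$relative_mixed <- file.path(output_dir, "relative_biomass_mixed.csv")
  utils::write.csv(rel_mixed, paths$relative_mixed, row.names = FALSE)

  # stage: complex vs simple environment ratios (long-starvation weeks)
  rel_env <- NULL
  weeks_both <- intersect(unique(plate$week[plate$environment == "simple"]),
                          unique(plate$week[plate$environment == "complex"]))
  weeks_both <- weeks_both[weeks_both >= 1]
  if (length(weeks_both)) {
    note("stage curves: complex/simple biomass ratios")
    env_rows <- lapply(sort(weeks_both), function(wk) {
      cx <- plate[plate$environment == "complex" & plate$week == wk, ]
      sx <- plate[plate$environment == "simple" & plate$week == wk, ]
      out <- relative_biomass_env(cx, sx)
      out$week <- wk
      out
    })
    rel_env <- do.call(rbind, env_rows)
    paths$relative_env <- file.path(output_dir, "relative_biomass_env.csv")
    utils::write.csv(rel_env, paths$relative_env, row.names = FALSE)
  }

  # stage: statistics
  note("stage stats: ANOVA + Tukey at ",
       paste(config$analysis_times, collapse = ", "), " h; lag t tests")
  stat_rows <- list()
  for (env in unique(plate$environment)) {
    for (wk in sort(unique(plate$week[plate$environment == env]))) {
      sub <- plate[plate$environment == env & plate$week == wk, ]
      for (tp in config$analysis_times) {
        at <- biomass_at_times(sub, tp)
        if (!nrow(at)) next
        groups <- data.frame(group = at$culture_type, value = at$biomass)
        if (length(unique(groups$group)) < 2L) next
        res <- anova_tukey(groups)
        tk <- res$tukey
        tk$environment <- env
        tk$week <- wk
        tk$time_h <- tp
        tk$anova_p <- res$anova$p
        stat_rows[[length(stat_rows) + 1L]] <- tk
      }
    }
  }
  stats_biomass <- do.call(rbind, stat_rows)
  paths$stats_biomass <- file.path(output_dir, "stats_biomass.csv")
  utils::write.csv(stats_biomass, paths$stats_biomass, row.names = FALSE)

  lag_rows <- list()
  for (env in unique(lags$environment)) {
    for (wk in sort(unique(lags$week[lags$environment == env]))) {
      a <- lags$lag_threshold[lags$environment == env & lags$week == wk &
                                lags$culture_type == "Q"]
      b <- lags$lag_threshold[lags$environment == env & lags$week == wk &
                                lags$culture_type == "NQ"]
      if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) next
      tt <- compare_lags_ttest(a, b)
      tt$comparison <- "Q-NQ"
      tt$environment <- env
      tt$week <- wk
      lag_rows[[length(lag_rows) + 1L]] <- tt
    }
  }
  stats_lags <- if (length(lag_rows)) do.call(rbind, lag_rows) else NULL
  if (!is.null(stats_lags)) {
    paths$stats_lags <- file.path(output_dir, "stats_lags.csv")
    utils::write.csv(stats_lags, paths$stats_lags, row.names = FALSE)
  }

  # stage: optional fit
  fit <- NULL
  if (!is.null(config$fit)) {
    note("stage fit: differential evolution on ",
         paste(names(config$fit$free), collapse = ", "))
    free <- lapply(config$fit$free, as.numeric)
    control <- config$fit$control
    if (is.null(control)) control <- list()
    if (is.null(control$seed)) control$seed <- config$seed
    fit <- fit_parameters(plate, free = free, fixed = params,
                          control = control)
    paths$fit <- file.path(output_dir, "fit.json")
    write_fit_json(fit, paths$fit)
  }

  summary <- list(config_hash = config_hash, seed = config$seed,
                  n_rows = nrow(plate),
                  n_curves = nrow(lags),
                  n_lag_sentinels = n_sentinel,
                  outputs = lapply(paths, basename))
  paths$summary <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA)
  paths$log <- file.path(output_dir, "log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(paths = paths, plate = plate, lags = lags,
                 relative_mixed = rel_mixed, relative_env = rel_env,
                 stats_biomass = stats_biomass, stats_lags = stats_lags,
                 fit = fit, config_hash = config_hash))
}
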