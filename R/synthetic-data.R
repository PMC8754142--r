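#' Measurement-noise model for generated plate data
#'
#' Describes how simulated trajectories are turned into noisy plate-reader
#' observations: a per-reading multiplicative and additive OD noise,
#' `od * (1 + e_mult) + e_add` with independent Gaussian terms truncated at
#' zero OD, plus a per-replicate jitter of the growth-onset lags emulating
#' biological replicate-to-replicate variability. By default the lag jitter
#' of each cell type is scaled by its death rate relative to the faster-dying
#' type, so NQ replicates (which keep dividing and diversifying during
#' starvation) scatter more than Q replicates, as observed in late-week
#' curves.
#'
#' @param sigma_add additive OD noise standard deviation.
#' @param sigma_mult multiplicative noise standard deviation (relative).
#' @param replicate_effect_sd per-replicate lag jitter SD in hours.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @param scale_jitter_with_death scale each type's lag jitter by
#'   `d_type / max(d_q, d_nq)`.
#' @param dropout probability that a replicate-week assay is missing
#'   (emulating the occasional lost replicate); default 0.
#' @return An object of class `qnq_noise`.
#' @export
noise_model <- function(sigma_add = 0.005, sigma_mult = 0.01,
                        replicate_effect_sd = 0.25, seed = 1L,
                        scale_jitter_with_death = TRUE, dropout = 0) {
  if (any(c(sigma_add, sigma_mult, replicate_effect_sd) < 0)) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("'dropout' must lie in [0, 1)",
                                        call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  structure(list(sigma_add = sigma_add, sigma_mult = sigma_mult,
                 replicate_effect_sd = replicate_effect_sd,
                 seed = as.integer(seed),
                 scale_jitter_with_death = scale_jitter_with_death,
                 dropout = dropout),
            class = "qnq_noise")
}

#' Default scenario set of the study design
#'
#' The full plate design: three culture compositions crossed with two
#' starvation environments, five replicates each, six weeks of starvation
#' with freezing pre-stress (30 independently starved cultures), plus,
#' optionally, the 16-replicate short-starvation plate for each composition.
#'
#' @param include_short include the three short-starvation scenarios.
#' @param starvation_weeks weeks of the long protocol.
#' @param n_replicates replicates per long-protocol culture type.
#' @return List of [qnq_scenario()] objects.
#' @export
qnq_default_scenarios <- function(include_short = TRUE, starvation_weeks = 6,
                                  n_replicates = 5) {
  long <- list()
  for (env in c("simple", "complex")) {
    for (comp in c("Q", "NQ", "mixed")) {
      long[[length(long) + 1L]] <-
        qnq_scenario(comp, env, freezing = TRUE,
                     starvation_weeks = starvation_weeks,
                     n_replicates = n_replicates)
    }
  }
  if (include_short) {
    for (comp in c("Q", "NQ", "mixed")) {
      long[[length(long) + 1L]] <- short_starvation_scenario(comp)
    }
  }
  long
}

jitter_sds <- function(noise, params) {
  base <- noise$replicate_effect_sd
  if (noise$scale_jitter_with_death) {
    top <- max(params$d_q, params$d_nq)
    if (top == 0) c(q = 0, nq = 0)
    else c(q = base * params$d_q / top, nq = base * params$d_nq / top)
  } else {
    c(q = base, nq = base)
  }
}

#' Generate a synthetic plate-reader dataset
#'
#' Simulates every scenario for every replicate with per-replicate
#' lag-jittered parameters, converts biomass to OD600 through the inverse
#' calibration cubic, applies the measurement noise, and assembles the
#' long-format plate series. Short-starvation assays are recorded as week 0.
#' Generation is fully deterministic under the noise model's seed.
#'
#' @param params a [qnq_params()] object.
#' @param scenarios list of [qnq_scenario()] objects (default: the full
#'   study design, [qnq_default_scenarios()]).
#' @param noise a [noise_model()].
#' @return Data frame of class `qnq_plate` with columns `culture_type`,
#'   `environment`, `replicate`, `week`, `time_h`, `od`, and a `metadata`
#'   attribute recording the seed, noise model, and number of
#'   noise-truncated readings.
#' @examples
#' \donttest{
#' plate <- generate_plate_dataset(qnq_params(),
#'                                 qnq_default_scenarios(FALSE,
#'                                                       starvation_weeks = 1),
#'                                 noise_model(seed = 7))
#' }
#' @export
generate_plate_dataset <- function(params,
                                   scenarios = qnq_default_scenarios(),
                                   noise = noise_model()) {
  p <- validate_params(params)
  stopifnot(inherits(noise, "qnq_noise"))
  if (!length(scenarios)) stop("the scenario set must be non-empty",
                               call. = FALSE)
  if (!all(vapply(scenarios, inherits, logical(1), "qnq_scenario"))) {
    stop("'scenarios' must be a list of qnq_scenario objects", call. = FALSE)
  }
  set.seed(noise$seed)
  sds <- jitter_sds(noise, p)
  n_truncated <- 0L
  blocks <- list()

  for (scen in scenarios) {
    for (rep_i in seq_len(scen$n_replicates)) {
      jq <- rnorm(1L, 0, sds[["q"]])
      jnq <- rnorm(1L, 0, sds[["nq"]])
      p_rep <- unclass(p)
      p_rep$lag_q0 <- max(0, p_rep$lag_q0 + jq)
      p_rep$lag_nq0 <- max(0, p_rep$lag_nq0 + jnq)
      p_rep$lag_q_short <- max(0, p_rep$lag_q_short + jq)
      p_rep$lag_nq_short <- max(0, p_rep$lag_nq_short + jnq)
      p_rep <- validate_params(structure(p_rep, class = "qnq_params"))

      assays <- if (scen$starvation_weeks >= 1) {
        run_long_starvation(scen, p_rep)
      } else {
        list(run_short_starvation(scen, p_rep))
      }
      for (assay in assays) {
        wk <- attr(assay, "week")
        if (noise$dropout > 0 && runif(1L) < noise$dropout) next
        n <- nrow(assay)
        od <- assay$od * (1 + rnorm(n, 0, noise$sigma_mult)) +
          rnorm(n, 0, noise$sigma_add)
        n_truncated <- n_truncated + sum(od < 0)
        od <- pmax(od, 0)
        blocks[[length(blocks) + 1L]] <- data.frame(
          culture_type = scen$composition,
          environment = scen$environment,
          replicate = rep_i,
          week = as.integer(wk),
          time_h = assay$time_h,
          od = od)
      }
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "metadata") <- list(seed = noise$seed, noise = unclass(noise),
                                n_truncated = n_truncated)
  class(out) <- c("qnq_plate", "data.frame")
  out
}

plate_columns <- c("culture_type", "environment", "replicate", "week",
                   "time_h", "od")

#' Write / read a plate series CSV
#'
#' The plate-series schema is a plain CSV with header
#' `culture_type, environment, replicate, week, time_h, od` (UTF-8, `.`
#' decimal). Reading restores column types (`replicate` and `week` integer,
#' `time_h` and `od` numeric) so `read_plate_csv(write_plate_csv(x, f))`
#' reproduces `x` including row order. Unknown extra columns are preserved
#' with a warning; a missing mandatory column is an error naming it. If the
#' data carries generation metadata it is written alongside as
#' `<path>.meta.json`.
#'
#' @param data a plate-series data frame.
#' @param path CSV file path.
#' @return `write_plate_csv()` returns `path` invisibly; `read_plate_csv()`
#'   returns a `qnq_plate` data frame.
#' @export
write_plate_csv <- function(data, path) {
  data <- as.data.frame(data)
  miss <- setdiff(plate_columns, names(data))
  if (length(miss)) stop("plate series is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(data, path, row.names = FALSE)
  meta <- attr(data, "metadata")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(plate_columns, names(raw))
  if (length(miss)) {
    stop("plate series file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), plate_columns)
  if (length(extra)) {
    warning("preserving unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  raw$culture_type <- as.character(raw$culture_type)
  raw$environment <- as.character(raw$environment)
  for (nm in c("replicate", "week")) {
    v <- suppressWarnings(as.integer(raw[[nm]]))
    if (anyNA(v) && !all(is.na(raw[[nm]]))) {
      stop("column '", nm, "' is not integer-coded", call. = FALSE)
    }
    raw[[nm]] <- v
  }
  for (nm in c("time_h", "od")) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    if (anyNA(v) && !all(is.na(raw[[nm]]))) {
      stop("column '", nm, "' is not numeric", call. = FALSE)
    }
    raw[[nm]] <- v
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    attr(raw, "metadata") <- jsonlite::read_json(meta_path,
                                                 simplifyVector = TRUE)
  }
  class(raw) <- c("qnq_plate", "data.frame")
  raw
}
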