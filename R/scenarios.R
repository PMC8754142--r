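#' Experimental scenario description
#'
#' One protocol: which culture composition is starved, in which environment,
#' for how long, whether a freezing pre-stress precedes starvation, and the
#' sampling/transfer geometry of the weekly regrowth assay. Defaults follow
#' the study protocol: cultures set up at OD 0.8 (long starvation) or OD 0.4
#' (4-day short starvation), mixed cultures at 3:1 Q:NQ by volume at equal
#' OD (75% Q biomass), weekly 275 ul samples resuspended in 550 ul fresh
#' medium of which 200 ul is plated, regrowth followed for 24 h at 0.5 h
#' resolution.
#'
#' @param composition `"Q"` (Q monoculture), `"NQ"` (NQ monoculture), or
#'   `"mixed"` (3:1 Q:NQ by volume).
#' @param environment starvation environment, `"simple"` (sterile water) or
#'   `"complex"` (spent medium, recycling possible).
#' @param freezing apply the freezing pre-stress before starvation (the
#'   long-starvation protocol stores fractionated cells frozen; the short
#'   protocol uses them immediately).
#' @param starvation_weeks weeks of starvation with weekly regrowth assays.
#' @param starvation_days starvation length of the short protocol, days.
#' @param regrowth_hours length of the analysed regrowth window (h).
#' @param sample_interval plate-reader sampling interval (h).
#' @param initial_od OD600 at culture set-up.
#' @param n_replicates replicate cultures for data generation.
#' @param mixed_q_fraction Q biomass fraction of the mixed culture.
#' @param sample_ul,resuspension_ul,plated_ul,well_ul transfer geometry in
#'   microlitres: sampled culture volume, fresh-medium resuspension volume,
#'   plated volume, and the well volume to which biomass is referred.
#' @return An object of class `qnq_scenario`.
#' @examples
#' qnq_scenario("NQ", "complex")
#' short_starvation_scenario("Q")
#' @export
qnq_scenario <- function(composition = c("Q", "NQ", "mixed"),
                         environment = c("simple", "complex"),
                         freezing = TRUE,
                         starvation_weeks = 6,
                         starvation_days = NULL,
                         regrowth_hours = 24,
                         sample_interval = 0.5,
                         initial_od = 0.8,
                         n_replicates = 5,
                         mixed_q_fraction = 0.75,
                         sample_ul = 275, resuspension_ul = 550,
                         plated_ul = 200, well_ul = 200) {
  composition <- match.arg(composition)
  environment <- match.arg(environment)
  stopifnot(is.logical(freezing), length(freezing) == 1L)
  if (starvation_weeks < 0 || starvation_weeks != round(starvation_weeks)) {
    stop("'starvation_weeks' must be a non-negative integer", call. = FALSE)
  }
  if (initial_od <= 0 || initial_od > 2) {
    stop("'initial_od' must lie in (0, 2]", call. = FALSE)
  }
  if (regrowth_hours <= 0 || sample_interval <= 0 ||
      sample_interval > regrowth_hours) {
    stop("invalid regrowth window or sampling interval", call. = FALSE)
  }
  if (mixed_q_fraction < 0 || mixed_q_fraction > 1) {
    stop("'mixed_q_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(sample_ul, resuspension_ul, plated_ul, well_ul) <= 0)) {
    stop("transfer volumes must be positive", call. = FALSE)
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("'n_replicates' must be a positive integer", call. = FALSE)
  }
  structure(list(composition = composition, environment = environment,
                 freezing = freezing, starvation_weeks = starvation_weeks,
                 starvation_days = starvation_days,
                 regrowth_hours = regrowth_hours,
                 sample_interval = sample_interval,
                 initial_od = initial_od, n_replicates = n_replicates,
                 mixed_q_fraction = mixed_q_fraction,
                 sample_ul = sample_ul, resuspension_ul = resuspension_ul,
                 plated_ul = plated_ul, well_ul = well_ul),
            class = "qnq_scenario")
}

#' @rdname qnq_scenario
#' @export
short_starvation_scenario <- function(composition = c("Q", "NQ", "mixed"),
                                      n_replicates = 16, ...) {
  qnq_scenario(composition = match.arg(composition), environment = "simple",
               freezing = FALSE, starvation_weeks = 0, starvation_days = 4,
               initial_od = 0.4, n_replicates = n_replicates, ...)
}

#' Freezing pre-stress
#'
#' Applies the survival fractions of the freezing stress that precedes long
#' starvation: by default 40% of Q and 10% of NQ cells survive. Killed
#' biomass joins the recyclable nutrient pool (which is only usable in the
#' complex environment); the fresh-medium resource is unchanged.
#'
#' @param state a [population_state()].
#' @param survival_q,survival_nq surviving fractions in `[0, 1]`.
#' @return The post-freezing [population_state()].
#' @examples
#' apply_freezing(population_state(q = 1e6, nq = 1e6))
#' @export
apply_freezing <- function(state, survival_q = 0.4, survival_nq = 0.1) {
  if (survival_q < 0 || survival_q > 1 || survival_nq < 0 ||
      survival_nq > 1) {
    stop("survival fractions must lie in [0, 1]", call. = FALSE)
  }
  y <- state_vec(state)
  killed <- (1 - survival_q) * y[["q"]] + (1 - survival_nq) * y[["nq"]]
  population_state(q = survival_q * y[["q"]],
                   nq = survival_nq * y[["nq"]],
                   resource = y[["resource"]],
                   recyclable = y[["recyclable"]] + killed)
}

#' Initial culture state for a scenario
#'
#' Total viable biomass is the OD-converted cell count at the scenario's
#' set-up OD, split by composition (Q monoculture all Q; NQ monoculture all
#' NQ; mixed 75% Q by default). Starvation media carry no fresh-medium
#' resource; the complex environment starts with a residual recyclable pool
#' of `residual_seed_frac * fresh_resource` cell-equivalents left in the
#' spent medium, the simple environment with none.
#'
#' @param scenario a [qnq_scenario()].
#' @param params a [qnq_params()] object.
#' @return A [population_state()].
#' @export
initialize_culture <- function(scenario, params) {
  stopifnot(inherits(scenario, "qnq_scenario"))
  p <- validate_params(params)
  total <- od_to_biomass(scenario$initial_od)
  split <- switch(scenario$composition,
                  Q = c(1, 0),
                  NQ = c(0, 1),
                  mixed = c(scenario$mixed_q_fraction,
                            1 - scenario$mixed_q_fraction),
                  stop("unknown composition label: ", scenario$composition,
                       call. = FALSE))
  seed <- if (scenario$environment == "complex") {
    p$residual_seed_frac * p$fresh_resource
  } else 0
  population_state(q = split[1] * total, nq = split[2] * total,
                   resource = 0, recyclable = seed)
}

#' Weekly sampling and transfer to fresh medium
#'
#' Models the regrowth transfer: a sample of the starved culture is spun
#' down, the starvation supernatant (and with it the recyclable pool) is
#' discarded, cells are resuspended in fresh medium and plated. With the
#' default geometry (275 ul sampled, resuspended in 550 ul, 200 ul plated)
#' the plated well contains the cells of 0.1 ml of culture, i.e. half the
#' per-well-equivalent biomass of the starved culture. Both cell types are
#' scaled equally, so the Q:NQ ratio is preserved.
#'
#' @inheritParams initialize_culture
#' @param state the starved culture [population_state()].
#' @param fresh_resource cell-equivalents of limiting nutrient supplied by
#'   the fresh medium (default from `params` when called through the runner;
#'   here explicit).
#' @return The plated [population_state()] starting regrowth.
#' @export
sample_and_transfer <- function(state, scenario, fresh_resource) {
  stopifnot(inherits(scenario, "qnq_scenario"))
  if (!is.numeric(fresh_resource) || fresh_resource <= 0) {
    stop("'fresh_resource' must be positive", call. = FALSE)
  }
  y <- state_vec(state)
  factor <- scenario$sample_ul * (scenario$plated_ul /
                                  scenario$resuspension_ul) /
    scenario$well_ul
  population_state(q = factor * y[["q"]], nq = factor * y[["nq"]],
                   resource = fresh_resource, recyclable = 0)
}

# OD emitted by the plate reader: biomass below the calibration intercept
# (about 2.2e5 cells/well) is below the reader's sensitivity and reads 0
od_reading <- function(biomass) {
  lo <- od_to_biomass(0)
  hi <- od_to_biomass(2)
  biomass_to_od(pmin(pmax(biomass, lo), hi))
}

regrow_assay <- function(plated, params, lags, scenario, week) {
  phase <- qnq_phase("regrowth", lags = lags)
  traj <- integrate_phase(plated, params, phase,
                          duration = scenario$regrowth_hours,
                          output_step = scenario$sample_interval)
  biomass <- traj$q + traj$nq
  out <- data.frame(time_h = traj$time, q = traj$q, nq = traj$nq,
                    biomass = biomass, od = od_reading(biomass),
                    resource = traj$resource)
  attr(out, "week") <- week
  attr(out, "lags") <- lags
  attr(out, "starting_state") <- plated
  attr(out, "scenario") <- scenario
  class(out) <- c("qnq_assay", "data.frame")
  out
}

#' Long-starvation protocol with weekly regrowth assays
#'
#' Starts the culture per [initialize_culture()], applies the freezing
#' pre-stress if the scenario requires it, integrates starvation
#' continuously, and at each week boundary draws a non-destructive sample
#' (weekly removal is a few percent of the culture and is ignored),
#' transfers it to fresh medium via [sample_and_transfer()], and simulates
#' regrowth with lags from [lag_schedule()] at that week.
#'
#' @inheritParams initialize_culture
#' @return A list of `qnq_assay` data frames, one per week `1..starvation_weeks`,
#'   each with columns `time_h`, `q`, `nq`, `biomass`, `od`, `resource` and
#'   attributes `week`, `lags`, `starting_state`.
#' @export
run_long_starvation <- function(scenario, params) {
  stopifnot(inherits(scenario, "qnq_scenario"))
  p <- validate_params(params)
  if (scenario$starvation_weeks < 1) {
    stop("long-starvation scenario needs starvation_weeks >= 1",
         call. = FALSE)
  }
  state <- initialize_culture(scenario, p)
  if (scenario$freezing) {
    state <- apply_freezing(state, p$freeze_survival_q, p$freeze_survival_nq)
  }
  starve <- qnq_phase("starvation", environment = scenario$environment)
  assays <- vector("list", scenario$starvation_weeks)
  for (week in seq_len(scenario$starvation_weeks)) {
    traj <- tryCatch(
      integrate_phase(state, p, starve, duration = 7 * 24, output_step = 24),
      error = function(e) stop("starvation week ", week, ": ",
                               conditionMessage(e), call. = FALSE))
    state <- final_state(traj)
    plated <- sample_and_transfer(state, scenario, p$fresh_resource)
    assays[[week]] <- tryCatch(
      regrow_assay(plated, p, lag_schedule(p, week), scenario, week),
      error = function(e) stop("regrowth week ", week, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  assays
}

#' Short-starvation regrowth assay
#'
#' The 4-day short-starvation protocol: freshly fractionated cells are
#' diluted to OD 0.4 and placed directly into fresh rich medium, so the
#' assay starts from the composition split with the full fresh resource and
#' uses the short-starvation lags (`lag_q_short`, `lag_nq_short`), under
#' which NQ cells start growing before Q cells.
#'
#' @inheritParams initialize_culture
#' @return A single `qnq_assay` data frame (week attribute 0).
#' @export
run_short_starvation <- function(scenario, params) {
  stopifnot(inherits(scenario, "qnq_scenario"))
  p <- validate_params(params)
  total <- od_to_biomass(scenario$initial_od)
  split <- switch(scenario$composition,
                  Q = c(1, 0), NQ = c(0, 1),
                  mixed = c(scenario$mixed_q_fraction,
                            1 - scenario$mixed_q_fraction))
  plated <- population_state(q = split[1] * total, nq = split[2] * total,
                             resource = p$fresh_resource, recyclable = 0)
  lags <- c(q = p$lag_q_short, nq = p$lag_nq_short)
  regrow_assay(plated, p, lags, scenario, week = 0L)
}
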