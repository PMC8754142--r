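test_that("the full long-starvation design yields the expected grid of rows", {
  p <- qnq_params()
  plate <- generate_plate_dataset(
    p, qnq_default_scenarios(include_short = FALSE),
    noise_model(seed = 4))
  # 3 compositions x 2 environments x 5 replicates x 6 weeks x 49 samples
  expect_equal(nrow(plate), 3 * 2 * 5 * 6 * 49)
  expect_setequal(unique(plate$culture_type), c("Q", "NQ", "mixed"))
  expect_setequal(unique(plate$week), 1:6)
  expect_true(all(plate$time_h >= 0 & plate$time_h <= 24))
  expect_true(all(plate$od >= 0))

  counts <- table(plate$culture_type, plate$environment, plate$replicate,
                  plate$week)
  expect_true(all(counts == 49))
})

test_that("with noise off the generated OD is exactly the deterministic trajectory", {
  p <- qnq_params()
  scen <- qnq_scenario("Q", "simple", starvation_weeks = 2,
                       n_replicates = 2)
  plate <- generate_plate_dataset(
    p, list(scen),
    noise_model(sigma_add = 0, sigma_mult = 0, replicate_effect_sd = 0,
                seed = 9))
  assays <- run_long_starvation(scen, p)
  for (w in 1:2) {
    for (r in 1:2) {
      sub <- plate[plate$week == w & plate$replicate == r, ]
      expect_equal(sub$od, assays[[w]]$od)
    }
  }
})

test_that("generation is byte-identical under a fixed seed", {
  p <- qnq_params()
  scen <- list(qnq_scenario("NQ", "complex", starvation_weeks = 1,
                            n_replicates = 2))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_plate_csv(generate_plate_dataset(p, scen, noise_model(seed = 42)),
                  f1)
  write_plate_csv(generate_plate_dataset(p, scen, noise_model(seed = 42)),
                  f2)
  expect_identical(readLines(f1), readLines(f2))

  d3 <- generate_plate_dataset(p, scen, noise_model(seed = 43))
  expect_false(identical(read_plate_csv(f1)$od, d3$od))
})

test_that("the CSV schema roundtrips including row order and integer coding", {
  p <- qnq_params()
  plate <- generate_plate_dataset(
    p, list(qnq_scenario("mixed", "simple", starvation_weeks = 1,
                         n_replicates = 2)),
    noise_model(seed = 6))
  path <- tempfile(fileext = ".csv")
  write_plate_csv(plate, path)
  back <- read_plate_csv(path)
  for (col in c("culture_type", "environment", "replicate", "week")) {
    expect_identical(back[[col]], plate[[col]])
  }
  expect_equal(back$time_h, plate$time_h)
  expect_equal(back$od, plate$od)
  expect_equal(attr(back, "metadata")$seed, 6)

  # week written as a quoted string is normalised to integer
  writeLines(c("culture_type,environment,replicate,week,time_h,od",
               "Q,simple,1,\"1\",0,0.4",
               "Q,simple,1,\"1\",0.5,0.41"), path)
  reread <- read_plate_csv(path)
  expect_identical(reread$week, c(1L, 1L))
})

test_that("schema violations are reported by column name, extras preserved with warning", {
  path <- tempfile(fileext = ".csv")
  d <- data.frame(culture_type = "Q", environment = "simple", replicate = 1,
                  week = 1, time_h = 0, od = 0.4)
  write_plate_csv(d, path)

  utils::write.csv(d[, setdiff(names(d), "od")], path, row.names = FALSE)
  expect_error(read_plate_csv(path), "od")

  d$plate_id <- "P1"
  utils::write.csv(d, path, row.names = FALSE)
  expect_warning(back <- read_plate_csv(path), "plate_id")
  expect_equal(back$plate_id, "P1")

  expect_error(write_plate_csv(d[, -1], tempfile()), "culture_type")
  expect_error(read_plate_csv("no/such/file.csv"), "not found")
})

test_that("noise-free generated curves recover the generating lags by the threshold rule", {
  p <- qnq_params()
  quiet <- noise_model(sigma_add = 0, sigma_mult = 0,
                       replicate_effect_sd = 0, seed = 1)
  plate <- generate_plate_dataset(
    p, list(short_starvation_scenario("Q", n_replicates = 1),
            short_starvation_scenario("NQ", n_replicates = 1)), quiet)
  lags <- lag_table(plate)
  expect_equal(lags$lag_threshold[lags$culture_type == "Q"], 2.0)
  expect_equal(lags$lag_threshold[lags$culture_type == "NQ"], 1.0)
})

test_that("late-week NQ replicates scatter more than Q replicates", {
  p <- qnq_params()
  plate <- generate_plate_dataset(
    p, list(qnq_scenario("Q", "simple", starvation_weeks = 6,
                         n_replicates = 5),
            qnq_scenario("NQ", "simple", starvation_weeks = 6,
                         n_replicates = 5)),
    noise_model(seed = 12))
  # the death-rate-scaled lag jitter makes NQ growth curves shift in time
  # between replicates far more than Q curves, so the replicate scatter of
  # the measured lag is larger for NQ
  lags <- lag_table(plate)
  lag_sd <- function(type) {
    sum(vapply(5:6, function(wk) {
      stats::sd(lags$lag_threshold[lags$culture_type == type &
                                     lags$week == wk])
    }, numeric(1)))
  }
  expect_gt(lag_sd("NQ"), lag_sd("Q"))
})

test_that("replicate dropout removes whole assays at the configured rate", {
  p <- qnq_params()
  scen <- list(qnq_scenario("Q", "simple", starvation_weeks = 3,
                            n_replicates = 4))
  full <- generate_plate_dataset(p, scen, noise_model(seed = 5))
  dropped <- generate_plate_dataset(p, scen,
                                    noise_model(seed = 5, dropout = 0.3))
  expect_lt(nrow(dropped), nrow(full))
  expect_equal(nrow(dropped) %% 49, 0)
})
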