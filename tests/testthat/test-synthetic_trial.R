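test_that("default design states the study's conditions", {
  d <- default_design()
  expect_equal(d$met_levels, c(9.5, 11.6, 14.0, 17.9, 21.5, 18.6))
  expect_equal(d$duration, 38)
  expect_equal(d$fish_per_tank, 14L)
  expect_equal(d$tanks_per_diet, 3L)
  expect_equal(d$cys_level, 4.5)
  expect_equal(d$initial_weight_mean, 83.9)
  expect_equal(d$initial_weight_sd, 8.4)
  expect_equal(inflection_lognormal(d$true_response), 15.8, tolerance = 1e-12)
  # true FCR curve: 0.86 at the lowest dose, plateau 0.80 beyond 14.6
  expect_equal(eval_model(d$fcr_response, 9.5), 0.86, tolerance = 1e-12)
  expect_equal(eval_model(d$fcr_response, 20), 0.80, tolerance = 1e-12)
})

test_that("generate_trial is deterministic and respects the noise model", {
  d <- default_design(seed = 7)
  t1 <- generate_trial(d)
  t2 <- generate_trial(d)
  expect_identical(t1, t2)
  t3 <- generate_trial(default_design(seed = 8))
  expect_false(identical(t1$tanks, t3$tanks))

  expect_length(t1$tanks, 18L)
  expect_length(t1$fish, 18L * 14L)

  # noiseless generation: diet-mean SGR equals the generating curve exactly
  tr0 <- generate_trial(default_design(seed = 3, tank_sd = 0))
  perf <- tank_performance(tr0$tanks)
  sgr_mean <- tapply(perf$sgr, perf$diet_id, mean)
  truth <- eval_model(tr0$truth$sgr_model, default_design()$met_levels)
  expect_equal(as.numeric(sgr_mean[paste0("D", 1:6)]), truth, tolerance = 1e-9)

  # feed intake back-solves the prescribed FCR curve exactly
  fcr_truth <- eval_model(tr0$truth$fcr_model, default_design()$met_levels)
  fcr_mean <- tapply(perf$fcr, perf$diet_id, mean)
  expect_equal(as.numeric(fcr_mean[paste0("D", 1:6)]), fcr_truth,
               tolerance = 1e-9)
})

test_that("generated tank SGR noise is Normal(model, tank_sd)", {
  # many replicate tanks at one dose via many seeds would be slow; instead
  # standardise all 18 tanks across 40 seeds and KS-test against N(0,1)
  sd_true <- 0.09
  z <- unlist(lapply(1:40, function(s) {
    tr <- generate_trial(default_design(seed = s, tank_sd = sd_true))
    perf <- tank_performance(tr$tanks)
    met <- c(9.5, 11.6, 14.0, 17.9, 21.5, 18.6)
    names(met) <- paste0("D", 1:6)
    (perf$sgr - eval_model(tr$truth$sgr_model, met[perf$diet_id])) / sd_true
  }))
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sd(z), 1, tolerance = 0.15)
})

test_that("simulated diet-mean SGRs land in the published 2.8-3.2 range", {
  ok <- vapply(1:40, function(s) {
    tr <- generate_trial(default_design(seed = s))
    perf <- tank_performance(tr$tanks)
    m <- tapply(perf$sgr, perf$diet_id, mean)
    all(m >= 2.8 - 0.15 & m <= 3.2 + 0.15)
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("feces_for_adc inverts the ADC formula", {
  d <- diet_formulation("D1", c(methionine = 9.5), marker = 1)
  f <- feces_for_adc(d, c(methionine = 88.5), fecal_marker = 4)
  expect_equal(unname(f$nutrients["methionine"]), 4.37, tolerance = 1e-9)

  f100 <- feces_for_adc(d, c(methionine = 100), fecal_marker = 4)
  expect_equal(unname(f100$nutrients["methionine"]), 0)

  f0 <- feces_for_adc(d, c(methionine = 0), fecal_marker = 4)
  expect_equal(unname(f0$nutrients["methionine"]) / f0$marker,
               9.5 / d$marker, tolerance = 1e-12)

  expect_error(feces_for_adc(d, c(methionine = 101), 4), "<= 100")
})

test_that("written trial file set round-trips through the readers", {
  tr <- generate_trial(default_design(seed = 12))
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  diets <- read_diet_table(file.path(dir, "diets.csv"))
  tanks <- read_tank_table(file.path(dir, "tanks.csv"), diets = diets)
  feces <- read_feces_table(file.path(dir, "feces.csv"))
  fish <- read_fish_table(file.path(dir, "fish.csv"))
  expect_length(diets, 6L)
  expect_length(tanks, 18L)
  expect_length(fish, 252L)
  expect_equal(tanks[[1]]$final_weight, tr$tanks[[1]]$final_weight,
               tolerance = 1e-12)
  # digestibility stage recovers the prescribed ADCs from the files
  tab <- adc_from_tables(diets, feces, nutrients = c("methionine", "cysteine"))
  expect_equal(adc_value(tab, "D3", "methionine"), 93.9, tolerance = 1e-9)
  expect_equal(adc_value(tab, "D5", "cysteine"), 53.9, tolerance = 1e-9)
})
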