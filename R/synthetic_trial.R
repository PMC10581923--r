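# Synthetic feeding-trial generator. Emulates the structure of a graded
# methionine dose-response trial in juvenile giant grouper: 6 diets (five
# graded Met levels 9.5-21.5 g/kg plus a taurine contrast at 18.6 g/kg),
# near-constant cysteine, triplicate tanks of 14 fish, 38 days, initial
# weights ~ N(83.9, 8.4), and a unimodal (lognormal-shaped) SGR response
# peaking near the requirement. Noise enters at tank level (the experimental
# unit); fish-level weights are decorative draws for I/O testing.

#' Trial design specification
#'
#' @param n_diets number of diets.
#' @param met_levels methionine contents, g/kg DM; positive and distinct.
#' @param cys_level constant cysteine content, g/kg DM.
#' @param taurine_levels taurine contents per diet, g/kg DM (the last diet of
#'   the default design is a taurine contrast).
#' @param marker_level inert-marker content of every diet, g/kg DM.
#' @param tanks_per_diet,fish_per_tank replication structure.
#' @param duration trial length, days.
#' @param initial_weight_mean,initial_weight_sd fish initial weight, g.
#' @param true_response a [lognormal_model()] giving the true tank SGR (%/day)
#'   as a function of dietary Met (g/kg).
#' @param fcr_response a `dose_response_model` giving the true FCR as a
#'   function of dietary Met; feed intake is back-solved from it.
#' @param adc_truth named list with numeric vectors `methionine` and
#'   `cysteine` (length `n_diets`), the prescribed ADCs in percent.
#' @param fecal_marker marker content of the generated feces, g/kg DM.
#' @param tank_sd between-tank SD of SGR, %/day.
#' @param seed integer master seed; all random streams are sub-seeded from it.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_diets, met_levels, cys_level, taurine_levels,
                         marker_level, tanks_per_diet, fish_per_tank, duration,
                         initial_weight_mean, initial_weight_sd,
                         true_response, fcr_response, adc_truth,
                         fecal_marker = 4, tank_sd = 0.09, seed = 1L) {
  stop_if(length(met_levels) != n_diets, "met_levels must have n_diets entries")
  stop_if(any(met_levels <= 0) || anyDuplicated(met_levels) > 0,
          "met_levels must be positive and distinct")
  stop_if(tanks_per_diet < 1, "tanks_per_diet must be >= 1")
  stop_if(tank_sd < 0, "tank_sd must be >= 0")
  stop_if(!inherits(true_response, "dose_response_model"),
          "true_response must be a dose_response_model")
  structure(list(n_diets = n_diets, met_levels = met_levels,
                 cys_level = cys_level, taurine_levels = taurine_levels,
                 marker_level = marker_level, tanks_per_diet = tanks_per_diet,
                 fish_per_tank = fish_per_tank, duration = duration,
                 initial_weight_mean = initial_weight_mean,
                 initial_weight_sd = initial_weight_sd,
                 true_response = true_response, fcr_response = fcr_response,
                 adc_truth = adc_truth, fecal_marker = fecal_marker,
                 tank_sd = tank_sd, seed = as.integer(seed)),
            class = "trial_design")
}

#' Default synthetic-trial design
#'
#' Mirrors the motivating study: Met levels 9.5, 11.6, 14.0, 17.9, 21.5 plus
#' a taurine arm at 18.6 g/kg; Cys 4.5 g/kg; marker 1.0 g/kg; 3 tanks x 14
#' fish per diet; 38 days; initial weight 83.9 +- 8.4 g. The true SGR curve
#' is lognormal with its peak at 15.8 g/kg (peak SGR 3.15 %/day; geometric SD
#' calibrated so the curve spans the published diet-mean SGR range, 2.83 at
#' the lowest dose to 3.15 at the peak); the true FCR curve is a broken stick
#' falling from 0.86 at 9.5 g/kg
#' to a plateau of 0.80 at 14.6 g/kg. Prescribed ADCs are the published
#' per-diet Met and Cys digestibilities. Between-tank SD defaults to 0.09
#' %/day, chosen to reproduce the printed SEM scale (~0.05 at n = 3).
#'
#' @param seed integer master seed.
#' @param tank_sd between-tank SGR standard deviation, %/day.
#' @param true_peak dose of the true SGR optimum, g/kg.
#' @return A [trial_design()].
#' @export
default_design <- function(seed = 1L, tank_sd = 0.09, true_peak = 15.8) {
  # geometric SD calibrated once so the true curve spans the published
  # diet-mean SGRs (2.83 at 9.5 g/kg up to 3.15 at the peak); the curve is
  # shallow, as real growth responses near the requirement are
  gsd <- 3.12
  s2 <- log(gsd)^2
  gm <- true_peak * exp(s2)                    # mode = exp(ln gm - s^2)
  amp <- 3.15 * true_peak * exp(0.5 * s2)      # peak SGR 3.15 %/day
  sgr_true <- lognormal_model(amplitude = amp, geo_mean = gm, geo_sd = gsd)
  slope1 <- -(0.86 - 0.80) / (14.6 - 9.5)
  fcr_true <- segmented_model(breakpoint = 14.6, slope1 = slope1, slope2 = 0,
                              intercept = 0.86 - slope1 * 9.5, blend_width = 0)
  trial_design(
    n_diets = 6L,
    met_levels = c(9.5, 11.6, 14.0, 17.9, 21.5, 18.6),
    cys_level = 4.5,
    taurine_levels = c(1.8, 1.7, 1.7, 1.9, 1.7, 8.0),
    marker_level = 1.0,
    tanks_per_diet = 3L, fish_per_tank = 14L, duration = 38,
    initial_weight_mean = 83.9, initial_weight_sd = 8.4,
    true_response = sgr_true, fcr_response = fcr_true,
    adc_truth = list(methionine = c(88.5, 95.9, 93.9, 93.1, 94.2, 94.7),
                     cysteine = c(60.9, 77.3, 56.5, 54.2, 53.9, 65.3),
                     taurine = c(43.5, 71.2, 34.3, 39.2, 23.0, 86.4)),
    fecal_marker = 4.0, tank_sd = tank_sd, seed = seed)
}

#' Invert the ADC formula to construct a fecal sample
#'
#' Given target ADCs, the fecal nutrient content consistent with the
#' marker-ratio formula is
#' `diet nutrient * (1 - adc/100) * (fecal_marker / diet marker)`;
#' running [compute_adc()] on the result returns the target exactly.
#'
#' @param diet a [diet_formulation()].
#' @param adc_targets named numeric vector of target ADCs in percent
#'   (<= 100).
#' @param fecal_marker marker content of the feces, g/kg DM; > 0.
#' @return A [fecal_sample()].
#' @export
feces_for_adc <- function(diet, adc_targets, fecal_marker) {
  stop_if(fecal_marker <= 0, "fecal_marker must be positive")
  stop_if(any(adc_targets > 100), "target ADCs must be <= 100")
  nn <- names(adc_targets)
  nv <- vapply(nn, function(n)
    diet_nutrient(diet, n) * (1 - adc_targets[[n]] / 100) *
      (fecal_marker / diet$marker), 0)
  names(nv) <- nn
  fecal_sample(diet$diet_id, nv, fecal_marker)
}

# documented sub-seeding: one derived stream per component, all < 2^31
sub_seed <- function(seed, k) (seed * 7L + k * 1009L) %% 2147483629L

#' Generate a complete synthetic feeding trial
#'
#' Tank SGRs are drawn as `eval_model(true_response, met) + N(0, tank_sd)`;
#' final weights are back-solved from the SGR definition; feed intake is
#' back-solved from the true FCR curve; fish weights are decorative draws
#' around the tank means; feces are constructed with [feces_for_adc()] so the
#' digestibility stage recovers the prescribed ADCs exactly. Byte-identical
#' output for identical designs (including the seed).
#'
#' @param design a [trial_design()].
#' @return A list with elements `diets`, `tanks`, `fish`, `feces` (domain
#'   record lists; `fish` is a list of [fish_record()]) and `truth` (the
#'   generating models, the true peak dose and the prescribed ADCs).
#' @export
generate_trial <- function(design) {
  stop_if(!inherits(design, "trial_design"), "design must be a trial_design")
  d <- design
  ids <- sprintf("D%d", seq_len(d$n_diets))
  diets <- lapply(seq_len(d$n_diets), function(i)
    diet_formulation(ids[i],
                     nutrients = c(methionine = d$met_levels[i],
                                   cysteine = d$cys_level,
                                   taurine = d$taurine_levels[i]),
                     marker = d$marker_level,
                     dry_matter = 0.90))
  feces <- lapply(seq_len(d$n_diets), function(i)
    feces_for_adc(diets[[i]],
                  vapply(d$adc_truth, `[[`, 0, i),
                  d$fecal_marker))

  tanks <- list(); fish <- list()
  tn <- 0L
  for (i in seq_len(d$n_diets)) {
    set.seed(sub_seed(d$seed, i))
    for (j in seq_len(d$tanks_per_diet)) {
      tn <- tn + 1L
      ibw_fish <- stats::rnorm(d$fish_per_tank, d$initial_weight_mean,
                               d$initial_weight_sd)
      ibw_fish <- pmax(ibw_fish, 0.3 * d$initial_weight_mean)
      ibw <- mean(ibw_fish)
      sgr <- eval_model(d$true_response, d$met_levels[i]) +
        stats::rnorm(1L, 0, d$tank_sd)
      fbw <- ibw * exp(sgr / 100 * d$duration)
      fcr <- eval_model(d$fcr_response, d$met_levels[i])
      fi <- fcr * (fbw - ibw)
      tank_id <- sprintf("T%02d", tn)
      tanks[[tn]] <- tank_record(tank_id, ids[i], d$fish_per_tank,
                                 ibw, fbw, fi, d$duration)
      fbw_fish <- ibw_fish * (fbw / ibw) *
        exp(stats::rnorm(d$fish_per_tank, 0, 0.05))
      hsi_true <- 3.2 - 0.035 * (d$met_levels[i] - min(d$met_levels))
      liver <- fbw_fish * pmax(hsi_true +
                                 stats::rnorm(d$fish_per_tank, 0, 0.15), 0.5) / 100
      fish <- c(fish, lapply(seq_len(d$fish_per_tank), function(q)
        fish_record(sprintf("%s_F%02d", tank_id, q), tank_id,
                    fbw_fish[q], liver[q])))
    }
  }
  list(diets = diets, tanks = tanks, fish = fish, feces = feces,
       truth = list(sgr_model = d$true_response, fcr_model = d$fcr_response,
                    true_peak = inflection_lognormal(d$true_response),
                    adc = d$adc_truth))
}

#' Write a generated trial as the standard file set
#'
#' Emits `diets.csv`, `tanks.csv`, `fish.csv` and `feces.csv` in the layout
#' the readers in this package expect.
#'
#' @param trial output of [generate_trial()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(trial$diets, file.path(dir, "diets.csv"))
  write_results(trial$tanks, file.path(dir, "tanks.csv"))
  write_results(trial$fish, file.path(dir, "fish.csv"))
  write_results(trial$feces, file.path(dir, "feces.csv"))
  invisible(dir)
}
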