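# Growth and feed-efficiency metrics. All are computed at tank level from
# tank-mean weights; per-fish organ data (HSI) are aggregated per tank when a
# fish table is supplied.

#' Percentage weight gain
#'
#' `(final - initial) / initial * 100`.
#'
#' @param initial,final body weights, g; `initial` must be > 0.
#' @return Weight gain in percent.
#' @export
weight_gain_pct <- function(initial, final) {
  stop_if(any(initial <= 0), "initial weight must be positive")
  (final - initial) / initial * 100
}

#' Specific growth rate
#'
#' `(ln(final) - ln(initial)) / days * 100`, in %/day.
#'
#' @param initial,final body weights, g; both must be > 0.
#' @param days trial duration, days; must be > 0.
#' @return SGR in %/day.
#' @export
specific_growth_rate <- function(initial, final, days) {
  stop_if(any(initial <= 0) || any(final <= 0), "weights must be positive")
  stop_if(any(days <= 0), "days must be positive")
  (log(final) - log(initial)) / days * 100
}

#' Feed conversion ratio
#'
#' Feed consumed per unit of weight gained. A non-growing tank
#' (gain <= 0) has an undefined FCR; it is reported as `NA` with a warning
#' rather than silently dropped.
#'
#' @param feed_intake total feed intake per fish, g.
#' @param weight_gain weight gain per fish, g.
#' @return FCR (dimensionless), `NA` where gain <= 0.
#' @export
feed_conversion_ratio <- function(feed_intake, weight_gain) {
  out <- feed_intake / weight_gain
  bad <- weight_gain <= 0
  if (any(bad)) {
    warning("FCR undefined for non-growing tank(s); returned NA", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Hepatosomatic index
#'
#' Liver weight as a percentage of body weight.
#'
#' @param liver liver weight, g; `0 <= liver < body`.
#' @param body body weight, g; must be > 0.
#' @return HSI in percent.
#' @export
hepatosomatic_index <- function(liver, body) {
  stop_if(any(body <= 0), "body weight must be positive")
  stop_if(any(liver < 0) || any(liver >= body),
          "liver weight must be >= 0 and < body weight")
  liver / body * 100
}

#' Per-tank performance metrics
#'
#' Computes weight gain (%), SGR (%/day), FCR, geometric body weight (kg) and,
#' when a fish table with liver weights is supplied, the tank-mean HSI.
#' Feed intake is used as provided (as fed) unless `dm_basis = TRUE`, in which
#' case it is converted to dry matter via each diet's `dry_matter` fraction.
#'
#' @param tanks list of [tank_record()].
#' @param fish optional list of [fish_record()] with liver weights.
#' @param diets optional list of [diet_formulation()]; required for
#'   `dm_basis = TRUE`.
#' @param dm_basis convert feed intake to dry matter before computing FCR?
#' @return A data frame with one row per tank and an `aggregation` attribute
#'   recording the computation level and intake basis.
#' @export
tank_performance <- function(tanks, fish = NULL, diets = NULL, dm_basis = FALSE) {
  stop_if(dm_basis && is.null(diets), "dm_basis = TRUE requires diets")
  rows <- lapply(tanks, function(tk) {
    fi <- tk$feed_intake
    if (dm_basis) fi <- fi * find_diet(diets, tk$diet_id)$dry_matter
    gain <- tk$final_weight - tk$initial_weight
    data.frame(
      tank_id = tk$tank_id, diet_id = tk$diet_id,
      weight_gain_pct = weight_gain_pct(tk$initial_weight, tk$final_weight),
      sgr = specific_growth_rate(tk$initial_weight, tk$final_weight, tk$duration),
      fcr = if (gain > 0) fi / gain else NA_real_,
      geometric_bw = geometric_body_weight(tk$initial_weight, tk$final_weight),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$fcr)))
    warning("FCR undefined for non-growing tank(s); returned NA", call. = FALSE)
  if (!is.null(fish)) {
    hsi <- vapply(fish, function(f)
      if (is.na(f$liver_weight)) NA_real_
      else hepatosomatic_index(f$liver_weight, f$body_weight), 0)
    tank_of <- vapply(fish, `[[`, "", "tank_id")
    out$hsi <- vapply(out$tank_id, function(id)
      mean(hsi[tank_of == id], na.rm = TRUE), 0)
  }
  attr(out, "aggregation") <- list(level = "tank",
                                   intake_basis = if (dm_basis) "dry_matter" else "as_fed")
  out
}

#' Per-diet mean and SEM of performance metrics
#'
#' SEM is `sd / sqrt(n)` over tanks within a diet. Single-tank diets get an
#' `NA` SEM and a warning (flagged, not silently dropped).
#'
#' @param perf data frame from [tank_performance()].
#' @return Long data frame with columns `diet_id`, `metric`, `mean`, `sem`, `n`.
#' @export
summarize_by_diet <- function(perf) {
  metrics <- setdiff(names(perf), c("tank_id", "diet_id"))
  out <- do.call(rbind, lapply(split(perf, perf$diet_id), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]][!is.na(g[[m]])]
      data.frame(diet_id = g$diet_id[1L], metric = m,
                 mean = mean(v),
                 sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  if (any(out$n == 1L))
    warning("SEM undefined for diets with a single tank", call. = FALSE)
  out
}
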