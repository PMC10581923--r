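# Inert-marker digestibility. The apparent digestibility coefficient (ADC)
# follows the classic marker-ratio formula: the fraction of an ingested
# nutrient not recovered in feces, inferred from the shift in the
# nutrient:marker ratio between diet and feces. Ratios are unit-invariant, so
# g/kg DM inputs behave exactly like the percent symbols of the original
# formulation.

#' Apparent digestibility coefficient from marker ratios
#'
#' `ADC (%) = (1 - (Nf/Nd) * (Md/Mf)) * 100`, where N is the nutrient and M
#' the inert marker, in diet (d) and feces (f).
#'
#' @param diet a [diet_formulation()].
#' @param feces a [fecal_sample()] from the same diet.
#' @param nutrient nutrient name, present in both records.
#' @return ADC in percent. Values outside [0, 100] are possible with noisy
#'   marker data and are returned unclipped.
#' @export
compute_adc <- function(diet, feces, nutrient) {
  nd <- diet_nutrient(diet, nutrient)
  nf <- diet_nutrient(feces, nutrient)
  stop_if(nd <= 0, sprintf("nutrient '%s' is zero in diet '%s'", nutrient, diet$diet_id))
  stop_if(feces$marker <= 0, "zero marker in feces")
  (1 - (nf / nd) * (diet$marker / feces$marker)) * 100
}

#' ADC table for all shared nutrients of a trial
#'
#' Pools are matched by `diet_id`; the default convention is pool-then-compute
#' (one fecal sample per diet). ADCs outside [0, 100] trigger a warning via
#' [adc_table()] but are never clipped.
#'
#' @param diets list of [diet_formulation()].
#' @param feces list of [fecal_sample()].
#' @param nutrients nutrient names to use; default: all nutrients present in
#'   both the diet and its fecal sample.
#' @return An [adc_table()].
#' @export
adc_from_tables <- function(diets, feces, nutrients = NULL) {
  rows <- lapply(diets, function(d) {
    f <- find_diet(feces, d$diet_id)
    nn <- if (is.null(nutrients))
      intersect(names(d$nutrients), names(f$nutrients)) else nutrients
    nn <- nn[vapply(nn, function(n) diet_nutrient(d, n) > 0, TRUE)]
    data.frame(diet_id = d$diet_id, nutrient = nn,
               adc = vapply(nn, function(n) compute_adc(d, f, n), 0),
               stringsAsFactors = FALSE)
  })
  adc_table(do.call(rbind, rows))
}

#' Digestible nutrient content
#'
#' @param dietary dietary content, g/kg DM.
#' @param adc apparent digestibility coefficient, percent.
#' @return Digestible content, g/kg DM (`dietary * adc / 100`).
#' @export
digestible_content <- function(dietary, adc) {
  stop_if(any(dietary < 0), "dietary content must be non-negative")
  dietary * adc / 100
}

#' Geometric mean body weight
#'
#' `sqrt(initial * final) / 1000`: the geometric mean of initial and final
#' body weight (g) expressed in kg, the conventional normaliser for daily
#' nutrient intake over a growth interval.
#'
#' @param initial,final body weights, g; both > 0.
#' @return Geometric body weight in kg.
#' @export
geometric_body_weight <- function(initial, final) {
  stop_if(any(initial <= 0) || any(final <= 0), "weights must be positive")
  sqrt(initial * final) / 1000
}

#' Daily digestible nutrient intake per unit geometric body weight
#'
#' `(feed_intake/duration) * content/1000 * adc/100 / geometric_bw`, in
#' g/kg BW/day. Feed intake is used as fed by default (the basis on which the
#' motivating trial's intake tables are reproducible); set `dm_basis = TRUE`
#' to convert via the diet's dry-matter fraction.
#'
#' @param tank a [tank_record()].
#' @param diet the matching [diet_formulation()].
#' @param adc ADC for the nutrient, percent.
#' @param nutrient nutrient name.
#' @param dm_basis convert feed intake to dry matter first?
#' @return Daily digestible intake, g/kg body weight/day.
#' @export
daily_digestible_intake <- function(tank, diet, adc, nutrient, dm_basis = FALSE) {
  fi <- tank$feed_intake
  if (dm_basis) fi <- fi * diet$dry_matter
  daily_nutrient <- (fi / tank$duration) * diet_nutrient(diet, nutrient) / 1000
  daily_nutrient * (adc / 100) /
    geometric_body_weight(tank$initial_weight, tank$final_weight)
}

#' Digestible contents and daily intakes for a whole trial
#'
#' One row per diet and nutrient: dietary content, ADC, digestible content,
#' and (averaged over the diet's tanks) the daily digestible intake per kg
#' geometric body weight.
#'
#' @param diets list of [diet_formulation()].
#' @param adc an [adc_table()].
#' @param tanks list of [tank_record()].
#' @param nutrients nutrient names; default: all nutrients in the ADC table.
#' @param dm_basis passed to [daily_digestible_intake()].
#' @return A data frame of class `digestible_profile`.
#' @export
digestible_profile <- function(diets, adc, tanks, nutrients = NULL,
                               dm_basis = FALSE) {
  tank_diet <- vapply(tanks, `[[`, "", "diet_id")
  rows <- lapply(diets, function(d) {
    nn <- if (is.null(nutrients))
      unique(adc$nutrient[adc$diet_id == d$diet_id]) else nutrients
    tks <- tanks[tank_diet == d$diet_id]
    do.call(rbind, lapply(nn, function(n) {
      a <- adc_value(adc, d$diet_id, n)
      dc <- digestible_content(diet_nutrient(d, n), a)
      ddi <- if (length(tks))
        mean(vapply(tks, daily_digestible_intake, 0, diet = d, adc = a,
                    nutrient = n, dm_basis = dm_basis)) else NA_real_
      data.frame(diet_id = d$diet_id, nutrient = n,
                 dietary_content = diet_nutrient(d, n), adc = a,
                 digestible_content = dc, daily_digestible_intake = ddi,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("digestible_profile", "data.frame")
  out
}
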