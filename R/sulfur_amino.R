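# Total sulfur amino acid (TSAA) dose algebra. Two conventions are in use:
# TSAA[Met + Cys] simply sums the two doses; TSAA[Met] expresses cysteine in
# methionine equivalents via the molecular-weight ratio, so that a mole of Cys
# counts as a mole of Met. All chained computations carry full precision;
# rounding to one decimal is a report-time concern only.

#' Molecular weights of methionine and cysteine
#'
#' Defaults: Met 149.21 g/mol, Cys 121.16 g/mol.
#'
#' @param met,cys molecular weights in g/mol, both > 0.
#' @return An object of class `molecular_weights`.
#' @export
molecular_weights <- function(met = 149.21, cys = 121.16) {
  stop_if(met <= 0 || cys <= 0, "molecular weights must be positive")
  structure(list(met = met, cys = cys), class = "molecular_weights")
}

#' TSAA as the plain sum of methionine and cysteine
#'
#' @param met,cys doses in the same units (g/kg or g/kg BW/day); >= 0.
#' @return `met + cys`.
#' @export
tsaa_met_plus_cys <- function(met, cys) {
  stop_if(any(met < 0) || any(cys < 0), "doses must be non-negative")
  met + cys
}

#' TSAA in methionine equivalents
#'
#' `met + cys * (MW_met / MW_cys)`: cysteine converted to the mass of
#' methionine carrying the same molar amount of sulfur amino acid.
#'
#' @param met,cys doses in the same units; >= 0.
#' @param mw a [molecular_weights()] object.
#' @return Methionine-equivalent TSAA dose.
#' @export
tsaa_met_equivalent <- function(met, cys, mw = molecular_weights()) {
  stop_if(any(met < 0) || any(cys < 0), "doses must be non-negative")
  met + cys * (mw$met / mw$cys)
}

#' TSAA dose table on dietary, digestible and daily-intake bases
#'
#' Chains the digestibility operations for the digestible and daily-intake
#' bases and evaluates both TSAA definitions per diet, at full precision.
#'
#' @param diets list of [diet_formulation()]; must contain `methionine` and
#'   `cysteine`.
#' @param adc an [adc_table()] with Met and Cys entries; required for the
#'   digestible and daily-intake bases.
#' @param tanks list of [tank_record()]; required for the daily-intake basis.
#' @param basis subset of `c("dietary", "digestible", "daily_intake")`.
#' @param mw a [molecular_weights()] object.
#' @param dm_basis passed to [daily_digestible_intake()].
#' @return A data frame with columns `diet_id`, `basis`, `met`, `cys`,
#'   `tsaa_met_plus_cys`, `tsaa_met_equivalent`.
#' @export
tsaa_dose_table <- function(diets, adc = NULL, tanks = NULL,
                            basis = c("dietary", "digestible", "daily_intake"),
                            mw = molecular_weights(), dm_basis = FALSE) {
  basis <- match.arg(basis, several.ok = TRUE)
  stop_if(any(basis != "dietary") && is.null(adc),
          "adc table required for digestible / daily-intake bases")
  stop_if("daily_intake" %in% basis && is.null(tanks),
          "tanks required for the daily-intake basis")
  tank_diet <- if (!is.null(tanks)) vapply(tanks, `[[`, "", "diet_id")
  rows <- lapply(diets, function(d) {
    met_d <- diet_nutrient(d, "methionine")
    cys_d <- diet_nutrient(d, "cysteine")
    do.call(rbind, lapply(basis, function(b) {
      if (b == "dietary") {
        met <- met_d; cys <- cys_d
      } else {
        a_met <- adc_value(adc, d$diet_id, "methionine")
        a_cys <- adc_value(adc, d$diet_id, "cysteine")
        if (b == "digestible") {
          met <- digestible_content(met_d, a_met)
          cys <- digestible_content(cys_d, a_cys)
        } else {
          tks <- tanks[tank_diet == d$diet_id]
          stop_if(length(tks) == 0L,
                  sprintf("no tanks for diet '%s'", d$diet_id))
          met <- mean(vapply(tks, daily_digestible_intake, 0, diet = d,
                             adc = a_met, nutrient = "methionine",
                             dm_basis = dm_basis))
          cys <- mean(vapply(tks, daily_digestible_intake, 0, diet = d,
                             adc = a_cys, nutrient = "cysteine",
                             dm_basis = dm_basis))
        }
      }
      data.frame(diet_id = d$diet_id, basis = b, met = met, cys = cys,
                 tsaa_met_plus_cys = tsaa_met_plus_cys(met, cys),
                 tsaa_met_equivalent = tsaa_met_equivalent(met, cys, mw),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
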