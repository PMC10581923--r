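#' Reference giant grouper methionine trial tables
#'
#' Loads the per-diet tables of the juvenile giant grouper
#' (*Epinephelus lanceolatus*) graded-methionine feeding trial that this
#' package's pipeline was designed around: amino acid composition (g/kg DM,
#' yttrium marker at 1.0 g/kg), amino acid apparent digestibility
#' coefficients, and tank biometry. The tank table is a constructed stand-in:
#' per-tank raw data were never published, so each diet's printed mean
#' biometry (initial/final weight, feed intake, 14 fish, 38 days) is
#' replicated across its three tanks -- hence the `_synthetic` file label.
#' Diet-level arithmetic (digestible contents, daily intakes, TSAA algebra)
#' is exact on these tables; between-tank variance is not represented.
#'
#' @return A list with elements `diets` (list of [diet_formulation()]),
#'   `adc` (an [adc_table()]) and `tanks` (list of [tank_record()]).
#' @examples
#' trial <- reference_trial()
#' length(trial$diets)
#' @export
reference_trial <- function() {
  ext <- function(f) system.file("extdata", f, package = "nutrireq",
                                 mustWork = TRUE)
  diets <- read_diet_table(ext("grouper_diets.csv"))
  list(diets = diets,
       adc = read_adc_table(ext("grouper_adc.csv")),
       tanks = read_tank_table(ext("grouper_tanks_synthetic.csv"),
                               diets = diets))
}
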