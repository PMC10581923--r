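#' @title Domain records for feeding-trial tables
#' @description
#' Lightweight S3 records shared by all pipeline stages. Nutrient contents are
#' always stored in g/kg dry matter (DM); percent inputs are unit-invariant in
#' the marker-ratio arithmetic and may be converted on read.
#' @name trial-records
NULL

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Diet formulation record
#'
#' One experimental diet: nutrient contents (g/kg DM), the inert-marker level
#' (e.g. yttrium oxide) and the dry-matter fraction of the feed as fed.
#'
#' @param diet_id character scalar, opaque identifier.
#' @param nutrients named numeric vector of contents in g/kg DM.
#' @param marker inert-marker content, g/kg DM; must be > 0.
#' @param dry_matter dry-matter fraction of the feed, in (0, 1].
#' @param gross_energy optional gross energy, MJ/kg.
#' @return An object of class `diet_formulation`.
#' @export
diet_formulation <- function(diet_id, nutrients, marker, dry_matter = 1,
                             gross_energy = NA_real_) {
  stop_if(length(diet_id) != 1L || is.na(diet_id) || !nzchar(diet_id),
          "diet_id must be a non-empty scalar")
  nutrients <- unlist(nutrients)
  stop_if(is.null(names(nutrients)) || any(!nzchar(names(nutrients))),
          "nutrients must be a named numeric vector")
  stop_if(!is.numeric(nutrients) || anyNA(nutrients) || any(nutrients < 0),
          "nutrient contents must be non-negative numbers")
  stop_if(!is.numeric(marker) || length(marker) != 1L || is.na(marker) || marker <= 0,
          "marker content must be a single positive number")
  stop_if(!is.numeric(dry_matter) || is.na(dry_matter) ||
            dry_matter <= 0 || dry_matter > 1,
          "dry_matter must lie in (0, 1]")
  structure(list(diet_id = as.character(diet_id),
                 nutrients = nutrients,
                 marker = as.numeric(marker),
                 dry_matter = as.numeric(dry_matter),
                 gross_energy = as.numeric(gross_energy)),
            class = "diet_formulation")
}

#' Fecal sample record (pooled per diet or per tank)
#'
#' @param diet_id diet the sample belongs to.
#' @param nutrients named numeric vector, g/kg DM (ratios are unit-invariant).
#' @param marker inert-marker content in the feces; must be > 0.
#' @return An object of class `fecal_sample`.
#' @export
fecal_sample <- function(diet_id, nutrients, marker) {
  nutrients <- unlist(nutrients)
  stop_if(!is.numeric(nutrients) || anyNA(nutrients) || any(nutrients < 0),
          "fecal nutrient contents must be non-negative")
  stop_if(!is.numeric(marker) || length(marker) != 1L || is.na(marker) || marker <= 0,
          "fecal marker content must be positive")
  structure(list(diet_id = as.character(diet_id),
                 nutrients = nutrients,
                 marker = as.numeric(marker)),
            class = "fecal_sample")
}

#' Tank biometry record
#'
#' Weights are tank means per fish (g); `feed_intake` is total feed per fish
#' over the trial (g, as fed unless converted by the caller).
#'
#' @param tank_id,diet_id identifiers.
#' @param n_fish number of fish stocked, >= 1.
#' @param initial_weight,final_weight mean body weight per fish, g.
#' @param feed_intake total feed intake per fish over the trial, g.
#' @param duration trial duration, days.
#' @return An object of class `tank_record`.
#' @export
tank_record <- function(tank_id, diet_id, n_fish, initial_weight, final_weight,
                        feed_intake, duration) {
  stop_if(n_fish < 1, "n_fish must be >= 1")
  stop_if(initial_weight <= 0 || final_weight <= 0, "weights must be positive")
  stop_if(feed_intake < 0, "feed_intake must be non-negative")
  stop_if(duration <= 0, "duration must be positive")
  structure(list(tank_id = as.character(tank_id), diet_id = as.character(diet_id),
                 n_fish = as.integer(n_fish),
                 initial_weight = as.numeric(initial_weight),
                 final_weight = as.numeric(final_weight),
                 feed_intake = as.numeric(feed_intake),
                 duration = as.numeric(duration)),
            class = "tank_record")
}

#' Individual fish record
#'
#' @param fish_id,tank_id identifiers.
#' @param body_weight total body weight, g.
#' @param liver_weight,viscera_weight optional organ weights, g; must be
#'   non-negative and smaller than `body_weight`.
#' @return An object of class `fish_record`.
#' @export
fish_record <- function(fish_id, tank_id, body_weight,
                        liver_weight = NA_real_, viscera_weight = NA_real_) {
  stop_if(body_weight <= 0, "body_weight must be positive")
  for (w in c(liver = liver_weight, viscera = viscera_weight)) {
    if (!is.na(w)) stop_if(w < 0 || w >= body_weight,
                           "organ weights must be >= 0 and < body_weight")
  }
  structure(list(fish_id = as.character(fish_id), tank_id = as.character(tank_id),
                 body_weight = as.numeric(body_weight),
                 liver_weight = as.numeric(liver_weight),
                 viscera_weight = as.numeric(viscera_weight)),
            class = "fish_record")
}

#' Apparent digestibility coefficient table
#'
#' Long-format table of per-diet, per-nutrient ADCs in percent. Values above
#' 100 or below 0 (possible with noisy marker analyses) are retained with a
#' warning and never clipped: downstream fits must see the real data.
#'
#' @param entries data frame with columns `diet_id`, `nutrient`, `adc`.
#' @return An object of classes `adc_table`, `data.frame`.
#' @export
adc_table <- function(entries) {
  need <- c("diet_id", "nutrient", "adc")
  stop_if(!all(need %in% names(entries)),
          "adc table needs columns diet_id, nutrient, adc")
  entries <- as.data.frame(entries)[need]
  stop_if(!is.numeric(entries$adc) || anyNA(entries$adc),
          "adc values must be numeric and non-missing")
  stop_if(anyDuplicated(entries[c("diet_id", "nutrient")]) > 0,
          "duplicated (diet_id, nutrient) entry in adc table")
  if (any(entries$adc > 100))
    warning("ADC > 100% retained unclipped (marker noise?)", call. = FALSE)
  if (any(entries$adc < 0))
    warning("negative ADC retained unclipped (marker noise?)", call. = FALSE)
  entries$diet_id <- as.character(entries$diet_id)
  entries$nutrient <- as.character(entries$nutrient)
  class(entries) <- c("adc_table", "data.frame")
  entries
}

#' Look up one ADC value
#'
#' @param adc an [adc_table()].
#' @param diet_id,nutrient the entry to retrieve.
#' @return ADC in percent.
#' @export
adc_value <- function(adc, diet_id, nutrient) {
  i <- adc$diet_id == diet_id & adc$nutrient == nutrient
  stop_if(sum(i) == 0L, sprintf("no ADC for diet '%s', nutrient '%s'",
                                diet_id, nutrient))
  adc$adc[which(i)[1L]]
}

# ---- readers -----------------------------------------------------------------

read_table_checked <- function(path, sep = ",") {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

first_col <- function(df, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit)) hit[1L] else NA_character_
}

as_num_checked <- function(x, what) {
  y <- suppressWarnings(as.numeric(x))
  stop_if(anyNA(y) && !anyNA(x), sprintf("non-numeric value in %s column", what))
  stop_if(anyNA(y), sprintf("missing or non-numeric value in %s column", what))
  y
}

#' Read a diet formulation table
#'
#' Expects a single header row; one row per diet. A diet-id column
#' (`diet_id` or `diet`), a `marker` column, optional `dry_matter` (fraction)
#' and `gross_energy` columns; every other column is treated as a nutrient in
#' g/kg DM and preserved.
#'
#' @param path file path of a delimited text file.
#' @param sep field delimiter, `","` by default, `"\t"` accepted.
#' @return A list of [diet_formulation()] records.
#' @export
read_diet_table <- function(path, sep = ",") {
  df <- read_table_checked(path, sep)
  if (nrow(df) == 0L) {
    warning("empty diet table", call. = FALSE)
    return(list())
  }
  idc <- first_col(df, c("diet_id", "diet"))
  stop_if(is.na(idc), "diet table has no diet_id column")
  stop_if(anyDuplicated(df[[idc]]) > 0, "duplicated diet_id in diet table")
  stop_if(!"marker" %in% names(df), "diet table has no marker column")
  special <- c(idc, "marker", "dry_matter", "gross_energy")
  nutr_cols <- setdiff(names(df), special)
  lapply(seq_len(nrow(df)), function(i) {
    nv <- vapply(nutr_cols, function(cl) as_num_checked(df[[cl]][i], cl), 0)
    names(nv) <- nutr_cols
    diet_formulation(
      diet_id = df[[idc]][i], nutrients = nv,
      marker = as_num_checked(df$marker[i], "marker"),
      dry_matter = if ("dry_matter" %in% names(df))
        as_num_checked(df$dry_matter[i], "dry_matter") else 1,
      gross_energy = if ("gross_energy" %in% names(df))
        suppressWarnings(as.numeric(df$gross_energy[i])) else NA_real_)
  })
}

#' Read a fecal composition table
#'
#' Same layout as the diet table: a diet-id column, a `marker` column, and
#' nutrient columns in g/kg DM.
#'
#' @inheritParams read_diet_table
#' @return A list of [fecal_sample()] records.
#' @export
read_feces_table <- function(path, sep = ",") {
  df <- read_table_checked(path, sep)
  if (nrow(df) == 0L) {
    warning("empty feces table", call. = FALSE)
    return(list())
  }
  idc <- first_col(df, c("diet_id", "diet"))
  stop_if(is.na(idc), "feces table has no diet_id column")
  stop_if(!"marker" %in% names(df), "feces table has no marker column")
  nutr_cols <- setdiff(names(df), c(idc, "marker"))
  lapply(seq_len(nrow(df)), function(i) {
    nv <- vapply(nutr_cols, function(cl) as_num_checked(df[[cl]][i], cl), 0)
    names(nv) <- nutr_cols
    fecal_sample(df[[idc]][i], nv, as_num_checked(df$marker[i], "marker"))
  })
}

#' Read a tank biometry table
#'
#' Columns: `tank_id`, `diet_id`, `n_fish`, `initial_weight`, `final_weight`,
#' `feed_intake`, `duration`. When `diets` is supplied every `diet_id` must
#' appear in it (cross-validation).
#'
#' @inheritParams read_diet_table
#' @param diets optional list of [diet_formulation()] for cross-checking.
#' @return A list of [tank_record()] records.
#' @export
read_tank_table <- function(path, sep = ",", diets = NULL) {
  df <- read_table_checked(path, sep)
  need <- c("tank_id", "diet_id", "n_fish", "initial_weight", "final_weight",
            "feed_intake", "duration")
  stop_if(!all(need %in% names(df)),
          paste("tank table needs columns:", paste(need, collapse = ", ")))
  if (!is.null(diets)) {
    known <- vapply(diets, `[[`, "", "diet_id")
    bad <- setdiff(unique(df$diet_id), known)
    stop_if(length(bad) > 0,
            paste("tank table references unknown diet_id:", paste(bad, collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i)
    tank_record(df$tank_id[i], df$diet_id[i],
                as_num_checked(df$n_fish[i], "n_fish"),
                as_num_checked(df$initial_weight[i], "initial_weight"),
                as_num_checked(df$final_weight[i], "final_weight"),
                as_num_checked(df$feed_intake[i], "feed_intake"),
                as_num_checked(df$duration[i], "duration")))
}

#' Read an individual-fish table
#'
#' Columns: `fish_id`, `tank_id`, `body_weight`; optional `liver_weight`
#' and `viscera_weight`.
#'
#' @inheritParams read_diet_table
#' @return A list of [fish_record()] records.
#' @export
read_fish_table <- function(path, sep = ",") {
  df <- read_table_checked(path, sep)
  need <- c("fish_id", "tank_id", "body_weight")
  stop_if(!all(need %in% names(df)),
          paste("fish table needs columns:", paste(need, collapse = ", ")))
  opt <- function(cl, i) if (cl %in% names(df))
    suppressWarnings(as.numeric(df[[cl]][i])) else NA_real_
  lapply(seq_len(nrow(df)), function(i)
    fish_record(df$fish_id[i], df$tank_id[i],
                as_num_checked(df$body_weight[i], "body_weight"),
                opt("liver_weight", i), opt("viscera_weight", i)))
}

#' Read an ADC table (long format)
#'
#' @inheritParams read_diet_table
#' @return An [adc_table()].
#' @export
read_adc_table <- function(path, sep = ",") {
  adc_table(read_table_checked(path, sep))
}

# ---- writers -----------------------------------------------------------------

write_precise_csv <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  stop_if(!ok, sprintf("cannot write to '%s'", path))
  invisible(path)
}

#' Write staged results to a delimited text file
#'
#' Numeric values are written at full (17 significant digits) precision so a
#' write/read round trip reproduces them; display rounding belongs in reports
#' only. Lists of dose-response fits are flattened to one row per fit and
#' sorted by AIC ascending.
#'
#' @param x an [adc_table()], a data frame of results, a list of
#'   `dose_response_fit` objects, or a list of tank/diet/fecal records.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, sep = ",") UseMethod("write_results")

#' @export
write_results.adc_table <- function(x, path, sep = ",") {
  write_precise_csv(as.data.frame(x), path, sep)
}

#' @export
write_results.data.frame <- function(x, path, sep = ",") {
  write_precise_csv(x, path, sep)
}

#' @export
write_results.list <- function(x, path, sep = ",") {
  stop_if(length(x) == 0L, "nothing to write")
  if (inherits(x[[1L]], "dose_response_fit")) {
    df <- do.call(rbind, lapply(x, as.data.frame))
    df <- df[order(df$aic), , drop = FALSE]
    return(write_precise_csv(df, path, sep))
  }
  if (inherits(x[[1L]], "tank_record") || inherits(x[[1L]], "fish_record")) {
    df <- do.call(rbind, lapply(x, function(r) as.data.frame(unclass(r))))
    return(write_precise_csv(df, path, sep))
  }
  if (inherits(x[[1L]], "diet_formulation") || inherits(x[[1L]], "fecal_sample")) {
    nut <- sort(unique(unlist(lapply(x, function(d) names(d$nutrients)))))
    rows <- lapply(x, function(d) {
      base <- data.frame(diet_id = d$diet_id, stringsAsFactors = FALSE)
      for (n in nut) base[[n]] <- unname(d$nutrients[n])
      base$marker <- d$marker
      if (inherits(d, "diet_formulation")) {
        base$dry_matter <- d$dry_matter
        base$gross_energy <- d$gross_energy
      }
      base
    })
    return(write_precise_csv(do.call(rbind, rows), path, sep))
  }
  stop("no write_results method for this list content", call. = FALSE)
}

#' Diet record utilities
#'
#' `diet_nutrient()` extracts one nutrient content; `diet_ids()` lists the
#' identifiers of a record list; `find_diet()` retrieves a record by id.
#'
#' @param diet a [diet_formulation()] or [fecal_sample()].
#' @param nutrient nutrient name.
#' @return `diet_nutrient()`: content in g/kg DM.
#' @export
diet_nutrient <- function(diet, nutrient) {
  stop_if(!nutrient %in% names(diet$nutrients),
          sprintf("nutrient '%s' absent from '%s'", nutrient, diet$diet_id))
  unname(diet$nutrients[nutrient])
}

#' @rdname diet_nutrient
#' @param x list of records having a `diet_id` field.
#' @export
diet_ids <- function(x) vapply(x, `[[`, "", "diet_id")

#' @rdname diet_nutrient
#' @param diet_id identifier to look up.
#' @export
find_diet <- function(x, diet_id) {
  i <- match(diet_id, diet_ids(x))
  stop_if(is.na(i), sprintf("no record with diet_id '%s'", diet_id))
  x[[i]]
}
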