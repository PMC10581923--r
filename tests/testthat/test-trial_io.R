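test_that("diet table round-trips through write/read at full precision", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  diets <- toy_diets()
  write_results(diets, tmp)
  back <- read_diet_table(tmp)
  expect_length(back, 2L)
  expect_identical(diet_ids(back), c("A", "B"))
  for (i in 1:2) {
    expect_equal(back[[i]]$nutrients[sort(names(back[[i]]$nutrients))],
                 diets[[i]]$nutrients[sort(names(diets[[i]]$nutrients))],
                 tolerance = 1e-12)
    expect_equal(back[[i]]$marker, diets[[i]]$marker)
    expect_equal(back[[i]]$dry_matter, diets[[i]]$dry_matter)
  }
})

test_that("reference diet table reproduces the published methionine series", {
  tr <- reference_trial()
  expect_length(tr$diets, 6L)
  met <- vapply(tr$diets, diet_nutrient, 0, nutrient = "methionine")
  expect_equal(met, c(9.5, 11.6, 14.0, 17.9, 21.5, 18.6))
  expect_length(tr$tanks, 18L)
})

test_that("degenerate and malformed diet tables are handled", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("diet_id,methionine,marker", tmp)
  expect_warning(out <- read_diet_table(tmp), "empty")
  expect_identical(out, list())

  writeLines(c("diet_id,methionine,marker", "D1,9.5,1", "D1,11.6,1"), tmp)
  expect_error(read_diet_table(tmp), "duplicated diet_id")

  writeLines(c("methionine,marker", "9.5,1"), tmp)
  expect_error(read_diet_table(tmp), "diet_id")

  writeLines(c("diet_id,methionine,marker", "D1,abc,1"), tmp)
  expect_error(read_diet_table(tmp), "non-numeric")
})

test_that("tank table validation catches bad rows and unknown diets", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  hdr <- "tank_id,diet_id,n_fish,initial_weight,final_weight,feed_intake,duration"
  writeLines(c(hdr, "T1,A,14,83.8,247.9,135.5,0"), tmp)
  expect_error(read_tank_table(tmp), "duration")
  writeLines(c(hdr, "T1,A,14,-5,247.9,135.5,38"), tmp)
  expect_error(read_tank_table(tmp), "positive")
  writeLines(c(hdr, "T1,Z,14,83.8,247.9,135.5,38"), tmp)
  expect_error(read_tank_table(tmp, diets = toy_diets()), "unknown diet_id")
  writeLines(c(hdr, "T1,A,14,83.8,247.9,135.5,38"), tmp)
  tks <- read_tank_table(tmp, diets = toy_diets())
  expect_length(tks, 1L)
  expect_s3_class(tks[[1]], "tank_record")
})

test_that("adc table validates, warns on out-of-range, and round-trips", {
  df <- data.frame(diet_id = c("A", "A", "B"),
                   nutrient = c("methionine", "cysteine", "methionine"),
                   adc = c(88.5, 60.9, 94.2))
  tab <- adc_table(df)
  expect_equal(adc_value(tab, "A", "cysteine"), 60.9)
  expect_error(adc_value(tab, "B", "cysteine"), "no ADC")
  expect_warning(adc_table(data.frame(diet_id = "A", nutrient = "x", adc = 104)),
                 "ADC > 100")
  expect_warning(adc_table(data.frame(diet_id = "A", nutrient = "x", adc = -3)),
                 "negative ADC")
  expect_error(adc_table(df[c(1, 1), ]), "duplicated")

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results(tab, tmp)
  expect_equal(read_adc_table(tmp)$adc, tab$adc, tolerance = 1e-12)
})

test_that("dose-response fit lists are written sorted by AIC", {
  set.seed(1)
  x <- c(6, 8, 10, 12, 14, 17, 20, 24)
  y <- eval_model(lognormal_model(47, 17, 1.35), x) + rnorm(8, 0, 0.05)
  fits <- list(fit_model("cubic", x, y), fit_model("lognormal", x, y))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results(fits, tmp)
  back <- utils::read.csv(tmp)
  expect_false(is.unsorted(back$aic))
})

test_that("record constructors enforce their invariants", {
  expect_error(diet_formulation("A", c(methionine = -1), marker = 1), "non-negative")
  expect_error(diet_formulation("A", c(methionine = 1), marker = 0), "positive")
  expect_error(diet_formulation("A", c(methionine = 1), marker = 1,
                                dry_matter = 1.2), "dry_matter")
  expect_error(tank_record("T", "A", 0, 80, 90, 10, 38), "n_fish")
  expect_error(fish_record("F", "T", 100, liver_weight = 101), "organ")
  expect_error(fecal_sample("A", c(methionine = 1), marker = -1), "positive")
})
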