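test_that("a small residue file reads with full validation and no rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_residue_table(tiny_study(), path)
  study <- read_residue_table(path)
  expect_s3_class(study, "residue_study")
  expect_equal(nrow(study$measurements), 2)
  expect_equal(nrow(study$rejected$measurements), 0)
  expect_equal(study$measurements$concentration_ug_per_kg, c(77, NA))
})

test_that("write-then-read round-trips are record-identical", {
  for (study in list(tiny_study(), example_study_2020(), example_study_2019())) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_residue_table(study, path)
    back <- read_residue_table(path)
    key <- function(s) {
      list(
        samples = dplyr::arrange(s$samples, .data$sample_id),
        measurements = dplyr::arrange(s$measurements, .data$sample_id, .data$substance)
      )
    }
    expect_equal(key(back), key(study))
  }
})

test_that("an empty data section gives empty collections and a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_residue_table(tiny_study(), path)
  writeLines(readLines(path)[1], path) # keep only the header
  expect_warning(study <- read_residue_table(path), "no data rows")
  expect_equal(nrow(study$samples), 0)
  expect_equal(nrow(study$measurements), 0)
})

test_that("invariant-violating rows are rejected with a reason, not dropped silently", {
  s <- tiny_study()
  m <- s$measurements
  m$concentration_ug_per_kg[m$status == "not_detected"] <- 5
  study <- as_residue_study(s$samples, m)
  expect_equal(nrow(study$measurements), 1)
  expect_match(study$rejected$measurements$reason, "non-detected")

  bad_samples <- s$samples
  bad_samples$matrix[1] <- "honey"
  bad_samples$treatment_arm[2] <- "placebo"
  study2 <- as_residue_study(bad_samples, s$measurements)
  expect_equal(nrow(study2$samples), 0)
  expect_setequal(study2$rejected$samples$reason,
                  c("unknown matrix value", "unknown treatment_arm value"))

  dup <- dplyr::bind_rows(s$samples, dplyr::mutate(s$samples[1, ], sample_id = "s3"))
  study3 <- as_residue_study(dup, s$measurements)
  expect_match(study3$rejected$samples$reason, "duplicate")
})

test_that("a missing mandatory column raises a schema error naming it", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_residue_table(tiny_study(), path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(tab[setdiff(names(tab), "loq_ug_kg")], path)
  expect_error(read_residue_table(path), "loq_ug_kg",
               class = "pollenrisk_validation_error")
})

test_that("schema mapping renames nonstandard headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_residue_table(tiny_study(), path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  names(tab)[names(tab) == "conc_ug_kg"] <- "concentration"
  readr::write_csv(tab, path)
  study <- read_residue_table(path, schema = c(conc_ug_kg = "concentration"))
  expect_equal(sort(study$measurements$concentration_ug_per_kg), 77)
})

test_that("resolve_concentration honors status and policy", {
  m <- tibble::tibble(
    sample_id = "s",
    substance = "x",
    status = c("quantified", "trace_below_loq", "not_detected"),
    concentration_ug_per_kg = c(1484, 1.0, NA),
    loq_ug_per_kg = 10,
    semiquantitative = FALSE
  )
  for (policy in c("reported_value", "zero", "half_loq", "loq")) {
    expect_equal(resolve_concentration(m[1, ], policy), 1484)
  }
  expect_equal(resolve_concentration(m[2, ], "reported_value"), 1.0)
  expect_equal(resolve_concentration(m[2, ], "zero"), 0)
  expect_equal(resolve_concentration(m[2, ], "half_loq"), 5)
  expect_equal(resolve_concentration(m[2, ], "loq"), 10)
  expect_equal(resolve_concentration(m[3, ], "reported_value"), 0)
  expect_equal(resolve_concentration(m[3, ], "half_loq"), 5)
  expect_equal(resolve_concentration(m[3, ], "loq"), 10)

  na <- dplyr::mutate(m[3, ], status = "not_analyzed")
  expect_error(resolve_concentration(na, "zero"), "not_analyzed",
               class = "pollenrisk_validation_error")

  lost <- dplyr::mutate(m[2, ], concentration_ug_per_kg = NA_real_)
  expect_warning(v <- resolve_concentration(lost, "reported_value"), "falling back")
  expect_equal(v, 10)
})

test_that("substance summaries count detections and bracket the range", {
  s20 <- example_study_2020()
  tau <- summarize_substance(s20, "tau-fluvalinate", "pollen")
  expect_equal(tau$n_samples, 41)
  expect_equal(tau$n_detected, 8)
  expect_equal(tau$min_conc_ug_per_kg, 1.0)
  expect_equal(tau$max_conc_ug_per_kg, 19.8)

  hbc <- summarize_substance(s20, "hexachlorobenzene", "pollen")
  expect_equal(hbc$n_detected, 1)
  expect_equal(hbc$min_conc_ug_per_kg, hbc$max_conc_ug_per_kg)

  nect <- summarize_substance(s20, "tau-fluvalinate", "nectar")
  expect_equal(nect$n_detected, 0)
  expect_true(is.na(nect$min_conc_ug_per_kg) && is.na(nect$max_conc_ug_per_kg))

  absent <- summarize_substance(s20, "deltamethrin", "pollen")
  expect_equal(absent$n_detected, 0)

  # glyphosate pollen rows are mostly not_analyzed: not counted as samples
  gly <- summarize_substance(s20, "glyphosate", "pollen")
  expect_lt(gly$n_samples, 41)
})

test_that("summaries are monotone in the censoring policy and detection counts are policy-invariant", {
  sim <- generate_study(synthetic_study_config(seed = 73))
  study <- sim$study
  subs <- unique(study$measurements$substance)
  for (s in subs) {
    z <- summarize_substance(study, s, "pollen", "zero")
    h <- summarize_substance(study, s, "pollen", "half_loq")
    l <- summarize_substance(study, s, "pollen", "loq")
    expect_equal(z$n_detected, h$n_detected)
    expect_equal(h$n_detected, l$n_detected)
    if (z$n_detected > 0) {
      expect_true(z$min_conc_ug_per_kg <= h$min_conc_ug_per_kg)
      expect_true(h$min_conc_ug_per_kg <= l$min_conc_ug_per_kg)
      expect_true(z$max_conc_ug_per_kg <= h$max_conc_ug_per_kg)
      expect_true(h$max_conc_ug_per_kg <= l$max_conc_ug_per_kg)
    }
  }
})
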