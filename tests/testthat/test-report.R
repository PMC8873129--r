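write_example_inputs <- function(dir, study = example_study_2020()) {
  residues <- file.path(dir, "residues.csv")
  tox <- file.path(dir, "toxicity.csv")
  write_residue_table(study, residues)
  readr::write_csv(toxicity_reference(), tox)
  list(residues = residues, toxicity = tox)
}

test_that("run_risk produces a risk CSV reproducing the derivable cells", {
  dir <- withr::local_tempdir()
  paths <- write_example_inputs(dir, example_study_2019())
  cfg <- list(residues = paths$residues, toxicity = paths$toxicity,
              year = "2019", out_dir = dir,
              profiles = list(nurse = list(pollen_low_mg = 6.5)))
  risk <- run_risk(cfg)
  on_disk <- readr::read_csv(file.path(dir, "risk_table.csv"), show_col_types = FALSE)
  expect_equal(nrow(on_disk), 5)
  thia <- on_disk[on_disk$substance == "thiacloprid", ]
  expect_equal(c(thia$nurse_low, thia$nurse_high), c(500.5, 17808))
  expect_equal(thia$acute_ratio_rounded, 1000)
  # thiacloprid carries the largest nurse-high exposure of the year
  expect_equal(which.max(on_disk$nurse_high), which(on_disk$substance == "thiacloprid"))
  log <- readLines(file.path(dir, "risk_run.log"))
  expect_true(any(grepl("policy: reported_value", log)))
})

test_that("substances without endpoints flow through as unknown", {
  dir <- withr::local_tempdir()
  paths <- write_example_inputs(dir)
  risk <- run_risk(list(residues = paths$residues, year = "2020", out_dir = dir))
  hbc <- risk[risk$substance == "hexachlorobenzene", ]
  expect_true(is.na(hbc$acute_ratio_rounded))
  expect_equal(hbc$chronic_flag, "unknown")
})

test_that("an empty residue table yields an empty risk table with a warning", {
  dir <- withr::local_tempdir()
  residues <- file.path(dir, "residues.csv")
  write_residue_table(tiny_study(), residues)
  writeLines(readLines(residues)[1], residues)
  expect_warning(
    expect_warning(risk <- run_risk(list(residues = residues, out_dir = dir)),
                   "no data rows"),
    "empty"
  )
  expect_equal(nrow(risk), 0)
  expect_equal(length(readLines(file.path(dir, "risk_table.csv"))), 1) # header only
})

test_that("run_stats writes per-timepoint tests and the composition correlation", {
  dir <- withr::local_tempdir()
  paths <- write_example_inputs(dir)
  out <- suppressWarnings(run_stats(list(
    residues = paths$residues, out_dir = dir,
    stats = list(substance = "tau-fluvalinate")
  )))
  tests <- readr::read_csv(file.path(dir, "stats_table.csv"), show_col_types = FALSE)
  expect_equal(tests$timepoint, 1:4)
  corr <- readr::read_csv(file.path(dir, "correlation.csv"), show_col_types = FALSE)
  expect_equal(nrow(corr), 1)
  expect_true(abs(corr$estimate) <= 1)
})

test_that("invalid configurations raise config errors", {
  expect_error(read_pipeline_config(list(sugar_fraction = 1.5)),
               class = "pollenrisk_config_error")
  expect_error(read_pipeline_config(list(stats = list(alpha = 0))),
               class = "pollenrisk_config_error")
  expect_error(run_risk(list()), "residues", class = "pollenrisk_config_error")
  expect_error(read_pipeline_config("/nonexistent.yml"),
               class = "pollenrisk_config_error")
})

test_that("markdown rendering fixes the column order and carries the footnote", {
  dir <- withr::local_tempdir()
  sums <- dplyr::mutate(summarize_matrix(example_study_2019(), "pollen"), year = "2019")
  rt <- build_risk_table(sums, profiles = default_profiles(list(nurse = list(pollen_low_mg = 6.5))))
  md <- file.path(dir, "risk.md")
  render_risk_table(rt, md, "markdown")
  lines <- readLines(md)
  expect_match(lines[1], "^\\| year \\| substance\\s+\\| residue_low")
  expect_true(any(grepl("1 000", lines))) # thiacloprid rounded ratio, thousands
  expect_true(any(grepl("nearest thousand", lines)))

  csv <- file.path(dir, "risk.csv")
  render_risk_table(rt, csv, "csv")
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 5)
  expect_error(render_risk_table(rt, md, "pdf"))
  expect_error(render_risk_table(rt[, -1], md, "markdown"),
               class = "pollenrisk_validation_error")
})

test_that("pipeline outputs are reproducible for identical inputs", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  paths <- write_example_inputs(dir1)
  cfg <- list(residues = paths$residues, year = "2020")
  r1 <- run_risk(c(cfg, list(out_dir = dir1)))
  r2 <- run_risk(c(cfg, list(out_dir = dir2)))
  expect_identical(r1, r2)
  expect_identical(readLines(file.path(dir1, "risk_table.csv")),
                   readLines(file.path(dir2, "risk_table.csv")))
})
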