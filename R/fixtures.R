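# Bundled example studies.
#
# Two deterministic, fully synthetic studies constructed in code to carry
# the published detection summaries of a two-year Finnish monitoring
# campaign: a preliminary year with semiquantitative pollen results
# (LOQ 10 ug/kg) and a main treated-vs-control year (per-substance LOQ
# 0.5-30 ug/kg, nectar entirely below LOQ). Only the detection summaries
# (counts, ranges) are anchored to the published study; which individual
# hive/timepoint carries each detection is this package's own arbitrary,
# documented assignment.

#' Example study: preliminary year (semiquantitative pollen screening)
#'
#' 24 pollen samples from 8 hives (2 per field, 4 fields, all treated; 3
#' collection timepoints), analyzed for 5 substances at LOQ 10 ug/kg. All
#' reported values are flagged semiquantitative, and several lie below the
#' LOQ, as screening-year results do. Detected ranges: lambda-cyhalothrin
#' 3.2-7.8 (3 samples), thiacloprid 77-1484 (3), tebuconazole 0.3-1.3 (2),
#' azoxystrobin 3.3-3.8 (2), indoxacarb 2.5 (1). No nectar was collected.
#'
#' @return a `residue_study`.
#' @export
example_study_2019 <- function() {
  fields <- c("F1", "F2", "F3", "F4")
  hives <- as.vector(outer(fields, c("a", "b"), function(f, k) paste0(f, "_H", k)))
  grid <- expand.grid(hive = hives, tp = 1:3, stringsAsFactors = FALSE)
  grid <- grid[order(grid$tp, grid$hive), ]
  samples <- tibble::tibble(
    sample_id = sprintf("Y19_%s_T%d", grid$hive, grid$tp),
    hive_id = grid$hive,
    field_id = substr(grid$hive, 1, 2),
    treatment_arm = "treated",
    matrix = "pollen",
    collection_date = as.Date("2019-06-02") + (grid$tp - 1) * 10L,
    timepoint = grid$tp,
    collection_duration_h = rep(c(24, 18, 6, 12, 20, 24, 8, 16), 3),
    crop_pollen_fraction = rep(c(0.59, 0.75, 0.147, 0.056, 0, 0.08, 0.97, 0.85), 3)
  )
  detections <- tibble::tribble(
    ~substance, ~sample_id, ~conc,
    "lambda-cyhalothrin", "Y19_F1_Ha_T2", 3.2,
    "lambda-cyhalothrin", "Y19_F2_Ha_T2", 5.0,
    "lambda-cyhalothrin", "Y19_F1_Hb_T3", 7.8,
    "thiacloprid", "Y19_F4_Ha_T1", 1484.0,
    "thiacloprid", "Y19_F4_Hb_T1", 210.0,
    "thiacloprid", "Y19_F4_Ha_T2", 77.0,
    "tebuconazole", "Y19_F1_Ha_T3", 0.3,
    "tebuconazole", "Y19_F3_Hb_T2", 1.3,
    "azoxystrobin", "Y19_F2_Hb_T1", 3.3,
    "azoxystrobin", "Y19_F3_Ha_T2", 3.8,
    "indoxacarb", "Y19_F4_Hb_T2", 2.5
  )
  substances <- unique(detections$substance)
  measurements <- expand.grid(sample_id = samples$sample_id,
                              substance = substances,
                              stringsAsFactors = FALSE)
  measurements <- dplyr::left_join(tibble::as_tibble(measurements), detections,
                                   by = c("sample_id", "substance"))
  measurements <- tibble::tibble(
    sample_id = measurements$sample_id,
    substance = measurements$substance,
    status = ifelse(is.na(measurements$conc), "not_detected", "quantified"),
    concentration_ug_per_kg = measurements$conc,
    loq_ug_per_kg = 10,
    semiquantitative = !is.na(measurements$conc)  # screening-year convention
  )
  as_residue_study(samples, measurements)
}

#' Example study: main year (treated vs control, nectar all below LOQ)
#'
#' 9 single-hive fields — 5 treated with a pyrethroid programme, 4 untreated
#' controls — sampled over 4 pollen timepoints (before treatment, after each
#' of three sprays), with 5 surplus collections from the treated hives
#' recorded as a 5th timepoint, for 41 pollen samples in total; plus 23
#' nectar samples (timepoints 1-3, four hives missing the first
#' collection), all below LOQ. Detections in pollen: tau-fluvalinate in 8 of
#' 41 samples, 1.0 (a trace below its 2 ug/kg LOQ) to 19.8 ug/kg, split
#' across the two post-spray timepoints in both arms; thiacloprid 3.0-101.0
#' (2 samples); hexachlorobenzene 1.0 (1 sample). Esfenvalerate was
#' analyzed but never found, and glyphosate only analyzed at timepoint 3.
#'
#' @return a `residue_study`.
#' @export
example_study_2020 <- function() {
  treated <- c("F1", "F3", "F4", "F8", "F9")
  fields <- sprintf("F%d", 1:9)
  arm <- ifelse(fields %in% treated, "treated", "control")
  hives <- tibble::tibble(field_id = fields, hive_id = sub("F", "H", fields),
                          treatment_arm = arm)
  dates <- as.Date(c("2020-06-26", "2020-06-29", "2020-07-06",
                     "2020-07-11", "2020-07-12"))
  mk <- function(h, tp, mtx) {
    tibble::tibble(
      sample_id = sprintf("Y20_%s_%s_T%d", h$hive_id, mtx, tp),
      hive_id = h$hive_id, field_id = h$field_id, treatment_arm = h$treatment_arm,
      matrix = mtx, collection_date = dates[tp], timepoint = tp,
      collection_duration_h = c(24, 18, 2, 8, 12, 24, 6, 16, 20)[match(h$hive_id, hives$hive_id)],
      crop_pollen_fraction = if (mtx == "pollen") {
        # 0-23% oilseed pollen, assigned independently of the residue pattern
        (c(5, 12, 0, 23, 8, 15, 2, 18, 10)[match(h$hive_id, hives$hive_id)] +
           2 * tp) / 100
      } else {
        NA_real_
      }
    )
  }
  pollen <- dplyr::bind_rows(lapply(1:4, function(tp) mk(hives, tp, "pollen")))
  surplus <- mk(hives[hives$treatment_arm == "treated", ], 5L, "pollen")
  nectar <- dplyr::bind_rows(lapply(1:3, function(tp) mk(hives, tp, "nectar")))
  nectar <- nectar[!(nectar$timepoint == 1 & nectar$hive_id %in% c("H6", "H7", "H8", "H9")), ]
  samples <- dplyr::bind_rows(pollen, surplus, nectar)

  loq <- c("tau-fluvalinate" = 2, "thiacloprid" = 0.5,
           "hexachlorobenzene" = 0.5, "esfenvalerate" = 1, "glyphosate" = 10)
  detections <- tibble::tribble(
    ~substance, ~sample_id, ~conc, ~status,
    "tau-fluvalinate", "Y20_H1_pollen_T3", 5.0, "quantified",
    "tau-fluvalinate", "Y20_H3_pollen_T3", 7.9, "quantified",
    "tau-fluvalinate", "Y20_H4_pollen_T3", 3.1, "quantified",
    "tau-fluvalinate", "Y20_H2_pollen_T3", 1.0, "trace_below_loq",
    "tau-fluvalinate", "Y20_H1_pollen_T4", 19.8, "quantified",
    "tau-fluvalinate", "Y20_H3_pollen_T4", 15.0, "quantified",
    "tau-fluvalinate", "Y20_H4_pollen_T4", 18.0, "quantified",
    "tau-fluvalinate", "Y20_H5_pollen_T4", 12.0, "quantified",
    "thiacloprid", "Y20_H5_pollen_T1", 101.0, "quantified",
    "thiacloprid", "Y20_H8_pollen_T2", 3.0, "quantified",
    "hexachlorobenzene", "Y20_H6_pollen_T2", 1.0, "quantified"
  )
  measurements <- expand.grid(sample_id = samples$sample_id,
                              substance = names(loq),
                              stringsAsFactors = FALSE)
  measurements <- dplyr::left_join(tibble::as_tibble(measurements), detections,
                                   by = c("sample_id", "substance"))
  is_nectar <- grepl("_nectar_", measurements$sample_id)
  tp3 <- grepl("_T3$", measurements$sample_id)
  status <- dplyr::case_when(
    !is.na(measurements$status) ~ measurements$status,
    # glyphosate: separate derivatization method, run only on one pollen date
    measurements$substance == "glyphosate" & !(tp3 & !is_nectar) & !is_nectar ~ "not_analyzed",
    .default = "not_detected"
  )
  measurements <- tibble::tibble(
    sample_id = measurements$sample_id,
    substance = measurements$substance,
    status = status,
    concentration_ug_per_kg = measurements$conc,
    loq_ug_per_kg = unname(loq[measurements$substance]),
    semiquantitative = FALSE
  )
  as_residue_study(samples, measurements)
}

#' Published residue extremes for the two example years
#'
#' The detected pollen residue ranges per substance and year, as carried by
#' the bundled example studies; input for [build_risk_table()] when
#' reproducing the published exposure/risk table without re-deriving the
#' summaries.
#'
#' @return summary tibble with a `year` column.
#' @export
example_residue_extremes <- function() {
  tibble::tribble(
    ~year, ~substance, ~min_conc_ug_per_kg, ~max_conc_ug_per_kg,
    "2019", "azoxystrobin", 3.3, 3.8,
    "2019", "indoxacarb", 2.5, 2.5,
    "2019", "lambda-cyhalothrin", 3.2, 7.8,
    "2019", "tebuconazole", 0.3, 1.3,
    "2019", "thiacloprid", 77, 1484,
    "2020", "tau-fluvalinate", 1.0, 19.8,
    "2020", "thiacloprid", 3.0, 101.0,
    "2020", "hexachlorobenzene", 1.0, 1.0
  ) |>
    dplyr::mutate(matrix = "pollen", n_samples = NA_integer_, n_detected = 1L)
}
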