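# Dietary exposure and acute/chronic risk characterization.
#
# Exposure bracketing follows first-tier oral risk assessment practice:
# lowest detected residue x lowest caste intake up to highest residue x
# highest intake. A residue of c ug/kg eaten at i mg of matrix per period
# delivers c * i * 1e-6 ug of substance; exposures are therefore carried in
# units of 1e-6 ug per period, the same scale on which LD50/LC50 endpoints
# (ug/bee) are compared after multiplying by 1e6.

#' Pollen-route exposure
#'
#' Dose from eating pollen: residue concentration (ug/kg) times pollen
#' intake (mg per period), expressed in 1e-6 ug per period (numerically the
#' plain product, since 1 ug/kg x 1 mg = 1e-6 ug).
#'
#' @param conc_ug_per_kg residue concentration in pollen, ug/kg.
#' @param intake_mg pollen intake, mg per period.
#' @return exposure in 1e-6 ug per period.
#' @examples
#' pollen_exposure(1484, 12) # 17808
#' @export
pollen_exposure <- function(conc_ug_per_kg, intake_mg) {
  if (any(conc_ug_per_kg < 0) || any(intake_mg < 0)) {
    abort_config("concentration and intake must be nonnegative")
  }
  conc_ug_per_kg * intake_mg
}

#' Nectar-route exposure
#'
#' Dose from a nectar sugar intake: the sugar mass is converted to nectar
#' mass via the nectar sugar content, then multiplied by the residue
#' concentration. Returned in ug per period (not the 1e-6 ug scale), the
#' unit in which such doses are usually quoted.
#'
#' @param conc_ug_per_kg residue concentration in nectar, ug/kg.
#' @param sugar_mg sugar intake, mg per period.
#' @param sugar_fraction nectar sugar content, proportion in (0, 1].
#' @return exposure in ug per period.
#' @examples
#' nectar_route_exposure(130, 50, 0.30) # 0.0217 -> prints as 0.02
#' @export
nectar_route_exposure <- function(conc_ug_per_kg, sugar_mg, sugar_fraction = 0.30) {
  if (any(conc_ug_per_kg < 0)) {
    abort_config("concentration must be nonnegative")
  }
  conc_ug_per_kg * nectar_intake(sugar_mg, sugar_fraction) * 1e-6
}

#' Exposure range for one substance and caste
#'
#' Brackets the dietary exposure of a caste between lowest residue x lowest
#' intake and highest residue x highest intake. A summary with no detections
#' yields a (0, 0) estimate, as does the pollen route for foragers (whose
#' pollen intake is 0).
#'
#' @param summary one-row substance summary from [summarize_substance()].
#' @param profile one-row caste profile from [default_profiles()].
#' @param route `"pollen"` or `"nectar"`.
#' @param sugar_fraction nectar sugar content, used for the nectar route.
#' @return one-row tibble: `substance, caste, route, low, high, period_days`,
#'   exposures in 1e-6 ug per period.
#' @export
exposure_range <- function(summary, profile, route = c("pollen", "nectar"),
                           sugar_fraction = 0.30) {
  route <- match.arg(route)
  lo_conc <- summary$min_conc_ug_per_kg
  hi_conc <- summary$max_conc_ug_per_kg
  if (summary$n_detected == 0 || is.na(lo_conc)) {
    lo_conc <- 0
    hi_conc <- 0
  }
  intakes <- switch(route,
    pollen = c(profile$pollen_low_mg, profile$pollen_high_mg),
    nectar = nectar_intake(c(profile$sugar_low_mg, profile$sugar_high_mg), sugar_fraction)
  )
  tibble::tibble(
    substance = summary$substance,
    caste = profile$caste,
    route = route,
    low = pollen_exposure(lo_conc, intakes[1]),
    high = pollen_exposure(hi_conc, intakes[2]),
    period_days = profile$period_days
  )
}

#' Acute risk ratio against the oral LD50
#'
#' How many times larger the acute oral LD50 is than the highest daily
#' exposure of a nurse bee. The raw ratio is kept alongside a display value
#' rounded half-up to the nearest thousand, the convention under which the
#' published ratios (e.g. raw 53030 -> 53 000, raw 7733 -> 8000) reproduce.
#' A ratio at or below 1 flags an exposure reaching the lethal dose.
#'
#' @param ld50_ug_per_bee oral acute LD50 in ug/bee, or `NA` if unknown.
#' @param nurse_high_1e6 highest nurse daily exposure, 1e-6 ug/day.
#' @return list with `raw`, `rounded`, `exceeds` (logical), all `NA` when
#'   the endpoint is unknown or the exposure is zero.
#' @examples
#' acute_risk_ratio(12.6, 237.6) # raw 53030.3, rounded 53000
#' @export
acute_risk_ratio <- function(ld50_ug_per_bee, nurse_high_1e6) {
  if (is.na(ld50_ug_per_bee) || is.na(nurse_high_1e6) || nurse_high_1e6 <= 0) {
    return(list(raw = NA_real_, rounded = NA_real_, exceeds = NA))
  }
  raw <- (ld50_ug_per_bee * 1e6) / nurse_high_1e6
  list(raw = raw, rounded = round_half_up(raw, -3), exceeds = raw <= 1)
}

#' Chronic risk check against the 10-day LC50
#'
#' Compares cumulative adult dietary exposure with the 10-day chronic LC50.
#' Under the default `"ten_day"` convention the highest daily exposure is
#' accumulated over the 10-day test duration; `"per_day"` compares the daily
#' exposure directly. A cumulative exposure equal to the endpoint is
#' classified `"exceeds"` (conservative boundary).
#'
#' @param lc50_ug_per_bee 10-day chronic LC50 in ug/bee, or `NA` if unknown.
#' @param daily_high_1e6 highest daily exposure, 1e-6 ug/day.
#' @param convention `"ten_day"` (default) or `"per_day"`.
#' @return `"below"`, `"exceeds"`, or `"unknown"`.
#' @export
chronic_check <- function(lc50_ug_per_bee, daily_high_1e6,
                          convention = c("ten_day", "per_day")) {
  convention <- match.arg(convention)
  if (is.na(lc50_ug_per_bee) || is.na(daily_high_1e6)) {
    return("unknown")
  }
  cumulative <- daily_high_1e6 * if (convention == "ten_day") 10 else 1
  if (cumulative < lc50_ug_per_bee * 1e6) "below" else "exceeds"
}

#' Read a toxicity reference table
#'
#' CSV columns: `substance, ld50_acute_oral_ug_per_bee, lc50_10d_ug_per_bee,
#' source`; empty endpoint cells mean the endpoint is unknown.
#'
#' @param path path to the CSV.
#' @return tibble with those columns.
#' @export
read_toxicity_reference <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("toxicity reference not found: ", path))
  }
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           substance = readr::col_character(),
                           ld50_acute_oral_ug_per_bee = readr::col_double(),
                           lc50_10d_ug_per_bee = readr::col_double(),
                           source = readr::col_character()
                         ))
  needed <- c("substance", "ld50_acute_oral_ug_per_bee", "lc50_10d_ug_per_bee")
  missing <- setdiff(needed, names(ref))
  if (length(missing)) {
    abort_validation(paste0("toxicity reference missing column(s): ",
                            paste(missing, collapse = ", ")))
  }
  if (any(ref$ld50_acute_oral_ug_per_bee <= 0, na.rm = TRUE) ||
      any(ref$lc50_10d_ug_per_bee <= 0, na.rm = TRUE)) {
    abort_validation("toxicity endpoints must be positive when present")
  }
  ref
}

#' Bundled toxicity endpoints for the monitored substances
#'
#' Oral acute LD50 and 10-day chronic LC50 endpoints (ug/bee) for the
#' substances detected in the bundled example studies, as reported in EFSA
#' pesticide peer-review conclusions. Chronic endpoints exist only for
#' indoxacarb and thiacloprid; hexachlorobenzene has no bee endpoints.
#'
#' @return tibble in [read_toxicity_reference()] layout.
#' @export
toxicity_reference <- function() {
  tibble::tibble(
    substance = c("azoxystrobin", "indoxacarb", "lambda-cyhalothrin",
                  "tebuconazole", "thiacloprid", "tau-fluvalinate",
                  "hexachlorobenzene"),
    ld50_acute_oral_ug_per_bee = c(25, 0.232, 0.91, 83.05, 17.32, 12.6, NA),
    lc50_10d_ug_per_bee = c(NA, 0.0649, NA, NA, 3.1, NA, NA),
    source = c(rep("EFSA pesticide peer-review conclusion", 6), "no bee endpoint available")
  )
}

#' Build the caste exposure / risk characterization table
#'
#' One row per detected substance and study year: the detected pollen
#' residue range, nurse and larval pollen exposure brackets, the acute
#' LD50 ratio (raw and rounded to the nearest thousand), and the chronic
#' flag. Substances lacking endpoints carry unknown (`NA`) risk fields.
#' Rows are ordered by year then substance.
#'
#' @param summaries tibble of substance summaries (see
#'   [summarize_substance()]) with an additional `year` column.
#' @param refs toxicity reference tibble ([toxicity_reference()] layout).
#' @param profiles caste profile tibble from [default_profiles()].
#' @param chronic_convention passed to [chronic_check()].
#' @return tibble of risk rows (one per substance x year).
#' @export
build_risk_table <- function(summaries, refs = toxicity_reference(),
                             profiles = default_profiles(),
                             chronic_convention = "ten_day") {
  if (!nrow(summaries)) {
    return(tibble::tibble(
      year = character(), substance = character(),
      residue_low_ug_per_kg = numeric(), residue_high_ug_per_kg = numeric(),
      nurse_low = numeric(), nurse_high = numeric(),
      larva_low = numeric(), larva_high = numeric(),
      ld50_1e6 = numeric(), lc50_1e6 = numeric(),
      acute_ratio_raw = numeric(), acute_ratio_rounded = numeric(),
      exceeds_acute = logical(), chronic_flag = character()
    ))
  }
  if (!"year" %in% names(summaries)) {
    abort_config("summaries must carry a 'year' column")
  }
  if (anyDuplicated(summaries[c("substance", "year")])) {
    abort_validation("duplicate (substance, year) in summaries")
  }
  summaries <- dplyr::arrange(summaries, .data$year, .data$substance)
  nurse <- profiles[profiles$caste == "nurse", , drop = FALSE]
  larva <- profiles[profiles$caste == "larva", , drop = FALSE]
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, , drop = FALSE]
    ne <- exposure_range(s, nurse, "pollen")
    le <- exposure_range(s, larva, "pollen")
    ref <- refs[refs$substance == s$substance, , drop = FALSE]
    ld50 <- if (nrow(ref)) ref$ld50_acute_oral_ug_per_bee[1] else NA_real_
    lc50 <- if (nrow(ref)) ref$lc50_10d_ug_per_bee[1] else NA_real_
    ratio <- acute_risk_ratio(ld50, ne$high)
    tibble::tibble(
      year = as.character(s$year), substance = s$substance,
      residue_low_ug_per_kg = s$min_conc_ug_per_kg,
      residue_high_ug_per_kg = s$max_conc_ug_per_kg,
      nurse_low = ne$low, nurse_high = ne$high,
      larva_low = le$low, larva_high = le$high,
      ld50_1e6 = ld50 * 1e6, lc50_1e6 = lc50 * 1e6,
      acute_ratio_raw = ratio$raw, acute_ratio_rounded = ratio$rounded,
      exceeds_acute = ratio$exceeds,
      chronic_flag = chronic_check(lc50, ne$high, chronic_convention)
    )
  })
  dplyr::bind_rows(rows)
}
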