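# Residue monitoring data model and I/O.
#
# A residue study is a pair of tibbles:
#   * samples      - one row per collected sample (pollen or nectar)
#   * measurements - one row per substance x sample result, with explicit
#                    censoring status relative to the analytical LOQ
# plus a parse report of rejected rows. Concentrations are ug/kg everywhere;
# any scaled display (e.g. 1e-6 ug/mg) is a report-time convention only.

RESIDUE_STATUSES <- c("quantified", "trace_below_loq", "not_detected", "not_analyzed")
CENSOR_POLICIES <- c("reported_value", "zero", "half_loq", "loq")
MATRICES <- c("pollen", "nectar")
ARMS <- c("treated", "control")

# canonical file column -> internal field
RESIDUE_FILE_COLUMNS <- c(
  sample_id = "sample_id", hive_id = "hive_id", field_id = "field_id",
  arm = "treatment_arm", matrix = "matrix", date = "collection_date",
  timepoint = "timepoint", duration_h = "collection_duration_h",
  crop_pollen_fraction = "crop_pollen_fraction", substance = "substance",
  status = "status", conc_ug_kg = "concentration_ug_per_kg",
  loq_ug_kg = "loq_ug_per_kg", semiquant = "semiquantitative"
)

#' Match a censoring policy argument
#'
#' Censoring policies state how a measurement below the limit of
#' quantification enters numeric computations: `"reported_value"` keeps the
#' laboratory's trace value as tabulated (the default, matching how published
#' monitoring tables use "<= LOQ" numbers as-is), `"zero"`, `"half_loq"` and
#' `"loq"` are the classical substitution rules for left-censored residue
#' data.
#'
#' @param policy character; one of `"reported_value"`, `"zero"`, `"half_loq"`,
#'   `"loq"`.
#' @return the matched policy string.
#' @export
censor_policy <- function(policy = CENSOR_POLICIES) {
  match.arg(policy, CENSOR_POLICIES)
}

# Validation -------------------------------------------------------------

validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  reasons <- character(nrow(samples))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  if (nrow(samples)) {
    bad(!samples$treatment_arm %in% ARMS, "unknown treatment_arm value")
    bad(!samples$matrix %in% MATRICES, "unknown matrix value")
    bad(samples$timepoint < 1 | samples$timepoint != floor(samples$timepoint),
        "timepoint must be a positive integer")
    bad(samples$collection_duration_h <= 0, "collection_duration_h must be positive")
    frac <- samples$crop_pollen_fraction
    bad(!is.na(frac) & (frac < 0 | frac > 1), "crop_pollen_fraction outside [0,1]")
    dup <- duplicated(samples[c("hive_id", "matrix", "timepoint")])
    reasons[dup & reasons == ""] <- "duplicate (hive_id, matrix, timepoint)"
  }
  list(valid = samples[reasons == "", , drop = FALSE],
       rejected = dplyr::mutate(samples[reasons != "", , drop = FALSE],
                                reason = reasons[reasons != ""]))
}

validate_measurements <- function(measurements, sample_ids = NULL) {
  m <- tibble::as_tibble(measurements)
  reasons <- character(nrow(m))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  if (nrow(m)) {
    bad(!m$status %in% RESIDUE_STATUSES, "unknown status value")
    bad(m$loq_ug_per_kg <= 0, "loq_ug_per_kg must be positive")
    conc <- m$concentration_ug_per_kg
    quantified <- m$status == "quantified"
    bad(quantified & is.na(conc), "quantified measurement lacks a concentration")
    bad(quantified & !is.na(conc) & conc < m$loq_ug_per_kg & !m$semiquantitative,
        "quantified concentration below LOQ without semiquantitative flag")
    trace <- m$status == "trace_below_loq"
    bad(trace & !is.na(conc) & (conc <= 0 | conc >= m$loq_ug_per_kg),
        "trace concentration must lie strictly between 0 and LOQ")
    absent <- m$status %in% c("not_detected", "not_analyzed")
    bad(absent & !is.na(conc), "concentration present for a non-detected/non-analyzed row")
    if (!is.null(sample_ids)) {
      bad(!m$sample_id %in% sample_ids, "sample_id not present in sample table")
    }
  }
  list(valid = m[reasons == "", , drop = FALSE],
       rejected = dplyr::mutate(m[reasons != "", , drop = FALSE],
                                reason = reasons[reasons != ""]))
}

# I/O --------------------------------------------------------------------

#' Read a residue monitoring table
#'
#' Reads the canonical long-format residue CSV (one row per substance x
#' sample), validates every row against the data-model invariants, and splits
#' the result into a sample-metadata tibble and a measurement tibble. Rows
#' violating an invariant are not silently dropped: they are returned in the
#' `rejected` parse report with a per-row reason.
#'
#' Expected columns: `sample_id, hive_id, field_id, arm, matrix, date,
#' timepoint, duration_h, crop_pollen_fraction, substance, status,
#' conc_ug_kg, loq_ug_kg, semiquant`. Alternative headers can be mapped with
#' `schema`, a named character vector `c(canonical = "actual_name", ...)`.
#' Dates must be ISO-8601. Concentrations are ug/kg.
#'
#' @param path path to a UTF-8 comma-separated file with a header row.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return a list of class `residue_study` with elements `samples`,
#'   `measurements`, and `rejected` (itself a list with `samples` and
#'   `measurements` tibbles carrying a `reason` column).
#' @seealso [write_residue_table()] for the lossless inverse.
#' @export
read_residue_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort_validation(paste0("residue table not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  expected <- names(RESIDUE_FILE_COLUMNS)
  actual <- expected
  if (!is.null(schema)) {
    idx <- match(names(schema), expected)
    if (anyNA(idx)) {
      abort_config(paste0("schema maps unknown column(s): ",
                          paste(names(schema)[is.na(idx)], collapse = ", ")))
    }
    actual[idx] <- unname(schema)
  }
  missing <- actual[!actual %in% names(raw)]
  if (length(missing)) {
    abort_validation(paste0("mandatory column(s) missing from ", path, ": ",
                            paste(missing, collapse = ", ")))
  }
  raw <- stats::setNames(raw[actual], expected)
  if (!nrow(raw)) {
    warn("residue table has a header but no data rows")
  }
  as_residue_study(
    samples = tibble::tibble(
      sample_id = raw$sample_id,
      hive_id = raw$hive_id,
      field_id = raw$field_id,
      treatment_arm = raw$arm,
      matrix = raw$matrix,
      collection_date = as.Date(raw$date),
      timepoint = suppressWarnings(as.integer(raw$timepoint)),
      collection_duration_h = suppressWarnings(as.numeric(raw$duration_h)),
      crop_pollen_fraction = suppressWarnings(as.numeric(raw$crop_pollen_fraction))
    ) |> dplyr::distinct(.data$sample_id, .keep_all = TRUE),
    measurements = tibble::tibble(
      sample_id = raw$sample_id,
      substance = raw$substance,
      status = raw$status,
      concentration_ug_per_kg = suppressWarnings(as.numeric(raw$conc_ug_kg)),
      loq_ug_per_kg = suppressWarnings(as.numeric(raw$loq_ug_kg)),
      semiquantitative = tolower(raw$semiquant %||% "false") %in% c("true", "1", "t")
    )
  )
}

#' Assemble and validate a residue study
#'
#' Validates sample metadata and measurements against the data-model
#' invariants and bundles them with the rejection report. Used by both the
#' file reader and the synthetic generator so all inputs pass through the
#' same gate.
#'
#' @param samples tibble of sample metadata.
#' @param measurements tibble of residue measurements.
#' @return a `residue_study` list: `samples`, `measurements`, `rejected`.
#' @export
as_residue_study <- function(samples, measurements) {
  vs <- validate_samples(samples)
  vm <- validate_measurements(measurements, sample_ids = vs$valid$sample_id)
  structure(
    list(samples = vs$valid, measurements = vm$valid,
         rejected = list(samples = vs$rejected, measurements = vm$rejected)),
    class = "residue_study"
  )
}

#' @export
print.residue_study <- function(x, ...) {
  n_rej <- nrow(x$rejected$samples) + nrow(x$rejected$measurements)
  cat(sprintf("<residue_study> %d samples, %d measurements, %d rejected rows\n",
              nrow(x$samples), nrow(x$measurements), n_rej))
  invisible(x)
}

#' Write a residue study back to the canonical CSV
#'
#' Inverse of [read_residue_table()]: joins metadata onto measurements and
#' writes the canonical column set, so that write-then-read round-trips are
#' record-identical.
#'
#' @param study a `residue_study` (or list with `samples` and `measurements`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(study, path) {
  joined <- dplyr::inner_join(study$measurements, study$samples, by = "sample_id")
  out <- tibble::tibble(
    sample_id = joined$sample_id,
    hive_id = joined$hive_id,
    field_id = joined$field_id,
    arm = joined$treatment_arm,
    matrix = joined$matrix,
    date = format(joined$collection_date, "%Y-%m-%d"),
    timepoint = joined$timepoint,
    duration_h = joined$collection_duration_h,
    crop_pollen_fraction = joined$crop_pollen_fraction,
    substance = joined$substance,
    status = joined$status,
    conc_ug_kg = joined$concentration_ug_per_kg,
    loq_ug_kg = joined$loq_ug_per_kg,
    semiquant = joined$semiquantitative
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Censoring resolution ---------------------------------------------------

#' Resolve measurements to numeric concentrations under a censoring policy
#'
#' Quantified results always keep their reported value. Trace results (below
#' LOQ) resolve per `policy`; under `"reported_value"` a trace without a
#' stored number falls back to the LOQ with a warning. Non-detects are 0
#' under `"reported_value"`/`"zero"`, LOQ/2 under `"half_loq"`, LOQ under
#' `"loq"`. `not_analyzed` rows have no defined concentration and raise an
#' error; filter them out first.
#'
#' @param measurements measurement tibble (see [read_residue_table()]).
#' @param policy a censoring policy, see [censor_policy()].
#' @return numeric vector of concentrations in ug/kg, one per row.
#' @export
resolve_concentration <- function(measurements, policy = "reported_value") {
  policy <- censor_policy(policy)
  m <- tibble::as_tibble(measurements)
  if (any(m$status == "not_analyzed")) {
    abort_validation("cannot resolve a concentration for status 'not_analyzed'")
  }
  conc <- m$concentration_ug_per_kg
  loq <- m$loq_ug_per_kg
  sub_nd <- switch(policy,
    reported_value = 0, zero = 0,
    half_loq = NA_real_, loq = NA_real_
  )
  out <- numeric(nrow(m))
  q <- m$status == "quantified"
  out[q] <- conc[q]
  tr <- m$status == "trace_below_loq"
  out[tr] <- switch(policy,
    reported_value = {
      v <- conc[tr]
      if (anyNA(v)) {
        warn("trace measurement(s) without a stored value: falling back to LOQ")
        v[is.na(v)] <- loq[tr][is.na(v)]
      }
      v
    },
    zero = 0,
    half_loq = loq[tr] / 2,
    loq = loq[tr]
  )
  nd <- m$status == "not_detected"
  out[nd] <- if (is.na(sub_nd)) {
    if (policy == "half_loq") loq[nd] / 2 else loq[nd]
  } else {
    sub_nd
  }
  out
}

# Summaries --------------------------------------------------------------

#' Summarize one substance in one matrix
#'
#' Counts analyzed samples and detections (`quantified` or
#' `trace_below_loq`) and reports the detected concentration range after
#' resolving trace values under `policy`. `not_analyzed` rows do not count as
#' analyzed samples. A substance absent from the table yields a summary with
#' `n_detected = 0` and missing range, as does an all-non-detect matrix.
#'
#' @param study a `residue_study`.
#' @param substance substance name.
#' @param matrix `"pollen"` or `"nectar"`.
#' @param policy censoring policy for trace values (detection counts are
#'   policy-invariant).
#' @return one-row tibble: `substance, matrix, n_samples, n_detected,
#'   min_conc_ug_per_kg, max_conc_ug_per_kg`.
#' @export
summarize_substance <- function(study, substance, matrix = "pollen",
                                policy = "reported_value") {
  matrix <- match.arg(matrix, MATRICES)
  ids <- study$samples$sample_id[study$samples$matrix == matrix]
  m <- dplyr::filter(study$measurements,
                     .data$substance == !!substance,
                     .data$sample_id %in% ids,
                     .data$status != "not_analyzed")
  det <- dplyr::filter(m, .data$status %in% c("quantified", "trace_below_loq"))
  conc <- if (nrow(det)) resolve_concentration(det, policy) else numeric(0)
  tibble::tibble(
    substance = substance,
    matrix = matrix,
    n_samples = nrow(m),
    n_detected = nrow(det),
    min_conc_ug_per_kg = if (length(conc)) min(conc) else NA_real_,
    max_conc_ug_per_kg = if (length(conc)) max(conc) else NA_real_
  )
}

#' Summarize every detected substance in a matrix
#'
#' @inheritParams summarize_substance
#' @param detected_only drop substances with no detections (default TRUE).
#' @return tibble with one [summarize_substance()] row per substance.
#' @export
summarize_matrix <- function(study, matrix = "pollen",
                             policy = "reported_value", detected_only = TRUE) {
  matrix <- match.arg(matrix, MATRICES)
  ids <- study$samples$sample_id[study$samples$matrix == matrix]
  subs <- sort(unique(study$measurements$substance[study$measurements$sample_id %in% ids]))
  out <- dplyr::bind_rows(lapply(subs, function(s) {
    summarize_substance(study, s, matrix, policy)
  }))
  if (detected_only && nrow(out)) out <- dplyr::filter(out, .data$n_detected > 0)
  out
}
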