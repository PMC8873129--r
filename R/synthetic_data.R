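# Synthetic residue-monitoring studies.
#
# The generator emulates the statistical structure the analysis assumes:
# a treated/control multi-field design sampled over repeated timepoints,
# zero-inflated residues (Bernoulli detection), lognormal concentrations for
# detected residues with a per-timepoint decay after first exposure, and
# LOQ censoring into quantified / trace / non-detect statuses. Nectar is
# all-censored by default, as observed in rainy-season monitoring.

#' Describe one substance's generating model
#'
#' @param name substance name.
#' @param detect_prob_treated per-sample detection probability in the
#'   treated arm from `first_exposed_timepoint` on (0 before it).
#' @param detect_prob_control per-sample background/drift detection
#'   probability in the control arm (all timepoints).
#' @param log_mean,log_sd lognormal parameters (log ug/kg) of detected
#'   concentrations at the first exposed timepoint.
#' @param decay_per_timepoint multiplicative concentration decay per
#'   timepoint after first exposure, in (0, 1].
#' @param first_exposed_timepoint first timepoint at which the treated arm
#'   can show the substance.
#' @return one-row tibble.
#' @export
substance_model <- function(name, detect_prob_treated, detect_prob_control,
                            log_mean, log_sd, decay_per_timepoint = 1,
                            first_exposed_timepoint = 1L) {
  if (detect_prob_treated < 0 || detect_prob_treated > 1 ||
      detect_prob_control < 0 || detect_prob_control > 1) {
    abort_config("detection probabilities must lie in [0, 1]")
  }
  if (log_sd <= 0) abort_config("log_sd must be positive")
  if (decay_per_timepoint <= 0 || decay_per_timepoint > 1) {
    abort_config("decay_per_timepoint must lie in (0, 1]")
  }
  if (first_exposed_timepoint < 1) abort_config("first_exposed_timepoint must be >= 1")
  tibble::tibble(
    name = name,
    detect_prob_treated = detect_prob_treated,
    detect_prob_control = detect_prob_control,
    log_mean = log_mean, log_sd = log_sd,
    decay_per_timepoint = decay_per_timepoint,
    first_exposed_timepoint = as.integer(first_exposed_timepoint)
  )
}

#' Default substance models
#'
#' Three archetypes seen in field monitoring: a sprayed pyrethroid appearing
#' in the treated arm after its application (with drift into controls), a
#' background neonicotinoid arriving from the surrounding agricultural area
#' in either arm, and a rare persistent legacy contaminant.
#'
#' @return tibble of [substance_model()] rows.
#' @export
default_substance_models <- function() {
  dplyr::bind_rows(
    substance_model("tau-fluvalinate", 0.35, 0.08, log(6), 1.0, 0.6, 3L),
    substance_model("thiacloprid", 0.05, 0.05, log(10), 1.5, 1, 1L),
    substance_model("hexachlorobenzene", 0.03, 0.03, log(1), 0.3, 1, 1L)
  )
}

#' Configure a synthetic residue study
#'
#' Defaults mirror the main-year monitoring design: 9 one-hive fields (5
#' treated, 4 control), 4 pollen collection timepoints, per-substance LOQ
#' drawn from 0.5-30 ug/kg, and nectar entirely below LOQ.
#'
#' @param n_treated_fields,n_control_fields,hives_per_field,timepoints
#'   design counts (all >= 1).
#' @param substances tibble of [substance_model()] rows.
#' @param loq_range length-2 numeric, low < high, ug/kg; each substance is
#'   assigned one LOQ uniformly from this range.
#' @param nectar_all_censored force all nectar measurements to non-detect.
#' @param nectar_timepoints timepoints with a nectar collection (default:
#'   all but the last, matching sampling that stops after the final
#'   treatment).
#' @param seed integer RNG seed; identical config + seed regenerates the
#'   study byte-identically.
#' @return validated list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_treated_fields = 5, n_control_fields = 4,
                                   hives_per_field = 1, timepoints = 4,
                                   substances = default_substance_models(),
                                   loq_range = c(0.5, 30),
                                   nectar_all_censored = TRUE,
                                   nectar_timepoints = NULL,
                                   seed = 1L) {
  counts <- c(n_treated_fields, n_control_fields, hives_per_field, timepoints)
  if (any(counts < 1) || any(counts != floor(counts))) {
    abort_config("design counts must be positive integers")
  }
  if (length(loq_range) != 2 || loq_range[1] <= 0 || loq_range[1] >= loq_range[2]) {
    abort_config("loq_range must be (low, high) with 0 < low < high")
  }
  if (!nrow(substances)) abort_config("at least one substance model is required")
  if (any(substances$first_exposed_timepoint > timepoints)) {
    abort_config("first_exposed_timepoint beyond the last timepoint")
  }
  structure(list(
    n_treated_fields = as.integer(n_treated_fields),
    n_control_fields = as.integer(n_control_fields),
    hives_per_field = as.integer(hives_per_field),
    timepoints = as.integer(timepoints),
    substances = substances,
    loq_range = as.numeric(loq_range),
    nectar_all_censored = isTRUE(nectar_all_censored),
    nectar_timepoints = as.integer(nectar_timepoints %||% seq_len(max(timepoints - 1, 1))),
    seed = as.integer(seed)
  ), class = "synthetic_study_config")
}

#' Censor a true concentration at the LOQ
#'
#' Maps a true concentration to a reported measurement: at or above the LOQ
#' it is `quantified`; strictly between 0 and the LOQ it is
#' `trace_below_loq` (value retained, as laboratories tabulate confirmed
#' traces); exactly 0 is `not_detected`.
#'
#' @param true_conc true concentration(s), ug/kg, nonnegative.
#' @param loq limit(s) of quantification, ug/kg, positive.
#' @return tibble: `status, concentration_ug_per_kg, loq_ug_per_kg,
#'   semiquantitative`.
#' @export
apply_censoring <- function(true_conc, loq) {
  if (any(true_conc < 0) || any(loq <= 0)) {
    abort_config("true_conc must be >= 0 and loq > 0")
  }
  n <- max(length(true_conc), length(loq))
  true_conc <- rep_len(true_conc, n)
  loq <- rep_len(loq, n)
  status <- dplyr::case_when(
    true_conc >= loq ~ "quantified",
    true_conc > 0 ~ "trace_below_loq",
    .default = "not_detected"
  )
  tibble::tibble(
    status = status,
    concentration_ug_per_kg = ifelse(status == "not_detected", NA_real_, true_conc),
    loq_ug_per_kg = loq,
    semiquantitative = FALSE
  )
}

#' Generate a synthetic residue study
#'
#' For every hive x timepoint x substance, detection is Bernoulli at the
#' arm's probability (zero in the treated arm before the substance's first
#' exposed timepoint); detected true concentrations are lognormal, decayed
#' multiplicatively per timepoint since first exposure, then censored at the
#' substance's LOQ. Nectar samples are forced below LOQ when configured.
#' The RNG state of the session is left untouched; the same config (incl.
#' seed) regenerates the study identically.
#'
#' @param config a [synthetic_study_config()].
#' @return list of class `synthetic_study`: `study` (a `residue_study`),
#'   `truth` (generating parameters incl. assigned LOQs, plus per-record
#'   true concentrations).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synthetic_study_config")) {
    abort_config("config must come from synthetic_study_config()")
  }
  runif_state <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(runif_state)) assign(".Random.seed", runif_state, envir = globalenv())
  })
  set.seed(config$seed)

  n_fields <- config$n_treated_fields + config$n_control_fields
  fields <- tibble::tibble(
    field_id = sprintf("F%d", seq_len(n_fields)),
    treatment_arm = rep(c("treated", "control"),
                        c(config$n_treated_fields, config$n_control_fields))
  )
  hives <- dplyr::bind_rows(lapply(seq_len(config$hives_per_field), function(k) {
    dplyr::mutate(fields, hive_id = sprintf("%s_H%d", .data$field_id, k))
  }))

  base_date <- as.Date("2020-06-25")
  make_samples <- function(mtx, tps) {
    grid <- tidyr_expand(hives, tps)
    tibble::tibble(
      sample_id = sprintf("%s_%s_T%d", grid$hive_id, mtx, grid$timepoint),
      hive_id = grid$hive_id,
      field_id = grid$field_id,
      treatment_arm = grid$treatment_arm,
      matrix = mtx,
      collection_date = base_date + (grid$timepoint - 1) * 5L,
      timepoint = grid$timepoint,
      collection_duration_h = round(runif(nrow(grid), 2, 24), 1),
      crop_pollen_fraction = if (mtx == "pollen") {
        round(runif(nrow(grid), 0, 0.25), 3)
      } else {
        NA_real_
      }
    )
  }
  pollen <- make_samples("pollen", seq_len(config$timepoints))
  nectar <- make_samples("nectar", config$nectar_timepoints)
  samples <- dplyr::bind_rows(pollen, nectar)

  loq <- round(runif(nrow(config$substances), config$loq_range[1], config$loq_range[2]), 2)
  subs <- dplyr::mutate(config$substances, loq_ug_per_kg = loq)

  simulate_matrix <- function(smp, censored) {
    dplyr::bind_rows(lapply(seq_len(nrow(subs)), function(j) {
      s <- subs[j, ]
      if (censored) {
        true_conc <- rep(0, nrow(smp))
      } else {
        p <- ifelse(smp$treatment_arm == "treated",
                    ifelse(smp$timepoint >= s$first_exposed_timepoint,
                           s$detect_prob_treated, 0),
                    s$detect_prob_control)
        detected <- rbinom(nrow(smp), 1, p) == 1
        conc <- rlnorm(nrow(smp), s$log_mean, s$log_sd) *
          s$decay_per_timepoint^pmax(0L, smp$timepoint - s$first_exposed_timepoint)
        true_conc <- ifelse(detected, conc, 0)
      }
      cens <- apply_censoring(true_conc, s$loq_ug_per_kg)
      dplyr::bind_cols(
        tibble::tibble(sample_id = smp$sample_id, substance = s$name),
        cens,
        tibble::tibble(true_conc_ug_per_kg = true_conc)
      )
    }))
  }
  meas <- dplyr::bind_rows(
    simulate_matrix(pollen, censored = FALSE),
    simulate_matrix(nectar, censored = config$nectar_all_censored)
  )
  truth_records <- meas[c("sample_id", "substance", "true_conc_ug_per_kg")]
  meas$true_conc_ug_per_kg <- NULL

  study <- as_residue_study(samples, meas)
  structure(list(
    study = study,
    truth = list(substances = subs, records = truth_records, config = config)
  ), class = "synthetic_study")
}

# minimal cross join (hives x timepoints) without pulling in tidyr
tidyr_expand <- function(hives, tps) {
  idx <- rep(seq_len(nrow(hives)), times = length(tps))
  out <- hives[idx, , drop = FALSE]
  out$timepoint <- rep(as.integer(tps), each = nrow(hives))
  out
}

#' Write a synthetic study to disk
#'
#' Emits the canonical residue CSV plus a truth CSV of generating
#' parameters, so simulated studies can round-trip through the file
#' interface.
#'
#' @param sim a `synthetic_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_synthetic_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  residues <- file.path(dir, "residues.csv")
  truth <- file.path(dir, "truth_substances.csv")
  write_residue_table(sim$study, residues)
  readr::write_csv(sim$truth$substances, truth, progress = FALSE)
  invisible(c(residues = residues, truth = truth))
}
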