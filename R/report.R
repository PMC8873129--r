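# Pipeline entry points and report rendering.
#
# run_risk() and run_stats() tie the stages together behind a single plain
# YAML config, for scripted use and for the thin command-line wrapper under
# inst/cli/. Outputs are deterministic for fixed inputs; timestamps appear
# only in the run log.

RISK_COLUMN_ORDER <- c(
  "year", "substance", "residue_low_ug_per_kg", "residue_high_ug_per_kg",
  "nurse_low", "nurse_high", "larva_low", "larva_high",
  "ld50_1e6", "lc50_1e6", "acute_ratio_rounded", "acute_ratio_raw",
  "exceeds_acute", "chronic_flag"
)

RATIO_FOOTNOTE <- paste(
  "Acute ratio: oral acute LD50 divided by the highest daily exposure of a",
  "nurse bee, rounded half-up to the nearest thousand; values <= 1 would",
  "indicate exposure at the lethal dose."
)

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent named list. Recognized keys:
#' `residues` (path), `toxicity` (path; bundled endpoints when absent),
#' `policy`, `sugar_fraction`, `profiles` (caste overrides, see
#' [default_profiles()]), `year` (label for risk rows), `stats` (list:
#' `substance`, `alpha`, `adjust`, `method`), `out_dir`, `seed`.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_config(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("config must be a list or a YAML file path")
  config$policy <- censor_policy(config$policy %||% "reported_value")
  config$sugar_fraction <- config$sugar_fraction %||% 0.30
  if (config$sugar_fraction <= 0 || config$sugar_fraction > 1) {
    abort_config("sugar_fraction must lie in (0, 1]")
  }
  stats_cfg <- config$stats %||% list()
  stats_cfg$alpha <- stats_cfg$alpha %||% 0.05
  if (stats_cfg$alpha <= 0 || stats_cfg$alpha >= 1) {
    abort_config("alpha must lie in (0, 1)")
  }
  stats_cfg$adjust <- match.arg(stats_cfg$adjust %||% "none", c("none", "holm"))
  stats_cfg$method <- match.arg(stats_cfg$method %||% "spearman",
                                c("spearman", "pearson"))
  config$stats <- stats_cfg
  config$year <- as.character(config$year %||% "study")
  config
}

load_config_inputs <- function(config) {
  if (is.null(config$residues)) abort_config("config lacks a 'residues' path")
  study <- read_residue_table(config$residues)
  refs <- if (is.null(config$toxicity)) {
    toxicity_reference()
  } else {
    read_toxicity_reference(config$toxicity)
  }
  list(study = study, refs = refs)
}

write_log <- function(path, lines) {
  writeLines(c(format(Sys.time(), "run at %Y-%m-%d %H:%M:%S"), lines), path)
  invisible(path)
}

#' Run the exposure/risk stage
#'
#' Reads the residue table, summarizes detected substances in pollen under
#' the configured censoring policy, characterizes acute and chronic risk,
#' and writes `risk_table.csv` plus `risk_run.log` to the output directory.
#' An empty residue table yields an empty (header-only) risk table with a
#' warning, not an error.
#'
#' @param config pipeline config (path or list), see
#'   [read_pipeline_config()].
#' @return the risk tibble, invisibly.
#' @export
run_risk <- function(config) {
  config <- read_pipeline_config(config)
  inputs <- load_config_inputs(config)
  summaries <- summarize_matrix(inputs$study, "pollen", config$policy)
  if (nrow(summaries)) summaries$year <- config$year
  profiles <- default_profiles(overrides = config$profiles)
  risk <- build_risk_table(summaries, inputs$refs, profiles)
  if (!nrow(risk)) warn("no detected substances: risk table is empty")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  render_risk_table(risk, file.path(out_dir, "risk_table.csv"), "csv")
  unknown <- risk$substance[is.na(risk$ld50_1e6)]
  write_log(file.path(out_dir, "risk_run.log"), c(
    paste0("residues: ", config$residues),
    paste0("policy: ", config$policy),
    paste0("profiles: ", paste(sprintf("%s pollen %.3g-%.3g mg, sugar %.3g-%.3g mg/%dd",
                                       profiles$caste, profiles$pollen_low_mg,
                                       profiles$pollen_high_mg, profiles$sugar_low_mg,
                                       profiles$sugar_high_mg, profiles$period_days),
                               collapse = "; ")),
    paste0("rows: ", nrow(risk)),
    paste0("substances without an acute endpoint: ",
           if (length(unknown)) paste(unknown, collapse = ", ") else "none")
  ))
  invisible(risk)
}

#' Run the statistics stage
#'
#' Per-timepoint treated-vs-control Kruskal-Wallis tests for each substance
#' named in `config$stats$substance` (default: every substance detected in
#' pollen), plus the composition correlation when crop-pollen fractions are
#' present. Writes `stats_table.csv`, `correlation.csv` and `stats_run.log`.
#'
#' @inheritParams run_risk
#' @return list with `tests` and `correlation` tibbles, invisibly.
#' @export
run_stats <- function(config) {
  config <- read_pipeline_config(config)
  inputs <- load_config_inputs(config)
  study <- inputs$study
  substances <- config$stats$substance %||%
    summarize_matrix(study, "pollen", config$policy)$substance
  tests <- dplyr::bind_rows(lapply(substances, function(s) {
    per_timepoint_comparison(study, s, config$policy, adjust = config$stats$adjust)
  }))
  corr <- NULL
  pollen <- dplyr::filter(study$samples, .data$matrix == "pollen",
                          !is.na(.data$crop_pollen_fraction))
  if (nrow(pollen) >= 3 && length(substances)) {
    corr <- dplyr::bind_rows(lapply(substances, function(s) {
      m <- dplyr::filter(study$measurements, .data$substance == !!s,
                         .data$status != "not_analyzed",
                         .data$sample_id %in% pollen$sample_id)
      conc <- resolve_concentration(m, config$policy)
      frac <- pollen$crop_pollen_fraction[match(m$sample_id, pollen$sample_id)]
      ct <- composition_correlation(frac, conc, config$stats$method)
      tibble::tibble(substance = s, method = ct$method, n = ct$n,
                     estimate = ct$estimate, p_value = ct$p_value, note = ct$note)
    }))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tests, file.path(out_dir, "stats_table.csv"), progress = FALSE)
  if (!is.null(corr)) {
    readr::write_csv(corr, file.path(out_dir, "correlation.csv"), progress = FALSE)
  }
  n_sig <- sum(tests$p_value < config$stats$alpha, na.rm = TRUE)
  write_log(file.path(out_dir, "stats_run.log"), c(
    paste0("residues: ", config$residues),
    paste0("policy: ", config$policy),
    paste0("substances: ", paste(substances, collapse = ", ")),
    sprintf("tests: %d; significant at alpha=%.3g: %d", nrow(tests),
            config$stats$alpha, n_sig)
  ))
  invisible(list(tests = tests, correlation = corr))
}

#' Render a risk table to CSV or aligned markdown
#'
#' Fixed column order: year, substance, residue range, nurse and larva
#' exposure brackets, endpoints, rounded then raw acute ratio, exceedance
#' flags. The markdown rendering appends the footnote defining the acute
#' ratio. Exposure cells display at 1 decimal; unknown risk fields render
#' as `"unknown"`.
#'
#' @param rows risk tibble from [build_risk_table()].
#' @param path output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_risk_table <- function(rows, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  missing_cols <- setdiff(RISK_COLUMN_ORDER, names(rows))
  if (length(missing_cols)) {
    abort_validation(paste0("risk table lacks column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  rows <- rows[RISK_COLUMN_ORDER]
  if (format == "csv") {
    readr::write_csv(rows, path, progress = FALSE)
    return(invisible(path))
  }
  disp <- rows
  for (col in c("nurse_low", "nurse_high", "larva_low", "larva_high",
                "ld50_1e6", "lc50_1e6")) {
    disp[[col]] <- ifelse(is.na(disp[[col]]), "unknown",
                          formatC(round_half_up(disp[[col]], 1),
                                  format = "f", digits = 1, big.mark = " "))
  }
  disp$acute_ratio_rounded <- ifelse(is.na(disp$acute_ratio_rounded), "unknown",
                                     formatC(disp$acute_ratio_rounded, format = "d",
                                             big.mark = " "))
  disp$acute_ratio_raw <- ifelse(is.na(disp$acute_ratio_raw), "unknown",
                                 formatC(disp$acute_ratio_raw, format = "f", digits = 1))
  disp$exceeds_acute <- ifelse(is.na(rows$exceeds_acute), "unknown",
                               ifelse(rows$exceeds_acute, "exceeds", "below"))
  disp <- dplyr::mutate(disp, dplyr::across(dplyr::everything(), as.character))
  widths <- vapply(names(disp), function(nm) {
    max(nchar(c(nm, disp[[nm]])), na.rm = TRUE)
  }, 0L)
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste0("| ", paste(mapply(pad, names(disp), widths), collapse = " | "), " |")
  sep <- paste0("|", paste(vapply(widths, function(w) strrep("-", w + 2), ""),
                           collapse = "|"), "|")
  body <- vapply(seq_len(nrow(disp)), function(i) {
    paste0("| ", paste(mapply(pad, unlist(disp[i, ]), widths), collapse = " | "), " |")
  }, "")
  writeLines(c(header, sep, body, "", RATIO_FOOTNOTE), path)
  invisible(path)
}
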