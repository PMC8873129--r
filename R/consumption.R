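# Dietary consumption model for honeybee castes.
#
# The intake constants are the EFSA Bee Guidance dietary values used in
# first-tier oral risk assessment: per day for adults, per 5-day feeding
# period for larvae. Nectar intake is given as sugar mass and converted to
# nectar mass via the nectar's sugar content (default 30%, the Bee Guidance
# average for oilseed rape).

#' Default caste consumption profiles
#'
#' Returns the EFSA Bee Guidance dietary intake constants per caste:
#' foragers eat 0 mg pollen and 32-128 mg sugar from nectar per day, nurse
#' bees 6.15-12 mg pollen and 34-50 mg sugar per day, and larvae 1.5-2 mg
#' pollen and 59.4 mg sugar over their 5-day feeding period.
#'
#' Published risk tables in this area sometimes tabulate the nurse lowest
#' pollen intake as 6.5 mg/day rather than 6.15; use `overrides` to match
#' such a convention, e.g. `list(nurse = list(pollen_low_mg = 6.5))`.
#'
#' @param overrides optional named list keyed by caste; each element a named
#'   list of profile fields to replace (`pollen_low_mg`, `pollen_high_mg`,
#'   `sugar_low_mg`, `sugar_high_mg`, `period_days`).
#' @return tibble with columns `caste, pollen_low_mg, pollen_high_mg,
#'   sugar_low_mg, sugar_high_mg, period_days`.
#' @examples
#' default_profiles()
#' default_profiles(overrides = list(nurse = list(pollen_low_mg = 6.5)))
#' @export
default_profiles <- function(overrides = NULL) {
  profiles <- tibble::tibble(
    caste = c("forager", "nurse", "larva"),
    pollen_low_mg = c(0, 6.15, 1.5),
    pollen_high_mg = c(0, 12, 2),
    sugar_low_mg = c(32, 34, 59.4),
    sugar_high_mg = c(128, 50, 59.4),
    period_days = c(1L, 1L, 5L)
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% profiles$caste)) {
      abort_config("profile overrides must be a named list keyed by caste")
    }
    for (caste in names(overrides)) {
      fields <- overrides[[caste]]
      unknown <- setdiff(names(fields), setdiff(names(profiles), "caste"))
      if (length(unknown)) {
        abort_config(paste0("unknown profile field(s): ", paste(unknown, collapse = ", ")))
      }
      for (f in names(fields)) {
        profiles[[f]][profiles$caste == caste] <- fields[[f]]
      }
    }
  }
  bad <- profiles$pollen_low_mg > profiles$pollen_high_mg |
    profiles$sugar_low_mg > profiles$sugar_high_mg
  if (any(bad)) {
    abort_config("profile low intake exceeds high intake")
  }
  profiles
}

#' Convert a sugar intake to a nectar intake
#'
#' Dietary intake tables give nectar consumption as sugar mass; the nectar
#' mass actually ingested is `sugar_mg / sugar_fraction`. At the default 30%
#' sugar content, the 128 mg/day forager sugar intake corresponds to
#' 426.67 mg of nectar, the 50 mg nurse intake to 166.67 mg, and the 59.4 mg
#' larval intake to 198 mg.
#'
#' @param sugar_mg sugar mass consumed (mg per period), nonnegative.
#' @param sugar_fraction nectar sugar content, a proportion in (0, 1].
#' @return nectar mass in mg per period (unrounded; round at display time).
#' @examples
#' nectar_intake(128, 0.30) # 426.666...
#' @export
nectar_intake <- function(sugar_mg, sugar_fraction = 0.30) {
  if (any(sugar_fraction <= 0) || any(sugar_fraction > 1)) {
    abort_config("sugar_fraction must lie in (0, 1]")
  }
  if (any(sugar_mg < 0)) {
    abort_config("sugar_mg must be nonnegative")
  }
  sugar_mg / sugar_fraction
}
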