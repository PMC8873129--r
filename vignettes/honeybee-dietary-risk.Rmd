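---
title: "Dietary pesticide exposure and risk characterization for honeybees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary pesticide exposure and risk characterization for honeybees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenrisk)
```

## The problem

Honeybees foraging near treated crops ingest pesticide residues with the
pollen and nectar they collect. Field monitoring programs analyze
honeybee-collected pollen and nectar for a broad panel of active substances
and ask two questions: do the measured residue levels translate into dietary
doses anywhere near the acute (LD50) or chronic (LC50) oral toxicity
endpoints used in EU risk assessment, and do hives next to treated fields
actually carry higher residues than hives next to untreated controls?

pollenrisk implements that analysis end to end: LOQ-aware ingestion of
multi-residue results, caste-specific dietary exposure from EFSA Bee
Guidance consumption values, toxicity-to-exposure ratios, per-timepoint
nonparametric treated-vs-control comparisons, and a synthetic-study
generator so every stage is testable without field data.

## Residue data and censoring

Multi-residue chemistry reports each substance x sample result in one of
four states: `quantified` (at or above the limit of quantification, LOQ),
`trace_below_loq` (reliably identified but below the LOQ, value retained),
`not_detected`, and `not_analyzed` (the substance was outside that sample's
analytical scope — e.g. nectar not analyzed in a screening year, or
glyphosate run only on a subset of dates by its separate derivatization
method). `not_analyzed` is deliberately distinct from `not_detected`: the
former contributes nothing to detection counts or sample totals.

Screening-year results reported below the validated LOQ are carried with a
`semiquantitative` flag: they are numerically usable but the usual
`quantified => concentration >= LOQ` invariant is waived for them.

Numeric computations resolve censored values under an explicit
`CensorPolicy`. The default, `reported_value`, uses trace values as
tabulated and zeros for non-detects — matching how published monitoring
tables use their "&le; LOQ" numbers directly. The classical substitution
rules `zero`, `half_loq` and `loq` are available for sensitivity analysis;
summaries are provably monotone across them (`zero <= half_loq <= loq`
element-wise), and detection counts are policy-invariant.

## The consumption model

`default_profiles()` returns the EFSA Bee Guidance dietary intakes:

| caste   | pollen (mg/period) | sugar from nectar (mg/period) | period |
|---------|--------------------|-------------------------------|--------|
| forager | 0                  | 32–128                        | 1 day  |
| nurse   | 6.15–12            | 34–50                         | 1 day  |
| larva   | 1.5–2              | 59.4                          | 5 days |

Nectar intake is quoted as sugar mass; the nectar mass ingested is
`sugar_mg / sugar_fraction`, with 30% sugar (the guidance average for
oilseed rape) as default: 128 mg sugar corresponds to 426.67 mg nectar for
a forager, 50 mg to 166.67 mg for a nurse, 59.4 mg to 198 mg for a larva.

The guidance larval line is sometimes misprinted as two sugar quantities;
here the 1.5–2 mg range is pollen (consistent with risk tables that apply
1.5 and 2 mg multipliers to pollen residues) and 59.4 mg is nectar sugar,
both per 5-day feeding period.

One convention deserves note: published exposure tables in this area often
tabulate the nurse *lowest* pollen intake as 6.5 mg/day while the guidance
text says 6.15. `default_profiles()` returns the guidance constant; the
table convention is one override away:

```{r}
default_profiles(overrides = list(nurse = list(pollen_low_mg = 6.5)))
```

## Exposure and risk characterization

A residue of $C$ µg/kg eaten at $I$ mg of matrix per period delivers a dose
$C \times I \times 10^{-6}$ µg. Exposures are therefore carried on the
$10^{-6}$ µg scale, where the dose is numerically the plain product
$C \times I$; a regression test confirms the shortcut agrees with a full
SI-unit computation to $10^{-9}$ relative tolerance. Exposure ranges
bracket lowest residue × lowest intake to highest residue × highest intake.

The **acute risk ratio** is the oral acute LD50 divided by the highest
daily exposure of a nurse bee (the caste with the highest pollen intake —
foragers eat no pollen and larvae are on a 5-day period). Ratios are
displayed rounded *half-up to the nearest thousand*: although such tables
sometimes describe the value as "rounded up", the published ratios the
bundled examples carry (e.g. raw 53 030 shown as 53 000, raw 7 733 as
8 000, raw 5 323 718 as 5 324 000) are consistent only with nearest-thousand rounding,
so that is what `acute_risk_ratio()` implements, keeping the raw ratio
alongside. A ratio at or below 1 flags exposure at the lethal dose.

The **chronic check** compares cumulative adult exposure with the 10-day
LC50. The underlying studies never show this arithmetic, so the convention
is explicit and configurable: by default the highest daily exposure is
accumulated over the 10-day test duration (`ten_day`); a per-day comparison
is available. Equality is classified `exceeds` (conservative boundary).
Substances without endpoints (most of them — chronic data exist for few
compounds) flow through as `unknown` rather than being dropped.

Two printed anomalies in the risk table the bundled examples reproduce are
deliberately not carried over: a larvae-lowest cell that equals highest-residue × lowest-intake
(contradicting the stated lowest × lowest rule, which the implementation
follows), and a forager nectar dose of 0.05 µg at 130 µg/kg whose arithmetic
(130 × 426.67 × 10⁻⁶ = 0.056) rounds to 0.06. The same study also lists a
thiacloprid LC50 in one year's row and "unknown" in the other's; the bundled
`toxicity_reference()` carries the one printed value (3.1 µg/bee), so the
chronic flag computes `below` for both years.

## Treated-vs-control statistics

Residue monitoring data are dominated by non-detects, so the group
comparison is rank-based: a Kruskal–Wallis test (midranks, standard tie
correction, chi-square reference with $k-1$ df) of treated vs control
hives, run for each timepoint separately on one resolved concentration per
hive. Three numerical choices matter:

* **Degenerate ties.** When every pooled value is identical (an
  all-non-detect timepoint) the tie-correction denominator is zero;
  `kruskal_wallis()` defines this case as $H = 0$, $p = 1$.
* **Discreteness at small n.** With 5 treated and 4 control hives the test
  has only 126 distinct rank allocations. Exhaustive enumeration shows the
  chi-square test's exact size at nominal $\alpha = 0.05$ is 4/126 ≈ 0.032
  for continuous data — within Monte-Carlo error (3 SE at 1000 replicates)
  of the nominal level, but not equal to it, and zero-inflation makes the
  test more conservative still. The calibration tests therefore anchor the
  simulated rejection rate to the enumerated exact size, and separately
  check that the exact size is within the Monte-Carlo band of 0.05; at tiny
  n the exact permutation oracle, not the chi-square approximation, is the
  arbiter (observed chi-square-vs-exact p gaps reach ~0.2 at pooled n ≤ 8).
* **No multiplicity adjustment by default.** The timepoints are reported as
  separate questions, mirroring how such designs are analyzed; a Holm
  adjustment is available by flag.

Non-detects enter the test as zeros (the default policy; configurable).
The pollen-composition correlation defaults to Spearman on midranks — the
surrounding analysis is nonparametric and no coefficient is canonical —
with Pearson by flag; it requires at least 3 complete pairs and flags
zero-variance inputs rather than returning a spurious coefficient.

## The synthetic generator

`generate_study()` emulates the statistical structure the analysis assumes:
a treated/control multi-field design (default 5 treated + 4 control fields,
one hive each, 4 pollen timepoints), per-sample Bernoulli detection (zero in
the treated arm before a substance's first exposed timepoint; a constant
background/drift probability in controls), lognormal concentrations for
detected residues with a phenomenological per-timepoint decay, per-substance
LOQ drawn from the configured regime (default 0.5–30 µg/kg), and nectar
forced below LOQ by default — the pattern seen in rainy-season monitoring.
The lognormal is the standard choice for residue concentrations and
produces the observed pattern of rare detections with occasional values
orders of magnitude above the minimum.

The generator is seed-deterministic (byte-identical regeneration, session
RNG untouched) and its output passes through the same validation gate as
file input, so every downstream stage runs on it unchanged. What it does
*not* emulate: foraging-landscape mechanisms, pesticide kinetics beyond the
decay factor, hive-level random effects, or correlation between substances.
Passing tests on synthetic data therefore demonstrate correctness of the
pipeline's computations and calibration of its tests under the stated
model, not ecological realism.

Two deterministic example studies (`example_study_2019()`,
`example_study_2020()`) carry the detection summaries of a published
two-year monitoring campaign — 24 semiquantitative pollen samples
at LOQ 10 µg/kg in the screening year; 41 pollen and 23 nectar samples in
the main year, with tau-fluvalinate in 8 of 41 pollen samples (1.0–19.8
µg/kg) and clean nectar. Only the summaries are anchored: which hive and
timepoint carries each detection is this package's own arbitrary,
documented assignment, chosen so that no timepoint reaches significance, as
reported for the original data. The main year's 41 pollen samples exceed
the 9 hives × 4 timepoints grid; the 5 surplus collections are recorded as
a 5th timepoint for the treated hives (sample-uniqueness holds; the
per-timepoint tests use timepoints 1–4). The screening year's sample count
is reported inconsistently in its source (23 vs 24); the fixture uses 24.

## Verification problem sizes

The statistical guarantees are checked at sizes chosen to make Monte-Carlo
error small relative to the tolerances: type-I calibration on 1000
replicate null studies (4000 per-timepoint tests) against the enumerated
exact size; detection-probability and log-mean recovery pooled over 100
replicate studies (≥ 3600 Bernoulli draws, ≥ 500 quantified
concentrations), both within 3 Monte-Carlo standard errors; power of a
strong post-treatment effect over 60 replicates. Log-mean recovery uses a
low-LOQ configuration so the left-truncation bias of conditioning on
quantified values is negligible relative to its tolerance.

## Limitations

* Oral exposure via pollen and nectar only — no contact, spray-drift, soil
  or water routes, and no colony-level or probabilistic refinement beyond
  the low/high bracketing.
* Exposure uses detected-range extremes, not a distributional model of the
  censored concentrations.
* The per-timepoint tests treat hives as independent units; no longitudinal
  modelling across timepoints.
* Toxicity endpoints are looked up per substance; mixture effects are out
  of scope.
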