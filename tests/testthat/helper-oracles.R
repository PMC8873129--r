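# Independent oracles used to cross-check the package implementation.

# Kruskal-Wallis H from first principles: midranks, rank-sum formula,
# explicit tie correction. Kept deliberately separate from the package code.
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  sizes <- vapply(groups, length, 0L)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  rank_sums <- mapply(function(a, b) sum(r[a:b]), starts, ends)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  tie_counts <- table(pooled)
  correction <- 1 - sum(tie_counts^3 - tie_counts) / (n^3 - n)
  if (correction == 0) return(0)
  h / correction
}

# Exact permutation p-value for small pooled n: enumerate every assignment
# of the pooled values to the two group sizes.
oracle_kw_exact_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n <- length(pooled)
  h_obs <- oracle_kw_h(list(g1, g2))
  idx <- utils::combn(n, length(g1))
  hs <- apply(idx, 2, function(i) oracle_kw_h(list(pooled[i], pooled[-i])))
  mean(hs >= h_obs - 1e-12)
}

# Exact size of the chi-square KW test for continuous data with two groups
# of the given sizes: enumerate rank allocations.
oracle_kw_exact_size <- function(n1, n2, alpha = 0.05) {
  n <- n1 + n2
  crit <- qchisq(1 - alpha, df = 1)
  idx <- utils::combn(n, n1)
  hs <- apply(idx, 2, function(i) oracle_kw_h(list(i, setdiff(seq_len(n), i))))
  mean(hs > crit)
}

# A tiny valid study for I/O edge-case tests.
tiny_study <- function() {
  samples <- tibble::tibble(
    sample_id = c("s1", "s2"),
    hive_id = c("h1", "h2"),
    field_id = c("f1", "f2"),
    treatment_arm = c("treated", "control"),
    matrix = "pollen",
    collection_date = as.Date("2020-07-01"),
    timepoint = 1L,
    collection_duration_h = 24,
    crop_pollen_fraction = c(0.1, NA)
  )
  measurements <- tibble::tibble(
    sample_id = c("s1", "s2"),
    substance = "thiacloprid",
    status = c("quantified", "not_detected"),
    concentration_ug_per_kg = c(77, NA),
    loq_ug_per_kg = 0.5,
    semiquantitative = FALSE
  )
  as_residue_study(samples, measurements)
}
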