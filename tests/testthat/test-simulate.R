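# Minimal outcome spec for configs that never call simulate_outcomes.
null_outcome <- list(list(name = "y", taxa = 1, coef = 0, noise_sd = 1,
                          timepoint = "G0"))

small_cfg <- function(seed = 1, ...) {
  sim_config(n_subjects_per_arm = 8, timepoints = c("G0", "G30"),
             n_taxa = 12, depth_mean = 2000, n_correlated_pairs = 2,
             diff_taxa_spec = list(), outcome_spec = null_outcome,
             seed = seed, ...)
}

test_that("planted basis correlation matrix has the stated structure", {
  expect_equal(generate_basis_correlation(4, 0, 0.8), diag(4))
  R <- generate_basis_correlation(4, 2, 0.8)
  expect_equal(R[1, 2], 0.8)
  expect_equal(R[3, 4], 0.8)
  expect_equal(R[1, 3], 0)
  expect_equal(R, t(R))
  # 2x2 blocks have eigenvalues 1 +- rho, so the spectrum is bounded away
  # from zero
  R50 <- generate_basis_correlation(50, 10, 0.8)
  expect_equal(min(eigen(R50, symmetric = TRUE)$values), 0.2, tolerance = 1e-12)
  expect_error(generate_basis_correlation(4, 1, 1.0), class = "gutstab_bad_config")
  expect_error(generate_basis_correlation(4, 3, 0.5), class = "gutstab_bad_config")
})

test_that("identical config and seed give bit-identical studies", {
  s1 <- simulate_counts(small_cfg(7))
  s2 <- simulate_counts(small_cfg(7))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$subject_effects, s2$truth$subject_effects)
  s3 <- simulate_counts(small_cfg(8))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("zero depth dispersion fixes every sample total at depth_mean", {
  st <- simulate_counts(small_cfg(3, depth_dispersion = 0))
  expect_true(all(rowSums(st$counts[, -1]) == 2000))
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(n_taxa = 0, diff_taxa_spec = list(),
                          outcome_spec = null_outcome),
               class = "gutstab_bad_config")
  expect_error(small_cfg(1, pair_rho = 1), class = "gutstab_bad_config")
  expect_error(sim_config(n_taxa = 10, n_correlated_pairs = 0,
                          diff_taxa_spec = list(list(taxon = 11, arm = "DF",
                                                     timepoints = "G0",
                                                     log2_effect = 1)),
                          outcome_spec = null_outcome),
               class = "gutstab_bad_config")
})

test_that("arms are exchangeable when no effects are planted", {
  # subject_sd = 0, no differential taxa: per-taxon mean relative
  # abundances agree between arms within Monte-Carlo error
  cfg <- sim_config(n_subjects_per_arm = 100, timepoints = "G0", n_taxa = 12,
                    depth_mean = 5000, n_correlated_pairs = 0,
                    diff_taxa_spec = list(), subject_sd = 0,
                    outcome_spec = null_outcome, seed = 31)
  st <- simulate_counts(cfg)
  rel <- as.matrix(relative_abundance(st$counts)[, -1])
  arm <- st$metadata$treatment
  for (j in seq_len(ncol(rel))) {
    d <- mean(rel[arm == "DF", j]) - mean(rel[arm == "CON", j])
    se <- sqrt(var(rel[arm == "DF", j]) / 100 + var(rel[arm == "CON", j]) / 100)
    expect_lt(abs(d), 4 * se + 1e-12)
  }
})

test_that("a planted +2 log2 effect quadruples mean relative abundance", {
  # minor planted taxon so compositional closure barely attenuates it
  mu <- rep(0, 12); mu[1] <- -2
  cfg <- sim_config(n_subjects_per_arm = 250, timepoints = c("G0", "G30"),
                    n_taxa = 12, depth_mean = 5000, n_correlated_pairs = 0,
                    taxon_log_means = mu, subject_sd = 0,
                    diff_taxa_spec = list(list(taxon = 1, arm = "DF",
                                               timepoints = "G30",
                                               log2_effect = 2)),
                    outcome_spec = null_outcome, seed = 17)
  st <- simulate_counts(cfg)
  rel <- as.matrix(relative_abundance(st$counts)[, -1])
  md <- st$metadata
  m_df <- mean(rel[md$treatment == "DF" & md$timepoint == "G30", 1])
  m_con <- mean(rel[md$treatment == "CON" & md$timepoint == "G30", 1])
  expect_equal(m_df / m_con, 4, tolerance = 0.15)
  # no effect leaks into G0
  g0 <- mean(rel[md$treatment == "DF" & md$timepoint == "G0", 1]) /
    mean(rel[md$treatment == "CON" & md$timepoint == "G0", 1])
  expect_equal(g0, 1, tolerance = 0.2)
})

test_that("outcome links behave as planted", {
  cfg <- sim_config(n_subjects_per_arm = 8, timepoints = "G0", n_taxa = 12,
                    depth_mean = 5000, n_correlated_pairs = 0,
                    diff_taxa_spec = list(), subject_sd = 0.5,
                    outcome_spec = list(
                      list(name = "null_out", taxa = 1, coef = 0, noise_sd = 1,
                           timepoint = "G0"),
                      list(name = "exact", taxa = 3, coef = 1, noise_sd = 0,
                           timepoint = "G0")),
                    seed = 23)
  st <- simulate_counts(cfg)
  md <- simulate_outcomes(st$counts, st$truth, st$metadata, seed = 23)
  rel <- as.matrix(relative_abundance(st$counts)[, -1])
  # noiseless single-taxon outcome is a monotone map of log abundance
  rho <- cor(md$exact, log10(rel[, 3] + 1e-6), method = "spearman")
  expect_equal(rho, 1)
  # null outcome centred at zero correlation over replicates
  rhos <- vapply(1:60, function(s) {
    mds <- simulate_outcomes(st$counts, st$truth, st$metadata, seed = s)
    cor(mds$null_out, rel[, 1], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))
  # missing linked taxon errors
  bad_truth <- st$truth
  bad_truth$outcome_spec <- list(list(name = "z", taxa = "nope", coef = 1,
                                      noise_sd = 0, timepoint = "G0"))
  expect_error(simulate_outcomes(st$counts, bad_truth, st$metadata, 1),
               class = "gutstab_missing_taxon")
})

test_that("equal signal and noise variance gives |rho| near 1/sqrt(2)", {
  cfg <- sim_config(n_subjects_per_arm = 8, timepoints = "G0", n_taxa = 12,
                    depth_mean = 5000, n_correlated_pairs = 0,
                    diff_taxa_spec = list(), subject_sd = 0.5,
                    outcome_spec = null_outcome, seed = 29)
  st <- simulate_counts(cfg)
  rel <- as.matrix(relative_abundance(st$counts)[, -1])
  signal <- log10(rel[, 3] + 1e-6)
  truth <- st$truth
  truth$outcome_spec <- list(list(name = "o", taxa = 3, coef = 1,
                                  noise_sd = sd(signal), timepoint = "G0"))
  rhos <- vapply(1:200, function(s) {
    md <- simulate_outcomes(st$counts, truth, st$metadata, seed = s)
    cor(md$o, signal, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 1 / sqrt(2)), 0.15)
})
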