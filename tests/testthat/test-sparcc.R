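test_that("fraction estimation matches Dirichlet posterior means", {
  tab0 <- tibble::tibble(sample_id = "s1", a = 0L, b = 0L)
  f <- estimate_fractions(tab0, n_draws = 0)[[1]]
  expect_equal(unname(f[1, ]), c(0.5, 0.5))
  tab9 <- tibble::tibble(sample_id = "s1", a = 9L, b = 0L)
  f9 <- estimate_fractions(tab9, n_draws = 0)[[1]]
  expect_equal(unname(f9[1, ]), c(10 / 11, 1 / 11))
  # Dirichlet mean (c + 1) / (n + D)
  tab31 <- tibble::tibble(sample_id = "s1", a = 3L, b = 1L)
  draws <- estimate_fractions(tab31, n_draws = 2000, seed = 1)
  f1 <- vapply(draws, function(m) m[1, 1], numeric(1))
  se <- sd(f1) / sqrt(length(f1))
  expect_lt(abs(mean(f1) - 4 / 6), 3 * se)
  expect_error(estimate_fractions(tibble::tibble(sample_id = character(0))),
               class = "gutstab_bad_table")
})

test_that("variation matrix is the log-ratio variance", {
  # proportional taxa have zero log-ratio variance
  f <- cbind(a = c(0.1, 0.2, 0.4), b = c(0.05, 0.1, 0.2),
             c = c(0.85, 0.7, 0.4))
  T_ <- variation_matrix(f)
  expect_equal(T_["a", "b"], 0)
  expect_equal(T_, t(T_))
  expect_true(all(diag(T_) == 0))
  # hand-computed arithmetic on fractions (.2,.8), (.5,.5), (.8,.2)
  f2 <- cbind(x = c(0.2, 0.5, 0.8), y = c(0.8, 0.5, 0.2))
  T2 <- variation_matrix(f2)
  expect_equal(T2["x", "y"], var(c(log(0.25), 0, log(4))), tolerance = 1e-12)
  expect_error(variation_matrix(cbind(c(0, 1), c(1, 0))),
               class = "gutstab_bad_table")
})

test_that("basis_correlations matches a hand-assembled 4-taxon solve", {
  set.seed(21)
  f <- matrix(rgamma(4 * 60, 2), ncol = 4)
  f <- f / rowSums(f)
  colnames(f) <- paste0("t", 1:4)
  T_ <- variation_matrix(f)
  # direct linear algebra: M w = rowSums(T), M = I*(D-2) + 1
  D <- 4
  M <- matrix(1, D, D); diag(M) <- D - 1
  w <- solve(M, rowSums(T_))
  rho_direct <- (outer(w, w, "+") - T_) / (2 * sqrt(outer(w, w)))
  rho_direct <- pmin(pmax(rho_direct, -1), 1); diag(rho_direct) <- 1
  rho <- basis_correlations(T_, exclusion_threshold = 1, max_exclusions = 0)
  expect_equal(unname(rho), unname(as.matrix(rho_direct)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(rho), unname(t(rho)))
  expect_true(all(diag(rho) == 1))
})

test_that("independent taxa yield small correlations, correlated ones large", {
  set.seed(33)
  n <- 400; D <- 20
  z <- matrix(rnorm(n * D), n)
  z[, 2] <- z[, 1]                     # perfectly correlated pair
  f <- exp(z); f <- f / rowSums(f)
  colnames(f) <- paste0("t", 1:D)
  rho <- basis_correlations(variation_matrix(f))
  expect_gt(rho[1, 2], 0.9)
  off <- rho[upper.tri(rho)]
  others <- off[-1]
  expect_lt(max(abs(others)), 0.25)
  expect_lt(mean(abs(others)), 0.15)
})

test_that("sparcc point estimate is compositional and order-invariant", {
  cfg <- sim_config(n_subjects_per_arm = 30, timepoints = "G0", n_taxa = 10,
                    depth_mean = 20000, n_correlated_pairs = 1, pair_rho = 0.8,
                    diff_taxa_spec = list(), subject_sd = 0,
                    outcome_spec = list(list(name = "y", taxa = 1, coef = 0,
                                             noise_sd = 1, timepoint = "G0")),
                    seed = 41)
  tab <- simulate_counts(cfg)$counts
  r0 <- sparcc(tab, n_inner = 0, seed = 1)$r
  # permuting sample order leaves the deterministic-mode estimate unchanged
  set.seed(5)
  perm <- tab[sample(nrow(tab)), ]
  r_perm <- sparcc(perm, n_inner = 0, seed = 1)$r
  expect_equal(r0, r_perm, tolerance = 1e-12)
  # closure: scaling one sample's counts barely moves the estimate
  tab2 <- tab
  tab2[3, -1] <- tab2[3, -1] * 4
  r_scaled <- sparcc(tab2, n_inner = 0, seed = 1)$r
  expect_lt(max(abs(r0 - r_scaled)), 0.02)
  expect_warning(sparcc(tab[1:5, ], n_inner = 0), "unstable")
  expect_error(sparcc(tab[, 1:3], n_inner = 0), class = "gutstab_bad_table")
})

test_that("pseudo-p-values respect the add-one rule and flag planted pairs", {
  cfg <- sim_config(n_subjects_per_arm = 50, timepoints = "G0", n_taxa = 10,
                    depth_mean = 20000, n_correlated_pairs = 1, pair_rho = 0.9,
                    diff_taxa_spec = list(), subject_sd = 0,
                    outcome_spec = list(list(name = "y", taxa = 1, coef = 0,
                                             noise_sd = 1, timepoint = "G0")),
                    seed = 43)
  tab <- simulate_counts(cfg)$counts
  fit <- sparcc(tab, n_inner = 5, seed = 1)
  fit <- sparcc_pvalues(tab, fit, n_null = 20, seed = 1)
  p_off <- fit$p[upper.tri(fit$p)]
  expect_true(all(p_off >= 1 / 21 & p_off <= 1))
  expect_equal(fit$p["g001", "g002"], 1 / 21)
  r2 <- sparcc_pvalues(tab, sparcc(tab, n_inner = 5, seed = 1),
                       n_null = 20, seed = 1)
  expect_identical(fit$p, r2$p)
})

test_that("build_network applies joint thresholds and keeps isolates", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.6
  r[1, 3] <- r[3, 1] <- 0.6
  r[2, 3] <- r[3, 2] <- 0.4
  p <- matrix(0.01, 3, 3)
  p[1, 3] <- p[3, 1] <- 0.2
  dimnames(r) <- dimnames(p) <- list(letters[1:3], letters[1:3])
  net <- build_network(fake_fit(r, p), r_threshold = 0.5, p_threshold = 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$from, net$edges$to)), c("a", "b"))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(build_network(fake_fit(r, p), drop_isolates = TRUE)$nodes), 2)
  # r_threshold = 1 gives an empty edge set; edge count is monotone in r
  expect_equal(nrow(build_network(fake_fit(r, p), r_threshold = 1)$edges), 0)
  n_thr <- vapply(c(0.3, 0.45, 0.55, 0.7),
                  function(t) nrow(build_network(fake_fit(r, p), t)$edges),
                  numeric(1))
  expect_true(all(diff(n_thr) <= 0))
  expect_error(build_network(fake_fit(r, p), r_threshold = 0),
               class = "gutstab_bad_threshold")
})
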