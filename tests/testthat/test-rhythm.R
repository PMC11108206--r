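# Harmonic regression, the consensus criterion, and the FDR calculus.

test_that("noiseless cosine is recovered in closed form", {
  t <- seq(0, 22, by = 2)
  y <- 3 + 2 * cos(2 * pi * (t - 8) / 24)
  fit <- fit_harmonic(t, y)
  expect_equal(fit$mesor, 3, tolerance = 1e-10)
  expect_equal(fit$amplitude, 2, tolerance = 1e-10)
  expect_equal(fit$phase, 8, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-20)

  const <- fit_harmonic(t, rep(5, length(t)))
  expect_equal(const$amplitude, 0)
  expect_equal(const$p_value, 1)

  expect_error(fit_harmonic(c(0, 12), c(1, 2)), "at least 4")
  expect_error(fit_harmonic(c(0, 0, 12, 12), c(1, 2, 3, 4)), "distinct")
})

test_that("fit agrees with a brute-force phase-profile oracle", {
  set.seed(31)
  for (i in 1:30) {
    t <- sort(runif(12, 0, 24))
    y <- runif(1, 1, 5) +
      runif(1, 0.5, 3) * cos(2 * pi * (t - runif(1, 0, 24)) / 24) +
      rnorm(12, 0, 0.3)
    fit <- fit_harmonic(t, y)
    ora <- harmonic_oracle(t, y)
    expect_equal(fit$amplitude, ora$amplitude, tolerance = 1e-4)
    expect_equal(fit$mesor, ora$mesor, tolerance = 1e-4)
    expect_lt(phase_diff_abs(fit$phase, ora$phase), 1e-3)
  }
})

test_that("phase is equivariant to time shifts, p-values invariant", {
  set.seed(32)
  t <- rep(seq(0, 22, 2), 2)
  y <- 4 + 1.5 * cos(2 * pi * (t - 15) / 24) + rnorm(length(t), 0, 0.4)
  base <- fit_harmonic(t, y)
  for (delta in c(1.5, 7, 23)) {
    shifted <- fit_harmonic(t + delta, y)
    expect_equal(shifted$phase, (base$phase + delta) %% 24,
                 tolerance = 1e-9)
    expect_equal(shifted$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("matrix fits equal per-gene fits and null p-values are uniform", {
  cfg <- sim_config(n_genes = 300, frac_cycling_18 = 0.1,
                    frac_cycling_25 = 0.1, seed = 33)
  sim <- simulate_experiment(cfg, "V1", "18C")
  fits <- rhythm_fits(sim$expr)
  i <- c(1, 57, 300)
  for (g in i) {
    single <- fit_harmonic(sim$expr$samples$zt,
                           log2(sim$expr$values[g, ] + 1))
    expect_equal(fits$p_value[g], single$p_value, tolerance = 1e-12)
    expect_equal(fits$phase[g], single$phase, tolerance = 1e-12)
    expect_equal(fits$amplitude[g], single$amplitude, tolerance = 1e-12)
  }

  null_cfg <- sim_config(n_genes = 10000, frac_cycling_18 = 0,
                         frac_cycling_25 = 0, seed = 34)
  null_fits <- rhythm_fits(simulate_experiment(null_cfg, "V1", "18C")$expr)
  ks <- suppressWarnings(ks.test(null_fits$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("harmonic regression recovers simulated phases accurately", {
  cfg <- sim_config(n_genes = 200, frac_cycling_18 = 1, frac_cycling_25 = 1,
                    frac_shared = 1, amplitude_range = c(1, 1),
                    noise_sd = 0.5, seed = 35)
  sim <- simulate_experiment(cfg, "V1", "18C")
  fits <- rhythm_fits(sim$expr)
  err <- phase_diff_abs(fits$phase, sim$truth$phase_18)
  expect_lt(mean(err), 0.5)
})

test_that("consensus criterion applies both thresholds strictly", {
  mk <- function(p, phase) data.frame(
    gene_id = c("g1", "g2", "g3"), mesor = 1, amplitude = 1,
    phase = phase, f_stat = 1, p_value = p, n_obs = 24,
    stringsAsFactors = FALSE)
  # g1 fails one p threshold; g2 is at the |dphi| = 3 boundary (2 vs 23);
  # g3 passes and gets the circular-mean consensus phase
  v1 <- mk(c(0.05, 0.05, 0.01), c(5, 2, 2))
  v2 <- mk(c(0.20, 0.05, 0.02), c(5, 23, 3.5))
  cc <- consensus_cyclers(v1, v2)
  expect_equal(cc$gene_id, "g3")
  expect_equal(cc$consensus_phase, 2.75)

  # same universe required
  expect_error(consensus_cyclers(v1, v2[-1, ]), "universe")
})

test_that("analytic false-positive calculus and FDR follow the formula", {
  expect_equal(expected_false_positives(6774, 0.1, 3), 16.935)
  expect_equal(expected_false_positives(1000, 0.1, 3), 2.5)
  expect_equal(expected_false_positives(5000, 0, 3), 0)
  expect_equal(fdr_estimate(10, 5), 1)  # capped
  expect_error(fdr_estimate(10, 0), "positive")
})

test_that("threshold sweep is consistent with consensus_cyclers and
           monotone in the p threshold", {
  cfg <- sim_config(n_genes = 800, frac_cycling_18 = 0.1,
                    frac_cycling_25 = 0.1, seed = 36)
  study <- simulate_study(cfg)
  fits <- list(
    "18C" = list(v1 = rhythm_fits(study$expr$V1_18C),
                 v2 = rhythm_fits(study$expr$V2_18C)),
    "25C" = list(v1 = rhythm_fits(study$expr$V1_25C),
                 v2 = rhythm_fits(study$expr$V2_25C)))
  sw <- fdr_threshold_sweep(fits, p_grid = c(0.05, 0.1), dphi_grid = 3)
  expect_equal(nrow(sw), 2)
  # singleton consistency with direct calls
  n18 <- nrow(consensus_cyclers(fits[["18C"]]$v1, fits[["18C"]]$v2, 0.1, 3))
  expect_equal(sw$n_detected_18[sw$p_thr == 0.1], n18)
  expect_equal(sw$fdr_18[sw$p_thr == 0.1],
               fdr_estimate(expected_false_positives(800, 0.1, 3), n18))
  # monotone non-decreasing in the p threshold
  expect_lte(sw$n_detected_18[1], sw$n_detected_18[2])
  expect_lte(sw$n_detected_25[1], sw$n_detected_25[2])
})

test_that("analytic FDR tracks the empirical FDR on labelled simulations", {
  cfg <- sim_config(n_genes = 4000, frac_cycling_18 = 0.1,
                    frac_cycling_25 = 0.1, frac_shared = 1,
                    amplitude_range = c(1, 2), noise_sd = 0.5, seed = 37)
  study <- simulate_study(cfg)
  f1 <- rhythm_fits(study$expr$V1_18C)
  f2 <- rhythm_fits(study$expr$V2_18C)
  cc <- consensus_cyclers(f1, f2)
  truth18 <- study$truth$is_cycling_18
  names(truth18) <- study$truth$gene_id
  emp_fdr <- mean(!truth18[cc$gene_id])
  ana_fdr <- fdr_estimate(
    expected_false_positives(sum(!truth18), 0.1, 3), nrow(cc))
  expect_lt(abs(emp_fdr - ana_fdr), 0.03)
})
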