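# Circular statistics: phase differences, means, correlation, tests,
# and the von Mises machinery.

test_that("signed phase difference matches the complex-argument definition", {
  # independent oracle: arg of the product of unit phasors
  oracle <- function(p1, p2) {
    Arg(exp(1i * 2 * pi * p1 / 24) * exp(-1i * 2 * pi * p2 / 24)) * 24 / (2 * pi)
  }
  expect_equal(phase_diff_signed(2, 2), 0)
  expect_equal(phase_diff_signed(1, 23), 2)   # advance across midnight
  expect_equal(oracle(1, 23), 2)
  expect_equal(phase_diff_signed(6, 18), 12)  # antipodal boundary -> +12
  expect_equal(abs(oracle(6, 18)), 12)

  set.seed(11)
  p1 <- runif(500, 0, 24)
  p2 <- runif(500, 0, 24)
  got <- phase_diff_signed(p1, p2)
  ref <- oracle(p1, p2)
  # oracle returns (-12, 12] up to the sign of Arg at the boundary
  expect_equal(got[abs(ref) < 12 - 1e-9], ref[abs(ref) < 12 - 1e-9])
  expect_true(all(got > -12 & got <= 12))
})

test_that("absolute phase difference is |signed| and a circular metric", {
  expect_equal(phase_diff_abs(23, 1), 2)   # min(22, 2)
  expect_equal(phase_diff_abs(5, 5), 0)
  expect_equal(phase_diff_abs(0, 12), 12)

  set.seed(12)
  a <- runif(10000, 0, 24); b <- runif(10000, 0, 24); c <- runif(10000, 0, 24)
  expect_equal(phase_diff_abs(a, b), abs(phase_diff_signed(a, b)))
  # metric properties
  expect_equal(phase_diff_abs(a, b), phase_diff_abs(b, a))
  expect_equal(phase_diff_abs(a, a), rep(0, length(a)))
  expect_true(all(phase_diff_abs(a, c) <=
                    phase_diff_abs(a, b) + phase_diff_abs(b, c) + 1e-12))
  # invariance to adding a full period
  expect_equal(phase_diff_abs(a + 24, b), phase_diff_abs(a, b))
  expect_equal(phase_diff_signed(a + 24, b), phase_diff_signed(a, b))
})

test_that("circular mean handles wrap-around and is shift-equivariant", {
  expect_equal(circular_mean(c(23, 1)), 0)
  expect_equal(circular_mean(c(2, 3.5)), 2.75)
  expect_equal(circular_mean(7), 7)
  expect_error(circular_mean(c(0, 12)), "zero resultant|antipodal")

  set.seed(13)
  for (i in 1:20) {
    ph <- runif(15, 0, 8)  # concentrated so the mean is well defined
    d <- runif(1, 0, 24)
    expect_equal(circular_mean((ph + d) %% 24),
                 (circular_mean(ph) + d) %% 24, tolerance = 1e-9)
  }
})

test_that("circular correlation is 1 for identical or rotated samples and
           near 0 for independent ones", {
  set.seed(14)
  ph <- runif(50, 0, 24)
  expect_equal(circular_correlation(ph, ph), 1)
  expect_equal(circular_correlation(ph, (ph + 5.5) %% 24), 1,
               tolerance = 1e-9)
  expect_error(circular_correlation(ph, ph[-1]), "equal length|paired")

  r <- circular_correlation(runif(300, 0, 24), runif(300, 0, 24))
  expect_lt(abs(r), 0.15)
})

test_that("Watson-Wheeler statistic is non-negative and detects antipodal
           separation", {
  set.seed(15)
  x <- rvonmises(50, 3, 20)
  y <- rvonmises(50, 15, 20)
  ww <- watson_wheeler_test(x, y)
  expect_gte(unname(ww$statistic), 0)
  expect_lt(ww$p.value, 1e-6)

  same <- watson_wheeler_test(rvonmises(40, 6, 2), rvonmises(40, 6, 2))
  expect_gte(unname(same$statistic), 0)
  expect_error(watson_wheeler_test(numeric(0), x), "non-empty")
  expect_warning(watson_wheeler_test(x[1:5], y), "below 10")
})

test_that("circular median sign test reproduces the exact binomial", {
  # 61 advanced of 79: cross-check against a direct binomial computation
  d <- c(rep(1.9, 61), rep(-1.2, 18))
  res <- circular_median_test(d)
  expect_equal(res$p.value, binom.test(61, 79, 0.5)$p.value)
  expect_equal(unname(res$statistic), 61)

  balanced <- c(seq(0.5, 5, 0.5), -seq(0.5, 5, 0.5))
  expect_equal(circular_median_test(balanced)$p.value, 1)

  all_pos <- rep(2, 20)
  expect_lt(circular_median_test(all_pos)$p.value, 1e-5)
  # ties at the hypothesized median are dropped
  with_ties <- c(rep(0, 3), rep(2, 20))
  expect_equal(circular_median_test(with_ties)$p.value,
               circular_median_test(all_pos)$p.value)
})

test_that("von Mises mixture EM recovers well-separated peaks", {
  set.seed(16)
  ph <- c(rvonmises(500, 2, 8), rvonmises(500, 20, 8))
  fit <- fit_vonmises_mixture(ph, seed = 1)
  expect_equal(length(fit$mu), 2)
  expect_lt(phase_diff_abs(fit$mu[1], 2), 0.5)
  expect_lt(phase_diff_abs(fit$mu[2], 20), 0.5)
  expect_equal(sum(fit$weight), 1, tolerance = 1e-9)
  # EM monotonicity: the log-likelihood trace never decreases
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("von Mises mixture handles the point-mass limit exactly", {
  ph <- c(rep(8.5, 30), rep(22, 30))
  fit <- fit_vonmises_mixture(ph, seed = 2)
  expect_equal(fit$mu, c(8.5, 22), tolerance = 1e-6)
  expect_true(all(fit$kappa <= 1e4))
})

test_that("the von Mises sampler concentrates around its mean direction", {
  set.seed(17)
  draws <- rvonmises(2000, 5, 10)
  expect_true(all(draws >= 0 & draws < 24))
  expect_lt(phase_diff_abs(circular_mean(draws), 5), 0.3)
  unif <- rvonmises(2000, 5, 0)
  expect_gt(suppressWarnings(ks.test(unif / 24, "punif"))$p.value, 1e-4)
})
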