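# Circular statistics on phases measured in hours on a 24-h clock.
# Radians are internal only; every public value is a Zeitgeber-time hour.

hours_to_rad <- function(h) h * (pi / 12)

rad_to_hours <- function(r) {
  h <- (r * (12 / pi)) %% 24
  # collapse the floating-point sliver just below 24 onto 0
  ifelse(h > 24 - 1e-9, 0, h)
}

#' Signed circular phase difference in hours
#'
#' Computes the signed angular separation between two phases on the 24-hour
#' circle, `arg(exp(i*2*pi*phi1/24) * exp(-i*2*pi*phi2/24)) * 24/(2*pi)`.
#' A positive value indicates a *phase advance* of `phi1` relative to `phi2`;
#' a negative value a phase delay. The result lies in `(-12, 12]`: the
#' antipodal boundary maps to `+12` so the output interval is half-open.
#'
#' @param phi1,phi2 Numeric vectors of phases in hours (recycled). Values
#'   are reduced modulo 24, so e.g. 26 and 2 are the same phase.
#' @return Numeric vector of signed differences in hours, in `(-12, 12]`.
#' @seealso [phase_diff_abs()] for the unsigned distance.
#' @examples
#' phase_diff_signed(1, 23)  # +2: an advance across midnight
#' phase_diff_signed(6, 18)  # +12 by convention
#' @export
phase_diff_signed <- function(phi1, phi2) {
  stopifnot(is.numeric(phi1), is.numeric(phi2),
            all(is.finite(phi1)), all(is.finite(phi2)))
  d <- (phi1 - phi2) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Absolute circular phase difference in hours
#'
#' The distance between two phases on the 24-hour circle,
#' `min(|phi1 - phi2|, 24 - |phi1 - phi2|)`, always in `[0, 12]`. Equals the
#' absolute value of [phase_diff_signed()] and is a metric on the circle.
#'
#' @inheritParams phase_diff_signed
#' @return Numeric vector of unsigned differences in hours, in `[0, 12]`.
#' @examples
#' phase_diff_abs(23, 1)  # 2
#' phase_diff_abs(0, 12)  # 12, maximal separation
#' @export
phase_diff_abs <- function(phi1, phi2) {
  stopifnot(is.numeric(phi1), is.numeric(phi2),
            all(is.finite(phi1)), all(is.finite(phi2)))
  a <- abs(phi1 - phi2) %% 24
  pmin(a, 24 - a)
}

#' Circular mean of phases
#'
#' The direction of the mean unit vector of the phases, mapped back to
#' hours in `[0, 24)`. Undefined (an error) when the resultant vector has
#' essentially zero length, e.g. for an exactly antipodal pair.
#'
#' @param phases Numeric vector of phases in hours; non-empty.
#' @return A single phase in hours in `[0, 24)`.
#' @examples
#' circular_mean(c(23, 1))   # 0
#' circular_mean(c(2, 3.5))  # 2.75
#' @export
circular_mean <- function(phases) {
  stopifnot(is.numeric(phases), length(phases) >= 1, all(is.finite(phases)))
  a <- hours_to_rad(phases)
  C <- mean(cos(a))
  S <- mean(sin(a))
  if (sqrt(C^2 + S^2) < 1e-10) {
    stop("circular mean undefined: resultant vector has zero length ",
         "(e.g. antipodal phases)")
  }
  rad_to_hours(atan2(S, C))
}

#' Circular correlation of paired phase samples
#'
#' The Jammalamadaka-SenGupta circular correlation coefficient of two
#' paired samples of phases, computed on the corresponding angles:
#' `sum(sin(a - mean_a) * sin(b - mean_b)) / sqrt(sum(sin(a - mean_a)^2) *
#' sum(sin(b - mean_b)^2))`, where `mean_a`, `mean_b` are circular means.
#' Invariant to rotating either sample by a constant.
#'
#' @param phases1,phases2 Paired numeric vectors of phases in hours, equal
#'   length of at least 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
circular_correlation <- function(phases1, phases2) {
  stopifnot(is.numeric(phases1), is.numeric(phases2))
  if (length(phases1) != length(phases2)) {
    stop("phases1 and phases2 must be paired (equal length)")
  }
  if (length(phases1) < 3) stop("need at least 3 pairs")
  a <- hours_to_rad(phases1)
  b <- hours_to_rad(phases2)
  da <- sin(a - hours_to_rad(circular_mean(phases1)))
  db <- sin(b - hours_to_rad(circular_mean(phases2)))
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) stop("a sample has zero angular variance")
  sum(da * db) / den
}

#' Watson-Wheeler (uniform-scores) two-sample test
#'
#' Tests whether two samples of phases come from the same circular
#' distribution using the Mardia uniform-scores construction: the pooled
#' sample is ranked around the circle (average ranks for ties), ranks are
#' mapped to uniform scores `beta = 2*pi*rank/N`, and the statistic
#' `W = 2 * sum_i (C_i^2 + S_i^2) / n_i` is computed from the per-sample
#' resultants of the scores. Under the null, `W` is asymptotically
#' chi-squared with 2 degrees of freedom (two samples).
#'
#' @param sample1,sample2 Numeric vectors of phases in hours. A warning is
#'   issued when either sample has fewer than 10 observations (the
#'   chi-squared approximation degrades).
#' @return A list of class `"htest"` with `statistic` (W), `parameter`
#'   (df = 2), and `p.value`.
#' @export
watson_wheeler_test <- function(sample1, sample2) {
  stopifnot(is.numeric(sample1), is.numeric(sample2))
  if (length(sample1) == 0 || length(sample2) == 0) {
    stop("both samples must be non-empty")
  }
  if (min(length(sample1), length(sample2)) < 10) {
    warning("sample size below 10; chi-squared approximation is rough")
  }
  n1 <- length(sample1)
  n2 <- length(sample2)
  N <- n1 + n2
  pooled <- c(sample1, sample2) %% 24
  beta <- 2 * pi * rank(pooled, ties.method = "average") / N
  grp <- rep(c(1L, 2L), c(n1, n2))
  W <- 0
  for (i in 1:2) {
    bi <- beta[grp == i]
    W <- W + (sum(cos(bi))^2 + sum(sin(bi))^2) / length(bi)
  }
  W <- 2 * W
  structure(
    list(statistic = c(W = W), parameter = c(df = 2),
         p.value = stats::pchisq(W, df = 2, lower.tail = FALSE),
         method = "Watson-Wheeler uniform-scores two-sample test",
         data.name = paste(deparse(substitute(sample1)), "and",
                           deparse(substitute(sample2)))),
    class = "htest"
  )
}

#' Sign test for the circular median of phase differences
#'
#' Tests whether the circular median of a sample of signed phase
#' differences departs from a hypothesized value, via the Fisher
#' common-median construction: observations are classified by the sign of
#' their signed circular difference from the hypothesized median, and the
#' counts on the two half-circles are compared with an exact two-sided
#' binomial test against probability 1/2. Observations falling exactly on
#' the hypothesized median are dropped (standard sign-test practice); the
#' antipodal boundary counts as positive, following the `(-12, 12]`
#' convention of [phase_diff_signed()].
#'
#' @param diffs Numeric vector of signed differences in hours, length >= 5.
#' @param hypothesized_median Hypothesized circular median, hours
#'   (default 0).
#' @return A list of class `"htest"` with `statistic` (number positive),
#'   `parameter` (number of non-tied observations), and `p.value`.
#' @examples
#' # 61 of 79 genes advanced: strong evidence the median shift exceeds 0
#' d <- c(rep(2, 61), rep(-2, 18))
#' circular_median_test(d)$p.value
#' @export
circular_median_test <- function(diffs, hypothesized_median = 0) {
  stopifnot(is.numeric(diffs))
  if (length(diffs) < 5) stop("need at least 5 observations")
  d <- phase_diff_signed(diffs, hypothesized_median)
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  if (n_pos + n_neg == 0) stop("all observations tie the hypothesized median")
  bt <- stats::binom.test(n_pos, n_pos + n_neg, p = 0.5)
  structure(
    list(statistic = c(n_positive = n_pos),
         parameter = c(n = n_pos + n_neg),
         p.value = bt$p.value,
         estimate = c(prop_positive = n_pos / (n_pos + n_neg)),
         method = "circular median sign test (exact binomial)",
         data.name = deparse(substitute(diffs))),
    class = "htest"
  )
}

#' Draw from a von Mises distribution on the 24-hour circle
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the uniform
#' distribution on `[0, 24)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in hours.
#' @param kappa Concentration, `>= 0`.
#' @return Numeric vector of phases in hours in `[0, 24)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, is.finite(mu), kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(stats::runif(n, 0, 24))
  mu_r <- hours_to_rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- mu_r + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  rad_to_hours(out)
}

# log von Mises density at angle theta (radians); overflow-safe via the
# exponentially scaled Bessel function.
dvonmises_log <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

# Inverse of A1(kappa) = I1/I0: Fisher's piecewise approximation refined
# by Newton steps; capped so concentrated components cannot overflow.
a1inv <- function(R, kappa_max = 1e4) {
  if (R >= 1) return(kappa_max)
  if (R <= 0) return(0)
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  k <- min(max(k, 1e-8), kappa_max)
  for (it in 1:25) {
    A <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
    Ap <- 1 - A / k - A^2       # d A1 / d kappa
    if (!is.finite(A) || !is.finite(Ap) || Ap <= 0) break
    step <- (A - R) / Ap
    k <- k - step
    if (!is.finite(k) || k <= 0) { k <- 1e-8; break }
    if (k > kappa_max) { k <- kappa_max; break }
    if (abs(step) < 1e-10 * max(1, k)) break
  }
  min(max(k, 0), kappa_max)
}

#' Fit a mixture of von Mises distributions to phases
#'
#' Expectation-maximization on the circle for a small number of
#' components, with multiple random restarts; the best fit by
#' log-likelihood is returned. Used to locate the peaks of a bimodal
#' phase distribution.
#'
#' @param phases Numeric vector of phases in hours, length >= 10.
#' @param k Number of components (default 2).
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-8).
#' @param seed Optional integer seed for the restarts.
#' @return An object of class `"vm_mixture"`: a list with `mu` (component
#'   means, hours, sorted), `kappa`, `weight`, `loglik`, `converged`, and
#'   `n_iter`. Concentrations are capped at 1e4 so point masses cannot
#'   overflow.
#' @export
fit_vonmises_mixture <- function(phases, k = 2, n_init = 10, max_iter = 500,
                                 tol = 1e-8, seed = NULL) {
  stopifnot(is.numeric(phases), k >= 1, n_init >= 1)
  if (length(phases) < 10) stop("need at least 10 phases")
  if (!is.null(seed)) set.seed(seed)
  theta <- hours_to_rad(phases %% 24)
  n <- length(theta)
  kappa_max <- 1e4

  best <- NULL
  for (init in seq_len(n_init)) {
    mu <- hours_to_rad(stats::runif(k, 0, 24))
    kap <- rep(1, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      # E step in log space
      logdens <- vapply(seq_len(k), function(j) {
        log(w[j]) + dvonmises_log(theta, mu[j], kap[j])
      }, numeric(n))
      m <- apply(logdens, 1, max)
      lse <- m + log(rowSums(exp(logdens - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(logdens - lse)
      # M step
      nj <- colSums(resp)
      nj <- pmax(nj, 1e-12)
      w <- nj / n
      for (j in seq_len(k)) {
        Cj <- sum(resp[, j] * cos(theta))
        Sj <- sum(resp[, j] * sin(theta))
        mu[j] <- atan2(Sj, Cj)
        Rbar <- min(sqrt(Cj^2 + Sj^2) / nj[j], 1 - 1e-12)
        kap[j] <- a1inv(Rbar, kappa_max)
      }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    if (is.null(best) || ll_old > best$loglik) {
      ord <- order(rad_to_hours(mu))
      best <- list(mu = rad_to_hours(mu)[ord], kappa = kap[ord],
                   weight = w[ord], loglik = ll_old,
                   loglik_trace = trace,
                   converged = converged, n_iter = iter)
    }
  }
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best iterate")
  }
  structure(best, class = "vm_mixture")
}

#' @export
print.vm_mixture <- function(x, ...) {
  cat("von Mises mixture (", length(x$mu), " components)\n", sep = "")
  for (j in seq_along(x$mu)) {
    cat(sprintf("  component %d: mu = ZT %.2f h, kappa = %.3g, weight = %.3f\n",
                j, x$mu[j], x$kappa[j], x$weight[j]))
  }
  cat(sprintf("  log-likelihood = %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
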