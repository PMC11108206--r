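# Harmonic (cosinor) regression rhythm detection, the dual-experiment
# consensus criterion, and the analytic false-discovery calculus.

#' Harmonic regression of one time course
#'
#' Ordinary least squares of `y = b0 + b1*cos(w*t) + b2*sin(w*t)` with
#' `w = 2*pi/period`. The amplitude is `sqrt(b1^2 + b2^2)`, the phase the
#' ZT hour of the fitted peak, `(period/(2*pi)) * atan2(b2, b1) mod
#' period`, and the p-value comes from the F test of the two harmonic
#' terms against the intercept-only model, on `(2, n - 3)` degrees of
#' freedom.
#'
#' @param times Numeric vector of sampling times in hours; at least 4
#'   observations at at least 3 distinct times modulo the period.
#' @param values Numeric vector of observations (same length). A constant
#'   series returns amplitude 0, p-value 1, phase `NA` rather than an
#'   error.
#' @param period Oscillation period in hours (default 24).
#' @return A list with `mesor`, `amplitude`, `phase`, `f_stat`, `p_value`,
#'   `n_obs`.
#' @examples
#' t <- seq(0, 22, by = 2)
#' fit <- fit_harmonic(t, 3 + 2 * cos(2 * pi * (t - 8) / 24))
#' fit$amplitude  # 2
#' fit$phase      # 8
#' @export
fit_harmonic <- function(times, values, period = 24) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  n <- length(times)
  if (n < 4) stop("need at least 4 observations")
  if (length(unique(round(times %% period, 9))) < 3) {
    stop("need at least 3 distinct times modulo the period")
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  qx <- qr(X)
  beta <- qr.coef(qx, values)
  res <- qr.resid(qx, values)
  rss <- sum(res^2)
  tss <- sum((values - mean(values))^2)
  if (tss < 1e-24) {
    return(list(mesor = mean(values), amplitude = 0, phase = NA_real_,
                f_stat = 0, p_value = 1, n_obs = n))
  }
  f <- ((tss - rss) / 2) / (rss / (n - 3))
  p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  list(mesor = unname(beta[1]),
       amplitude = sqrt(beta[2]^2 + beta[3]^2),
       phase = (atan2(beta[3], beta[2]) * period / (2 * pi)) %% period,
       f_stat = f, p_value = p, n_obs = n)
}

#' Harmonic regression across all genes of an expression set
#'
#' Fits the cosinor model to every gene of an [expression_set()] at once
#' (a single least-squares factorization, since all genes share the
#' design). By default fits `log2(TPM + 1)`; set `log_transform = FALSE`
#' to fit raw TPM.
#'
#' @param expr An `expr_set` (one experiment, one condition).
#' @param period Oscillation period in hours (default 24).
#' @param log_transform Fit `log2(TPM + 1)` (default `TRUE`) or raw TPM.
#' @return A data.frame with one row per gene: `gene_id`, `mesor`,
#'   `amplitude`, `phase`, `f_stat`, `p_value`, `n_obs`.
#' @export
rhythm_fits <- function(expr, period = 24, log_transform = TRUE) {
  stopifnot(inherits(expr, "expr_set"))
  times <- expr$samples$zt
  n <- length(times)
  if (n < 4) stop("need at least 4 samples")
  if (length(unique(round(times %% period, 9))) < 3) {
    stop("need at least 3 distinct times modulo the period")
  }
  Y <- t(if (log_transform) log2(expr$values + 1) else expr$values)
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  qx <- qr(X)
  B <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  rss <- colSums(res^2)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  f <- ((tss - rss) / 2) / (rss / (n - 3))
  p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  amplitude <- sqrt(B[2, ]^2 + B[3, ]^2)
  phase <- (atan2(B[3, ], B[2, ]) * period / (2 * pi)) %% period
  degenerate <- tss < 1e-24
  f[degenerate] <- 0
  p[degenerate] <- 1
  amplitude[degenerate] <- 0
  phase[degenerate] <- NA_real_
  # a perfect (noiseless) fit has rss ~ 0: report p = 0, keep estimates
  exact <- !degenerate & rss < 1e-24 * pmax(tss, 1)
  f[exact] <- Inf
  p[exact] <- 0
  data.frame(gene_id = rownames(expr$values), mesor = unname(B[1, ]),
             amplitude = unname(amplitude), phase = unname(phase),
             f_stat = unname(f), p_value = unname(p), n_obs = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dual-experiment consensus cyclers
#'
#' A gene is called cycling when its harmonic-regression p-value is below
#' `p_threshold` in *both* experiments and the two phase estimates agree
#' to within `dphi_threshold` hours on the circle (both criteria strict).
#' The consensus phase is the circular mean of the two estimates.
#'
#' @param fits_v1,fits_v2 Per-gene fit tables from [rhythm_fits()] for the
#'   two experiments; must cover the same gene universe.
#' @param p_threshold Per-experiment p-value threshold (default 0.1).
#' @param dphi_threshold Maximum absolute inter-experiment phase
#'   difference in hours (default 3).
#' @return A data.frame with columns `gene_id`, `phase_v1`, `phase_v2`,
#'   `consensus_phase`, `p_v1`, `p_v2`.
#' @export
consensus_cyclers <- function(fits_v1, fits_v2, p_threshold = 0.1,
                              dphi_threshold = 3) {
  stopifnot(is.data.frame(fits_v1), is.data.frame(fits_v2),
            p_threshold > 0, dphi_threshold > 0)
  if (!setequal(fits_v1$gene_id, fits_v2$gene_id) ||
      nrow(fits_v1) != nrow(fits_v2)) {
    stop("the two fit tables must cover the same gene universe")
  }
  fits_v2 <- fits_v2[match(fits_v1$gene_id, fits_v2$gene_id), ]
  ok <- fits_v1$p_value < p_threshold & fits_v2$p_value < p_threshold &
    !is.na(fits_v1$phase) & !is.na(fits_v2$phase)
  ok[is.na(ok)] <- FALSE
  p1 <- fits_v1$phase[ok]
  p2 <- fits_v2$phase[ok]
  dphi <- phase_diff_abs(p1, p2)
  keep <- dphi < dphi_threshold
  a1 <- hours_to_rad(p1[keep]); a2 <- hours_to_rad(p2[keep])
  consensus <- rad_to_hours(atan2(sin(a1) + sin(a2), cos(a1) + cos(a2)))
  data.frame(gene_id = fits_v1$gene_id[ok][keep],
             phase_v1 = p1[keep], phase_v2 = p2[keep],
             consensus_phase = consensus,
             p_v1 = fits_v1$p_value[ok][keep],
             p_v2 = fits_v2$p_value[ok][keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected number of false-positive cyclers
#'
#' Under the null, per-experiment p-values are uniform, so both fall below
#' `p_threshold` with probability `p_threshold^2`; null phases are uniform
#' on the circle, so they agree to within `dphi_threshold` hours with
#' probability `2 * dphi_threshold / 24`. The expected count of genes
#' passing the dual criterion by chance is the product times `n_genes`.
#' At the defaults the chance-pass probability is `0.1^2 * (6/24) =
#' 0.0025`.
#'
#' @param n_genes Number of genes tested.
#' @param p_threshold Per-experiment p-value threshold in `(0, 1]`.
#' @param dphi_threshold Phase-agreement threshold in hours, `[0, 12]`.
#' @return Expected false-positive count (a real number).
#' @examples
#' expected_false_positives(6774, 0.1, 3)  # 16.935, i.e. ~17 genes
#' @export
expected_false_positives <- function(n_genes, p_threshold = 0.1,
                                     dphi_threshold = 3) {
  stopifnot(n_genes >= 0, p_threshold >= 0, p_threshold <= 1,
            dphi_threshold >= 0, dphi_threshold <= 12)
  n_genes * p_threshold^2 * (2 * dphi_threshold / 24)
}

#' Analytic false-discovery-rate estimate
#'
#' The expected false-positive count divided by the observed number of
#' detections, capped at 1.
#'
#' @param expected_fp Expected number of false positives (see
#'   [expected_false_positives()]).
#' @param n_detected Number of genes actually detected; must be positive.
#' @return Estimated FDR in `[0, 1]`.
#' @examples
#' fdr_estimate(expected_false_positives(6774, 0.1, 3), 242)  # ~0.07
#' @export
fdr_estimate <- function(expected_fp, n_detected) {
  stopifnot(expected_fp >= 0)
  if (n_detected <= 0) stop("n_detected must be positive")
  min(expected_fp / n_detected, 1)
}

#' Sweep detection thresholds and tabulate counts and FDR
#'
#' Applies [consensus_cyclers()] over a grid of p-value and
#' phase-agreement thresholds for both conditions and reports the number
#' of detections and the analytic FDR at each grid point.
#'
#' @param fits A named list with elements `` `18C` `` and `` `25C` ``,
#'   each itself a list with fit tables `v1` and `v2`.
#' @param p_grid Numeric vector of p-value thresholds.
#' @param dphi_grid Numeric vector of phase-agreement thresholds (hours).
#' @return A data.frame with columns `p_thr`, `dphi_thr`,
#'   `n_detected_18`, `n_detected_25`, `fdr_18`, `fdr_25` (FDR is `NA`
#'   when nothing is detected).
#' @export
fdr_threshold_sweep <- function(fits, p_grid, dphi_grid) {
  stopifnot(all(c("18C", "25C") %in% names(fits)),
            length(p_grid) >= 1, length(dphi_grid) >= 1)
  n_genes <- nrow(fits[["18C"]]$v1)
  grid <- expand.grid(p_thr = sort(p_grid), dphi_thr = sort(dphi_grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$p_thr[i]; d <- grid$dphi_thr[i]
    n18 <- nrow(consensus_cyclers(fits[["18C"]]$v1, fits[["18C"]]$v2, p, d))
    n25 <- nrow(consensus_cyclers(fits[["25C"]]$v1, fits[["25C"]]$v2, p, d))
    efp <- expected_false_positives(n_genes, p, d)
    data.frame(p_thr = p, dphi_thr = d,
               n_detected_18 = n18, n_detected_25 = n25,
               fdr_18 = if (n18 > 0) fdr_estimate(efp, n18) else NA_real_,
               fdr_25 = if (n25 > 0) fdr_estimate(efp, n25) else NA_real_)
  })
  do.call(rbind, res)
}
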