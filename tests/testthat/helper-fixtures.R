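# Shared fixtures and independent oracles used across the test files.

# Build a small expr_set from a matrix of TPM values and design metadata.
make_expr <- function(values, experiment = "V1", condition = "18C",
                      zt = NULL, replicate = NULL) {
  n_samp <- ncol(values)
  if (is.null(zt)) zt <- seq(0, by = 2, length.out = n_samp)
  if (is.null(replicate)) replicate <- rep(1L, n_samp)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  ids <- sprintf("%s_%s_s%02d", experiment, condition, seq_len(n_samp))
  colnames(values) <- ids
  expression_set(values, data.frame(
    sample_id = ids, experiment = experiment, condition = condition,
    zt = zt, replicate = replicate, stringsAsFactors = FALSE))
}

# An expr_set whose per-gene medians are exactly the supplied vector:
# every sample holds the same value per gene (median == that value).
constant_expr <- function(medians, experiment, condition, n_samp = 6) {
  vals <- matrix(rep(medians, n_samp), nrow = length(medians))
  rownames(vals) <- names(medians)
  make_expr(vals, experiment, condition)
}

# Brute-force all-pairs shortest paths (Floyd-Warshall) on an igraph;
# independent of the BFS-based distances used by the package.
floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    D[el[r, 1], el[r, 2]] <- 1
    D[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  rownames(D) <- colnames(D) <- igraph::V(g)$name
  D
}

# Independent cosinor oracle: profile the SSE over a fine phase grid,
# refining with optimize(); amplitude/mesor by OLS at the best phase.
harmonic_oracle <- function(times, values, period = 24) {
  sse_at <- function(phi) {
    X <- cbind(1, cos(2 * pi * (times - phi) / period))
    sum(stats::lm.fit(X, values)$residuals^2)
  }
  grid <- seq(0, period, length.out = 241)[-241]
  phi0 <- grid[which.min(vapply(grid, sse_at, numeric(1)))]
  opt <- stats::optimize(sse_at, c(phi0 - 0.2, phi0 + 0.2))
  phi <- opt$minimum %% period
  X <- cbind(1, cos(2 * pi * (times - phi) / period))
  b <- stats::lm.fit(X, values)$coefficients
  # a negative cosine coefficient means the true peak is antipodal
  if (b[2] < 0) {
    phi <- (phi + period / 2) %% period
    b[2] <- -b[2]
  }
  list(mesor = unname(b[1]), amplitude = unname(b[2]), phase = phi)
}

# A path graph with named nodes, for constructed-profile tests.
path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- sprintf("p%03d", seq_len(n))
  g
}
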