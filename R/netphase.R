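# Network construction and the phase-organization analysis: degree and
# localization control tests, the geodesic-distance phase-difference
# profile, and its permutation null.

#' Load an undirected gene network from a two-column edge list
#'
#' Reads a tab-delimited two-column edge list, builds a simple undirected
#' graph, and drops duplicate edges and self-loops (counts are reported
#' via `message()`). Blank or malformed lines are an error naming the
#' line number.
#'
#' @param edge_list_path Path to the TSV edge list (no header).
#' @return An igraph object with named nodes.
#' @export
load_network <- function(edge_list_path) {
  lines <- readLines(edge_list_path)
  if (length(lines) == 0) stop("empty edge list: ", edge_list_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2 |
                 !nzchar(trimws(lines)))
  if (length(bad)) {
    stop("malformed edge list line ", bad[1], " in ", edge_list_path,
         ": expected two tab-separated gene ids")
  }
  el <- t(vapply(fields, function(f) trimws(f[1:2]), character(2)))
  if (any(!nzchar(el))) {
    stop("malformed edge list line ",
         which(apply(el == "", 1, any))[1], " in ", edge_list_path,
         ": empty gene id")
  }
  g_raw <- igraph::graph_from_edgelist(el, directed = FALSE)
  n_self <- sum(igraph::which_loop(g_raw))
  g <- igraph::simplify(g_raw)
  n_dup <- igraph::ecount(g_raw) - n_self - igraph::ecount(g)
  if (n_self + n_dup > 0) {
    message("dropped ", n_self, " self-loop(s) and ", n_dup,
            " duplicate edge(s)")
  }
  g
}

#' Largest connected component of a network
#'
#' Returns the induced subgraph on the largest connected component; a tie
#' in component size is broken in favour of the component containing the
#' lexicographically smallest node name.
#'
#' @param net An igraph with named nodes; non-empty.
#' @return An igraph, the induced subgraph.
#' @export
largest_connected_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0) stop("empty graph")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Compare degree distributions of cycling genes to the network
#'
#' Two-sample Kolmogorov-Smirnov tests of the node-degree distributions
#' for three comparisons: 18C cyclers vs 25C cyclers, 18C cyclers vs all
#' nodes, and 25C cyclers vs all nodes.
#'
#' @param net An igraph with named nodes.
#' @param cyclers_18,cyclers_25 Character vectors of node names; must be
#'   subsets of the network's nodes and non-empty.
#' @return A data.frame with columns `comparison`, `D`, `p_value`.
#' @export
degree_comparison <- function(net, cyclers_18, cyclers_25) {
  stopifnot(igraph::is_igraph(net))
  nodes <- igraph::V(net)$name
  for (s in list(cyclers_18, cyclers_25)) {
    if (length(s) == 0) stop("empty cycler set")
    if (!all(s %in% nodes)) {
      stop("cycler set contains genes not on the network: ",
           paste(utils::head(setdiff(s, nodes), 5), collapse = ", "))
    }
  }
  deg <- igraph::degree(net)
  d18 <- deg[cyclers_18]
  d25 <- deg[cyclers_25]
  run_ks <- function(a, b) {
    kt <- suppressWarnings(stats::ks.test(a, b))
    c(D = unname(kt$statistic), p_value = kt$p.value)
  }
  out <- rbind(run_ks(d18, d25), run_ks(d18, deg), run_ks(d25, deg))
  data.frame(comparison = c("18C vs 25C", "18C vs all", "25C vs all"),
             D = out[, "D"], p_value = out[, "p_value"],
             stringsAsFactors = FALSE, row.names = NULL)
}

# finite pairwise geodesic distances among a node set (upper triangle)
pairwise_distances <- function(net, nodes) {
  D <- igraph::distances(net, v = nodes, to = nodes)
  d <- D[upper.tri(D)]
  list(finite = d[is.finite(d)], n_disconnected = sum(!is.finite(d)))
}

#' Test whether cycling genes are co-localized on the network
#'
#' Compares the pairwise geodesic distances among cycling genes to the
#' pairwise distances among all genes on the network with a one-sided
#' (less) Wilcoxon rank-sum test: a small p-value indicates that cyclers
#' sit closer together than a typical gene pair. Disconnected pairs are
#' excluded and counted.
#'
#' @param net An igraph with named nodes.
#' @param cyclers Character vector of cycler node names, length >= 2.
#' @param all_genes Character vector of background node names (default:
#'   every node of `net`).
#' @return A list with `p_value`, `statistic`, `n_pairs_cyclers`,
#'   `n_pairs_background`, `n_disconnected` (cycler pairs dropped),
#'   `median_cyclers`, `median_background`.
#' @export
localization_test <- function(net, cyclers,
                              all_genes = igraph::V(net)$name) {
  stopifnot(igraph::is_igraph(net), length(cyclers) >= 2)
  nodes <- igraph::V(net)$name
  if (!all(cyclers %in% nodes)) stop("cyclers must be nodes of the network")
  if (!all(all_genes %in% nodes)) stop("background must be nodes of the network")
  pc <- pairwise_distances(net, cyclers)
  pa <- pairwise_distances(net, all_genes)
  if (length(pc$finite) == 0) stop("all cycler pairs are disconnected")
  # integer distances always tie; the normal approximation is intended
  wt <- suppressWarnings(
    stats::wilcox.test(pc$finite, pa$finite, alternative = "less"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_pairs_cyclers = length(pc$finite),
       n_pairs_background = length(pa$finite),
       n_disconnected = pc$n_disconnected,
       median_cyclers = stats::median(pc$finite),
       median_background = stats::median(pa$finite))
}

# per-distance medians of |dphi| given a pair-distance vector and the
# fixed pair |dphi| vector; returns a length-d_max vector (NA if empty)
medians_by_distance <- function(dd, dphi, d_max) {
  out <- rep(NA_real_, d_max)
  for (d in seq_len(d_max)) {
    v <- dphi[dd == d]
    if (length(v)) out[d] <- stats::median(v)
  }
  out
}

#' Phase-difference profile over geodesic distance
#'
#' For every unordered pair of phase-mapped genes with geodesic distance
#' `d <= d_max`, computes the absolute circular phase difference, bins the
#' pairs by distance, takes the per-bin median, and regresses the medians
#' on distance by ordinary least squares. The slope (hours per step) and
#' its t-test p-value summarize how phase similarity decays with network
#' distance; with all `d_max` bins occupied the regression has
#' `d_max - 2` degrees of freedom. Empty bins are dropped from the
#' regression (reducing the df) and reported with zero pair count.
#'
#' @param net An igraph with named nodes.
#' @param phases Named numeric vector: phase in hours per gene; names must
#'   be nodes of `net`, length >= 2.
#' @param d_max Largest geodesic distance considered (default 6).
#' @return An object of class `"phase_profile"`: a list with
#'   `by_distance` (data.frame: `distance`, `n_pairs`, `median_dphi`),
#'   `slope`, `slope_p`, `df`, `d_max`, `n_genes`, `n_pairs_used`.
#' @export
phase_distance_profile <- function(net, phases, d_max = 6) {
  stopifnot(igraph::is_igraph(net), is.numeric(phases), d_max >= 2)
  genes <- names(phases)
  if (is.null(genes) || length(genes) < 2) {
    stop("phases must be a named vector with at least 2 genes")
  }
  if (!all(genes %in% igraph::V(net)$name)) {
    stop("phase map contains genes not on the network: ",
         paste(utils::head(setdiff(genes, igraph::V(net)$name), 5),
               collapse = ", "))
  }
  D <- igraph::distances(net, v = genes, to = genes)
  ut <- upper.tri(D)
  dd <- D[ut]
  ph <- phases %% 24
  P1 <- matrix(ph, nrow = length(ph), ncol = length(ph))
  dphi_all <- phase_diff_abs(t(P1)[ut], P1[ut])
  keep <- is.finite(dd) & dd >= 1 & dd <= d_max
  if (!any(keep)) stop("no gene pair within d_max = ", d_max)
  dd <- dd[keep]
  dphi <- dphi_all[keep]
  med <- medians_by_distance(dd, dphi, d_max)
  counts <- vapply(seq_len(d_max), function(d) sum(dd == d), integer(1))
  by_distance <- data.frame(distance = seq_len(d_max), n_pairs = counts,
                            median_dphi = med)
  occupied <- !is.na(med)
  if (sum(occupied) < 3) {
    slope <- NA_real_; slope_p <- NA_real_; df <- NA_integer_
  } else {
    fit <- stats::lm(median_dphi ~ distance, data = by_distance[occupied, ])
    # an exact linear profile (zero residuals) is legitimate here
    sm <- suppressWarnings(summary(fit))$coefficients
    slope <- sm["distance", "Estimate"]
    slope_p <- sm["distance", "Pr(>|t|)"]
    df <- sum(occupied) - 2L
  }
  structure(list(by_distance = by_distance, slope = slope,
                 slope_p = slope_p, df = df, d_max = d_max,
                 n_genes = length(genes), n_pairs_used = length(dd)),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat(sprintf("phase-distance profile: %d genes, %d pairs (d <= %d)\n",
              x$n_genes, x$n_pairs_used, x$d_max))
  print(x$by_distance, row.names = FALSE)
  if (!is.na(x$slope)) {
    cat(sprintf("slope = %.3f h/step, p = %.3g, df = %d\n",
                x$slope, x$slope_p, x$df))
  }
  invisible(x)
}

#' Permutation null for the phase-distance profile
#'
#' Re-places the cycling-gene set uniformly at random (without
#' replacement) over all nodes of the network, keeping the observed phase
#' multiset attached in fixed order, and recomputes the per-distance
#' median absolute phase difference for each of `n_perm` permutations.
#' Reports, per distance, the 0.025 and 0.975 null quantiles and the
#' empirical two-sided p-value `2 * min(r, 1 - r)` with
#' `r = (1 + #\{null <= observed\}) / (n_perm + 1)` (add-one estimator, so
#' p is never 0). An alternative null that keeps the observed node
#' positions and shuffles the phases among them is available via
#' `mode = "shuffle_phases"`.
#'
#' @param net An igraph with named nodes (typically the largest connected
#'   component).
#' @param phases Named numeric vector of phases (hours) for the observed
#'   placement; names must be nodes of `net`.
#' @param n_perm Number of permutations, at least 100 (default 5000).
#' @param d_max Largest geodesic distance considered (default 6).
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   results.
#' @param mode `"relocate"` (default; re-place genes over all nodes) or
#'   `"shuffle_phases"`.
#' @return An object of class `"permutation_null"`: a list with
#'   `by_distance` (data.frame: `distance`, `n_pairs`, `median_dphi`,
#'   `null_q025`, `null_q975`, `p_two_sided`), `n_perm`, `seed`, `mode`,
#'   and `null_medians` (the `n_perm` x `d_max` matrix of null medians).
#' @export
permutation_null <- function(net, phases, n_perm = 5000, d_max = 6,
                             seed = NULL, mode = c("relocate",
                                                   "shuffle_phases")) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(net), is.numeric(phases))
  if (n_perm < 100) stop("n_perm < 100: null quantiles would be unstable")
  genes <- names(phases)
  if (is.null(genes) || length(genes) < 2) {
    stop("phases must be a named vector with at least 2 genes")
  }
  nodes <- igraph::V(net)$name
  if (!all(genes %in% nodes)) stop("phase map contains genes not on the network")
  if (!is.null(seed)) set.seed(seed)
  m <- length(phases)
  ph <- phases %% 24
  # pairwise |dphi| in the fixed multiset order: identical across
  # permutations, only the pair distances change
  P1 <- matrix(ph, nrow = m, ncol = m)
  ut <- upper.tri(P1)
  dphi <- phase_diff_abs(t(P1)[ut], P1[ut])

  obs <- phase_distance_profile(net, phases, d_max = d_max)

  if (mode == "relocate") {
    Dall <- igraph::distances(net)
    null_med <- matrix(NA_real_, n_perm, d_max)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(nodes), m)
      dd <- Dall[idx, idx][ut]
      ok <- is.finite(dd)
      null_med[b, ] <- medians_by_distance(dd[ok], dphi[ok], d_max)
    }
  } else {
    Dsub <- igraph::distances(net, v = genes, to = genes)
    dd_fixed <- Dsub[ut]
    ok <- is.finite(dd_fixed)
    null_med <- matrix(NA_real_, n_perm, d_max)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(m)
      Pp <- matrix(ph[perm], nrow = m, ncol = m)
      dphi_b <- phase_diff_abs(t(Pp)[ut], Pp[ut])
      null_med[b, ] <- medians_by_distance(dd_fixed[ok], dphi_b[ok], d_max)
    }
  }

  q025 <- apply(null_med, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
                names = FALSE)
  q975 <- apply(null_med, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
                names = FALSE)
  obs_med <- obs$by_distance$median_dphi
  p_two <- rep(NA_real_, d_max)
  for (d in seq_len(d_max)) {
    nn <- null_med[!is.na(null_med[, d]), d]
    if (length(nn) == 0 || is.na(obs_med[d])) next
    r <- (1 + sum(nn <= obs_med[d])) / (length(nn) + 1)
    p_two[d] <- min(2 * min(r, 1 - r), 1)
  }
  by_distance <- cbind(obs$by_distance,
                       null_q025 = q025, null_q975 = q975,
                       p_two_sided = p_two)
  structure(list(by_distance = by_distance, n_perm = n_perm,
                 seed = seed, mode = mode, observed = obs,
                 null_medians = null_med),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation null (%s), %d permutations\n", x$mode, x$n_perm))
  print(x$by_distance, row.names = FALSE)
  invisible(x)
}
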