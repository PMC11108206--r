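# Synthetic two-experiment circadian expression data and phase-assortative
# networks with known ground truth. The generator mirrors the statistical
# structure the detection pipeline assumes: 24-h cosine signals of varying
# amplitude and phase on a log2-TPM baseline with additive Gaussian noise,
# exponentiated to TPM; two sampling schemes emulating a dense every-2-h
# design (V1) and an unbalanced every-2-h + every-6-h design (V2).

# Deterministic child seeds so each stage draws from its own stream while
# a single study-level seed reproduces everything. Kept below 2^31 - 1.
child_seed <- function(seed, ...) {
  codes <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in codes) {
    h <- (h * 48271 + as.double(k)) %% 2147483647
  }
  as.integer(h)
}

code_of <- function(x) {
  sum(utf8ToInt(as.character(x)) * seq_along(utf8ToInt(as.character(x))))
}

#' Describe a circular phase model
#'
#' A unimodal von Mises or a mixture of von Mises components on the
#' 24-hour circle, used to draw true peak phases for simulated cyclers.
#'
#' @param type `"unimodal"` or `"bimodal"`.
#' @param mu Component mean(s) in ZT hours.
#' @param kappa Component concentration(s), `>= 0` (0 = uniform).
#' @param weight Component weights, summing to 1.
#' @return A list of class `"phase_model"`.
#' @export
phase_model <- function(type = c("bimodal", "unimodal"), mu = c(2, 20),
                        kappa = c(3, 3), weight = NULL) {
  type <- match.arg(type)
  if (type == "unimodal") {
    mu <- mu[1]; kappa <- kappa[1]; weight <- 1
  } else {
    if (is.null(weight)) weight <- rep(1 / length(mu), length(mu))
  }
  stopifnot(length(mu) == length(kappa), length(mu) == length(weight),
            all(kappa >= 0), abs(sum(weight) - 1) < 1e-8)
  structure(list(type = type, mu = mu %% 24, kappa = kappa, weight = weight),
            class = "phase_model")
}

draw_phases <- function(n, model) {
  stopifnot(inherits(model, "phase_model"))
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(model$mu), n, replace = TRUE, prob = model$weight)
  out <- numeric(n)
  for (j in seq_along(model$mu)) {
    idx <- comp == j
    out[idx] <- rvonmises(sum(idx), model$mu[j], model$kappa[j])
  }
  out
}

#' Describe a sampling scheme
#'
#' @param zt Numeric vector of Zeitgeber times in hours, each in `[0, 24)`
#'   after modular reduction.
#' @param reps Integer replicate count at each ZT (recycled).
#' @return A data.frame with columns `zt` and `reps`.
#' @export
sampling_scheme <- function(zt, reps = 1) {
  zt <- as.numeric(zt) %% 24
  reps <- as.integer(rep(reps, length.out = length(zt)))
  if (length(zt) == 0) stop("sampling scheme is empty")
  stopifnot(all(reps >= 1))
  data.frame(zt = zt, reps = reps)
}

#' Default V1-style sampling scheme: every 2 h, 2 replicates
#' @return A sampling-scheme data.frame (12 timepoints x 2 replicates).
#' @export
scheme_v1 <- function() sampling_scheme(seq(2, 24, by = 2), reps = 2)

#' Default V2-style sampling scheme: every 2 h, plus a second replicate
#' approximately every 6 h (at ZT 4, 10, 16, 22)
#' @return A sampling-scheme data.frame (16 samples over 12 timepoints).
#' @export
scheme_v2 <- function() {
  zt <- seq(0, 22, by = 2)
  sampling_scheme(zt, reps = 1L + as.integer(zt %in% c(4, 10, 16, 22)))
}

expand_scheme <- function(scheme) rep(scheme$zt, scheme$reps)

#' Configuration for the expression simulator
#'
#' Defines a two-experiment, two-temperature study with known ground
#' truth: which genes cycle in each condition, their true phases and
#' amplitudes, a shared log2-TPM baseline, observation noise, and the
#' per-experiment sampling schemes.
#'
#' @param n_genes Number of genes.
#' @param frac_cycling_18,frac_cycling_25 Fractions of genes truly cycling
#'   at 18C / 25C, in `[0, 1]`.
#' @param frac_shared Fraction of the smaller cycler set shared between
#'   the two conditions, in `[0, 1]`.
#' @param amplitude_range Lower/upper bound of true amplitudes (log2-TPM).
#' @param phase_model_18,phase_model_25 [phase_model()]s for true phases;
#'   defaults are bimodal with peaks near ZT 8.5/22 (18C-like) and
#'   ZT 2/20 (25C-like).
#' @param baseline_log_tpm_mean,baseline_log_tpm_sd Per-gene baseline
#'   (mesor) distribution on the log2-TPM scale.
#' @param noise_sd Observation noise SD, log2-TPM units, `>= 0`.
#' @param sampling_scheme_v1,sampling_scheme_v2 Sampling schemes for the
#'   two experiments (see [sampling_scheme()]).
#' @param seed Integer seed; the same config and seed reproduce the data
#'   bit for bit.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       frac_cycling_18 = 0.04,
                       frac_cycling_25 = 0.06,
                       frac_shared = 0.3,
                       amplitude_range = c(0.5, 2),
                       phase_model_18 = phase_model("bimodal", mu = c(8.5, 22),
                                                    kappa = c(3, 3)),
                       phase_model_25 = phase_model("bimodal", mu = c(2, 20),
                                                    kappa = c(3, 3)),
                       baseline_log_tpm_mean = 5,
                       baseline_log_tpm_sd = 1.5,
                       noise_sd = 0.5,
                       sampling_scheme_v1 = scheme_v1(),
                       sampling_scheme_v2 = scheme_v2(),
                       seed = 1L) {
  stopifnot(n_genes >= 1,
            frac_cycling_18 >= 0, frac_cycling_18 <= 1,
            frac_cycling_25 >= 0, frac_cycling_25 <= 1,
            frac_shared >= 0, frac_shared <= 1,
            length(amplitude_range) == 2,
            amplitude_range[1] > 0,
            amplitude_range[1] <= amplitude_range[2],
            baseline_log_tpm_sd >= 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(inherits(phase_model_18, "phase_model"),
            inherits(phase_model_25, "phase_model"))
  sampling_scheme_v1 <- sampling_scheme(sampling_scheme_v1$zt,
                                        sampling_scheme_v1$reps)
  sampling_scheme_v2 <- sampling_scheme(sampling_scheme_v2$zt,
                                        sampling_scheme_v2$reps)
  structure(list(n_genes = as.integer(n_genes),
                 frac_cycling_18 = frac_cycling_18,
                 frac_cycling_25 = frac_cycling_25,
                 frac_shared = frac_shared,
                 amplitude_range = amplitude_range,
                 phase_model_18 = phase_model_18,
                 phase_model_25 = phase_model_25,
                 baseline_log_tpm_mean = baseline_log_tpm_mean,
                 baseline_log_tpm_sd = baseline_log_tpm_sd,
                 noise_sd = noise_sd,
                 sampling_scheme_v1 = sampling_scheme_v1,
                 sampling_scheme_v2 = sampling_scheme_v2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw the per-gene ground truth of a simulated study
#'
#' Cycling status, true phase and amplitude per condition, and the shared
#' baseline. The truth depends only on the config (and its seed), not on
#' the experiment, so V1 and V2 observe the same underlying genes --
#' exactly the premise of the dual-experiment consensus criterion.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `gene_id`, `baseline`,
#'   `is_cycling_18`, `is_cycling_25`, `phase_18`, `phase_25`, `amp_18`,
#'   `amp_25` (phases/amplitudes are `NA` for non-cyclers).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 101))
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_log_tpm_mean,
                           config$baseline_log_tpm_sd)
  n18 <- round(config$frac_cycling_18 * n)
  n25 <- round(config$frac_cycling_25 * n)
  n_shared <- min(round(config$frac_shared * min(n18, n25)), n18, n25)
  if (n18 + n25 - n_shared > n) stop("cycling fractions exceed gene count")
  pool <- sample.int(n, n18 + n25 - n_shared)
  shared <- pool[seq_len(n_shared)]
  only18 <- pool[seq_len(n18 - n_shared) + n_shared]
  only25 <- pool[seq_len(n25 - n_shared) + n18]
  cyc18 <- sort(c(shared, only18))
  cyc25 <- sort(c(shared, only25))
  is18 <- seq_len(n) %in% cyc18
  is25 <- seq_len(n) %in% cyc25
  draw_amp <- function(m) stats::runif(m, config$amplitude_range[1],
                                       config$amplitude_range[2])
  phase_18 <- rep(NA_real_, n)
  phase_25 <- rep(NA_real_, n)
  amp_18 <- rep(NA_real_, n)
  amp_25 <- rep(NA_real_, n)
  phase_18[is18] <- draw_phases(sum(is18), config$phase_model_18)
  phase_25[is25] <- draw_phases(sum(is25), config$phase_model_25)
  amp_18[is18] <- draw_amp(sum(is18))
  amp_25[is25] <- draw_amp(sum(is25))
  data.frame(gene_id = gene_id, baseline = baseline,
             is_cycling_18 = is18, is_cycling_25 = is25,
             phase_18 = phase_18, phase_25 = phase_25,
             amp_18 = amp_18, amp_25 = amp_25,
             stringsAsFactors = FALSE)
}

#' Simulate one experiment under one condition
#'
#' Per gene and sample, log2-expression is
#' `baseline + A * cos(2*pi*(t - phi)/24) * [cycling] + N(0, noise_sd)`;
#' TPM is `2^x - 1`, floored at 0. Columns follow the experiment's
#' sampling scheme. The same config + seed yields bit-identical output.
#'
#' @param config A [sim_config()].
#' @param experiment `"V1"` or `"V2"` (selects the sampling scheme and the
#'   noise stream).
#' @param condition `"18C"` or `"25C"` (selects which truth columns drive
#'   the signal).
#' @param truth Optional precomputed [simulate_truth()] output; computed
#'   from the config when omitted.
#' @return A list with elements `expr` (an [expression_set()]) and
#'   `truth` (the ground-truth data.frame).
#' @export
simulate_experiment <- function(config, experiment = c("V1", "V2"),
                                condition = c("18C", "25C"), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  experiment <- match.arg(experiment)
  condition <- match.arg(condition)
  if (is.null(truth)) truth <- simulate_truth(config)
  scheme <- if (experiment == "V1") config$sampling_scheme_v1 else
    config$sampling_scheme_v2
  if (nrow(scheme) == 0) stop("empty sampling scheme")
  times <- expand_scheme(scheme)
  rep_idx <- unlist(lapply(scheme$reps, seq_len))
  n <- config$n_genes
  set.seed(child_seed(config$seed, 202, code_of(experiment),
                      code_of(condition)))
  cyc <- if (condition == "18C") truth$is_cycling_18 else truth$is_cycling_25
  phi <- if (condition == "18C") truth$phase_18 else truth$phase_25
  amp <- if (condition == "18C") truth$amp_18 else truth$amp_25
  amp_eff <- ifelse(cyc, amp, 0)
  phi_eff <- ifelse(cyc, phi, 0)
  signal <- outer(amp_eff, times, function(a, t) a) *
    cos(outer(phi_eff, times, function(p, t) 2 * pi * (t - p) / 24))
  x <- truth$baseline + signal +
    matrix(stats::rnorm(n * length(times), 0, config$noise_sd),
           nrow = n)
  tpm <- pmax(2^x - 1, 0)
  sample_id <- sprintf("%s_%s_ZT%02g_r%d", experiment, condition,
                       times, rep_idx)
  colnames(tpm) <- sample_id
  rownames(tpm) <- truth$gene_id
  samples <- data.frame(sample_id = sample_id, experiment = experiment,
                        condition = condition, zt = times,
                        replicate = rep_idx, stringsAsFactors = FALSE)
  list(expr = expression_set(tpm, samples), truth = truth)
}

#' Simulate the full two-experiment, two-condition study
#'
#' @param config A [sim_config()].
#' @return A list with `truth` and `expr`, the latter a named list of four
#'   [expression_set()]s (`V1_18C`, `V1_25C`, `V2_18C`, `V2_25C`).
#' @export
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  combos <- expand.grid(experiment = c("V1", "V2"),
                        condition = c("18C", "25C"),
                        stringsAsFactors = FALSE)
  expr <- list()
  for (i in seq_len(nrow(combos))) {
    ex <- combos$experiment[i]; cond <- combos$condition[i]
    expr[[paste(ex, cond, sep = "_")]] <-
      simulate_experiment(config, ex, cond, truth = truth)$expr
  }
  list(truth = truth, expr = expr)
}

#' Write a simulated study to disk
#'
#' Expression matrices as TSV (genes x samples), one per (experiment,
#' condition); a single CSV sample sheet; the ground truth as CSV.
#'
#' @param study Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sheets <- list()
  for (nm in names(study$expr)) {
    es <- study$expr[[nm]]
    p <- file.path(outdir, paste0("expression_", nm, ".tsv"))
    df <- data.frame(gene_id = rownames(es$values), es$values,
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    sh <- es$samples
    names(sh)[names(sh) == "zt"] <- "zt_hours"
    sheets[[nm]] <- sh
  }
  sheet_path <- file.path(outdir, "samples.csv")
  utils::write.csv(do.call(rbind, sheets), sheet_path, row.names = FALSE)
  truth_path <- file.path(outdir, "ground_truth.csv")
  utils::write.csv(study$truth, truth_path, row.names = FALSE)
  invisible(c(paths, sheet_path, truth_path))
}

#' Configuration for the network simulator
#'
#' @param n_nodes Number of nodes, `>= 2`.
#' @param graph_model `"watts-strogatz"`, `"barabasi-albert"`, or
#'   `"erdos-renyi"`.
#' @param graph_params Named list of model parameters: `nei` and `p` for
#'   Watts-Strogatz (defaults 2, 0.05), `m` for Barabasi-Albert (default
#'   2), `p` for Erdos-Renyi (default chosen to make the graph connected
#'   with high probability).
#' @param assortativity_mode `"assortative"` (cyclers occupy a connected
#'   region, phases drift per hop) or `"random"` (uniform placement,
#'   phases shuffled).
#' @param per_edge_phase_step Expected phase drift per hop in hours,
#'   `>= 0` (assortative mode).
#' @param placement_noise_sd SD of per-node phase noise in hours
#'   (assortative mode).
#' @param seed Integer seed.
#' @return A list of class `"net_sim_config"`.
#' @export
net_sim_config <- function(n_nodes = 500,
                           graph_model = c("watts-strogatz",
                                           "barabasi-albert", "erdos-renyi"),
                           graph_params = list(),
                           assortativity_mode = c("assortative", "random"),
                           per_edge_phase_step = 0.5,
                           placement_noise_sd = 0.5,
                           seed = 1L) {
  graph_model <- match.arg(graph_model)
  assortativity_mode <- match.arg(assortativity_mode)
  stopifnot(n_nodes >= 2, per_edge_phase_step >= 0, placement_noise_sd >= 0)
  structure(list(n_nodes = as.integer(n_nodes), graph_model = graph_model,
                 graph_params = graph_params,
                 assortativity_mode = assortativity_mode,
                 per_edge_phase_step = per_edge_phase_step,
                 placement_noise_sd = placement_noise_sd,
                 seed = as.integer(seed)),
            class = "net_sim_config")
}

build_sim_graph <- function(config) {
  n <- config$n_nodes
  p <- config$graph_params
  g <- switch(config$graph_model,
    "watts-strogatz" = igraph::sample_smallworld(
      dim = 1, size = n,
      nei = if (is.null(p$nei)) 2 else p$nei,
      p = if (is.null(p$p)) 0.05 else p$p),
    "barabasi-albert" = igraph::sample_pa(
      n, m = if (is.null(p$m)) 2 else p$m, directed = FALSE),
    "erdos-renyi" = igraph::sample_gnp(
      n, p = if (is.null(p$p)) min(1, 2 * log(n) / n) else p$p)
  )
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("n%05d", seq_len(igraph::vcount(g)))
  g
}

#' Place cycler phases on a graph by assortative region growth
#'
#' Grows a connected region by breadth-first search from a start node and
#' assigns each placed node the phase
#' `(start_phase + step * depth + noise) mod 24`, where depth is the BFS
#' distance from the start. With zero noise on a path graph seeded at an
#' endpoint, the median absolute phase difference at geodesic distance `d`
#' is exactly `d * step` for `d * step <= 12`.
#'
#' @param graph An igraph (named nodes).
#' @param n_place Number of nodes to place.
#' @param step Phase drift per hop, hours.
#' @param noise_sd Per-node phase noise SD, hours.
#' @param start Optional start node name or index (random when `NULL`).
#' @param start_phase Phase of the start node, hours (default 0).
#' @return Named numeric vector: phase (hours) per placed node.
#' @export
place_phases_assortative <- function(graph, n_place, step, noise_sd,
                                     start = NULL, start_phase = 0) {
  stopifnot(igraph::is_igraph(graph), n_place >= 1,
            n_place <= igraph::vcount(graph), step >= 0, noise_sd >= 0)
  if (is.null(start)) start <- sample.int(igraph::vcount(graph), 1)
  bfs <- igraph::bfs(graph, root = start, unreachable = FALSE,
                     dist = TRUE)
  ord <- bfs$order[!is.na(bfs$order)]
  if (length(ord) < n_place) {
    stop("connected region of requested size unobtainable from start node")
  }
  placed <- ord[seq_len(n_place)]
  depth <- bfs$dist[placed]
  phases <- (start_phase + step * depth +
               stats::rnorm(n_place, 0, noise_sd)) %% 24
  names(phases) <- igraph::V(graph)$name[as.integer(placed)]
  phases
}

#' Simulate a gene network with cycling genes placed on it
#'
#' Builds a random graph, restricts it to its largest connected component,
#' and places `length(cycler_phases)` cycling genes on it. In assortative
#' mode the placement is a connected BFS region whose phases drift by
#' `per_edge_phase_step` per hop (plus noise) from the first supplied
#' phase, so the expected median absolute phase difference grows with
#' geodesic distance. In random mode nodes are drawn uniformly and the
#' supplied phase multiset is shuffled onto them.
#'
#' @param config A [net_sim_config()].
#' @param cycler_phases Numeric vector of phases in hours; its length sets
#'   the number of placed genes.
#' @return A list with `graph` (igraph, the largest connected component)
#'   and `placement` (named numeric vector of phases by node name).
#' @export
simulate_network <- function(config, cycler_phases) {
  stopifnot(inherits(config, "net_sim_config"), is.numeric(cycler_phases),
            length(cycler_phases) >= 1)
  set.seed(child_seed(config$seed, 303))
  g <- build_sim_graph(config)
  g <- largest_connected_component(g)
  m <- length(cycler_phases)
  if (m > igraph::vcount(g)) {
    stop("more cycler phases (", m, ") than nodes in the largest component (",
         igraph::vcount(g), ")")
  }
  placement <- if (config$assortativity_mode == "assortative") {
    place_phases_assortative(g, m, config$per_edge_phase_step,
                             config$placement_noise_sd,
                             start_phase = cycler_phases[1])
  } else {
    nodes <- sample.int(igraph::vcount(g), m)
    ph <- sample(cycler_phases)
    names(ph) <- igraph::V(g)$name[nodes]
    ph
  }
  list(graph = g, placement = placement)
}

#' Write a network as a two-column edge list TSV
#'
#' @param graph An igraph with named nodes.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
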