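# End-to-end orchestration: simulate (or read) -> filter -> detect ->
# phase statistics -> network test, with deterministic per-stage seeds
# and a JSON run manifest.

#' Build a pipeline run configuration
#'
#' Either supply file paths (`expression_paths`, a named list of TSVs per
#' `experiment_condition`, plus `samplesheet_path` and `network_path`) or
#' a [sim_config()] (plus optionally a [net_sim_config()]) to generate
#' the inputs. A YAML file with the same keys can be given as `yaml`.
#'
#' @param sim A [sim_config()] to simulate expression inputs, or `NULL`.
#' @param net_sim A [net_sim_config()] to simulate the network, or `NULL`
#'   (the network stage then requires `network_path` or is skipped).
#' @param expression_paths Named list of TSV paths (`V1_18C`, ...), used
#'   when `sim` is `NULL`.
#' @param samplesheet_path CSV sample sheet path (with `expression_paths`).
#' @param network_path Edge-list TSV path, or `NULL`.
#' @param tpm_threshold Median-TPM expression filter threshold (default 5).
#' @param p_threshold,dphi_threshold Consensus-cycler thresholds
#'   (defaults 0.1 and 3 h).
#' @param d_max,n_perm Network-profile settings (defaults 6 and 5000).
#' @param skip_network Skip the network stage entirely (default `FALSE`).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param outdir Output directory, or `NULL` to write nothing.
#' @param yaml Optional path to a YAML file whose keys override nothing
#'   explicitly passed but fill the rest.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = NULL, net_sim = NULL,
                       expression_paths = NULL, samplesheet_path = NULL,
                       network_path = NULL,
                       tpm_threshold = 5, p_threshold = 0.1,
                       dphi_threshold = 3, d_max = 6, n_perm = 5000,
                       skip_network = FALSE, seed = 1L, outdir = NULL,
                       yaml = NULL) {
  cfg <- list(sim = sim, net_sim = net_sim,
              expression_paths = expression_paths,
              samplesheet_path = samplesheet_path,
              network_path = network_path,
              tpm_threshold = tpm_threshold, p_threshold = p_threshold,
              dphi_threshold = dphi_threshold, d_max = d_max,
              n_perm = n_perm, skip_network = skip_network,
              seed = as.integer(seed), outdir = outdir)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    for (k in names(y)) if (is.null(cfg[[k]])) cfg[[k]] <- y[[k]]
  }
  stopifnot(cfg$tpm_threshold >= 0, cfg$p_threshold > 0,
            cfg$dphi_threshold > 0, cfg$d_max >= 2, cfg$n_perm >= 100)
  if (is.null(cfg$sim) && is.null(cfg$expression_paths)) {
    stop("either sim or expression_paths must be given")
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates or reads the four expression sets, applies the expression
#' filter, fits harmonic regressions per experiment and condition, calls
#' consensus cyclers, computes phase-distribution statistics
#' (Watson-Wheeler between conditions, von Mises mixture peaks, circular
#' correlation and median test of the common cyclers), and -- unless
#' skipped -- runs the network phase-organization analysis per condition.
#' All randomness derives from the config seed, so re-running with the
#' same config reproduces every output exactly. Results are written to
#' `outdir` (CSV tables and a JSON manifest) when it is set.
#'
#' @param config A [run_config()].
#' @return A "bundle": a list with elements `filtered_genes`, `fits`,
#'   `cyclers` (per condition), `phase_stats`, `network` (per condition,
#'   or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  bundle <- list()
  if (!is.null(config$sim)) {
    study <- stage("simulate", simulate_study(config$sim))
    exprs <- study$expr
    bundle$truth <- study$truth
  } else {
    exprs <- stage("ingest", {
      lapply(config$expression_paths, read_expression,
             samplesheet_path = config$samplesheet_path)
    })
  }

  keep <- stage("filter", filter_genes(unname(exprs), config$tpm_threshold))
  if (length(keep) == 0) stop("pipeline stage 'filter' failed: no gene passes")
  exprs <- lapply(exprs, subset_genes, gene_ids = keep)
  bundle$filtered_genes <- keep

  fits <- stage("detect", lapply(exprs, rhythm_fits))
  bundle$fits <- fits

  cyclers <- stage("consensus", list(
    "18C" = consensus_cyclers(fits$V1_18C, fits$V2_18C,
                              config$p_threshold, config$dphi_threshold),
    "25C" = consensus_cyclers(fits$V1_25C, fits$V2_25C,
                              config$p_threshold, config$dphi_threshold)))
  bundle$cyclers <- cyclers

  efp <- expected_false_positives(length(keep), config$p_threshold,
                                  config$dphi_threshold)
  bundle$expected_fp <- efp

  bundle$phase_stats <- stage("phases", {
    ph18 <- cyclers[["18C"]]$consensus_phase
    ph25 <- cyclers[["25C"]]$consensus_phase
    out <- list()
    if (length(ph18) >= 10 && length(ph25) >= 10) {
      ww <- watson_wheeler_test(ph18, ph25)
      out$watson_wheeler <- list(W = unname(ww$statistic),
                                 p_value = ww$p.value)
      set.seed(child_seed(config$seed, 404))
      out$mixture_18 <- unclass(fit_vonmises_mixture(ph18))[
        c("mu", "kappa", "weight")]
      out$mixture_25 <- unclass(fit_vonmises_mixture(ph25))[
        c("mu", "kappa", "weight")]
    }
    common <- intersect(cyclers[["18C"]]$gene_id, cyclers[["25C"]]$gene_id)
    out$n_common <- length(common)
    if (length(common) >= 5) {
      p18 <- cyclers[["18C"]]$consensus_phase[
        match(common, cyclers[["18C"]]$gene_id)]
      p25 <- cyclers[["25C"]]$consensus_phase[
        match(common, cyclers[["25C"]]$gene_id)]
      out$circular_correlation <- circular_correlation(p18, p25)
      shift <- phase_diff_signed(p18, p25)
      mt <- circular_median_test(shift)
      out$phase_advance <- list(
        n_advanced = unname(mt$statistic), n = unname(mt$parameter),
        median_shift = stats::median(shift), p_value = mt$p.value)
    }
    out
  })

  if (!config$skip_network) {
    bundle$network <- stage("network", {
      if (!is.null(config$net_sim)) {
        net <- NULL
        res <- list()
        for (cond in c("18C", "25C")) {
          cyc <- cyclers[[cond]]
          if (nrow(cyc) < 3) next
          ns <- config$net_sim
          sim_net <- simulate_network(ns, cyc$consensus_phase)
          phases <- sim_net$placement
          prof <- phase_distance_profile(sim_net$graph, phases,
                                         d_max = config$d_max)
          pn <- permutation_null(sim_net$graph, phases,
                                 n_perm = config$n_perm,
                                 d_max = config$d_max,
                                 seed = child_seed(config$seed, 505,
                                                   code_of(cond)))
          res[[cond]] <- list(profile = prof, null = pn,
                              graph = sim_net$graph)
        }
        res
      } else {
        if (is.null(config$network_path)) {
          stop("network stage enabled but no network given")
        }
        if (!file.exists(config$network_path)) {
          stop("network file not found: ", config$network_path)
        }
        net <- largest_connected_component(load_network(config$network_path))
        res <- list()
        for (cond in c("18C", "25C")) {
          cyc <- cyclers[[cond]]
          on_net <- cyc$gene_id %in% igraph::V(net)$name
          if (sum(on_net) < 3) next
          phases <- cyc$consensus_phase[on_net]
          names(phases) <- cyc$gene_id[on_net]
          prof <- phase_distance_profile(net, phases, d_max = config$d_max)
          pn <- permutation_null(net, phases, n_perm = config$n_perm,
                                 d_max = config$d_max,
                                 seed = child_seed(config$seed, 505,
                                                   code_of(cond)))
          other <- setdiff(c("18C", "25C"), cond)
          res[[cond]] <- list(
            profile = prof, null = pn,
            degree = degree_comparison(
              net,
              intersect(cyclers[[cond]]$gene_id, igraph::V(net)$name),
              intersect(cyclers[[other]]$gene_id, igraph::V(net)$name)),
            localization = localization_test(
              net, cyc$gene_id[on_net]))
        }
        res
      }
    })
  } else {
    bundle$network <- NULL
  }

  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("rhythmnet")),
    seed = config$seed,
    thresholds = list(tpm = config$tpm_threshold, p = config$p_threshold,
                      dphi = config$dphi_threshold, d_max = config$d_max,
                      n_perm = config$n_perm),
    n_genes_filtered = length(keep),
    n_cyclers_18 = nrow(cyclers[["18C"]]),
    n_cyclers_25 = nrow(cyclers[["25C"]]),
    expected_false_positives = efp)

  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  class(bundle) <- "rhythm_bundle"
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$fits)) {
    utils::write.csv(bundle$fits[[nm]],
                     file.path(outdir, paste0("fits_", nm, ".csv")),
                     row.names = FALSE)
  }
  for (cond in names(bundle$cyclers)) {
    utils::write.csv(bundle$cyclers[[cond]],
                     file.path(outdir, paste0("cyclers_", cond, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(bundle$network)) {
    for (cond in names(bundle$network)) {
      utils::write.csv(bundle$network[[cond]]$null$by_distance,
                       file.path(outdir, paste0("profile_", cond, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Summarize a pipeline bundle
#'
#' Condenses a [run_pipeline()] bundle into a fixed-schema list (and its
#' JSON rendering): gene and cycler counts, expected false positives and
#' FDR per condition, mixture peak locations, circular correlation and
#' phase-advance test of the common cyclers, and per-condition profile
#' slope with per-distance significance flags.
#'
#' @param bundle Output of [run_pipeline()].
#' @return A list of class `"rhythm_summary"` with elements
#'   `n_genes_filtered`, `n_cyclers_18`, `n_cyclers_25`, `n_common`,
#'   `expected_fp`, `fdr_18`, `fdr_25`, `phase_stats`, `network`.
#' @export
report_summary <- function(bundle) {
  stopifnot(inherits(bundle, "rhythm_bundle"))
  need <- c("filtered_genes", "cyclers", "expected_fp", "phase_stats")
  if (!all(need %in% names(bundle))) {
    stop("incomplete bundle: missing ",
         paste(setdiff(need, names(bundle)), collapse = ", "))
  }
  n18 <- nrow(bundle$cyclers[["18C"]])
  n25 <- nrow(bundle$cyclers[["25C"]])
  out <- list(
    n_genes_filtered = length(bundle$filtered_genes),
    n_cyclers_18 = n18,
    n_cyclers_25 = n25,
    n_common = bundle$phase_stats$n_common,
    expected_fp = bundle$expected_fp,
    fdr_18 = if (n18 > 0) fdr_estimate(bundle$expected_fp, n18) else NA,
    fdr_25 = if (n25 > 0) fdr_estimate(bundle$expected_fp, n25) else NA,
    phase_stats = bundle$phase_stats,
    network = if (is.null(bundle$network)) NULL else {
      lapply(bundle$network, function(x) {
        list(slope = x$profile$slope, slope_p = x$profile$slope_p,
             df = x$profile$df,
             significant_distances =
               x$null$by_distance$distance[
                 !is.na(x$null$by_distance$p_two_sided) &
                   x$null$by_distance$p_two_sided < 0.05])
      })
    })
  class(out) <- "rhythm_summary"
  out
}

#' @export
print.rhythm_summary <- function(x, ...) {
  cat("rhythm detection summary\n")
  cat(sprintf("  genes after expression filter: %d\n", x$n_genes_filtered))
  cat(sprintf("  consensus cyclers: %d (18C), %d (25C), %d common\n",
              x$n_cyclers_18, x$n_cyclers_25, x$n_common))
  cat(sprintf("  expected false positives: %.2f (FDR %.1f%% / %.1f%%)\n",
              x$expected_fp, 100 * x$fdr_18, 100 * x$fdr_25))
  if (!is.null(x$network)) {
    for (cond in names(x$network)) {
      nw <- x$network[[cond]]
      cat(sprintf("  %s profile slope: %.3f h/step (p = %.3g, df = %s)\n",
                  cond, nw$slope, nw$slope_p, nw$df))
    }
  }
  invisible(x)
}

#' Render a summary as JSON
#' @param x A `rhythm_summary`.
#' @return A JSON string.
#' @export
summary_json <- function(x) {
  stopifnot(inherits(x, "rhythm_summary"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, null = "null")
}
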