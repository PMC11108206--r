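# Network loading, components, control tests, the phase-distance
# profile, and its permutation null.

test_that("edge lists are deduplicated and self-loops dropped", {
  dir <- withr::local_tempdir()
  writeLines(c("A\tB", "B\tA", "A\tA"), file.path(dir, "net.tsv"))
  g <- suppressMessages(load_network(file.path(dir, "net.tsv")))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  writeLines(c("A\tB", "B\tC"), file.path(dir, "path.tsv"))
  p <- load_network(file.path(dir, "path.tsv"))
  expect_equal(igraph::vcount(p), 3)
  expect_equal(igraph::ecount(p), 2)

  writeLines(c("A\tB", "", "B\tC"), file.path(dir, "blank.tsv"))
  expect_error(load_network(file.path(dir, "blank.tsv")), "line 2")
  writeLines(character(0), file.path(dir, "empty.tsv"))
  expect_error(load_network(file.path(dir, "empty.tsv")), "empty")
})

test_that("largest connected component picks the biggest piece", {
  g <- igraph::graph_from_literal(a - b - c - d - e, x - y - z)
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c", "d", "e"))
  # a connected graph maps to itself
  conn <- path_graph(10)
  expect_equal(igraph::vcount(largest_connected_component(conn)), 10)
  # simulated networks are delivered as one component
  for (s in 1:5) {
    sim <- simulate_network(net_sim_config(n_nodes = 80, seed = 50 + s),
                            c(0, 6, 12))
    expect_equal(igraph::components(sim$graph)$no, 1)
  }
})

test_that("BFS geodesic distances match a Floyd-Warshall oracle", {
  set.seed(51)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    g <- igraph::sample_gnp(n, p = 2.5 / n)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    expect_equal(igraph::distances(g), floyd_warshall(g))
  }
})

test_that("degree comparison flags degree-biased cycler sets only", {
  set.seed(52)
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%04d", 1:1000)
  deg <- igraph::degree(g)
  all_nodes <- igraph::V(g)$name

  res_same <- degree_comparison(g, all_nodes, all_nodes)
  expect_equal(res_same$D[res_same$comparison == "18C vs all"], 0)

  top <- all_nodes[order(deg, decreasing = TRUE)][1:100]
  unif <- sample(all_nodes, 100)
  res <- degree_comparison(g, top, unif)
  expect_lt(res$p_value[res$comparison == "18C vs all"], 0.01)
  expect_error(degree_comparison(g, character(0), unif), "empty")
  expect_error(degree_comparison(g, "nope", unif), "not on the network")
})

test_that("localization test detects a clique and handles the minimal case", {
  set.seed(53)
  g <- igraph::sample_gnp(300, 0.01)
  igraph::V(g)$name <- sprintf("v%03d", 1:300)
  g <- largest_connected_component(g)
  clique_nodes <- igraph::V(g)$name[1:12]
  g2 <- igraph::add_edges(g, as.vector(t(t(utils::combn(clique_nodes, 2)))))
  g2 <- igraph::simplify(g2)
  res <- localization_test(g2, clique_nodes)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$median_cyclers, 1)

  # two adjacent cyclers: the distance list is exactly {1}
  pg <- path_graph(5)
  res2 <- localization_test(pg, c("p001", "p002"))
  expect_equal(res2$n_pairs_cyclers, 1)
  expect_equal(res2$median_cyclers, 1)
})

test_that("the phase-distance profile matches its construction on a path", {
  g <- path_graph(7)
  ph <- c(0, 1, 2, 3, 4, 5)
  names(ph) <- igraph::V(g)$name[1:6]
  prof <- phase_distance_profile(g, ph, d_max = 5)
  expect_equal(prof$by_distance$median_dphi, as.numeric(1:5))
  expect_equal(prof$by_distance$n_pairs, c(5L, 4L, 3L, 2L, 1L))
  expect_equal(prof$slope, 1, tolerance = 1e-12)
  expect_equal(prof$df, 3)
  # residuals are exactly zero, so the slope p-value is ~0
  expect_lt(prof$slope_p, 1e-10)

  flat <- rep(7.5, 6)
  names(flat) <- names(ph)
  prof0 <- phase_distance_profile(g, flat, d_max = 5)
  expect_equal(prof0$by_distance$median_dphi, rep(0, 5))
  expect_equal(prof0$slope, 0)
})

test_that("profile is invariant to relabeling and global phase shifts", {
  set.seed(54)
  sim <- simulate_network(net_sim_config(n_nodes = 150, seed = 55,
                                         per_edge_phase_step = 0.6),
                          runif(40, 0, 24))
  ph <- sim$placement
  prof <- phase_distance_profile(sim$graph, ph, d_max = 5)
  shifted <- phase_distance_profile(sim$graph, (ph + 9.25) %% 24, d_max = 5)
  expect_equal(prof$by_distance$median_dphi,
               shifted$by_distance$median_dphi, tolerance = 1e-9)
  perm <- sample(length(ph))
  reordered <- phase_distance_profile(sim$graph, ph[perm], d_max = 5)
  expect_equal(prof$by_distance, reordered$by_distance, tolerance = 1e-12)
})

test_that("pair counts are bounded by the number of mapped-gene pairs", {
  set.seed(56)
  sim <- simulate_network(net_sim_config(n_nodes = 100, seed = 57),
                          runif(20, 0, 24))
  prof <- phase_distance_profile(sim$graph, sim$placement, d_max = 4)
  expect_lte(sum(prof$by_distance$n_pairs), choose(20, 2))
  wide <- phase_distance_profile(sim$graph, sim$placement, d_max = 50)
  # on one connected component every pair is within a large d_max
  expect_equal(sum(wide$by_distance$n_pairs), choose(20, 2))
})

test_that("permutation null is deterministic and detects assortativity", {
  # sparse small-world graph so the assortative region spans many depths
  cfg <- net_sim_config(n_nodes = 300, graph_params = list(nei = 1, p = 0.02),
                        per_edge_phase_step = 1,
                        placement_noise_sd = 0.25, seed = 58)
  sim <- simulate_network(cfg, c(0, runif(49, 0, 24)))
  a <- permutation_null(sim$graph, sim$placement, n_perm = 300, d_max = 5,
                        seed = 59)
  b <- permutation_null(sim$graph, sim$placement, n_perm = 300, d_max = 5,
                        seed = 59)
  expect_identical(a$by_distance, b$by_distance)
  expect_identical(a$null_medians, b$null_medians)
  # neighbours are more synchronized than any random placement
  expect_lt(a$by_distance$median_dphi[1], a$by_distance$null_q025[1])
  expect_true(all(a$by_distance$null_q025 <= a$by_distance$null_q975,
                  na.rm = TRUE))
  expect_true(all(a$by_distance$p_two_sided > 0, na.rm = TRUE))

  expect_error(permutation_null(sim$graph, sim$placement, n_perm = 50),
               "unstable")
})

test_that("phase-shuffling null mode runs and keeps positions fixed", {
  set.seed(60)
  sim <- simulate_network(net_sim_config(n_nodes = 120, seed = 61),
                          runif(25, 0, 24))
  pn <- permutation_null(sim$graph, sim$placement, n_perm = 150, d_max = 4,
                         seed = 62, mode = "shuffle_phases")
  expect_equal(pn$mode, "shuffle_phases")
  expect_equal(pn$by_distance$n_pairs,
               phase_distance_profile(sim$graph, sim$placement,
                                      d_max = 4)$by_distance$n_pairs)
})
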