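make_cm <- function(C) {
  n <- nrow(C)
  structure(
    list(C = C, n_synchr = matrix(0L, n, n, dimnames = dimnames(C)),
         n_post = rep(1L, n), delay = matrix(0, n, n), delta_ms = 2,
         velocity = 300,
         undefined = matrix(FALSE, n, n, dimnames = dimnames(C))),
    class = "connectivity_matrix")
}

test_that("pairwise delays follow distance / velocity", {
  geo <- mea_geometry()
  tau <- pairwise_delays(geo, velocity = 200)
  expect_true(all(diag(tau) == 0))
  # neighbours at one 200-um pitch, 200 um/ms -> 1 ms
  d <- electrode_distances(geo)
  nb <- which(abs(d - 200) < 1e-9, arr.ind = TRUE)[1, ]
  expect_equal(tau[nb[1], nb[2]], 1)
  expect_equal(tau, t(tau))
  expect_error(pairwise_delays(geo, velocity = 0), "velocity")
})

test_that("delayed synchrony handles degenerate channels and perfect shifts", {
  geo <- geo4()
  ids <- geo$electrode_ids
  # channel ids[2] empty: C[., 2] = 0 and flagged undefined
  r <- make_raster(rep(ids[1], 5), seq(0.1, 0.5, by = 0.1), duration = 1,
                   geometry = geo)
  cm <- delayed_synchrony(r)
  expect_true(all(cm$C[, as.character(ids[2])] == 0))
  expect_true(all(cm$undefined[-2, 2]))
  # target = source shifted by exactly tau -> C = 1
  tau <- pairwise_delays(geo, 300)[1, 2] / 1000
  r2 <- make_raster(c(rep(ids[1], 5), rep(ids[2], 5)),
                    c(seq(0.1, 0.5, by = 0.1),
                      seq(0.1, 0.5, by = 0.1) + tau),
                    duration = 1, geometry = geo)
  cm2 <- delayed_synchrony(r2)
  expect_equal(cm2$C[as.character(ids[1]), as.character(ids[2])], 1)
})

test_that("delayed synchrony equals the brute-force pair-scan oracle", {
  geo <- geo6()
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(200:600, 1)
    r <- make_raster(sample(geo$electrode_ids, n, replace = TRUE),
                     runif(n, 0, 30), duration = 30, geometry = geo)
    cm <- delayed_synchrony(r, velocity = 300, delta_ms = 2)
    oracle <- brute_force_synchrony(r, velocity = 300, delta_ms = 2)
    expect_identical(unname(cm$n_synchr), unname(oracle))
    # bounds: 0 <= C <= 1 and n_synchr <= n_j
    expect_true(all(cm$C >= 0 & cm$C <= 1))
    expect_true(all(t(cm$n_synchr) <= cm$n_post))
  }
})

test_that("top-fraction edge selection retains exactly floor(0.05 * P) edges", {
  ids <- mea_geometry()$electrode_ids
  set.seed(23)
  C <- matrix(runif(59 * 59, 0.01, 1), 59, 59, dimnames = list(ids, ids))
  diag(C) <- 0
  g <- significant_edges(make_cm(C), fraction = 0.05)
  expect_equal(igraph::ecount(g), floor(0.05 * 59 * 58)) # 171
  expect_equal(igraph::vcount(g), 59)
  # deterministic across repeated selection
  g2 <- significant_edges(make_cm(C), fraction = 0.05)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # retained edges carry the largest coefficients
  expect_gte(min(igraph::E(g)$weight), sort(C[C > 0], decreasing = TRUE)[171])
})

test_that("degenerate selections give empty graphs", {
  ids <- geo4()$electrode_ids
  Z <- matrix(0, 4, 4, dimnames = list(ids, ids))
  expect_equal(igraph::ecount(significant_edges(make_cm(Z))), 0)
  C <- matrix(runif(16), 4, 4, dimnames = list(ids, ids)); diag(C) <- 0
  # fraction small enough that floor(f * P) = 0
  expect_equal(igraph::ecount(significant_edges(make_cm(C),
                                                fraction = 0.05)), 0)
})

test_that("hubs and hub coefficients follow the degree/edge-count definitions", {
  star <- igraph::graph_from_data_frame(
    data.frame(from = "50", to = as.character(c(11:19, 21, 22, 23))),
    directed = TRUE,
    vertices = data.frame(name = as.character(c(50, 11:19, 21:23, 99))))
  hs <- find_hubs(star, min_degree = 10)
  expect_equal(hs$n_hubs, 1L)
  expect_equal(hs$hubs$electrode, 50L)
  expect_equal(hs$hubs$connections, 12L)
  expect_equal(hs$mean_connections, 12)
  # star centre holds every connection -> hub coefficient 1
  expect_equal(hub_coefficient(star, 50), 1)
  expect_equal(hub_coefficient(star, 99), 0) # isolated vertex
  expect_equal(find_hubs(igraph::make_empty_graph() , 10)$n_hubs, 0L)
  empty <- igraph::graph_from_data_frame(
    data.frame(from = character(0), to = character(0)),
    vertices = data.frame(name = c("1", "2")))
  expect_error(hub_coefficient(empty, 1), "no edges")
})

test_that("network overlap is 100% on identical and 0% on disjoint graphs", {
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = c("1", "2", "3"), to = c("2", "3", "4")),
    vertices = data.frame(name = as.character(1:4)))
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("4", "3"), to = c("1", "1")),
    vertices = data.frame(name = as.character(1:4)))
  expect_equal(network_overlap(g1, g1), 100)
  expect_equal(network_overlap(g1, g2), 0)
  empty <- igraph::graph_from_data_frame(
    data.frame(from = character(0), to = character(0)),
    vertices = data.frame(name = as.character(1:4)))
  expect_error(network_overlap(empty, g1), "no edges")
  expect_error(network_overlap(g1, igraph::make_ring(3)), "vertex set")
})

test_that("stable planted connectivity keeps overlap high; shuffled is near chance", {
  base_cfg <- function(seed) {
    raster_sim_config(duration = 200, background_rate = 1,
                      hub_ids = c(21, 44, 67, 82, 35), hub_out_degree = 20,
                      propagation_probability = 0.6, jitter_sd = 0.1,
                      seed = seed)
  }
  # two sessions, identical planted wiring (same seed controls edge draw,
  # different noise would need a split seed; re-simulating with the same
  # seed gives the stable-network case)
  g_a <- significant_edges(delayed_synchrony(
    simulate_raster(base_cfg(31))$raster))
  g_b <- significant_edges(delayed_synchrony(
    simulate_raster(base_cfg(31))$raster))
  expect_gt(network_overlap(g_a, g_b), 90)
  # independently wired sessions: overlap near the chance level (~5%)
  g_c <- significant_edges(delayed_synchrony(
    simulate_raster(base_cfg(77))$raster))
  expect_lt(network_overlap(g_a, g_c), 25)
})

test_that("planted hubs are recovered with precision and recall >= 0.9", {
  prec <- c(); rec <- c()
  for (s in 1:10) {
    cfg <- raster_sim_config(duration = 300, background_rate = 1,
                             hub_ids = c(21, 44, 67, 82, 35),
                             hub_out_degree = 20,
                             propagation_probability = 0.6,
                             jitter_sd = 0.1, seed = s)
    sim <- simulate_raster(cfg)
    g <- significant_edges(delayed_synchrony(sim$raster))
    found <- find_hubs(g, min_degree = 15)$hubs$electrode
    tp <- length(intersect(found, cfg$hub_ids))
    prec <- c(prec, tp / max(1, length(found)))
    rec <- c(rec, tp / length(cfg$hub_ids))
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})
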