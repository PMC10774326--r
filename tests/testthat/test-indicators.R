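# Indicator derivation: Haversine, node matching, descriptive statistics,
# node averaging, tidal range, proximities, circular angle statistics, MADm,
# and the NaN rules.

test_that("haversine distance matches closed forms and is symmetric", {
  expect_equal(haversine_km(0, 0, 0, 0), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 1e-5)
  set.seed(1)
  a <- cbind(runif(1000, -180, 180), runif(1000, -89, 89))
  b <- cbind(runif(1000, -180, 180), runif(1000, -89, 89))
  expect_equal(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_km(b[, 1], b[, 2], a[, 1], a[, 2]))
  # independent implementation as oracle
  expect_equal(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]),
               geosphere::distHaversine(a, b, r = 6371000) / 1000,
               tolerance = 1e-9)
})

test_that("node matching applies the k-nearest rule with the 100 km cap", {
  kmdeg <- 2 * pi * 6371 / 360
  nodes <- data.frame(node_id = c("n1", "n2", "n3"),
                      lon = c(10, 50, 150) / kmdeg, lat = 0)
  m <- match_nodes(c(0, 0), nodes, k = 3, max_km = 100)
  expect_equal(nodes$node_id[m], c("n1", "n2"))
  far <- data.frame(node_id = "f", lon = 150 / kmdeg, lat = 0)
  expect_length(match_nodes(c(0, 0), far, k = 2), 0)
  # equidistant tie broken by ascending node id
  tie <- data.frame(node_id = c("b", "a"), lon = c(0.5, -0.5), lat = c(0, 0))
  m <- match_nodes(c(0, 0), tie, k = 1)
  expect_equal(tie$node_id[m], "a")
})

test_that("series statistics follow the documented conventions", {
  expect_equal(series_stats(1:100, "median"), 50.5)
  expect_equal(series_stats(1:100, "p95"), 95.05)  # linear interpolation
  expect_equal(series_stats(rep(3.3, 50), "std"), 0)
  expect_true(is.nan(series_stats(c(NA_real_, NaN), "median")))
  set.seed(2)
  x <- rnorm(1e5)
  expect_lt(abs(series_stats(x, "p95") - qnorm(0.95)), 0.02)
  # std uses the n-1 divisor
  y <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(series_stats(y, "std"), sd(y))
})

test_that("per-node statistics are averaged over matched nodes", {
  # two nodes straddling the CLC, constant series 1 and 3 -> indicator 2
  cfg <- synth_config(
    seed = 1, coastline = straight_coastline(300), n_timesteps = 10,
    env_fields = list(env_field_spec("hs", list(type = "constant", value = 1),
                                     noise_sd = 0)))
  nodes <- generate_env_timeseries(cfg)
  nd <- nodes$classes$era5_wave
  nd$series$hs[2, ] <- 3
  nodes$classes$era5_wave <- nd
  clc <- c(mean(nd$nodes$lon[1:2]), mean(nd$nodes$lat[1:2]))
  tr <- make_transects(clc[1], clc[2])
  idx <- planar_hex_indexer(26, lon0 = clc[1], lat0 = clc[2])
  g <- build_grid(tr, idx, grid_config(min_transects = 1))
  tab <- derive_node_indicators(g, nodes, match_rule(k = c(era5_wave = 2,
    era5_atmos = 2, gtsm = 3, oras5 = 2)))
  expect_equal(tab$H_s_med, 2)
})

test_that("a NaN-only node is excluded from the node average", {
  cfg <- synth_config(
    seed = 1, coastline = straight_coastline(300), n_timesteps = 10,
    env_fields = list(env_field_spec("hs", list(type = "constant", value = 1),
                                     noise_sd = 0)))
  nodes <- generate_env_timeseries(cfg)
  nodes$classes$era5_wave$series$hs[2, ] <- NaN
  nd <- nodes$classes$era5_wave$nodes
  clc <- c(mean(nd$lon[1:2]), mean(nd$lat[1:2]))
  tr <- make_transects(clc[1], clc[2])
  idx <- planar_hex_indexer(26, lon0 = clc[1], lat0 = clc[2])
  g <- build_grid(tr, idx, grid_config(min_transects = 1))
  tab <- derive_node_indicators(g, nodes, match_rule(k = c(era5_wave = 2,
    era5_atmos = 2, gtsm = 3, oras5 = 2)))
  expect_equal(tab$H_s_med, 1)
})

test_that("tidal range of a pure sinusoid is twice the amplitude", {
  t <- seq(0, 24.8333 * 10, by = 0.5)
  x <- 1 * sin(2 * pi * t / 12.4206)
  expect_lt(abs(tidal_range(x, dt_hours = 0.5, cycle_hours = 24 + 50 / 60) - 2),
            0.01)
  expect_true(is.nan(tidal_range(x[1:10], dt_hours = 0.5)))  # no full window
})

test_that("current proximity uses an inclusive threshold and NaN for no qualifier", {
  kmdeg <- 2 * pi * 6371 / 360
  nodes <- data.frame(node_id = c("a", "b", "c"),
                      lon = c(0, 40, 90) / kmdeg, lat = 0)
  med <- c(0.1, 0.5, 0.6)
  expect_equal(current_proximity(c(0, 0), nodes, med), 40, tolerance = 1e-6)
  expect_equal(current_proximity(c(0, 0), nodes, c(0.3, 0.1, 0.1)), 0)
  # exactly at the threshold qualifies
  expect_equal(current_proximity(c(0, 0), nodes, c(0.1, 0.3, 0.1)), 40,
               tolerance = 1e-6)
  expect_true(is.nan(current_proximity(c(0, 0), nodes, c(0.1, 0.1, 0.1))))
})

test_that("habitat distance handles containment, proximity, and empty sets", {
  expect_true(is.nan(habitat_distance(c(0, 0), list())))
  patch <- cbind(lon = c(-1, 1, 1, -1), lat = c(-1, -1, 1, 1))
  expect_equal(habitat_distance(c(0, 0), list(patch)), 0)
  kmdeg <- 2 * pi * 6371 / 360
  # square patch whose west edge is ~100 km east of the CLC
  sq <- cbind(lon = c(0.9, 1.1, 1.1, 0.9), lat = c(-0.1, -0.1, 0.1, 0.1))
  got <- habitat_distance(c(0, 0), list(sq))
  # dense-sampling oracle along the west edge at ~10 m resolution
  dense_lat <- seq(-0.1, 0.1, length.out = 2500)
  oracle <- min(haversine_km(0, 0, rep(0.9, 2500), dense_lat))
  expect_lt(abs(got - oracle), 1)
  near <- cbind(lon = c(0.18, 0.3, 0.3, 0.18), lat = c(-0.05, -0.05, 0.05, 0.05))
  farp <- cbind(lon = c(0.63, 0.8, 0.8, 0.63), lat = c(-0.05, -0.05, 0.05, 0.05))
  expect_equal(habitat_distance(c(0, 0), list(near, farp)),
               habitat_distance(c(0, 0), list(near)))
})

test_that("shoreline angle dispersion uses circular statistics", {
  expect_equal(circular_sd_deg(rep(45, 10)), 0)
  expect_equal(circular_sd_deg(c(359, 1)), 1, tolerance = 1e-3)
  tr <- make_transects(c(0, 0.01), c(0, 0), angle = c(359, 1))
  v <- derive_geophysical(tr)
  expect_equal(unname(v["phi_std"]), 1, tolerance = 1e-3)
  expect_equal(unname(derive_geophysical(
    make_transects(c(0, 0.01), c(0, 0), angle = c(0, 100)),
    indicator_config(circular_angles = FALSE))["phi_std"]),
    sd(c(0, 100)))
  tr2 <- make_transects(c(0, 0.01), c(0, 0))
  tr2$p_built <- c(0, 100)
  expect_equal(unname(derive_geophysical(tr2)["p_built"]), 50)
})

test_that("MADm matches hand computations and is scale invariant", {
  expect_equal(compute_madm(rep(7, 9)), 0)
  expect_equal(compute_madm(c(1, 2, 3)), 0.5)
  expect_warning(out <- compute_madm(c(-1, 0, 1)), "zero")
  expect_true(is.nan(out))
  set.seed(3)
  x <- rlnorm(100)
  expect_equal(compute_madm(x), compute_madm(17.3 * x), tolerance = 1e-12)
})

test_that("p95 >= median and NaN propagation hold on a synthetic world", {
  w <- demo_world()
  tab <- w$indicators
  for (pair in list(c("H_s_med", "H_s_p95"), c("T_p_med", "T_p_p95"),
                    c("h_S_med", "h_S_p95"), c("U10_med", "U10_p95"))) {
    both <- is.finite(tab[[pair[1]]]) & is.finite(tab[[pair[2]]])
    expect_true(all(tab[[pair[2]]][both] >= tab[[pair[1]]][both] - 1e-12))
  }
  expect_false(any(is.na(tab[, indicator_names()])))
})

test_that("scaling all node series scales the derived statistics linearly", {
  cfg <- tiny_config(seed = 15)
  tr <- generate_coastline(cfg)
  idx <- planar_hex_indexer(26, lon0 = mean(tr$lon), lat0 = mean(tr$lat))
  g <- build_grid(tr, idx, grid_config())
  nodes <- generate_env_timeseries(cfg)
  t1 <- derive_node_indicators(g, nodes)
  scaled <- nodes
  for (cls in names(scaled$classes)) {
    for (v in names(scaled$classes[[cls]]$series)) {
      scaled$classes[[cls]]$series[[v]] <- 3 * scaled$classes[[cls]]$series[[v]]
    }
  }
  t3 <- derive_node_indicators(g, scaled)
  for (col in c("H_s_med", "H_s_p95", "T_p_std", "h_tide", "u_c_med",
                "SST_med")) {
    expect_equal(t3[[col]], 3 * t1[[col]], tolerance = 1e-9)
  }
})

test_that("a Coastgon with no matched nodes gets NaN for that class only", {
  cfg <- synth_config(seed = 6, coastline = straight_coastline(300),
                      n_timesteps = 60,
                      node_spacing_km = c(era5_wave = 60, era5_atmos = 60,
                                          gtsm = 60, oras5 = 60))
  tr <- generate_coastline(cfg)
  idx <- planar_hex_indexer(26, lon0 = mean(tr$lon), lat0 = mean(tr$lat))
  g <- build_grid(tr, idx, grid_config())
  nodes <- generate_env_timeseries(cfg)
  # push the wave nodes far away: no era5_wave match for any cell
  nodes$classes$era5_wave$nodes$lat <- nodes$classes$era5_wave$nodes$lat + 2
  tab <- derive_node_indicators(g, nodes)
  expect_true(all(is.nan(tab$H_s_med)))
  expect_true(all(is.nan(tab$T_p_p95)))
  expect_true(all(is.finite(tab$SST_med)))
  expect_true(all(is.finite(tab$h_tide)))
})
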