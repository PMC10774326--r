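# Shared fixtures. The acceptance-scale demo world (~390 Coastgons) is
# expensive (~10 s), so it is built once per test run and memoized.

.world_cache <- new.env(parent = emptyenv())

demo_world <- function() {
  if (is.null(.world_cache$w)) {
    .world_cache$w <- synthesize_world(synth_config(seed = 1))
  }
  .world_cache$w
}

straight_coastline <- function(length_km = 100, lat = 0, lon0 = 0) {
  dlon <- length_km / (2 * pi * 6371 / 360 * cos(lat * pi / 180))
  cbind(lon = c(lon0, lon0 + dlon), lat = c(lat, lat))
}

# circular arc of given radius spanning `span_deg` of arc, centered on the
# equator so the small-circle is close to a great circle locally
arc_coastline <- function(radius_km = 500, span_deg = 90, n = 40) {
  ang <- seq(0, span_deg, length.out = n) * pi / 180
  kmdeg <- 2 * pi * 6371 / 360
  cbind(lon = radius_km * cos(ang) / kmdeg,
        lat = radius_km * sin(ang) / kmdeg)
}

# a small, fast synthetic configuration (~800 km of coast, ~30 cells)
tiny_config <- function(seed = 7, ...) {
  synth_config(
    seed = seed,
    coastline = default_coastline(length_km = 800, lat_base = 2,
                                  amp_deg = 1.5, cycles = 1),
    n_timesteps = 120,
    node_spacing_km = c(era5_wave = 60, era5_atmos = 55, gtsm = 40,
                        oras5 = 55),
    ...
  )
}

# transect data frame at explicit positions with constant attributes
make_transects <- function(lon, lat, angle = 90) {
  n <- length(lon)
  data.frame(id = seq_len(n), lon = lon, lat = lat,
             shoreline_angle = rep_len(angle, n),
             beta_ns = rep_len(0.02, n), beta_bs = rep_len(0.08, n),
             z_max = rep_len(10, n), p_built = rep_len(10, n))
}

# a minimal grid-like object for functions that only need cells + indexer
fake_grid <- function(cells, indexer = planar_hex_indexer(26),
                      config = grid_config()) {
  structure(list(cells = cells, links = NULL, dropped = character(0),
                 indexer = indexer, config = config),
            class = "coastgon_grid")
}
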