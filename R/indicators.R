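# Regional coastal indicators
#
# Derives the 22 indicators per Coastgon: hydrodynamic and atmospheric
# statistics from node time series (k-nearest-node matching within 100 km,
# per-node statistic then node averaging), geophysical statistics from the
# linked transects, habitat proximities from polygons, and the built
# environment fraction. Missing matches yield NaN.

#' The 22 indicator names
#'
#' ASCII transliteration of the standard symbols: `H_s_med`/`H_s_p95`
#' (significant wave height, m), `T_p_med`/`T_p_p95`/`T_p_std` (peak wave
#' period, s), `h_S_med`/`h_S_p95` (surge level, m), `h_tide` (mean tidal
#' range, m), `u_c_med` (ocean current velocity, m/s), `D_c_03` (distance to
#' nearest current >= 0.3 m/s, km), `U10_med`/`U10_p95` (10-m wind speed,
#' m/s), `SST_med` (sea surface temperature, degC), `P_med` (total
#' precipitation, mm/y), `phi_std` (shoreline angle spread, deg),
#' `beta_ns_med`/`beta_bs_med` (nearshore/backshore slope), `z_max_med`/
#' `z_max_std` (max coastal elevation, m+msl), `D_cor`/`D_sgr` (coral /
#' seagrass habitat proximity, km), `p_built` (built environment, %).
#'
#' @return Character vector of the 22 indicator column names.
#' @export
indicator_names <- function() INDICATOR_NAMES

INDICATOR_NAMES <- c(
  "H_s_med", "H_s_p95", "T_p_med", "T_p_p95", "T_p_std",
  "h_S_med", "h_S_p95", "h_tide", "u_c_med", "D_c_03",
  "U10_med", "U10_p95", "SST_med", "P_med",
  "phi_std", "beta_ns_med", "beta_bs_med", "z_max_med", "z_max_std",
  "D_cor", "D_sgr", "p_built"
)

# (variable, statistic) -> indicator column, for the time-series indicators
NODE_INDICATORS <- list(
  list(ind = "H_s_med", var = "hs", stat = "median"),
  list(ind = "H_s_p95", var = "hs", stat = "p95"),
  list(ind = "T_p_med", var = "tp", stat = "median"),
  list(ind = "T_p_p95", var = "tp", stat = "p95"),
  list(ind = "T_p_std", var = "tp", stat = "std"),
  list(ind = "h_S_med", var = "surge", stat = "median"),
  list(ind = "h_S_p95", var = "surge", stat = "p95"),
  list(ind = "h_tide", var = "tide", stat = "tidal_range"),
  list(ind = "u_c_med", var = "current", stat = "median"),
  list(ind = "U10_med", var = "u10", stat = "median"),
  list(ind = "U10_p95", var = "u10", stat = "p95"),
  list(ind = "SST_med", var = "sst", stat = "median"),
  list(ind = "P_med", var = "precip", stat = "median")
)

#' Node-matching rule per dataset class
#'
#' The `k` nearest nodes to each coastline centroid are used, up to a
#' maximum distance of 100 km: k = 1 for wave nodes, 2 for atmospheric and
#' ocean-reanalysis nodes, 3 for surge/tide nodes.
#'
#' @param k Named integer vector per dataset class.
#' @param max_km Maximum matching distance, km (inclusive).
#' @return A `match_rule` list.
#' @export
match_rule <- function(k = c(era5_wave = 1, era5_atmos = 2, gtsm = 3,
                             oras5 = 2),
                       max_km = 100) {
  stopifnot(all(k >= 1), max_km > 0)
  structure(list(k = k, max_km = max_km), class = "match_rule")
}

#' Match the nearest nodes to a coastline centroid
#'
#' Returns the indices of the `<= k` nearest nodes within `max_km`
#' (Haversine), sorted by distance, ties broken by ascending node id.
#'
#' @param clc Numeric `c(lon, lat)`.
#' @param nodes Data frame with `node_id`, `lon`, `lat`.
#' @param k Number of nodes to use.
#' @param max_km Maximum distance, km (inclusive).
#' @return Integer vector of row indices into `nodes` (possibly empty).
#' @export
match_nodes <- function(clc, nodes, k, max_km = 100) {
  if (nrow(nodes) == 0) return(integer(0))
  d <- haversine_km(clc[1], clc[2], nodes$lon, nodes$lat)
  ord <- order(d, nodes$node_id)
  ord <- ord[d[ord] <= max_km]
  utils::head(ord, k)
}

#' Descriptive statistic of a time series
#'
#' Median and 95th percentile use linear interpolation between order
#' statistics (type-7 quantiles); the standard deviation uses the sample
#' (n - 1) divisor. Non-finite values are dropped; an empty series gives NaN.
#'
#' @param values Numeric vector.
#' @param which One of `"median"`, `"p95"`, `"std"`.
#' @return A single numeric value.
#' @export
series_stats <- function(values, which = c("median", "p95", "std")) {
  which <- match.arg(which)
  values <- values[is.finite(values)]
  if (length(values) == 0) return(NaN)
  switch(which,
    median = unname(stats::quantile(values, 0.5, type = 7)),
    p95 = unname(stats::quantile(values, 0.95, type = 7)),
    std = if (length(values) < 2) NaN else stats::sd(values)
  )
}

#' Mean tidal range of one tide series
#'
#' The series is cut into successive windows of one tidal-cycle length
#' (default 24 h 50 min, i.e. one lunar day); the mean over windows of
#' (window max - window min) is the tidal range. A trailing partial window
#' is dropped.
#'
#' @param values Tide levels, m.
#' @param dt_hours Time step of the series, hours.
#' @param cycle_hours Window length, hours.
#' @return Mean tidal range, m (NaN if no complete window).
#' @export
tidal_range <- function(values, dt_hours, cycle_hours = 24 + 50 / 60) {
  n_per <- max(1L, round(cycle_hours / dt_hours))
  n_win <- floor(length(values) / n_per)
  if (n_win < 1) return(NaN)
  r <- vapply(seq_len(n_win), function(w) {
    x <- values[((w - 1) * n_per + 1):(w * n_per)]
    x <- x[is.finite(x)]
    if (length(x) == 0) return(NaN)
    max(x) - min(x)
  }, numeric(1))
  mean(r, na.rm = TRUE)
}

#' Indicator derivation configuration
#'
#' @param tidal_cycle_hours Window length for the tidal range, hours.
#' @param circular_angles Use circular statistics for the shoreline-angle
#'   spread (plain standard deviation if `FALSE`).
#' @param current_threshold Current-speed threshold for `D_c_03`, m/s
#'   (inclusive).
#' @return An `indicator_config` list.
#' @export
indicator_config <- function(tidal_cycle_hours = 24 + 50 / 60,
                             circular_angles = TRUE,
                             current_threshold = 0.3) {
  structure(list(tidal_cycle_hours = tidal_cycle_hours,
                 circular_angles = circular_angles,
                 current_threshold = current_threshold),
            class = "indicator_config")
}

# per-node statistics for one variable matrix (nodes x time)
node_statistic <- function(mat, stat, dt_hours, cycle_hours) {
  if (stat == "tidal_range") {
    apply(mat, 1, tidal_range, dt_hours = dt_hours, cycle_hours = cycle_hours)
  } else {
    apply(mat, 1, series_stats, which = stat)
  }
}

#' Derive the time-series indicators for every Coastgon
#'
#' For each Coastgon and dataset class, the k nearest nodes within 100 km of
#' the CLC are matched; each statistic is computed per node first and then
#' arithmetically averaged over the matched nodes (nodes whose statistic is
#' NaN are skipped). Coastgons with no matched nodes get NaN for that
#' class's indicators. Also computes `D_c_03` from the per-node median
#' current speeds.
#'
#' @param grid A [build_grid()] result.
#' @param nodes A `node_series_set` from [generate_env_timeseries()] or
#'   [read_node_series()].
#' @param rule A [match_rule()].
#' @param config An [indicator_config()].
#' @return Data frame: `cell` plus the 14 time-series indicator columns.
#' @export
derive_node_indicators <- function(grid, nodes, rule = match_rule(),
                                   config = indicator_config()) {
  stopifnot(inherits(grid, "coastgon_grid"),
            inherits(nodes, "node_series_set"),
            inherits(rule, "match_rule"))
  cells <- grid$cells
  out <- data.frame(cell = cells$cell, stringsAsFactors = FALSE)

  # per-class matched node indices for each cell
  matches <- list()
  for (cls in names(nodes$classes)) {
    nd <- nodes$classes[[cls]]$nodes
    k <- rule$k[[cls]]
    matches[[cls]] <- lapply(seq_len(nrow(cells)), function(i) {
      match_nodes(c(cells$clc_lon[i], cells$clc_lat[i]), nd, k, rule$max_km)
    })
  }

  for (def in NODE_INDICATORS) {
    cls <- VAR_CLASS[[def$var]]
    cls_data <- nodes$classes[[cls]]
    if (is.null(cls_data) || is.null(cls_data$series[[def$var]])) {
      out[[def$ind]] <- NaN
      next
    }
    per_node <- node_statistic(cls_data$series[[def$var]], def$stat,
                               nodes$dt_hours, config$tidal_cycle_hours)
    out[[def$ind]] <- vapply(matches[[cls]], function(m) {
      v <- per_node[m]
      v <- v[is.finite(v)]
      if (length(v) == 0) NaN else mean(v)
    }, numeric(1))
  }

  # D_c_03: distance to the nearest node whose median current >= threshold
  cls_data <- nodes$classes[["oras5"]]
  if (!is.null(cls_data) && !is.null(cls_data$series$current)) {
    med <- node_statistic(cls_data$series$current, "median",
                          nodes$dt_hours, config$tidal_cycle_hours)
    out$D_c_03 <- current_proximity_all(cells, cls_data$nodes, med,
                                        config$current_threshold)
  } else {
    out$D_c_03 <- NaN
  }
  out
}

current_proximity_all <- function(cells, nodes, node_medians, threshold) {
  qual <- which(is.finite(node_medians) & node_medians >= threshold)
  if (length(qual) == 0) return(rep(NaN, nrow(cells)))
  vapply(seq_len(nrow(cells)), function(i) {
    min(haversine_km(cells$clc_lon[i], cells$clc_lat[i],
                     nodes$lon[qual], nodes$lat[qual]))
  }, numeric(1))
}

#' Distance to the nearest strong-current node
#'
#' Haversine distance from a CLC to the nearest node whose median current
#' speed meets the threshold (inclusive); NaN if no node qualifies.
#'
#' @param clc Numeric `c(lon, lat)`.
#' @param nodes Data frame of current nodes (`lon`, `lat`).
#' @param node_medians Per-node median current speed, m/s.
#' @param threshold Qualifying speed, m/s.
#' @return Distance in km, or NaN.
#' @export
current_proximity <- function(clc, nodes, node_medians, threshold = 0.3) {
  cells <- data.frame(clc_lon = clc[1], clc_lat = clc[2])
  current_proximity_all(cells, nodes, node_medians, threshold)[1]
}

densify_polygon <- function(polygon, max_seg_km = 1) {
  n <- nrow(polygon)
  closed <- rbind(polygon, polygon[1, , drop = FALSE])
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    len <- haversine_km(closed[i, 1], closed[i, 2],
                        closed[i + 1, 1], closed[i + 1, 2])
    np <- max(2L, ceiling(len / max_seg_km) + 1L)
    tt <- seq(0, 1, length.out = np)
    seg <- cbind(closed[i, 1] + tt * (closed[i + 1, 1] - closed[i, 1]),
                 closed[i, 2] + tt * (closed[i + 1, 2] - closed[i, 2]))
    pieces[[i]] <- seg[-np, , drop = FALSE]
  }
  do.call(rbind, pieces)
}

#' Distance from a coastline centroid to the nearest habitat patch
#'
#' Minimum Haversine distance from the CLC to any polygon boundary vertex
#' after densifying edges to <= 1 km segments; 0 if the CLC lies inside a
#' polygon; NaN for an empty polygon set.
#'
#' @param clc Numeric `c(lon, lat)`.
#' @param polygons List of `lon`/`lat` vertex matrices.
#' @return Distance in km.
#' @export
habitat_distance <- function(clc, polygons) {
  if (length(polygons) == 0) return(NaN)
  best <- Inf
  for (p in polygons) {
    if (mgcv::in.out(rbind(p, p[1, , drop = FALSE]),
                     matrix(clc, 1, 2))) {
      return(0)
    }
    dp <- densify_polygon(p)
    best <- min(best, min(haversine_km(clc[1], clc[2], dp[, 1], dp[, 2])))
  }
  best
}

#' Circular standard deviation of angles
#'
#' @param angles_deg Angles in degrees.
#' @return Circular standard deviation in degrees
#'   (`sqrt(-2 log Rbar)`, Rbar the mean resultant length).
#' @export
circular_sd_deg <- function(angles_deg) {
  a <- angles_deg[is.finite(angles_deg)] * pi / 180
  if (length(a) == 0) return(NaN)
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  rbar <- min(1, rbar)
  if (rbar <= 0) return(Inf)
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' Geophysical and human indicators of one Coastgon
#'
#' From the linked transects: `phi_std` = circular standard deviation of
#' shoreline angles (shoreline complexity; plain sd behind the
#' `circular_angles` config flag), medians of the slopes and of the maximum
#' coastal elevation, sample sd of the elevation, and mean percent built
#' environment.
#'
#' @param transects Data frame of the Coastgon's linked transects.
#' @param config An [indicator_config()].
#' @return Named numeric vector of the 6 geophysical/human indicators.
#' @export
derive_geophysical <- function(transects, config = indicator_config()) {
  stopifnot(nrow(transects) >= 1)
  phi <- if (config$circular_angles) {
    circular_sd_deg(transects$shoreline_angle)
  } else {
    if (nrow(transects) < 2) 0 else stats::sd(transects$shoreline_angle)
  }
  c(phi_std = phi,
    beta_ns_med = series_stats(transects$beta_ns, "median"),
    beta_bs_med = series_stats(transects$beta_bs, "median"),
    z_max_med = series_stats(transects$z_max, "median"),
    z_max_std = if (nrow(transects) < 2) 0 else stats::sd(transects$z_max),
    p_built = mean(transects$p_built, na.rm = TRUE))
}

#' Derive the full 22-indicator table
#'
#' Assembles the time-series, geophysical, and habitat indicators for every
#' Coastgon, together with its CLC and any nesting flags present on the
#' grid.
#'
#' @param grid A [build_grid()] result (optionally after [assign_nesting()]).
#' @param nodes A `node_series_set`.
#' @param habitats A `habitat_set` (see [generate_habitats()]).
#' @param transects The transect data frame used to build the grid.
#' @param rule A [match_rule()].
#' @param config An [indicator_config()].
#' @return Data frame: `cell`, `clc_lon`, `clc_lat`, the 22 indicator
#'   columns, and `nesting_<species>` flags if present.
#' @export
derive_indicators <- function(grid, nodes, habitats, transects,
                              rule = match_rule(),
                              config = indicator_config()) {
  tab <- derive_node_indicators(grid, nodes, rule, config)
  cells <- grid$cells
  tab$clc_lon <- cells$clc_lon
  tab$clc_lat <- cells$clc_lat

  geo <- t(vapply(seq_len(nrow(cells)), function(i) {
    ids <- grid$links$transect_id[grid$links$cell == cells$cell[i]]
    derive_geophysical(transects[transects$id %in% ids, , drop = FALSE],
                       config)
  }, numeric(6)))
  tab <- cbind(tab, as.data.frame(geo))

  coral <- lapply(Filter(function(h) h$variable == "coral", habitats),
                  `[[`, "polygon")
  sgr <- lapply(Filter(function(h) h$variable == "seagrass", habitats),
                `[[`, "polygon")
  tab$D_cor <- vapply(seq_len(nrow(cells)), function(i) {
    habitat_distance(c(cells$clc_lon[i], cells$clc_lat[i]), coral)
  }, numeric(1))
  tab$D_sgr <- vapply(seq_len(nrow(cells)), function(i) {
    habitat_distance(c(cells$clc_lon[i], cells$clc_lat[i]), sgr)
  }, numeric(1))

  nest_cols <- grep("^nesting_", names(cells), value = TRUE)
  for (nc in nest_cols) tab[[nc]] <- cells[[nc]]
  tab[, c("cell", "clc_lon", "clc_lat", INDICATOR_NAMES, nest_cols)]
}
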