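# Synthetic coastal world generator
#
# Emulates the four input classes of the real pipeline — shoreline transects,
# environmental time-series nodes, habitat polygons, nesting sites — with
# known planted statistical structure (smooth spatial gradients, AR(1)
# temporal noise, a logistic presence model on chosen indicators) so every
# downstream stage can be tested without external global datasets.

SPECIES_CODES <- c("CC", "CM", "EI", "DC", "LO")

# dataset class of each synthetic environmental variable
VAR_CLASS <- c(
  hs = "era5_wave", tp = "era5_wave",
  u10 = "era5_atmos", sst = "era5_atmos", precip = "era5_atmos",
  surge = "gtsm", tide = "gtsm",
  current = "oras5"
)

DATASET_CLASSES <- c("era5_wave", "era5_atmos", "gtsm", "oras5")

#' Specify the spatial-temporal model of one environmental field
#'
#' Each field is an AR(1) process around a smooth spatial mean
#' `x_t = mu(s) + phi (x_{t-1} - mu(s)) + eps_t`, `eps_t ~ N(0, sd^2)`,
#' evaluated at nodes laid along (and offset seaward of) the coastline.
#' The `tide` variable is generated instead as a sinusoid whose amplitude
#' follows the spatial-mean function.
#'
#' @param variable One of `r paste(names(VAR_CLASS), collapse = ", ")`.
#' @param spatial_mean A list describing mu(s) as a function of the fractional
#'   position `s` in \[0,1\] along the coast: `list(type = "constant", value=)`,
#'   `list(type = "linear", from=, to=)`,
#'   `list(type = "bump", base=, height=, center=, width=)` (Gaussian bump), or
#'   `list(type = "sine", base=, amplitude=, cycles=)`.
#' @param ar1_phi AR(1) coefficient, `|phi| < 1` (stationarity).
#' @param noise_sd Innovation standard deviation, in the variable's units.
#' @param units Unit string (documentation only).
#' @return An `env_field_spec` list.
#' @export
env_field_spec <- function(variable, spatial_mean, ar1_phi = 0.8,
                           noise_sd = 1, units = "") {
  if (!variable %in% names(VAR_CLASS)) {
    stop(sprintf("unknown variable '%s'; valid names: %s",
                 variable, paste(names(VAR_CLASS), collapse = ", ")))
  }
  stopifnot(abs(ar1_phi) < 1, noise_sd >= 0)
  structure(list(variable = variable, spatial_mean = spatial_mean,
                 ar1_phi = ar1_phi, noise_sd = noise_sd, units = units),
            class = "env_field_spec")
}

eval_spatial_mean <- function(spec, frac) {
  switch(spec$type,
    constant = rep(spec$value, length(frac)),
    linear   = spec$from + (spec$to - spec$from) * frac,
    bump     = spec$base + spec$height * exp(-0.5 * ((frac - spec$center) / spec$width)^2),
    sine     = spec$base + spec$amplitude * sin(2 * pi * spec$cycles * frac),
    stop(sprintf("unknown spatial_mean type '%s'", spec$type))
  )
}

#' Specify the planted nesting presence model
#'
#' Presence probability per coastal region is logistic in percentile-scaled
#' indicators: `p = plogis(beta0 + sum_j beta_j z_j)`. With
#' `deterministic_threshold` set, presence is the deterministic event
#' `p >= threshold`; otherwise presences are seeded Bernoulli draws.
#'
#' @param species Species code (CC loggerhead, CM green, EI hawksbill,
#'   DC leatherback, LO olive ridley).
#' @param beta0 Intercept on the logit scale.
#' @param beta Named numeric vector of planted effects; names must be valid
#'   indicator names (see [indicator_names()]).
#' @param deterministic_threshold Optional probability cutoff.
#' @return A `nesting_model_spec` list.
#' @export
nesting_model_spec <- function(species = "CC", beta0 = 0, beta = numeric(0),
                               deterministic_threshold = NULL) {
  species <- match.arg(species, SPECIES_CODES)
  bad <- setdiff(names(beta), INDICATOR_NAMES)
  if (length(bad)) {
    stop(sprintf("invalid indicator name(s) in beta: %s",
                 paste(bad, collapse = ", ")))
  }
  structure(list(species = species, beta0 = beta0, beta = beta,
                 deterministic_threshold = deterministic_threshold),
            class = "nesting_model_spec")
}

default_env_fields <- function() {
  list(
    env_field_spec("hs", list(type = "sine", base = 2, amplitude = 0.8,
                              cycles = 1.2),
                   ar1_phi = 0.9, noise_sd = 0.3, units = "m"),
    env_field_spec("tp", list(type = "sine", base = 8, amplitude = 2, cycles = 1.5),
                   ar1_phi = 0.8, noise_sd = 1.0, units = "s"),
    env_field_spec("u10", list(type = "bump", base = 4.5, height = 4,
                               center = 0.75, width = 0.2),
                   ar1_phi = 0.7, noise_sd = 1.5, units = "m/s"),
    env_field_spec("sst", list(type = "linear", from = 18, to = 29),
                   ar1_phi = 0.95, noise_sd = 0.25, units = "degC"),
    env_field_spec("precip", list(type = "bump", base = 800, height = 1500,
                                  center = 0.6, width = 0.15),
                   ar1_phi = 0.6, noise_sd = 100, units = "mm/y"),
    env_field_spec("surge", list(type = "sine", base = 0.12, amplitude = 0.08,
                                 cycles = 2),
                   ar1_phi = 0.8, noise_sd = 0.04, units = "m"),
    # spatial_mean here is the tidal *amplitude*; range = 2 x amplitude
    env_field_spec("tide", list(type = "sine", base = 0.8, amplitude = 0.7,
                                cycles = 3),
                   ar1_phi = 0, noise_sd = 0.05, units = "m"),
    env_field_spec("current", list(type = "bump", base = 0.1, height = 0.5,
                                   center = 0.35, width = 0.1),
                   ar1_phi = 0.7, noise_sd = 0.05, units = "m/s")
  )
}

default_transect_fields <- function() {
  list(
    beta_ns = list(mean = list(type = "constant", value = 0.02), sd = 0.01,
                   min = 0.001),
    beta_bs = list(mean = list(type = "constant", value = 0.08), sd = 0.04,
                   min = 0.001),
    z_max = list(mean = list(type = "sine", base = 12, amplitude = 8,
                             cycles = 1.7),
                 sd = 3, min = 0),
    p_built = list(mean = list(type = "bump", base = 5, height = 40,
                               center = 0.85, width = 0.1), sd = 10,
                   min = 0, max = 100)
  )
}

#' Default wavy mid-latitude coastline control points
#'
#' @param length_km Approximate total length, km.
#' @param lat_base,amp_deg,cycles Shape of the sinusoidal path.
#' @return Matrix of control points (`lon`, `lat`).
#' @export
default_coastline <- function(length_km = 13100, lat_base = 5, amp_deg = 6,
                              cycles = 2.5) {
  frac <- seq(0, 1, length.out = 80)
  lon_extent <- length_km / (KM_PER_DEG * cos(lat_base * pi / 180)) * 0.95
  cbind(lon = frac * lon_extent,
        lat = lat_base + amp_deg * sin(2 * pi * cycles * frac))
}

#' Configuration of the synthetic coastal world
#'
#' Defaults generate a ~13,000 km wavy coastline at mid latitudes with 1-km
#' transects (~400 coastal regions on the default 26-km hex grid), 720 hourly
#' time steps per environmental node, smooth spatial gradients with AR(1)
#' noise, six habitat patches, and a steep planted logistic nesting model on
#' tidal range (negative) and sea surface temperature (positive).
#'
#' @param seed Integer master seed; all stages derive their streams from it.
#' @param coastline Matrix of control points (`lon`, `lat`).
#' @param transect_spacing_km Alongshore transect spacing, km (> 0).
#' @param node_spacing_km Named vector of alongshore node spacings per
#'   dataset class, km.
#' @param offshore_km Seaward offset of environmental nodes, km.
#' @param n_timesteps Number of time steps (>= 2).
#' @param dt_hours Time step, hours.
#' @param tide_period_hours Tidal (semidiurnal) period, hours.
#' @param env_fields List of [env_field_spec()]s.
#' @param transect_fields Per-attribute spatial mean / noise specs for the
#'   geophysical transect attributes.
#' @param habitat_patches List of `list(variable, lon, lat, radius_km)` with
#'   variable in `coral`, `seagrass`; `NULL` for defaults placed along the
#'   coastline.
#' @param nesting_model A [nesting_model_spec()] or list of them.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         coastline = default_coastline(),
                         transect_spacing_km = 1,
                         node_spacing_km = c(era5_wave = 55, era5_atmos = 50,
                                             gtsm = 30, oras5 = 50),
                         offshore_km = 20,
                         n_timesteps = 720,
                         dt_hours = 1,
                         tide_period_hours = 12.4206,
                         env_fields = default_env_fields(),
                         transect_fields = default_transect_fields(),
                         habitat_patches = NULL,
                         nesting_model = nesting_model_spec(
                           "CC", beta0 = -11.5,
                           beta = c(h_tide = -20, SST_med = 20))) {
  stopifnot(transect_spacing_km > 0, n_timesteps >= 2, dt_hours > 0)
  stopifnot(is.matrix(coastline), ncol(coastline) == 2, nrow(coastline) >= 2)
  stopifnot(all(DATASET_CLASSES %in% names(node_spacing_km)))
  for (f in env_fields) stopifnot(inherits(f, "env_field_spec"))
  if (inherits(nesting_model, "nesting_model_spec")) {
    nesting_model <- list(nesting_model)
  }
  structure(
    list(seed = as.integer(seed), coastline = coastline,
         transect_spacing_km = transect_spacing_km,
         node_spacing_km = node_spacing_km, offshore_km = offshore_km,
         n_timesteps = as.integer(n_timesteps), dt_hours = dt_hours,
         tide_period_hours = tide_period_hours,
         env_fields = env_fields, transect_fields = transect_fields,
         habitat_patches = habitat_patches, nesting_model = nesting_model),
    class = "synth_config"
  )
}

# Arc-length parameterization of the coastline polyline. Returns the total
# length and vectorized point()/bearing()/frac() lookups.
coast_path <- function(config) {
  cp <- config$coastline
  # densify each segment to ~0.25 km pieces (linear in lon/lat)
  seg_len <- haversine_km(cp[-nrow(cp), 1], cp[-nrow(cp), 2],
                          cp[-1, 1], cp[-1, 2])
  if (sum(seg_len) <= 0) stop("degenerate coastline: zero total length")
  pts <- vector("list", nrow(cp) - 1)
  for (i in seq_len(nrow(cp) - 1)) {
    np <- max(2L, ceiling(seg_len[i] / 0.25) + 1L)
    tt <- seq(0, 1, length.out = np)
    pts[[i]] <- cbind(lon = cp[i, 1] + tt * (cp[i + 1, 1] - cp[i, 1]),
                      lat = cp[i, 2] + tt * (cp[i + 1, 2] - cp[i, 2]))
    if (i > 1) pts[[i]] <- pts[[i]][-1, , drop = FALSE]
  }
  v <- do.call(rbind, pts)
  d <- c(0, cumsum(haversine_km(v[-nrow(v), 1], v[-nrow(v), 2],
                                v[-1, 1], v[-1, 2])))
  total <- d[length(d)]
  point <- function(at) {
    at <- pmin(pmax(at, 0), total)
    cbind(lon = stats::approx(d, v[, 1], xout = at, ties = "ordered")$y,
          lat = stats::approx(d, v[, 2], xout = at, ties = "ordered")$y)
  }
  bearing <- function(at) {
    h <- min(0.1, total / 100)
    a <- point(pmin(at, total - h))
    b <- point(pmin(at + h, total))
    bearing_deg(a[, "lon"], a[, "lat"], b[, "lon"], b[, "lat"])
  }
  list(length = total, point = point, bearing = bearing)
}

#' Generate shoreline transects along the synthetic coastline
#'
#' Transects are placed at even arc-length intervals (both endpoints
#' included: `n = floor(L / spacing) + 1`), each carrying its position, the
#' local tangent bearing as shoreline angle, and geophysical/human attributes
#' drawn around smooth alongshore means. Deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns `id`, `lon`, `lat`, `shoreline_angle`,
#'   `beta_ns`, `beta_bs`, `z_max`, `p_built`.
#' @export
generate_coastline <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  path <- coast_path(config)
  if (path$length < 10 * config$transect_spacing_km) {
    stop("coastline too short: length must be >= 10 x transect spacing")
  }
  n <- floor(path$length / config$transect_spacing_km) + 1
  at <- (seq_len(n) - 1) * config$transect_spacing_km
  pts <- path$point(at)
  ang <- path$bearing(at) %% 360
  frac <- at / path$length
  set.seed(config$seed + 1L)
  out <- data.frame(id = seq_len(n), lon = pts[, "lon"], lat = pts[, "lat"],
                    shoreline_angle = ang)
  for (nm in names(config$transect_fields)) {
    spec <- config$transect_fields[[nm]]
    val <- eval_spatial_mean(spec$mean, frac) + stats::rnorm(n, 0, spec$sd)
    if (!is.null(spec$min)) val <- pmax(val, spec$min)
    if (!is.null(spec$max)) val <- pmin(val, spec$max)
    out[[nm]] <- val
  }
  out
}

#' Generate environmental node time series
#'
#' Nodes are laid per dataset class on a coarse alongshore lattice offset
#' seaward of the coastline. Each variable follows a stationary AR(1) process
#' around its spatial mean; the tide is a sinusoid of spatially varying
#' amplitude plus noise. Deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @return A `node_series_set`: list with `classes` (per dataset class a list
#'   of `nodes` data frame and `series` matrices node x time), `times` (hours)
#'   and `dt_hours`.
#' @export
generate_env_timeseries <- function(config) {
  stopifnot(inherits(config, "synth_config"), config$n_timesteps >= 2)
  path <- coast_path(config)
  tt <- (seq_len(config$n_timesteps) - 1) * config$dt_hours
  set.seed(config$seed + 2L)
  classes <- list()
  for (cls in DATASET_CLASSES) {
    sp <- config$node_spacing_km[[cls]]
    at <- if (sp / 2 > path$length) path$length / 2 else {
      seq(sp / 2, path$length, by = sp)
    }
    pts <- path$point(at)
    brg <- path$bearing(at)
    # offset seaward: displace along bearing + 90 degrees
    theta <- (brg + 90) * pi / 180
    de <- config$offshore_km * sin(theta)
    dn <- config$offshore_km * cos(theta)
    lon <- pts[, "lon"] + de / (KM_PER_DEG * cos(pts[, "lat"] * pi / 180))
    lat <- pts[, "lat"] + dn / KM_PER_DEG
    nodes <- data.frame(
      node_id = sprintf("%s_%04d", cls, seq_along(at)),
      lon = lon, lat = lat, frac = at / path$length
    )
    series <- list()
    for (f in config$env_fields) {
      if (VAR_CLASS[[f$variable]] != cls) next
      mu <- eval_spatial_mean(f$spatial_mean, nodes$frac)
      nn <- nrow(nodes); nt <- config$n_timesteps
      x <- matrix(0, nn, nt)
      if (f$variable == "tide") {
        phase <- stats::runif(nn, 0, 2 * pi)
        for (j in seq_len(nn)) {
          x[j, ] <- mu[j] * sin(2 * pi * tt / config$tide_period_hours + phase[j])
        }
        x <- x + matrix(stats::rnorm(nn * nt, 0, f$noise_sd), nn, nt)
      } else {
        phi <- f$ar1_phi
        x[, 1] <- mu + stats::rnorm(nn, 0, f$noise_sd / sqrt(1 - phi^2))
        if (nt > 1) {
          eps <- matrix(stats::rnorm(nn * (nt - 1), 0, f$noise_sd), nn, nt - 1)
          for (t in 2:nt) x[, t] <- mu + phi * (x[, t - 1] - mu) + eps[, t - 1]
        }
      }
      rownames(x) <- nodes$node_id
      series[[f$variable]] <- x
    }
    classes[[cls]] <- list(nodes = nodes, series = series)
  }
  structure(list(classes = classes, times = tt, dt_hours = config$dt_hours),
            class = "node_series_set")
}

# circle polygon of radius_km around (lon, lat)
circle_polygon <- function(lon, lat, radius_km, n_vertices = 36) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  local_lonlat(radius_km * cos(ang), radius_km * sin(ang), lon, lat)
}

#' Generate habitat polygons (coral and seagrass patches)
#'
#' Circular patches at the configured centers; with no configured patches,
#' six default patches (three coral, three seagrass) are placed just offshore
#' at fixed fractions of the coastline.
#'
#' @param config A [synth_config()].
#' @return A `habitat_set`: list of `list(variable, polygon)` where `polygon`
#'   is a matrix of `lon`/`lat` vertices.
#' @export
generate_habitats <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  patches <- config$habitat_patches
  if (is.null(patches)) {
    path <- coast_path(config)
    fr <- list(coral = c(0.15, 0.45, 0.8), seagrass = c(0.25, 0.6, 0.9))
    patches <- list()
    for (vv in names(fr)) {
      for (f in fr[[vv]]) {
        p <- path$point(f * path$length)
        patches[[length(patches) + 1]] <- list(
          variable = vv, lon = p[1, "lon"], lat = p[1, "lat"] - 0.15,
          radius_km = 30)
      }
    }
  }
  out <- lapply(patches, function(p) {
    stopifnot(p$variable %in% c("coral", "seagrass"))
    list(variable = p$variable,
         polygon = circle_polygon(p$lon, p$lat, p$radius_km))
  })
  structure(out, class = "habitat_set")
}

#' Generate nesting sites from the planted logistic model
#'
#' For each coastal region, presence probability is logistic in the
#' percentile-scaled planted indicators; a presence emits one nesting point
#' at the region's coastline centroid. Regions with missing values in a
#' planted indicator are treated as absences.
#'
#' @param config A [synth_config()].
#' @param indicators An indicator table (from [derive_indicators()]) with
#'   columns `cell`, `clc_lon`, `clc_lat` and the indicator columns.
#' @return Data frame of sites (`lon`, `lat`, `species`) with attributes
#'   `prob` (true presence probability per cell) and `presence` (0/1 per cell
#'   per species).
#' @export
generate_nesting <- function(config, indicators) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(indicators))
  sites <- list()
  probs <- list()
  pres <- list()
  set.seed(config$seed + 3L)
  for (model in config$nesting_model) {
    missing_ind <- setdiff(names(model$beta), names(indicators))
    if (length(missing_ind)) {
      stop(sprintf("planted coefficient(s) reference indicator(s) absent from the table: %s",
                   paste(missing_ind, collapse = ", ")))
    }
    if (length(model$beta)) {
      sc <- fit_scaler(indicators, names(model$beta))
      z <- scale_indicators(sc, indicators)
      eta <- model$beta0 + as.vector(z %*% model$beta)
    } else {
      eta <- rep(model$beta0, nrow(indicators))
    }
    p <- stats::plogis(eta)
    p[is.na(p)] <- 0
    if (!is.null(model$deterministic_threshold)) {
      y <- as.integer(p >= model$deterministic_threshold)
    } else {
      y <- stats::rbinom(length(p), 1, p)
    }
    names(p) <- indicators$cell
    probs[[model$species]] <- p
    pres[[model$species]] <- stats::setNames(y, indicators$cell)
    idx <- which(y == 1)
    if (length(idx)) {
      sites[[length(sites) + 1]] <- data.frame(
        lon = indicators$clc_lon[idx], lat = indicators$clc_lat[idx],
        species = model$species)
    }
  }
  out <- if (length(sites)) do.call(rbind, sites) else
    data.frame(lon = numeric(0), lat = numeric(0), species = character(0))
  attr(out, "prob") <- probs
  attr(out, "presence") <- pres
  out
}
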