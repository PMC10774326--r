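# Coastgon grid construction
#
# Overlays a hexagonal grid on shoreline transect centroids, refines it under
# a no-gap constraint, assigns coastline centroids (CLC = unit-vector mean of
# linked transects), and flags per-species nesting as a binary state.

#' Grid construction configuration
#'
#' @param min_transects Cells with fewer transects than this AND fewer
#'   coastal neighbors than `min_neighbors` are removal candidates.
#' @param min_neighbors See `min_transects`.
#' @param max_link_km Maximum great-circle distance at which an orphaned
#'   transect may be linked to a surviving cell (inclusive).
#' @param lat_bounds Latitude band of the grid, degrees.
#' @param snap_km Maximum distance at which a nesting site outside every
#'   cell is snapped to the nearest coastline centroid.
#' @return A `grid_config` list.
#' @export
grid_config <- function(min_transects = 5, min_neighbors = 1,
                        max_link_km = 100, lat_bounds = c(-39, 48),
                        snap_km = 25) {
  stopifnot(min_transects >= 1, min_neighbors >= 0, max_link_km > 0,
            length(lat_bounds) == 2, lat_bounds[1] < lat_bounds[2])
  structure(list(min_transects = min_transects, min_neighbors = min_neighbors,
                 max_link_km = max_link_km, lat_bounds = lat_bounds,
                 snap_km = snap_km),
            class = "grid_config")
}

clc_of_cells <- function(transects, links) {
  cells <- sort(unique(links$cell))
  out <- matrix(NA_real_, length(cells), 2,
                dimnames = list(cells, c("lon", "lat")))
  idx <- match(links$transect_id, transects$id)
  for (i in seq_along(cells)) {
    j <- idx[links$cell == cells[i]]
    out[i, ] <- unit_vector_mean(transects$lon[j], transects$lat[j])
  }
  out
}

#' Build the Coastgon grid from shoreline transects
#'
#' Three stages: (1) overlay — every hexagonal cell containing at least one
#' transect centroid becomes a candidate; (2) refinement — candidates with
#' fewer than `min_transects` transects and fewer than `min_neighbors`
#' coastal neighbors are removed greedily from fewest transects upward,
#' skipping any removal that would strand one of its transects beyond
#' `max_link_km` of all surviving cells (the no-gap constraint); (3) orphaned
#' transects are relinked to the nearest surviving cell's running CLC within
#' `max_link_km`, or dropped with a warning. CLCs are then recomputed as the
#' unit-vector mean of linked transect positions.
#'
#' @param transects Data frame of transects (`id`, `lon`, `lat`,
#'   `shoreline_angle`, ...).
#' @param indexer A [planar_hex_indexer()].
#' @param config A [grid_config()].
#' @return A `coastgon_grid`: list with `cells` (data frame: `cell`,
#'   `clc_lon`, `clc_lat`, `n_transects`), `links` (`transect_id`, `cell`),
#'   `dropped` (transect ids), `indexer`, `config`.
#' @export
build_grid <- function(transects, indexer, config = grid_config()) {
  stopifnot(is.data.frame(transects), inherits(indexer, "hex_indexer"))
  if (nrow(transects) == 0) stop("empty transect set")
  inb <- transects$lat >= config$lat_bounds[1] &
    transects$lat <= config$lat_bounds[2]
  if (!any(inb)) stop("all transects outside the grid latitude bounds")
  tr <- transects[inb, , drop = FALSE]

  cell <- hex_cell_of(indexer, tr$lon, tr$lat)
  links <- data.frame(transect_id = tr$id, cell = cell,
                      stringsAsFactors = FALSE)
  survivors <- sort(unique(cell))
  counts <- table(links$cell)

  # greedy refinement, repeated ordered passes until stable
  repeat {
    clc <- clc_of_cells(tr, links[links$cell %in% survivors, , drop = FALSE])
    ord <- order(as.integer(counts[survivors]), survivors)
    removed_any <- FALSE
    for (cand in survivors[ord]) {
      n_tr <- as.integer(counts[[cand]])
      if (n_tr >= config$min_transects) next
      nb <- hex_neighbors(indexer, cand)
      n_nb <- sum(nb %in% survivors)
      if (n_nb >= config$min_neighbors) next
      others <- setdiff(survivors, cand)
      if (length(others) == 0) next
      # no-gap constraint: a cell that is part of the connected coastline
      # (has a surviving neighbor) may not be removed if that would strand
      # one of its transects beyond max_link_km of every surviving cell;
      # a fully isolated cell is removable and its transects are dropped
      # by the relink step (the grid does not represent coast > 100 km away)
      if (n_nb >= 1) {
        mine <- links$transect_id[links$cell == cand]
        j <- match(mine, tr$id)
        ok <- vapply(j, function(jj) {
          d <- haversine_km(tr$lon[jj], tr$lat[jj],
                            clc[others, "lon"], clc[others, "lat"])
          any(d <= config$max_link_km)
        }, logical(1))
        if (!all(ok)) next
      }
      survivors <- others
      removed_any <- TRUE
    }
    if (!removed_any) break
  }

  # relink orphans to the nearest surviving cell's running CLC
  clc <- clc_of_cells(tr, links[links$cell %in% survivors, , drop = FALSE])
  orphan <- which(!(links$cell %in% survivors))
  dropped <- character(0)
  members <- split(match(links$transect_id[links$cell %in% survivors], tr$id),
                   links$cell[links$cell %in% survivors])
  for (i in orphan) {
    jj <- match(links$transect_id[i], tr$id)
    d <- haversine_km(tr$lon[jj], tr$lat[jj], clc[, "lon"], clc[, "lat"])
    k <- which.min(d)
    if (d[k] <= config$max_link_km) {
      target <- rownames(clc)[k]
      links$cell[i] <- target
      members[[target]] <- c(members[[target]], jj)
      clc[k, ] <- unit_vector_mean(tr$lon[members[[target]]],
                                   tr$lat[members[[target]]])
    } else {
      links$cell[i] <- NA_character_
      dropped <- c(dropped, as.character(links$transect_id[i]))
    }
  }
  if (length(dropped)) {
    warning(sprintf("%d transect(s) dropped: beyond %g km of every surviving cell",
                    length(dropped), config$max_link_km))
  }
  links <- links[!is.na(links$cell), , drop = FALSE]

  clc <- clc_of_cells(tr, links)
  counts <- table(links$cell)
  cells <- data.frame(cell = rownames(clc),
                      clc_lon = clc[, "lon"], clc_lat = clc[, "lat"],
                      n_transects = as.integer(counts[rownames(clc)]),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cells = cells, links = links, dropped = dropped,
                 indexer = indexer, config = config,
                 n_input_transects = nrow(tr)),
            class = "coastgon_grid")
}

#' @export
print.coastgon_grid <- function(x, ...) {
  cat(sprintf("<coastgon_grid: %d cells, %d linked transects, %d dropped>\n",
              nrow(x$cells), nrow(x$links), length(x$dropped)))
  invisible(x)
}

#' Flag per-species nesting state of each Coastgon
#'
#' A Coastgon is a nesting region for a species iff at least one site of
#' that species falls inside its cell (binary state; site counts are not
#' recorded). Sites falling in no coastal cell are snapped to the nearest
#' CLC within `snap_km`, else ignored with a warning.
#'
#' @param grid A [build_grid()] result.
#' @param sites Data frame of nesting sites (`lon`, `lat`, `species`).
#' @return The grid with per-species 0/1 columns `nesting_<species>` added
#'   to `grid$cells`.
#' @export
assign_nesting <- function(grid, sites) {
  stopifnot(inherits(grid, "coastgon_grid"), is.data.frame(sites))
  bad <- setdiff(unique(sites$species), SPECIES_CODES)
  if (length(bad)) {
    stop(sprintf("unknown species code(s): %s; valid: %s",
                 paste(bad, collapse = ", "),
                 paste(SPECIES_CODES, collapse = ", ")))
  }
  for (sp in SPECIES_CODES) {
    grid$cells[[paste0("nesting_", sp)]] <- 0L
  }
  if (nrow(sites) == 0) return(grid)
  cell <- hex_cell_of(grid$indexer, sites$lon, sites$lat)
  inside <- cell %in% grid$cells$cell
  n_ignored <- 0
  for (i in seq_len(nrow(sites))) {
    target <- if (inside[i]) cell[i] else {
      d <- haversine_km(sites$lon[i], sites$lat[i],
                        grid$cells$clc_lon, grid$cells$clc_lat)
      k <- which.min(d)
      if (d[k] <= grid$config$snap_km) grid$cells$cell[k] else NA_character_
    }
    if (is.na(target)) { n_ignored <- n_ignored + 1; next }
    col <- paste0("nesting_", sites$species[i])
    grid$cells[[col]][grid$cells$cell == target] <- 1L
  }
  if (n_ignored > 0) {
    warning(sprintf("%d nesting site(s) ignored: outside every cell and > %g km from every CLC",
                    n_ignored, grid$config$snap_km))
  }
  grid
}

# spherical polygon area in km2 (sphere of radius EARTH_RADIUS_KM)
spherical_area_km2 <- function(polygon) {
  geosphere::areaPolygon(polygon, a = EARTH_RADIUS_KM * 1000, f = 0) / 1e6
}

#' Summary statistics of a Coastgon grid
#'
#' @param grid A [build_grid()] result.
#' @return List with `n_cells`, `area_mean_km2`, `area_sd_km2`,
#'   `diameter_mean_km`, `diameter_sd_km` (max vertex-to-vertex great-circle
#'   distance), and `transects_per_cell` (min/median/max).
#' @export
grid_stats <- function(grid) {
  stopifnot(inherits(grid, "coastgon_grid"))
  areas <- numeric(nrow(grid$cells))
  diams <- numeric(nrow(grid$cells))
  for (i in seq_len(nrow(grid$cells))) {
    b <- hex_boundary(grid$indexer, grid$cells$cell[i])
    areas[i] <- spherical_area_km2(b)
    dmax <- 0
    for (u in 1:5) for (v in (u + 1):6) {
      dmax <- max(dmax, haversine_km(b[u, 1], b[u, 2], b[v, 1], b[v, 2]))
    }
    diams[i] <- dmax
  }
  n <- grid$cells$n_transects
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  list(n_cells = nrow(grid$cells),
       area_mean_km2 = mean(areas), area_sd_km2 = sd0(areas),
       diameter_mean_km = mean(diams), diameter_sd_km = sd0(diams),
       transects_per_cell = c(min = min(n), median = stats::median(n),
                              max = max(n)))
}
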