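# Plain-text I/O: CSV for tabular artifacts, GeoJSON for geometries.

#' Write / read shoreline transects
#'
#' @param transects Transect data frame.
#' @param path CSV path.
#' @export
write_transects <- function(transects, path) {
  utils::write.csv(transects, path, row.names = FALSE)
}

#' @rdname write_transects
#' @export
read_transects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read node time series as long-format CSV
#'
#' Columns: `class`, `node_id`, `lon`, `lat`, `variable`, `time_hours`,
#' `value`.
#'
#' @param nodes A `node_series_set`.
#' @param path CSV path.
#' @export
write_node_series <- function(nodes, path) {
  stopifnot(inherits(nodes, "node_series_set"))
  rows <- list()
  for (cls in names(nodes$classes)) {
    nd <- nodes$classes[[cls]]$nodes
    for (var in names(nodes$classes[[cls]]$series)) {
      mat <- nodes$classes[[cls]]$series[[var]]
      rows[[length(rows) + 1]] <- data.frame(
        class = cls,
        node_id = rep(nd$node_id, times = ncol(mat)),
        lon = rep(nd$lon, times = ncol(mat)),
        lat = rep(nd$lat, times = ncol(mat)),
        variable = var,
        time_hours = rep(nodes$times, each = nrow(mat)),
        value = as.vector(mat))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' @rdname write_node_series
#' @export
read_node_series <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  times <- sort(unique(long$time_hours))
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  classes <- list()
  for (cls in unique(long$class)) {
    sub <- long[long$class == cls, , drop = FALSE]
    nd <- unique(sub[, c("node_id", "lon", "lat")])
    nd <- nd[order(nd$node_id), , drop = FALSE]
    rownames(nd) <- NULL
    series <- list()
    for (var in unique(sub$variable)) {
      ss <- sub[sub$variable == var, , drop = FALSE]
      mat <- matrix(NA_real_, nrow(nd), length(times),
                    dimnames = list(nd$node_id, NULL))
      mat[cbind(match(ss$node_id, nd$node_id),
                match(ss$time_hours, times))] <- ss$value
      series[[var]] <- mat
    }
    classes[[cls]] <- list(nodes = nd, series = series)
  }
  structure(list(classes = classes, times = times, dt_hours = dt),
            class = "node_series_set")
}

geojson_polygon_feature <- function(polygon, properties) {
  closed <- rbind(polygon, polygon[1, , drop = FALSE])
  list(type = "Feature", properties = properties,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(closed)),
                                                 function(i) unname(closed[i, 1:2])))))
}

#' Write a Coastgon grid as a GeoJSON FeatureCollection
#'
#' One polygon feature per Coastgon with its cell id, CLC, transect count
#' and nesting flags; the transect-to-cell links go to a companion CSV.
#'
#' @param grid A [build_grid()] result.
#' @param path GeoJSON path.
#' @param links_path Optional CSV path for the transect links.
#' @export
write_grid_geojson <- function(grid, path, links_path = NULL) {
  feats <- lapply(seq_len(nrow(grid$cells)), function(i) {
    b <- hex_boundary(grid$indexer, grid$cells$cell[i])
    geojson_polygon_feature(b, as.list(grid$cells[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(links_path)) {
    utils::write.csv(grid$links, links_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write habitat patches as GeoJSON
#'
#' @param habitats A `habitat_set`.
#' @param path GeoJSON path.
#' @export
write_habitats_geojson <- function(habitats, path) {
  feats <- lapply(habitats, function(h) {
    geojson_polygon_feature(h$polygon, list(variable = h$variable))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read habitat patches from GeoJSON
#'
#' @param path GeoJSON path (Polygon features with a `variable` property).
#' @return A `habitat_set`.
#' @export
read_habitats_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    # drop the closing vertex
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    list(variable = f$properties$variable, polygon = m)
  })
  structure(out, class = "habitat_set")
}

#' Read region polygons from GeoJSON
#'
#' @param path GeoJSON path (Polygon features with a `name` property).
#' @return Named list of `lon`/`lat` polygon matrices.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list()
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    out[[f$properties$name]] <- m
  }
  out
}

#' Write a suitability map as GeoJSON
#'
#' @param map A [classify_suitability()] result (or several rbind-ed).
#' @param grid The grid (for cell boundaries).
#' @param path GeoJSON path.
#' @export
write_suitability_geojson <- function(map, grid, path) {
  feats <- lapply(seq_len(nrow(map)), function(i) {
    b <- hex_boundary(grid$indexer, map$cell[i])
    geojson_polygon_feature(b, list(cell = map$cell[i],
                                    species = map$species[i],
                                    category = as.character(map$category[i]),
                                    unclustered = map$unclustered[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
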