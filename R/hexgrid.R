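# Planar hexagonal indexer
#
# Pointy-top hexagons on axial coordinates (q, r) in a local equirectangular
# plane (km) anchored at (lon0, lat0). Cell ids are strings "q:r". This is
# the built-in backend used throughout; an icosahedral backend could be
# plugged in by implementing the same four operations.

#' Create a planar hexagonal grid indexer
#'
#' Builds a pointy-top hexagonal tessellation of a local planar projection
#' of the coastal band. Cell ids are axial coordinates `"q:r"`. The default
#' edge length of 26 km gives a vertex-to-vertex cell diameter of 52 km and
#' a cell area of about 1755 km2, i.e. coastal regions of roughly 50 km
#' extent.
#'
#' @param edge_km Hexagon edge (= circumradius), km.
#' @param lon0,lat0 Projection anchor, decimal degrees.
#' @return An object of class `hex_indexer` supporting [hex_cell_of()],
#'   [hex_neighbors()], [hex_boundary()] and [hex_centroid()].
#' @export
planar_hex_indexer <- function(edge_km = 26, lon0 = 0, lat0 = 0) {
  stopifnot(is.numeric(edge_km), edge_km > 0)
  structure(
    list(backend = "planar", edge_km = edge_km, lon0 = lon0, lat0 = lat0,
         resolution = sprintf("planar-e%g", edge_km)),
    class = "hex_indexer"
  )
}

#' @export
print.hex_indexer <- function(x, ...) {
  cat(sprintf("<hex_indexer backend=%s edge=%g km anchor=(%g, %g)>\n",
              x$backend, x$edge_km, x$lon0, x$lat0))
  invisible(x)
}

axial_round <- function(qf, rf) {
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = rx, r = rz)
}

cell_id <- function(q, r) sprintf("%d:%d", as.integer(q), as.integer(r))

parse_cell <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  q <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  r <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  cbind(q = q, r = r)
}

#' Hexagonal cell of a point
#'
#' @param indexer A [planar_hex_indexer()].
#' @param lon,lat Coordinates, decimal degrees (vectorized).
#' @return Character vector of cell ids.
#' @export
hex_cell_of <- function(indexer, lon, lat) {
  s <- indexer$edge_km
  xy <- local_xy_km(lon, lat, indexer$lon0, indexer$lat0)
  qf <- (sqrt(3) / 3 * xy[, "x"] - 1 / 3 * xy[, "y"]) / s
  rf <- (2 / 3 * xy[, "y"]) / s
  qr <- axial_round(qf, rf)
  cell_id(qr[, "q"], qr[, "r"])
}

#' Neighbors of a hexagonal cell
#'
#' @param indexer A [planar_hex_indexer()].
#' @param cell A single cell id.
#' @return Character vector of the 6 neighboring cell ids.
#' @export
hex_neighbors <- function(indexer, cell) {
  qr <- parse_cell(cell)
  dq <- c(1, 1, 0, -1, -1, 0)
  dr <- c(0, -1, -1, 0, 1, 1)
  cell_id(qr[1, "q"] + dq, qr[1, "r"] + dr)
}

hex_center_xy <- function(indexer, cells) {
  s <- indexer$edge_km
  qr <- parse_cell(cells)
  cbind(x = s * sqrt(3) * (qr[, "q"] + qr[, "r"] / 2),
        y = s * 1.5 * qr[, "r"])
}

#' Centroid of a hexagonal cell
#'
#' @param indexer A [planar_hex_indexer()].
#' @param cells Character vector of cell ids.
#' @return Matrix with columns `lon`, `lat`.
#' @export
hex_centroid <- function(indexer, cells) {
  xy <- hex_center_xy(indexer, cells)
  local_lonlat(xy[, "x"], xy[, "y"], indexer$lon0, indexer$lat0)
}

#' Boundary polygon of a hexagonal cell
#'
#' @param indexer A [planar_hex_indexer()].
#' @param cell A single cell id.
#' @return 6 x 2 matrix of vertices (`lon`, `lat`), counter-clockwise,
#'   not closed.
#' @export
hex_boundary <- function(indexer, cell) {
  s <- indexer$edge_km
  ctr <- hex_center_xy(indexer, cell)
  ang <- (60 * (0:5) - 30) * pi / 180  # pointy-top vertices
  vx <- ctr[1, "x"] + s * cos(ang)
  vy <- ctr[1, "y"] + s * sin(ang)
  local_lonlat(vx, vy, indexer$lon0, indexer$lat0)
}
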