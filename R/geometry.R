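#' Mean Earth radius (IUGG), km
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Spherical area of a grid cell
#'
#' Area of a `resolution` x `resolution` degree cell centred at latitude
#' `lat_center`, on a sphere of radius 6371.0088 km:
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\varphi_{top} - \sin\varphi_{bot})}
#' Area is strictly decreasing in absolute latitude and symmetric about the
#' equator.
#'
#' @param lat_center Cell-centre latitude(s), degrees; the cell must lie
#'   within \[-90, 90\].
#' @param resolution Cell edge, degrees.
#' @return Cell area(s) in square kilometres.
#' @examples
#' cell_area(0, 1 / 12) # ~85.9 km^2
#' @export
cell_area <- function(lat_center, resolution = 1 / 12) {
  if (any(abs(lat_center) + resolution / 2 > 90 + 1e-9)) {
    stop("cell extends beyond [-90, 90] latitude", call. = FALSE)
  }
  top <- (lat_center + resolution / 2) * pi / 180
  bot <- (lat_center - resolution / 2) * pi / 180
  EARTH_RADIUS_KM^2 * (resolution * pi / 180) * (sin(top) - sin(bot))
}

#' Per-cell area grid
#'
#' @param g A [grid_layer()] supplying the lattice.
#' @return A [grid_layer()] of cell areas (km^2), constant along rows.
#' @export
grid_cell_areas <- function(g) {
  a <- cell_area(grid_lat_centers(g), g$resolution)
  grid_like(g, matrix(a, nrow = nrow(g$values), ncol = ncol(g$values)))
}

#' Great-circle distance from every cell centre to its nearest port
#'
#' Haversine distance (via \pkg{geosphere}, R = 6371.0088 km) from each cell
#' centre to the closest port in the set; no coastline routing. Nodata in the
#' template propagates to the output. The result is invariant under
#' permutation of the port list.
#'
#' @param g A [grid_layer()] whose lattice (and nodata mask) to use.
#' @param ports Tibble with columns `name`, `lat`, `lon`; must be non-empty.
#' @return A [grid_layer()] of distances in km.
#' @export
nearest_port_distance <- function(g, ports) {
  validate_ports(ports)
  nr <- nrow(g$values)
  nc <- ncol(g$values)
  pts <- cbind(
    lon = rep(grid_lon_centers(g), each = nr),
    lat = rep(grid_lat_centers(g), times = nc)
  )
  d <- rep(Inf, nr * nc)
  for (i in seq_len(nrow(ports))) {
    di <- geosphere::distHaversine(pts, c(ports$lon[i], ports$lat[i]),
                                   r = EARTH_RADIUS_KM)
    d <- pmin(d, di)
  }
  m <- matrix(d, nrow = nr, ncol = nc)
  m[is.na(g$values)] <- NA_real_
  grid_like(g, m)
}
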