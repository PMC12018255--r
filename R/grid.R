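#' Gridded raster layer on a regular latitude/longitude lattice
#'
#' `grid_layer()` builds the package's basic spatial container: a matrix of
#' cell values on a regular geographic lattice, cell-centre registered, with
#' row 1 the northernmost row. Missing cells are `NA` internally; the nodata
#' sentinel only appears in files (see [write_grid()]).
#'
#' @param values Numeric (or logical/integer) matrix; row 1 = northernmost row.
#' @param lat_max Latitude of the northern edge of the lattice (degrees).
#'   Give exactly one of `lat_max` or `lat_min`.
#' @param lat_min Latitude of the southern edge (degrees); the canonical
#'   stored field, so grids read from disk round-trip exactly.
#' @param lon_min Longitude of the western edge (degrees, in \[-180, 180)).
#' @param resolution Cell edge length in degrees (default 1/12 degree, i.e.
#'   five arcminutes).
#'
#' @return An object of class `grid_layer`.
#' @examples
#' g <- grid_layer(matrix(1:6, 2, 3), lat_max = 10, lon_min = -80,
#'                 resolution = 1 / 12)
#' grid_lat_centers(g)
#' @export
grid_layer <- function(values, lat_max = NULL, lat_min = NULL, lon_min,
                       resolution = 1 / 12) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    stop("`resolution` must be a single positive number", call. = FALSE)
  }
  if (is.null(lat_min) == is.null(lat_max)) {
    stop("give exactly one of `lat_max` or `lat_min`", call. = FALSE)
  }
  if (is.null(lat_min)) lat_min <- lat_max - nrow(values) * resolution
  if (lat_min < -90 - 1e-9 || lat_min + nrow(values) * resolution > 90 + 1e-9) {
    stop("cell latitudes fall outside [-90, 90]", call. = FALSE)
  }
  if (lon_min < -180 - 1e-9 || lon_min >= 180) {
    stop("`lon_min` must lie in [-180, 180)", call. = FALSE)
  }
  structure(
    list(values = values, lat_min = lat_min, lon_min = lon_min,
         resolution = resolution),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf(
    "<grid_layer> %d x %d cells at %.6g deg; lat [%.4f, %.4f], lon [%.4f, %.4f]\n",
    nrow(x$values), ncol(x$values), x$resolution,
    x$lat_min, grid_lat_max(x), x$lon_min,
    x$lon_min + ncol(x$values) * x$resolution
  ))
  cat(sprintf("  valid cells: %d / %d\n", sum(!is.na(x$values)),
              length(x$values)))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Georeferencing accessors
#'
#' @param g A [grid_layer()].
#' @return `grid_lat_max()` the northern edge latitude; `grid_lat_centers()` /
#'   `grid_lon_centers()` cell-centre coordinate vectors (north to south /
#'   west to east).
#' @export
grid_lat_max <- function(g) g$lat_min + nrow(g$values) * g$resolution

#' @rdname grid_lat_max
#' @export
grid_lat_centers <- function(g) {
  n <- nrow(g$values)
  g$lat_min + (n - seq_len(n) + 0.5) * g$resolution
}

#' @rdname grid_lat_max
#' @export
grid_lon_centers <- function(g) {
  g$lon_min + (seq_len(ncol(g$values)) - 0.5) * g$resolution
}

#' Test or assert that grids share one lattice
#'
#' Every multi-layer operation in the package requires its inputs to be
#' aligned: identical dimensions, origin and resolution. `grids_aligned()`
#' tests; `assert_aligned()` stops with an informative error.
#'
#' @param ... Two or more [grid_layer()] objects.
#' @return `grids_aligned()` a logical scalar; `assert_aligned()` invisibly
#'   `TRUE` or an error.
#' @export
grids_aligned <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !inherits(gs[[1]], "grid_layer")) {
    gs <- gs[[1]]
  }
  stopifnot(length(gs) >= 2)
  ref <- gs[[1]]
  all(vapply(gs[-1], function(g) {
    identical(dim(g$values), dim(ref$values)) &&
      abs(g$lat_min - ref$lat_min) < 1e-9 &&
      abs(g$lon_min - ref$lon_min) < 1e-9 &&
      abs(g$resolution - ref$resolution) < 1e-12
  }, logical(1)))
}

#' @rdname grids_aligned
#' @export
assert_aligned <- function(...) {
  if (!grids_aligned(...)) {
    stop("grids are not aligned (shape, origin or resolution differ)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Derive a grid with new values on the same lattice
#'
#' @param g A [grid_layer()] supplying the georeferencing.
#' @param values Replacement matrix of identical dimensions.
#' @return A [grid_layer()].
#' @export
grid_like <- function(g, values) {
  stopifnot(identical(dim(values), dim(g$values)))
  grid_layer(values, lat_min = g$lat_min, lon_min = g$lon_min,
             resolution = g$resolution)
}

#' Convert a grid layer to a tibble of cell records
#'
#' One row per cell with cell-centre coordinates, suitable for dplyr/ggplot2
#' work. Invalid (nodata) cells are kept with `value = NA` unless
#' `drop_na = TRUE`.
#'
#' @param x A [grid_layer()].
#' @param drop_na Drop nodata cells?
#' @param ... Ignored.
#' @return A tibble with columns `row`, `col`, `lat`, `lon`, `value`.
#' @method as_tibble grid_layer
#' @export
as_tibble.grid_layer <- function(x, ..., drop_na = FALSE) {
  nr <- nrow(x$values)
  nc <- ncol(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    lat = rep(grid_lat_centers(x), times = nc),
    lon = rep(grid_lon_centers(x), each = nr),
    value = as.vector(x$values)
  )
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' @method autoplot grid_layer
#' @export
autoplot.grid_layer <- function(object, name = "value", ...) {
  df <- as_tibble.grid_layer(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (°)", y = "Latitude (°)",
                  fill = name)
}

#' Block-aggregate a grid to a coarser resolution
#'
#' Aggregates `factor` x `factor` blocks of cells into one, with `sum` for
#' extensive variables (e.g. banana hectares) and `mean` for intensive ones
#' (temperature, pH). For `sum`, nodata cells contribute zero so the grand
#' total is conserved exactly; for `mean`, nodata cells are excluded and an
#' all-nodata block stays nodata.
#'
#' @param g A [grid_layer()].
#' @param factor Integer aggregation factor; must divide both dimensions.
#' @param method `"sum"` or `"mean"`.
#' @return A [grid_layer()] with `factor`-times coarser resolution.
#' @export
aggregate_grid <- function(g, factor, method = c("sum", "mean")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  nr <- nrow(g$values)
  nc <- ncol(g$values)
  if (factor < 1 || nr %% factor != 0 || nc %% factor != 0) {
    stop("`factor` must divide both grid dimensions", call. = FALSE)
  }
  ri <- (seq_len(nr) - 1L) %/% factor
  ci <- (seq_len(nc) - 1L) %/% factor
  block <- ri[row(g$values)] + (nr %/% factor) * ci[col(g$values)]
  v <- as.vector(g$values)
  if (method == "sum") {
    out <- tapply(ifelse(is.na(v), 0, v), block, sum)
  } else {
    out <- tapply(v, block, function(z) {
      z <- z[!is.na(z)]
      if (length(z) == 0) NA_real_ else mean(z)
    })
  }
  m <- matrix(as.numeric(out), nrow = nr %/% factor, ncol = nc %/% factor)
  grid_layer(m, lat_min = g$lat_min, lon_min = g$lon_min,
             resolution = g$resolution * factor)
}

#' Weighted summary statistic of one layer under another layer's weights
#'
#' Computes a banana-area-weighted (or any nonnegative-weighted) mean, median
#' or quantile of a layer over the cells where both the layer and the weights
#' are valid.
#'
#' @param layer,weights Aligned [grid_layer()] objects; weights must be
#'   nonnegative with positive total over the jointly valid cells.
#' @param statistic `"mean"`, `"median"` or `"q"`.
#' @param q Quantile level when `statistic = "q"`.
#' @param mask Optional logical matrix (or logical-valued grid) restricting
#'   the cells considered.
#' @return A scalar.
#' @export
weighted_layer_summary <- function(layer, weights,
                                   statistic = c("mean", "median", "q"),
                                   q = 0.5, mask = NULL) {
  statistic <- match.arg(statistic)
  assert_aligned(layer, weights)
  keep <- !is.na(layer$values) & !is.na(weights$values)
  if (!is.null(mask)) {
    mm <- if (inherits(mask, "grid_layer")) mask$values else mask
    keep <- keep & !is.na(mm) & mm
  }
  x <- layer$values[keep]
  w <- weights$values[keep]
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (length(x) == 0 || sum(w) <= 0) {
    stop("zero total weight over valid cells", call. = FALSE)
  }
  switch(statistic,
    mean = sum(w * x) / sum(w),
    median = weighted_quantile(x, w, 0.5),
    q = weighted_quantile(x, w, q)
  )
}
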