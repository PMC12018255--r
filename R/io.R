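#' Read and write raster layers as ESRI ASCII grids
#'
#' The package stores every raster layer in the ESRI ASCII grid dialect
#' (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by `nrows` whitespace-separated rows,
#' northernmost row first. Values are written with 17 significant digits so a
#' write/read round trip reproduces values, the nodata mask and the
#' georeferencing exactly. The nodata sentinel is -9999.
#'
#' A file whose header is missing or malformed (e.g. a bare matrix of numbers
#' with no georeferencing) is rejected with an error rather than silently
#' assigned a default lattice.
#'
#' @param path File path.
#' @param g A [grid_layer()].
#' @param nodata Sentinel written for `NA` cells.
#' @return `read_grid()` a [grid_layer()]; `write_grid()` the path, invisibly.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L, warn = FALSE)
  if (length(lines) < 6L) {
    stop("not an ASCII grid: missing georeferencing header in ", path,
         call. = FALSE)
  }
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || !(tolower(parts[1]) %in% keys) ||
        is.na(suppressWarnings(as.numeric(parts[2])))) {
      stop("not an ASCII grid: missing georeferencing header in ", path,
           call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  if (!all(keys %in% names(hdr))) {
    stop("incomplete ASCII grid header in ", path, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  v <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  if (length(v) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(v),
                 path), call. = FALSE)
  }
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid_layer(m, lat_min = hdr$yllcorner, lon_min = hdr$xllcorner,
             resolution = hdr$cellsize)
}

#' @rdname read_grid
#' @export
write_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "grid_layer"))
  v <- g$values
  storage.mode(v) <- "double"
  if (any(v == nodata, na.rm = TRUE)) {
    stop("grid contains the nodata sentinel as a real value", call. = FALSE)
  }
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", g$lon_min),
    sprintf("yllcorner %.17g", g$lat_min),
    sprintf("cellsize %.17g", g$resolution),
    sprintf("NODATA_value %.17g", nodata)
  )
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read and write port coordinate tables
#'
#' Ports are stored as a CSV with header `name,lat,lon`.
#'
#' @param path File path.
#' @param ports A tibble with columns `name`, `lat`, `lon`.
#' @return `read_ports()` a tibble; coordinates are validated.
#' @export
read_ports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "lat", "lon") %in% names(df))) {
    stop("ports file must have columns name,lat,lon", call. = FALSE)
  }
  out <- tibble::as_tibble(df[, c("name", "lat", "lon")])
  validate_ports(out)
  out
}

#' @rdname read_ports
#' @export
write_ports <- function(ports, path) {
  validate_ports(ports)
  utils::write.csv(ports[, c("name", "lat", "lon")], path, row.names = FALSE)
  invisible(path)
}

validate_ports <- function(ports) {
  if (nrow(ports) == 0) stop("port set is empty", call. = FALSE)
  if (any(abs(ports$lat) > 90) || any(ports$lon < -180 | ports$lon > 180)) {
    stop("port coordinates out of range", call. = FALSE)
  }
  invisible(TRUE)
}

#' Region label sets
#'
#' A region label set couples a grid of integer region codes with a
#' code-to-name lookup table (CSV columns `code,name`). Every labelled cell's
#' code must appear in the table.
#'
#' @param grid Integer-valued [grid_layer()] of region codes.
#' @param table Tibble with columns `code`, `name`.
#' @return An object of class `region_labels`.
#' @export
region_labels <- function(grid, table) {
  stopifnot(inherits(grid, "grid_layer"))
  table <- tibble::as_tibble(table)
  if (!all(c("code", "name") %in% names(table))) {
    stop("region table must have columns code,name", call. = FALSE)
  }
  codes <- unique(grid$values[!is.na(grid$values)])
  if (!all(codes %in% table$code)) {
    stop("region grid contains codes absent from the table", call. = FALSE)
  }
  structure(list(grid = grid, table = table), class = "region_labels")
}

#' @rdname region_labels
#' @param path CSV path for the lookup table.
#' @export
read_region_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(df))) {
    stop("region table must have columns code,name", call. = FALSE)
  }
  tibble::as_tibble(df[, c("code", "name")])
}

#' Serialize suitability criteria to an auditable text file
#'
#' Criteria are written as a tab-separated table (`variable`, `stratum`,
#' `lower`, `upper`, `level`) preceded by `#`-prefixed key-value lines for the
#' scalar settings, so a run can be audited and replayed without re-running
#' the estimation.
#'
#' @param criteria A [build_criteria()] result.
#' @param path File path.
#' @return `read_criteria()` a `suitability_criteria` object.
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "suitability_criteria"))
  hdr <- c(
    sprintf("# scenario %s", criteria$scenario),
    sprintf("# crop_cover_min %.17g", criteria$crop_cover_min),
    sprintf("# irrigation_threshold %.17g", criteria$irrigation_threshold),
    sprintf("# one_sided_static %s", criteria$one_sided_static)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(criteria$envelopes, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), " "))
  get <- function(k) kv[kv[, 1] == k, 2]
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  new_suitability_criteria(
    envelopes = tibble::as_tibble(df),
    crop_cover_min = as.numeric(get("crop_cover_min")),
    scenario = get("scenario"),
    irrigation_threshold = as.numeric(get("irrigation_threshold")),
    one_sided_static = as.logical(get("one_sided_static"))
  )
}
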