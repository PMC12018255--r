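envelope_for <- function(criteria, var, stratum) {
  e <- criteria$envelopes
  row <- e[e$variable == var & e$stratum == stratum, ]
  if (nrow(row) != 1) {
    stop(sprintf("criteria lack a '%s' envelope for stratum '%s'",
                 var, stratum), call. = FALSE)
  }
  c(lower = row$lower, upper = row$upper)
}

#' Classify cells as suitable (optimal) for intensive banana production
#'
#' A cell is suitable iff (a) its three climate values (BIO1, BIO4, BIO12)
#' fall inside the climate envelopes of its irrigation stratum — or inside
#' the merged envelopes when the criteria were built for the
#' unrestricted-irrigation scenario; (b) every static variable (elevation,
#' soil pH, population density, port distance) falls inside its envelope;
#' and (c) cropland cover reaches `crop_cover_min`. All interval membership
#' is closed (`lower <= x <= upper`). Cells where any required layer is
#' nodata are nodata in the result.
#'
#' @param criteria A [build_criteria()] result.
#' @param layers Named list of aligned [grid_layer()]s: the climate layers of
#'   the period being classified plus `elevation`, `soil_ph`, `population`,
#'   `port_distance` and `cropland`.
#' @param strata An [stratify_by_irrigation()] result (defines each cell's
#'   stratum; ignored for merged criteria).
#' @return Logical-valued [grid_layer()] suitability mask.
#' @export
classify_suitability <- function(criteria, layers, strata) {
  stopifnot(inherits(criteria, "suitability_criteria"))
  needed <- c(climate_vars, static_vars, "cropland")
  missing <- setdiff(needed, names(layers))
  if (length(missing) > 0) {
    stop("missing layers: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  assert_aligned(layers[needed])
  merged <- criteria$scenario == "unrestricted_irrigation"
  if (!merged) {
    assert_aligned(layers[[1]], strata$low_mask)
  }

  ok <- matrix(TRUE, nrow(layers[[1]]$values), ncol(layers[[1]]$values))
  for (var in climate_vars) {
    x <- layers[[var]]$values
    if (merged) {
      b <- envelope_for(criteria, var, "merged")
      inside <- x >= b["lower"] & x <= b["upper"]
    } else {
      blo <- envelope_for(criteria, var, "low")
      bhi <- envelope_for(criteria, var, "high")
      in_lo <- x >= blo["lower"] & x <= blo["upper"]
      in_hi <- x >= bhi["lower"] & x <= bhi["upper"]
      lowm <- strata$low_mask$values
      inside <- ifelse(is.na(lowm), NA, ifelse(lowm, in_lo, in_hi))
    }
    ok <- ok & inside
  }
  for (var in static_vars) {
    b <- envelope_for(criteria, var, "all")
    x <- layers[[var]]$values
    ok <- ok & (x >= b["lower"] & x <= b["upper"])
  }
  ok <- ok & (layers$cropland$values >= criteria$crop_cover_min)
  grid_like(layers[[1]], ok)
}

#' Eight-way observed/current/future categorization
#'
#' Classifies each analysed cell by observed banana presence (`o+`/`o-`),
#' predicted current suitability (`c+`/`c-`) and predicted future
#' suitability (`f+`/`f-`). Every valid cell carries exactly one of the
#' eight categories, so category areas partition the analysed area.
#'
#' @param observed Banana-hectares [grid_layer()]; presence means
#'   `> min_observed_ha` (default 0, i.e. any mapped banana).
#' @param current_mask,future_mask Logical suitability masks from
#'   [classify_suitability()].
#' @param min_observed_ha Presence threshold in hectares.
#' @return An object of class `category_grid`: list with `grid` (integer
#'   codes 1-8) and `table` (tibble `code`, `label`).
#' @export
categorize <- function(observed, current_mask, future_mask,
                       min_observed_ha = 0) {
  assert_aligned(observed, current_mask, future_mask)
  obs <- observed$values > min_observed_ha
  cur <- current_mask$values
  fut <- future_mask$values
  labels <- as.vector(outer(
    outer(c("o+", "o-"), c("c+", "c-"), paste0),
    c("f+", "f-"), paste0
  ))
  # code = 1 + obs_bit + 2*cur_bit + 4*fut_bit with bit 0 = "+"
  code <- 1L + (!obs) + 2L * (!cur) + 4L * (!fut)
  code[is.na(obs) | is.na(cur) | is.na(fut)] <- NA_integer_
  structure(
    list(grid = grid_like(observed, matrix(code, nrow(obs), ncol(obs))),
         table = tibble::tibble(code = 1:8, label = labels)),
    class = "category_grid"
  )
}

#' @export
print.category_grid <- function(x, ...) {
  cat("<category_grid>\n")
  print(category_areas(x), n = Inf)
  invisible(x)
}

#' Areas of the eight observed/current/future categories
#'
#' @param cats A [categorize()] result.
#' @return Tibble with `code`, `label`, `n_cells` and spherical `area_km2`;
#'   the rows partition the analysed cells exactly.
#' @export
category_areas <- function(cats) {
  g <- cats$grid
  areas <- grid_cell_areas(g)$values
  code <- g$values
  keep <- !is.na(code)
  dplyr::left_join(
    cats$table,
    tibble::tibble(code = as.integer(code[keep]), area = areas[keep]) |>
      dplyr::group_by(.data$code) |>
      dplyr::summarise(n_cells = dplyr::n(), area_km2 = sum(.data$area)),
    by = "code"
  ) |>
    tidyr::replace_na(list(n_cells = 0L, area_km2 = 0))
}

#' @method autoplot category_grid
#' @export
autoplot.category_grid <- function(object, ...) {
  df <- as_tibble.grid_layer(object$grid) |>
    dplyr::left_join(object$table, by = c(value = "code"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (°)", y = "Latitude (°)", fill = "category")
}

mask_area <- function(mask) {
  a <- grid_cell_areas(mask)$values
  m <- mask$values
  keep <- !is.na(m) & m
  c(cells = sum(keep), km2 = sum(a[keep]))
}

#' Suitable-area change between two scenarios
#'
#' @param current_mask,future_mask Aligned logical suitability masks.
#' @return Tibble with one row per basis (`cells`, `km2`): current and future
#'   suitable area and the fractional change `(future - current)/current`
#'   (negative = loss).
#' @export
area_change <- function(current_mask, future_mask) {
  assert_aligned(current_mask, future_mask)
  cur <- mask_area(current_mask)
  fut <- mask_area(future_mask)
  if (all(cur == 0)) stop("current suitable area is zero", call. = FALSE)
  tibble::tibble(
    basis = c("cells", "km2"),
    current = as.numeric(cur),
    future = as.numeric(fut),
    change = (as.numeric(fut) - as.numeric(cur)) / as.numeric(cur)
  )
}

#' Suitability under a single climate driver's future change
#'
#' Recomputes suitability with only one driver's layers taken from the
#' future period: `driver = "temperature"` swaps BIO1 and BIO4,
#' `driver = "precipitation"` swaps BIO12; everything else stays at current
#' values. Comparing these masks with the full future mask attributes
#' suitability change to warming versus drying.
#'
#' @param criteria,strata As for [classify_suitability()].
#' @param current_layers Full named layer list for the current period.
#' @param future_layers Named list with at least the future climate layers.
#' @param driver `"temperature"` or `"precipitation"`.
#' @return Logical suitability mask [grid_layer()].
#' @export
single_driver_mask <- function(criteria, current_layers, future_layers,
                               strata,
                               driver = c("temperature", "precipitation")) {
  driver <- match.arg(driver)
  swap <- if (driver == "temperature") c("bio1", "bio4") else "bio12"
  layers <- current_layers
  for (v in swap) {
    if (is.null(future_layers[[v]])) {
      stop("future layer missing: ", v, call. = FALSE)
    }
    layers[[v]] <- future_layers[[v]]
  }
  classify_suitability(criteria, layers, strata)
}

#' Fraction of predicted-suitable cells that hold observed banana
#'
#' Computed on a grid-cell basis: the number of suitable cells with observed
#' banana area above the presence threshold, divided by the number of
#' suitable cells.
#'
#' @param observed Banana-hectares [grid_layer()].
#' @param mask Logical suitability mask.
#' @param min_observed_ha Presence threshold (default 0 ha).
#' @return A fraction in \[0, 1\].
#' @export
occupancy_fraction <- function(observed, mask, min_observed_ha = 0) {
  assert_aligned(observed, mask)
  suit <- !is.na(mask$values) & mask$values
  if (sum(suit) == 0) stop("no suitable cells", call. = FALSE)
  occ <- suit & !is.na(observed$values) &
    observed$values > min_observed_ha
  sum(occ) / sum(suit)
}

#' Heat-exposure summary: weighted mean BIO5 over masks and periods
#'
#' Summarises the maximum temperature of the warmest month (BIO5) over each
#' supplied mask for the current and future periods, weighted by cell area
#' (or banana area if an alternative weight grid is given). Rising values
#' flag growing heat risk for plantation labour in the areas that remain
#' suitable.
#'
#' @param bio5_current,bio5_future Aligned BIO5 [grid_layer()]s (deg C).
#' @param masks Named list of logical masks.
#' @param weights Optional weight grid; default spherical cell areas.
#' @return Tibble with `mask`, `period`, `mean_bio5`.
#' @export
exposure_summary <- function(bio5_current, bio5_future, masks,
                             weights = NULL) {
  if (is.null(weights)) weights <- grid_cell_areas(bio5_current)
  purrr::imap_dfr(masks, function(m, nm) {
    tibble::tibble(
      mask = nm,
      period = c("current", "future"),
      mean_bio5 = c(
        weighted_layer_summary(bio5_current, weights, "mean", mask = m),
        weighted_layer_summary(bio5_future, weights, "mean", mask = m)
      )
    )
  })
}
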