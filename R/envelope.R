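#' Weighted quantile (left-continuous inverse CDF)
#'
#' Returns the smallest value `v` such that the cumulative weight fraction of
#' observations with value `<= v` reaches `q`. With equal weights this is the
#' type-1 sample quantile. The convention involves no interpolation, so
#' results are deterministic and exactly reproducible.
#'
#' @param values Numeric vector; `NA`/`NaN` must be filtered beforehand and
#'   raise an error here.
#' @param weights Nonnegative weights of the same length; total must be
#'   positive.
#' @param q Quantile level(s) in \[0, 1\].
#' @return Numeric vector of the same length as `q`.
#' @examples
#' weighted_quantile(1:10, rep(1, 10), 0.5) # 5
#' @export
weighted_quantile <- function(values, weights, q) {
  if (length(values) != length(weights)) {
    stop("`values` and `weights` must have equal length", call. = FALSE)
  }
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  if (anyNA(values) || anyNA(weights)) {
    stop("NA/NaN present: pre-filter values and weights", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]", call. = FALSE)
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  tw <- sum(weights)
  if (tw <= 0) stop("total weight is zero", call. = FALSE)
  o <- order(values)
  v <- values[o]
  cf <- cumsum(weights[o]) / tw
  vapply(q, function(qq) v[which(cf >= qq - 1e-12)[1]], numeric(1))
}

#' Estimate an area-weighted rectilinear envelope (R90)
#'
#' The rectilinear surface-range envelope of a variable is the interval
#' containing a stated central fraction (default 90%) of the crop-weighted
#' distribution: lower bound the weighted 5th percentile, upper the weighted
#' 95th. Weighting grid cells by crop (banana) area concentrates the envelope
#' on the conditions where production actually occurs. By construction the
#' weighted fraction of cells inside the closed interval is at least `level`.
#'
#' @param layer Variable [grid_layer()].
#' @param weights Aligned nonnegative weight grid (e.g. banana hectares).
#' @param mask Optional logical matrix / logical grid restricting cells.
#' @param level Central coverage fraction in (0, 1); default 0.90.
#' @param variable Name recorded in the output.
#' @return A one-row tibble of class `envelope_bounds` with columns
#'   `variable`, `lower`, `upper`, `level`, `n_cells`, `total_weight`.
#' @export
estimate_r90 <- function(layer, weights, mask = NULL, level = 0.90,
                         variable = "layer") {
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)", call. = FALSE)
  assert_aligned(layer, weights)
  keep <- !is.na(layer$values) & !is.na(weights$values)
  if (!is.null(mask)) {
    mm <- if (inherits(mask, "grid_layer")) mask$values else mask
    keep <- keep & !is.na(mm) & mm
  }
  x <- layer$values[keep]
  w <- weights$values[keep]
  pos <- w > 0
  if (sum(w) <= 0) stop("zero total weight within mask", call. = FALSE)
  alpha <- (1 - level) / 2
  b <- weighted_quantile(x, w, c(alpha, 1 - alpha))
  out <- tibble::tibble(variable = variable, lower = b[1], upper = b[2],
                        level = level, n_cells = sum(pos),
                        total_weight = sum(w))
  class(out) <- c("envelope_bounds", class(out))
  out
}

#' Split cells into low- and high-irrigation strata
#'
#' Splits the analysed cells at a threshold on the area equipped for
#' irrigation (AEI, fraction of cell area). Cells with AEI at or below the
#' threshold form the low stratum ("0-5%"); cells strictly above form the
#' high stratum. When no threshold is given it is the crop-weighted median
#' AEI, which in the source analysis lands at about 5%.
#'
#' @param aei AEI [grid_layer()], values in \[0, 1\].
#' @param weights Aligned crop-area weight grid (used only to compute a
#'   default threshold).
#' @param threshold Stratum boundary in \[0, 1\]; default the weighted median.
#' @return An object of class `irrigation_strata`: list with `threshold`,
#'   `low_mask` and `high_mask` (logical-valued [grid_layer()]s, disjoint,
#'   jointly covering every valid-AEI cell).
#' @export
stratify_by_irrigation <- function(aei, weights, threshold = NULL) {
  assert_aligned(aei, weights)
  rng <- range(aei$values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("AEI values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(threshold)) {
    threshold <- weighted_layer_summary(aei, weights, "median")
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  low <- aei$values <= threshold
  high <- aei$values > threshold
  structure(
    list(threshold = threshold,
         low_mask = grid_like(aei, low),
         high_mask = grid_like(aei, high)),
    class = "irrigation_strata"
  )
}

#' @export
print.irrigation_strata <- function(x, ...) {
  cat(sprintf("<irrigation_strata> threshold %.4g; low %d cells, high %d cells\n",
              x$threshold, sum(x$low_mask$values, na.rm = TRUE),
              sum(x$high_mask$values, na.rm = TRUE)))
  invisible(x)
}

#' @method tidy irrigation_strata
#' @export
tidy.irrigation_strata <- function(x, ...) {
  tibble::tibble(
    stratum = c("low", "high"),
    n_cells = c(sum(x$low_mask$values, na.rm = TRUE),
                sum(x$high_mask$values, na.rm = TRUE)),
    threshold = x$threshold
  )
}

climate_vars <- c("bio1", "bio4", "bio12")
static_vars <- c("elevation", "soil_ph", "population", "port_distance")

new_suitability_criteria <- function(envelopes, crop_cover_min, scenario,
                                     irrigation_threshold, one_sided_static) {
  structure(
    list(envelopes = tibble::as_tibble(envelopes),
         crop_cover_min = crop_cover_min,
         scenario = scenario,
         irrigation_threshold = irrigation_threshold,
         one_sided_static = one_sided_static),
    class = "suitability_criteria"
  )
}

#' Assemble the full suitability criteria set
#'
#' Estimates crop-weighted envelopes for the three climate constraints (mean
#' annual temperature BIO1, temperature seasonality BIO4, annual
#' precipitation BIO12) separately in the low- and high-irrigation strata,
#' applies the precipitation adjustment for irrigated production — the
#' high-irrigation precipitation envelope keeps its own lower bound (rain can
#' be replaced by irrigation) but inherits the low-irrigation upper bound
#' (irrigation is rarely installed where rain is plentiful, so the observed
#' irrigated upper bound understates tolerance) — and estimates unstratified
#' envelopes for the static constraints (elevation, soil pH, population
#' density, port distance). A minimum crop-cover fraction completes the set.
#'
#' Under `scenario = "unrestricted_irrigation"` each per-stratum climate
#' envelope is replaced by the union interval
#' `[min(lower_low, lower_high), max(upper_low, upper_high)]`, applied to
#' every cell regardless of its irrigation level: the widest conditions
#' attainable if irrigation could be established wherever needed.
#'
#' @param layers Named list of aligned [grid_layer()]s; must contain
#'   `bio1`, `bio4`, `bio12`, `elevation`, `soil_ph`, `population`,
#'   `port_distance`.
#' @param weights Crop-area weight grid.
#' @param strata An [stratify_by_irrigation()] result.
#' @param scenario `"observed"` or `"unrestricted_irrigation"`.
#' @param level Envelope coverage level (default 0.90).
#' @param crop_cover_min Minimum cropland fraction for a cell to qualify
#'   (default 0.01).
#' @param one_sided_static If `TRUE`, port distance and elevation envelopes
#'   keep only their upper bound and population only its lower bound,
#'   dropping the constraint that cells can be "too close" to ports or too
#'   populous.
#' @return A `suitability_criteria` object; see [tidy.suitability_criteria()].
#' @export
build_criteria <- function(layers, weights, strata,
                           scenario = c("observed", "unrestricted_irrigation"),
                           level = 0.90, crop_cover_min = 0.01,
                           one_sided_static = FALSE) {
  scenario <- match.arg(scenario)
  needed <- c(climate_vars, static_vars)
  missing <- setdiff(needed, names(layers))
  if (length(missing) > 0) {
    stop("missing layers: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  assert_aligned(c(layers[needed], list(weights)))

  stratum_env <- function(var, mask, label) {
    keep <- !is.na(mask$values) & mask$values &
      !is.na(layers[[var]]$values) & !is.na(weights$values)
    w_in <- weights$values[keep]
    if (length(w_in) == 0 || sum(w_in) <= 0) {
      warning(sprintf("stratum '%s' carries no weight for %s; %s",
                      label, var, "falling back to unstratified envelope"),
              call. = FALSE)
      return(estimate_r90(layers[[var]], weights, level = level,
                          variable = var))
    }
    estimate_r90(layers[[var]], weights, mask = mask, level = level,
                 variable = var)
  }

  rows <- list()
  raw <- list()
  for (var in climate_vars) {
    lo_env <- stratum_env(var, strata$low_mask, "low")
    hi_env <- stratum_env(var, strata$high_mask, "high")
    raw[[var]] <- list(low = lo_env, high = hi_env)
    if (var == "bio12") {
      # irrigated stratum: own lower bound, rainfed upper bound
      hi_env$upper <- lo_env$upper
    }
    if (scenario == "unrestricted_irrigation") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = var, stratum = "merged",
        lower = min(lo_env$lower, hi_env$lower),
        upper = max(lo_env$upper, hi_env$upper), level = level
      )
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = var, stratum = c("low", "high"),
        lower = c(lo_env$lower, hi_env$lower),
        upper = c(lo_env$upper, hi_env$upper), level = level
      )
    }
  }
  for (var in static_vars) {
    env <- estimate_r90(layers[[var]], weights, level = level, variable = var)
    lo <- env$lower
    up <- env$upper
    if (one_sided_static) {
      if (var %in% c("port_distance", "elevation")) lo <- -Inf
      if (var == "population") up <- Inf
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = var, stratum = "all", lower = lo, upper = up, level = level
    )
  }
  out <- new_suitability_criteria(
    envelopes = dplyr::bind_rows(rows),
    crop_cover_min = crop_cover_min,
    scenario = scenario,
    irrigation_threshold = strata$threshold,
    one_sided_static = one_sided_static
  )
  attr(out, "raw_stratum_envelopes") <- raw
  out
}

#' @export
print.suitability_criteria <- function(x, ...) {
  cat(sprintf("<suitability_criteria> scenario '%s', level %.2f, %s\n",
              x$scenario, x$envelopes$level[1],
              sprintf("crop cover >= %.2g", x$crop_cover_min)))
  print(x$envelopes, n = Inf)
  invisible(x)
}

#' Tidy and glance methods for suitability criteria
#'
#' @param x A `suitability_criteria` object.
#' @param ... Ignored.
#' @return `tidy()` the envelope table (one row per variable x stratum);
#'   `glance()` a one-row tibble of the scalar settings.
#' @method tidy suitability_criteria
#' @export
tidy.suitability_criteria <- function(x, ...) x$envelopes

#' @rdname tidy.suitability_criteria
#' @method glance suitability_criteria
#' @export
glance.suitability_criteria <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    level = x$envelopes$level[1],
    n_envelopes = nrow(x$envelopes),
    crop_cover_min = x$crop_cover_min,
    irrigation_threshold = x$irrigation_threshold,
    one_sided_static = x$one_sided_static
  )
}

#' Crop-weighted distribution summaries across comparison groups
#'
#' For each supplied variable, computes weighted quantiles (5, 25, 50, 75,
#' 95%) in three comparison groups: `all` (every valid cell, weighted by
#' spherical cell area), `crops` (weighted by cropland area = cropland
#' fraction x cell area) and `banana` (weighted by mapped banana area). A
#' variable whose banana interval sits well inside its all-land interval is
#' restrictive for the crop's distribution; this reproduces the
#' box-and-whisker comparison view of envelope analyses.
#'
#' @param layers Named list of variable [grid_layer()]s.
#' @param banana_area Banana hectares per cell.
#' @param cropland Cropland fraction per cell.
#' @return A tibble with columns `variable`, `group`, `q05`, `q25`, `q50`,
#'   `q75`, `q95`.
#' @export
distribution_summaries <- function(layers, banana_area, cropland) {
  assert_aligned(c(layers, list(banana_area, cropland)))
  areas <- grid_cell_areas(banana_area)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  groups <- list(
    all = areas$values,
    crops = cropland$values * areas$values,
    banana = banana_area$values
  )
  purrr::imap_dfr(layers, function(layer, var) {
    purrr::imap_dfr(groups, function(w, grp) {
      keep <- !is.na(layer$values) & !is.na(w)
      vals <- weighted_quantile(layer$values[keep], w[keep], qs)
      tibble::tibble(variable = var, group = grp,
                     q05 = vals[1], q25 = vals[2], q50 = vals[3],
                     q75 = vals[4], q95 = vals[5])
    })
  })
}

#' Box-and-whisker view of distribution summaries
#'
#' @param summaries A [distribution_summaries()] tibble.
#' @return A ggplot: one panel per variable, whiskers at the weighted 5th and
#'   95th percentiles, boxes at the quartiles.
#' @export
plot_distribution_summaries <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$group, fill = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$q05, lower = .data$q25, middle = .data$q50,
                   upper = .data$q75, ymax = .data$q95),
      stat = "identity", width = 0.6
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
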