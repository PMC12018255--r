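#' Configuration of a synthetic study scenario
#'
#' Defines a seeded synthetic landscape with the statistical structure the
#' suitability analysis assumes: smooth climate fields with latitudinal and
#' elevational gradients, irrigation anti-correlated with precipitation and
#' increasing with temperature, banana area confined to cells inside known
#' "true" environmental ranges, and a future climate engineered so that a
#' designed fraction of currently suitable cells warms out of the
#' temperature envelope.
#'
#' The true precipitation ranges default to the published stratified
#' envelope bounds (rainfed 912-3690 mm; irrigated 543-2356 mm), the
#' irrigation stratum boundary to 5% AEI and the designed suitability-loss
#' fraction to 0.60, mirroring the headline conditions of the source
#' analysis at desk scale.
#'
#' @param seed Integer seed; one seed drives the whole pseudo-random stream.
#' @param n_rows,n_cols Lattice size (default 200 x 200).
#' @param resolution Degrees per cell (default 1/12, five arcminutes).
#' @param lat_max,lon_min North-west corner of the lattice.
#' @param true_ranges Named list of true `[lower, upper]` ranges for `bio1`
#'   (degC), `bio4`, `bio12_low`, `bio12_high` (mm), `elevation` (m),
#'   `soil_ph`, `population` (persons/km2), `port_distance` (km).
#' @param aei_threshold True irrigation stratum boundary (fraction).
#' @param loss_fraction Designed fractional loss of currently suitable area
#'   under the future climate (0 disables warming).
#' @param precip_multiplier Future = current precipitation x this factor.
#' @param banana_occupancy Probability that an in-envelope cell carries
#'   banana.
#' @param banana_weight `"lognormal"` (heavy-tailed hectares per cell) or
#'   `"uniform"` (equal weight on every banana cell).
#' @param n_ports Number of randomly placed ports.
#' @param n_regions Number of longitudinal region bands.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_rows = 200L, n_cols = 200L,
                            resolution = 1 / 12,
                            lat_max = 12, lon_min = -85,
                            true_ranges = list(
                              bio1 = c(22.9, 27.9),
                              bio4 = c(300, 1500),
                              bio12_low = c(912, 3690),
                              bio12_high = c(543, 2356),
                              elevation = c(0, 1200),
                              soil_ph = c(5.0, 7.0),
                              population = c(20, 1500),
                              port_distance = c(0, 600)
                            ),
                            aei_threshold = 0.05,
                            loss_fraction = 0.60,
                            precip_multiplier = 1.0,
                            banana_occupancy = 0.9,
                            banana_weight = c("lognormal", "uniform"),
                            n_ports = 6L,
                            n_regions = 5L) {
  banana_weight <- match.arg(banana_weight)
  for (r in true_ranges) stopifnot(length(r) == 2, r[1] < r[2])
  stopifnot(loss_fraction >= 0, loss_fraction < 1,
            banana_occupancy > 0, banana_occupancy <= 1)
  structure(
    list(seed = as.integer(seed), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), resolution = resolution,
         lat_max = lat_max, lon_min = lon_min, true_ranges = true_ranges,
         aei_threshold = aei_threshold, loss_fraction = loss_fraction,
         precip_multiplier = precip_multiplier,
         banana_occupancy = banana_occupancy,
         banana_weight = banana_weight,
         n_ports = as.integer(n_ports), n_regions = as.integer(n_regions)),
    class = "scenario_config"
  )
}

# Smooth standardized random field: white noise convolved with a separable
# Gaussian kernel (reflects at the borders via kernel renormalization).
smooth_field <- function(n_rows, n_cols, range_cells = 12) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  half <- max(1L, as.integer(2 * range_cells))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  pad_conv <- function(m, kern) {
    # column-wise convolution, zero-padded and renormalized at the edges
    h <- length(kern) %/% 2
    n <- nrow(m)
    zeros <- matrix(0, h, ncol(m))
    num <- stats::filter(rbind(zeros, m, zeros), kern, sides = 2)
    den <- stats::filter(rbind(zeros, matrix(1, n, ncol(m)), zeros),
                         kern, sides = 2)
    mid <- (h + 1):(h + n)
    as.matrix(num[mid, , drop = FALSE] / den[mid, , drop = FALSE])
  }
  s <- pad_conv(z, k)
  s <- t(pad_conv(t(s), k))
  (s - mean(s)) / stats::sd(s)
}

#' Generate a full synthetic study scenario
#'
#' Produces mutually aligned current and future raster layers, a port table,
#' region labels and a ground-truth record of every designed quantity. The
#' future period shifts mean annual temperature (and BIO5) by a warming
#' offset calibrated so that the suitable area — classified with envelopes
#' estimated from the generated banana distribution, exactly as the pipeline
#' does — shrinks by the configured loss fraction (km2 basis, tolerance 0.5
#' percentage points at generation time; an unreachable target is an error).
#'
#' @param cfg A [scenario_config()].
#' @return An object of class `banana_scenario`: list with `layers` (named
#'   current-period [grid_layer()]s including `banana_area`, `aei`,
#'   `cropland`, `port_distance`), `future` (future `bio1`, `bio4`, `bio12`,
#'   `bio5`), `ports`, `regions`, `config` and `ground_truth`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  nr <- cfg$n_rows
  nc <- cfg$n_cols
  res <- cfg$resolution
  tr <- cfg$true_ranges

  template <- grid_layer(matrix(NA_real_, nr, nc), lat_max = cfg$lat_max,
                         lon_min = cfg$lon_min, resolution = res)
  lat <- matrix(grid_lat_centers(template), nr, nc)
  gl <- function(m) grid_like(template, m)

  elevation <- pmax(300 + 450 * smooth_field(nr, nc, 10), 0)
  bio1 <- 29.0 - 0.15 * abs(lat) - 0.0065 * elevation +
    1.2 * smooth_field(nr, nc, 14)
  bio4 <- pmax(600 + 40 * abs(lat) + 250 * smooth_field(nr, nc, 12), 50)
  bio12 <- pmax(2000 + 1100 * smooth_field(nr, nc, 12) -
                  35 * (lat - mean(lat)), 100)
  soil_ph <- 6.0 + 0.8 * smooth_field(nr, nc, 10)
  population <- exp(4 + 1.3 * smooth_field(nr, nc, 8) +
                      0.6 * stats::rnorm(nr * nc))
  cropland <- pmin(pmax(0.45 + 0.30 * smooth_field(nr, nc, 10) +
                        0.10 * stats::rnorm(nr * nc), 0), 1)
  # irrigation: high where rain is short of ~1500 mm and temperature > 25 C
  aei <- pmin(pmax(0.55 * stats::plogis((1500 - bio12) / 250) *
                   stats::plogis((bio1 - 25) / 1.5) +
                   0.05 * stats::rnorm(nr * nc), 0), 1)
  bio5 <- bio1 + 4.2 + 0.5 * smooth_field(nr, nc, 14)

  ports <- tibble::tibble(
    name = sprintf("port_%02d", seq_len(cfg$n_ports)),
    lat = stats::runif(cfg$n_ports, min(lat), max(lat)),
    lon = stats::runif(cfg$n_ports, cfg$lon_min, cfg$lon_min + nc * res)
  )
  port_distance <- nearest_port_distance(gl(bio1), ports)

  band <- ceiling(col(lat) / (nc / cfg$n_regions))
  region_table <- tibble::tibble(code = seq_len(cfg$n_regions),
                                 name = sprintf("Region %s",
                                                LETTERS[seq_len(cfg$n_regions)]))
  regions <- region_labels(gl(band), region_table)

  within <- function(x, r) x >= r[1] & x <= r[2]
  high_true <- aei > cfg$aei_threshold
  bio12_ok <- ifelse(high_true, within(bio12, tr$bio12_high),
                     within(bio12, tr$bio12_low))
  inside <- within(bio1, tr$bio1) & within(bio4, tr$bio4) & bio12_ok &
    within(elevation, tr$elevation) & within(soil_ph, tr$soil_ph) &
    within(population, tr$population) &
    within(port_distance$values, tr$port_distance) &
    cropland >= 0.01
  present <- inside & (stats::runif(nr * nc) < cfg$banana_occupancy)
  banana_area <- matrix(0, nr, nc)
  if (cfg$banana_weight == "lognormal") {
    banana_area[present] <- stats::rlnorm(sum(present), log(50), 1)
  } else {
    banana_area[present] <- 1
  }

  layers <- list(
    bio1 = gl(bio1), bio4 = gl(bio4), bio12 = gl(bio12), bio5 = gl(bio5),
    elevation = gl(elevation), soil_ph = gl(soil_ph),
    population = gl(population), aei = gl(aei), cropland = gl(cropland),
    port_distance = port_distance, banana_area = gl(banana_area)
  )

  # estimate envelopes from the generated banana distribution, as the
  # pipeline will, then calibrate the warming offset against them
  strata <- stratify_by_irrigation(layers$aei, layers$banana_area,
                                   threshold = cfg$aei_threshold)
  criteria <- build_criteria(layers, layers$banana_area, strata)
  current_mask <- classify_suitability(criteria, layers, strata)

  delta_t <- 0
  realized <- 0
  if (cfg$loss_fraction > 0 || cfg$precip_multiplier != 1) {
    cal <- calibrate_warming(cfg, layers, strata, criteria, current_mask)
    delta_t <- cal$delta_t
    realized <- cal$realized
  }

  future <- list(
    bio1 = gl(bio1 + delta_t),
    bio4 = gl(bio4),
    bio12 = gl(bio12 * cfg$precip_multiplier),
    bio5 = gl(bio5 + delta_t)
  )

  structure(
    list(layers = layers, future = future, ports = ports, regions = regions,
         config = cfg,
         ground_truth = list(
           true_ranges = tr,
           aei_threshold = cfg$aei_threshold,
           n_banana_cells = sum(present),
           inside_cells = sum(inside),
           delta_t = delta_t,
           precip_multiplier = cfg$precip_multiplier,
           loss_target = cfg$loss_fraction,
           realized_change_km2 = realized,
           criteria = criteria,
           current_mask = current_mask
         )),
    class = "banana_scenario"
  )
}

# Find the uniform warming offset whose classified suitable-area change
# (km2 basis) equals -loss_fraction; coarse-to-fine grid search, tolerance
# 0.5 percentage points.
calibrate_warming <- function(cfg, layers, strata, criteria, current_mask) {
  areas <- grid_cell_areas(layers$bio1)$values
  cur <- current_mask$values
  cur_area <- sum(areas[!is.na(cur) & cur])
  if (cur_area <= 0) stop("no currently suitable cells to calibrate against",
                          call. = FALSE)
  fut_layers <- layers
  fut_layers$bio12 <- grid_like(layers$bio12,
                                layers$bio12$values * cfg$precip_multiplier)
  change_at <- function(dt) {
    fut_layers$bio1 <- grid_like(layers$bio1, layers$bio1$values + dt)
    m <- classify_suitability(criteria, fut_layers, strata)$values
    (sum(areas[!is.na(m) & m]) - cur_area) / cur_area
  }
  target <- -cfg$loss_fraction
  coarse <- seq(0, 12, by = 0.05)
  err <- vapply(coarse, function(dt) abs(change_at(dt) - target), numeric(1))
  best <- coarse[which.min(err)]
  fine <- seq(max(0, best - 0.05), best + 0.05, by = 0.002)
  err <- vapply(fine, function(dt) abs(change_at(dt) - target), numeric(1))
  delta_t <- fine[which.min(err)]
  realized <- change_at(delta_t)
  if (abs(realized - target) > 0.005) {
    stop(sprintf(
      "designed loss fraction %.2f not attainable (closest %.3f)",
      cfg$loss_fraction, -realized), call. = FALSE)
  }
  list(delta_t = delta_t, realized = realized)
}

#' @export
print.banana_scenario <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "<banana_scenario> %d x %d cells; %d banana cells; delta_T %.3f C\n",
    x$config$n_rows, x$config$n_cols, gt$n_banana_cells, gt$delta_t))
  invisible(x)
}

#' @method glance banana_scenario
#' @export
glance.banana_scenario <- function(x, ...) {
  gt <- x$ground_truth
  tibble::tibble(
    seed = x$config$seed,
    n_rows = x$config$n_rows,
    n_cols = x$config$n_cols,
    n_banana_cells = gt$n_banana_cells,
    delta_t = gt$delta_t,
    loss_target = gt$loss_target,
    realized_change_km2 = gt$realized_change_km2
  )
}

#' Write a scenario to a directory of plain-text artifacts
#'
#' Writes every raster layer as an ASCII grid, the ports and region tables
#' as CSV, and the designed ground-truth quantities as a key-value text
#' file, so the pipeline can be run from files alone.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scenario$layers)) {
    write_grid(scenario$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  for (nm in names(scenario$future)) {
    write_grid(scenario$future[[nm]],
               file.path(dir, paste0("future_", nm, ".asc")))
  }
  write_ports(scenario$ports, file.path(dir, "ports.csv"))
  rg <- scenario$regions$grid
  write_grid(rg, file.path(dir, "regions.asc"))
  utils::write.csv(scenario$regions$table, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  gt <- scenario$ground_truth
  lines <- c(
    sprintf("seed %d", scenario$config$seed),
    sprintf("delta_t %.17g", gt$delta_t),
    sprintf("precip_multiplier %.17g", gt$precip_multiplier),
    sprintf("loss_target %.17g", gt$loss_target),
    sprintf("realized_change_km2 %.17g", gt$realized_change_km2),
    sprintf("n_banana_cells %d", gt$n_banana_cells),
    sprintf("aei_threshold %.17g", gt$aei_threshold)
  )
  writeLines(lines, file.path(dir, "ground_truth.txt"))
  invisible(dir)
}

#' Read a scenario directory back into layer lists
#'
#' @param dir A directory written by [write_scenario()].
#' @return A list with `layers`, `future`, `ports`, `regions`.
#' @export
read_scenario <- function(dir) {
  asc <- list.files(dir, pattern = "\\.asc$", full.names = FALSE)
  current_names <- setdiff(sub("\\.asc$", "", asc),
                           c(grep("^future_", sub("\\.asc$", "", asc),
                                  value = TRUE), "regions"))
  layers <- purrr::map(rlang::set_names(current_names), function(nm) {
    read_grid(file.path(dir, paste0(nm, ".asc")))
  })
  future_names <- grep("^future_", sub("\\.asc$", "", asc), value = TRUE)
  future <- purrr::map(
    rlang::set_names(future_names, sub("^future_", "", future_names)),
    function(nm) read_grid(file.path(dir, paste0(nm, ".asc")))
  )
  ports <- read_ports(file.path(dir, "ports.csv"))
  regions <- region_labels(read_grid(file.path(dir, "regions.asc")),
                           read_region_table(file.path(dir, "regions.csv")))
  list(layers = layers, future = future, ports = ports, regions = regions)
}

#' Deterministic labelled patch fixture for map evaluation
#'
#' Lays out connected patches of exactly the requested pixel counts on a
#' background grid, separated by at least two background pixels so the
#' patches stay distinct under 8-connectivity. Each patch is a row-major
#' fill of a near-square bounding box, which is connected under both 4- and
#' 8-connectivity. Optionally flips labels at a stated corruption rate to
#' produce an imperfect "predicted" map for confusion testing.
#'
#' @param seed Seed for the corruption stream.
#' @param patch_sizes Integer vector of exact component sizes.
#' @param pixel_size Pixel edge in metres (default 10).
#' @param corruption_rate Per-pixel label-flip probability for the predicted
#'   grid (default 0 = predicted equals truth).
#' @return List with `truth` and `predicted` [label_grid()]s.
#' @export
generate_label_fixture <- function(seed = 1L, patch_sizes = integer(),
                                   pixel_size = 10, corruption_rate = 0) {
  set.seed(seed)
  patch_sizes <- as.integer(patch_sizes)
  stopifnot(all(patch_sizes >= 1))
  if (length(patch_sizes) == 0) {
    truth <- label_grid(matrix(0L, 8, 8), pixel_size)
    return(list(truth = truth, predicted = truth))
  }
  widths <- ceiling(sqrt(patch_sizes))
  heights <- ceiling(patch_sizes / widths)
  gap <- 2L
  per_row <- max(1L, floor(sqrt(length(patch_sizes))))
  slot_w <- max(widths) + gap
  slot_h <- max(heights) + gap
  n_rows_slots <- ceiling(length(patch_sizes) / per_row)
  m <- matrix(0L, n_rows_slots * slot_h + gap, per_row * slot_w + gap)
  for (i in seq_along(patch_sizes)) {
    sr <- ((i - 1L) %/% per_row) * slot_h + gap + 1L
    sc <- ((i - 1L) %% per_row) * slot_w + gap + 1L
    s <- patch_sizes[i]
    w <- widths[i]
    for (p in seq_len(s) - 1L) {
      m[sr + p %/% w, sc + p %% w] <- 1L
    }
  }
  truth <- label_grid(m, pixel_size)
  pred <- m
  if (corruption_rate > 0) {
    flip <- stats::runif(length(pred)) < corruption_rate
    pred[flip] <- 1L - pred[flip]
  }
  list(truth = truth, predicted = label_grid(pred, pixel_size))
}

#' Published validation confusion counts
#'
#' The printed test outcome of the plantation classifier: all 500 plantation
#' validation cells identified (no false negatives) and 20 of the remaining
#' 2,500 cells misclassified as plantation, of which 17 were mangrove
#' (stored as the `fp_mangrove` attribute).
#'
#' @return A [confusion_counts()] with tp = 500, fp = 20, fn = 0, tn = 2480.
#' @export
confusion_fixture <- function() {
  out <- confusion_counts(tp = 500, fp = 20, fn = 0, tn = 2480)
  attr(out, "fp_mangrove") <- 17
  out
}
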