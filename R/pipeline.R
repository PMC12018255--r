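#' Run one stage of the suitability pipeline
#'
#' Orchestrates the analysis stages end-to-end from plain-text inputs to
#' plain-text outputs, with a JSON manifest (configuration, package version,
#' input checksums) written alongside every run so results are auditable and
#' replayable. Stages:
#'
#' * `simulate` — generate a seeded synthetic scenario into `output_dir`.
#' * `envelope` — estimate irrigation strata, suitability criteria
#'   (`criteria.tsv`) and the cross-group distribution summaries
#'   (`distribution_summaries.csv`).
#' * `suitability` — current/future/unrestricted-irrigation masks,
#'   single-driver masks, the eight-way category grid and area tables.
#' * `yield` — yield-change grid and per-region weighted summary.
#' * `evaluate` — patch-filter a classified label fixture and write its
#'   confusion metrics.
#' * `report` — one consolidated summary table (suitable-area change on both
#'   bases, unrestricted-irrigation expansion, occupancy, BIO5 exposure).
#'
#' @param command One of `simulate`, `envelope`, `suitability`, `yield`,
#'   `evaluate`, `report`.
#' @param input_dir Scenario directory (all stages except `simulate`).
#' @param output_dir Directory for outputs (created if needed).
#' @param config Named list of overrides: `seed`, `level`, `crop_cover_min`,
#'   `irrigation_threshold`, `one_sided_static`, `unrestricted_irrigation`,
#'   `driver`, `connectivity`, `min_pixels`, `n_rows`, `n_cols`,
#'   `loss_fraction`, `cardinal_t`, `cardinal_p`.
#' @return Invisibly, a list of the stage's main objects.
#' @export
run_pipeline <- function(command = c("simulate", "envelope", "suitability",
                                     "yield", "evaluate", "report"),
                         input_dir = NULL, output_dir, config = list()) {
  command <- match.arg(command)
  defaults <- list(
    seed = 1L, level = 0.90, crop_cover_min = 0.01,
    irrigation_threshold = NULL, one_sided_static = FALSE,
    unrestricted_irrigation = FALSE, driver = NULL,
    connectivity = 8, min_pixels = 50,
    n_rows = 200L, n_cols = 200L, loss_fraction = 0.60,
    cardinal_t = unclass(cardinal_temperature()),
    cardinal_p = unclass(cardinal_precipitation())
  )
  cfg <- utils::modifyList(defaults, config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  result <- switch(command,
    simulate = stage_simulate(cfg, output_dir),
    envelope = stage_envelope(cfg, input_dir, output_dir),
    suitability = stage_suitability(cfg, input_dir, output_dir),
    yield = stage_yield(cfg, input_dir, output_dir),
    evaluate = stage_evaluate(cfg, output_dir),
    report = stage_report(cfg, input_dir, output_dir)
  )
  write_manifest(command, cfg, input_dir, output_dir)
  invisible(result)
}

write_manifest <- function(command, cfg, input_dir, output_dir) {
  checksums <- NULL
  if (!is.null(input_dir) && dir.exists(input_dir)) {
    files <- list.files(input_dir, full.names = TRUE)
    checksums <- as.list(tools::md5sum(files))
    names(checksums) <- basename(files)
  }
  manifest <- list(
    command = command,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    package_version = as.character(utils::packageVersion("bananaclim")),
    input_checksums = checksums
  )
  jsonlite::write_json(manifest,
                       file.path(output_dir,
                                 paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_simulate <- function(cfg, output_dir) {
  sc_cfg <- scenario_config(seed = cfg$seed, n_rows = cfg$n_rows,
                            n_cols = cfg$n_cols,
                            loss_fraction = cfg$loss_fraction)
  scenario <- generate_scenario(sc_cfg)
  write_scenario(scenario, output_dir)
  scenario
}

load_inputs <- function(input_dir) {
  if (is.null(input_dir) || !dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir, call. = FALSE)
  }
  sc <- read_scenario(input_dir)
  needed <- c(climate_vars, static_vars, "aei", "cropland", "banana_area")
  missing <- setdiff(needed, names(sc$layers))
  if (length(missing) > 0) {
    stop("scenario is missing layers: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sc
}

fit_criteria <- function(cfg, sc) {
  strata <- stratify_by_irrigation(sc$layers$aei, sc$layers$banana_area,
                                   threshold = cfg$irrigation_threshold)
  scenario_kind <- if (isTRUE(cfg$unrestricted_irrigation)) {
    "unrestricted_irrigation"
  } else {
    "observed"
  }
  criteria <- build_criteria(sc$layers, sc$layers$banana_area, strata,
                             scenario = scenario_kind, level = cfg$level,
                             crop_cover_min = cfg$crop_cover_min,
                             one_sided_static = cfg$one_sided_static)
  list(strata = strata, criteria = criteria)
}

stage_envelope <- function(cfg, input_dir, output_dir) {
  sc <- load_inputs(input_dir)
  fit <- fit_criteria(cfg, sc)
  write_criteria(fit$criteria, file.path(output_dir, "criteria.tsv"))
  summaries <- distribution_summaries(
    sc$layers[c(climate_vars, static_vars)],
    sc$layers$banana_area, sc$layers$cropland
  )
  utils::write.csv(summaries,
                   file.path(output_dir, "distribution_summaries.csv"),
                   row.names = FALSE)
  list(criteria = fit$criteria, strata = fit$strata, summaries = summaries)
}

future_layers_of <- function(sc) {
  layers <- sc$layers
  for (v in names(sc$future)) layers[[v]] <- sc$future[[v]]
  layers
}

stage_suitability <- function(cfg, input_dir, output_dir) {
  sc <- load_inputs(input_dir)
  fit <- fit_criteria(cfg, sc)
  fut <- future_layers_of(sc)

  cur_mask <- classify_suitability(fit$criteria, sc$layers, fit$strata)
  fut_mask <- classify_suitability(fit$criteria, fut, fit$strata)
  merged_criteria <- build_criteria(sc$layers, sc$layers$banana_area,
                                    fit$strata,
                                    scenario = "unrestricted_irrigation",
                                    level = cfg$level,
                                    crop_cover_min = cfg$crop_cover_min,
                                    one_sided_static = cfg$one_sided_static)
  unres_mask <- classify_suitability(merged_criteria, fut, fit$strata)
  temp_mask <- single_driver_mask(fit$criteria, sc$layers, sc$future,
                                  fit$strata, "temperature")
  prec_mask <- single_driver_mask(fit$criteria, sc$layers, sc$future,
                                  fit$strata, "precipitation")

  masks <- list(current = cur_mask, future = fut_mask,
                future_unrestricted_irrigation = unres_mask,
                future_temperature_only = temp_mask,
                future_precipitation_only = prec_mask)
  for (nm in names(masks)) {
    write_grid(grid_like(masks[[nm]], masks[[nm]]$values + 0),
               file.path(output_dir, paste0("mask_", nm, ".asc")))
  }

  cats <- categorize(sc$layers$banana_area, cur_mask, fut_mask)
  write_grid(grid_like(cats$grid, cats$grid$values + 0),
             file.path(output_dir, "categories.asc"))
  utils::write.csv(cats$table, file.path(output_dir, "category_codes.csv"),
                   row.names = FALSE)
  areas <- category_areas(cats)
  utils::write.csv(areas, file.path(output_dir, "category_areas.csv"),
                   row.names = FALSE)
  change <- area_change(cur_mask, fut_mask)
  utils::write.csv(change, file.path(output_dir, "area_change.csv"),
                   row.names = FALSE)
  list(masks = masks, categories = cats, category_areas = areas,
       change = change, criteria = fit$criteria, strata = fit$strata)
}

stage_yield <- function(cfg, input_dir, output_dir) {
  sc <- load_inputs(input_dir)
  ct <- do.call(cardinal_values, cfg$cardinal_t)
  cp <- do.call(cardinal_values, cfg$cardinal_p)
  delta <- yield_change_grid(sc$layers$bio1, sc$layers$bio12,
                             sc$future$bio1, sc$future$bio12, ct, cp)
  write_grid(delta, file.path(output_dir, "yield_change.asc"))
  summary <- yield_change_summary(delta, sc$layers$banana_area, sc$regions)
  utils::write.csv(summary, file.path(output_dir, "yield_by_region.csv"),
                   row.names = FALSE)
  list(delta = delta, summary = summary)
}

stage_evaluate <- function(cfg, output_dir) {
  fix <- generate_label_fixture(seed = cfg$seed, patch_sizes = 1:100,
                                corruption_rate = 0.02)
  filtered <- patch_filter(fix$predicted, min_pixels = cfg$min_pixels,
                           connectivity = cfg$connectivity)
  counts <- confusion_from_grids(fix$predicted, fix$truth)
  metrics <- confusion_metrics(counts)
  utils::write.csv(cbind(tidy.confusion_counts(counts), metrics),
                   file.path(output_dir, "map_metrics.csv"),
                   row.names = FALSE)
  writeLines(
    apply(filtered$values, 1, paste, collapse = " "),
    file.path(output_dir, "filtered_labels.txt")
  )
  list(filtered = filtered, counts = counts, metrics = metrics)
}

stage_report <- function(cfg, input_dir, output_dir) {
  sc <- load_inputs(input_dir)
  fit <- fit_criteria(cfg, sc)
  fut <- future_layers_of(sc)
  cur_mask <- classify_suitability(fit$criteria, sc$layers, fit$strata)
  fut_mask <- classify_suitability(fit$criteria, fut, fit$strata)
  merged_criteria <- build_criteria(sc$layers, sc$layers$banana_area,
                                    fit$strata,
                                    scenario = "unrestricted_irrigation",
                                    level = cfg$level,
                                    crop_cover_min = cfg$crop_cover_min,
                                    one_sided_static = cfg$one_sided_static)
  unres_mask <- classify_suitability(merged_criteria, fut, fit$strata)

  change <- area_change(cur_mask, fut_mask)
  unres_change <- area_change(fut_mask, unres_mask)
  occ <- occupancy_fraction(sc$layers$banana_area, cur_mask)
  expo <- exposure_summary(sc$layers$bio5, sc$future$bio5,
                           list(current_suitable = cur_mask))
  report <- tibble::tibble(
    quantity = c(
      "suitable_area_change_km2", "suitable_area_change_cells",
      "unrestricted_irrigation_expansion_km2",
      "occupancy_fraction",
      "mean_bio5_current_suitable_now", "mean_bio5_current_suitable_future"
    ),
    value = c(
      change$change[change$basis == "km2"],
      change$change[change$basis == "cells"],
      unres_change$change[unres_change$basis == "km2"],
      occ,
      expo$mean_bio5[expo$period == "current"],
      expo$mean_bio5[expo$period == "future"]
    )
  )
  utils::write.csv(report, file.path(output_dir, "report.csv"),
                   row.names = FALSE)
  list(report = report, change = change, unrestricted_change = unres_change)
}
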