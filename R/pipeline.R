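# Orchestration: a single run configuration (YAML-backed) and the
# end-to-end pipeline preprocess -> district level -> street level ->
# verification, with structured logging of thresholds fired and
# conservation checks.

#' Default run configuration
#'
#' All numeric knobs of the pipeline with their standard defaults: the
#' extraction-completeness thresholds (`t1 = t2 = t = 0.20`,
#' `dmax = 1` person/m2), cell sizes (250 m district, 50 m street), and the
#' local Moran settings (queen contiguity, 999 permutations, alpha 0.05).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    t1 = 0.20, t2 = 0.20, t = 0.20, dmax = 1.0,
    district_cell_size = 250, street_cell_size = 50,
    r2_min = 0.5,
    lisa = list(contiguity = "queen", n_perm = 999, alpha = 0.05),
    scenario = NULL, seed = 1L,
    buildings = NULL, rq_units = NULL, nrq_units = NULL,
    communities = NULL, streets = NULL,
    street_census = NULL, community_census = NULL,
    field_map = list(category = "category"),
    out_dir = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (k in c("t1", "t2", "t", "dmax", "district_cell_size", "street_cell_size")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) abort(paste0("config field ", k, " must be non-negative"))
  }
  if (cfg$district_cell_size %% cfg$street_cell_size != 0) {
    abort("district cell size must be a multiple of the street cell size")
  }
  if (is.null(cfg$scenario)) {
    for (k in c("buildings", "streets", "communities", "street_census", "community_census")) {
      if (is.null(cfg[[k]])) {
        abort(paste0("config needs either a scenario or a path for ", k))
      } else if (is.character(cfg[[k]]) && !file.exists(cfg[[k]])) {
        abort(paste0("config path for ", k, " does not exist: ", cfg[[k]]))
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys override [default_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  do.call(default_config, yaml::read_yaml(path))
}

log_add <- function(log, stage, event, value) {
  bind_rows(log, tibble(stage = stage, event = event, value = as.character(value)))
}

#' Run the full multi-level pipeline
#'
#' Stages run in order: obtain inputs (simulate a scenario, or load and
#' preprocess the configured layers), fit and map the district level, map
#' the street level, then verify (local Moran's I on the district grid,
#' street-grid aggregation and cross-level relative error, occupancy
#' histogram). Every stage logs its inputs, fired thresholds and
#' conservation checks; any failure aborts with a stage-specific message.
#'
#' @param config A `run_config` from [default_config()] or
#'   [read_run_config()].
#' @return A list of class `popgrid_run`: `buildings`, `street_aggregates`,
#'   `model`, `corrected`, `district_grid`, `community_densities`,
#'   `street_grid`, `lisa`, `crossval`, `occupancy`, `log`, and
#'   `conservation` (per-level relative errors of grid totals against
#'   censuses).
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(unclass(config))
  log <- tibble(stage = character(), event = character(), value = character())

  if (!is.null(config$scenario)) {
    city <- generate_city(scenario(config$scenario, seed = config$seed))
    buildings <- city$buildings
    streets <- city$streets
    communities <- city$communities
    street_census <- city$street_census
    community_census <- city$community_census
    log <- log_add(log, "input", "scenario", config$scenario)
  } else {
    buildings <- read_buildings(config$buildings, field_map = config$field_map)
    streets <- read_admin_units(config$streets, "street")
    communities <- read_admin_units(config$communities, "community")
    rq <- if (!is.null(config$rq_units)) read_admin_units(config$rq_units, "residential_quarter") else tibble(id = character(), geometry = list())
    nrq <- if (!is.null(config$nrq_units)) read_admin_units(config$nrq_units, "non_residential_quarter") else NULL
    pre <- preprocess_buildings(buildings, nrq, rq, communities, streets)
    buildings <- pre$buildings
    log <- log_add(log, "preprocess", "deleted", pre$report$deleted)
    log <- log_add(log, "preprocess", "unattributed", length(pre$report$unattributed[[1]]))
    street_census <- read_census(config$street_census)
    community_census <- read_census(config$community_census)
  }
  log <- log_add(log, "input", "buildings", nrow(buildings))

  # district level
  agg <- aggregate_streets(buildings, street_census)
  agg <- extraction_complete(agg, t1 = config$t1, t2 = config$t2)
  log <- log_add(log, "district", "incomplete_streets", sum(!agg$complete))
  agg <- augment_residential(agg, buildings, t1 = config$t1, t2 = config$t2)
  model <- fit_density_model(agg, r2_min = config$r2_min)
  log <- log_add(log, "district", "merged", model$merged)
  log <- log_add(log, "district", "r_squared", signif(model$r_squared, 6))
  corrected <- correct_coefficients(model)
  dspec <- grid_from_extent(buildings$geometry, config$district_cell_size)
  district_grid <- disaggregate_district(buildings, corrected, dspec)
  cons_d <- abs(grid_total(district_grid) - sum(model$streets$population)) /
    sum(model$streets$population)
  log <- log_add(log, "district", "conservation_rel_err", signif(cons_d, 3))
  if (cons_d > 1e-6) abort("district grid total does not conserve the street censuses")

  # street level
  cagg <- aggregate_communities(buildings, community_census)
  cagg <- extraction_complete_community(cagg, t = config$t, dmax = config$dmax)
  log <- log_add(log, "street", "incomplete_communities", sum(!cagg$complete))
  cagg <- augment_residential_community(cagg, buildings, t = config$t, dmax = config$dmax)
  dens <- community_density(cagg)
  sspec <- grid_spec(
    dspec$origin_x, dspec$origin_y, config$street_cell_size,
    dspec$n_cols * config$district_cell_size / config$street_cell_size,
    dspec$n_rows * config$district_cell_size / config$street_cell_size
  )
  street_grid <- disaggregate_street(buildings, dens, sspec)
  cons_s <- abs(grid_total(street_grid) - sum(dens$P)) / max(1, sum(dens$P))
  log <- log_add(log, "street", "conservation_rel_err", signif(cons_s, 3))
  if (cons_s > 1e-6) abort("street grid total does not conserve the community censuses")

  # verification
  lisa <- local_morans_i(
    district_grid,
    contiguity = config$lisa$contiguity, n_perm = config$lisa$n_perm,
    alpha = config$lisa$alpha, seed = config$seed
  )
  factor <- config$district_cell_size / config$street_cell_size
  log <- log_add(log, "validate", "aggregation_factor", factor)
  cv <- cross_validate(district_grid, aggregate_grid(street_grid, factor))
  occupancy <- grid_occupancy(street_grid)

  out <- structure(
    list(
      buildings = buildings, street_aggregates = agg, model = model,
      corrected = corrected, district_grid = district_grid,
      community_densities = dens, street_grid = street_grid,
      lisa = lisa, crossval = cv, occupancy = occupancy,
      conservation = tibble(
        level = c("district", "street"), relative_error = c(cons_d, cons_s)
      ),
      log = log
    ),
    class = "popgrid_run"
  )
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' @export
print.popgrid_run <- function(x, ...) {
  cat("<popgrid_run>\n")
  cat(sprintf(
    "  district grid: %d cells, total %.1f\n",
    length(x$district_grid$values), grid_total(x$district_grid)
  ))
  cat(sprintf(
    "  street grid:   %d cells, total %.1f\n",
    length(x$street_grid$values), grid_total(x$street_grid)
  ))
  cat(sprintf(
    "  model: %s, R^2 = %.3f\n",
    if (x$model$merged) "merged (2 classes)" else "4 classes", x$model$r_squared
  ))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_grid(run$district_grid, file.path(out_dir, "district_grid.csv"))
  write_grid(run$street_grid, file.path(out_dir, "street_grid.csv"))
  readr::write_csv(tidy(run$model), file.path(out_dir, "model_coefficients.csv"))
  readr::write_csv(run$corrected, file.path(out_dir, "corrected_coefficients.csv"))
  readr::write_csv(
    run$community_densities[, c("community_id", "street_id", "C1", "C2", "P", "density")],
    file.path(out_dir, "community_densities.csv")
  )
  readr::write_csv(run$lisa, file.path(out_dir, "lisa.csv"))
  readr::write_csv(run$crossval$histogram, file.path(out_dir, "crossval_histogram.csv"))
  readr::write_csv(run$occupancy, file.path(out_dir, "occupancy.csv"))
  readr::write_csv(run$log, file.path(out_dir, "log.csv"))
  invisible(out_dir)
}
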