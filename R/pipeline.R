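#' Pipeline configuration
#'
#' One declarative object driving [run_pipeline()]: the synthetic study-area
#' configuration (or a study-area directory written by
#' [write_study_area()]), the scenario list, horizon, seed and carbon
#' parameters. Round-trips losslessly through YAML.
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param years simulation horizon (default 13 annual iterations).
#' @param calibration_years length of the synthetic calibration window.
#' @param scenarios character vector of scenario names.
#' @param synth a [synth_config()] (used when `study_area_dir` is NULL).
#' @param study_area_dir optional directory of study-area inputs.
#' @param carbon a [carbon_params()].
#' @param road road-feedback options (see [run_scenario()]).
#' @param windows fuzzy-validation window sizes.
#' @param out_dir output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, years = 13, calibration_years = 5,
                            scenarios = c("BASELINE", "CODE1965", "CODE2012"),
                            synth = synth_config(seed = seed),
                            study_area_dir = NULL,
                            carbon = carbon_params(),
                            road = list(enabled = TRUE, budget_km = 3, beta = 1),
                            windows = c(1, 3, 5, 7, 9, 11),
                            out_dir = tempfile("forestca_run_")) {
  structure(list(seed = seed, years = years, calibration_years = calibration_years,
                 scenarios = scenarios, synth = synth,
                 study_area_dir = study_area_dir, carbon = carbon, road = road,
                 windows = windows, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a [pipeline_config()]; `path` a YAML file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$synth <- unclass(x$synth)
  x$synth$true_rates <- as.data.frame(x$synth$true_rates)
  x$carbon <- unclass(x$carbon)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  synth_args <- x$synth
  if (!is.null(synth_args$true_rates)) {
    synth_args$true_rates <- rate_table(as.data.frame(
      lapply(synth_args$true_rates, unlist)))
  }
  synth_args$river_spec <- lapply(synth_args$river_spec, function(r) r)
  synth_args$road_spec <- lapply(synth_args$road_spec, function(p) {
    matrix(unlist(p), ncol = 2)
  })
  cfg <- pipeline_config(
    seed = x$seed, years = x$years, calibration_years = x$calibration_years,
    scenarios = unlist(x$scenarios),
    synth = do.call(synth_config, synth_args),
    study_area_dir = x$study_area_dir,
    carbon = do.call(carbon_params, x$carbon),
    road = x$road, windows = unlist(x$windows),
    out_dir = x$out_dir)
  cfg
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' One command from inputs to report: generate (or load) the study area,
#' evolve it under the true rates to create the calibration pair, build each
#' scenario's region map, calibrate per scenario, simulate, account carbon,
#' validate against a held-out evolved map, and write rasters, ledgers and
#' CSV reports to the output directory. Deterministic given the seed; each
#' stage logs its parameters, and a failing stage raises an error naming it
#' while earlier stages' outputs remain on disk.
#'
#' @param cfg a [pipeline_config()] or the path to its YAML form.
#' @return Invisibly, a list: `landscape`, `fits`, `runs`, `ledgers`,
#'   `summaries`, `similarity`, `comparison`, `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logf))
  stage <- function(name, expr) {
    log_line(logf, "stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  landscape <- stage("synth", {
    if (!is.null(cfg$study_area_dir)) {
      read_study_area(cfg$study_area_dir)
    } else {
      syn <- generate_landscape(cfg$synth)
      write_study_area(syn, file.path(cfg$out_dir, "study_area"))
      syn
    }
  })
  log_line(logf, sprintf("  landscape %dx%d, seed %d", nrow(landscape$landcover$values),
                         ncol(landscape$landcover$values), cfg$seed))

  # calibration pair: evolve t0 under the true rates for the window length
  lc_t1 <- stage("evolve", {
    evolve_landscape(landscape$landcover, landscape$true_rates,
                     years = cfg$calibration_years,
                     seed = child_seed(cfg$seed, "calibration-pair"),
                     variables = landscape$static)
  })
  write_grid(lc_t1, file.path(cfg$out_dir, "landcover_t1.asc"))

  lc <- landscape$landcover
  nr <- nrow(lc$values); nc <- ncol(lc$values)
  fits <- list(); runs <- list(); ledgers <- list(); summaries <- list()
  for (sc_name in cfg$scenarios) {
    sc <- scenario_config(sc_name)
    regions <- stage(paste0("regions-", sc_name), {
      app <- app_buffer(landscape$rivers, app_rule(), sc$app_reference,
                        nr, nc, lc$cell_size, lc$xll, lc$yll)
      build_regions(landscape$cu_mask, landscape$il_mask, landscape$rivers,
                    landscape$roads, app, sc, lc_2008 = landscape$lc2008,
                    template = lc)
    })
    write_grid(regions, file.path(cfg$out_dir, paste0("regions_", sc_name, ".asc")))
    fit <- stage(paste0("calibrate-", sc_name), {
      lucc_fit(lc, lc_t1, landscape$static, regions = regions,
               years = cfg$calibration_years)
    })
    write_rates(fit$rates, file.path(cfg$out_dir, paste0("rates_", sc_name, ".csv")))
    write_weights(fit$weights, file.path(cfg$out_dir, paste0("weights_", sc_name, ".csv")))
    run <- stage(paste0("simulate-", sc_name), {
      run_scenario(fit, landscape, sc, years = cfg$years,
                   seed = child_seed(cfg$seed, "simulate"), regions = regions,
                   road = cfg$road,
                   initial_secondary_age = cfg$carbon$initial_secondary_age)
    })
    write_grid(run$states[[length(run$states)]]$lc,
               file.path(cfg$out_dir, paste0("landcover_final_", sc_name, ".asc")))
    utils::write.csv(run$areas,
                     file.path(cfg$out_dir, paste0("areas_", sc_name, ".csv")),
                     row.names = FALSE)
    ledger <- stage(paste0("carbon-", sc_name), {
      carbon_ledger(run$states, landscape$biomass, cfg$carbon,
                    regions = regions, scenario = sc_name)
    })
    utils::write.csv(as.data.frame(ledger),
                     file.path(cfg$out_dir, paste0("carbon_", sc_name, ".csv")),
                     row.names = FALSE)
    fits[[sc_name]] <- fit
    runs[[sc_name]] <- run
    ledgers[[sc_name]] <- ledger
    summaries[[sc_name]] <- summarize_carbon(ledger, run$states)
    log_line(logf, sprintf("  %s: mean annual forest loss %.2f km2, cumulative net %.0f MgC",
                           sc_name, summaries[[sc_name]]$mean_annual_forest_loss_km2,
                           summaries[[sc_name]]$cumulative_net_MgC))
  }

  similarity <- stage("validate", {
    # reproduce the calibration window with the baseline fit and score the
    # simulated change against the "real" (evolved) change
    sc0 <- scenario_config(cfg$scenarios[1])
    fit0 <- fits[[cfg$scenarios[1]]]
    rerun <- run_scenario(fit0, landscape, sc0, years = cfg$calibration_years,
                          seed = child_seed(cfg$seed, "validation"),
                          regions = runs[[cfg$scenarios[1]]]$regions,
                          road = list(enabled = FALSE))
    sim_t1 <- rerun$states[[length(rerun$states)]]$lc
    fuzzy_similarity(lc, lc_t1, sim_t1, windows = cfg$windows)
  })
  utils::write.csv(similarity, file.path(cfg$out_dir, "similarity.csv"),
                   row.names = FALSE)

  comparison <- stage("report", {
    finals <- lapply(runs, function(r) r$states[[length(r$states)]]$lc)
    cmp <- compare_scenarios(lc, finals)
    utils::write.csv(cmp$change, file.path(cfg$out_dir, "scenario_change.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp$pairwise, file.path(cfg$out_dir, "scenario_pairwise.csv"),
                     row.names = FALSE)
    cmp
  })
  log_line(logf, "pipeline complete")
  invisible(list(landscape = landscape, fits = fits, runs = runs,
                 ledgers = ledgers, summaries = summaries,
                 similarity = similarity, comparison = comparison,
                 out_dir = cfg$out_dir))
}

#' Read a study area written by [write_study_area()]
#'
#' @param dir directory containing the ASCII grids, GeoJSON vectors and the
#'   true-rates CSV.
#' @return The same list structure [generate_landscape()] returns.
#' @export
read_study_area <- function(dir) {
  lc <- read_grid(file.path(dir, "landcover_t0.asc"), role = "landcover")
  static <- list(
    dist_road = read_grid(file.path(dir, "dist_road.asc")),
    dist_river = read_grid(file.path(dir, "dist_river.asc")),
    altitude = read_grid(file.path(dir, "altitude.asc")),
    slope = read_grid(file.path(dir, "slope.asc")))
  msk <- function(f) read_grid(file.path(dir, f), role = "mask")$values == 1
  roads_net <- read_rivers(file.path(dir, "roads.geojson"))
  list(
    landcover = lc,
    static = static,
    rivers = read_rivers(file.path(dir, "rivers.geojson")),
    roads = lapply(roads_net$reaches, `[[`, "coords"),
    cu_mask = msk("cu.asc"),
    il_mask = msk("il.asc"),
    urban_mask = msk("urban.asc"),
    biomass = read_grid(file.path(dir, "biomass.asc"), role = "biomass"),
    lc2008 = read_grid(file.path(dir, "landcover_2008.asc"), role = "landcover"),
    true_rates = read_rates(file.path(dir, "true_rates.csv")))
}
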