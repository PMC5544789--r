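#' Run a scenario simulation
#'
#' Projects a calibrated model forward under one scenario's rules: builds
#' (or accepts) the scenario's region map, applies the leakage transfer when
#' the scenario demands it, then iterates the cellular automaton one year at
#' a time with optional road-network feedback. Each iteration is a year.
#'
#' @param model a [lucc_fit()] model calibrated on `regions` (or on a
#'   compatible region map).
#' @param landscape study-area list as produced by [generate_landscape()]
#'   (fields `landcover`, `static`, `rivers`, `roads`, `cu_mask`, `il_mask`,
#'   `urban_mask`, `lc2008`).
#' @param scenario a [scenario_config()].
#' @param years number of annual iterations (default 13).
#' @param seed integer seed for all stochastic allocation.
#' @param regions region `grid_map`; built from the landscape and scenario
#'   when `NULL`.
#' @param road list of road-feedback options: `enabled` (default TRUE),
#'   `budget_km` per year, `beta`, `n_targets`.
#' @param pruning_factor candidate-pool multiplier for [allocate()].
#' @param initial_secondary_age age given to secondary vegetation in the
#'   start map (years).
#' @param start_year calendar label of the start map (default 0).
#' @return An object of class `sim_result`: `states` (list of [ca_state()]s,
#'   one per year incl. the start), `areas` (per-year class areas), the
#'   region map, the rate table actually used (after leakage), the final
#'   road network, and the scenario.
#' @export
run_scenario <- function(model, landscape, scenario, years = 13, seed = 1,
                         regions = NULL, road = list(), pruning_factor = 10,
                         initial_secondary_age = 5, start_year = 0L) {
  stopifnot(inherits(model, "lucc_model"), inherits(scenario, "scenario_config"))
  road <- utils::modifyList(list(enabled = TRUE, budget_km = 3, beta = 1,
                                 n_targets = 1), road)
  lc <- landscape$landcover
  nr <- nrow(lc$values); nc <- ncol(lc$values); cs <- lc$cell_size
  if (is.null(regions)) {
    app <- app_buffer(landscape$rivers, app_rule(), scenario$app_reference,
                      nr, nc, cs, lc$xll, lc$yll)
    regions <- build_regions(landscape$cu_mask, landscape$il_mask,
                             landscape$rivers, landscape$roads, app, scenario,
                             lc_2008 = landscape$lc2008, template = lc)
  }
  rates <- model$rates

  # leakage: displaced APP demand moves into receiving regions' net
  # secondary-cutting rates, proportional to their secondary source areas
  if (scenario$leakage_enabled) {
    reg <- regions$values; v <- lc$values
    appm <- !is.na(reg) & reg == region_code("APP")
    app_demand <- vapply(TRANSITIONS[c("F2D", "S2D")], function(tr) {
      from <- lc_code(transition_from(tr))
      get_rate_fb(rates, "APP", tr) * sum(appm & !is.na(v) & v == from)
    }, numeric(1))
    recv_regions <- setdiff(region_name(sort(unique(reg[!is.na(reg)]))),
                            c("APP", "APP2008"))
    receiving <- vapply(recv_regions, function(rn) {
      sum(!is.na(reg) & reg == region_code(rn) & !is.na(v) &
            v == lc_code("SECONDARY"))
    }, numeric(1))
    rates <- leakage_transfer(rates, app_demand, receiving)
  }

  static <- landscape$static
  roads_now <- landscape$roads
  state <- ca_state(lc, year = start_year,
                    initial_secondary_age = initial_secondary_age,
                    roads = roads_now)
  states <- list(state)
  road_cells_per_region <- function(rd) {
    m <- rasterize_lines(rd, nr, nc, cs, lc$xll, lc$yll)
    tab <- table(regions$values[m])
    stats::setNames(as.numeric(tab) * cs / 1000, region_name(as.integer(names(tab))))
  }
  with_seed(child_seed(seed, "sim"), {
    for (y in seq_len(years)) {
      if (road$enabled && road$budget_km > 0) {
        fric <- friction_surface(static, landscape$cu_mask, landscape$il_mask)
        before <- road_cells_per_region(roads_now)
        built <- build_roads(roads_now, fric, road$budget_km,
                             seed = child_seed(seed, paste0("roads-", y)),
                             cell_size = cs, n_targets = road$n_targets,
                             xll = lc$xll, yll = lc$yll)
        if (built$new_km > 0) {
          roads_now <- built$roads
          after <- road_cells_per_region(roads_now)
          regs <- union(names(before), names(after))
          aft <- ifelse(is.na(after[regs]), 0, after[regs])
          bef <- ifelse(is.na(before[regs]), 0, before[regs])
          new_len <- stats::setNames(pmax(aft - bef, 0), regs)
          net_len <- stats::setNames(aft, regs)
          rates <- update_rates(rates, as.list(new_len), as.list(pmax(net_len, 1e-9)),
                                beta = road$beta)
          rm <- rasterize_lines(roads_now, nr, nc, cs, lc$xll, lc$yll)
          static$dist_road <- grid_map(distance_to(rm, cs), cell_size = cs,
                                       xll = lc$xll, yll = lc$yll)
        }
      }
      state <- ca_step(state, rates, regions, weights = model$weights,
                       variables = static, restrictions = scenario$forbidden,
                       urban_mask = landscape$urban_mask,
                       pruning_factor = pruning_factor)
      state$roads <- roads_now
      states[[y + 1L]] <- state
    }
  })
  areas <- do.call(rbind, lapply(states, function(st) {
    cbind(data.frame(year = st$year), class_areas(st$lc))
  }))
  structure(list(states = states, areas = areas, regions = regions,
                 rates_used = rates, roads = roads_now, scenario = scenario,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  yrs <- range(vapply(x$states, `[[`, integer(1), "year"))
  cat(sprintf("<sim_result '%s'> years %d-%d\n", x$scenario$name, yrs[1], yrs[2]))
  a0 <- x$areas[x$areas$year == yrs[1], ]
  a1 <- x$areas[x$areas$year == yrs[2], ]
  chg <- merge(a0, a1, by = "class", suffixes = c("_start", "_end"))
  chg <- chg[, c("class", "area_km2_start", "area_km2_end")]
  print(chg, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sim_result <- function(x, classes = c("FOREST", "DEFORESTED", "SECONDARY"), ...) {
  a <- x$areas[x$areas$class %in% classes, ]
  w <- stats::reshape(a, direction = "wide", idvar = "year", timevar = "class")
  graphics::matplot(w$year, as.matrix(w[, -1]), type = "l", lty = 1,
                    xlab = "year", ylab = "area (km2)",
                    main = x$scenario$name, ...)
  graphics::legend("right", legend = classes, lty = 1,
                   col = seq_along(classes), bty = "n")
  invisible(x)
}

#' Simulate land-cover trajectories from a fitted model
#'
#' `simulate()` method for `lucc_model`: runs the cellular automaton `nsim`
#' times with independent seeds and returns the runs.
#'
#' @param object a `lucc_model`.
#' @param nsim number of replicate runs.
#' @param seed integer master seed (replicate r uses a derived child seed).
#' @param landscape,scenario,years,... passed to [run_scenario()].
#' @return A list of `sim_result` (length `nsim`); a single `sim_result`
#'   when `nsim = 1`.
#' @export
simulate.lucc_model <- function(object, nsim = 1, seed = 1, landscape,
                                scenario = scenario_config("BASELINE"),
                                years = 13, ...) {
  runs <- lapply(seq_len(nsim), function(r) {
    run_scenario(object, landscape, scenario, years = years,
                 seed = child_seed(seed, paste0("rep", r)), ...)
  })
  if (nsim == 1) runs[[1]] else runs
}

#' Residual change of a simulated run against a reference map
#'
#' @param object a `sim_result`.
#' @param reference observed land-cover map at the final year; when given,
#'   residuals are the per-class area differences (observed minus
#'   simulated); otherwise the per-year realized-minus-demanded conversion
#'   residue is returned (always within one patch of zero).
#' @param ... unused.
#' @export
residuals.sim_result <- function(object, reference = NULL, ...) {
  if (!is.null(reference)) {
    last <- object$states[[length(object$states)]]$lc
    return(quantitative_validation(reference, last))
  }
  unlist(object$states[[length(object$states)]]$residual %||% list())
}
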