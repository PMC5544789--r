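#' Carbon-accounting parameters
#'
#' Constants of the committed-emission bookkeeping: the carbon fraction of
#' dry forest biomass (0.485), the carbon fraction of secondary-vegetation
#' dry biomass (0.45), the linear biomass growth rate of secondary
#' vegetation (Mg dry biomass/ha/yr; site-dependent, default 10 — supply a
#' literature value for real landscapes), and the mean age assigned to
#' secondary vegetation present in the initial map (5 years).
#'
#' @param forest_carbon_fraction,secondary_carbon_fraction fractions in (0,1).
#' @param secondary_growth Mg/ha/yr, >= 0.
#' @param initial_secondary_age years.
#' @param secondary_biomass_cap optional cap (Mg/ha) on accumulated
#'   secondary biomass; `Inf` (default) leaves accumulation uncapped over
#'   the short simulation horizon.
#' @return An object of class `carbon_params`.
#' @export
carbon_params <- function(forest_carbon_fraction = 0.485,
                          secondary_carbon_fraction = 0.45,
                          secondary_growth = 10,
                          initial_secondary_age = 5,
                          secondary_biomass_cap = Inf) {
  stopifnot(forest_carbon_fraction > 0, forest_carbon_fraction < 1,
            secondary_carbon_fraction > 0, secondary_carbon_fraction < 1,
            secondary_growth >= 0, initial_secondary_age >= 0)
  structure(list(forest_carbon_fraction = forest_carbon_fraction,
                 secondary_carbon_fraction = secondary_carbon_fraction,
                 secondary_growth = secondary_growth,
                 initial_secondary_age = initial_secondary_age,
                 secondary_biomass_cap = secondary_biomass_cap),
            class = "carbon_params")
}

#' Forest carbon density from a biomass map
#'
#' Multiplies total (above- plus below-ground) dry biomass by the forest
#' carbon fraction, cellwise.
#'
#' @param biomass a biomass `grid_map` (Mg/ha).
#' @param params a [carbon_params()].
#' @return A `grid_map` of carbon density (MgC/ha).
#' @export
forest_carbon <- function(biomass, params = carbon_params()) {
  grid_map(biomass$values * params$forest_carbon_fraction,
           cell_size = biomass$cell_size, xll = biomass$xll, yll = biomass$yll,
           nodata = biomass$nodata, role = "biomass")
}

#' Secondary-vegetation carbon density at a given age
#'
#' Linear accumulation: carbon fraction x growth rate x age, optionally
#' capped.
#'
#' @param age stand age in years (scalar, vector or matrix).
#' @param params a [carbon_params()].
#' @return Carbon density, MgC/ha, same shape as `age`.
#' @export
secondary_carbon <- function(age, params = carbon_params()) {
  stopifnot(all(age >= 0, na.rm = TRUE))
  b <- pmin(params$secondary_growth * age, params$secondary_biomass_cap)
  params$secondary_carbon_fraction * b
}

#' Annual net carbon emission between two consecutive states
#'
#' Committed (instantaneous) accounting: gross emission is the full carbon
#' content of forest cells cleared plus of secondary cells cut this year (at
#' their age when cut); uptake is the carbon accumulated by cells that
#' remain in, or enter, secondary vegetation; net = gross - uptake. The
#' ledger identity stock(t) - stock(t+1) = net(t+1) holds exactly because
#' both sides are computed from the same cellwise densities.
#'
#' @param state_t,state_t1 consecutive [ca_state()]s (years must differ by 1).
#' @param fcarbon forest carbon-density `grid_map` (MgC/ha), from
#'   [forest_carbon()].
#' @param params a [carbon_params()].
#' @return One-row data.frame: year, gross_MgC, uptake_MgC, net_MgC.
#' @export
annual_emission <- function(state_t, state_t1, fcarbon, params = carbon_params()) {
  if (state_t1$year != state_t$year + 1L) {
    stop("states must be consecutive years (got ", state_t$year, " and ", state_t1$year, ")")
  }
  v0 <- state_t$lc$values; v1 <- state_t1$lc$values
  a0 <- state_t$age; a1 <- state_t1$age
  area_ha <- cell_area_ha(state_t$lc)
  fc <- fcarbon$values

  f2d <- !is.na(v0) & !is.na(v1) & v0 == lc_code("FOREST") & v1 == lc_code("DEFORESTED")
  s_lost <- !is.na(v0) & !is.na(v1) & v0 == lc_code("SECONDARY") &
    v1 != lc_code("SECONDARY")
  gross <- sum(fc[f2d]) * area_ha + sum(secondary_carbon(a0[s_lost], params)) * area_ha

  sec1 <- !is.na(v1) & v1 == lc_code("SECONDARY")
  prev <- ifelse(!is.na(v0) & v0 == lc_code("SECONDARY"), a0, 0)
  uptake <- sum(secondary_carbon(a1[sec1], params) -
                  secondary_carbon(prev[sec1], params)) * area_ha

  data.frame(year = state_t1$year, gross_MgC = gross, uptake_MgC = uptake,
             net_MgC = gross - uptake)
}

#' Carbon ledger of a simulated trajectory
#'
#' Computes the stock and emission series of a run: per year, the total
#' carbon stock (forest + secondary), the gross committed emission, the
#' secondary-vegetation uptake and the net emission. Satisfies
#' stock(t) - stock(t+1) = net(t+1).
#'
#' @param states list of consecutive [ca_state()]s (a `sim_result$states`).
#' @param biomass biomass `grid_map` (Mg/ha).
#' @param params a [carbon_params()].
#' @param regions optional region `grid_map`: adds a per-region breakdown
#'   attribute `"by_region"`.
#' @param scenario scenario name recorded in the output.
#' @return data.frame of class `carbon_ledger`: year, scenario, stock_MgC,
#'   gross_MgC, uptake_MgC, net_MgC.
#' @export
carbon_ledger <- function(states, biomass, params = carbon_params(),
                          regions = NULL, scenario = NA_character_) {
  fc <- forest_carbon(biomass, params)
  area_ha <- cell_area_ha(states[[1]]$lc)
  stock_of <- function(st) {
    v <- st$lc$values
    f <- !is.na(v) & v == lc_code("FOREST")
    s <- !is.na(v) & v == lc_code("SECONDARY")
    (sum(fc$values[f]) + sum(secondary_carbon(st$age[s], params))) * area_ha
  }
  rows <- data.frame(year = states[[1]]$year, scenario = scenario,
                     stock_MgC = stock_of(states[[1]]),
                     gross_MgC = 0, uptake_MgC = 0, net_MgC = 0)
  by_region <- NULL
  for (i in seq_along(states)[-1]) {
    em <- annual_emission(states[[i - 1]], states[[i]], fc, params)
    rows <- rbind(rows, data.frame(year = em$year, scenario = scenario,
                                   stock_MgC = stock_of(states[[i]]),
                                   gross_MgC = em$gross_MgC,
                                   uptake_MgC = em$uptake_MgC,
                                   net_MgC = em$net_MgC))
  }
  if (!is.null(regions)) {
    by_region <- region_stocks(states, fc, params, regions, area_ha, scenario)
  }
  structure(rows, by_region = by_region, class = c("carbon_ledger", "data.frame"))
}

region_stocks <- function(states, fc, params, regions, area_ha, scenario) {
  reg <- regions$values
  out <- list()
  for (rg in sort(unique(reg[!is.na(reg)]))) {
    rname <- region_name(rg)
    m <- !is.na(reg) & reg == rg
    for (st in states) {
      v <- st$lc$values
      f <- m & !is.na(v) & v == lc_code("FOREST")
      s <- m & !is.na(v) & v == lc_code("SECONDARY")
      out[[length(out) + 1L]] <- data.frame(
        year = st$year, scenario = scenario, region = rname,
        stock_MgC = (sum(fc$values[f]) + sum(secondary_carbon(st$age[s], params))) * area_ha)
    }
  }
  do.call(rbind, out)
}

#' Summarize a simulation run's ledger and areas
#'
#' Per-scenario totals: cumulative net emission, stock change, mean annual
#' forest loss (total forest-area reduction divided by the number of annual
#' iterations, i.e. the year span of the states) and per-region stock-loss
#' percentages when a regional breakdown is present.
#'
#' @param ledger a [carbon_ledger()], or `NULL` for area-only summaries.
#' @param states the simulated state list the ledger was computed from.
#' @return list with `mean_annual_forest_loss_km2`, `total_forest_loss_km2`,
#'   `cumulative_net_MgC`, `stock_change_MgC`, and `region_loss_pct` (or
#'   NULL).
#' @export
summarize_carbon <- function(ledger = NULL, states) {
  first <- states[[1]]; last <- states[[length(states)]]
  a0 <- class_areas(first$lc); a1 <- class_areas(last$lc)
  floss <- a0$area_km2[a0$class == "FOREST"] - a1$area_km2[a1$class == "FOREST"]
  iters <- last$year - first$year
  br <- if (is.null(ledger)) NULL else attr(ledger, "by_region")
  region_loss <- NULL
  if (!is.null(br)) {
    w <- stats::reshape(br[, c("year", "region", "stock_MgC")],
                        direction = "wide", idvar = "region", timevar = "year")
    v0 <- w[[2]]; v1 <- w[[ncol(w)]]
    region_loss <- data.frame(region = w$region,
                              loss_pct = ifelse(v0 > 0, 100 * (v0 - v1) / v0, 0))
  }
  list(mean_annual_forest_loss_km2 = floss / max(iters, 1L),
       total_forest_loss_km2 = floss,
       cumulative_net_MgC = if (is.null(ledger)) NA_real_ else sum(ledger$net_MgC),
       stock_change_MgC = if (is.null(ledger)) NA_real_ else
         ledger$stock_MgC[1] - ledger$stock_MgC[nrow(ledger)],
       region_loss_pct = region_loss)
}
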