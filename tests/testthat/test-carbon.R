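test_that("forest carbon is biomass times the carbon fraction", {
  b <- grid_map(matrix(c(400, 0, 250, 100), 2, 2), role = "biomass")
  fc <- forest_carbon(b)
  expect_equal(fc$values[1, 1], 194)
  expect_equal(fc$values[2, 1], 0)
  expect_equal(fc$values, b$values * 0.485)
})

test_that("secondary carbon accumulates linearly with age", {
  expect_equal(secondary_carbon(0), 0)
  expect_equal(secondary_carbon(5, carbon_params(secondary_growth = 10)), 22.5)
  ages <- 0:12
  dens <- secondary_carbon(ages)
  expect_true(all(diff(dens) > 0))
  expect_equal(diff(dens), rep(dens[2], 12))  # constant annual increment
  capped <- carbon_params(secondary_growth = 10, secondary_biomass_cap = 30)
  expect_equal(secondary_carbon(10, capped), 0.45 * 30)
})

test_that("annual emissions follow committed accounting", {
  b <- grid_map(matrix(400, 4, 4), role = "biomass")
  fc <- forest_carbon(b)
  lc0 <- make_lc("FOREST", 4, 4)
  st0 <- ca_state(lc0, 0)

  # no transitions, no secondary: net zero
  st1 <- st0; st1$year <- 1L
  em <- annual_emission(st0, st1, fc)
  expect_equal(em$net_MgC, 0)

  # one cleared 0.09-ha cell of 194 MgC/ha emits 17.46 MgC
  v1 <- lc0$values; v1[1, 1] <- LC_CODES[["DEFORESTED"]]
  st1b <- st1; st1b$lc <- make_lc(v1)
  em <- annual_emission(st0, st1b, fc)
  expect_equal(em$gross_MgC, 194 * 0.09)
  expect_equal(em$net_MgC, 17.46)

  # a pure-regrowth year has negative net emission
  vd <- matrix(LC_CODES[["DEFORESTED"]], 4, 4)
  std0 <- ca_state(make_lc(vd), 0)
  vs <- matrix(LC_CODES[["SECONDARY"]], 4, 4)
  std1 <- ca_state(make_lc(vs), 0, initial_secondary_age = 1)
  std1$year <- 1L
  em <- annual_emission(std0, std1, fc)
  expect_lt(em$net_MgC, 0)

  expect_error(annual_emission(st0, st0, fc), "consecutive")
})

test_that("the ledger identity holds along a simulated trajectory", {
  syn <- shared_landscape()
  regions <- grid_map(matrix(REGION_CODES[["IA"]], 100, 100), role = "region")
  rts <- rate_table(data.frame(region = "IA", transition = unname(TRANSITIONS),
                               rate = c(0.03, 0.10, 0.12)))
  st <- ca_state(syn$landcover, 0, 5)
  states <- list(st)
  set.seed(12)
  for (y in 1:6) { st <- ca_step(st, rts, regions); states[[y + 1]] <- st }
  led <- carbon_ledger(states, syn$biomass)
  resid <- -diff(led$stock_MgC) - led$net_MgC[-1]
  expect_true(all(abs(resid) <= 1e-6 * pmax(abs(led$net_MgC[-1]), 1)))
})

test_that("stocks never decrease when clearing is forbidden", {
  syn <- shared_landscape()
  regions <- grid_map(matrix(REGION_CODES[["IA"]], 100, 100), role = "region")
  regrow_only <- rate_table(data.frame(region = "IA",
                                       transition = unname(TRANSITIONS),
                                       rate = c(0, 0.10, 0)))
  st <- ca_state(syn$landcover, 0, 5)
  states <- list(st)
  set.seed(13)
  for (y in 1:5) { st <- ca_step(st, regrow_only, regions); states[[y + 1]] <- st }
  led <- carbon_ledger(states, syn$biomass)
  expect_true(all(diff(led$stock_MgC) >= 0))
  expect_true(all(led$net_MgC <= 0))
})

test_that("summaries report mean annual loss over the year span", {
  syn <- shared_landscape()
  regions <- grid_map(matrix(REGION_CODES[["IA"]], 100, 100), role = "region")
  rts <- rate_table(data.frame(region = "IA", transition = TRANSITIONS[["F2D"]],
                               rate = 0.05))
  st <- ca_state(syn$landcover, 0, 5)
  set.seed(14)
  st1 <- ca_step(st, rts, regions)
  led <- carbon_ledger(list(st, st1), syn$biomass, regions = regions,
                       scenario = "unit")
  s <- summarize_carbon(led, list(st, st1))
  a0 <- class_areas(st$lc); a1 <- class_areas(st1$lc)
  loss <- a0$area_km2[a0$class == "FOREST"] - a1$area_km2[a1$class == "FOREST"]
  expect_equal(s$mean_annual_forest_loss_km2, loss)   # single year: the mean is it
  expect_equal(s$total_forest_loss_km2, loss)
  expect_s3_class(s$region_loss_pct, "data.frame")
})
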