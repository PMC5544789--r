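test_that("the APP width-class rule matches the statutory table", {
  expect_equal(app_buffer_width(150), 100)
  expect_equal(app_buffer_width(700), 500)
  expect_equal(app_buffer_width(c(5, 25, 40, 55, 250, 601)),
               c(30, 30, 50, 100, 200, 500))
  expect_error(app_buffer_width(0), "positive")
  expect_error(app_rule(data.frame(min_width = c(0, 40), max_width = c(30, 60),
                                   buffer_m = c(30, 50))), "gaps")
  expect_error(app_rule(data.frame(min_width = c(0, 30), max_width = c(30, Inf),
                                   buffer_m = c(50, 30))), "non-decreasing")
})

test_that("the 1965-rule APP contains the 2012-rule APP", {
  rv <- straight_river(width = 150, maxlevel = 450, y = 1500)
  reg <- app_buffer(rv, app_rule(), "REGULAR_CHANNEL", 100, 100, 30)
  mx <- app_buffer(rv, app_rule(), "MAX_WATER_LEVEL", 100, 100, 30)
  expect_gte(sum(mx$values), sum(reg$values))
  # with a floodplain strictly wider than the channel the containment is strict
  expect_gt(sum(mx$values), sum(reg$values))
})

test_that("region assembly follows the documented precedence", {
  syn <- shared_landscape()
  lc <- syn$landcover
  nr <- nrow(lc$values); nc <- ncol(lc$values)
  app <- app_buffer(syn$rivers, app_rule(), "MAX_WATER_LEVEL", nr, nc, 30)
  sc <- scenario_config("CODE1965")
  reg <- build_regions(syn$cu_mask, syn$il_mask, syn$rivers, syn$roads, app, sc,
                       template = lc)
  appm <- app$values == 1
  # CU overrides APP
  both <- appm & syn$cu_mask
  if (any(both)) expect_true(all(reg$values[both] == REGION_CODES[["CU"]]))
  # APP overrides IL and the residual isolated areas
  il_app <- appm & syn$il_mask & !syn$cu_mask
  road_mask <- forestca:::rasterize_lines(syn$roads, nr, nc, 30)
  ir <- forestca:::distance_to(road_mask, 30) <= 900
  if (any(il_app & !ir)) {
    expect_true(all(reg$values[il_app & !ir] == REGION_CODES[["APP"]]))
  }
  # IR overrides APP
  if (any(appm & ir & !syn$cu_mask)) {
    expect_true(all(reg$values[appm & ir & !syn$cu_mask] == REGION_CODES[["IR"]]))
  }
  # every land cell carries exactly one region code
  expect_true(all(reg$values[!is.na(lc$values)] %in% REGION_CODES))

  # APP2008 appears only under the 2012 Code, and needs the 2008 map
  expect_false(any(reg$values == REGION_CODES[["APP2008"]], na.rm = TRUE))
  sc12 <- scenario_config("CODE2012")
  expect_error(build_regions(syn$cu_mask, syn$il_mask, syn$rivers, syn$roads,
                             app, sc12, template = lc), "2008")
  app12 <- app_buffer(syn$rivers, app_rule(), "REGULAR_CHANNEL", nr, nc, 30)
  reg12 <- build_regions(syn$cu_mask, syn$il_mask, syn$rivers, syn$roads, app12,
                         sc12, lc_2008 = syn$lc2008, template = lc)
  expect_true(any(reg12$values == REGION_CODES[["APP2008"]], na.rm = TRUE))

  # without wide rivers there is no river-buffer region
  narrow <- river_network(list(list(coords = cbind(c(0, 3000), c(1500, 1500)),
                                    regular_width_m = 10, maxlevel_width_m = 20)))
  app_n <- app_buffer(narrow, app_rule(), "MAX_WATER_LEVEL", nr, nc, 30)
  reg_n <- build_regions(syn$cu_mask, syn$il_mask, narrow, syn$roads, app_n, sc,
                         template = lc)
  expect_false(any(reg_n$values == REGION_CODES[["RB"]], na.rm = TRUE))
})

test_that("scenario configs encode the statutory rules", {
  b <- scenario_config("BASELINE")
  expect_equal(nrow(b$forbidden), 0)
  expect_false(b$leakage_enabled)
  s65 <- scenario_config("CODE1965")
  expect_true(s65$leakage_enabled)
  expect_equal(s65$app_reference, "MAX_WATER_LEVEL")
  expect_error(scenario_config("CODE1965", leakage_enabled = FALSE), "leakage")
  s12 <- scenario_config("CODE2012")
  expect_equal(s12$app_reference, "REGULAR_CHANNEL")
  expect_equal(s12$regions_used, 7)
  # secondary cutting stays permitted in APP2008
  expect_false(any(s12$forbidden$region == "APP2008" &
                     s12$forbidden$transition == TRANSITIONS[["S2D"]]))
})

test_that("leakage transfer conserves displaced demand", {
  rt <- rate_table(data.frame(
    region = c("APP", "APP", "IR", "RB"),
    transition = c(TRANSITIONS[["F2D"]], TRANSITIONS[["S2D"]],
                   TRANSITIONS[["S2D"]], TRANSITIONS[["S2D"]]),
    rate = c(0.03, 0.05, 0.02, 0.02)))

  unchanged <- leakage_transfer(rt, c(0, 0), c(IR = 400, RB = 600))
  expect_equal(unchanged$rate[unchanged$region %in% c("IR", "RB")],
               rt$rate[rt$region %in% c("IR", "RB")])
  expect_true(all(unchanged$rate[unchanged$region == "APP" &
    unchanged$transition != TRANSITIONS[["D2S"]]] == 0))

  # 100 cells/yr into regions with 400 and 600 secondary cells: both
  # increments are 0.10, and increments times source areas re-sum to 100
  out <- leakage_transfer(rt, c("FOREST>DEFORESTED" = 100), c(IR = 400, RB = 600))
  inc_ir <- out$rate[out$region == "IR"] - 0.02
  inc_rb <- out$rate[out$region == "RB"] - 0.02
  expect_equal(inc_ir, 0.10)
  expect_equal(inc_rb, 0.10)
  expect_equal(inc_ir * 400 + inc_rb * 600, 100)

  expect_warning(leakage_transfer(rt, c(50), numeric(0)), "dropped")
})
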