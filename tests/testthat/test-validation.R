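test_that("fuzzy similarity is 1 for identical change maps and grows with window", {
  syn <- shared_landscape()
  t1 <- evolve_landscape(syn$landcover, syn$true_rates, 2, seed = 30,
                         variables = syn$static)
  res <- fuzzy_similarity(syn$landcover, t1, t1, windows = c(1, 3, 5))
  expect_true(all(res$similarity == 1))

  t1b <- evolve_landscape(syn$landcover, syn$true_rates, 2, seed = 31,
                          variables = syn$static)
  res2 <- fuzzy_similarity(syn$landcover, t1, t1b, windows = c(1, 3, 5, 7, 9))
  expect_true(all(diff(res2$similarity) >= 0))
  expect_true(all(res2$similarity >= 0 & res2$similarity <= 1))
  # the min of the two directions is reported
  expect_equal(res2$similarity, pmin(res2$real_to_sim, res2$sim_to_real))
})

test_that("single-cell offsets score 0 at 1x1 and 1 at 3x3", {
  v0 <- matrix(LC_CODES[["FOREST"]], 9, 9)
  real1 <- v0; real1[5, 5] <- LC_CODES[["DEFORESTED"]]
  sim1 <- v0; sim1[5, 6] <- LC_CODES[["DEFORESTED"]]
  res <- fuzzy_similarity(make_lc(v0), make_lc(real1), make_lc(sim1),
                          windows = c(1, 3))
  expect_equal(res$similarity, c(0, 1))

  # far-apart changes never match at the tested windows
  simfar <- v0; simfar[1, 1] <- LC_CODES[["DEFORESTED"]]
  resf <- fuzzy_similarity(make_lc(v0), make_lc(real1), make_lc(simfar),
                           windows = c(1, 3, 5))
  expect_true(all(resf$similarity == 0))

  # different change types do not match even when collocated
  simtype <- v0; simtype[5, 5] <- LC_CODES[["SECONDARY"]]
  rest <- fuzzy_similarity(make_lc(v0), make_lc(real1), make_lc(simtype),
                           windows = 3)
  expect_equal(rest$similarity, 0)

  # no change anywhere: similarity is undefined
  resna <- fuzzy_similarity(make_lc(v0), make_lc(v0), make_lc(v0), windows = 3)
  expect_true(is.na(resna$similarity))

  expect_error(fuzzy_similarity(make_lc(v0), make_lc(real1), make_lc(sim1),
                                windows = 2), "odd")
})

test_that("exponential decay scores are bounded by the crisp scores", {
  v0 <- matrix(LC_CODES[["FOREST"]], 9, 9)
  real1 <- v0; real1[5, 5] <- LC_CODES[["DEFORESTED"]]
  sim1 <- v0; sim1[5, 7] <- LC_CODES[["DEFORESTED"]]
  crisp <- fuzzy_similarity(make_lc(v0), make_lc(real1), make_lc(sim1),
                            windows = 5)
  expo <- fuzzy_similarity(make_lc(v0), make_lc(real1), make_lc(sim1),
                           windows = 5, decay = "exponential")
  expect_lte(expo$similarity, crisp$similarity)
  expect_gt(expo$similarity, 0)
})

test_that("quantitative validation reports signed per-class differences", {
  syn <- shared_landscape()
  same <- quantitative_validation(syn$landcover, syn$landcover)
  expect_true(all(same$absolute_km2 == 0))

  # simulation overshooting a class gives a negative absolute difference
  v <- syn$landcover$values
  sim <- v
  idx <- which(v == LC_CODES[["FOREST"]])[1:10]
  sim[idx] <- LC_CODES[["SECONDARY"]]
  qv <- quantitative_validation(syn$landcover, make_lc(sim))
  expect_lt(qv$absolute_km2[qv$class == "SECONDARY"], 0)
  expect_gt(qv$absolute_km2[qv$class == "FOREST"], 0)
  # hand-counted differences on the constructed example
  expect_equal(qv$absolute_km2[qv$class == "FOREST"], 10 * 9e-4)
  expect_equal(qv$percent[qv$class == "FOREST"],
               10 * 9e-4 / (sum(v == LC_CODES[["FOREST"]]) * 9e-4) * 100)
  # differences sum to zero when the maps share their footprint
  expect_equal(sum(qv$absolute_km2), 0)
})

test_that("scenario comparison is self-consistent", {
  syn <- shared_landscape()
  t1 <- evolve_landscape(syn$landcover, syn$true_rates, 3, seed = 33,
                         variables = syn$static)
  cmp <- compare_scenarios(syn$landcover, list(A = syn$landcover, B = t1))
  a_rows <- cmp$change[cmp$change$scenario == "A", ]
  expect_true(all(a_rows$change_pct == 0, na.rm = TRUE))
  # percentages recomputed from the report's own areas agree
  b_rows <- cmp$change[cmp$change$scenario == "B", ]
  ok <- b_rows$initial_km2 > 0
  expect_equal(b_rows$change_pct[ok],
               100 * (b_rows$final_km2[ok] - b_rows$initial_km2[ok]) /
                 b_rows$initial_km2[ok])
  # pairwise differences match the change table
  pw <- cmp$pairwise
  expect_equal(pw$diff_km2,
               a_rows$final_km2 - b_rows$final_km2)
})
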