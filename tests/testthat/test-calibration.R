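# constructs a 1000-cell landscape where 100 forest cells transition and a
# binary evidence layer takes value 1 on a chosen share of each group
make_woe_case <- function(p_bin_T = 0.5, p_bin_N = 0.25, n = 1000, n_T = 100) {
  v0 <- matrix(LC_CODES[["FOREST"]], 25, 40)
  v1 <- v0
  v1[seq_len(n_T)] <- LC_CODES[["DEFORESTED"]]
  x <- matrix(0, 25, 40)
  x[seq_len(round(p_bin_T * n_T))] <- 1
  idx_N <- (n_T + 1):n
  x[idx_N[seq_len(round(p_bin_N * length(idx_N)))]] <- 1
  list(t0 = make_lc(v0), t1 = make_lc(v1),
       vars = list(layer = grid_map(x + 0L, role = "generic")),
       in_bin = x == 1, event = as.vector(v1 == LC_CODES[["DEFORESTED"]]))
}

test_that("weights of evidence match the brute-force contingency oracle", {
  case <- make_woe_case(0.5, 0.25)
  w <- suppressWarnings(compute_weights(case$t0, case$t1, case$vars,
                                        bins = list(layer = list(type = "categorical"))))
  w1 <- w$weight[w$transition == TRANSITIONS[["F2D"]] &
                   w$variable == "layer" & w$bin_low == 1]
  expect_equal(w1, log(2), tolerance = 1e-12)
  expect_equal(w1, woe_oracle(case$in_bin, case$event), tolerance = 1e-12)

  # bin occupied proportionally by both groups carries no evidence
  even <- make_woe_case(0.4, 0.4)
  we <- suppressWarnings(compute_weights(even$t0, even$t1, even$vars,
                                         bins = list(layer = list(type = "categorical"))))
  expect_equal(we$weight[we$transition == TRANSITIONS[["F2D"]] &
                           we$bin_low == 1], 0, tolerance = 1e-12)

  # absent transition: all weights zero, with a warning
  same <- make_woe_case()
  expect_warning(
    w0 <- compute_weights(same$t0, same$t0, same$vars,
                          transitions = TRANSITIONS[["F2D"]]),
    "no .* transitions")
  expect_true(all(w0$weight == 0))
})

test_that("posterior probability combines weights on the log-odds scale", {
  case <- make_woe_case(0.5, 0.25)
  w <- suppressWarnings(compute_weights(case$t0, case$t1, case$vars,
                                        bins = list(layer = list(type = "categorical"))))
  # all-zero weights leave the prior untouched
  w0 <- w; w0$weight <- 0
  attr(w0, "bins") <- attr(w, "bins")
  expect_equal(posterior_probability(w0, 0.37, list(layer = 1)), 0.37)
  # prior 0.2 with a single ln 2 weight: odds 0.25 * 2 -> P = 1/3
  wln2 <- w; wln2$weight <- ifelse(wln2$bin_low == 1, log(2), 0)
  attr(wln2, "bins") <- attr(w, "bins")
  expect_equal(posterior_probability(wln2, 0.2, list(layer = 1)), 1 / 3,
               tolerance = 1e-12)
  # monotone in the weight
  probs <- vapply(c(0, 0.5, 1, 2), function(b) {
    wb <- w; wb$weight <- ifelse(wb$bin_low == 1, b, 0)
    attr(wb, "bins") <- attr(w, "bins")
    posterior_probability(wb, 0.2, list(layer = 1))
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("posterior equals exhaustive contingency Bayes for two independent layers", {
  # counts constructed to satisfy conditional independence exactly
  n_T <- 100; n_N <- 900
  pa_T <- 0.6; pb_T <- 0.5; pa_N <- 0.3; pb_N <- 0.4
  cells_T <- expand.grid(a = c(1, 0), b = c(1, 0))
  cells_T$n <- round(n_T * c(pa_T * pb_T, (1 - pa_T) * pb_T,
                             pa_T * (1 - pb_T), (1 - pa_T) * (1 - pb_T)))
  cells_N <- cells_T
  cells_N$n <- round(n_N * c(pa_N * pb_N, (1 - pa_N) * pb_N,
                             pa_N * (1 - pb_N), (1 - pa_N) * (1 - pb_N)))
  stopifnot(sum(cells_T$n) == n_T, sum(cells_N$n) == n_N)
  a <- integer(0); b <- integer(0); ev <- logical(0)
  for (i in seq_len(4)) {
    a <- c(a, rep(cells_T$a[i], cells_T$n[i]), rep(cells_N$a[i], cells_N$n[i]))
    b <- c(b, rep(cells_T$b[i], cells_T$n[i]), rep(cells_N$b[i], cells_N$n[i]))
    ev <- c(ev, rep(TRUE, cells_T$n[i]), rep(FALSE, cells_N$n[i]))
  }
  nr <- 25; nc <- 40
  v0 <- matrix(LC_CODES[["FOREST"]], nr, nc)
  v1 <- v0; v1[ev] <- LC_CODES[["DEFORESTED"]]
  vars <- list(A = grid_map(matrix(a, nr, nc), role = "generic"),
               B = grid_map(matrix(b, nr, nc), role = "generic"))
  bins <- list(A = list(type = "categorical"), B = list(type = "categorical"))
  w <- suppressWarnings(compute_weights(make_lc(v0), make_lc(v1), vars, bins))
  prior <- n_T / (n_T + n_N)
  for (av in 0:1) for (bv in 0:1) {
    post <- posterior_probability(w, prior, list(A = av, B = bv),
                                  transition = TRANSITIONS[["F2D"]])
    exact <- sum(ev & a == av & b == bv) / sum(a == av & b == bv)
    expect_equal(post, exact, tolerance = 1e-10)
  }
})

test_that("weights are invariant to the order bin breaks are supplied in", {
  syn <- shared_landscape()
  lc1 <- evolve_landscape(syn$landcover, syn$true_rates, 2, seed = 8,
                          variables = syn$static)
  br <- c(0, 300, 900, 1800, 6000)
  w1 <- suppressWarnings(compute_weights(
    syn$landcover, lc1, syn$static["dist_road"],
    bins = list(dist_road = list(type = "continuous", breaks = br))))
  w2 <- suppressWarnings(compute_weights(
    syn$landcover, lc1, syn$static["dist_road"],
    bins = list(dist_road = list(type = "continuous", breaks = rev(br)))))
  expect_equal(w1$weight, w2$weight)
})

test_that("transition rates annualize correctly", {
  lc <- make_lc("FOREST", 25, 40)
  expect_true(all(suppressWarnings(compute_rates(lc, lc, years = 5))$rate == 0))

  # 50 of 1000 forest cells cleared over 5 years -> annual 0.010206
  v1 <- lc$values; v1[seq_len(50)] <- LC_CODES[["DEFORESTED"]]
  rt <- suppressWarnings(compute_rates(lc, make_lc(v1), years = 5))
  expect_equal(rt$rate[rt$transition == TRANSITIONS[["F2D"]]],
               1 - (1 - 0.05)^(1 / 5), tolerance = 1e-9)

  # one-year window: annual rate equals the period fraction exactly
  rt1 <- suppressWarnings(compute_rates(lc, make_lc(v1), years = 1))
  expect_equal(rt1$rate[rt1$transition == TRANSITIONS[["F2D"]]], 0.05)

  # zero source cells warn (once per empty transition) and give rate 0
  lcd <- make_lc("DEFORESTED", 5, 5)
  warns <- capture_warnings(rz <- compute_rates(lcd, lcd, years = 1))
  expect_match(warns, "no source cells", all = TRUE)
  expect_length(warns, 2)  # forest and secondary sources are both absent
  expect_true(all(rz$rate == 0))
})

test_that("rates and weights serialize losslessly to CSV", {
  syn <- shared_landscape()
  lc1 <- evolve_landscape(syn$landcover, syn$true_rates, 2, seed = 4,
                          variables = syn$static)
  fit <- suppressWarnings(lucc_fit(syn$landcover, lc1, syn$static, years = 2))
  rp <- withr::local_tempfile(fileext = ".csv")
  wp <- withr::local_tempfile(fileext = ".csv")
  write_rates(fit$rates, rp)
  write_weights(fit$weights, wp)
  rt <- read_rates(rp)
  expect_equal(rt$rate, fit$rates$rate, tolerance = 1e-12)
  expect_equal(attr(rt, "patch")$expander_fraction,
               attr(fit$rates, "patch")$expander_fraction, tolerance = 1e-12)
  wb <- read_weights(wp)
  expect_equal(wb$weight, fit$weights$weight, tolerance = 1e-12)
})

test_that("the fitted model exposes coef, predict and print methods", {
  syn <- shared_landscape()
  lc1 <- evolve_landscape(syn$landcover, syn$true_rates, 3, seed = 21,
                          variables = syn$static)
  fit <- suppressWarnings(lucc_fit(syn$landcover, lc1, syn$static, years = 3))
  cf <- coef(fit)
  expect_named(cf)
  expect_true(all(cf >= 0 & cf <= 1))
  p <- predict(fit, syn$static, transition = TRANSITIONS[["F2D"]], region = "NONE")
  expect_s3_class(p, "grid_map")
  expect_true(all(p$values > 0 & p$values < 1, na.rm = TRUE))
  # cells near roads are more susceptible than remote cells
  d <- syn$static$dist_road$values
  expect_gt(mean(p$values[d < 300]), mean(p$values[d > 2000]))
  expect_output(print(fit), "transition rates")
  expect_output(print(summary(fit)), "Patch geometry")
})
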