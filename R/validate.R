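#' Multi-window fuzzy similarity of simulated vs observed change
#'
#' Compares the two change maps (cells whose class differs between t0 and
#' t1, labelled by their from-to transition) with a moving-window crisp
#' (constant-decay) fuzzy score: a changed cell earns credit 1 if a cell
#' with the same change lies within the k x k window, else 0. The
#' directional score is the mean credit over that map's changed cells, and
#' the reported value per window is the minimum of the two directions
#' (real vs simulated and simulated vs real). Scores are non-decreasing in
#' window size and equal 1 for identical change maps. Optional exponential
#' distance decay replaces the crisp credit with exp(-d/halfdist).
#'
#' @param real_t0,real_t1 observed land-cover pair.
#' @param sim_t1 simulated map at t1 (shares `real_t0` as its start).
#' @param windows odd window sizes (default 1,3,5,7,9,11).
#' @param decay `"constant"` (crisp, default) or `"exponential"`.
#' @param halfdist half-distance in cells for exponential decay.
#' @return data.frame of class `similarity_result`: window, similarity,
#'   plus the two directional scores. `similarity` is `NA` (undefined) when
#'   either map has no changed cells.
#' @export
fuzzy_similarity <- function(real_t0, real_t1, sim_t1,
                             windows = c(1, 3, 5, 7, 9, 11),
                             decay = c("constant", "exponential"),
                             halfdist = 2) {
  decay <- match.arg(decay)
  stopifnot(same_geometry(real_t0, real_t1), same_geometry(real_t0, sim_t1))
  if (any(windows %% 2 != 1)) stop("window sizes must be odd")
  ch_real <- change_map(real_t0, real_t1)
  ch_sim <- change_map(real_t0, sim_t1)
  n_real <- sum(!is.na(ch_real)); n_sim <- sum(!is.na(ch_sim))
  rows <- lapply(sort(windows), function(k) {
    if (n_real == 0 || n_sim == 0) {
      return(data.frame(window = k, similarity = NA_real_,
                        real_to_sim = NA_real_, sim_to_real = NA_real_))
    }
    rs <- directional_score(ch_real, ch_sim, k, decay, halfdist)
    sr <- directional_score(ch_sim, ch_real, k, decay, halfdist)
    data.frame(window = k, similarity = min(rs, sr),
               real_to_sim = rs, sim_to_real = sr)
  })
  structure(do.call(rbind, rows), class = c("similarity_result", "data.frame"))
}

# change map: transition label (small integer) where class changed, NA else
change_map <- function(lc_t0, lc_t1) {
  v0 <- lc_t0$values; v1 <- lc_t1$values
  ch <- v0 * 10L + v1
  ch[is.na(v0) | is.na(v1) | v0 == v1] <- NA
  ch
}

# mean credit of map a's changed cells against matching changes in map b
directional_score <- function(a, b, k, decay, halfdist) {
  half <- (k - 1L) %/% 2L
  nr <- nrow(a); nc <- ncol(a)
  idx <- which(!is.na(a))
  credit <- numeric(length(idx))
  r <- (idx - 1L) %% nr + 1L
  cl <- (idx - 1L) %/% nr + 1L
  for (i in seq_along(idx)) {
    rr <- max(1L, r[i] - half):min(nr, r[i] + half)
    cc <- max(1L, cl[i] - half):min(nc, cl[i] + half)
    sub <- b[rr, cc, drop = FALSE]
    hit <- which(!is.na(sub) & sub == a[idx[i]], arr.ind = TRUE)
    if (!nrow(hit)) next
    if (decay == "constant") {
      credit[i] <- 1
    } else {
      d <- sqrt((rr[hit[, 1]] - r[i])^2 + (cc[hit[, 2]] - cl[i])^2)
      credit[i] <- max(exp(-min(d) / halfdist))
    }
  }
  mean(credit)
}

#' Quantitative validation: per-class area differences
#'
#' Absolute difference (real minus simulated, km²) and percentage difference
#' relative to the real class area, per land-cover class. Overshooting a
#' class in the simulation yields a negative absolute difference.
#'
#' @param real,simulated land-cover `grid_map`s.
#' @return data.frame: class, real_km2, simulated_km2, absolute_km2,
#'   percent (NA, flagged, when the class is absent from the real map).
#' @export
quantitative_validation <- function(real, simulated) {
  stopifnot(same_geometry(real, simulated))
  a <- class_areas(real); b <- class_areas(simulated)
  abs_diff <- a$area_km2 - b$area_km2
  pct <- ifelse(a$area_km2 > 0, abs_diff / a$area_km2 * 100, NA_real_)
  if (any(is.na(pct) & abs_diff != 0)) {
    warning("class absent from the real map: percentage difference undefined")
  }
  data.frame(class = a$class, real_km2 = a$area_km2, simulated_km2 = b$area_km2,
             absolute_km2 = abs_diff, percent = pct)
}

#' Compare scenario runs against the initial map and each other
#'
#' Per class and scenario, the percentage change of the final-year area
#' relative to the initial year, plus pairwise differences in final class
#' areas between scenarios.
#'
#' @param initial land-cover `grid_map` at the common start year.
#' @param finals named list of final land-cover `grid_map`s, one per
#'   scenario.
#' @return list with `change` (class x scenario percentage-change table,
#'   with absolute areas) and `pairwise` (per class, scenario differences in
#'   final km²).
#' @export
compare_scenarios <- function(initial, finals) {
  a0 <- class_areas(initial)
  change <- do.call(rbind, lapply(names(finals), function(sc) {
    a1 <- class_areas(finals[[sc]])
    data.frame(scenario = sc, class = a0$class,
               initial_km2 = a0$area_km2, final_km2 = a1$area_km2,
               change_km2 = a1$area_km2 - a0$area_km2,
               change_pct = ifelse(a0$area_km2 > 0,
                                   100 * (a1$area_km2 - a0$area_km2) / a0$area_km2,
                                   NA_real_))
  }))
  prs <- utils::combn(names(finals), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(prs, function(pr) {
    x <- class_areas(finals[[pr[1]]]); y <- class_areas(finals[[pr[2]]])
    data.frame(scenario_a = pr[1], scenario_b = pr[2], class = x$class,
               diff_km2 = x$area_km2 - y$area_km2)
  }))
  list(change = change, pairwise = pairwise)
}
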