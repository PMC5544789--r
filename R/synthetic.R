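#' Configuration for a synthetic study area
#'
#' Bundles everything [generate_landscape()] needs to build a complete,
#' reproducible synthetic landscape: grid size, the true transition rates
#' the landscape will evolve under (the recovery target for calibration
#' tests), river and road geometry, the protected-area share and the
#' forest-biomass distribution.
#'
#' Defaults describe a plausibly Amazonian frontier landscape at 30 m
#' resolution: 2%/yr deforestation, 8%/yr regeneration of cleared land,
#' 10%/yr re-cutting of secondary vegetation, two rivers (a 20 m stream and
#' a 150 m river whose floodplain is three times the channel width), a
#' highway entering from the southern edge, 15% of the area protected, and forest biomass around
#' 350 +/- 60 Mg/ha dry weight.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param seed integer seed; the same config yields identical landscapes.
#' @param true_rates a [rate_table()]; default single-region table with the
#'   rates above under region `"NONE"`.
#' @param river_spec list of rivers, each
#'   `list(regular_width_m=, maxlevel_width_m=, frac=)` where `frac` is the
#'   vertical position of the (horizontal) river across the grid.
#' @param road_spec list of roads, each a two-column matrix of x,y map
#'   coordinates given as fractions of the grid extent.
#' @param protected_fraction share of the area assigned to CU + IL.
#' @param deforested_fraction initial share of land already cleared.
#' @param biomass_mean,biomass_sd forest dry-biomass distribution (Mg/ha).
#' @param cell_size cell edge (m).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_rows = 200, n_cols = 200, seed = 1,
                         true_rates = NULL, river_spec = NULL, road_spec = NULL,
                         protected_fraction = 0.15, deforested_fraction = 0.12,
                         biomass_mean = 350, biomass_sd = 60, cell_size = 30) {
  if (is.null(true_rates)) {
    true_rates <- rate_table(data.frame(
      region = "NONE",
      transition = unname(TRANSITIONS),
      rate = c(0.02, 0.08, 0.10)))
  }
  if (any(true_rates$rate < 0 | true_rates$rate > 1)) stop("rates must lie in [0,1]")
  if (protected_fraction < 0 || protected_fraction > 1) {
    stop("protected_fraction must lie in [0,1]")
  }
  if (is.null(river_spec)) {
    river_spec <- list(
      list(regular_width_m = 150, maxlevel_width_m = 450, frac = 0.75),
      list(regular_width_m = 20,  maxlevel_width_m = 60,  frac = 0.35))
  }
  if (is.null(road_spec)) {
    # highway entering from the southern edge, as on a typical frontier
    road_spec <- list(rbind(c(0.25, 0.00), c(0.25, 0.40)))
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, seed = seed, true_rates = true_rates,
    river_spec = river_spec, road_spec = road_spec,
    protected_fraction = protected_fraction,
    deforested_fraction = deforested_fraction,
    biomass_mean = biomass_mean, biomass_sd = biomass_sd,
    cell_size = cell_size), class = "synth_config")
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a reproducible 31-bit child seed from a parent seed and a stage tag
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# smooth Gaussian random field via repeated 3x3 box blur of white noise
smooth_field <- function(nr, nc, passes = 8) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (k in seq_len(passes)) {
    f <- (f + neighbor_sum(f)) / 9
  }
  (f - mean(f)) / stats::sd(f)
}

# sum of 8-neighbors (edge cells reuse own value for missing neighbors)
neighbor_sum <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad_r <- function(i) pmin(pmax(i, 1L), nr)
  pad_c <- function(j) pmin(pmax(j, 1L), nc)
  s <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + x[pad_r(seq_len(nr) + dr), pad_c(seq_len(nc) + dc)]
  }
  s
}

#' Generate a complete synthetic study area
#'
#' Builds a land-cover map, static evidence variables, a river network with
#' floodplains, roads, protected-area masks and a biomass map, all on one
#' grid. Initial clearing is clustered near roads and rivers (so
#' weights-of-evidence calibration has spatial signal to recover), rivers
#' carry a regular and a wider maximum-water-level width, and terrain is a
#' smoothed random field.
#'
#' @param cfg a [synth_config()].
#' @return A list with elements `landcover` (`grid_map`), `static` (named
#'   list: `dist_road`, `dist_river`, `altitude`, `slope`), `rivers`
#'   (`river_network`), `roads` (list of coordinate matrices), `cu_mask`,
#'   `il_mask`, `urban_mask` (logical matrices), `biomass` (`grid_map`),
#'   `lc2008` (an "earlier" land-cover map for APP2008 construction),
#'   `true_rates`, and `cfg`.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  nr <- cfg$n_rows; nc <- cfg$n_cols; cs <- cfg$cell_size
  if (nr < 40 || nc < 40) stop("grid too small to place the requested features (need >= 40x40)")
  W <- nc * cs; H <- nr * cs
  max_chan <- max(vapply(cfg$river_spec, `[[`, numeric(1), "maxlevel_width_m"))
  if (max_chan >= H / 2) stop("grid too small for the requested river widths")

  with_seed(cfg$seed, {
    # rivers: horizontal polylines with gentle sinuosity
    reaches <- lapply(cfg$river_spec, function(rs) {
      y0 <- rs$frac * H
      xs <- seq(0, W, length.out = 24)
      amp <- min(0.03 * H, 10 * cs)
      ys <- y0 + amp * sin(xs / W * 2 * pi + stats::runif(1, 0, 2 * pi))
      list(coords = cbind(xs, ys),
           regular_width_m = rs$regular_width_m,
           maxlevel_width_m = rs$maxlevel_width_m)
    })
    rivers <- river_network(reaches)
    water <- channel_mask(rivers, nr, nc, cs)
    flood <- floodplain_mask(rivers, nr, nc, cs)

    # roads from fractional waypoints
    roads <- lapply(cfg$road_spec, function(p) cbind(p[, 1] * W, p[, 2] * H))
    road_mask <- rasterize_lines(roads, nr, nc, cs)
    road_mask[water] <- FALSE

    d_road <- distance_to(road_mask, cs)
    d_river <- distance_to(water, cs)

    # terrain
    alt_f <- smooth_field(nr, nc, passes = 10)
    altitude <- 120 + 60 * alt_f
    altitude[water] <- pmin(altitude[water], 100)
    gx <- cbind(altitude[, 2:nc] - altitude[, 1:(nc - 1)], 0) / cs
    gy <- rbind(altitude[2:nr, ] - altitude[1:(nr - 1), ], 0) / cs
    slope <- sqrt(gx^2 + gy^2) * 100  # percent

    # initial land cover: clearing clustered near roads and rivers
    lc <- matrix(lc_code("FOREST"), nr, nc)
    lc[water] <- lc_code("WATER")
    clump <- smooth_field(nr, nc, passes = 6)
    score <- exp(-d_road / 900) + 0.6 * exp(-d_river / 900) + 0.35 * clump
    land <- !water
    n_clear <- round(cfg$deforested_fraction * sum(land))
    if (n_clear > 0) {
      ord <- order(score[land], decreasing = TRUE)
      idx_land <- which(land)
      cleared <- idx_land[ord[seq_len(n_clear)]]
      lc[cleared] <- lc_code("DEFORESTED")
      # older clearings carry secondary regrowth, clustered by a second field
      sec_f <- smooth_field(nr, nc, passes = 6)
      sec <- cleared[sec_f[cleared] > stats::quantile(sec_f[cleared], 0.75)]
      lc[sec] <- lc_code("SECONDARY")
    }

    # natural non-forest: high-altitude open patch far from rivers
    nf <- land & lc == lc_code("FOREST") & alt_f > stats::quantile(alt_f, 0.985) &
      d_river > 1500
    lc[nf] <- lc_code("NONFOREST")

    # small urban nucleus on the main road near the large river
    urban_mask <- matrix(FALSE, nr, nc)
    near <- which(road_mask & d_river < 2000 & !water)
    if (length(near)) {
      ctr <- near[which.min(d_river[near])]
      cr <- (ctr - 1L) %% nr + 1L; cc <- (ctr - 1L) %/% nr + 1L
      rr <- pmax(1, cr - 2):pmin(nr, cr + 2)
      ccs <- pmax(1, cc - 2):pmin(nc, cc + 2)
      urban_mask[rr, ccs] <- TRUE
      urban_mask <- urban_mask & !water
      lc[urban_mask] <- lc_code("URBAN")
    }

    # protected areas: two blobs in the zone far from roads
    cu_mask <- matrix(FALSE, nr, nc); il_mask <- matrix(FALSE, nr, nc)
    if (cfg$protected_fraction > 0) {
      prot_f <- smooth_field(nr, nc, passes = 10)
      eligibility <- d_road + 3000 * prot_f  # clustered, biased away from roads
      eligibility[water | urban_mask] <- -Inf
      n_prot <- round(cfg$protected_fraction * sum(land))
      ordp <- order(eligibility, decreasing = TRUE)
      prot <- ordp[seq_len(min(n_prot, length(ordp)))]
      # split by column into CU (left half of protected cells) and IL (right)
      pc <- (prot - 1L) %/% nr + 1L
      med <- stats::median(pc)
      cu_mask[prot[pc <= med]] <- TRUE
      il_mask[prot[pc > med]] <- TRUE
    }

    # biomass: spatially smooth forest biomass, strictly non-negative
    bio <- cfg$biomass_mean + cfg$biomass_sd * smooth_field(nr, nc, passes = 8)
    bio <- pmax(bio, 0)

    # an "earlier" map for APP2008: a random ~60% subset of current clearing,
    # spatially coherent (threshold on a smooth field)
    lc2008 <- lc
    cur_clear <- lc %in% c(lc_code("DEFORESTED"), lc_code("SECONDARY"))
    keep_f <- smooth_field(nr, nc, passes = 5)
    revert <- cur_clear & keep_f < stats::quantile(keep_f[cur_clear], 0.4)
    lc2008[revert] <- lc_code("FOREST")

    gm <- function(v, role = "generic") grid_map(v, cell_size = cs, role = role)
    list(
      landcover = gm(lc, "landcover"),
      static = list(dist_road = gm(d_road), dist_river = gm(d_river),
                    altitude = gm(altitude), slope = gm(slope)),
      rivers = rivers,
      roads = roads,
      cu_mask = cu_mask,
      il_mask = il_mask,
      urban_mask = urban_mask,
      biomass = gm(bio, "biomass"),
      lc2008 = gm(lc2008, "landcover"),
      true_rates = cfg$true_rates,
      cfg = cfg)
  })
}

#' Evolve a land cover map under known transition rates
#'
#' The synthetic "true model": each year, for each region and each of the
#' three transitions, a binomial number of source cells converts
#' (expectation = rate x source count) and the converting cells are sampled
#' with probability proportional to a multiplicative function of the
#' evidence layers (nearness to roads and rivers favours clearing), i.e. the
#' same conditional-independence family the weights-of-evidence calibrator
#' assumes. Realized per-region annual fractions therefore converge to the
#' true rates as the cell count grows.
#'
#' @param lc land-cover `grid_map` at t0.
#' @param true_rates a [rate_table()] (regions must match `regions`, or a
#'   single `"NONE"` row applied everywhere).
#' @param years number of annual steps (>= 1).
#' @param seed integer seed.
#' @param variables optional static list with `dist_road` / `dist_river`
#'   used for the spatial preference; uniform allocation when absent.
#' @param regions optional region `grid_map`.
#' @return The land-cover `grid_map` after `years` steps.
#' @export
evolve_landscape <- function(lc, true_rates, years, seed, variables = NULL,
                             regions = NULL) {
  stopifnot(inherits(lc, "grid_map"), years >= 1)
  v <- lc$values
  reg <- if (is.null(regions)) matrix(0L, nrow(v), ncol(v)) else regions$values
  pref <- evolve_preference(variables, dim(v))
  with_seed(seed, {
    for (yr in seq_len(years)) {
      v_next <- v
      for (rg in sort(unique(reg[!is.na(reg)]))) {
        rname <- region_name(rg)
        for (tr in TRANSITIONS) {
          rate <- get_rate(true_rates, rname, tr)
          if (rate == 0 && rname != "NONE") {
            # fall back to the catch-all region if this one has no row
            if (!any(true_rates$region == rname)) rate <- get_rate(true_rates, "NONE", tr)
          }
          if (rate <= 0) next
          from <- lc_code(transition_from(tr)); to <- lc_code(transition_to(tr))
          src <- which(!is.na(v) & v == from & !is.na(reg) & reg == rg)
          if (!length(src)) next
          n <- stats::rbinom(1L, length(src), rate)
          if (n == 0) next
          w <- if (tr == TRANSITIONS[["F2D"]]) pref[src] else rep(1, length(src))
          pick <- if (length(src) == 1L) src else sample(src, n, prob = w)
          v_next[pick] <- to
        }
      }
      v <- v_next
    }
  })
  grid_map(v, cell_size = lc$cell_size, xll = lc$xll, yll = lc$yll,
           nodata = lc$nodata, role = "landcover")
}

evolve_preference <- function(variables, dims) {
  if (is.null(variables)) return(matrix(1, dims[1], dims[2]))
  p <- matrix(1, dims[1], dims[2])
  if (!is.null(variables$dist_road)) p <- p * exp(-variables$dist_road$values / 900)
  if (!is.null(variables$dist_river)) p <- p * exp(-variables$dist_river$values / 1800)
  p + 1e-9
}

#' Write a synthetic study area to a directory
#'
#' Emits every generated layer in the package's on-disk formats (ASCII
#' grids, GeoJSON rivers, CSV rates), producing a ready-to-run study-area
#' directory.
#'
#' @param syn output of [generate_landscape()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_area <- function(syn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grid(syn$landcover, file.path(dir, "landcover_t0.asc"))
  write_grid(syn$lc2008, file.path(dir, "landcover_2008.asc"))
  write_grid(syn$biomass, file.path(dir, "biomass.asc"))
  for (nm in names(syn$static)) {
    write_grid(syn$static[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  cs <- syn$landcover$cell_size
  gm <- function(mask) grid_map(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                                cell_size = cs, role = "mask")
  write_grid(gm(syn$cu_mask), file.path(dir, "cu.asc"))
  write_grid(gm(syn$il_mask), file.path(dir, "il.asc"))
  write_grid(gm(syn$urban_mask), file.path(dir, "urban.asc"))
  write_rivers(syn$rivers, file.path(dir, "rivers.geojson"))
  write_rates(syn$true_rates, file.path(dir, "true_rates.csv"))
  roads <- river_network(lapply(syn$roads, function(cc) {
    list(coords = cc, regular_width_m = 1, maxlevel_width_m = 1)
  }))
  write_rivers(roads, file.path(dir, "roads.geojson"))
  invisible(dir)
}
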