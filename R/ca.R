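#' Annual cell demand of a transition
#'
#' Number of cells a region must convert this iteration: the annual rate
#' times the current source-class cell count, rounded to the nearest
#' integer. Deterministic; fractional residues are carried across years by
#' the simulation loop, not here.
#'
#' @param rate annual rate in [0, 1].
#' @param source_count cells of the source class currently in the region.
#' @return Integer cell count.
#' @export
demand <- function(rate, source_count) {
  stopifnot(rate >= 0, rate <= 1, source_count >= 0)
  as.integer(round(rate * source_count))
}

#' Create a simulation state
#'
#' @param lc land-cover `grid_map` at the start year.
#' @param year calendar year of `lc`.
#' @param initial_secondary_age age (years) assigned to secondary vegetation
#'   present in the initial map.
#' @param roads optional list of road polylines (coordinate matrices).
#' @return An object of class `ca_state` with the land cover, a per-cell
#'   secondary-vegetation age matrix, the year, the road network and the
#'   demand-rounding residuals.
#' @export
ca_state <- function(lc, year = 0L, initial_secondary_age = 5, roads = list()) {
  stopifnot(inherits(lc, "grid_map"))
  age <- matrix(0, nrow(lc$values), ncol(lc$values))
  age[!is.na(lc$values) & lc$values == lc_code("SECONDARY")] <- initial_secondary_age
  structure(list(lc = lc, age = age, year = as.integer(year), roads = roads,
                 residual = list()), class = "ca_state")
}

#' @export
print.ca_state <- function(x, ...) {
  cat(sprintf("<ca_state> year %d\n", x$year))
  print(x$lc)
  invisible(x)
}

#' Allocate a transition's cell demand onto the grid
#'
#' The patcher/expander allocator. A share `expander_fraction` of the demand
#' is taken from source cells 8-adjacent to existing target-class cells
#' (patch expansion); the remainder seeds new patches whose sizes are drawn
#' lognormally around the region's mean patch size and grown by repeatedly
#' adding the neighboring cell maximizing posterior probability plus an
#' isometry bonus for compactness. Cells are drawn probability-weighted from
#' a candidate pool pruned to the top `demand * pruning_factor` cells by
#' posterior probability. If demand exceeds the eligible candidates, all
#' candidates convert and the shortfall is recorded.
#'
#' @param lc_values integer land-cover matrix (modified copy returned).
#' @param transition one of `TRANSITIONS`.
#' @param n_demand cells to convert.
#' @param prob posterior-probability matrix (NA allowed outside the region).
#' @param params patch-geometry parameters (list with `mean_patch_size_ha`,
#'   `patch_size_variance`, `isometry`, `expander_fraction`).
#' @param region_mask logical matrix restricting eligibility.
#' @param cell_size cell edge (m), for converting patch sizes to cells.
#' @param pruning_factor candidate-pool multiplier (default 10).
#' @param exclude optional logical matrix of cells never allowed to convert
#'   (e.g. the urban mask for regeneration).
#' @return list(values = updated matrix, converted = logical matrix of the
#'   cells converted this call, shortfall = unmet demand).
#' @export
allocate <- function(lc_values, transition, n_demand, prob, params, region_mask,
                     cell_size = 30, pruning_factor = 10, exclude = NULL) {
  from <- lc_code(transition_from(transition))
  to <- lc_code(transition_to(transition))
  converted <- matrix(FALSE, nrow(lc_values), ncol(lc_values))
  if (n_demand <= 0) {
    return(list(values = lc_values, converted = converted, shortfall = 0L))
  }
  elig <- !is.na(lc_values) & lc_values == from & region_mask
  if (!is.null(exclude)) elig <- elig & !exclude
  p <- prob
  p[is.na(p)] <- 0
  p <- p + 1e-12  # keep sampling defined on flat surfaces
  navail <- sum(elig)
  if (navail == 0) {
    return(list(values = lc_values, converted = converted, shortfall = as.integer(n_demand)))
  }
  n_demand <- as.integer(n_demand)
  n_take <- min(n_demand, navail)

  # candidate pool: top demand x pruning_factor cells by probability
  pool_size <- min(navail, max(n_take * pruning_factor, n_take))
  elig_idx <- which(elig)
  pool <- elig_idx[order(p[elig_idx], decreasing = TRUE)[seq_len(pool_size)]]

  # --- expander: cells adjacent to existing target-class patches
  n_exp_want <- round(params$expander_fraction * n_take)
  done <- 0L
  if (n_exp_want > 0) {
    adj <- neighbor_count(!is.na(lc_values) & lc_values == to) > 0
    cand <- pool[adj[pool]]
    if (length(cand)) {
      n_exp <- min(n_exp_want, length(cand))
      pick <- if (length(cand) == 1L) cand else sample(cand, n_exp, prob = p[cand])
      lc_values[pick] <- to
      converted[pick] <- TRUE
      done <- done + length(pick)
    }
  }

  # --- patcher: seed and grow new patches
  mean_cells <- max(params$mean_patch_size_ha / (cell_size / 100)^2, 1)
  var_cells <- max(params$patch_size_variance / (cell_size / 100)^4, 0.01)
  sig2 <- log(1 + var_cells / mean_cells^2)
  mu <- log(mean_cells) - sig2 / 2
  nr <- nrow(lc_values); nc <- ncol(lc_values)
  still <- function(i) !converted[i] & elig[i] & !is.na(lc_values[i]) & lc_values[i] == from

  while (done < n_take) {
    remaining <- n_take - done
    size <- min(max(1L, round(stats::rlnorm(1, mu, sqrt(sig2)))), remaining)
    cand <- pool[still(pool)]
    if (!length(cand)) break
    seed_cell <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = p[cand])
    patch <- seed_cell
    lc_values[seed_cell] <- to
    converted[seed_cell] <- TRUE
    done <- done + 1L
    inpatch <- matrix(FALSE, nr, nc); inpatch[seed_cell] <- TRUE
    while (length(patch) < size) {
      nbrs <- patch_neighbors(patch, nr, nc)
      nbrs <- nbrs[still(nbrs)]
      if (!length(nbrs)) break
      bonus <- vapply(nbrs, function(i) {
        r <- (i - 1L) %% nr + 1L; cl <- (i - 1L) %/% nr + 1L
        sum(inpatch[max(1, r - 1):min(nr, r + 1), max(1, cl - 1):min(nc, cl + 1)])
      }, numeric(1))
      score <- p[nbrs] + params$isometry * bonus / 8
      nxt <- nbrs[which.max(score)]
      lc_values[nxt] <- to
      converted[nxt] <- TRUE
      inpatch[nxt] <- TRUE
      patch <- c(patch, nxt)
      done <- done + 1L
      if (done >= n_take) break
    }
  }
  list(values = lc_values, converted = converted,
       shortfall = as.integer(n_demand - done))
}

# linear indices of all 8-neighbors of a set of cells (deduplicated)
patch_neighbors <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  cl <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- cl + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- c(out, (cc[ok] - 1L) * nr + rr[ok])
  }
  setdiff(unique(out), idx)
}

#' Advance the simulation one year
#'
#' Applies the three transitions region by region in fixed order
#' (forest-to-deforested, then secondary-cutting, then regeneration),
#' honouring scenario restrictions, carrying demand-rounding residuals
#' across years, ageing secondary vegetation, and blocking regeneration on
#' urban-masked cells.
#'
#' @param state a [ca_state()].
#' @param rates a [rate_table()].
#' @param regions region `grid_map`.
#' @param weights optional `evidence_weights`; uniform probability when
#'   absent.
#' @param variables named list of static-variable maps for the posterior
#'   surfaces.
#' @param restrictions data.frame(region, transition) pairs forbidden by the
#'   scenario.
#' @param urban_mask logical matrix where regeneration is nullified.
#' @param pruning_factor candidate-pool multiplier.
#' @return The updated `ca_state` (year incremented by 1); its `log` field
#'   records demand, realized conversions and any shortfall per region and
#'   transition for the step.
#' @export
ca_step <- function(state, rates, regions, weights = NULL, variables = NULL,
                    restrictions = NULL, urban_mask = NULL, pruning_factor = 10) {
  v <- state$lc$values
  v_start <- v  # synchronous update: eligibility is fixed by the year-start
                # state, so a cell undergoes at most one transition per year
  reg <- regions$values
  cs <- state$lc$cell_size
  order_tr <- TRANSITIONS[c("F2D", "S2D", "D2S")]
  log_rows <- list()
  for (rg in sort(unique(reg[!is.na(reg)]))) {
    rname <- region_name(rg)
    region_mask <- !is.na(reg) & reg == rg
    for (tr in order_tr) {
      if (!is.null(restrictions) &&
          any(restrictions$region == rname & restrictions$transition == tr)) next
      rate <- get_rate_fb(rates, rname, tr)
      if (rate <= 0) next
      from <- lc_code(transition_from(tr))
      elig_mask <- region_mask & !is.na(v_start) & v_start == from
      n_src <- sum(elig_mask & !is.na(v) & v == from)
      key <- paste(rname, tr, sep = "|")
      carry <- state$residual[[key]] %||% 0
      x <- rate * n_src + carry
      dem <- round(x)
      state$residual[[key]] <- x - dem
      if (dem <= 0) next
      prob <- if (is.null(weights)) {
        matrix(0.5, nrow(v), ncol(v))
      } else {
        posterior_surface(weights, min(max(rate, 1e-6), 1 - 1e-6), variables, tr,
                          weights_region_fb(weights, rname, tr))
      }
      excl <- if (tr == TRANSITIONS[["D2S"]]) urban_mask else NULL
      pp <- patch_params(rates, if (any(attr(rates, "patch")$region == rname))
        rname else "NONE")
      res <- allocate(v, tr, dem, prob, pp, elig_mask,
                      cell_size = cs, pruning_factor = pruning_factor,
                      exclude = excl)
      v <- res$values
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        year = state$year + 1L, region = rname, transition = tr,
        demand = dem, converted = dem - res$shortfall, shortfall = res$shortfall)
    }
  }
  # age bookkeeping: surviving secondary ages one year, new secondary is age 1
  sec_now <- !is.na(v) & v == lc_code("SECONDARY")
  sec_before <- !is.na(state$lc$values) & state$lc$values == lc_code("SECONDARY")
  age <- state$age
  age[sec_now & sec_before] <- age[sec_now & sec_before] + 1
  age[sec_now & !sec_before] <- 1
  age[!sec_now] <- 0
  state$age <- age
  state$lc <- grid_map(v, cell_size = cs, xll = state$lc$xll, yll = state$lc$yll,
                       nodata = state$lc$nodata, role = "landcover")
  state$year <- state$year + 1L
  state$log <- if (length(log_rows)) do.call(rbind, log_rows) else NULL
  state
}
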