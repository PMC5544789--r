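#' Friction surface for road construction
#'
#' Per-cell traversal cost for the road builder. Attractors (existing roads,
#' rivers) lower the cost, repellents (conservation units, indigenous lands,
#' steep slopes) raise it or make cells impassable. Costs are strictly
#' positive; `Inf` marks impassable cells.
#'
#' @param static named list of static maps (`dist_road`, `dist_river`,
#'   `slope` used when present).
#' @param cu_mask,il_mask logical matrices of protected areas.
#' @param weights list of multipliers: `road_attract`, `river_attract`
#'   (cost reduction near features), `protected` (multiplier on CU/IL,
#'   `Inf` allowed), `steep` (multiplier where slope > `slope_limit`),
#'   `slope_limit` (percent).
#' @return An object of class `friction_surface` (matrix with attributes).
#' @export
friction_surface <- function(static, cu_mask = NULL, il_mask = NULL,
                             weights = list()) {
  w <- utils::modifyList(list(road_attract = 0.5, river_attract = 0.7,
                              protected = 10, steep = 5, slope_limit = 20),
                         weights)
  dims <- dim(static[[1]]$values)
  cost <- matrix(1, dims[1], dims[2])
  if (!is.null(static$dist_road)) {
    cost <- cost * (1 - (1 - w$road_attract) * exp(-static$dist_road$values / 1000))
  }
  if (!is.null(static$dist_river)) {
    cost <- cost * (1 - (1 - w$river_attract) * exp(-static$dist_river$values / 1000))
  }
  if (!is.null(static$slope)) {
    cost[static$slope$values > w$slope_limit] <-
      cost[static$slope$values > w$slope_limit] * w$steep
  }
  if (!is.null(cu_mask)) cost[cu_mask] <- cost[cu_mask] * w$protected
  if (!is.null(il_mask)) cost[il_mask] <- cost[il_mask] * w$protected
  if (any(cost[is.finite(cost)] <= 0)) stop("friction costs must be positive")
  structure(cost, class = c("friction_surface", "matrix", "array"))
}

# lattice graph over the grid with edge weights = mean endpoint friction
# times step length (1 or sqrt(2) cells); Inf cells are excluded
friction_graph <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  edges <- list(); wts <- list()
  shifts <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]; len <- s[3]
    r0 <- seq_len(nr - dr)
    c0 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- outer(r0, c0, id)
    b <- outer(r0 + dr, c0 + dc, id)
    wab <- (cost[a] + cost[b]) / 2 * len
    keep <- is.finite(wab)
    edges[[length(edges) + 1L]] <- rbind(a[keep], b[keep])
    wts[[length(wts) + 1L]] <- wab[keep]
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  igraph::E(g)$weight <- unlist(wts)
  g
}

#' Grow the road network over a friction surface
#'
#' Each call extends the network toward targets sampled
#' probability-weighted from the attractiveness surface (the reciprocal of
#' friction): new segments are least-cost paths from the nearest existing
#' road cell, and construction stops when the annual budget (km) is
#' exhausted. Impassable (`Inf` friction) cells are never crossed.
#'
#' @param roads list of road polylines (coordinate matrices, map units).
#' @param friction a [friction_surface()].
#' @param budget_km total new length allowed (km).
#' @param seed integer seed.
#' @param cell_size cell edge (m).
#' @param n_targets how many targets to attempt (default 1).
#' @param xll,yll grid origin.
#' @return list(roads = extended polyline list, new_km = km actually built).
#' @export
build_roads <- function(roads, friction, budget_km, seed, cell_size = 30,
                        n_targets = 1, xll = 0, yll = 0) {
  stopifnot(budget_km >= 0)
  if (budget_km == 0 || n_targets == 0) return(list(roads = roads, new_km = 0))
  nr <- nrow(friction); nc <- ncol(friction)
  road_mask <- rasterize_lines(roads, nr, nc, cell_size, xll, yll)
  if (!any(road_mask)) return(list(roads = roads, new_km = 0))
  g <- friction_graph(friction)
  new_km <- 0
  with_seed(seed, {
    attract <- 1 / friction
    attract[!is.finite(attract)] <- 0
    for (k in seq_len(n_targets)) {
      if (new_km >= budget_km) break
      pool <- which(!road_mask & attract > 0)
      if (!length(pool)) break
      target <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = attract[pool])
      sources <- which(road_mask)
      # nearest road cell to the target (straight-line) as path origin
      tr <- (target - 1L) %% nr + 1L; tc <- (target - 1L) %/% nr + 1L
      sr <- (sources - 1L) %% nr + 1L; sc <- (sources - 1L) %/% nr + 1L
      origin <- sources[which.min((sr - tr)^2 + (sc - tc)^2)]
      sp <- suppressWarnings(igraph::shortest_paths(g, from = origin, to = target,
                                                    output = "vpath"))
      path <- as.integer(sp$vpath[[1]])
      if (length(path) < 2) next  # unreachable target
      pr <- (path - 1L) %% nr + 1L; pc <- (path - 1L) %/% nr + 1L
      coords <- cbind(xll + (pc - 0.5) * cell_size,
                      yll + (nr - pr + 0.5) * cell_size)
      len_km <- polyline_length_km(coords)
      if (len_km == 0) next
      if (new_km + len_km > budget_km) {
        # truncate the path to the remaining budget
        keep_m <- (budget_km - new_km) * 1000
        seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                               coords[-nrow(coords), , drop = FALSE])^2))
        cum <- cumsum(seg)
        cut <- which(cum <= keep_m)
        if (!length(cut)) break
        coords <- coords[seq_len(max(cut) + 1L), , drop = FALSE]
        len_km <- polyline_length_km(coords)
      }
      roads[[length(roads) + 1L]] <- coords
      road_mask[path] <- TRUE
      new_km <- new_km + len_km
    }
  })
  list(roads = roads, new_km = new_km)
}

#' Road-feedback update of deforestation rates
#'
#' Scales each region's rates by the relative increment of the road network:
#' rate' = rate * (1 + beta * new_length / network_length), clipped to
#' [0, 1]. With `beta = 0` or no new roads the table is returned unchanged.
#'
#' @param base a [rate_table()].
#' @param new_length named numeric, km of new road per region.
#' @param network_length named numeric, total network km per region.
#' @param beta feedback coefficient (default 1).
#' @param transitions which transitions respond to roads (default
#'   deforestation only).
#' @return Updated `rate_table`.
#' @export
update_rates <- function(base, new_length, network_length, beta = 1,
                         transitions = TRANSITIONS[["F2D"]]) {
  stopifnot(all(new_length >= 0), all(network_length >= 0))
  rt <- as.data.frame(base)
  for (rg in names(new_length)) {
    inc <- new_length[[rg]] / max(network_length[[rg]], 1e-9)
    sel <- rt$region == rg & rt$transition %in% transitions
    rt$rate[sel] <- pmin(pmax(rt$rate[sel] * (1 + beta * inc), 0), 1)
  }
  rate_table(rt, attr(base, "patch"))
}
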