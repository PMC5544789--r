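#' Per-region annual transition rates and patch geometry
#'
#' The rate table drives the cellular automaton: for each region and each of
#' the three transitions it holds the annual rate (fraction of the source
#' class converting per year), and per region the geometry of simulated
#' change patches: mean patch size (ha), patch-size variance (ha²), isometry
#' in [0,1] (how compact grown patches are) and the expander fraction in
#' [0,1] (share of annual demand allocated by expanding existing patches
#' rather than seeding new ones).
#'
#' @param rates data.frame with columns `region`, `transition`, `rate`.
#' @param patch data.frame with columns `region`, `mean_patch_size_ha`,
#'   `patch_size_variance`, `isometry`, `expander_fraction`; defaults are
#'   filled for regions absent from it.
#' @return An object of class `rate_table` (a data.frame with a `patch`
#'   attribute).
#' @export
rate_table <- function(rates, patch = NULL) {
  stopifnot(all(c("region", "transition", "rate") %in% names(rates)))
  if (any(rates$rate < 0 | rates$rate > 1)) stop("rates must lie in [0, 1]")
  bad <- setdiff(rates$transition, TRANSITIONS)
  if (length(bad)) stop("unknown transition(s): ", paste(bad, collapse = ", "))
  regions <- unique(rates$region)
  default_patch <- data.frame(
    region = regions,
    mean_patch_size_ha = 1.5,
    patch_size_variance = 1.0,
    isometry = 0.5,
    expander_fraction = 0.5,
    stringsAsFactors = FALSE)
  if (is.null(patch)) {
    patch <- default_patch
  } else {
    miss <- setdiff(regions, patch$region)
    if (length(miss)) patch <- rbind(patch, default_patch[default_patch$region %in% miss, ])
  }
  if (any(patch$expander_fraction < 0 | patch$expander_fraction > 1)) {
    stop("expander_fraction must lie in [0, 1]")
  }
  if (any(patch$isometry < 0 | patch$isometry > 1)) stop("isometry must lie in [0, 1]")
  structure(as.data.frame(rates), patch = patch, class = c("rate_table", "data.frame"))
}

patch_params <- function(rt, region) {
  p <- attr(rt, "patch")
  row <- p[p$region == region, ]
  if (!nrow(row)) row <- data.frame(region = region, mean_patch_size_ha = 1.5,
                                    patch_size_variance = 1.0, isometry = 0.5,
                                    expander_fraction = 0.5)
  as.list(row[1, ])
}

get_rate <- function(rt, region, transition) {
  hit <- rt$rate[rt$region == region & rt$transition == transition]
  if (!length(hit)) 0 else hit[1]
}

# rate lookup that falls back to the catch-all "NONE" region when the table
# has no row for this (region, transition) pair; lets a model calibrated
# without regions drive a regionalized simulation
get_rate_fb <- function(rt, region, transition) {
  if (any(rt$region == region & rt$transition == transition)) {
    get_rate(rt, region, transition)
  } else {
    get_rate(rt, "NONE", transition)
  }
}

# weights region with the same fallback semantics
weights_region_fb <- function(weights, region, transition) {
  if (any(weights$region == region & weights$transition == transition)) region
  else "NONE"
}

set_rate <- function(rt, region, transition, value) {
  i <- which(rt$region == region & rt$transition == transition)
  if (length(i)) {
    rt$rate[i[1]] <- value
  } else {
    rt <- rbind(rt, data.frame(region = region, transition = transition, rate = value))
  }
  rate_table(as.data.frame(rt), attr(rt, "patch"))
}

#' Read / write a rate table as CSV
#'
#' Two files: `<path>` with region, transition, rate; `<path>` patch columns
#' are carried in the same file (patch parameters repeated per region).
#' @param rt a `rate_table`; `path` a CSV path.
#' @export
write_rates <- function(rt, path) {
  p <- attr(rt, "patch")
  merged <- merge(as.data.frame(rt), p, by = "region", all.x = TRUE, sort = FALSE)
  utils::write.csv(merged, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  patch_cols <- c("region", "mean_patch_size_ha", "patch_size_variance",
                  "isometry", "expander_fraction")
  patch <- unique(df[, intersect(patch_cols, names(df)), drop = FALSE])
  rate_table(df[, c("region", "transition", "rate")],
             if (ncol(patch) > 1) patch else NULL)
}

# ---- bins ------------------------------------------------------------------

# Resolve a bin specification against the observed variables.
# spec per variable: list(type = "continuous", breaks = numeric) or
# list(type = "categorical"); NULL -> default 10 quantile bins (continuous)
# or categories (<= 25 distinct integer values).
resolve_bins <- function(variables, bins = NULL, n_default = 10) {
  out <- list()
  for (nm in names(variables)) {
    v <- variables[[nm]]$values
    v <- v[!is.na(v)]
    spec <- bins[[nm]]
    if (is.null(spec)) {
      u <- unique(v)
      if (length(u) <= 25 && all(u == round(u))) {
        spec <- list(type = "categorical")
      } else {
        br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_default + 1),
                                     names = FALSE))
        spec <- list(type = "continuous", breaks = br)
      }
    }
    if (spec$type == "continuous") spec$breaks <- sort(unique(spec$breaks))
    if (spec$type == "categorical") {
      spec$levels <- sort(unique(v))
    } else {
      # breaks must partition the observed range
      spec$breaks[1] <- min(spec$breaks[1], min(v))
      spec$breaks[length(spec$breaks)] <- max(spec$breaks[length(spec$breaks)], max(v))
    }
    out[[nm]] <- spec
  }
  out
}

# bin index of each cell for one variable (NA preserved)
bin_index <- function(values, spec) {
  if (spec$type == "categorical") {
    match(values, spec$levels)
  } else {
    i <- findInterval(values, spec$breaks, rightmost.closed = TRUE, all.inside = TRUE)
    i[is.na(values)] <- NA
    i
  }
}

n_bins <- function(spec) {
  if (spec$type == "categorical") length(spec$levels) else length(spec$breaks) - 1L
}

bin_bounds <- function(spec, i) {
  if (spec$type == "categorical") c(spec$levels[i], spec$levels[i])
  else c(spec$breaks[i], spec$breaks[i + 1])
}

# ---- weights of evidence ---------------------------------------------------

#' Weights of evidence for land-cover transitions
#'
#' For every region, transition and evidence-variable bin, computes the
#' positive weight of evidence W+ = ln[ P(B | T) / P(B | not T) ] over the
#' cells eligible for the transition at t0 (cells of the source class).
#' Bins with no eligible cells, and transitions with no observed changes,
#' get weight 0 ("no information"); an entirely absent transition raises a
#' warning.
#'
#' @param lc_t0,lc_t1 land-cover `grid_map`s at the start and end of the
#'   calibration period.
#' @param variables named list of static-variable `grid_map`s.
#' @param bins optional named list of bin specifications (see Details);
#'   default: 10 quantile bins for continuous variables, categories for
#'   discrete ones.
#' @param region optional region `grid_map`; weights are computed per region.
#' @param transitions character vector of transitions (default all three).
#' @return An object of class `evidence_weights`: a data.frame with columns
#'   `region`, `transition`, `variable`, `bin`, `bin_low`, `bin_high`,
#'   `weight`, carrying the resolved bin definitions as attribute `"bins"`.
#' @export
compute_weights <- function(lc_t0, lc_t1, variables, bins = NULL, region = NULL,
                            transitions = TRANSITIONS) {
  stopifnot(same_geometry(lc_t0, lc_t1))
  for (v in variables) stopifnot(same_geometry(lc_t0, v))
  bins <- resolve_bins(variables, bins)
  v0 <- lc_t0$values; v1 <- lc_t1$values
  reg <- if (is.null(region)) matrix(0L, nrow(v0), ncol(v0)) else region$values
  regions <- sort(unique(reg[!is.na(reg)]))
  binned <- lapply(names(variables), function(nm) bin_index(variables[[nm]]$values, bins[[nm]]))
  names(binned) <- names(variables)

  rows <- list()
  for (rg in regions) {
    rname <- region_name(rg)
    in_reg <- !is.na(reg) & reg == rg & !is.na(v0) & !is.na(v1)
    for (tr in transitions) {
      from <- lc_code(transition_from(tr)); to <- lc_code(transition_to(tr))
      elig <- in_reg & v0 == from
      event <- elig & v1 == to
      nT <- sum(event); nE <- sum(elig)
      if (nE > 0 && nT == 0) {
        warning(sprintf("no '%s' transitions observed in region %s; weights set to 0",
                        tr, rname))
      }
      for (nm in names(variables)) {
        spec <- bins[[nm]]
        nb <- n_bins(spec)
        b <- binned[[nm]]
        for (k in seq_len(nb)) {
          in_bin <- elig & !is.na(b) & b == k
          n_bT <- sum(in_bin & event)
          n_b <- sum(in_bin)
          w <- woe_weight(n_bT, nT, n_b - n_bT, nE - nT)
          bb <- bin_bounds(spec, k)
          rows[[length(rows) + 1L]] <- data.frame(
            region = rname, transition = tr, variable = nm, bin = k,
            bin_low = bb[1], bin_high = bb[2], weight = w,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  structure(df, bins = bins, class = c("evidence_weights", "data.frame"))
}

# W+ from the 2x2 contingency table; degenerate counts -> 0 (no information)
woe_weight <- function(n_bT, n_T, n_bN, n_N) {
  if (n_T == 0 || n_N == 0 || n_bT == 0 || n_bN == 0) return(0)
  log((n_bT / n_T) / (n_bN / n_N))
}

#' Posterior transition probability of a cell
#'
#' Combines weights of evidence additively on the log-odds scale:
#' logit(P) = logit(prior) + sum of the cell's bin weights, assuming
#' conditional independence of the evidence layers.
#'
#' @param weights an `evidence_weights` table.
#' @param prior prior transition probability in (0, 1).
#' @param evidence named list/vector of the cell's variable values (binned
#'   internally against the weights' bin definitions).
#' @param transition,region which weight set to use (defaults: first
#'   present).
#' @return Posterior probability in (0, 1).
#' @export
posterior_probability <- function(weights, prior, evidence,
                                  transition = NULL, region = NULL) {
  stopifnot(prior > 0, prior < 1)
  transition <- transition %||% weights$transition[1]
  region <- region %||% weights$region[1]
  bins <- attr(weights, "bins")
  wsum <- 0
  for (nm in names(evidence)) {
    spec <- bins[[nm]]
    if (is.null(spec)) stop("no bin definition for variable '", nm, "'")
    k <- bin_index(evidence[[nm]], spec)
    hit <- weights$weight[weights$variable == nm & weights$bin == k &
                            weights$transition == transition &
                            weights$region == region]
    if (length(hit)) wsum <- wsum + hit[1]
  }
  stats::plogis(stats::qlogis(prior) + wsum)
}

# posterior-probability surface over the whole grid for one (region,
# transition); returns a matrix (NA outside the region)
posterior_surface <- function(weights, prior, variables, transition, region_name,
                              region_mask = NULL) {
  bins <- attr(weights, "bins")
  dims <- dim(variables[[1]]$values)
  logit <- matrix(stats::qlogis(max(min(prior, 1 - 1e-12), 1e-12)), dims[1], dims[2])
  sub <- weights[weights$transition == transition & weights$region == region_name, ]
  for (nm in unique(sub$variable)) {
    spec <- bins[[nm]]
    b <- bin_index(variables[[nm]]$values, spec)
    wv <- numeric(n_bins(spec))
    rows <- sub[sub$variable == nm, ]
    wv[rows$bin] <- rows$weight
    add <- wv[b]
    add[is.na(add)] <- 0
    logit <- logit + add
  }
  p <- stats::plogis(logit)
  if (!is.null(region_mask)) p[!region_mask] <- NA
  p
}

#' Read / write an evidence-weights table as CSV
#'
#' Human-readable serialization: one row per (transition, region, variable,
#' bin) with the bin bounds and the weight. Bin definitions are
#' reconstructed from the bounds on read.
#' @param weights an `evidence_weights`; `path` a CSV path.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(as.data.frame(weights), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bins <- list()
  for (nm in unique(df$variable)) {
    sub <- unique(df[df$variable == nm, c("bin", "bin_low", "bin_high")])
    sub <- sub[order(sub$bin), ]
    if (all(sub$bin_low == sub$bin_high)) {
      bins[[nm]] <- list(type = "categorical", levels = sub$bin_low)
    } else {
      bins[[nm]] <- list(type = "continuous",
                         breaks = c(sub$bin_low, sub$bin_high[nrow(sub)]))
    }
  }
  structure(df, bins = bins, class = c("evidence_weights", "data.frame"))
}

# ---- transition rates ------------------------------------------------------

#' Annual transition rates from two dated land-cover maps
#'
#' Estimates, per region, the annual rate of the three simulated transitions
#' from the empirical transition matrix of the calibration window. The
#' default annualization (`method = "markov"`) takes the matrix root of the
#' period transition matrix over the three dynamic classes (forest,
#' deforested, secondary), A = P^(1/years), via eigendecomposition; this
#' correctly unchains multi-year sequences such as clearing followed by
#' regeneration within the window, and reduces exactly to compound survival,
#' annual = 1 - (1 - f)^(1/years), whenever a class only loses cells.
#' `method = "survival"` applies that per-transition survival formula to the
#' endpoint fractions directly. Patch geometry (mean size, variance,
#' expander fraction) is estimated from the connected components of the
#' observed change.
#'
#' @inheritParams compute_weights
#' @param years length of the calibration window in years (>= 1).
#' @param method `"markov"` (matrix-root of the period transition matrix,
#'   default) or `"survival"` (per-transition compound survival).
#' @return A [rate_table()].
#' @export
compute_rates <- function(lc_t0, lc_t1, region = NULL, years = 1,
                          method = c("markov", "survival")) {
  stopifnot(same_geometry(lc_t0, lc_t1), years >= 1)
  method <- match.arg(method)
  v0 <- lc_t0$values; v1 <- lc_t1$values
  reg <- if (is.null(region)) matrix(0L, nrow(v0), ncol(v0)) else region$values
  regions <- sort(unique(reg[!is.na(reg)]))
  area_ha <- cell_area_ha(lc_t0)

  rows <- list(); prows <- list()
  for (rg in regions) {
    rname <- region_name(rg)
    in_reg <- !is.na(reg) & reg == rg & !is.na(v0) & !is.na(v1)
    ann <- annualize_region(v0[in_reg], v1[in_reg], years, method, rname)
    for (tr in TRANSITIONS) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = rname, transition = tr, rate = ann[[tr]], stringsAsFactors = FALSE)
    }
    # patch geometry of observed deforestation change in this region
    f2d <- in_reg & v0 == lc_code("FOREST") & v1 == lc_code("DEFORESTED")
    sizes <- component_sizes(f2d)
    exp_frac <- if (any(f2d)) {
      adj <- neighbor_count(!is.na(v0) & v0 == lc_code("DEFORESTED")) > 0
      sum(f2d & adj) / sum(f2d)
    } else 0.5
    prows[[length(prows) + 1L]] <- data.frame(
      region = rname,
      mean_patch_size_ha = if (length(sizes)) mean(sizes) * area_ha else 1.5,
      patch_size_variance = if (length(sizes) > 1) stats::var(sizes * area_ha) else 1.0,
      isometry = 0.5,
      expander_fraction = exp_frac,
      stringsAsFactors = FALSE)
  }
  rate_table(do.call(rbind, rows), do.call(rbind, prows))
}

# annual rates of the three transitions within one region's cells
annualize_region <- function(s0, s1, years, method, rname) {
  dyn <- c(FOREST = lc_code("FOREST"), DEFORESTED = lc_code("DEFORESTED"),
           SECONDARY = lc_code("SECONDARY"))
  counts <- matrix(0, 3, 3, dimnames = list(names(dyn), names(dyn)))
  for (a in 1:3) for (b in 1:3) counts[a, b] <- sum(s0 == dyn[a] & s1 == dyn[b])
  # cells leaving the dynamic system (none of the three transitions allows
  # it) are folded into persistence so rows stay stochastic
  n_src <- rowSums(counts) + vapply(seq_len(3), function(a) {
    sum(s0 == dyn[a] & !(s1 %in% dyn))
  }, numeric(1))
  out <- stats::setNames(rep(0, 3), unname(TRANSITIONS))
  empty <- n_src == 0
  if (any(empty)) {
    for (tr in TRANSITIONS[transition_from(TRANSITIONS) %in% names(dyn)[empty]]) {
      warning(sprintf("region %s has no source cells for '%s'; rate 0", rname, tr))
    }
  }
  P <- diag(3)
  dimnames(P) <- dimnames(counts)
  ok <- which(!empty)
  for (a in ok) {
    P[a, ] <- counts[a, ] / n_src[a]
    P[a, a] <- P[a, a] + (1 - sum(P[a, ]))  # fold exits into persistence
  }
  A <- if (method == "survival" || years == 1) NULL else markov_root(P, years)
  if (is.null(A)) {
    # per-transition compound survival on endpoint fractions
    A <- matrix(0, 3, 3, dimnames = dimnames(P))
    for (a in 1:3) for (b in 1:3) {
      if (a != b) A[a, b] <- 1 - (1 - P[a, b])^(1 / years)
    }
  }
  out[TRANSITIONS[["F2D"]]] <- A["FOREST", "DEFORESTED"]
  out[TRANSITIONS[["D2S"]]] <- A["DEFORESTED", "SECONDARY"]
  out[TRANSITIONS[["S2D"]]] <- A["SECONDARY", "DEFORESTED"]
  pmin(pmax(out, 0), 1)
}

# real matrix root P^(1/years) via eigendecomposition; NULL when the root is
# not real/stochastic enough to trust (caller falls back to survival)
markov_root <- function(P, years) {
  e <- eigen(P)
  if (any(abs(Im(e$values)) > 1e-9) || any(Re(e$values) <= 0)) return(NULL)
  lam <- Re(e$values)^(1 / years)
  V <- Re(e$vectors)
  A <- try(V %*% diag(lam, nrow = length(lam)) %*% solve(V), silent = TRUE)
  if (inherits(A, "try-error")) return(NULL)
  # sampling noise can push structurally-zero entries slightly negative;
  # clamp those, but reject roots that are substantially non-stochastic
  if (any(!is.finite(A)) || any(A < -1e-3)) return(NULL)
  A[A < 0] <- 0
  A <- A / rowSums(A)
  dimnames(A) <- dimnames(P)
  A
}

# sizes (cells) of 8-connected components of a logical matrix
component_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  sizes <- integer(0)
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    n <- 0L
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      n <- n + length(cur)
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- cl + dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        if (!any(ok)) next
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
    sizes <- c(sizes, n)
  }
  sizes
}

# ---- the model object ------------------------------------------------------

#' Fit a regionalized weights-of-evidence land-cover change model
#'
#' Calibrates the two components of the land-change model from a pair of
#' dated land-cover maps: per-region annual transition rates (the amount of
#' change) and weights of evidence over static variables (where change
#' happens). The fitted object drives forward simulation via [simulate()].
#'
#' @param lc_t0,lc_t1 land-cover maps at the calibration start and end dates.
#' @param variables named list of static-variable `grid_map`s (e.g. distance
#'   to roads, distance to rivers, altitude, slope).
#' @param regions optional region `grid_map`; rates and weights become
#'   region-specific.
#' @param years calibration window length in years.
#' @param bins optional bin specification (see [compute_weights()]).
#' @return An object of class `lucc_model` with components `rates`
#'   (a [rate_table()]), `weights` (an `evidence_weights` table), `bins`,
#'   `years`, and `call`.
#' @seealso [simulate.lucc_model()], [predict.lucc_model()]
#' @examples
#' syn <- generate_landscape(synth_config(n_rows = 60, n_cols = 60, seed = 1))
#' lc1 <- evolve_landscape(syn$landcover, syn$true_rates, years = 3, seed = 2,
#'                         variables = syn$static)
#' fit <- lucc_fit(syn$landcover, lc1, syn$static, years = 3)
#' coef(fit)
#' @export
lucc_fit <- function(lc_t0, lc_t1, variables, regions = NULL, years = 1,
                     bins = NULL) {
  rates <- compute_rates(lc_t0, lc_t1, regions, years)
  weights <- suppressWarnings(
    compute_weights(lc_t0, lc_t1, variables, bins, regions))
  structure(
    list(rates = rates, weights = weights, bins = attr(weights, "bins"),
         years = years, variables = names(variables),
         regions = sort(unique(rates$region)), call = match.call()),
    class = "lucc_model")
}

#' @export
print.lucc_model <- function(x, ...) {
  cat("Weights-of-evidence land-cover change model\n")
  cat(sprintf("  regions: %s\n", paste(x$regions, collapse = ", ")))
  cat(sprintf("  evidence variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  calibration window: %d year(s)\n", x$years))
  cat("Annual transition rates:\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}

#' @export
summary.lucc_model <- function(object, ...) {
  w <- object$weights
  structure(list(
    rates = as.data.frame(object$rates),
    patch = attr(object$rates, "patch"),
    n_weights = nrow(w),
    weight_range = if (nrow(w)) range(w$weight) else c(NA, NA),
    regions = object$regions,
    variables = object$variables),
    class = "summary.lucc_model")
}

#' @export
print.summary.lucc_model <- function(x, ...) {
  cat("Annual transition rates:\n"); print(x$rates, row.names = FALSE)
  cat("\nPatch geometry:\n"); print(x$patch, row.names = FALSE)
  cat(sprintf("\n%d evidence weights over %d variable(s); range [%.3f, %.3f]\n",
              x$n_weights, length(x$variables), x$weight_range[1], x$weight_range[2]))
  invisible(x)
}

#' @export
coef.lucc_model <- function(object, ...) {
  stats::setNames(object$rates$rate,
                  paste(object$rates$region, object$rates$transition, sep = ":"))
}

#' Posterior transition-probability surface from a fitted model
#'
#' @param object a `lucc_model`.
#' @param variables named list of static-variable maps (current landscape).
#' @param transition one of `TRANSITIONS`.
#' @param region region name whose weights and prior to use.
#' @param prior optional prior; defaults to the region's calibrated annual
#'   rate (floored away from 0).
#' @param ... unused.
#' @return A `grid_map` (role `"generic"`) of posterior probabilities.
#' @export
predict.lucc_model <- function(object, variables, transition = TRANSITIONS[["F2D"]],
                               region = "NONE", prior = NULL, ...) {
  prior <- prior %||% max(get_rate(object$rates, region, transition), 1e-6)
  p <- posterior_surface(object$weights, prior, variables, transition, region)
  tmpl <- variables[[1]]
  grid_map(p, cell_size = tmpl$cell_size, xll = tmpl$xll, yll = tmpl$yll,
           role = "generic")
}
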