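#' Riparian APP buffer-width rule
#'
#' The width-class table mapping watercourse width to the width of its area
#' of permanent preservation (APP) under Law 12,651/2012 at 30-m raster
#' resolution: channels under 30 m get a single 30-m buffer; 30-50 m get
#' 50 m; 50-200 m get 100 m; 200-600 m get 200 m; wider than 600 m get
#' 500 m. Class intervals are left-closed.
#'
#' @param table optional replacement data.frame with columns `min_width`,
#'   `max_width`, `buffer_m` (must totally order widths with no gaps and
#'   non-decreasing buffers).
#' @return An object of class `app_rule`.
#' @export
app_rule <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      min_width = c(0, 30, 50, 200, 600),
      max_width = c(30, 50, 200, 600, Inf),
      buffer_m  = c(30, 50, 100, 200, 500))
  }
  table <- table[order(table$min_width), ]
  if (any(table$min_width[-1] != table$max_width[-nrow(table)])) {
    stop("width classes must be contiguous (no gaps)")
  }
  if (is.unsorted(table$buffer_m)) stop("buffer width must be non-decreasing in channel width")
  structure(table, class = c("app_rule", "data.frame"))
}

#' @rdname app_rule
#' @param width_m watercourse width(s), meters (> 0).
#' @param rule an `app_rule`.
#' @return `app_buffer_width()`: buffer width(s) in meters.
#' @export
app_buffer_width <- function(width_m, rule = app_rule()) {
  if (any(width_m <= 0)) stop("watercourse width must be positive")
  i <- findInterval(width_m, c(rule$min_width, Inf), rightmost.closed = FALSE)
  rule$buffer_m[i]
}

#' Rasterize the riparian APP of a river network
#'
#' Buffers every reach outward from the chosen reference edge by its width
#' class's APP width and unions the result. Under the 2012 Code
#' (`reference = "REGULAR_CHANNEL"`) the buffer is measured from the edge of
#' the regular channel; under the 1965 Code (`"MAX_WATER_LEVEL"`) from the
#' edge of the floodplain at maximum water level, so the floodplain itself
#' (beyond the channel) is part of the protected strip. Channel water cells
#' are excluded from the returned membership mask.
#'
#' @param rivers a [river_network()].
#' @param rule an [app_rule()].
#' @param reference `"REGULAR_CHANNEL"` or `"MAX_WATER_LEVEL"`.
#' @param nr,nc,cell_size,xll,yll target grid geometry.
#' @return A 0/1 `grid_map` of APP membership.
#' @export
app_buffer <- function(rivers, rule = app_rule(),
                       reference = c("REGULAR_CHANNEL", "MAX_WATER_LEVEL"),
                       nr, nc, cell_size = 30, xll = 0, yll = 0) {
  reference <- match.arg(reference)
  app <- matrix(FALSE, nr, nc)
  chan_all <- matrix(FALSE, nr, nc)
  for (r in rivers$reaches) {
    width <- if (reference == "REGULAR_CHANNEL") r$regular_width_m else r$maxlevel_width_m
    buf <- app_buffer_width(width, rule)
    edge <- reach_channel_mask(r, nr, nc, cell_size, xll, yll,
                               if (reference == "REGULAR_CHANNEL") "regular" else "maxlevel")
    app <- app | dilate_mask(edge, buf, cell_size)
    chan_all <- chan_all | reach_channel_mask(r, nr, nc, cell_size, xll, yll, "regular")
  }
  app <- app & !chan_all
  grid_map(matrix(as.integer(app), nr, nc), cell_size = cell_size,
           xll = xll, yll = yll, role = "mask")
}

#' Scenario definition
#'
#' Encodes the rules of the three simulated futures. `BASELINE`: historical
#' behavior, six regions, APP delimited at the maximum water level but with
#' no restriction on its use. `CODE1965`: full compliance with Law
#' 4771/1965 — APP from the maximum water level, clearing and
#' secondary-cutting forbidden inside it, and the displaced (leaked) demand
#' transferred to the secondary-cutting rates of the receiving regions.
#' `CODE2012`: full compliance with Law 12,651/2012 — APP from the regular
#' channel, a seventh APP2008 region (APP already cleared by 2008) where
#' secondary cutting remains permitted.
#'
#' @param name one of `"BASELINE"`, `"CODE1965"`, `"CODE2012"`.
#' @param leakage_enabled override the default leakage flag (must stay `TRUE`
#'   for `CODE1965`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("BASELINE", "CODE1965", "CODE2012"),
                            leakage_enabled = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    BASELINE = list(
      app_reference = "MAX_WATER_LEVEL", regions_used = 6,
      forbidden = data.frame(region = character(), transition = character()),
      leakage_enabled = FALSE),
    CODE1965 = list(
      app_reference = "MAX_WATER_LEVEL", regions_used = 6,
      forbidden = data.frame(
        region = "APP",
        transition = TRANSITIONS[c("F2D", "S2D")],
        stringsAsFactors = FALSE),
      leakage_enabled = TRUE),
    CODE2012 = list(
      app_reference = "REGULAR_CHANNEL", regions_used = 7,
      forbidden = data.frame(
        region = c("APP", "APP", "APP2008"),
        transition = TRANSITIONS[c("F2D", "S2D", "F2D")],
        stringsAsFactors = FALSE),
      leakage_enabled = FALSE)
  )
  if (!is.null(leakage_enabled)) {
    if (name == "CODE1965" && !leakage_enabled) {
      stop("the 1965-Code scenario requires leakage_enabled = TRUE")
    }
    cfg$leakage_enabled <- leakage_enabled
  }
  structure(c(list(name = name), cfg), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario '%s'> APP from %s, %d regions, leakage %s\n",
              x$name, x$app_reference, x$regions_used,
              if (x$leakage_enabled) "on" else "off"))
  if (nrow(x$forbidden)) {
    cat("  forbidden:", paste(x$forbidden$region, x$forbidden$transition,
                              sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble the region map of a scenario
#'
#' Combines protected areas, the river buffer, road influence, isolated
#' areas and the APP into one categorical region raster with the precedence
#' CU > IR > APP (> APP2008 carve-out) > IL > RB > IA: the APP overrides all
#' regions except conservation units and the road-influence zone. The RB
#' region is a 1-km buffer around rivers at least 30 m wide. Under the 2012
#' Code the part of the APP already cleared (deforested or secondary) in the
#' 2008 map becomes the APP2008 region.
#'
#' @param cu_mask,il_mask logical protected-area matrices.
#' @param rivers a [river_network()].
#' @param roads list of road polylines.
#' @param app 0/1 APP `grid_map` (from [app_buffer()]).
#' @param scenario a [scenario_config()].
#' @param lc_2008 land-cover `grid_map` for 2008 (required for `CODE2012`).
#' @param ir_distance_m roads within this distance define the IR region
#'   (default 900 m).
#' @param template `grid_map` supplying geometry (e.g. the land-cover map).
#' @return A region `grid_map`.
#' @export
build_regions <- function(cu_mask, il_mask, rivers, roads, app, scenario,
                          lc_2008 = NULL, ir_distance_m = 900, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  if (scenario$name == "CODE2012" && is.null(lc_2008)) {
    stop("the 2012-Code scenario requires the 2008 land-cover map (lc_2008)")
  }
  # RB: 1-km buffer around rivers with regular width >= 30 m
  wide <- Filter(function(r) r$regular_width_m >= 30, rivers$reaches)
  rb <- matrix(FALSE, nr, nc)
  if (length(wide)) {
    chan <- matrix(FALSE, nr, nc)
    for (r in wide) chan <- chan | reach_channel_mask(r, nr, nc, cs,
                                                      template$xll, template$yll, "regular")
    rb <- dilate_mask(chan, 1000, cs)
  }
  road_mask <- rasterize_lines(roads, nr, nc, cs, template$xll, template$yll)
  ir <- distance_to(road_mask, cs) <= ir_distance_m
  appm <- !is.na(app$values) & app$values == 1

  reg <- matrix(region_code("IA"), nr, nc)  # residual region: isolated areas
  reg[rb] <- region_code("RB")
  reg[il_mask] <- region_code("IL")
  reg[appm] <- region_code("APP")
  if (scenario$name == "CODE2012") {
    cleared08 <- !is.na(lc_2008$values) &
      lc_2008$values %in% lc_code(c("DEFORESTED", "SECONDARY"))
    reg[appm & cleared08] <- region_code("APP2008")
  }
  reg[ir] <- region_code("IR")
  reg[cu_mask] <- region_code("CU")
  reg[is.na(template$values)] <- NA
  grid_map(reg, cell_size = cs, xll = template$xll, yll = template$yll,
           nodata = template$nodata, role = "region")
}

#' Transfer leaked clearing demand out of the APP
#'
#' Implements the 1965-scenario leakage: the APP's gross deforestation and
#' secondary-cutting rates are zeroed, and the displaced annual cell demand
#' is apportioned to the receiving regions in proportion to their
#' secondary-vegetation source areas, entering as increments to their net
#' secondary-cutting rates. Total displaced demand is conserved by
#' construction.
#'
#' @param rates a [rate_table()].
#' @param app_demand named numeric: displaced annual demand (cells/yr) per
#'   transition, e.g. `c("FOREST>DEFORESTED" = 120, "SECONDARY>DEFORESTED" = 40)`.
#' @param receiving named numeric: secondary-vegetation source cells per
#'   receiving region.
#' @return Updated `rate_table` with APP rates zeroed and receiving regions'
#'   secondary-cutting rates incremented.
#' @export
leakage_transfer <- function(rates, app_demand, receiving) {
  total <- sum(app_demand)
  rt <- as.data.frame(rates)
  zero <- rt$region == "APP" &
    rt$transition %in% TRANSITIONS[c("F2D", "S2D")]
  rt$rate[zero] <- 0
  if (total > 0) {
    if (!length(receiving) || sum(receiving) == 0) {
      warning("leakage transfer dropped ", round(total, 2),
              " cells/yr: no receiving secondary-vegetation source cells")
    } else {
      shares <- receiving / sum(receiving)
      for (rg in names(receiving)) {
        if (receiving[[rg]] == 0) next
        inc <- total * shares[[rg]] / receiving[[rg]]
        s2d <- TRANSITIONS[["S2D"]]
        cur <- get_rate_fb(rate_table(rt, attr(rates, "patch")), rg, s2d)
        i <- which(rt$region == rg & rt$transition == s2d)
        if (length(i)) {
          rt$rate[i[1]] <- min(cur + inc, 1)
        } else {
          rt <- rbind(rt, data.frame(region = rg, transition = s2d,
                                     rate = min(inc, 1)))
        }
      }
    }
  }
  rate_table(rt, attr(rates, "patch"))
}
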