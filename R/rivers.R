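#' Create a river network
#'
#' A set of river reaches, each a polyline with a regular-channel width and a
#' maximum-water-level (floodplain) width, plus the floodplain mask implied
#' by the latter. Widths are in meters; the maximum-level width must be at
#' least the regular width.
#'
#' @param reaches list of reaches; each a list with elements `coords`
#'   (two-column matrix of x,y map coordinates), `regular_width_m`,
#'   `maxlevel_width_m`.
#' @return An object of class `river_network`.
#' @export
river_network <- function(reaches) {
  for (r in reaches) {
    stopifnot(is.matrix(r$coords), ncol(r$coords) == 2)
    if (!(r$regular_width_m > 0)) stop("regular_width_m must be > 0")
    if (r$maxlevel_width_m < r$regular_width_m) {
      stop("maxlevel_width_m must be >= regular_width_m")
    }
  }
  structure(list(reaches = reaches), class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  w <- vapply(x$reaches, `[[`, numeric(1), "regular_width_m")
  cat(sprintf("<river_network> %d reaches, regular widths %s m\n",
              length(x$reaches), paste(sort(unique(w)), collapse = "/")))
  invisible(x)
}

#' Read / write a river network as GeoJSON
#'
#' LineString features with numeric properties `regular_width_m` and
#' `maxlevel_width_m`.
#'
#' @param path file path.
#' @return `read_rivers()` a `river_network`; `write_rivers()` the path,
#'   invisibly.
#' @export
read_rivers <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  reaches <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      stop("river features must be LineString geometries")
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    list(coords = coords,
         regular_width_m = as.numeric(f$properties$regular_width_m),
         maxlevel_width_m = as.numeric(f$properties$maxlevel_width_m))
  })
  river_network(reaches)
}

#' @rdname read_rivers
#' @param rivers a `river_network`.
#' @export
write_rivers <- function(rivers, path) {
  feats <- lapply(rivers$reaches, function(r) {
    list(type = "Feature",
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(r$coords)),
                                function(i) as.numeric(r$coords[i, ]))),
         properties = list(regular_width_m = r$regular_width_m,
                           maxlevel_width_m = r$maxlevel_width_m))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# channel mask of one reach: cells within regular_width/2 of the centerline
reach_channel_mask <- function(reach, nr, nc, cell_size, xll = 0, yll = 0,
                               reference = c("regular", "maxlevel")) {
  reference <- match.arg(reference)
  w <- if (reference == "regular") reach$regular_width_m else reach$maxlevel_width_m
  center <- rasterize_lines(reach$coords, nr, nc, cell_size, xll, yll)
  dilate_mask(center, w / 2, cell_size)
}

# channel mask (regular widths) of the whole network
channel_mask <- function(rivers, nr, nc, cell_size, xll = 0, yll = 0) {
  m <- matrix(FALSE, nr, nc)
  for (r in rivers$reaches) {
    m <- m | reach_channel_mask(r, nr, nc, cell_size, xll, yll, "regular")
  }
  m
}

# floodplain mask (maximum water level widths) of the whole network
floodplain_mask <- function(rivers, nr, nc, cell_size, xll = 0, yll = 0) {
  m <- matrix(FALSE, nr, nc)
  for (r in rivers$reaches) {
    m <- m | reach_channel_mask(r, nr, nc, cell_size, xll, yll, "maxlevel")
  }
  m
}
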