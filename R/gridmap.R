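#' Create a grid map
#'
#' The package's raster container: a numeric or integer matrix on a regular
#' grid with 0-based row-major indexing, top-left origin, and an explicit
#' cell size in meters (default 30 m, the working resolution of the model).
#' Missing cells are stored as `NA`; the nodata sentinel only appears on
#' disk. A `role` declares what the values mean and activates validation:
#' `"landcover"` and `"region"` enforce their closed code sets, `"biomass"`
#' enforces non-negativity, `"mask"` enforces {0,1}; `"generic"` accepts any
#' finite values.
#'
#' @param values numeric matrix (rows = grid rows from the top).
#' @param cell_size cell edge length in meters.
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata sentinel written to / read from disk for missing cells.
#' @param role one of `"landcover"`, `"region"`, `"mask"`, `"biomass"`,
#'   `"generic"`.
#' @return An object of class `grid_map`.
#' @export
grid_map <- function(values, cell_size = 30, xll = 0, yll = 0,
                     nodata = -9999, role = "generic") {
  if (!is.matrix(values)) values <- as.matrix(values)
  role <- match.arg(role, c("generic", "landcover", "region", "mask", "biomass"))
  storage.mode(values) <- if (role %in% c("landcover", "region", "mask")) "integer" else "double"
  g <- structure(
    list(values = values, cell_size = cell_size, xll = xll, yll = yll,
         nodata = nodata, role = role),
    class = "grid_map")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  v <- g$values
  ok <- switch(g$role,
    landcover = all(v[!is.na(v)] %in% LC_CODES),
    region    = all(v[!is.na(v)] %in% REGION_CODES),
    mask      = all(v[!is.na(v)] %in% c(0L, 1L)),
    biomass   = all(v[!is.na(v)] >= 0),
    generic   = all(is.finite(v[!is.na(v)]))
  )
  if (!ok) {
    bad <- which(!is.na(v) & !grid_value_legal(v, g$role), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("invalid value %s for role '%s' at cell (row %d, col %d) [0-based]",
                 format(v[bad[1], bad[2]]), g$role, bad[1] - 1L, bad[2] - 1L))
  }
  invisible(g)
}

grid_value_legal <- function(v, role) {
  switch(role,
    landcover = v %in% LC_CODES,
    region    = v %in% REGION_CODES,
    mask      = v %in% c(0L, 1L),
    biomass   = v >= 0,
    generic   = is.finite(v)
  )
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map role='%s'> %d x %d cells, %g m resolution\n",
              x$role, nrow(x$values), ncol(x$values), x$cell_size))
  nv <- x$values[!is.na(x$values)]
  if (x$role %in% c("landcover", "region", "mask")) {
    tab <- table(nv)
    cat("  codes:", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  } else if (length(nv)) {
    cat(sprintf("  range: [%g, %g]\n", min(nv), max(nv)))
  }
  invisible(x)
}

#' @export
plot.grid_map <- function(x, main = NULL, ...) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), useRaster = TRUE, axes = FALSE,
                  main = main %||% sprintf("grid_map (%s)", x$role), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.grid_map <- function(x) dim(x$values)

cell_area_ha <- function(g) (g$cell_size / 100)^2
cell_area_km2 <- function(g) (g$cell_size / 1000)^2

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

#' Read a grid map from an ESRI ASCII grid file
#'
#' The on-disk raster format is the plain-text ESRI ASCII grid: a 6-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `nodata_value`) followed by rows of values, top row first.
#'
#' @param path file path.
#' @param role map role passed to [grid_map()]; invalid codes for the role
#'   raise a validation error naming the offending cell.
#' @return A `grid_map`.
#' @export
read_grid <- function(path, role = "generic") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, " (missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid body has %d values, expected %d", length(vals), nr * nc))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  grid_map(m, cell_size = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner,
           nodata = hdr$nodata_value, role = role)
}

#' Write a grid map to an ESRI ASCII grid file
#'
#' @param g a `grid_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  stopifnot(inherits(g, "grid_map"))
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("nodata_value %.10g", g$nodata)
  )
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-class areas of a land-cover map
#'
#' Counts cells per land-cover class and converts to km² using the map's
#' cell size. Nodata cells are excluded; the per-class areas sum to the
#' total non-nodata area.
#'
#' @param map a land-cover `grid_map`.
#' @return data.frame with columns `class` and `area_km2`, one row per class
#'   in `LC_CODES` (zero area when absent).
#' @export
class_areas <- function(map) {
  stopifnot(inherits(map, "grid_map"))
  v <- map$values
  counts <- vapply(LC_CODES, function(code) sum(v == code, na.rm = TRUE), numeric(1))
  data.frame(class = names(LC_CODES),
             area_km2 = counts * cell_area_km2(map),
             row.names = NULL)
}

# ---- raster utilities ------------------------------------------------------

#' Chamfer distance transform
#'
#' Quasi-Euclidean (two-pass 1/sqrt(2) chamfer) distance in meters from every
#' cell to the nearest `TRUE` cell of a logical mask.
#'
#' @param mask logical matrix (or 0/1 `grid_map`).
#' @param cell_size cell edge length in meters (taken from the map if a
#'   `grid_map` is given).
#' @return numeric matrix of distances (0 on the mask, `Inf` if the mask is
#'   empty).
#' @export
distance_to <- function(mask, cell_size = 30) {
  if (inherits(mask, "grid_map")) {
    cell_size <- mask$cell_size
    mask <- !is.na(mask$values) & mask$values != 0
  }
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  if (!any(mask)) return(d)
  s2 <- sqrt(2)
  jj <- seq_len(nc)
  # in-row scans: min_k<=j (x[k] + (j-k)) = j + cummin(x - j); exactly the
  # sequential left-neighbor chamfer update, vectorized
  scan_lr <- function(x) jj + cummin(x - jj)
  scan_rl <- function(x) rev(jj + cummin(rev(x) - jj))
  # forward pass (top row to bottom row)
  d[1, ] <- scan_lr(d[1, ])
  if (nr > 1) for (i in 2:nr) {
    up <- d[i - 1, ]
    row <- pmin(d[i, ], up + 1,
                c(Inf, up[-nc] + s2),
                c(up[-1] + s2, Inf))
    d[i, ] <- scan_lr(row)
  }
  # backward pass (bottom row to top row)
  d[nr, ] <- pmin(d[nr, ], scan_rl(d[nr, ]))
  if (nr > 1) for (i in (nr - 1):1) {
    dn <- d[i + 1, ]
    row <- pmin(d[i, ], dn + 1,
                c(Inf, dn[-nc] + s2),
                c(dn[-1] + s2, Inf))
    d[i, ] <- pmin(row, scan_rl(row))
  }
  d * cell_size
}

# binary dilation of a logical matrix by a metric radius (meters);
# uses the chamfer transform so the structuring element is quasi-circular
dilate_mask <- function(mask, radius_m, cell_size = 30) {
  if (radius_m <= 0) return(mask)
  distance_to(mask, cell_size) <= radius_m
}

# count of 8-neighbors of each cell satisfying a logical matrix
neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr, nc)
  x <- matrix(as.integer(mask), nr, nc)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  for (s in shifts) {
    ri <- seq_len(nr) + s[1]; ci <- seq_len(nc) + s[2]
    keep_r <- ri >= 1 & ri <= nr; keep_c <- ci >= 1 & ci <= nc
    m[keep_r, keep_c] <- m[keep_r, keep_c] + x[ri[keep_r], ci[keep_c]]
  }
  m
}

# rasterize a polyline (matrix of x,y coords in map units) onto a logical
# matrix; optional half-width in meters thickens the line into a band
rasterize_lines <- function(lines, nr, nc, cell_size = 30, xll = 0, yll = 0,
                            half_width_m = 0) {
  mask <- matrix(FALSE, nr, nc)
  if (!length(lines)) return(mask)
  if (is.matrix(lines)) lines <- list(lines)
  for (ln in lines) {
    for (k in seq_len(nrow(ln) - 1L)) {
      p0 <- ln[k, ]; p1 <- ln[k + 1L, ]
      seg_len <- sqrt(sum((p1 - p0)^2))
      n <- max(2L, ceiling(seg_len / (cell_size / 2)))
      t <- seq(0, 1, length.out = n)
      xs <- p0[1] + t * (p1[1] - p0[1])
      ys <- p0[2] + t * (p1[2] - p0[2])
      cols <- pmin(pmax(floor((xs - xll) / cell_size) + 1L, 1L), nc)
      rows <- pmin(pmax(nr - floor((ys - yll) / cell_size), 1L), nr)
      mask[cbind(rows, cols)] <- TRUE
    }
  }
  if (half_width_m > 0) mask <- dilate_mask(mask, half_width_m, cell_size)
  mask
}

polyline_length_km <- function(line) {
  if (nrow(line) < 2) return(0)
  sum(sqrt(rowSums((line[-1, , drop = FALSE] - line[-nrow(line), , drop = FALSE])^2))) / 1000
}
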