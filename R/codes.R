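#' Land-cover and region code tables
#'
#' Integer codes used throughout the package for categorical rasters.
#' `LC_CODES` holds the six land-cover classes; `REGION_CODES` the model
#' regions that govern transition rates and scenario rules. `WATER`,
#' `NONFOREST` and `URBAN` are immutable during simulation.
#'
#' @format Named integer vectors.
#' @export
LC_CODES <- c(
  FOREST     = 1L,
  DEFORESTED = 2L,
  SECONDARY  = 3L,
  WATER      = 4L,
  NONFOREST  = 5L,
  URBAN      = 6L
)

#' @rdname LC_CODES
#' @export
REGION_CODES <- c(
  NONE    = 0L,
  CU      = 1L,  # conservation units
  IL      = 2L,  # indigenous lands
  RB      = 3L,  # 1-km buffer around rivers >= 30 m wide
  IR      = 4L,  # area under the influence of roads
  IA      = 5L,  # isolated areas without land access
  APP     = 6L,  # riparian permanent-preservation area
  APP2008 = 7L   # APP already cleared by 2008 (2012-Code scenario only)
)

# classes that never change state during simulation
IMMUTABLE_LC <- c(4L, 5L, 6L)

#' The three land-cover transitions the model simulates
#'
#' Deforestation (`F2D`), regeneration (`D2S`) and cutting of secondary
#' vegetation (`S2D`), encoded as "from>to" strings over `LC_CODES` names.
#' @export
TRANSITIONS <- c(
  F2D = "FOREST>DEFORESTED",
  D2S = "DEFORESTED>SECONDARY",
  S2D = "SECONDARY>DEFORESTED"
)

transition_from <- function(tr) {
  vapply(strsplit(tr, ">", fixed = TRUE), `[`, character(1), 1L)
}

transition_to <- function(tr) {
  vapply(strsplit(tr, ">", fixed = TRUE), `[`, character(1), 2L)
}

lc_code <- function(name) {
  out <- LC_CODES[name]
  if (anyNA(out)) stop("unknown land-cover class: ", paste(name[is.na(out)], collapse = ", "))
  unname(out)
}

region_code <- function(name) {
  out <- REGION_CODES[name]
  if (anyNA(out)) stop("unknown region: ", paste(name[is.na(out)], collapse = ", "))
  unname(out)
}

lc_name <- function(code) {
  names(LC_CODES)[match(code, LC_CODES)]
}

region_name <- function(code) {
  names(REGION_CODES)[match(code, REGION_CODES)]
}
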