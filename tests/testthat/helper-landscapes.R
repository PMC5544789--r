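# shared fixtures, built in code

# uniform land-cover map from a class name (or matrix of codes)
make_lc <- function(x, nr = 10, nc = 10, cell_size = 30) {
  if (is.character(x)) x <- matrix(LC_CODES[[x]], nr, nc)
  grid_map(x, cell_size = cell_size, role = "landcover")
}

# a small synthetic study area shared across tests (built once per run)
.shared <- new.env(parent = emptyenv())
shared_landscape <- function() {
  if (is.null(.shared$syn)) {
    .shared$syn <- generate_landscape(synth_config(n_rows = 100, n_cols = 100, seed = 42))
  }
  .shared$syn
}

# a single straight east-west river, no sinuosity
straight_river <- function(width = 150, maxlevel = width, y = 1500, xmax = 3000) {
  river_network(list(list(coords = cbind(c(0, xmax), c(y, y)),
                          regular_width_m = width, maxlevel_width_m = maxlevel)))
}

# brute-force 2x2 contingency weight-of-evidence oracle
woe_oracle <- function(in_bin, event) {
  nT <- sum(event); nN <- sum(!event)
  pBT <- sum(in_bin & event) / nT
  pBN <- sum(in_bin & !event) / nN
  log(pBT / pBN)
}
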