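# Shared fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# A small but complete seascape reused across test files.
tiny_seascape <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- simulate_seascape(
      seascape_config(seed = 101, grid_extent = c(60, 80),
                      n_presences = 200, n_bottle_casts = 100))
  }
  .fixtures$tiny
}

# Full pipeline run on the tiny seascape, cached.
tiny_pipeline <- function() {
  if (is.null(.fixtures$tiny_cv)) {
    .fixtures$tiny_cv <- suppressWarnings(
      run_pipeline(tiny_seascape(), n_background = 1500, jackknife = FALSE))
  }
  .fixtures$tiny_cv
}

# A planar grid z = gx * x + gy * y (+ constant), for slope oracles.
plane_grid <- function(nr, nc, cellsize = 500, gx = 0, gy = 0, z0 = 1000) {
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), nc), nr, nc)
  x <- (col - 0.5) * cellsize
  y <- (row - 0.5) * cellsize
  chs_grid(z0 + gx * x + gy * y, 0, 0, cellsize)
}

# Brute-force AUC oracle: all pairwise comparisons, ties credited half.
auc_oracle <- function(p, b) {
  cmp <- outer(p, b, function(a, d) (a > d) + 0.5 * (a == d))
  mean(cmp)
}

# Degenerate climatology: value is an exact function of depth only.
flat_climatology <- function(levels, profile, nr = 4, nc = 5,
                             cellsize = 5000, variable = "temperature") {
  grids <- lapply(levels, function(z) {
    chs_grid(matrix(profile(z), nr, nc), 0, 0, cellsize)
  })
  depth_binned_field(variable, levels, grids)
}

# The 7-record QC toy: r1 clean (cell A), r2 trawl, r3 shallow,
# r4 unknown family, r5 duplicate of r1, r6 other taxon in cell A,
# r7 same taxon as r1 in cell B.
qc_toy_records <- function() {
  data.frame(
    x = c(100, 600, 700, 800, 150, 120, 900),
    y = c(100, 100, 200, 300, 200, 300, 100),
    depth = c(500, 500, 30, 500, 500, 500, 500),
    gear = c("ROV", "trawl", "ROV", "ROV", "ROV", "camera", "ROV"),
    order = c("Alcyonacea", "Alcyonacea", "Alcyonacea", "Alcyonacea",
              "Alcyonacea", "Antipatharia", "Alcyonacea"),
    suborder = c("Calcaxonia", "Calcaxonia", "Calcaxonia", "Calcaxonia",
                 "Calcaxonia", NA, "Calcaxonia"),
    family = c("Primnoidae", "Primnoidae", "Primnoidae", "unknown",
               "Primnoidae", "Antipathidae", "Primnoidae"),
    source = c("a", "b", "c", "d", "e", "f", "g"),
    id = paste0("r", 1:7))
}

qc_toy_grid <- function() chs_grid(matrix(0, 4, 4), 0, 0, 500)
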