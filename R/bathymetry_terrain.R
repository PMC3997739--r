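#' Clean raw soundings
#'
#' Drops soundings with non-finite coordinates or depths, non-positive
#' depths (depth is metres positive-down, so zero or negative values are
#' erroneous for seafloor soundings), and, when a target grid is given,
#' points outside its extent.  Removal counts are returned as an audit.
#'
#' @param raw data.frame with columns `x`, `y`, `depth`
#' @param extent optional `chs_grid` whose extent bounds valid soundings
#' @return data.frame of surviving soundings with an `audit` attribute
#'   (named integer vector: `nonfinite`, `nonpositive_depth`,
#'   `out_of_extent`)
#' @export
clean_soundings <- function(raw, extent = NULL) {
  if (nrow(raw) == 0L) {
    out <- raw
    attr(out, "audit") <- c(nonfinite = 0L, nonpositive_depth = 0L,
                            out_of_extent = 0L)
    return(out)
  }
  finite <- is.finite(raw$x) & is.finite(raw$y) & is.finite(raw$depth)
  pos <- finite & raw$depth > 0
  inext <- pos
  if (!is.null(extent)) {
    xmax <- extent$xll + ncol(extent$values) * extent$cellsize
    ymax <- extent$yll + nrow(extent$values) * extent$cellsize
    inext <- pos & raw$x >= extent$xll & raw$x < xmax &
      raw$y >= extent$yll & raw$y < ymax
  }
  out <- raw[inext, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- c(
    nonfinite = sum(!finite),
    nonpositive_depth = sum(finite & !pos),
    out_of_extent = sum(pos & !inext)
  )
  out
}

#' Grid scattered soundings to a bathymetry raster
#'
#' Cell value is the median of all soundings whose coordinates fall in the
#' cell's half-open footprint.  Cells that no sounding constrains are
#' filled from a coarser infill grid by nearest-neighbour resampling;
#' cells empty in both are no-data.  The per-cell median replaces the
#' spline gridder used in comparable GIS workflows: it is deterministic,
#' dependency-free and robust to outliers, and none of the downstream
#' statistics depend on the interpolator's smoothness.
#'
#' @param soundings data.frame with `x`, `y`, `depth` (already cleaned)
#' @param grid_spec `chs_grid` giving the target geometry (values ignored)
#' @param infill optional coarser `chs_grid` used to fill unconstrained cells
#' @return `chs_grid` of depths with attributes `fraction_constrained`
#'   (share of cells holding >= 1 sounding) and `n_infilled`
#' @export
grid_soundings <- function(soundings, grid_spec, infill = NULL) {
  if (grid_spec$cellsize <= 0) stop("cell size must be positive")
  nr <- nrow(grid_spec$values); nc <- ncol(grid_spec$values)
  m <- matrix(NA_real_, nr, nc)
  if (nrow(soundings)) {
    idx <- grid_cell_at(soundings$x, soundings$y, grid_spec)
    ok <- idx$inside
    cell <- (idx$col[ok] - 1L) * nr + idx$row[ok]
    med <- tapply(soundings$depth[ok], cell, stats::median)
    m[as.integer(names(med))] <- as.numeric(med)
  }
  frac <- mean(!is.na(m))
  n_infilled <- 0L
  if (!is.null(infill)) {
    res <- grid_resample_nearest(infill, grid_spec)
    fill <- is.na(m) & !is.na(res$values)
    m[fill] <- res$values[fill]
    n_infilled <- sum(fill)
  }
  g <- chs_grid(m, grid_spec$xll, grid_spec$yll, grid_spec$cellsize)
  attr(g, "fraction_constrained") <- frac
  attr(g, "n_infilled") <- n_infilled
  g
}

#' Horn slope at a configurable moving-window scale
#'
#' Computes terrain slope in degrees with Horn's 8-neighbour weighted
#' finite differences.  For windows larger than one cell the grid is first
#' aggregated by block means to the window resolution, Horn's gradient is
#' evaluated there, and the result is assigned back to every constituent
#' fine cell — the multiscale "moving window" behaviour used for
#' broad-scale slope proxies of current acceleration and mixing.  Horn's
#' estimator reproduces the gradient of a plane exactly, so planar inputs
#' give `atan(|g|)` at every interior cell for every window.
#'
#' @param bathymetry `chs_grid` of depth (metres, positive-down; slope is
#'   sign-invariant)
#' @param window window edge length in metres (>= cell size); rounded to
#'   the nearest integer multiple of the cell size
#' @return `chs_grid` of slope in degrees with attribute `window`
#'   (the realized window, metres); no-data wherever the Horn stencil
#'   touches a missing or out-of-grid cell
#' @export
horn_slope <- function(bathymetry, window = NULL) {
  s <- bathymetry$cellsize
  if (is.null(window)) window <- s
  if (window < s) stop("window must be at least one cell size")
  factor <- max(1L, as.integer(round(window / s)))
  coarse <- grid_block_mean(bathymetry, factor)
  sl <- horn_slope_matrix(coarse$values, coarse$cellsize)
  # assign the coarse slope back to constituent fine cells
  nr <- nrow(bathymetry$values); nc <- ncol(bathymetry$values)
  ri <- pmin((seq_len(nr) - 1L) %/% factor + 1L, nrow(sl))
  ci <- pmin((seq_len(nc) - 1L) %/% factor + 1L, ncol(sl))
  fine <- sl[ri, ci, drop = FALSE]
  # fine cells in trailing partial blocks have no coarse parent
  if (nr > nrow(sl) * factor) fine[(nrow(sl) * factor + 1L):nr, ] <- NA_real_
  if (nc > ncol(sl) * factor) fine[, (ncol(sl) * factor + 1L):nc] <- NA_real_
  fine[is.na(bathymetry$values)] <- NA_real_
  out <- chs_grid(fine, bathymetry$xll, bathymetry$yll, bathymetry$cellsize)
  attr(out, "window") <- factor * s
  out
}

# Horn gradient on a bare matrix; returns slope degrees with NA border.
horn_slope_matrix <- function(z, cellsize) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  if (nr < 3L || nc < 3L) return(out)
  # 8 neighbours of interior cells (rows run south->north, cols west->east)
  i <- 2:(nr - 1L); j <- 2:(nc - 1L)
  nw <- z[i + 1L, j - 1L]; n_ <- z[i + 1L, j]; ne <- z[i + 1L, j + 1L]
  w_ <- z[i, j - 1L];                         e_ <- z[i, j + 1L]
  sw <- z[i - 1L, j - 1L]; s_ <- z[i - 1L, j]; se <- z[i - 1L, j + 1L]
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cellsize)
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cellsize)
  out[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  out
}
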