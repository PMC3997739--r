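#' Planar raster grid
#'
#' A minimal planar raster container used throughout the pipeline for
#' bathymetry, environmental layers, habitat suitability, consensus,
#' substrate and trawl-intensity surfaces.  Values live in a numeric matrix;
#' row `i` counts northwards from the southern edge, column `j` eastwards
#' from the western edge, so cell `(i, j)` has the half-open footprint
#' `[xll + (j-1)*s, xll + j*s) x [yll + (i-1)*s, yll + i*s)` with `s` the
#' cell size in metres.  `NA` is the no-data sentinel.
#'
#' Coordinates are planar metres: the analysis treats the 500 m grid as
#' equal-area, so every cell covers exactly `cellsize^2` square metres and
#' no geodesy is involved.
#'
#' @param values numeric matrix (rows = south to north, cols = west to east)
#' @param xll,yll coordinates of the lower-left (south-west) grid corner, metres
#' @param cellsize cell edge length, metres (> 0)
#' @return an object of class `chs_grid`
#' @export
chs_grid <- function(values, xll = 0, yll = 0, cellsize = 500) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0) {
    stop("cellsize must be a single positive number (metres)")
  }
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize)),
    class = "chs_grid"
  )
}

#' @export
print.chs_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<chs_grid> %d x %d cells, %.9g m cells, origin (%.9g, %.9g)\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  cat(sprintf("  valid cells: %d / %d; range [%.6g, %.6g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.chs_grid <- function(x) dim(x$values)

grid_ncell <- function(g) length(g$values)

#' Cell-center coordinates of every cell
#'
#' @param g a `chs_grid`
#' @return data.frame with columns `row`, `col`, `x`, `y`, `value`
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  row <- rep.int(seq_len(nr), nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    row = row, col = col,
    x = g$xll + (col - 0.5) * g$cellsize,
    y = g$yll + (row - 0.5) * g$cellsize,
    value = as.vector(g$values)
  )
}

#' Map planar coordinates to grid cell indices
#'
#' Uses the half-open footprint convention: a point exactly on a cell's
#' west/south edge belongs to that cell; a point on the grid's east/north
#' outer edge is out of extent.
#'
#' @param x,y coordinates in metres
#' @param g a `chs_grid` (or anything with `xll`, `yll`, `cellsize` and a
#'   `values` matrix)
#' @return data.frame with integer columns `row`, `col` (`NA` when out of
#'   extent) and logical `inside`
#' @export
grid_cell_at <- function(x, y, g) {
  col <- floor((x - g$xll) / g$cellsize) + 1L
  row <- floor((y - g$yll) / g$cellsize) + 1L
  inside <- !is.na(row) & !is.na(col) &
    row >= 1L & row <= nrow(g$values) & col >= 1L & col <= ncol(g$values)
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Value of a grid at planar points (cell lookup, no interpolation)
#'
#' @inheritParams grid_cell_at
#' @return numeric vector, `NA` outside the extent or over no-data
#' @export
grid_value_at <- function(x, y, g) {
  idx <- grid_cell_at(x, y, g)
  out <- rep(NA_real_, length(x))
  ok <- idx$inside
  out[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

grid_same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stopifnot_same_geometry <- function(a, b) {
  if (!grid_same_geometry(a, b)) stop("grids have mismatched geometry")
}

#' Nearest-neighbour resampling of a grid onto another grid's geometry
#'
#' Each target cell takes the value of the source cell containing its
#' center (nearest-neighbour; no interpolation, matching the pipeline's
#' "resampled ... with no further interpolation" convention).
#'
#' @param src source `chs_grid`
#' @param target `chs_grid` supplying the output geometry
#' @return `chs_grid` on `target`'s geometry
#' @export
grid_resample_nearest <- function(src, target) {
  cc <- grid_coords(target)
  # clamp centers into the source extent so targets that merely abut the
  # source edge still pick up the nearest source cell
  nr <- nrow(src$values); nc <- ncol(src$values)
  col <- pmin(pmax(floor((cc$x - src$xll) / src$cellsize) + 1, 1), nc)
  row <- pmin(pmax(floor((cc$y - src$yll) / src$cellsize) + 1, 1), nr)
  vals <- src$values[cbind(row, col)]
  chs_grid(matrix(vals, nrow(target$values), ncol(target$values)),
           target$xll, target$yll, target$cellsize)
}

#' Block-mean aggregation of a grid
#'
#' Aggregates `factor x factor` blocks of cells by their mean (ignoring
#' no-data); trailing rows/columns that do not fill a block are dropped.
#' Used to evaluate terrain derivatives at coarser moving-window scales.
#'
#' @param g a `chs_grid`
#' @param factor integer >= 1
#' @return `chs_grid` with cell size `factor * g$cellsize`
#' @export
grid_block_mean <- function(g, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("aggregation factor must be >= 1")
  if (factor == 1L) return(g)
  v <- g$values
  nr <- (nrow(v) %/% factor) * factor
  nc <- (ncol(v) %/% factor) * factor
  if (nr < factor || nc < factor) stop("grid smaller than one aggregation block")
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  dim(v) <- c(factor, nr %/% factor, factor, nc %/% factor)
  agg <- apply(v, c(2L, 4L), function(b) {
    b <- b[!is.na(b)]
    if (length(b)) mean(b) else NA_real_
  })
  chs_grid(agg, g$xll, g$yll, g$cellsize * factor)
}

#' Majority-rule aggregation of a categorical grid
#'
#' Resamples a finer categorical grid (integer class codes) onto a coarser
#' target geometry: each target cell takes the most frequent class among
#' the fine cells whose centers fall inside it.  Ties are broken by the
#' order of `tie_order` (first listed wins).
#'
#' @param fine `chs_grid` of integer class codes
#' @param target `chs_grid` giving the output geometry
#' @param tie_order integer vector of class codes, highest priority first
#' @return `chs_grid` of class codes on `target`'s geometry
#' @export
grid_majority_resample <- function(fine, target, tie_order = NULL) {
  cc <- grid_coords(fine)
  idx <- grid_cell_at(cc$x, cc$y, target)
  ok <- idx$inside & !is.na(cc$value)
  if (!any(ok)) stop("no fine cells fall inside the target extent")
  cell <- (idx$col[ok] - 1L) * nrow(target$values) + idx$row[ok]
  val <- as.integer(cc$value[ok])
  classes <- sort(unique(val))
  if (is.null(tie_order)) tie_order <- classes
  counts <- matrix(0L, grid_ncell(target), length(classes))
  for (k in seq_along(classes)) {
    tab <- tabulate(cell[val == classes[k]], nbins = grid_ncell(target))
    counts[, k] <- tab
  }
  # reorder columns by tie priority so max.col(ties.method = "first")
  # implements the documented tie-break
  pri <- match(tie_order, classes)
  pri <- pri[!is.na(pri)]
  pri <- c(pri, setdiff(seq_along(classes), pri))
  counts <- counts[, pri, drop = FALSE]
  cls <- classes[pri][max.col(counts, ties.method = "first")]
  cls[rowSums(counts) == 0L] <- NA_integer_
  chs_grid(matrix(cls, nrow(target$values), ncol(target$values)),
           target$xll, target$yll, target$cellsize)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows from north to south).
#'
#' @param path file path
#' @param g a `chs_grid`
#' @param nodata no-data sentinel written in place of `NA`
#' @return `read_ascii_grid` returns a `chs_grid`; `write_ascii_grid`
#'   returns `path` invisibly
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  m <- m[nr:1, , drop = FALSE]  # file is north-first; internal rows run south-first
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  chs_grid(m, xll, yll, hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  for (i in nrow(v):1) {
    writeLines(paste(format(v[i, ], trim = TRUE, digits = 10), collapse = " "),
               con)
  }
  invisible(path)
}
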