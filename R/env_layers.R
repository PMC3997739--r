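#' Depth-binned climatology field
#'
#' An oceanographic variable gridded at standard depth levels: one coarse
#' horizontal grid per level, all sharing the same geometry, with strictly
#' increasing level depths (metres).  This mirrors how global climatology
#' products distribute annual-mean water-column properties.
#'
#' @param variable variable name (e.g. `"temperature"`)
#' @param levels strictly increasing depths, metres
#' @param grids list of `chs_grid`s, one per level, common geometry
#' @param units free-text units string
#' @return object of class `chs_dbf`
#' @export
depth_binned_field <- function(variable, levels, grids, units = "") {
  levels <- as.numeric(levels)
  if (length(levels) != length(grids)) stop("one grid per level required")
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("depth levels must be strictly increasing")
  }
  for (g in grids[-1]) stopifnot_same_geometry(grids[[1]], g)
  structure(list(variable = variable, levels = levels, grids = grids,
                 units = units),
            class = "chs_dbf")
}

#' @export
print.chs_dbf <- function(x, ...) {
  cat(sprintf("<chs_dbf> %s [%s]: %d levels (%g..%g m), %d x %d coarse cells\n",
              x$variable, x$units, length(x$levels), min(x$levels),
              max(x$levels), nrow(x$grids[[1]]$values),
              ncol(x$grids[[1]]$values)))
  invisible(x)
}

#' Inverse-distance-weighted interpolation of one depth-bin layer
#'
#' Interpolates a coarse layer onto a finer target geometry using
#' inverse-distance weighting over the `max_neighbors` nearest valid
#' source cell centers, `w_i = d_i^-power`.  A target point coincident
#' with a source center returns that source value exactly.  This is the
#' step that closes the horizontal gaps which otherwise open between
#' adjacent depth bins when each is clipped to its own seafloor band.
#'
#' @param level_grid coarse `chs_grid` (>= 1 valid cell)
#' @param target `chs_grid` giving the output geometry
#' @param power IDW exponent (default 2)
#' @param max_neighbors number of nearest sources used (default 8)
#' @return `chs_grid` on `target`'s geometry
#' @export
interp_bin_idw <- function(level_grid, target, power = 2, max_neighbors = 8) {
  src <- grid_coords(level_grid)
  src <- src[!is.na(src$value), , drop = FALSE]
  if (nrow(src) == 0L) stop("no valid source cells to interpolate from")
  tgt <- grid_coords(target)
  vals <- idw_interp(src$x, src$y, src$value, tgt$x, tgt$y,
                     power = power, k = max_neighbors)
  chs_grid(matrix(vals, nrow(target$values), ncol(target$values)),
           target$xll, target$yll, target$cellsize)
}

# k-nearest IDW from scattered sources to scattered targets.
idw_interp <- function(sx, sy, sv, tx, ty, power = 2, k = 8) {
  ns <- length(sx)
  k <- min(k, ns)
  out <- numeric(length(tx))
  # distance matrix in manageable blocks of target points
  block <- max(1L, floor(2e6 / ns))
  for (start in seq(1L, length(tx), by = block)) {
    idx <- start:min(start + block - 1L, length(tx))
    d2 <- outer(tx[idx], sx, "-")^2 + outer(ty[idx], sy, "-")^2
    for (r in seq_along(idx)) {
      dr <- d2[r, ]
      near <- order(dr)[seq_len(k)]
      dn <- sqrt(dr[near])
      if (dn[1] == 0) {
        out[idx[r]] <- sv[near[1]]
      } else {
        w <- dn^(-power)
        out[idx[r]] <- sum(w * sv[near]) / sum(w)
      }
    }
  }
  out
}

#' Extrude a depth-binned field onto the seafloor
#'
#' Implements the three-step up-scaling that turns a climatology volume
#' into a continuous seafloor raster: each depth bin is IDW-interpolated
#' to an intermediate resolution, resampled to the bathymetry geometry by
#' nearest-neighbour (no further interpolation), and clipped to the band
#' of seafloor whose depth is nearest that bin's level (ties to the
#' shallower level; depths beyond the deepest level clamp to the deepest
#' bin).  The bands partition the valid seafloor, so each cell receives a
#' value from exactly one bin, recorded in the provenance grid.
#'
#' @param field a `chs_dbf`
#' @param bathymetry `chs_grid` of depth, metres positive-down
#' @param power,max_neighbors IDW parameters (see [interp_bin_idw()])
#' @param intermediate_factor the intermediate interpolation geometry is
#'   this many times coarser than the bathymetry (default 5)
#' @return list of class `chs_seafloor_layer`: `grid` (values at
#'   bathymetry geometry, no-data exactly where bathymetry is no-data),
#'   `provenance` (`chs_grid` of 1-based source-bin indices), `variable`
#' @export
extrude_to_seafloor <- function(field, bathymetry, power = 2,
                                max_neighbors = 8, intermediate_factor = 5) {
  if (!length(field$levels)) stop("empty depth-binned field")
  depth <- bathymetry$values
  valid <- !is.na(depth)
  levels <- field$levels
  bin <- nearest_level_index(depth, levels)
  bin[!valid] <- NA_integer_

  # intermediate geometry: coarser than the bathymetry, finer than the bins
  ifac <- max(1L, as.integer(intermediate_factor))
  nr <- max(1L, nrow(depth) %/% ifac); nc <- max(1L, ncol(depth) %/% ifac)
  inter <- chs_grid(matrix(NA_real_, nr, nc), bathymetry$xll, bathymetry$yll,
                    bathymetry$cellsize * ifac)

  out <- matrix(NA_real_, nrow(depth), ncol(depth))
  for (k in sort(unique(bin[valid]))) {
    interp <- interp_bin_idw(field$grids[[k]], inter, power, max_neighbors)
    res <- grid_resample_nearest(interp, bathymetry)
    sel <- which(bin == k)
    out[sel] <- res$values[sel]
  }
  structure(list(
    grid = chs_grid(out, bathymetry$xll, bathymetry$yll, bathymetry$cellsize),
    provenance = chs_grid(matrix(as.numeric(bin), nrow(depth), ncol(depth)),
                          bathymetry$xll, bathymetry$yll, bathymetry$cellsize),
    variable = field$variable
  ), class = "chs_seafloor_layer")
}

# Index of the standard level nearest each depth; ties go to the
# shallower level; depths beyond the extremes clamp to the nearest end.
nearest_level_index <- function(depth, levels) {
  if (length(levels) == 1L) {
    idx <- ifelse(is.na(depth), NA_integer_, 1L)
    return(idx)
  }
  mid <- (levels[-1] + levels[-length(levels)]) / 2
  # (mid[k-1], mid[k]] intervals: a depth exactly at a midpoint joins the
  # shallower bin
  idx <- findInterval(depth, mid, left.open = TRUE) + 1L
  idx[is.na(depth)] <- NA_integer_
  idx
}

#' Validate a seafloor layer against water-bottle casts
#'
#' Applies the three cast filters — collected after 2001, carrying a
#' bottom-depth flag, and sampled within 5% of the local bathymetric
#' depth — then pairs each surviving cast with the layer value at its
#' cell and reports Pearson r and r-squared.  Casts with missing values
#' or falling over no-data cells are excluded and counted.
#'
#' @param layer a `chs_seafloor_layer` (or bare `chs_grid`)
#' @param casts data.frame with columns `x`, `y`, `sample_depth`, `year`,
#'   `bottom_flag`, `value`
#' @param bathymetry `chs_grid` of depth
#' @param depth_tolerance relative depth mismatch allowed (default 0.05)
#' @param min_year first admissible collection year (default 2002,
#'   i.e. "post-2001")
#' @return list: `n`, `r`, `r2` (NA when fewer than 3 survivors),
#'   `excluded` (named counts per filter), `pairs` (data.frame of
#'   bottle/layer value pairs)
#' @export
validate_with_bottles <- function(layer, casts, bathymetry,
                                  depth_tolerance = 0.05, min_year = 2002) {
  grid <- if (inherits(layer, "chs_seafloor_layer")) layer$grid else layer
  excl <- c(missing_value = 0L, pre_cutoff_year = 0L, no_bottom_flag = 0L,
            depth_mismatch = 0L, no_data_cell = 0L)
  keep <- rep(TRUE, nrow(casts))

  bad <- keep & !is.finite(casts$value)
  excl["missing_value"] <- sum(bad); keep <- keep & !bad
  bad <- keep & casts$year < min_year
  excl["pre_cutoff_year"] <- sum(bad); keep <- keep & !bad
  bad <- keep & !casts$bottom_flag
  excl["no_bottom_flag"] <- sum(bad); keep <- keep & !bad

  bd <- grid_value_at(casts$x, casts$y, bathymetry)
  bad <- keep & (is.na(bd) | abs(casts$sample_depth - bd) > depth_tolerance * bd)
  excl["depth_mismatch"] <- sum(bad); keep <- keep & !bad

  lv <- grid_value_at(casts$x, casts$y, grid)
  bad <- keep & is.na(lv)
  excl["no_data_cell"] <- sum(bad); keep <- keep & !bad

  pairs <- data.frame(bottle = casts$value[keep], layer = lv[keep])
  n <- nrow(pairs)
  if (n >= 3L && stats::sd(pairs$bottle) > 0 && stats::sd(pairs$layer) > 0) {
    r <- stats::cor(pairs$bottle, pairs$layer)
  } else if (n >= 3L) {
    r <- if (all(pairs$bottle == pairs$layer)) 1 else NA_real_
  } else {
    r <- NA_real_
  }
  list(n = n, r = r, r2 = r^2, excluded = excl, pairs = pairs)
}

#' Prune highly correlated variables
#'
#' Computes the full pairwise Pearson correlation matrix of candidate
#' layers sampled at common points and iteratively resolves every pair
#' with `|r|` above the threshold: the member not on the keep list is
#' dropped; if both are droppable the later-listed one goes; if both are
#' protected the pair is left in place (the ecophysiologically motivated
#' exception for depth, temperature and carbonate saturation).
#'
#' @param samples data.frame / matrix, one column per variable, sampled at
#'   >= 10 common points
#' @param threshold absolute-correlation cutoff (default 0.7)
#' @param keep_list variable names never dropped
#' @return list: `retained`, `dropped` (data.frame variable / partner / r),
#'   `matrix` (full Pearson matrix)
#' @export
correlation_prune <- function(samples, threshold = 0.7,
                              keep_list = character()) {
  samples <- as.data.frame(samples)
  vars <- names(samples)
  if (length(vars) < 2L) stop("need at least 2 variables")
  if (nrow(samples) < 10L) stop("need at least 10 sample points")
  unknown <- setdiff(keep_list, vars)
  if (length(unknown)) {
    stop("keep_list names unknown variables: ", paste(unknown, collapse = ", "))
  }
  cm <- stats::cor(as.matrix(samples), use = "pairwise.complete.obs")
  active <- vars
  dropped <- data.frame(variable = character(), partner = character(),
                        r = numeric())
  exempt <- matrix(FALSE, length(vars), length(vars),
                   dimnames = list(vars, vars))
  repeat {
    sub <- abs(cm[active, active, drop = FALSE])
    diag(sub) <- 0
    sub[exempt[active, active, drop = FALSE]] <- 0
    if (!length(sub) || max(sub, na.rm = TRUE) <= threshold) break
    ij <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    if (a %in% keep_list && b %in% keep_list) {
      exempt[a, b] <- exempt[b, a] <- TRUE
      next
    }
    drop <- if (a %in% keep_list) b
    else if (b %in% keep_list) a
    else vars[max(match(a, vars), match(b, vars))]  # later-listed goes
    other <- setdiff(c(a, b), drop)
    dropped <- rbind(dropped, data.frame(variable = drop, partner = other,
                                         r = cm[drop, other]))
    active <- setdiff(active, drop)
  }
  list(retained = active, dropped = dropped, matrix = cm)
}
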