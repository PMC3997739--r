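#' Substrate class codes
#'
#' Integer codes used in substrate grids: hard = 1, mixed = 2, soft = 3.
#' The order doubles as the majority-resampling tie-break (hard wins).
#' @export
SUBSTRATE_CLASSES <- c(hard = 1L, mixed = 2L, soft = 3L)

# fixed conversion: 1 square nautical mile = 1.852^2 km^2
KM2_PER_NM2 <- 3.429904

#' Suitability area within polygons
#'
#' Tabulates consensus-class areas inside each polygon.  A cell belongs
#' to a polygon iff its center is inside (no partial-cell weighting), so
#' areas are exact cell counts times the cell area, reported in both km^2
#' and nm^2.  The "suitable" summary counts every cell with consensus
#' value above zero.
#'
#' @param consensus `chs_grid` of integer consensus values 0..K
#' @param polygons named list of polygon rings (data.frames with `x`, `y`)
#' @param cell_area_km2 area of one cell; defaults to `cellsize^2` in km^2
#' @return list: `by_class` (data.frame polygon / class / n_cells /
#'   area_km2 / area_nm2) and `summary` (per polygon: total valid area,
#'   suitable area, suitable percentage)
#' @export
zonal_area <- function(consensus, polygons, cell_area_km2 = NULL) {
  if (is.null(cell_area_km2)) cell_area_km2 <- (consensus$cellsize / 1000)^2
  cc <- grid_coords(consensus)
  K <- attr(consensus, "K")
  if (is.null(K)) K <- max(cc$value, na.rm = TRUE)
  classes <- 0:K
  by_class <- list(); summary <- list()
  for (nm in names(polygons)) {
    inside <- point_in_polygon(cc$x, cc$y, polygons[[nm]]) & !is.na(cc$value)
    if (!any(inside)) {
      warning("polygon ", nm, " covers no valid cells")
    }
    counts <- vapply(classes, function(k) sum(cc$value[inside] == k),
                     integer(1))
    by_class[[nm]] <- data.frame(
      polygon = nm, class = classes, n_cells = counts,
      area_km2 = counts * cell_area_km2,
      area_nm2 = counts * cell_area_km2 / KM2_PER_NM2)
    total <- sum(counts); suitable <- sum(counts[classes > 0])
    summary[[nm]] <- data.frame(
      polygon = nm, total_km2 = total * cell_area_km2,
      suitable_km2 = suitable * cell_area_km2,
      suitable_nm2 = suitable * cell_area_km2 / KM2_PER_NM2,
      suitable_pct = if (total > 0) 100 * suitable / total else 0)
  }
  list(by_class = do.call(rbind, c(by_class, make.row.names = FALSE)),
       summary = do.call(rbind, c(summary, make.row.names = FALSE)))
}

#' Substrate composition of each suitability class
#'
#' Intersects the consensus map with the substrate classification and
#' reports, for every suitability class, the percentage of its cells on
#' hard, mixed and soft ground.  A finer substrate grid is first
#' resampled to the analysis geometry by majority rule (ties hard >
#' mixed > soft).  Suitability classes with no cells yield `NA` rows.
#'
#' @param consensus `chs_grid` of consensus values 0..K
#' @param substrate `chs_grid` of substrate codes (see
#'   [SUBSTRATE_CLASSES]), possibly at finer resolution
#' @return data.frame: `class`, `n_cells`, `hard_pct`, `mixed_pct`,
#'   `soft_pct` (each row summing to 100 up to rounding)
#' @export
substrate_cross_tab <- function(consensus, substrate) {
  if (!grid_same_geometry(consensus, substrate)) {
    substrate <- grid_majority_resample(substrate, consensus,
                                        tie_order = SUBSTRATE_CLASSES)
  }
  K <- attr(consensus, "K")
  if (is.null(K)) K <- max(consensus$values, na.rm = TRUE)
  cons <- as.vector(consensus$values)
  sub <- as.vector(substrate$values)
  ok <- !is.na(cons) & !is.na(sub)
  rows <- lapply(0:K, function(k) {
    sel <- ok & cons == k
    n <- sum(sel)
    pct <- if (n > 0) {
      100 * vapply(SUBSTRATE_CLASSES, function(code) sum(sub[sel] == code),
                   numeric(1)) / n
    } else rep(NA_real_, 3)
    data.frame(class = k, n_cells = n,
               hard_pct = pct[1], mixed_pct = pct[2], soft_pct = pct[3])
  })
  do.call(rbind, rows)
}

#' Trawl-line density with vessel-privacy masking
#'
#' For every cell center, sums the length of all trawl-line segments
#' clipped to the disc of the given radius and divides by the disc area,
#' yielding km of trawl line per km^2.  Cells to which fewer than
#' `min_vessels` distinct vessels contribute are masked to no-data,
#' mirroring the confidentiality rule of fishery logbook products.
#'
#' @param lines data.frame of segments: `x0, y0, x1, y1, vessel_id`
#' @param grid_spec `chs_grid` giving the output geometry
#' @param radius neighbourhood radius in metres (default 3000)
#' @param min_vessels privacy threshold (default 3); set `privacy = FALSE`
#'   to disable masking
#' @param privacy apply the vessel-count mask (default TRUE)
#' @return `chs_grid` of density (km/km^2) with attribute `vessel_count`
#'   (`chs_grid` of contributing-vessel counts)
#' @export
trawl_line_density <- function(lines, grid_spec, radius = 3000,
                               min_vessels = 3, privacy = TRUE) {
  if (radius <= 0) stop("radius must be positive")
  nr <- nrow(grid_spec$values); nc <- ncol(grid_spec$values)
  total <- matrix(0, nr, nc)
  vessels <- if (nrow(lines)) unique(lines$vessel_id) else character(0)
  seen <- matrix(FALSE, length(vessels), nr * nc)
  s <- grid_spec$cellsize
  cx <- grid_spec$xll + (seq_len(nc) - 0.5) * s
  cy <- grid_spec$yll + (seq_len(nr) - 0.5) * s
  for (i in seq_len(nrow(lines))) {
    p0 <- c(lines$x0[i], lines$y0[i]); p1 <- c(lines$x1[i], lines$y1[i])
    d <- p1 - p0; L2 <- sum(d^2)
    if (L2 == 0) next
    L <- sqrt(L2)
    # candidate cells: segment bounding box inflated by the radius
    jr <- which(cx >= min(p0[1], p1[1]) - radius &
                  cx <= max(p0[1], p1[1]) + radius)
    ir <- which(cy >= min(p0[2], p1[2]) - radius &
                  cy <= max(p0[2], p1[2]) + radius)
    if (!length(jr) || !length(ir)) next
    ex <- rep(cx[jr], each = length(ir)); ey <- rep(cy[ir], length(jr))
    fx <- p0[1] - ex; fy <- p0[2] - ey
    b <- 2 * (d[1] * fx + d[2] * fy)
    cq <- fx^2 + fy^2 - radius^2
    disc <- b^2 - 4 * L2 * cq
    hit <- disc > 0
    if (!any(hit)) next
    sq <- sqrt(disc[hit])
    t1 <- pmax((-b[hit] - sq) / (2 * L2), 0)
    t2 <- pmin((-b[hit] + sq) / (2 * L2), 1)
    clen <- pmax(t2 - t1, 0) * L
    rows <- rep(ir, length(jr))[hit]
    cols <- rep(jr, each = length(ir))[hit]
    pos <- (cols - 1L) * nr + rows
    nonzero <- clen > 0
    if (any(nonzero)) {
      idx <- pos[nonzero]
      add <- clen[nonzero]
      total[idx] <- total[idx] + add
      seen[match(lines$vessel_id[i], vessels), idx] <- TRUE
    }
  }
  disc_area_km2 <- pi * (radius / 1000)^2
  dens <- total / 1000 / disc_area_km2
  vcount <- matrix(colSums(seen), nr, nc)
  if (privacy) dens[vcount < min_vessels] <- NA_real_
  out <- chs_grid(dens, grid_spec$xll, grid_spec$yll, grid_spec$cellsize)
  attr(out, "vessel_count") <- chs_grid(vcount, grid_spec$xll,
                                        grid_spec$yll, grid_spec$cellsize)
  out
}

#' Joint histogram of trawl intensity by suitability class
#'
#' Counts unmasked valid cells in each (consensus class, intensity bin)
#' combination; intensity bins are half-open on the right
#' (`[b_k, b_{k+1})`), so zero intensity falls in the first bin.
#'
#' @param consensus `chs_grid` of consensus values 0..K
#' @param intensity `chs_grid` of trawl density (same geometry)
#' @param bins increasing numeric break points (default
#'   `c(0, 0.5, 1, 2, 4, 8, Inf)`)
#' @return list: `counts` (matrix class x bin), `class_totals`,
#'   `bin_totals`, `n` (total cells counted)
#' @export
intensity_by_class <- function(consensus, intensity,
                               bins = c(0, 0.5, 1, 2, 4, 8, Inf)) {
  stopifnot_same_geometry(consensus, intensity)
  K <- attr(consensus, "K")
  if (is.null(K)) K <- max(consensus$values, na.rm = TRUE)
  cons <- as.vector(consensus$values)
  inten <- as.vector(intensity$values)
  ok <- !is.na(cons) & !is.na(inten)
  bin <- cut(inten[ok], breaks = bins, right = FALSE, include.lowest = TRUE)
  cls <- factor(cons[ok], levels = 0:K)
  counts <- table(class = cls, bin = bin)
  list(counts = unclass(counts),
       class_totals = rowSums(counts), bin_totals = colSums(counts),
       n = sum(ok))
}

#' Environmental niche summary at presence sites
#'
#' Summarizes the environmental conditions occupied by a presence set:
#' per-variable minimum, maximum, mean and percentiles, the fraction of
#' presences falling within user-specified half-open ranges `[a, b)`
#' (supporting statements like "82% of presences lie at saturation
#' states between 1 and 2"), and a smoothed density trace per variable
#' for bean-plot style rendering.
#'
#' @param presence_env data.frame of layer values at presences (NA rows
#'   mark no-data intersections and are excluded but counted)
#' @param ranges optional named list: variable -> `c(a, b)` (or a list of
#'   such ranges) for the fraction-within computation
#' @param percentiles probabilities reported (default 5/25/50/75/95)
#' @param bw density bandwidth passed to [stats::density()] (default
#'   `"nrd0"`)
#' @return list: `summary` (data.frame per variable), `fractions`
#'   (data.frame variable / lower / upper / fraction_pct), `density`
#'   (named list of x/y data.frames), `n_no_data` (per variable)
#' @export
niche_summary <- function(presence_env, ranges = NULL,
                          percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                          bw = "nrd0") {
  presence_env <- as.data.frame(presence_env)
  summ <- list(); dens <- list(); fracs <- list()
  n_na <- vapply(presence_env, function(v) sum(is.na(v)), integer(1))
  for (v in names(presence_env)) {
    x <- presence_env[[v]]; x <- x[!is.na(x)]
    if (!length(x)) {
      warning("all presence intersections are no-data for ", v)
      next
    }
    qs <- stats::quantile(x, percentiles, names = FALSE)
    row <- data.frame(variable = v, n = length(x), min = min(x),
                      max = max(x), mean = mean(x))
    for (i in seq_along(percentiles)) {
      row[[sprintf("p%g", 100 * percentiles[i])]] <- qs[i]
    }
    summ[[v]] <- row
    dens[[v]] <- if (length(x) >= 2 && stats::sd(x) > 0) {
      d <- stats::density(x, bw = bw)
      data.frame(x = d$x, y = d$y)
    } else data.frame(x = x[1], y = 1)
    if (!is.null(ranges[[v]])) {
      rgs <- ranges[[v]]
      if (!is.list(rgs)) rgs <- list(rgs)
      for (rg in rgs) {
        fracs[[length(fracs) + 1L]] <- data.frame(
          variable = v, lower = rg[1], upper = rg[2],
          fraction_pct = 100 * mean(x >= rg[1] & x < rg[2]))
      }
    }
  }
  list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
       fractions = if (length(fracs)) {
         do.call(rbind, c(fracs, make.row.names = FALSE))
       } else NULL,
       density = dens, n_no_data = n_na)
}
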