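#' Configuration of a synthetic seascape
#'
#' The generator states a complete world: a shelf-slope bathymetry cut by
#' canyons and studded with seamounts, depth-monotone climatology
#' profiles with coarse horizontal structure, coral presences sampled
#' from a known suitability surface with clustered sampling bias (an
#' intensively surveyed canyon analog) plus injected contaminant records,
#' sanctuary polygons, a slope-correlated substrate classification and
#' vessel-attributed trawl lines.  Every downstream stage can then be
#' validated against known truth without external data.
#'
#' @param seed integer master seed; every generator call derives its own
#'   deterministic sub-stream, so outputs are byte-identical per seed and
#'   adding one generator never perturbs another
#' @param grid_extent cells as `c(rows, cols)` (default 120 x 160)
#' @param cell_size metres (default 500)
#' @param depth_levels strictly increasing standard levels, metres
#' @param n_presences clean presence records to draw (default 300)
#' @param sampling_bias_strength extra sampling weight multiplier inside
#'   the bias polygon (>= 0; default 2, i.e. 3x oversampling)
#' @param suitability_exponent gamma: sampling probability is
#'   `suitability^gamma` (default 3); with a negative-intercept logistic
#'   `s^gamma ~ exp(gamma * lin)`, i.e. presence intensity approximately
#'   log-linear in the environment, the canonical presence-background
#'   simulation design
#' @param contaminant_rates named fractions in `[0, 1]` of `n_presences`
#'   appended as trawl-gear, shallow (< 50 m), unknown-family and
#'   spatial-duplicate contaminants
#' @param true_weights named coefficients of the generative suitability
#'   function on standardized layers (defaults: temperature -3, slope 3,
#'   depth -5).  The negative temperature and depth weights give the
#'   cold-water azooxanthellate niche its interior depth optimum: warm
#'   shallow water and the abyssal plain are both unsuitable, and the
#'   suitable band sits on the mid-depth slope where canyon walls and
#'   seamount flanks are steep
#' @param suitability_intercept intercept of the generative logistic
#'   (default -2): suitable habitat is rare relative to the extent
#' @param shelf_depth,max_depth depth range of the ramp, metres
#' @param n_canyons,canyon_amp,n_seamounts,seamount_amp relief features:
#'   counts and Gaussian amplitudes (metres)
#' @param noise_sd,noise_smooth bathymetric noise (metres) and its
#'   smoothing length (cells)
#' @param coverage_fraction fraction of cells the simulated survey tracks
#'   must touch (in (0, 1]; default 0.35)
#' @param sounding_noise_sd additive sounding noise, metres
#' @param coarse_factor climatology grids are this many times coarser
#'   than the bathymetry (default 10)
#' @param n_bottle_casts water-bottle casts generated for layer validation
#' @param n_trawl_lines,n_vessels trawl segments and distinct vessels
#' @return object of class `chs_config`
#' @export
seascape_config <- function(seed = 1,
                            grid_extent = c(120, 160),
                            cell_size = 500,
                            depth_levels = c(0, 50, 100, 150, 200,
                                             seq(300, 5500, by = 100)),
                            n_presences = 300,
                            sampling_bias_strength = 2,
                            suitability_exponent = 3,
                            contaminant_rates = c(trawl = 0.10,
                                                  shallow = 0.05,
                                                  unknown_family = 0.05,
                                                  duplicate = 0.05),
                            true_weights = c(temperature = -3,
                                             slope = 3,
                                             depth = -5),
                            suitability_intercept = -2,
                            shelf_depth = 30, max_depth = 3000,
                            n_canyons = 3, canyon_amp = 700,
                            n_seamounts = 6, seamount_amp = 900,
                            noise_sd = 15, noise_smooth = 3,
                            coverage_fraction = 0.35,
                            sounding_noise_sd = 5,
                            coarse_factor = 10,
                            n_bottle_casts = 120,
                            n_trawl_lines = 60, n_vessels = 12) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (is.unsorted(depth_levels, strictly = TRUE)) {
    stop("depth_levels must be strictly increasing")
  }
  if (any(contaminant_rates < 0 | contaminant_rates > 1)) {
    stop("contaminant rates must lie in [0, 1]")
  }
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    stop("coverage_fraction must lie in (0, 1]")
  }
  if (sampling_bias_strength < 0) stop("sampling_bias_strength must be >= 0")
  structure(as.list(environment()), class = "chs_config")
}

# Deterministic sub-seed per generator, so generators never share or
# reorder each other's random streams.
sub_seed <- function(seed, tag) {
  offs <- c(bathymetry = 1L, soundings = 2L, climatology = 3L,
            presences = 4L, overlays = 5L, bottles = 6L)
  (as.integer(seed) * 1009L + offs[[tag]] * 7919L) %% 2147483111L
}

# Separable Gaussian smoothing with edge renormalization.
smooth_matrix <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(2 * sd_cells))
  k <- stats::dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  sm1 <- function(mm) {
    n <- nrow(mm)
    pad <- rbind(mm[rep(1L, half), , drop = FALSE], mm,
                 mm[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(mm))
    for (o in seq_along(k)) {
      out <- out + k[o] * pad[(o - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(sm1(t(sm1(m))))
}

#' Generate bathymetry and survey soundings
#'
#' Depth (metres, positive-down) is a linear west-east shelf-to-basin
#' ramp plus Gaussian canyon incisions (deepening seaward), Gaussian
#' seamounts, and smoothed noise, clipped to `[10, max_depth]` — a
#' caricature of a continental margin's canyons, ridges and seamounts.
#' Soundings are sampled along random straight survey tracks (with small
#' lateral jitter and additive depth noise) until the requested fraction
#' of cells holds at least one sounding, mimicking partial survey
#' coverage.  Both the truth grid and the soundings are returned so the
#' gridding stage can be validated against truth.
#'
#' @param config `chs_config` (extent at least 50 x 50 cells)
#' @return list: `bathymetry` (`chs_grid`), `soundings` (data.frame
#'   `x`, `y`, `depth`)
#' @export
make_bathymetry <- function(config) {
  nr <- config$grid_extent[1]; nc <- config$grid_extent[2]
  if (nr < 50 || nc < 50) stop("extent must be at least 50 x 50 cells")
  s <- config$cell_size
  set.seed(sub_seed(config$seed, "bathymetry"))
  xn <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  yn <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)
  depth <- config$shelf_depth + (config$max_depth - config$shelf_depth) * xn
  canyons <- list()
  for (k in seq_len(config$n_canyons)) {
    yc <- stats::runif(1, 0.15, 0.85)
    w <- stats::runif(1, 0.02, 0.05)
    canyons[[k]] <- c(yc = yc, w = w)
    depth <- depth + config$canyon_amp * exp(-((yn - yc)^2) / (2 * w^2)) * xn
  }
  # seamounts and banks occur at all depths, so steep terrain is not
  # confined to the cold deep end (keeps slope partly orthogonal to the
  # temperature/depth gradient)
  for (k in seq_len(config$n_seamounts)) {
    xc <- stats::runif(1, 0.15, 0.95); yc <- stats::runif(1, 0.1, 0.9)
    rad <- stats::runif(1, 0.02, 0.06)
    d2 <- (xn - xc)^2 + (yn - yc)^2
    depth <- depth - config$seamount_amp * exp(-d2 / (2 * rad^2))
  }
  if (config$noise_sd > 0) {
    noise <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                           config$noise_smooth)
    # renormalize so the smoothed field keeps the requested sd
    noise <- noise / stats::sd(noise) * config$noise_sd
    depth <- depth + noise
  }
  depth <- pmin(pmax(depth, 10), config$max_depth)
  bathy <- chs_grid(depth, 0, 0, s)
  attr(bathy, "canyons") <- canyons

  set.seed(sub_seed(config$seed, "soundings"))
  xmax <- nc * s; ymax <- nr * s
  covered <- matrix(FALSE, nr, nc)
  pts <- vector("list", 0L)
  iter <- 0L
  while (mean(covered) < config$coverage_fraction && iter < 10000L) {
    iter <- iter + 1L
    theta <- stats::runif(1, 0, pi)
    px <- stats::runif(1, 0, xmax); py <- stats::runif(1, 0, ymax)
    dx <- cos(theta); dy <- sin(theta)
    # span the whole extent along the track direction
    tmax <- sqrt(xmax^2 + ymax^2)
    t <- seq(-tmax, tmax, by = s / 2)
    x <- px + t * dx + stats::rnorm(length(t), 0, s / 8)
    y <- py + t * dy + stats::rnorm(length(t), 0, s / 8)
    keep <- x >= 0 & x < xmax & y >= 0 & y < ymax
    if (!any(keep)) next
    x <- x[keep]; y <- y[keep]
    idx <- grid_cell_at(x, y, bathy)
    covered[cbind(idx$row, idx$col)] <- TRUE
    d <- depth[cbind(idx$row, idx$col)] +
      stats::rnorm(length(x), 0, config$sounding_noise_sd)
    pts[[length(pts) + 1L]] <- data.frame(x = x, y = y, depth = d)
  }
  soundings <- do.call(rbind, pts)
  rownames(soundings) <- NULL
  list(bathymetry = bathy, soundings = soundings)
}

#' Default water-column profiles
#'
#' Temperature decays from 10 degC at the surface toward a 2 degC deep
#' value; salinity increases monotonically toward a deep asymptote;
#' dissolved oxygen carries a pronounced minimum centered at 1700 m
#' emulating an oxygen minimum zone on the deeper slope.
#'
#' @return named list of functions of depth (metres)
#' @export
default_profiles <- function() {
  list(
    temperature = function(z) 2 + 8 * exp(-z / 300),
    salinity = function(z) 33.9 + 0.9 * (1 - exp(-z / 300)),
    oxygen = function(z) 6 - 5.2 * exp(-((z - 1700) / 700)^2)
  )
}

#' Generate depth-binned climatology volumes
#'
#' For each variable, builds a coarse horizontal grid per standard depth
#' level whose value is `profile(level) + horizontal gradient + noise`.
#' The horizontal gradient is a centered linear trend across the extent;
#' noise is independent per cell and level.
#'
#' @param config `chs_config`
#' @param profiles named list of depth functions (default
#'   [default_profiles()]); each must be finite on all requested levels
#' @param gradients named horizontal-gradient amplitudes (full-extent
#'   swing, variable units)
#' @param noise_sd named per-cell noise standard deviations
#' @return named list of `chs_dbf` fields
#' @export
make_climatology <- function(config, profiles = default_profiles(),
                             gradients = c(temperature = 0.8,
                                           salinity = 0.15, oxygen = 0.4),
                             noise_sd = c(temperature = 0.10,
                                          salinity = 0.02, oxygen = 0.05)) {
  set.seed(sub_seed(config$seed, "climatology"))
  cf <- config$coarse_factor
  nr <- max(2L, config$grid_extent[1] %/% cf)
  nc <- max(2L, config$grid_extent[2] %/% cf)
  cs <- config$cell_size * cf
  xn <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc) - 0.5
  yn <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc) - 0.5
  trend <- (xn + yn) / 2
  levels <- config$depth_levels
  out <- list()
  for (v in names(profiles)) {
    vals <- vapply(levels, profiles[[v]], numeric(1))
    if (any(!is.finite(vals))) {
      stop("profile for ", v, " undefined at a requested level")
    }
    g <- if (!is.na(gradients[v])) gradients[[v]] else 0
    nsd <- if (!is.na(noise_sd[v])) noise_sd[[v]] else 0
    grids <- lapply(seq_along(levels), function(k) {
      m <- vals[k] + g * trend
      if (nsd > 0) m <- m + matrix(stats::rnorm(nr * nc, 0, nsd), nr, nc)
      chs_grid(m, 0, 0, cs)
    })
    out[[v]] <- depth_binned_field(v, levels, grids)
  }
  out
}

# Noise-free evaluation of the generative layers on the analysis grid:
# profile(depth) plus the same centered horizontal trend the climatology
# carries.  These are the ground-truth layers the pipeline tries to
# recover through binning and interpolation.
true_layers_at <- function(config, bathymetry, profiles = default_profiles(),
                           gradients = c(temperature = 0.8,
                                         salinity = 0.15, oxygen = 0.4)) {
  nr <- nrow(bathymetry$values); nc <- ncol(bathymetry$values)
  xn <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc) - 0.5
  yn <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc) - 0.5
  trend <- (xn + yn) / 2
  out <- list()
  for (v in names(profiles)) {
    g <- if (!is.na(gradients[v])) gradients[[v]] else 0
    m <- profiles[[v]](bathymetry$values) + g * trend
    m[is.na(bathymetry$values)] <- NA_real_
    out[[v]] <- chs_grid(m, bathymetry$xll, bathymetry$yll,
                         bathymetry$cellsize)
  }
  out$depth <- bathymetry
  out$slope <- horn_slope(bathymetry, window = bathymetry$cellsize)
  out
}

# Logistic suitability from standardized truth layers and true_weights.
true_suitability_grid <- function(true_layers, true_weights, intercept = 0) {
  vars <- names(true_weights)
  mats <- lapply(vars, function(v) {
    if (is.null(true_layers[[v]])) stop("true_weights names unknown layer: ", v)
    true_layers[[v]]$values
  })
  valid <- Reduce(`&`, lapply(mats, function(m) !is.na(m)))
  lin <- matrix(intercept, nrow(mats[[1]]), ncol(mats[[1]]))
  for (i in seq_along(vars)) {
    v <- mats[[i]][valid]
    z <- (mats[[i]] - mean(v)) / stats::sd(v)
    lin <- lin + true_weights[[vars[i]]] * z
  }
  suit <- 1 / (1 + exp(-lin))
  suit[!valid] <- NA_real_
  tpl <- true_layers[[vars[1]]]
  chs_grid(suit, tpl$xll, tpl$yll, tpl$cellsize)
}

#' Sample presence records from the true suitability surface
#'
#' Clean records are drawn (with replacement over cells) with probability
#' proportional to `suitability^gamma`, inflated by
#' `1 + sampling_bias_strength` inside the bias polygon — the analog of
#' an intensively surveyed canyon skewing the record set.  Contaminant
#' records are appended per the configured rates: trawl-gear records with
#' up to 2 km positional jitter, shallow records (< 50 m), records with
#' unknown family, and exact-cell duplicates of existing records.  Every
#' record carries a hidden `truth` label (`clean` / `contaminant_*`)
#' which the analysis stages ignore but the QC tests use as an answer
#' key.
#'
#' @param truth `chs_seascape` (or a list with `true_suitability`,
#'   `bathymetry`, optionally `bias_polygon`)
#' @param config `chs_config`
#' @return data.frame of presence records (`x, y, depth, gear, order,
#'   suborder, family, source, truth`)
#' @export
sample_presences <- function(truth, config) {
  if (config$n_presences <= 0) stop("n_presences must be positive")
  suit <- truth$true_suitability
  bathy <- truth$bathymetry
  set.seed(sub_seed(config$seed, "presences"))
  cc <- grid_coords(suit)
  w <- cc$value^config$suitability_exponent
  w[is.na(w)] <- 0
  if (!is.null(truth$bias_polygon)) {
    inb <- point_in_polygon(cc$x, cc$y, truth$bias_polygon)
    if (!any(inb)) stop("bias polygon lies outside the grid extent")
    w[inb] <- w[inb] * (1 + config$sampling_bias_strength)
  }
  if (sum(w) <= 0) stop("suitability is zero everywhere; cannot sample")
  s <- suit$cellsize
  taxa <- data.frame(
    taxon = c("Alcyoniina", "Calcaxonia", "Holaxonia", "Scleraxonia",
              "Antipatharia", "Scleractinia"),
    order = c("Alcyonacea", "Alcyonacea", "Alcyonacea", "Alcyonacea",
              "Antipatharia", "Scleractinia"),
    suborder = c("Alcyoniina", "Calcaxonia", "Holaxonia", "Scleraxonia",
                 NA, NA),
    family = c("Alcyoniidae", "Primnoidae", "Plexauridae", "Paragorgiidae",
               "Antipathidae", "Caryophylliidae"),
    p = c(0.35, 0.20, 0.15, 0.12, 0.08, 0.10))

  draw <- function(n, family_override = NULL, gear_pool =
                     c("ROV", "submersible", "camera", "grab")) {
    cell <- sample.int(nrow(cc), n, replace = TRUE, prob = w)
    ti <- sample.int(nrow(taxa), n, replace = TRUE, prob = taxa$p)
    data.frame(
      x = cc$x[cell] + stats::runif(n, -0.499, 0.499) * s,
      y = cc$y[cell] + stats::runif(n, -0.499, 0.499) * s,
      depth = grid_value_at(cc$x[cell], cc$y[cell], bathy) +
        stats::rnorm(n, 0, 2),
      gear = sample(gear_pool, n, replace = TRUE,
                    prob = if (length(gear_pool) == 4)
                      c(0.5, 0.2, 0.2, 0.1) else NULL),
      order = taxa$order[ti], suborder = taxa$suborder[ti],
      family = if (is.null(family_override)) taxa$family[ti]
               else family_override,
      source = sample(c("MBARI", "NOAA", "NMNH"), n, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)))
  }

  clean <- draw(config$n_presences)
  clean$depth <- pmax(clean$depth, 51)  # clean records are deep-sea by construction
  clean$truth <- "clean"
  out <- clean
  rates <- config$contaminant_rates
  ncont <- function(nm) {
    r <- if (!is.na(rates[nm])) rates[[nm]] else 0
    round(r * config$n_presences)
  }
  n <- ncont("trawl")
  if (n > 0) {
    tr <- draw(n, gear_pool = "trawl")
    tr$x <- tr$x + stats::runif(n, -2000, 2000)
    tr$y <- tr$y + stats::runif(n, -2000, 2000)
    tr$gear <- "trawl"
    tr$depth <- pmax(tr$depth, 51)
    tr$truth <- "contaminant_trawl"
    out <- rbind(out, tr)
  }
  n <- ncont("shallow")
  if (n > 0) {
    sh <- draw(n)
    sh$depth <- stats::runif(n, 5, 49.9)
    sh$truth <- "contaminant_shallow"
    out <- rbind(out, sh)
  }
  n <- ncont("unknown_family")
  if (n > 0) {
    uf <- draw(n, family_override = "unknown")
    uf$depth <- pmax(uf$depth, 51)
    uf$truth <- "contaminant_unknown_family"
    out <- rbind(out, uf)
  }
  n <- ncont("duplicate")
  if (n > 0 && nrow(clean) > 0) {
    src <- clean[sample.int(nrow(clean), n, replace = TRUE), , drop = FALSE]
    # same taxon, same analysis cell: guaranteed spatial duplicates
    src$truth <- "contaminant_duplicate"
    out <- rbind(out, src)
  }
  rownames(out) <- NULL
  out
}

#' Generate overlay layers: polygons, substrate, trawl lines
#'
#' Builds sanctuary-analog polygons (two rectangles and one circular
#' 24-gon placed inside the extent), a substrate classification on a
#' finer grid whose hard-substrate probability increases with the local
#' slope percentile (so the substrate/suitability cross-tabulation has
#' signal), and random trawl segments concentrated on the shelf, each
#' tagged with a vessel id.
#'
#' @param config `chs_config`
#' @param truth list with `bathymetry` and `true_layers$slope`
#' @param substrate_factor substrate grid is this many times finer than
#'   the analysis grid (default 5)
#' @return list: `polygons` (named rings), `bias_polygon`, `substrate`
#'   (`chs_grid` of codes), `trawl_lines` (segment data.frame)
#' @export
make_overlays <- function(config, truth, substrate_factor = 5) {
  set.seed(sub_seed(config$seed, "overlays"))
  bathy <- truth$bathymetry
  nr <- nrow(bathy$values); nc <- ncol(bathy$values)
  s <- bathy$cellsize
  xmax <- nc * s; ymax <- nr * s
  rect <- function(x0, y0, x1, y1) {
    data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  circle <- function(cx, cy, r, n = 24) {
    a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    data.frame(x = cx + r * cos(a), y = cy + r * sin(a))
  }
  polygons <- list(
    shelf_sanctuary = rect(0.05 * xmax, 0.55 * ymax, 0.30 * xmax, 0.85 * ymax),
    slope_closure = rect(0.40 * xmax, 0.10 * ymax, 0.70 * xmax, 0.40 * ymax),
    seamount_reserve = circle(0.75 * xmax, 0.70 * ymax, 0.12 * min(xmax, ymax))
  )
  bias_polygon <- rect(0.10 * xmax, 0.30 * ymax, 0.35 * xmax, 0.55 * ymax)
  # cross-validation regions: four along-shore bands, each spanning the
  # whole shelf-to-basin gradient (the along-coast partition the spatial
  # cross-validation is designed around)
  region_boundaries <- lapply(1:4, function(k) {
    rect(-s, (k - 1) / 4 * ymax - s * (k == 1),
         xmax + s, k / 4 * ymax + s * (k == 4))
  })
  names(region_boundaries) <- paste0("region_", 1:4)

  slope <- truth$true_layers$slope$values
  sl <- slope; sl[is.na(sl)] <- 0
  rk <- matrix(rank(sl) / length(sl), nr, nc)  # slope percentile per parent cell
  f <- substrate_factor
  # hard ground is the minority class overall but dominates the steepest
  # percentiles (rock walls, scarps); majority resampling later sharpens
  # whichever class dominates a block
  p_hard <- 1 / (1 + exp(-(-3.5 + 5 * rk)))
  fine_nr <- nr * f; fine_nc <- nc * f
  parent <- cbind(rep(rep(seq_len(nr), each = f), fine_nc),
                  rep(seq_len(nc), each = fine_nr * f))
  ph <- p_hard[parent]
  u <- stats::runif(fine_nr * fine_nc)
  cls <- ifelse(u < ph, SUBSTRATE_CLASSES["hard"],
                ifelse(u < ph + 0.35 * (1 - ph), SUBSTRATE_CLASSES["mixed"],
                       SUBSTRATE_CLASSES["soft"]))
  valid_parent <- !is.na(bathy$values)[parent]
  cls[!valid_parent] <- NA_integer_
  substrate <- chs_grid(matrix(cls, fine_nr, fine_nc), bathy$xll, bathy$yll,
                        s / f)

  n <- config$n_trawl_lines
  trawl <- if (n > 0) {
    x0 <- stats::runif(n, 0, 0.6 * xmax)  # effort concentrated shelf-ward
    y0 <- stats::runif(n, 0, ymax)
    len <- stats::runif(n, 2000, 10000)
    ang <- stats::runif(n, 0, 2 * pi)
    data.frame(x0 = x0, y0 = y0,
               x1 = pmin(pmax(x0 + len * cos(ang), 0), xmax),
               y1 = pmin(pmax(y0 + len * sin(ang), 0), ymax),
               vessel_id = sprintf("V%02d",
                                   sample.int(config$n_vessels, n,
                                              replace = TRUE)))
  } else {
    data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
               y1 = numeric(0), vessel_id = character(0))
  }
  list(polygons = polygons, bias_polygon = bias_polygon,
       region_boundaries = region_boundaries,
       substrate = substrate, trawl_lines = trawl)
}

# Water-bottle casts sampled from the truth layers with small noise;
# includes pre-cutoff years, missing bottom flags and off-bottom sample
# depths so the validation filters have work to do.
make_bottle_casts <- function(config, truth) {
  set.seed(sub_seed(config$seed, "bottles"))
  n <- config$n_bottle_casts
  cc <- grid_coords(truth$bathymetry)
  cc <- cc[!is.na(cc$value), , drop = FALSE]
  pick <- cc[sample.int(nrow(cc), n, replace = TRUE), , drop = FALSE]
  rel_err <- stats::rnorm(n, 0, 0.015)
  off <- sample.int(n, max(1L, round(0.1 * n)))     # casts far off the bottom
  rel_err[off] <- stats::runif(length(off), 0.10, 0.40)
  out <- data.frame(
    x = pick$x, y = pick$y,
    sample_depth = pmax(1, pick$value * (1 - abs(rel_err))),
    year = sample(1995:2012, n, replace = TRUE),
    bottom_flag = stats::runif(n) < 0.85)
  for (v in setdiff(names(truth$true_layers), c("depth", "slope"))) {
    out[[v]] <- grid_value_at(pick$x, pick$y, truth$true_layers[[v]]) +
      stats::rnorm(n, 0, 0.02)
  }
  out
}

#' Generate a complete synthetic seascape
#'
#' Orchestrates every generator into one truth object consumed by the
#' pipeline and the tests.
#'
#' @param config `chs_config` (see [seascape_config()])
#' @return object of class `chs_seascape`: `config`, `bathymetry`,
#'   `soundings`, `climatology`, `true_layers`, `true_suitability`,
#'   `presences`, `bottle_casts`, `polygons`, `bias_polygon`,
#'   `substrate`, `trawl_lines`
#' @export
simulate_seascape <- function(config = seascape_config()) {
  b <- make_bathymetry(config)
  clim <- make_climatology(config)
  tl <- true_layers_at(config, b$bathymetry)
  suit <- true_suitability_grid(tl, config$true_weights,
                                intercept = config$suitability_intercept)
  truth <- list(config = config, bathymetry = b$bathymetry,
                soundings = b$soundings, climatology = clim,
                true_layers = tl, true_suitability = suit)
  ov <- make_overlays(config, truth)
  truth <- c(truth, ov)
  class(truth) <- "chs_seascape"
  truth$presences <- sample_presences(truth, config)
  truth$bottle_casts <- make_bottle_casts(config, truth)
  truth
}

#' @export
print.chs_seascape <- function(x, ...) {
  cat(sprintf(
    "<chs_seascape> seed %d: %d x %d cells @ %g m, %d presences, %d soundings\n",
    x$config$seed, x$config$grid_extent[1], x$config$grid_extent[2],
    x$config$cell_size, nrow(x$presences), nrow(x$soundings)))
  invisible(x)
}

#' Write a seascape to disk in plain-text exchange formats
#'
#' Bathymetry, layers and suitability as ESRI ASCII grids; soundings as
#' XYZ; presences and bottle casts as CSV; polygons and trawl lines as
#' GeoJSON.
#'
#' @param truth `chs_seascape`
#' @param dir output directory (created if needed)
#' @return `dir` invisibly
#' @export
write_seascape <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(truth$bathymetry, file.path(dir, "bathymetry.asc"))
  write_ascii_grid(truth$true_suitability, file.path(dir, "true_suitability.asc"))
  for (v in names(truth$true_layers)) {
    write_ascii_grid(truth$true_layers[[v]],
                     file.path(dir, paste0("true_", v, ".asc")))
  }
  write_ascii_grid(truth$substrate, file.path(dir, "substrate.asc"))
  write_xyz(truth$soundings, file.path(dir, "soundings.xyz"))
  utils::write.csv(truth$presences, file.path(dir, "presences.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$bottle_casts, file.path(dir, "bottle_casts.csv"),
                   row.names = FALSE)
  write_polygons_geojson(truth$polygons, file.path(dir, "polygons.geojson"))
  write_polygons_geojson(list(bias = truth$bias_polygon),
                         file.path(dir, "bias_polygon.geojson"))
  write_trawl_geojson(truth$trawl_lines, file.path(dir, "trawl_lines.geojson"))
  invisible(dir)
}
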