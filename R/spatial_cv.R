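#' Stack seafloor layers into a per-cell environment table
#'
#' Collects co-registered layers into one data.frame with a row per cell
#' that is valid (non-missing) in every layer, the common currency of the
#' modelling stages.
#'
#' @param layers named list of `chs_seafloor_layer` / `chs_grid` objects
#'   sharing one geometry
#' @return object of class `chs_stack`: `env` (data.frame), `cell`
#'   (1-based linear indices of valid cells), `grid` (geometry template)
#' @export
layer_stack <- function(layers) {
  grids <- lapply(layers, function(l) {
    if (inherits(l, "chs_seafloor_layer")) l$grid else l
  })
  for (g in grids[-1]) stopifnot_same_geometry(grids[[1]], g)
  vals <- lapply(grids, function(g) as.vector(g$values))
  valid <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  cell <- which(valid)
  env <- as.data.frame(lapply(vals, function(v) v[cell]))
  names(env) <- names(layers)
  structure(list(env = env, cell = cell, grid = grids[[1]]),
            class = "chs_stack")
}

#' Rebuild a grid from per-cell values of a stack
#'
#' @param stack `chs_stack`
#' @param values numeric vector aligned with `stack$cell`
#' @return `chs_grid`
#' @export
stack_grid <- function(stack, values) {
  tpl <- stack$grid
  m <- matrix(NA_real_, nrow(tpl$values), ncol(tpl$values))
  m[stack$cell] <- values
  chs_grid(m, tpl$xll, tpl$yll, tpl$cellsize)
}

#' Partition presences into four spatial regions
#'
#' With explicit boundary polygons, assignment is point-in-polygon (first
#' containing polygon wins; a point in none goes to the polygon with the
#' nearest centroid).  Without boundaries, the default is the quadrant
#' split at the median easting and northing of the presences.  Region
#' indices are `1 + (x > mx) + 2 * (y > my)`, so a presence exactly on a
#' split line falls in the lower-index region.
#'
#' @param presences data.frame with columns `x`, `y` (>= 4 rows)
#' @param boundaries optional named list of exactly 4 polygon rings
#' @return object of class `chs_partition`: `region` (integer 1..4 per
#'   presence), `split` (median easting/northing, quadrant mode only),
#'   `boundaries`
#' @export
partition_regions <- function(presences, boundaries = NULL) {
  if (nrow(presences) < 4L) stop("need at least 4 presences to partition")
  if (is.null(boundaries)) {
    mx <- stats::median(presences$x); my <- stats::median(presences$y)
    region <- 1L + (presences$x > mx) + 2L * (presences$y > my)
    return(structure(list(region = as.integer(region), split = c(x = mx, y = my),
                          boundaries = NULL), class = "chs_partition"))
  }
  if (length(boundaries) != 4L) stop("exactly 4 region boundaries required")
  region <- rep(NA_integer_, nrow(presences))
  for (k in seq_along(boundaries)) {
    hit <- is.na(region) &
      point_in_polygon(presences$x, presences$y, boundaries[[k]])
    region[hit] <- k
  }
  if (anyNA(region)) {
    cx <- vapply(boundaries, function(b) mean(b$x), numeric(1))
    cy <- vapply(boundaries, function(b) mean(b$y), numeric(1))
    miss <- which(is.na(region))
    d2 <- outer(presences$x[miss], cx, "-")^2 +
      outer(presences$y[miss], cy, "-")^2
    region[miss] <- max.col(-d2, ties.method = "first")
  }
  structure(list(region = region, split = NULL, boundaries = boundaries),
            class = "chs_partition")
}

#' Presence-background AUC
#'
#' The probability that a presence site is ranked above a random
#' background site, with ties credited one half: the normalized
#' Mann-Whitney rank-sum statistic.
#'
#' @param presence_scores,background_scores non-empty numeric vectors
#' @return AUC in `[0, 1]`
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Two-sided rank-sum significance of an AUC
#'
#' Tests whether presence scores rank differently from background scores
#' (i.e. AUC differs from the random-ranking value 0.5) with the normal
#' approximation to the Wilcoxon rank-sum statistic, including the tie
#' correction.  Degenerate all-tied input returns p = 1.
#'
#' @param presence_scores,background_scores numeric vectors, >= 5 each
#' @return two-sided p-value
#' @export
auc_significance <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 5L || nb < 5L) stop("need at least 5 scores per group")
  all_scores <- c(presence_scores, background_scores)
  N <- np + nb
  r <- rank(all_scores)
  U <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  ties <- table(all_scores)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- np * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (U - np * nb / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Threshold statistics of a fitted fold
#'
#' Two threshold summaries reported per cross-validation fold: the 10th
#' percentile (nearest-rank) of the habitat suitability index at training
#' presences, and the HSI threshold maximizing test sensitivity plus
#' background specificity, reported as the midpoint of the optimal
#' threshold interval.  Sensitivity and specificity use the strict
#' comparison (`score > threshold` is a positive call) consistent with
#' the binary thresholding rule.
#'
#' @param train_scores HSI at training presences (>= 10 values for a
#'   meaningful percentile)
#' @param test_scores HSI at held-out presences
#' @param bg_scores HSI over the background
#' @return list: `p10_training_presence`, `max_sens_spec_threshold`,
#'   `max_sens_spec` (the achieved sensitivity + specificity)
#' @export
threshold_stats <- function(train_scores, test_scores, bg_scores) {
  st <- sort(train_scores)
  p10 <- st[max(1L, ceiling(0.1 * length(st)))]
  cand <- sort(unique(c(test_scores, bg_scores)))
  # candidate thresholds: below the minimum, at midpoints, above the max
  grid <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  ss <- vapply(grid, function(t) {
    mean(test_scores > t) + mean(bg_scores <= t)
  }, numeric(1))
  best <- which.max(ss)
  # midpoint of the optimal open interval between adjacent observed scores
  lo <- if (best == 1L) cand[1] else cand[best - 1L]
  hi <- if (best == length(grid)) cand[length(cand)] else cand[best]
  list(p10_training_presence = p10,
       max_sens_spec_threshold = (lo + hi) / 2,
       max_sens_spec = ss[best])
}

#' Threshold a suitability grid into a binary map
#'
#' Strictly-greater comparison: a cell exactly at the cutoff is 0.
#' No-data propagates.
#'
#' @param hsi `chs_grid` of habitat suitability in `[0, 1]`
#' @param cutoff threshold, strictly inside (0, 1); the pipeline uses 0.5
#'   and 0.75
#' @return `chs_grid` of 0/1 with attribute `cutoff`
#' @export
threshold_binary <- function(hsi, cutoff) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie strictly inside (0, 1)")
  }
  g <- chs_grid((hsi$values > cutoff) + 0, hsi$xll, hsi$yll, hsi$cellsize)
  attr(g, "cutoff") <- cutoff
  g
}

#' Sum retained binary fold maps into a consensus grid
#'
#' Cellwise integer sum over the retained folds: values run 0..K with K
#' the number of retained folds (at most 4; when a fold is eliminated by
#' the AUC bar the maximum attainable consensus drops accordingly).
#'
#' @param binaries non-empty list of 0/1 `chs_grid`s on one geometry
#' @return `chs_grid` of integer consensus values with attribute `K`
#' @export
consensus_sum <- function(binaries) {
  if (!length(binaries)) stop("need at least one retained fold")
  for (b in binaries[-1]) stopifnot_same_geometry(binaries[[1]], b)
  v <- Reduce(`+`, lapply(binaries, `[[`, "values"))
  g <- chs_grid(v, binaries[[1]]$xll, binaries[[1]]$yll,
                binaries[[1]]$cellsize)
  attr(g, "K") <- length(binaries)
  g
}

#' Four-region spatially cross-validated habitat suitability models
#'
#' For each of the four regions in turn, fits a maximum-entropy model on
#' the presences of the other three regions, scores the held-out
#' presences against the background, and records test AUC (with a
#' bootstrap standard deviation over test presences), rank-sum
#' significance, threshold statistics and the retention flag
#' (`AUC > 0.7`, strict).  Retained folds are thresholded at each cutoff
#' and summed into consensus grids valued `0..K`.
#'
#' The background is a study-wide uniform sample of valid cells without
#' replacement (default 10,000 or all cells if fewer) with the taxon's
#' presence cells merged in; `test_background = "region"` instead scores
#' each fold against only the background cells of the held-out region.
#'
#' @param taxon `chs_taxon_set` with retained records carrying cell indices
#' @param stack `chs_stack` of predictor layers
#' @param partition optional `chs_partition` for the taxon's records
#'   (default: quadrant split at the record medians)
#' @param n_background background sample size (default 10000)
#' @param seed seed for background sampling and bootstrap (required)
#' @param reg_multiplier,convergence,max_iterations passed to [fit_maxent()]
#' @param cutoffs binary thresholds for consensus maps (default 0.5, 0.75)
#' @param boot_reps bootstrap replicates for the AUC standard deviation
#' @param test_background `"whole"` (default) or `"region"`
#' @param min_auc retention bar (default 0.7, strict inequality)
#' @return object of class `chs_cv`: `folds` (per-fold summary
#'   data.frame), `models`, `hsi` (per-fold HSI `chs_grid`s), `consensus`
#'   (named by cutoff), `K`, `partition`, `background_cells`
#' @export
run_spatial_cv <- function(taxon, stack, partition = NULL,
                           n_background = 10000, seed,
                           reg_multiplier = 1, convergence = 1e-5,
                           max_iterations = 500,
                           cutoffs = c(0.5, 0.75), boot_reps = 100,
                           test_background = c("whole", "region"),
                           min_auc = 0.7) {
  test_background <- match.arg(test_background)
  rec <- taxon$records
  if (is.null(partition)) partition <- partition_regions(rec)
  region <- partition$region
  nrg <- nrow(stack$grid$values)
  rec_cell <- (rec$col - 1L) * nrg + rec$row
  usable <- rec_cell %in% stack$cell
  if (!all(usable)) {
    warning(sum(!usable), " records over no-data cells ignored")
  }

  set.seed(seed)
  n_bg <- min(n_background, length(stack$cell))
  bg_rows <- sort(sample.int(length(stack$cell), n_bg))
  pres_rows_all <- match(unique(rec_cell[usable]), stack$cell)
  bg_rows <- sort(union(bg_rows, pres_rows_all))
  bg_env <- stack$env[bg_rows, , drop = FALSE]
  bg_xy <- grid_coords(stack$grid)[stack$cell[bg_rows], c("x", "y")]

  folds <- list(); models <- list(); hsi <- list()
  for (k in 1:4) {
    tr <- which(region != k & usable)
    te <- which(region == k & usable)
    if (!length(te)) { warning("fold ", k, " has no test presences; skipped"); next }
    tr_cells <- unique(rec_cell[tr])
    te_cells <- unique(rec_cell[te])
    if (length(tr_cells) < 2L) { warning("fold ", k, " has <2 training cells; skipped"); next }
    tr_env <- stack$env[match(tr_cells, stack$cell), , drop = FALSE]
    te_env <- stack$env[match(te_cells, stack$cell), , drop = FALSE]
    fe <- build_features(bg_env, m = length(tr_cells))
    model <- fit_maxent(feature_matrix(fe, tr_env),
                        feature_matrix(fe, bg_env), features = fe,
                        reg_multiplier = reg_multiplier,
                        convergence = convergence,
                        max_iterations = max_iterations)
    Xbg <- feature_matrix(fe, bg_env)
    bg_scores <- logistic_output(model, Xbg)
    if (test_background == "region") {
      rb <- region_of(bg_xy$x, bg_xy$y, partition)
      sel <- rb == k
      if (sum(sel) >= 5) bg_scores <- bg_scores[sel]
    }
    tr_scores <- logistic_output(model, feature_matrix(fe, tr_env))
    te_scores <- logistic_output(model, feature_matrix(fe, te_env))
    auc <- auc_presence_background(te_scores, bg_scores)
    boot <- vapply(seq_len(boot_reps), function(b) {
      s <- te_scores[sample.int(length(te_scores), replace = TRUE)]
      auc_presence_background(s, bg_scores)
    }, numeric(1))
    pval <- if (length(te_scores) >= 5) {
      auc_significance(te_scores, bg_scores)
    } else NA_real_
    ts <- threshold_stats(tr_scores, te_scores, bg_scores)
    Xall <- feature_matrix(fe, stack$env)
    hsi[[as.character(k)]] <- stack_grid(stack, logistic_output(model, Xall))
    models[[as.character(k)]] <- model
    folds[[as.character(k)]] <- data.frame(
      fold = k, n_train = length(tr_cells), n_test = length(te_cells),
      auc = auc, auc_sd = stats::sd(boot), p_value = pval,
      p10_training_presence = ts$p10_training_presence,
      max_sens_spec_threshold = ts$max_sens_spec_threshold,
      gain = model$gain, retained = auc > min_auc)
  }
  folds <- do.call(rbind, folds)
  if (is.null(folds) || nrow(folds) < 2L) {
    stop("fewer than 2 usable folds for taxon ", taxon$label)
  }
  retained <- as.character(folds$fold[folds$retained])
  consensus <- NULL
  if (length(retained)) {
    consensus <- lapply(cutoffs, function(ct) {
      consensus_sum(lapply(hsi[retained], threshold_binary, cutoff = ct))
    })
    names(consensus) <- as.character(cutoffs)
  }
  structure(list(taxon = taxon$label, folds = folds, models = models,
                 hsi = hsi, consensus = consensus, K = length(retained),
                 partition = partition, background_cells = stack$cell[bg_rows]),
            class = "chs_cv")
}

# Region index of arbitrary points under a partition.
region_of <- function(x, y, partition) {
  if (!is.null(partition$split)) {
    return(1L + (x > partition$split["x"]) + 2L * (y > partition$split["y"]))
  }
  region <- rep(NA_integer_, length(x))
  for (k in seq_along(partition$boundaries)) {
    hit <- is.na(region) & point_in_polygon(x, y, partition$boundaries[[k]])
    region[hit] <- k
  }
  region
}

#' @export
print.chs_cv <- function(x, ...) {
  cat(sprintf("<chs_cv> taxon %s: %d folds, K=%d retained\n",
              x$taxon, nrow(x$folds), x$K))
  print(x$folds, digits = 3)
  invisible(x)
}
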