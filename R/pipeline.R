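#' Run the full habitat-suitability pipeline on a seascape
#'
#' Chains every stage exactly as the analysis prescribes: clean and grid
#' the soundings (with a coarse block-mean reference grid standing in
#' for satellite-altimetry infill), derive Horn slope, extrude each
#' depth-binned climatology variable to the seafloor, prune covarying
#' variables (protecting depth and temperature, the ecophysiologically
#' motivated exception), quality-control the presence records, build
#' taxon sets, and run the four-region spatial cross-validation with
#' thresholded consensus mapping.  Optionally adds the jack-knife of
#' variable importance using region 1 as the held-out evaluation split.
#'
#' @param truth `chs_seascape` from [simulate_seascape()] (or an
#'   equivalently shaped list of real inputs)
#' @param seed seed for background sampling / bootstrap
#' @param taxon which taxon set to cross-validate (default `"all"`)
#' @param slope_window Horn slope window, metres (default 1000)
#' @param n_background background sample size (default 10000)
#' @param min_records modelable-taxon threshold (default 50)
#' @param keep_list variables protected from correlation pruning
#' @param cutoffs consensus thresholds (default 0.5 and 0.75)
#' @param jackknife run the jack-knife importance analysis (default TRUE)
#' @param infill_factor block-mean factor of the coarse infill grid
#' @param ... further arguments passed to [run_spatial_cv()]
#' @return list: `bathymetry`, `slope`, `layers`, `stack` (pruned),
#'   `pruning`, `qc`, `taxon_sets`, `cv` (`chs_cv`), `jackknife`
#' @export
run_pipeline <- function(truth, seed = truth$config$seed, taxon = "all",
                         slope_window = 1000, n_background = 10000,
                         min_records = 50,
                         keep_list = c("depth", "temperature"),
                         cutoffs = c(0.5, 0.75), jackknife = TRUE,
                         infill_factor = 4, ...) {
  snd <- clean_soundings(truth$soundings, extent = truth$bathymetry)
  infill <- grid_block_mean(truth$bathymetry, infill_factor)
  bathy <- grid_soundings(snd, truth$bathymetry, infill = infill)
  slope <- horn_slope(bathy, window = slope_window)

  layers <- lapply(truth$climatology, extrude_to_seafloor,
                   bathymetry = bathy)
  layers <- c(layers, list(depth = bathy, slope = slope))
  stack <- layer_stack(layers)

  set.seed(seed)
  samp <- stack$env[sample.int(nrow(stack$env),
                               min(1000L, nrow(stack$env))), , drop = FALSE]
  pruning <- correlation_prune(samp, threshold = 0.7,
                               keep_list = intersect(keep_list,
                                                     names(stack$env)))
  stack$env <- stack$env[, pruning$retained, drop = FALSE]

  qc <- filter_records(truth$presences, bathy)
  sets <- build_taxon_sets(qc, bathy, min_records = min_records)
  if (is.null(sets[[taxon]])) stop("no taxon set named ", taxon)
  if (!sets[[taxon]]$modelable) stop("taxon ", taxon, " is unmodelable")

  part <- if (!is.null(truth$region_boundaries)) {
    partition_regions(sets[[taxon]]$records,
                      boundaries = truth$region_boundaries)
  } else NULL
  cv <- run_spatial_cv(sets[[taxon]], stack, partition = part,
                       n_background = n_background,
                       seed = seed, cutoffs = cutoffs, ...)

  jk <- NULL
  if (jackknife) {
    rec <- sets[[taxon]]$records
    region <- cv$partition$region
    nrg <- nrow(stack$grid$values)
    cell <- (rec$col - 1L) * nrg + rec$row
    tr <- match(unique(cell[region != 1L]), stack$cell)
    te <- match(unique(cell[region == 1L]), stack$cell)
    tr <- tr[!is.na(tr)]; te <- te[!is.na(te)]
    bg <- match(cv$background_cells, stack$cell)
    jk <- jackknife_importance(stack$env[tr, , drop = FALSE],
                               stack$env[bg, , drop = FALSE],
                               test_pres_env = stack$env[te, , drop = FALSE])
  }
  list(bathymetry = bathy, slope = slope, layers = layers, stack = stack,
       pruning = pruning, qc = qc, taxon_sets = sets, cv = cv,
       jackknife = jk)
}
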