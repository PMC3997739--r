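#' Taxon label of presence records
#'
#' Records are modelled at order or suborder level: the label is the
#' suborder when present, otherwise the order.
#'
#' @param records data.frame with columns `order`, `suborder`
#' @return character vector of labels
#' @export
taxon_label <- function(records) {
  sub <- as.character(records$suborder)
  ord <- as.character(records$order)
  ifelse(!is.na(sub) & nzchar(sub), sub, ord)
}

#' Assign a point to its analysis grid cell
#'
#' Half-open footprint convention shared with the bathymetry gridder: a
#' point on a cell's west/south edge belongs to that cell.
#'
#' @param x,y planar coordinates, metres
#' @param grid_spec `chs_grid` defining the analysis grid
#' @return data.frame with integer columns `row`, `col` (1-based)
#' @export
assign_cell <- function(x, y, grid_spec) {
  idx <- grid_cell_at(x, y, grid_spec)
  if (any(!idx$inside)) stop("point outside the grid extent")
  idx[, c("row", "col")]
}

#' Quality-control raw coral presence records
#'
#' Applies the four elimination rules in their canonical order, each
#' record receiving exactly one primary removal reason:
#' 1. bottom-trawl bycatch (positionally and taxonomically unreliable);
#' 2. depth shallower than `min_depth` (strictly less than; a record at
#'    exactly 50 m survives) — the deep-sea azooxanthellate cutoff;
#' 3. taxonomy uncertain at family level;
#' 4. spatial duplicate: a further record of the same taxon (order or
#'    suborder) in an already occupied analysis cell.
#'
#' Records outside the grid extent are flagged separately and excluded
#' from cell assignment.  Duplicate resolution keeps the first record per
#' (taxon, cell) after a deterministic sort by (source, x, y, depth) —
#' for presence-only modelling the choice of survivor is inert (only cell
#' occupancy enters the model) but the audit needs determinism.
#'
#' @param records data.frame with columns `x`, `y`, `depth`, `gear`,
#'   `order`, `suborder`, `family`, `source`
#' @param grid_spec `chs_grid` defining the analysis cells
#' @param min_depth depth cutoff, metres (default 50)
#' @param depth_from `"record"` (default) uses the recorded depth for rule
#'   2; `"bathymetry"` uses the bathymetric depth at the record's cell
#' @param bathymetry required when `depth_from = "bathymetry"`
#' @return the input with added columns `qc_status`, `taxon`, `row`,
#'   `col` (cell indices, NA unless retained), plus attributes `audit`
#'   (named counts; conservation: they sum to the input count) and
#'   `audit_by_taxon` (counts per taxon and rule)
#' @export
filter_records <- function(records, grid_spec, min_depth = 50,
                           depth_from = c("record", "bathymetry"),
                           bathymetry = NULL) {
  depth_from <- match.arg(depth_from)
  n <- nrow(records)
  records$taxon <- if (n) taxon_label(records) else character(0)
  status <- rep(NA_character_, n)
  records$row <- rep(NA_integer_, n)
  records$col <- rep(NA_integer_, n)

  if (n) {
    # rule 1: trawl bycatch
    status[is.na(status) & records$gear == "trawl"] <- "removed_trawl"
    # rule 2: shallow-water records
    d <- records$depth
    if (depth_from == "bathymetry") {
      if (is.null(bathymetry)) stop("bathymetry required for depth_from='bathymetry'")
      d <- grid_value_at(records$x, records$y, bathymetry)
      d[is.na(d)] <- records$depth[is.na(d)]
    }
    status[is.na(status) & d < min_depth] <- "removed_shallow"
    # rule 3: family-level taxonomy unknown
    fam <- as.character(records$family)
    badfam <- is.na(fam) | !nzchar(fam) | tolower(fam) == "unknown"
    status[is.na(status) & badfam] <- "removed_taxonomy"
    # extent check before cell assignment
    idx <- grid_cell_at(records$x, records$y, grid_spec)
    status[is.na(status) & !idx$inside] <- "out_of_extent"
    # rule 4: spatial duplicates per (taxon, cell), first after sort wins
    cand <- which(is.na(status))
    if (length(cand)) {
      ord <- cand[order(records$source[cand], records$x[cand],
                        records$y[cand], records$depth[cand])]
      key <- paste(records$taxon[ord], idx$row[ord], idx$col[ord])
      dup <- duplicated(key)
      status[ord[dup]] <- "removed_duplicate"
      keep <- ord[!dup]
      status[keep] <- "retained"
      records$row[keep] <- idx$row[keep]
      records$col[keep] <- idx$col[keep]
    }
  }
  records$qc_status <- status

  rules <- c("retained", "removed_trawl", "removed_shallow",
             "removed_taxonomy", "removed_duplicate", "out_of_extent")
  audit <- vapply(rules, function(r) sum(status == r), integer(1))
  by_taxon <- if (n) table(taxon = records$taxon,
                           rule = factor(status, levels = rules))
  else table(taxon = character(0), rule = factor(character(0), levels = rules))
  attr(records, "audit") <- audit
  attr(records, "audit_by_taxon") <- by_taxon
  records
}

#' Group retained records into modelable taxon sets
#'
#' Builds one set per taxon (order or suborder) plus an `"all"` union over
#' every distinct retained record.  Sets smaller than `min_records` are
#' flagged unmodelable and excluded from model fitting — taxa with only a
#' few dozen records do not support a four-region cross-validated model.
#'
#' @param retained output of [filter_records()] (only rows with
#'   `qc_status == "retained"` are used)
#' @param grid_spec `chs_grid` used for cell bookkeeping
#' @param min_records minimum records for a modelable set (default 50)
#' @return named list of `chs_taxon_set` objects, each with `label`,
#'   `records`, `cells` (unique 1-based linear cell indices), `n`,
#'   `modelable`
#' @export
build_taxon_sets <- function(retained, grid_spec, min_records = 50) {
  rec <- retained[!is.na(retained$qc_status) &
                    retained$qc_status == "retained", , drop = FALSE]
  nr <- nrow(grid_spec$values)
  cell_id <- (rec$col - 1L) * nr + rec$row
  make_set <- function(label, rows) {
    r <- rec[rows, , drop = FALSE]
    cells <- unique(cell_id[rows])
    structure(list(label = label, records = r, cells = cells,
                   n = nrow(r), modelable = nrow(r) >= min_records),
              class = "chs_taxon_set")
  }
  labels <- sort(unique(rec$taxon))
  out <- lapply(labels, function(tx) make_set(tx, which(rec$taxon == tx)))
  names(out) <- labels
  out[["all"]] <- make_set("all", seq_len(nrow(rec)))
  out
}

#' @export
print.chs_taxon_set <- function(x, ...) {
  cat(sprintf("<chs_taxon_set> %s: %d records, %d occupied cells%s\n",
              x$label, x$n, length(x$cells),
              if (x$modelable) "" else " (unmodelable)"))
  invisible(x)
}
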