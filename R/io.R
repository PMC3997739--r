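#' Read scattered soundings from an XYZ text file
#'
#' Accepts whitespace- or comma-delimited columns `x y depth` (metres,
#' depth positive-down).  Lines starting with `#` are ignored.
#'
#' @param path file path
#' @return data.frame with columns `x`, `y`, `depth`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- gsub(",", " ", lines, fixed = TRUE)
  df <- utils::read.table(text = paste(lines, collapse = "\n"),
                          col.names = c("x", "y", "depth"),
                          colClasses = "numeric", fill = TRUE)
  df
}

#' @rdname read_xyz
#' @param soundings data.frame with columns `x`, `y`, `depth`
#' @export
write_xyz <- function(soundings, path) {
  utils::write.table(soundings[, c("x", "y", "depth")], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write named polygons as GeoJSON
#'
#' Polygons are represented in R as a named list, each element a
#' data.frame ring with columns `x`, `y` (closed or open; the first vertex
#' is implicitly repeated).  Only single-ring Polygon features are
#' supported, which covers sanctuary / closure boundaries.
#'
#' @param path file path
#' @return named list of data.frames with columns `x`, `y`
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  out <- list()
  for (f in feats) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("polygon_", length(out) + 1L)
    out[[nm]] <- data.frame(x = xy[, 1], y = xy[, 2])
  }
  out
}

#' @rdname read_polygons_geojson
#' @param polygons named list of data.frames with columns `x`, `y`
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(names(polygons), function(nm) {
    ring <- polygons[[nm]]
    if (ring$x[1] != ring$x[nrow(ring)] || ring$y[1] != ring$y[nrow(ring)]) {
      ring <- rbind(ring, ring[1, ])
    }
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) c(ring$x[i], ring$y[i])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write vessel-attributed trawl polylines as GeoJSON
#'
#' Each LineString feature carries a `vessel_id` property.  In R a trawl
#' line set is a data.frame of segments with columns `x0, y0, x1, y1,
#' vessel_id` (polylines are decomposed into consecutive segments).
#'
#' @param path file path
#' @return data.frame of segments
#' @export
read_trawl_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  segs <- list()
  for (f in gj$features) {
    pts <- do.call(rbind, lapply(f$geometry$coordinates,
                                 function(p) c(p[[1]], p[[2]])))
    vid <- f$properties$vessel_id
    if (nrow(pts) >= 2) {
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = pts[-nrow(pts), 1], y0 = pts[-nrow(pts), 2],
        x1 = pts[-1, 1], y1 = pts[-1, 2],
        vessel_id = vid)
    }
  }
  do.call(rbind, segs)
}

#' @rdname read_trawl_geojson
#' @param lines data.frame of segments with `x0, y0, x1, y1, vessel_id`
#' @export
write_trawl_geojson <- function(lines, path) {
  feats <- lapply(seq_len(nrow(lines)), function(i) {
    list(type = "Feature",
         properties = list(vessel_id = lines$vessel_id[i]),
         geometry = list(type = "LineString",
                         coordinates = list(c(lines$x0[i], lines$y0[i]),
                                            c(lines$x1[i], lines$y1[i]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read coral presence records from CSV with a column mapping
#'
#' Positions may be supplied as planar `x`/`y` metres or as `lon`/`lat`
#' degrees; degrees are converted through a declared equirectangular
#' projection about (`lon0`, `lat0`).  Missing optional columns are filled
#' with sensible defaults (`gear = "other"`, `family = "unknown"`).
#'
#' @param path CSV path
#' @param mapping named list mapping the canonical names
#'   (`x, y, lon, lat, depth, gear, order, suborder, family, source`) to
#'   the file's column names; identity for names not listed
#' @param lon0,lat0 projection origin, degrees (used only for lon/lat input)
#' @return data.frame of presence records
#' @export
read_presences_csv <- function(path, mapping = list(), lon0 = 0, lat0 = 45) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(canon) {
    nm <- if (!is.null(mapping[[canon]])) mapping[[canon]] else canon
    if (nm %in% names(df)) df[[nm]] else NULL
  }
  x <- pick("x"); y <- pick("y")
  if (is.null(x) || is.null(y)) {
    lon <- pick("lon"); lat <- pick("lat")
    if (is.null(lon) || is.null(lat)) {
      stop("presence CSV must provide x/y (metres) or lon/lat (degrees)")
    }
    # equirectangular: metres per degree at the declared origin latitude
    x <- (lon - lon0) * 111320 * cos(lat0 * pi / 180)
    y <- (lat - lat0) * 110540
  }
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    depth = as.numeric(pick("depth")),
                    stringsAsFactors = FALSE)
  out$gear <- if (is.null(pick("gear"))) "other" else as.character(pick("gear"))
  out$order <- if (is.null(pick("order"))) NA_character_ else as.character(pick("order"))
  sub <- pick("suborder")
  out$suborder <- if (is.null(sub)) NA_character_ else as.character(sub)
  fam <- pick("family")
  out$family <- if (is.null(fam)) "unknown" else as.character(fam)
  src <- pick("source")
  out$source <- if (is.null(src)) "" else as.character(src)
  out
}

#' Even-odd (ray casting) point-in-polygon test
#'
#' Brute-force crossing-number test against a single ring.  A point on an
#' edge may fall on either side at floating-point precision; the pipeline
#' only ever applies this to cell centers, which generic polygons do not
#' touch exactly.
#'
#' @param x,y point coordinates (vectors)
#' @param ring data.frame with columns `x`, `y` (closed or open ring)
#' @return logical vector
#' @export
point_in_polygon <- function(x, y, ring) {
  px <- ring$x; py <- ring$y
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
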