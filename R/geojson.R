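#' Write points with attributes as GeoJSON
#'
#' @param df data frame with `x`, `y` columns (planar metres) plus any number
#'   of property columns.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_geojson_points <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  props <- df[setdiff(names(df), c("x", "y"))]
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON point collection back into a data frame
#'
#' @param path GeoJSON file written by [write_geojson_points()] (or any
#'   FeatureCollection of Points with scalar properties).
#' @return data frame with `x`, `y` and one column per property.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

#' Write polygons with attributes as GeoJSON
#'
#' @param rings list of closed rings (matrices with columns x, y; first and
#'   last vertex equal), one polygon per feature.
#' @param props data frame of per-feature properties (same length as `rings`).
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_geojson_polygons <- function(rings, props, path) {
  stopifnot(length(rings) == nrow(props))
  feats <- lapply(seq_along(rings), function(i) {
    ring <- rings[[i]]
    list(type = "Feature",
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(k) c(ring[k, 1], ring[k, 2])))),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON polygon collection
#'
#' @param path GeoJSON file of single-ring Polygon features.
#' @return list with `rings` (list of x/y matrices) and `props` (data frame).
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  rings <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) unlist(p)[1:2]))
    colnames(m) <- c("x", "y")
    m
  })
  props <- do.call(rbind.data.frame,
                   c(lapply(gj$features, function(f) f$properties),
                     stringsAsFactors = FALSE))
  list(rings = rings, props = props)
}
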