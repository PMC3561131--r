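#' Georeferenced raster grid
#'
#' Lightweight planar raster container used throughout the package. Values are
#' stored as a numeric matrix whose first row is the northernmost row. The
#' origin is the north-west corner of the grid in planar metres, so the centre
#' of cell `(r, c)` is at `origin + (c - 1/2, -(r - 1/2)) * cell_size`.
#'
#' Categorical layers (land class, road class, biotic unit) are stored as
#' integer-coded rasters; see [land_class_codes()], [road_class_codes()] and
#' [biotic_unit_codes()] for the mappings.
#'
#' @param values numeric matrix (row 1 = north).
#' @param origin length-2 numeric, x/y of the north-west corner in metres.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata value used to mark missing cells on disk; in memory missing
#'   cells are `NA`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 30,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(origin), length(origin) == 2, is.finite(origin))
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g m, NW corner (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values in [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates
#'
#' @param grid a [raster_grid()].
#' @param rows,cols cell indices (1-based, recycled together).
#' @return two-column matrix of x/y centre coordinates in metres.
#' @export
cell_center <- function(grid, rows, cols) {
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] - (rows - 0.5) * grid$cell_size)
}

#' Cell indices containing planar points
#'
#' @param grid a [raster_grid()].
#' @param x,y planar coordinates in metres.
#' @return two-column integer matrix (row, col); points outside the extent
#'   give `NA`.
#' @export
cell_at <- function(grid, x, y) {
  r <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  c <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  bad <- r < 1L | r > nrow(grid$values) | c < 1L | c > ncol(grid$values)
  r[bad] <- NA_integer_; c[bad] <- NA_integer_
  cbind(row = as.integer(r), col = as.integer(c))
}

#' Check that two rasters share dimensions, origin and resolution
#'
#' @param a,b raster grids.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; errors on misalignment.
#' @export
check_aligned <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$origin - b$origin)) > 1e-6 ||
      abs(a$cell_size - b$cell_size) > 1e-9)
    stop(sprintf("%s are not aligned (dimensions, origin or cell size differ)",
                 what))
  invisible(TRUE)
}

#' Write a raster to ESRI ASCII grid format
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nrow(v) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a [raster_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("grid body has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  raster_grid(m,
              origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
              cell_size = hdr$cellsize, nodata = nodata)
}

#' Integer codes for land-class rasters
#' @return named integer vector: open = 0, forest = 1, water = 2.
#' @export
land_class_codes <- function() c(open = 0L, forest = 1L, water = 2L)

#' Integer codes for road-class rasters
#' @return named integer vector: none = 0, primary = 1, secondary_urban = 2,
#'   tertiary = 3.
#' @export
road_class_codes <- function() {
  c(none = 0L, primary = 1L, secondary_urban = 2L, tertiary = 3L)
}

#' Integer codes for biotic-unit rasters
#' @return named integer vector over the fixed vocabulary
#'   Moist, Wet, Pluvial, Dry, Other.
#' @export
biotic_unit_codes <- function() {
  c(Moist = 1L, Wet = 2L, Pluvial = 3L, Dry = 4L, Other = 5L)
}
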