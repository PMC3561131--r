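#' Speed model for the cost surface
#'
#' Assumed travel speeds: primary roads 60 km/h, secondary and urban roads
#' 40 km/h, tertiary/local/other roads 20 km/h. Off-road movement is 6 km/h
#' in open terrain, 50% slower (3 km/h) under forest, and one fifth of open
#' speed (1.2 km/h) across water not crossed by a road — cells carrying a
#' road keep the road speed regardless of land class. The slope penalty
#' coefficient `beta_r` is 0.001 s/deg^2 on roads and 0.02 s/deg^2 off road.
#'
#' @param road named speeds in km/h for primary, secondary_urban, tertiary.
#' @param open,forest,water off-road speeds in km/h.
#' @param beta_road,beta_offroad slope penalty coefficients (seconds per
#'   squared degree).
#' @return a `speed_model` list.
#' @export
speed_model <- function(road = c(primary = 60, secondary_urban = 40,
                                 tertiary = 20),
                        open = 6, forest = 3, water = 1.2,
                        beta_road = 0.001, beta_offroad = 0.02) {
  if (any(c(road, open, forest, water) <= 0))
    stop("all speeds must be positive")
  structure(list(road = road, open = open, forest = forest, water = water,
                 beta_road = beta_road, beta_offroad = beta_offroad),
            class = "speed_model")
}

#' Rasterise classed road segments
#'
#' Cells crossed by a segment take its class; where classes overlap the
#' fastest wins (primary > secondary_urban > tertiary).
#'
#' @param segments data frame with x0, y0, x1, y1 (metres) and `class`
#'   (primary, secondary_urban or tertiary).
#' @param grid a [raster_grid()] supplying the geometry.
#' @return integer-coded road-class [raster_grid()] (see
#'   [road_class_codes()]).
#' @export
rasterize_roads <- function(segments, grid) {
  codes <- road_class_codes()
  m <- matrix(codes[["none"]], nrow(grid$values), ncol(grid$values))
  if (nrow(segments)) {
    unknown <- setdiff(unique(segments$class),
                       setdiff(names(codes), "none"))
    if (length(unknown))
      stop("unknown road class(es): ", paste(unknown, collapse = ", "))
    for (k in seq_len(nrow(segments))) {
      a <- cell_at(grid, segments$x0[k], segments$y0[k])
      b <- cell_at(grid, segments$x1[k], segments$y1[k])
      if (anyNA(c(a, b))) stop("road segment endpoint outside the grid")
      line <- raster_line(a[1], a[2], b[1], b[2])
      cls <- codes[[segments$class[k]]]
      for (p in seq_len(nrow(line))) {
        cur <- m[line[p, 1], line[p, 2]]
        if (cur == codes[["none"]] || cls < cur) m[line[p, 1], line[p, 2]] <- cls
      }
    }
  }
  raster_grid(m, origin = grid$origin, cell_size = grid$cell_size)
}

#' Combine road and land class into a speed raster
#'
#' @param road_class integer-coded road raster.
#' @param land_class integer-coded land raster.
#' @param model a [speed_model()].
#' @return speed [raster_grid()] in km/h.
#' @export
build_speed_raster <- function(road_class, land_class,
                               model = speed_model()) {
  check_aligned(road_class, land_class, "road and land rasters")
  rc <- road_class$values
  lc <- land_class$values
  rcd <- road_class_codes(); lcd <- land_class_codes()
  v <- matrix(NA_real_, nrow(rc), ncol(rc))
  v[lc == lcd[["open"]]] <- model$open
  v[lc == lcd[["forest"]]] <- model$forest
  v[lc == lcd[["water"]]] <- model$water
  # roads override land class: a road across water keeps the road speed
  v[rc == rcd[["primary"]]] <- model$road[["primary"]]
  v[rc == rcd[["secondary_urban"]]] <- model$road[["secondary_urban"]]
  v[rc == rcd[["tertiary"]]] <- model$road[["tertiary"]]
  raster_grid(v, origin = road_class$origin, cell_size = road_class$cell_size)
}

#' Slope raster in degrees
#'
#' Gradient magnitude by central differences (one-sided at edges);
#' `alpha = atan(|grad z|)` in degrees, in \[0, 90).
#'
#' @param elevation elevation [raster_grid()] in metres.
#' @return slope [raster_grid()] in degrees.
#' @export
slope_raster <- function(elevation) {
  z <- elevation$values
  h <- elevation$cell_size
  nr <- nrow(z); nc <- ncol(z)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 2) {
    gx[, 2:(nc - 1)] <- (z[, 3:nc, drop = FALSE] -
                           z[, 1:(nc - 2), drop = FALSE]) / (2 * h)
    gx[, 1] <- (z[, 2] - z[, 1]) / h
    gx[, nc] <- (z[, nc] - z[, nc - 1]) / h
  }
  if (nr >= 2) {
    gy[2:(nr - 1), ] <- (z[3:nr, , drop = FALSE] -
                           z[1:(nr - 2), , drop = FALSE]) / (2 * h)
    gy[1, ] <- (z[2, ] - z[1, ]) / h
    gy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / h
  }
  alpha <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  raster_grid(alpha, origin = elevation$origin,
              cell_size = elevation$cell_size)
}

#' Time to traverse one cell
#'
#' `t = (cell_size / cos(alpha)) / v + beta_r * alpha^2` with `v` converted
#' from km/h to m/s, `alpha` the slope in degrees, and `beta_r` the road or
#' off-road penalty coefficient. The first term is the slope-lengthened
#' distance (the hypotenuse) over the flat speed; the second adds time
#' proportional to the squared slope, creating barriers on extreme terrain.
#'
#' @param speed_kmh speed in km/h (> 0).
#' @param alpha_deg slope in degrees, in \[0, 90).
#' @param is_road logical: use the road or off-road penalty coefficient.
#' @param cell_size cell edge in metres.
#' @param model a [speed_model()].
#' @return traversal time in seconds (vectorised).
#' @export
cell_cost <- function(speed_kmh, alpha_deg, is_road, cell_size = 30,
                      model = speed_model()) {
  if (any(speed_kmh <= 0)) stop("speed must be positive")
  if (any(alpha_deg < 0 | alpha_deg >= 90))
    stop("slope must lie in [0, 90) degrees")
  v_ms <- speed_kmh * 1000 / 3600
  beta <- ifelse(is_road, model$beta_road, model$beta_offroad)
  (cell_size / cos(alpha_deg * pi / 180)) / v_ms + beta * alpha_deg^2
}

#' Cost surface from speed, slope and road rasters
#'
#' @param speed speed [raster_grid()] (km/h).
#' @param slope slope [raster_grid()] (degrees).
#' @param road_class integer-coded road raster (selects the penalty
#'   coefficient).
#' @param model a [speed_model()].
#' @return a `cost_surface`: [raster_grid()] of per-cell traversal seconds.
#' @export
cost_surface <- function(speed, slope, road_class, model = speed_model()) {
  check_aligned(speed, slope, "speed and slope rasters")
  check_aligned(speed, road_class, "speed and road rasters")
  is_road <- road_class$values != road_class_codes()[["none"]]
  t <- cell_cost(speed$values, slope$values, is_road,
                 cell_size = speed$cell_size, model = model)
  out <- raster_grid(matrix(t, nrow(speed$values)), origin = speed$origin,
                     cell_size = speed$cell_size)
  class(out) <- c("cost_surface", class(out))
  out
}

#' Accumulated travel time from a source set
#'
#' Minimum cumulative time from the nearest source over 8-connected moves;
#' the cost of a move between adjacent cells is the mean of the two cells'
#' traversal times, scaled by sqrt(2) for diagonal moves. Computed by
#' Dijkstra's algorithm; source cells are exactly zero and unreachable cells
#' are `NA`.
#'
#' @param cost a [cost_surface()] (seconds per cell; `NA` = impassable).
#' @param sources data frame with `x`, `y` (metres) of source points.
#' @param label optional source-set label carried on the result.
#' @return accumulated-time [raster_grid()] in seconds, with attribute
#'   `sources`.
#' @export
accumulate_time <- function(cost, sources, label = NULL) {
  if (nrow(sources) == 0) stop("no source points")
  rc <- cell_at(cost, sources$x, sources$y)
  if (anyNA(rc)) stop("source point outside the grid extent")
  acc <- accumulate_time_cpp(cost$values, rc)
  out <- raster_grid(acc, origin = cost$origin, cell_size = cost$cell_size)
  attr(out, "sources") <- label
  out
}

#' Total travel time via ambulance
#'
#' Cellwise sum of the station-to-cell and cell-to-facility accumulated
#' times, converted to hours: the ambulance drives from its station to the
#' victim, then to the hospital or clinic. Cells unreachable from either
#' source set are `NA`. Off-road stretches are traversed in both legs, so
#' their effective speed is halved — exactly the double counting the model
#' intends.
#'
#' @param from_stations,from_facilities accumulated-time rasters (seconds).
#' @return total-time [raster_grid()] in hours.
#' @export
total_time <- function(from_stations, from_facilities) {
  check_aligned(from_stations, from_facilities, "accumulated-time rasters")
  raster_grid((from_stations$values + from_facilities$values) / 3600,
              origin = from_stations$origin,
              cell_size = from_stations$cell_size)
}

#' Mean travel time over each unit's populated buffer
#'
#' For every census unit, averages the total-time raster over the cells
#' within `radius` of the unit's centroid (`NA` cells excluded). Units whose
#' buffer holds no finite time are reported unreachable.
#'
#' @param total total-time [raster_grid()] in hours.
#' @param units census-unit data frame with unit_id, x, y.
#' @param radius buffer radius in metres.
#' @return data frame: unit_id, mean_hours (`NA` when unreachable),
#'   unreachable flag.
#' @export
extract_mean_time <- function(total, units, radius = 2000) {
  nr <- nrow(total$values); nc <- ncol(total$values)
  cs <- total$cell_size
  out <- data.frame(unit_id = units$unit_id, mean_hours = NA_real_,
                    unreachable = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(units))) {
    rc <- cell_at(total, units$x[k], units$y[k])
    if (anyNA(rc)) stop("census unit outside the grid extent")
    span <- ceiling(radius / cs) + 1L
    rows <- max(1L, rc[1] - span):min(nr, rc[1] + span)
    cols <- max(1L, rc[2] - span):min(nc, rc[2] + span)
    ctr <- cell_center(total, rep(rows, length(cols)),
                       rep(cols, each = length(rows)))
    hit <- (ctr[, 1] - units$x[k])^2 + (ctr[, 2] - units$y[k])^2 <= radius^2
    vals <- total$values[cbind(rep(rows, length(cols))[hit],
                               rep(cols, each = length(rows))[hit])]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out$mean_hours[k] <- mean(vals)
    else out$unreachable[k] <- TRUE
  }
  out
}

#' Categorise travel time
#'
#' Half-open convention: \[0, 2) hours is "<2 h", \[2, 3) is "2-3 h", and
#' 3 hours or more is ">3 h".
#'
#' @param hours nonnegative travel times in hours (`NA` allowed,
#'   propagated).
#' @param bounds increasing category bounds in hours (default 2 and 3).
#' @return factor with levels "<2 h", "2-3 h", ">3 h" (labels follow
#'   `bounds`).
#' @export
categorize_time <- function(hours, bounds = c(2, 3)) {
  if (any(hours < 0, na.rm = TRUE)) stop("travel time cannot be negative")
  if (length(bounds) != 2 || diff(bounds) <= 0)
    stop("category bounds must be increasing")
  cut(hours, breaks = c(0, bounds, Inf), right = FALSE,
      labels = c(sprintf("<%g h", bounds[1]),
                 sprintf("%g-%g h", bounds[1], bounds[2]),
                 sprintf(">%g h", bounds[2])), include.lowest = TRUE)
}

#' Population fractions per travel-time category
#'
#' Population-weighted fractions of the high-risk population in each
#' travel-time category, plus the unreachable remainder; fractions sum to 1.
#'
#' @param mean_times data frame from [extract_mean_time()] restricted to the
#'   units of interest.
#' @param units matching census-unit data frame carrying `population`.
#' @return named list of fractions: `<2 h`, `2-3 h`, `>3 h`, unreachable.
#' @export
population_time_summary <- function(mean_times, units) {
  stopifnot(identical(mean_times$unit_id, units$unit_id))
  tot <- sum(units$population)
  if (tot <= 0) stop("zero total population")
  cat <- categorize_time(mean_times$mean_hours)
  f <- vapply(levels(cat), function(l)
    sum(units$population[!is.na(cat) & cat == l]) / tot, numeric(1))
  c(as.list(f), list(unreachable = sum(units$population[is.na(cat)]) / tot))
}
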