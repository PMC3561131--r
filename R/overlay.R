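#' Remove duplicate case records
#'
#' Records identical on the four key fields (age, sex, month of bite,
#' district of residence) are collapsed to the first occurrence in input
#' order. Records missing any key field are not deduplicated silently: they
#' are routed to a rejected-records report.
#'
#' @param records data frame with columns age, sex, month, district_id.
#' @return list: `records` (cleaned), `n_removed`, `rejected` (records with
#'   missing key fields).
#' @export
deduplicate_cases <- function(records) {
  key_cols <- c("age", "sex", "month", "district_id")
  if (!all(key_cols %in% names(records)))
    stop("records must carry the key fields: ",
         paste(key_cols, collapse = ", "))
  bad <- rowSums(is.na(records[key_cols])) > 0
  rejected <- records[bad, , drop = FALSE]
  keep <- records[!bad, , drop = FALSE]
  dup <- duplicated(keep[key_cols])
  cleaned <- keep[!dup, , drop = FALSE]
  rownames(cleaned) <- NULL
  list(records = cleaned, n_removed = sum(dup), rejected = rejected)
}

#' Mean imputation of missing covariate values
#'
#' Used for districts whose satellite-derived forest coverage was obscured by
#' cloud: missing entries take the arithmetic mean of the observed ones.
#'
#' @param values numeric vector.
#' @param missing logical mask (defaults to `is.na(values)`).
#' @return completed numeric vector.
#' @export
impute_mean <- function(values, missing = is.na(values)) {
  if (all(missing)) stop("all values missing: nothing to impute from")
  values[missing] <- mean(values[!missing])
  values
}

#' Snake-habitat suitability rule
#'
#' The terciopelo (*Bothrops asper*) habitat rule: suitable when elevation is
#' strictly below `max_elevation_m` and the biotic unit is Moist, Wet or
#' Pluvial.
#'
#' @param max_elevation_m elevation ceiling in metres (default 1200).
#' @param suitable_units character vector of suitable biotic units.
#' @return a `habitat_rule` list.
#' @export
habitat_rule <- function(max_elevation_m = 1200,
                         suitable_units = c("Moist", "Wet", "Pluvial")) {
  if (max_elevation_m <= 0) stop("max_elevation_m must be positive")
  if (!length(suitable_units)) stop("suitable unit set must be non-empty")
  unknown <- setdiff(suitable_units, names(biotic_unit_codes()))
  if (length(unknown))
    stop("unknown biotic unit(s): ", paste(unknown, collapse = ", "))
  structure(list(max_elevation_m = max_elevation_m,
                 suitable_units = suitable_units), class = "habitat_rule")
}

#' Classify habitat suitability
#'
#' @param elevation_m elevation in metres (vectorised).
#' @param biotic_unit biotic unit names from the fixed vocabulary
#'   (Moist, Wet, Pluvial, Dry, Other).
#' @param rule a [habitat_rule()].
#' @return logical vector: suitable for the snake or not.
#' @export
classify_habitat <- function(elevation_m, biotic_unit, rule = habitat_rule()) {
  unknown <- setdiff(unique(biotic_unit), names(biotic_unit_codes()))
  if (length(unknown))
    stop("unknown biotic unit(s): ", paste(unknown, collapse = ", "))
  elevation_m < rule$max_elevation_m & biotic_unit %in% rule$suitable_units
}

#' Habitat-suitability raster
#'
#' Applies [classify_habitat()] cellwise to aligned elevation and
#' biotic-unit rasters.
#'
#' @param elevation a [raster_grid()] of metres.
#' @param biotic a [raster_grid()] of [biotic_unit_codes()].
#' @param rule a [habitat_rule()].
#' @return a 0/1 [raster_grid()].
#' @export
habitat_raster <- function(elevation, biotic, rule = habitat_rule()) {
  check_aligned(elevation, biotic, "elevation and biotic rasters")
  codes <- biotic_unit_codes()
  unit <- names(codes)[match(as.vector(biotic$values), codes)]
  ok <- classify_habitat(as.vector(elevation$values), unit, rule)
  raster_grid(matrix(as.numeric(ok), nrow(elevation$values)),
              origin = elevation$origin, cell_size = elevation$cell_size)
}

#' Populated-area mask around census centroids
#'
#' A cell is populated when its centre lies within `radius` metres
#' (Euclidean, planar) of at least one census-unit centroid — the raster
#' proxy for populated areas.
#'
#' @param units data frame with `x`, `y` (metres).
#' @param grid a [raster_grid()] providing the geometry.
#' @param radius buffer radius in metres (default 2000).
#' @return a 0/1 [raster_grid()].
#' @export
populated_area_mask <- function(units, grid, radius = 2000) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  inside <- matrix(FALSE, nr, nc)
  r2 <- radius^2
  cs <- grid$cell_size
  for (k in seq_len(nrow(units))) {
    rc <- cell_at(grid, units$x[k], units$y[k])
    if (anyNA(rc)) stop("census unit outside the grid extent")
    # only cells within the bounding square can be inside the circle
    span <- ceiling(radius / cs) + 1L
    rows <- max(1L, rc[1] - span):min(nr, rc[1] + span)
    cols <- max(1L, rc[2] - span):min(nc, rc[2] + span)
    ctr <- cell_center(grid, rep(rows, length(cols)),
                       rep(cols, each = length(rows)))
    hit <- (ctr[, 1] - units$x[k])^2 + (ctr[, 2] - units$y[k])^2 <= r2
    inside[cbind(rep(rows, length(cols))[hit],
                 rep(cols, each = length(rows))[hit])] <- TRUE
  }
  raster_grid(matrix(as.numeric(inside), nr, nc), origin = grid$origin,
              cell_size = grid$cell_size)
}

#' Flag high-risk districts from exceedance probabilities
#'
#' A district is high risk when its posterior probability of exceeding the
#' incidence threshold is at least the cutoff (inclusive; the calibrated
#' default is 10%).
#'
#' @param probs named numeric vector of exceedance probabilities in \[0,1\].
#' @param cutoff probability cutoff.
#' @return character vector of flagged district ids (names of `probs`).
#' @export
high_risk_districts <- function(probs, cutoff = 0.10) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  names(probs)[probs >= cutoff]
}

#' Combine incidence-based and habitat-based risk
#'
#' A census unit is high risk when its district is flagged for incidence,
#' or when it is rural and sits on habitat suitable for the snake (the
#' habitat branch applies to the rural population only). The populated
#' high-risk mask buffers 2 km around the high-risk units.
#'
#' @param units census-unit data frame (unit_id, x, y, population, urban,
#'   district_id).
#' @param habitat a 0/1 habitat [raster_grid()] from [habitat_raster()].
#' @param flagged character vector of high-risk district ids.
#' @param buffer_m buffer radius for the populated-risk mask (metres).
#' @return a `risk_classification`: `units` data frame with `high_risk`
#'   logical and `reason` (district-incidence, habitat, both, or NA), plus
#'   `mask` (0/1 raster of populated high-risk areas).
#' @export
combine_risk <- function(units, habitat, flagged, buffer_m = 2000) {
  rc <- cell_at(habitat, units$x, units$y)
  if (anyNA(rc))
    stop("census unit(s) outside the raster extent: ",
         paste(units$unit_id[is.na(rc[, 1])], collapse = ", "))
  suitable <- habitat$values[rc] > 0
  by_district <- units$district_id %in% flagged
  by_habitat <- !units$urban & suitable
  high <- by_district | by_habitat
  reason <- rep(NA_character_, nrow(units))
  reason[by_district & !by_habitat] <- "district-incidence"
  reason[!by_district & by_habitat] <- "habitat"
  reason[by_district & by_habitat] <- "both"
  out <- units
  out$high_risk <- high
  out$reason <- reason
  mask <- populated_area_mask(units[high, , drop = FALSE], habitat,
                              radius = buffer_m)
  structure(list(units = out, mask = mask), class = "risk_classification")
}

#' Population fractions by risk reason
#'
#' Splits the total census population into the exhaustive partition:
#' living in incidence-flagged districts; at habitat-only risk; either;
#' neither. Fractions account for the overlap and sum to one.
#'
#' @param classification a `risk_classification` from [combine_risk()].
#' @return named list of fractions: district, habitat_only, either, neither.
#' @export
population_risk_summary <- function(classification) {
  u <- classification$units
  tot <- sum(u$population)
  if (tot <= 0) stop("zero total population")
  in_flagged <- u$reason %in% c("district-incidence", "both")
  habitat_only <- u$reason %in% "habitat"
  list(district = sum(u$population[in_flagged]) / tot,
       habitat_only = sum(u$population[habitat_only]) / tot,
       either = sum(u$population[u$high_risk]) / tot,
       neither = sum(u$population[!u$high_risk]) / tot)
}
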