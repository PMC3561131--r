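#' Configuration of the synthetic world
#'
#' The generator emulates the data a national snakebite-risk study consumes:
#' an administrative district map with queen adjacency, per-district
#' populations and environmental covariates, individual case records drawn
#' from a Poisson log-linear model with a spatially correlated residual risk
#' field, and a raster terrain with land classes, a road network, health
#' facilities, ambulance stations and census-unit centroids.
#'
#' Defaults encode the study conditions: a 10 x 15 lattice (150 districts),
#' 30 m cells, an 18-year observation span (1990-2007), a baseline incidence
#' of 15 cases per 100,000 person-years, CAR field standard deviation 0.3,
#' fixed effects on the fitted (standardised) scale, 72% male victims and age
#' bands 27/32/21/22%.
#'
#' @param lattice_rows,lattice_cols district-lattice dimensions (each >= 2,
#'   and at least 2 districts overall).
#' @param raster_rows,raster_cols raster grid dimensions (>= 2).
#' @param cell_size raster cell edge in metres.
#' @param n_years observation span in years.
#' @param start_year first calendar year of the span.
#' @param beta0_true intercept of the generative log-linear model (log
#'   incidence ratio relative to `baseline_rate`; 0 means the realized
#'   population-average rate equals `baseline_rate`).
#' @param beta_true named fixed-effect coefficients per +1 SD of each
#'   covariate (the standardized scale). Defaults are the study's published
#'   multivariate incidence ratios: elevation 0.60 per SD, dry months 0.66
#'   per SD, precipitation 1.45 per SD, forest 1.53 and urban 0.39 per
#'   +100%-units (converted to per-SD using the Beta covariate spreads).
#' @param sigma_u standard deviation of the intrinsic CAR residual field.
#' @param baseline_rate expected incidence per 100,000 person-years when all
#'   covariate effects and spatial effects are zero.
#' @param population_range min/max district population (integers).
#' @param duplicate_rate fraction of case records duplicated to exercise the
#'   deduplication rule (in \[0,1\]).
#' @param pct_male probability a victim is male.
#' @param age_band_probs probabilities of the four age bands <15, 15-30,
#'   30-45, >45.
#' @param n_facilities,n_stations,n_ebais,n_census_units point-set sizes for
#'   the raster world (facilities and stations must be >= 1).
#' @param seed integer seed; every generator output is deterministic under
#'   (config, seed).
#' @return a validated `world_config` list.
#' @export
world_config <- function(lattice_rows = 10, lattice_cols = 15,
                         raster_rows = 200, raster_cols = 200,
                         cell_size = 30,
                         n_years = 18, start_year = 1990,
                         beta0_true = 0,
                         beta_true = c(urban_frac = log(0.39) * 0.201,
                                       forest_frac = log(1.53) * 0.224,
                                       elevation_m = log(0.60),
                                       precipitation_mm_yr = log(1.45),
                                       dry_months = log(0.66)),
                         sigma_u = 0.3,
                         baseline_rate = 15,
                         population_range = c(2000, 20000),
                         duplicate_rate = 0.013,
                         pct_male = 0.72,
                         age_band_probs = c(0.27, 0.32, 0.21, 0.22),
                         n_facilities = 5, n_stations = 6, n_ebais = 10,
                         n_census_units = 250,
                         seed = 1L) {
  cfg <- list(lattice_rows = as.integer(lattice_rows),
              lattice_cols = as.integer(lattice_cols),
              raster_rows = as.integer(raster_rows),
              raster_cols = as.integer(raster_cols),
              cell_size = cell_size, n_years = as.integer(n_years),
              start_year = as.integer(start_year),
              beta0_true = beta0_true, beta_true = beta_true,
              sigma_u = sigma_u, baseline_rate = baseline_rate,
              population_range = as.integer(population_range),
              duplicate_rate = duplicate_rate, pct_male = pct_male,
              age_band_probs = age_band_probs,
              n_facilities = as.integer(n_facilities),
              n_stations = as.integer(n_stations),
              n_ebais = as.integer(n_ebais),
              n_census_units = as.integer(n_census_units),
              seed = as.integer(seed))
  if (cfg$lattice_rows < 2 || cfg$lattice_cols < 2 ||
      cfg$raster_rows < 2 || cfg$raster_cols < 2)
    stop("all lattice/raster dimensions must be >= 2")
  if (cfg$cell_size <= 0) stop("cell_size must be > 0")
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1)
    stop("duplicate_rate must lie in [0, 1]")
  if (cfg$sigma_u < 0) stop("sigma_u must be >= 0")
  if (cfg$population_range[1] < 1 ||
      cfg$population_range[2] < cfg$population_range[1])
    stop("population_range must be increasing and positive")
  if (abs(sum(cfg$age_band_probs) - 1) > 0.05)
    stop("age_band_probs must sum to (approximately) 1")
  # the published band percentages sum to 102%; normalise proportionally
  cfg$age_band_probs <- cfg$age_band_probs / sum(cfg$age_band_probs)
  class(cfg) <- "world_config"
  cfg
}

#' District lattice with queen adjacency
#'
#' Districts are axis-aligned rectangles tiling the raster extent, numbered
#' row-major from the north-west. Queen contiguity: sharing a border or a
#' corner makes two districts neighbours.
#'
#' @param config a [world_config()].
#' @return list with `ids`, `rings` (closed polygon rings), `centers`
#'   (x/y matrix), `adjacency` (an `adjacency_graph`), and lattice dims.
#' @export
generate_district_lattice <- function(config) {
  nr <- config$lattice_rows; nc <- config$lattice_cols
  width <- config$raster_cols * config$cell_size
  height <- config$raster_rows * config$cell_size
  dx <- width / nc; dy <- height / nr
  n <- nr * nc
  rings <- vector("list", n)
  centers <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- k + 1L
    x0 <- (c - 1) * dx; x1 <- c * dx
    # y decreases southwards from the top of the extent
    y1 <- height - (r - 1) * dy; y0 <- height - r * dy
    rings[[k]] <- cbind(x = c(x0, x1, x1, x0, x0),
                        y = c(y0, y0, y1, y1, y0))
    centers[k, ] <- c((x0 + x1) / 2, (y0 + y1) / 2)
  }
  list(ids = sprintf("D%03d", seq_len(n)), rings = rings, centers = centers,
       adjacency = lattice_adjacency(nr, nc),
       lattice_rows = nr, lattice_cols = nc,
       extent = c(xmin = 0, xmax = width, ymin = 0, ymax = height))
}

# Smooth random field: sum of k Gaussian bumps with random centres, signs and
# widths, evaluated at the given points. Uses the current RNG stream.
gaussian_bump_field <- function(pts, extent, k = 8, rel_scale = 0.35) {
  span <- c(extent["xmax"] - extent["xmin"], extent["ymax"] - extent["ymin"])
  cx <- stats::runif(k, extent["xmin"], extent["xmax"])
  cy <- stats::runif(k, extent["ymin"], extent["ymax"])
  amp <- stats::rnorm(k)
  ell <- stats::runif(k, 0.5, 1.5) * rel_scale * mean(span)
  z <- numeric(nrow(pts))
  for (j in seq_len(k))
    z <- z + amp[j] * exp(-((pts[, 1] - cx[j])^2 + (pts[, 2] - cy[j])^2) /
                            (2 * ell[j]^2))
  z
}

rescale01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

#' Per-district covariates and population
#'
#' Elevation is a spatially smooth field scaled to 0-2000 m; precipitation is
#' negatively correlated with elevation plus noise (humid lowlands); dry
#' months discretise the inverse of precipitation; forest and urban fractions
#' are Beta-distributed; population is uniform over the configured range.
#'
#' @param districts output of [generate_district_lattice()].
#' @param config a [world_config()].
#' @param seed optional integer seed (defaults to `config$seed + 101`).
#' @return data frame: district_id, population, urban_frac, forest_frac,
#'   elevation_m, precipitation_mm_yr, dry_months.
#' @export
sample_covariates <- function(districts, config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 101L else as.integer(seed))
  n <- length(districts$ids)
  elev <- 2000 * rescale01(gaussian_bump_field(districts$centers,
                                               districts$extent))
  precip <- 6000 - 2 * elev + stats::rnorm(n, 0, 400)
  precip <- pmax(precip, 800)
  dry <- pmax(0L, pmin(7L, round(7 * rescale01(-precip) +
                                   stats::rnorm(n, 0, 0.4))))
  data.frame(
    district_id = districts$ids,
    population = as.integer(round(stats::runif(
      n, config$population_range[1], config$population_range[2]))),
    urban_frac = stats::rbeta(n, 1.5, 3),
    forest_frac = stats::rbeta(n, 2, 2),
    elevation_m = elev,
    precipitation_mm_yr = precip,
    dry_months = as.numeric(dry),
    stringsAsFactors = FALSE)
}

#' Exact draw from the intrinsic CAR (Besag) field
#'
#' Simulates `u ~ N(0, sigma_u^2 * Q^+)` where `Q = D - W` is the intrinsic
#' Besag precision of the adjacency graph and `Q^+` its Moore-Penrose
#' generalised inverse (null space removed by eigen-decomposition), then
#' centres the draw to mean zero. Exact — no MCMC burn-in involved.
#'
#' @param adj a connected `adjacency_graph`.
#' @param sigma_u CAR standard deviation; 0 gives the zero field.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector `u` with `sum(u) == 0` (numerically).
#' @export
sample_car_field <- function(adj, sigma_u, seed = NULL) {
  check_connected(adj)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- adj$n
  if (sigma_u == 0) return(numeric(n))
  Q <- diag(adj$n_nbr) - adjacency_matrix(adj)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  z <- stats::rnorm(sum(pos))
  u <- as.vector(eg$vectors[, pos, drop = FALSE] %*%
                   (z / sqrt(eg$values[pos]))) * sigma_u
  u - mean(u)
}

# Generative design matrix: beta_true is defined per +1 SD of every
# covariate, so all five columns are standardised (population-SD
# convention). The fitting module uses its own working scale (fractions
# raw); [standardized_coefficients()] converts fitted draws back to this
# scale for recovery comparisons.
world_design_matrix <- function(covariates) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  std <- function(x) (x - mean(x)) / pop_sd(x)
  cbind(urban_frac = std(covariates$urban_frac),
        forest_frac = std(covariates$forest_frac),
        elevation_m = std(covariates$elevation_m),
        precipitation_mm_yr = std(covariates$precipitation_mm_yr),
        dry_months = std(covariates$dry_months))
}

#' Spatially structured case counts
#'
#' Draws yearly district counts as independent Poisson variates with annual
#' mean `E_i * exp(eta_i) / n_years`, where the generative offset is
#' `E_i = baseline_rate/1e5 * population_i * n_years` and the linear
#' predictor `eta = beta0 + X beta + u` is centred so that the
#' population-weighted mean of `exp(eta)` equals `exp(beta0)`. The centring
#' pins the realized population-average incidence at
#' `baseline_rate * exp(beta0)` (the study's overall rate), which a raw
#' log-linear predictor would otherwise inflate (Jensen's inequality). Row
#' sums are the modeled period totals `Y_i ~ Poisson(E_i exp(eta_i))`.
#'
#' @param districts output of [generate_district_lattice()].
#' @param covariates data frame from [sample_covariates()].
#' @param beta_true named coefficient vector (working scale; see
#'   [world_config()]).
#' @param u CAR field from [sample_car_field()].
#' @param config a [world_config()].
#' @param seed optional integer seed (defaults to `config$seed + 103`).
#' @return list: `yearly` (district x year count matrix with year colnames),
#'   `total` (row sums), `E` (generative offsets), `eta` (linear predictor).
#' @export
sample_case_counts <- function(districts, covariates, beta_true, u, config,
                               seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 103L else as.integer(seed))
  X <- world_design_matrix(covariates)
  stopifnot(identical(colnames(X), names(beta_true)))
  eta_rel <- as.vector(X %*% beta_true) + u
  if (any(!is.finite(eta_rel))) stop("non-finite linear predictor")
  w <- covariates$population / sum(covariates$population)
  eta <- config$beta0_true + eta_rel - log(sum(w * exp(eta_rel)))
  E <- config$baseline_rate / 1e5 * covariates$population * config$n_years
  mu_year <- E * exp(eta) / config$n_years
  n <- length(E)
  yearly <- matrix(stats::rpois(n * config$n_years, rep(mu_year,
                                                        config$n_years)),
                   nrow = n, ncol = config$n_years,
                   dimnames = list(covariates$district_id,
                                   config$start_year +
                                     seq_len(config$n_years) - 1L))
  list(yearly = yearly, total = rowSums(yearly), E = E, eta = eta)
}

#' Individual case records with injected duplicates
#'
#' One record per case: age from the four configured bands (uniform within
#' band), sex with the configured male fraction, month uniform over 1-12.
#' A seeded binomial draw duplicates a fraction of records exactly on the
#' four key fields (age, sex, month, district) so the downstream
#' deduplication rule has something to remove.
#'
#' @param counts integer vector of per-district case totals.
#' @param district_ids district identifiers aligned with `counts`.
#' @param config a [world_config()].
#' @param seed optional integer seed (defaults to `config$seed + 104`).
#' @return data frame (id, age, sex, month, district_id) with attribute
#'   `n_duplicates`.
#' @export
sample_case_records <- function(counts, district_ids, config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 104L else as.integer(seed))
  stopifnot(all(counts >= 0), length(counts) == length(district_ids))
  n <- sum(counts)
  band <- sample.int(4L, n, replace = TRUE, prob = config$age_band_probs)
  lo <- c(1, 15, 30, 45)[band]
  hi <- c(14, 29, 44, 90)[band]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1))
  rec <- data.frame(
    id = seq_len(n),
    age = as.integer(age),
    sex = ifelse(stats::runif(n) < config$pct_male, "M", "F"),
    month = sample.int(12L, n, replace = TRUE),
    district_id = rep(district_ids, counts),
    stringsAsFactors = FALSE)
  dup <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup)) {
    extra <- rec[dup, , drop = FALSE]
    extra$id <- n + seq_along(dup)
    rec <- rbind(rec, extra)
  }
  rownames(rec) <- NULL
  attr(rec, "n_duplicates") <- length(dup)
  rec
}

# Bresenham-style raster line between two cells; returns matrix of (row, col).
raster_line <- function(r0, c0, r1, c1) {
  n_steps <- max(abs(r1 - r0), abs(c1 - c0))
  if (n_steps == 0) return(cbind(row = r0, col = c0))
  t <- seq(0, 1, length.out = n_steps + 1L)
  cbind(row = round(r0 + t * (r1 - r0)), col = round(c0 + t * (c1 - c0)))
}

# Minimum spanning tree over points by Prim's algorithm; returns edge matrix.
prim_mst <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(0), 0, 2))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  d2 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  parent <- rep(1L, n)
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(d2[cand])]
    edges[k, ] <- c(parent[j], j)
    in_tree[j] <- TRUE
    nd2 <- (pts[, 1] - pts[j, 1])^2 + (pts[, 2] - pts[j, 2])^2
    upd <- !in_tree & nd2 < d2
    d2[upd] <- nd2[upd]
    parent[upd] <- j
  }
  edges
}

#' Synthetic raster world
#'
#' Generates aligned rasters (elevation, land class, road class, biotic unit)
#' plus facility, ambulance-station, EBAIS and census-centroid point sets.
#' Elevation is a sum of seeded Gaussian bumps scaled to 0-1600 m. Land
#' classes cover open, forest and water. The road network is the rasterised
#' minimum spanning tree over facilities, stations and town nodes, so it is
#' connected and touches every facility and station; trunk edges between
#' facilities are primary, edges at stations secondary/urban, the rest
#' tertiary. Census units sit on or near the network; a unit is urban when it
#' lies within 1.5 km of a facility. The biotic unit raster follows moisture:
#' low/wet cells are Moist/Wet/Pluvial, high dry cells Dry, the rest Other.
#'
#' @param config a [world_config()].
#' @param seed optional integer seed (defaults to `config$seed + 105`).
#' @return a `raster_world`: list of `raster_grid` layers `elevation`,
#'   `land`, `road`, `biotic`, plus data frames `facilities`, `stations`,
#'   `ebais`, `census_units`.
#' @export
generate_raster_world <- function(config, seed = NULL) {
  if (config$n_facilities < 1 || config$n_stations < 1)
    stop("config must yield at least one facility and one ambulance station")
  set.seed(if (is.null(seed)) config$seed + 105L else as.integer(seed))
  nr <- config$raster_rows; nc <- config$raster_cols
  cs <- config$cell_size
  extent <- c(xmin = 0, xmax = nc * cs, ymin = 0, ymax = nr * cs)
  grid0 <- raster_grid(matrix(0, nr, nc), origin = c(0, nr * cs),
                       cell_size = cs)
  centers <- cell_center(grid0, rep(seq_len(nr), nc),
                         rep(seq_len(nc), each = nr))

  elev_v <- 1600 * rescale01(gaussian_bump_field(centers, extent, k = 10))
  elevation <- raster_grid(matrix(elev_v, nr, nc), origin = c(0, nr * cs),
                           cell_size = cs)

  moisture <- rescale01(gaussian_bump_field(centers, extent, k = 6,
                                            rel_scale = 0.25)) -
    0.3 * rescale01(elev_v)
  forest_f <- rescale01(gaussian_bump_field(centers, extent, k = 6,
                                            rel_scale = 0.2))
  lc <- matrix(land_class_codes()[["open"]], nr, nc)
  lc[matrix(forest_f, nr, nc) > stats::quantile(forest_f, 0.75)] <-
    land_class_codes()[["forest"]]
  # water: lowest-moisture-basin strip — carve a meandering river west-east
  rr <- round(nr / 2 + (nr / 6) * sin(seq(0, 3 * pi, length.out = nc)) +
                cumsum(stats::rnorm(nc, 0, 0.6)))
  rr <- pmin(pmax(rr, 1L), nr)
  for (j in seq_len(nc)) lc[rr[j], j] <- land_class_codes()[["water"]]

  # nodes: facilities, stations, towns — biased towards lowland
  n_towns <- max(4L, config$n_census_units %/% 25L)
  pick_cells <- function(k) {
    w <- (1 - rescale01(elev_v))^2 + 0.05
    idx <- sample.int(nr * nc, k, prob = w)
    cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
  }
  fac_rc <- pick_cells(config$n_facilities)
  sta_rc <- pick_cells(config$n_stations)
  town_rc <- pick_cells(n_towns)
  ebais_rc <- pick_cells(config$n_ebais)

  nodes <- rbind(fac_rc, sta_rc, town_rc)
  node_kind <- rep(c("facility", "station", "town"),
                   c(nrow(fac_rc), nrow(sta_rc), nrow(town_rc)))
  rc <- matrix(road_class_codes()[["none"]], nr, nc)
  codes <- road_class_codes()
  edges <- prim_mst(nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    cls <- if (node_kind[a] == "facility" || node_kind[b] == "facility") {
      codes[["primary"]]
    } else if (node_kind[a] == "station" || node_kind[b] == "station") {
      codes[["secondary_urban"]]
    } else codes[["tertiary"]]
    line <- raster_line(nodes[a, 1], nodes[a, 2], nodes[b, 1], nodes[b, 2])
    for (p in seq_len(nrow(line))) {
      cur <- rc[line[p, 1], line[p, 2]]
      # overlaps resolve to the fastest (lowest nonzero code) class
      if (cur == codes[["none"]] || cls < cur) rc[line[p, 1], line[p, 2]] <- cls
    }
  }

  # guarantee all land classes present even on odd draws
  lcc <- land_class_codes()
  if (!any(lc == lcc[["forest"]])) lc[1, 1] <- lcc[["forest"]]
  if (!any(lc == lcc[["open"]])) lc[1, 2] <- lcc[["open"]]

  # biotic units from moisture and elevation
  bu <- biotic_unit_codes()
  bm <- matrix(bu[["Other"]], nr, nc)
  mq <- stats::quantile(moisture, c(0.35, 0.6, 0.85))
  mmat <- matrix(moisture, nr, nc)
  bm[mmat > mq[1]] <- bu[["Moist"]]
  bm[mmat > mq[2]] <- bu[["Wet"]]
  bm[mmat > mq[3]] <- bu[["Pluvial"]]
  bm[mmat <= mq[1] & matrix(elev_v, nr, nc) >
       stats::quantile(elev_v, 0.7)] <- bu[["Dry"]]

  mk <- function(m) raster_grid(m, origin = c(0, nr * cs), cell_size = cs)
  rc_to_xy <- function(m, kind) {
    xy <- cell_center(grid0, m[, 1], m[, 2])
    data.frame(id = sprintf("%s%02d", toupper(substr(kind, 1, 1)),
                            seq_len(nrow(m))),
               x = xy[, 1], y = xy[, 2], kind = kind,
               stringsAsFactors = FALSE)
  }

  # census units: mostly jittered around road cells, remainder uniform
  road_cells <- which(rc != road_class_codes()[["none"]], arr.ind = TRUE)
  n_cu <- config$n_census_units
  n_on <- round(0.6 * n_cu)
  pick <- road_cells[sample.int(nrow(road_cells), n_on, replace = TRUE), ,
                     drop = FALSE]
  jit <- matrix(sample(-3:3, 2 * n_on, replace = TRUE), ncol = 2)
  cu_rc <- pick + jit
  cu_rc <- rbind(cu_rc,
                 cbind(sample.int(nr, n_cu - n_on, replace = TRUE),
                       sample.int(nc, n_cu - n_on, replace = TRUE)))
  cu_rc[, 1] <- pmin(pmax(cu_rc[, 1], 1L), nr)
  cu_rc[, 2] <- pmin(pmax(cu_rc[, 2], 1L), nc)
  cu_xy <- cell_center(grid0, cu_rc[, 1], cu_rc[, 2])
  fac_xy <- cell_center(grid0, fac_rc[, 1], fac_rc[, 2])
  near_fac <- vapply(seq_len(n_cu), function(i)
    min(sqrt((fac_xy[, 1] - cu_xy[i, 1])^2 +
               (fac_xy[, 2] - cu_xy[i, 2])^2)), numeric(1))
  # district of each unit from its position on the district lattice
  dcol <- pmin(pmax(ceiling(cu_xy[, 1] / (nc * cs / config$lattice_cols)),
                    1L), config$lattice_cols)
  drow_north <- pmin(pmax(ceiling((nr * cs - cu_xy[, 2]) /
                                    (nr * cs / config$lattice_rows)), 1L),
                     config$lattice_rows)
  census_units <- data.frame(
    unit_id = sprintf("U%04d", seq_len(n_cu)),
    x = cu_xy[, 1], y = cu_xy[, 2],
    population = as.integer(pmax(20, round(stats::rlnorm(n_cu, 5.5, 0.8)))),
    urban = near_fac < 1500,
    district_id = sprintf("D%03d",
                          (drow_north - 1L) * config$lattice_cols + dcol),
    stringsAsFactors = FALSE)

  structure(list(elevation = elevation, land = mk(lc), road = mk(rc),
                 biotic = mk(bm),
                 facilities = rc_to_xy(fac_rc, "facility"),
                 stations = rc_to_xy(sta_rc, "station"),
                 ebais = rc_to_xy(ebais_rc, "ebais"),
                 census_units = census_units),
            class = "raster_world")
}

#' Simulate the complete synthetic world
#'
#' Runs every generator stage under seeds derived from `config$seed`
#' (distinct fixed offsets per stage), returning all intermediate truth so
#' tests can check parameter recovery.
#'
#' @param config a [world_config()].
#' @return list with `config`, `districts`, `covariates`, `u_true`, `counts`
#'   (yearly matrix, totals, generative offsets, linear predictor),
#'   `records`, and `raster_world`.
#' @export
simulate_world <- function(config = world_config()) {
  districts <- generate_district_lattice(config)
  covariates <- sample_covariates(districts, config)
  u <- sample_car_field(districts$adjacency, config$sigma_u,
                        seed = config$seed + 102L)
  counts <- sample_case_counts(districts, covariates, config$beta_true, u,
                               config)
  records <- sample_case_records(counts$total, districts$ids, config)
  rw <- generate_raster_world(config)
  list(config = config, districts = districts, covariates = covariates,
       u_true = u, counts = counts, records = records, raster_world = rw)
}

#' Assemble the modelling table for a span of years
#'
#' Sums yearly counts over `years`, joins the covariates, and computes the
#' even-distribution offsets.
#'
#' @param world output of [simulate_world()].
#' @param years calendar years to aggregate (default: the last five).
#' @return a district table data frame (district_id, Y, population,
#'   covariates, E, n_years) satisfying the offset conservation invariant.
#' @export
world_district_table <- function(world, years = NULL) {
  yr <- as.integer(colnames(world$counts$yearly))
  if (is.null(years)) years <- utils::tail(yr, 5)
  if (!all(years %in% yr)) stop("requested years outside the simulated span")
  tab <- world$covariates
  tab$Y <- as.integer(rowSums(world$counts$yearly[, as.character(years),
                                                  drop = FALSE]))
  tab$n_years <- length(years)
  tab$E <- compute_offsets(tab)
  tab
}
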