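#' Pipeline configuration
#'
#' Bundles every stage's settings: the synthetic-world configuration, model
#' priors and MCMC sizes, the incidence threshold (30 per 100,000 per year),
#' the calibrated exceedance cutoff (10%), the habitat rule, the speed
#' model, the travel-time category bounds (2 and 3 hours), the
#' training/test split and a global seed from which per-stage seeds are
#' derived.
#'
#' @param world a [world_config()].
#' @param priors a [model_priors()].
#' @param mcmc an [mcmc_config()] for the main fit.
#' @param eval_mcmc an [mcmc_config()] for the method-comparison fits
#'   (smaller by default: six extra model fits run in that stage).
#' @param threshold annual incidence threshold per 100,000 (> 0).
#' @param cutoff exceedance-probability cutoff in \[0,1\].
#' @param habitat a [habitat_rule()].
#' @param speed a [speed_model()].
#' @param time_bounds increasing travel-time category bounds in hours.
#' @param split a [split_spec()].
#' @param fit_years years for the main fit (default: the last test window).
#' @param buffer_m populated-area buffer radius in metres.
#' @param n_sim_auc simulations for the AUC confidence intervals.
#' @param seed global integer seed.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(world = world_config(),
                            priors = model_priors(),
                            mcmc = mcmc_config(),
                            eval_mcmc = mcmc_config(n_burn = 500,
                                                    n_keep = 500),
                            threshold = 30, cutoff = 0.10,
                            habitat = habitat_rule(),
                            speed = speed_model(),
                            time_bounds = c(2, 3),
                            split = split_spec(),
                            fit_years = NULL,
                            buffer_m = 2000,
                            n_sim_auc = 10000,
                            seed = 1L) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  if (length(time_bounds) != 2 || diff(time_bounds) <= 0)
    stop("time category bounds must be increasing")
  if (buffer_m <= 0) stop("buffer_m must be positive")
  seed <- as.integer(seed)
  # one global seed deterministically derives per-stage seeds
  world$seed <- seed
  mcmc$seed <- seed + 500L
  eval_mcmc$seed <- seed + 700L
  structure(list(world = world, priors = priors, mcmc = mcmc,
                 eval_mcmc = eval_mcmc, threshold = threshold,
                 cutoff = cutoff, habitat = habitat, speed = speed,
                 time_bounds = time_bounds, split = split,
                 fit_years = fit_years, buffer_m = buffer_m,
                 n_sim_auc = n_sim_auc, seed = seed),
            class = "pipeline_config")
}

#' Load and validate a pipeline configuration from JSON
#'
#' An empty or absent section falls back to the full defaults (the study's
#' parameter values). Unknown keys anywhere are rejected.
#'
#' @param path JSON file; top-level keys mirror the arguments of
#'   [pipeline_config()], with `world`, `priors`, `mcmc`, `eval_mcmc`,
#'   `habitat`, `speed` and `split` as nested objects.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) return(pipeline_config())
  build <- function(args, fn, what) {
    if (is.null(args)) return(fn())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", what,
                   paste(bad, collapse = ", ")))
    do.call(fn, lapply(args, function(a) if (is.list(a)) unlist(a) else a))
  }
  top_fns <- list(world = world_config, priors = model_priors,
                  mcmc = mcmc_config, eval_mcmc = mcmc_config,
                  habitat = habitat_rule, speed = speed_model,
                  split = split_spec)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list()
  for (nm in names(raw)) {
    args[[nm]] <- if (nm %in% names(top_fns)) {
      build(raw[[nm]], top_fns[[nm]], nm)
    } else raw[[nm]]
  }
  do.call(pipeline_config, args)
}

#' Descriptive statistics of cleaned case records
#'
#' @param records cleaned case records (age, sex, month, district_id).
#' @param total_population persons at risk.
#' @param n_years observation span in years.
#' @return list: n_cases, annual_rate_per_100k, frac_male, age band
#'   fractions (<15, 15-30, 30-45, >45).
#' @export
descriptive_stats <- function(records, total_population, n_years) {
  if (nrow(records) == 0) stop("no case records")
  bands <- cut(records$age, breaks = c(0, 15, 30, 45, Inf), right = FALSE,
               labels = c("<15", "15-30", "30-45", ">45"))
  list(n_cases = nrow(records),
       annual_rate_per_100k =
         1e5 * nrow(records) / (total_population * n_years),
       frac_male = mean(records$sex == "M"),
       age_bands = as.list(table(bands) / nrow(records)))
}

write_csv0 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
read_csv0 <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

stage_simulate <- function(cfg, dir) {
  world <- simulate_world(cfg$world)
  write_geojson_polygons(world$districts$rings,
                         data.frame(district_id = world$districts$ids,
                                    stringsAsFactors = FALSE),
                         file.path(dir, "districts.geojson"))
  write_csv0(world$covariates, file.path(dir, "covariates.csv"))
  yc <- data.frame(district_id = rownames(world$counts$yearly),
                   world$counts$yearly, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_csv0(yc, file.path(dir, "yearly_counts.csv"))
  write_csv0(world$records, file.path(dir, "case_records.csv"))
  rw <- world$raster_world
  write_ascii_grid(rw$elevation, file.path(dir, "elevation.asc"))
  write_ascii_grid(rw$land, file.path(dir, "land.asc"))
  write_ascii_grid(rw$road, file.path(dir, "road.asc"))
  write_ascii_grid(rw$biotic, file.path(dir, "biotic.asc"))
  write_geojson_points(rw$facilities, file.path(dir, "facilities.geojson"))
  write_geojson_points(rw$stations, file.path(dir, "stations.geojson"))
  write_geojson_points(rw$ebais, file.path(dir, "ebais.geojson"))
  write_geojson_points(rw$census_units,
                       file.path(dir, "census_units.geojson"))
  invisible(dir)
}

stage_clean <- function(cfg, dir) {
  records <- read_csv0(file.path(dir, "case_records.csv"))
  dd <- deduplicate_cases(records)
  write_csv0(dd$records, file.path(dir, "cleaned_records.csv"))
  write_csv0(dd$rejected, file.path(dir, "rejected_records.csv"))
  cov <- read_csv0(file.path(dir, "covariates.csv"))
  stats <- descriptive_stats(dd$records, sum(cov$population),
                             cfg$world$n_years)
  stats$n_removed_duplicates <- dd$n_removed
  jsonlite::write_json(stats, file.path(dir, "descriptive_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

pipeline_fit_years <- function(cfg) {
  if (!is.null(cfg$fit_years)) return(cfg$fit_years)
  w <- cfg$split$test[[length(cfg$split$test)]]
  seq(w[1], w[2])
}

stage_fit <- function(cfg, dir) {
  cov <- read_csv0(file.path(dir, "covariates.csv"))
  yc <- read_csv0(file.path(dir, "yearly_counts.csv"))
  yearly <- as.matrix(yc[, -1, drop = FALSE])
  rownames(yearly) <- yc$district_id
  polys <- read_geojson_polygons(file.path(dir, "districts.geojson"))
  adjacency <- build_adjacency(polys$rings)
  years <- pipeline_fit_years(cfg)
  tab <- cov
  tab$Y <- window_counts(yearly, range(years))
  tab$n_years <- length(years)
  tab$E <- compute_offsets(tab)
  fit <- fit_car_poisson(tab, adjacency, cfg$priors, cfg$mcmc)
  rates <- posterior_incidence(fit)
  exceed <- exceedance_probability(rates, cfg$threshold)
  risk <- data.frame(district_id = tab$district_id, Y = tab$Y,
                     population = tab$population,
                     raw_rate = raw_incidence(tab$Y, tab$population,
                                              tab$n_years),
                     smoothed_rate = colMeans(rates),
                     exceed_prob = as.numeric(exceed),
                     stringsAsFactors = FALSE)
  write_csv0(risk, file.path(dir, "district_risk.csv"))
  write_csv0(incidence_ratio_summary(fit), file.path(dir, "ir_summary.csv"))
  draws <- data.frame(beta0 = as.vector(fit$beta0),
                      matrix(fit$beta, nrow(fit$beta0) * ncol(fit$beta0),
                             dim(fit$beta)[2],
                             dimnames = list(NULL, fit$covariates)),
                      sigma2_u = as.vector(fit$sigma2_u),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_csv0(draws, file.path(dir, "posterior_draws.csv"))
  rh <- rhat(fit)
  write_csv0(data.frame(parameter = names(rh), rhat = as.numeric(rh),
                        stringsAsFactors = FALSE),
             file.path(dir, "rhat.csv"))
  invisible(dir)
}

stage_evaluate <- function(cfg, dir) {
  cov <- read_csv0(file.path(dir, "covariates.csv"))
  yc <- read_csv0(file.path(dir, "yearly_counts.csv"))
  yearly <- as.matrix(yc[, -1, drop = FALSE])
  rownames(yearly) <- yc$district_id
  polys <- read_geojson_polygons(file.path(dir, "districts.geojson"))
  adjacency <- build_adjacency(polys$rings)
  cmp <- compare_methods(yearly, cov, adjacency, cfg$split, cfg$priors,
                         cfg$eval_mcmc, threshold = cfg$threshold,
                         n_sim = cfg$n_sim_auc, seed = cfg$seed + 900L)
  write_csv0(cmp$table, file.path(dir, "method_comparison.csv"))
  pairs <- cmp$scores[["t5_A"]]
  cal <- calibrate_cutoff(lapply(pairs, `[[`, "scores"),
                          lapply(pairs, `[[`, "labels"),
                          target_sensitivity = 0.9)
  write_csv0(data.frame(pair = seq_along(cal$per_pair),
                        cutoff = cal$per_pair, stringsAsFactors = FALSE),
             file.path(dir, "calibration_pairs.csv"))
  jsonlite::write_json(list(mean_cutoff = cal$cutoff),
                       file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

stage_habitat <- function(cfg, dir) {
  elev <- read_ascii_grid(file.path(dir, "elevation.asc"))
  biotic <- read_ascii_grid(file.path(dir, "biotic.asc"))
  write_ascii_grid(habitat_raster(elev, biotic, cfg$habitat),
                   file.path(dir, "habitat.asc"))
  invisible(dir)
}

stage_traveltime <- function(cfg, dir) {
  elev <- read_ascii_grid(file.path(dir, "elevation.asc"))
  land <- read_ascii_grid(file.path(dir, "land.asc"))
  road <- read_ascii_grid(file.path(dir, "road.asc"))
  stations <- read_geojson_points(file.path(dir, "stations.geojson"))
  facilities <- read_geojson_points(file.path(dir, "facilities.geojson"))
  units <- read_geojson_points(file.path(dir, "census_units.geojson"))
  speed <- build_speed_raster(road, land, cfg$speed)
  slope <- slope_raster(elev)
  cost <- cost_surface(speed, slope, road, cfg$speed)
  write_ascii_grid(cost, file.path(dir, "cost_surface.asc"))
  acc_s <- accumulate_time(cost, stations, "stations")
  acc_f <- accumulate_time(cost, facilities, "facilities")
  write_ascii_grid(acc_s, file.path(dir, "time_from_stations.asc"))
  write_ascii_grid(acc_f, file.path(dir, "time_from_facilities.asc"))
  total <- total_time(acc_s, acc_f)
  write_ascii_grid(total, file.path(dir, "total_time_hours.asc"))
  mt <- extract_mean_time(total, units, radius = cfg$buffer_m)
  mt$category <- as.character(categorize_time(mt$mean_hours,
                                              cfg$time_bounds))
  write_csv0(mt, file.path(dir, "unit_times.csv"))
  invisible(dir)
}

stage_overlay <- function(cfg, dir) {
  units <- read_geojson_points(file.path(dir, "census_units.geojson"))
  habitat <- read_ascii_grid(file.path(dir, "habitat.asc"))
  risk <- read_csv0(file.path(dir, "district_risk.csv"))
  probs <- stats::setNames(risk$exceed_prob, risk$district_id)
  flagged <- high_risk_districts(probs, cfg$cutoff)
  cls <- combine_risk(units, habitat, flagged, buffer_m = cfg$buffer_m)
  write_csv0(cls$units, file.path(dir, "unit_risk.csv"))
  write_ascii_grid(cls$mask, file.path(dir, "risk_mask.asc"))
  jsonlite::write_json(population_risk_summary(cls),
                       file.path(dir, "population_risk.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

stage_report <- function(cfg, dir) {
  unit_risk <- read_csv0(file.path(dir, "unit_risk.csv"))
  unit_times <- read_csv0(file.path(dir, "unit_times.csv"))
  m <- merge(unit_risk, unit_times, by = "unit_id", sort = FALSE)
  hr <- m[m$high_risk, , drop = FALSE]
  if (nrow(hr)) {
    summ <- population_time_summary(
      data.frame(unit_id = hr$unit_id, mean_hours = hr$mean_hours,
                 unreachable = hr$unreachable, stringsAsFactors = FALSE),
      hr)
  } else {
    summ <- list(unreachable = 0)
  }
  jsonlite::write_json(list(high_risk_population_fractions = summ,
                            n_high_risk_units = nrow(hr)),
                       file.path(dir, "accessibility_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  # close-up report per flagged region: the units of each high-risk district
  closeup <- do.call(rbind, lapply(split(hr, hr$district_id), function(d) {
    data.frame(district_id = d$district_id[1], n_units = nrow(d),
               population = sum(d$population),
               mean_hours = mean(d$mean_hours, na.rm = TRUE),
               frac_over_2h = sum(d$population[!is.na(d$mean_hours) &
                                                 d$mean_hours >=
                                                 cfg$time_bounds[1]]) /
                 sum(d$population),
               stringsAsFactors = FALSE)
  }))
  if (is.null(closeup))
    closeup <- data.frame(district_id = character(), n_units = integer(),
                          population = integer(), mean_hours = numeric(),
                          frac_over_2h = numeric())
  write_csv0(closeup, file.path(dir, "closeup_report.csv"))
  invisible(dir)
}

pipeline_stages <- function() {
  list(simulate = stage_simulate, clean = stage_clean, fit = stage_fit,
       evaluate = stage_evaluate, habitat = stage_habitat,
       traveltime = stage_traveltime, overlay = stage_overlay,
       report = stage_report)
}

#' Run the full analysis pipeline
#'
#' Simulate, clean, fit, evaluate, habitat, travel time, overlay, report —
#' in order, each stage reading only files written by earlier stages, so any
#' stage can be re-run individually with [run_stage()]. A manifest with the
#' configuration snapshot, seed, package version and per-file MD5 checksums
#' is written last. A stage failure aborts with the stage named; outputs of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage timing messages.
#' @return invisibly the manifest list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(pipeline_stages())) {
    t0 <- Sys.time()
    tryCatch(run_stage(nm, config, out_dir),
             error = function(e)
               stop(sprintf("stage '%s' failed: %s", nm,
                            conditionMessage(e)), call. = FALSE))
    if (!quiet)
      message(sprintf("stage %-10s %6.1f s", nm,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  manifest <- write_manifest(config, out_dir)
  invisible(manifest)
}

#' Run a single pipeline stage
#'
#' @param name one of simulate, clean, fit, evaluate, habitat, traveltime,
#'   overlay, report.
#' @param config a [pipeline_config()].
#' @param out_dir run directory holding prior stages' outputs.
#' @return invisibly the run directory.
#' @export
run_stage <- function(name, config, out_dir) {
  stages <- pipeline_stages()
  if (!name %in% names(stages))
    stop("unknown stage: ", name, " (expected one of ",
         paste(names(stages), collapse = ", "), ")")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages[[name]](config, out_dir)
}

write_manifest <- function(config, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("snakerisk")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass_deep(config),
    files = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Command-line entry point
#'
#' `snakerisk_cli(c("run-all", "--out", "run/", "--seed", "42"))` runs the
#' whole pipeline; each stage name is also a subcommand operating on an
#' existing run directory. `--config cfg.json` supplies a JSON configuration
#' ([load_config()]); `--paper-scale` raises the main fit to 50,000 + 50,000
#' iterations.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly `NULL`.
#' @export
snakerisk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: snakerisk <run-all|simulate|clean|fit|evaluate|habitat|",
    "                  traveltime|overlay|report>",
    "                 [--config cfg.json] [--out dir] [--seed N]",
    "                 [--paper-scale]", sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list(config = NULL, out = "snakerisk_run", seed = NULL,
              paper_scale = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--config") { opt$config <- args[i + 1]; i <- i + 2L }
    else if (a == "--out") { opt$out <- args[i + 1]; i <- i + 2L }
    else if (a == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2L }
    else if (a == "--paper-scale") { opt$paper_scale <- TRUE; i <- i + 1L }
    else stop("unknown argument: ", a)
  }
  cfg <- if (is.null(opt$config)) pipeline_config() else load_config(opt$config)
  if (!is.null(opt$seed))
    cfg <- pipeline_config(world = cfg$world, priors = cfg$priors,
                           mcmc = cfg$mcmc, eval_mcmc = cfg$eval_mcmc,
                           threshold = cfg$threshold, cutoff = cfg$cutoff,
                           habitat = cfg$habitat, speed = cfg$speed,
                           time_bounds = cfg$time_bounds, split = cfg$split,
                           fit_years = cfg$fit_years,
                           buffer_m = cfg$buffer_m,
                           n_sim_auc = cfg$n_sim_auc, seed = opt$seed)
  if (opt$paper_scale) {
    cfg$mcmc$n_burn <- 50000L
    cfg$mcmc$n_keep <- 50000L
  }
  if (cmd == "run-all") run_pipeline(cfg, opt$out)
  else run_stage(cmd, cfg, opt$out)
  invisible(NULL)
}
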