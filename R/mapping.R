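#' Covariate columns used by the incidence model
#'
#' Urban and forest fractions stay on their natural \[0,1\] scale (reported
#' per +100 percentage points); elevation, precipitation and dry months are
#' standardised before fitting.
#' @return character vector of column names.
#' @export
model_covariates <- function() {
  c("urban_frac", "forest_frac", "elevation_m", "precipitation_mm_yr",
    "dry_months")
}

continuous_covariates <- function() {
  c("elevation_m", "precipitation_mm_yr", "dry_months")
}

#' Expected counts under even distribution (the offset)
#'
#' `E_i = total_cases * population_i / total_population`: the cases district
#' i would see if all cases were spread evenly over the population. By
#' construction `sum(E) == sum(Y)`.
#'
#' @param table district table with columns `Y` and `population`.
#' @return numeric vector of offsets.
#' @export
compute_offsets <- function(table) {
  stopifnot(all(c("Y", "population") %in% names(table)))
  if (any(table$population <= 0)) stop("all populations must be positive")
  tot_pop <- sum(table$population)
  if (tot_pop <= 0) stop("zero total population")
  tot_y <- sum(table$Y)
  if (tot_y <= 0) stop("no cases: offsets undefined")
  tot_y * table$population / tot_pop
}

#' Standardise continuous covariates
#'
#' Centres and scales the continuous covariates (elevation, precipitation,
#' dry months) to mean 0, SD 1 using the population-SD convention (divide by
#' n). Fraction-valued covariates (urban, forest) are left on \[0,1\] and
#' recorded with unit scaling. The scaling record allows coefficients to be
#' reported per natural unit (one original-scale SD, or +100 percentage
#' points for fractions).
#'
#' @param table district table containing the [model_covariates()] columns.
#' @param cols columns to standardise (default the continuous three).
#' @return list: `table` (standardised copy) and `scaling` (data frame with
#'   covariate, center, scale, standardized flag).
#' @export
standardize_covariates <- function(table, cols = continuous_covariates()) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  all_cols <- intersect(model_covariates(), names(table))
  scaling <- data.frame(covariate = all_cols, center = 0, scale = 1,
                        sd = vapply(all_cols,
                                    function(cc) pop_sd(table[[cc]]),
                                    numeric(1)),
                        standardized = FALSE, stringsAsFactors = FALSE)
  for (cc in cols) {
    if (!cc %in% names(table)) next
    s <- pop_sd(table[[cc]])
    if (s == 0) stop("constant covariate cannot be standardised: ", cc)
    m <- mean(table[[cc]])
    table[[cc]] <- (table[[cc]] - m) / s
    k <- match(cc, scaling$covariate)
    scaling$center[k] <- m
    scaling$scale[k] <- s
    scaling$standardized[k] <- TRUE
  }
  list(table = table, scaling = scaling)
}

#' Priors of the incidence model
#'
#' Fixed effects get vague normal priors (mean 0, precision 1e-4); the
#' intercept an improper flat prior; the CAR precision `tau = 1/sigma_u^2` a
#' gamma prior with the disease-mapping convention shape 0.5, rate 5e-4.
#'
#' @param coef_precision normal prior precision for fixed effects.
#' @param tau_shape,tau_rate gamma hyperparameters for the CAR precision.
#' @return a `model_priors` list.
#' @export
model_priors <- function(coef_precision = 1e-4, tau_shape = 0.5,
                         tau_rate = 5e-4) {
  if (coef_precision <= 0 || tau_shape <= 0 || tau_rate <= 0)
    stop("prior precision and gamma hyperparameters must be positive")
  structure(list(coef_precision = coef_precision, tau_shape = tau_shape,
                 tau_rate = tau_rate), class = "model_priors")
}

#' MCMC settings
#'
#' Desk-scale defaults (2,000 burn-in + 2,000 kept); the full-scale run of
#' 50,000 + 50,000 iterations is available via `paper_scale = TRUE`.
#'
#' @param n_burn burn-in iterations.
#' @param n_keep retained draws (after thinning).
#' @param thin thinning interval.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain k runs under `seed + 1000 * k`.
#' @param paper_scale if `TRUE`, override to 50,000 + 50,000.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_burn = 2000, n_keep = 2000, thin = 1, n_chains = 1,
                        seed = 1L, paper_scale = FALSE) {
  if (paper_scale) { n_burn <- 50000; n_keep <- 50000 }
  if (n_burn <= 0 || n_keep <= 0) stop("n_burn and n_keep must be positive")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)), class = "mcmc_config")
}

flatten_adjacency <- function(adj) {
  list(flat = as.integer(unlist(adj$nbr) - 1L),
       start = as.integer(c(0L, cumsum(adj$n_nbr))))
}

#' Fit the CAR Poisson incidence model by MCMC
#'
#' `Y_i ~ Poisson(E_i exp(beta0 + X_i beta + u_i))` with an intrinsic Besag
#' CAR prior on `u` (sum-to-zero constraint re-imposed each sweep), vague
#' normal priors on `beta`, a flat prior on the intercept and a gamma prior
#' on the CAR precision. Sampling is Metropolis-within-Gibbs with adaptive
#' random-walk scales (target acceptance 0.44) and a conjugate gamma update
#' for the precision.
#'
#' The offset `E` is computed with [compute_offsets()] when missing, and the
#' continuous covariates are standardised internally; the scaling record
#' travels with the samples so summaries can be reported per natural unit.
#'
#' @param table district table (district_id, Y, population, covariates,
#'   n_years, optionally E).
#' @param adjacency an `adjacency_graph` over the same districts (connected).
#' @param priors a [model_priors()].
#' @param mcmc an [mcmc_config()].
#' @param covariates covariate columns to include.
#' @return a `car_posterior`: arrays of draws for `beta0` (draws x chains),
#'   `beta` (draws x p x chains), `u` (draws x n x chains), `sigma2_u`
#'   (draws x chains), the `scaling` record, acceptance rates and the data
#'   used.
#' @export
fit_car_poisson <- function(table, adjacency, priors = model_priors(),
                            mcmc = mcmc_config(),
                            covariates = model_covariates()) {
  stopifnot(inherits(adjacency, "adjacency_graph"))
  if (nrow(table) != adjacency$n)
    stop("table and adjacency disagree on the number of districts")
  check_connected(adjacency)
  if (any(table$Y < 0) || any(table$Y != round(table$Y)))
    stop("Y must be nonnegative integers")
  if (is.null(table$E)) table$E <- compute_offsets(table)
  if (any(table$E <= 0)) stop("offsets must be positive")

  covariates <- intersect(covariates, names(table))
  std <- standardize_covariates(table)
  X <- as.matrix(std$table[covariates])
  adj <- flatten_adjacency(adjacency)

  n_keep <- mcmc$n_keep
  p <- ncol(X)
  beta0 <- matrix(NA_real_, n_keep, mcmc$n_chains)
  beta <- array(NA_real_, c(n_keep, p, mcmc$n_chains),
                dimnames = list(NULL, covariates, NULL))
  u <- array(NA_real_, c(n_keep, adjacency$n, mcmc$n_chains))
  sigma2_u <- matrix(NA_real_, n_keep, mcmc$n_chains)
  accept <- vector("list", mcmc$n_chains)
  for (k in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 1000L * k)
    fit <- car_mcmc_cpp(as.integer(table$Y), table$E, X,
                        adj$flat, adj$start,
                        priors$coef_precision, priors$tau_shape,
                        priors$tau_rate,
                        mcmc$n_burn, n_keep, mcmc$thin)
    beta0[, k] <- fit$beta0
    beta[, , k] <- fit$beta
    u[, , k] <- fit$u
    sigma2_u[, k] <- fit$sigma2_u
    accept[[k]] <- fit$accept
  }
  structure(list(beta0 = beta0, beta = beta, u = u, sigma2_u = sigma2_u,
                 scaling = std$scaling, accept = accept,
                 covariates = covariates,
                 data = list(district_id = table$district_id, Y = table$Y,
                             E = table$E, population = table$population,
                             n_years = table$n_years[1], X = X),
                 mcmc = mcmc, priors = priors),
            class = "car_posterior")
}

#' @export
print.car_posterior <- function(x, ...) {
  cat(sprintf(
    "car_posterior: %d draws x %d chain(s), %d districts, %d covariates\n",
    nrow(x$beta0), ncol(x$beta0), dim(x$u)[2], length(x$covariates)))
  cat("posterior means:\n")
  print(round(c(beta0 = mean(x$beta0), apply(x$beta, 2, mean),
                sigma2_u = mean(x$sigma2_u)), 4))
  invisible(x)
}

# all draws pooled over chains, as a draws x parameter matrix
pool_draws <- function(samples) {
  p <- dim(samples$beta)[2]; n <- dim(samples$u)[2]
  nk <- nrow(samples$beta0); m <- ncol(samples$beta0)
  cbind(beta0 = as.vector(samples$beta0),
        matrix(aperm(samples$beta, c(1, 3, 2)), nk * m, p,
               dimnames = list(NULL, samples$covariates)),
        matrix(aperm(samples$u, c(1, 3, 2)), nk * m, n,
               dimnames = list(NULL, paste0("u", seq_len(n)))),
        sigma2_u = as.vector(samples$sigma2_u))
}

#' Log posterior density of the CAR Poisson model
#'
#' Evaluates the unnormalised-model log posterior at a fixed parameter
#' point: Poisson log-likelihood (including the `-log(y!)` terms), normal
#' log-priors on the fixed effects, the intrinsic CAR term
#' `0.5 (n-1) log(tau/2pi) - 0.5 tau sum_(i~j) (u_i - u_j)^2` (pairwise over
#' edges; the density on the sum-to-zero subspace up to a constant), and the
#' gamma log-prior on `tau`. The flat intercept prior contributes nothing.
#'
#' @param beta0,beta,u,sigma2_u parameter point (`u` on the constrained
#'   scale; `sigma2_u = 1/tau`).
#' @param table district table with `Y` and `E` and the covariate columns
#'   already on the fitting scale.
#' @param adjacency an `adjacency_graph`.
#' @param priors a [model_priors()].
#' @param covariates covariate columns matching `beta`.
#' @return scalar log posterior density.
#' @export
car_log_posterior <- function(beta0, beta, u, sigma2_u, table, adjacency,
                              priors = model_priors(),
                              covariates = model_covariates()) {
  covariates <- intersect(covariates, names(table))
  X <- as.matrix(table[covariates])
  eta <- beta0 + as.vector(X %*% beta) + u
  mu <- table$E * exp(eta)
  ll <- sum(table$Y * log(mu) - mu - lgamma(table$Y + 1))
  lp_beta <- sum(-0.5 * log(2 * pi) + 0.5 * log(priors$coef_precision) -
                   0.5 * priors$coef_precision * beta^2)
  tau <- 1 / sigma2_u
  ss <- 0
  for (i in seq_len(adjacency$n))
    for (j in adjacency$nbr[[i]])
      if (j > i) ss <- ss + (u[i] - u[j])^2
  lp_u <- 0.5 * (adjacency$n - 1) * log(tau / (2 * pi)) - 0.5 * tau * ss
  lp_tau <- priors$tau_shape * log(priors$tau_rate) -
    lgamma(priors$tau_shape) + (priors$tau_shape - 1) * log(tau) -
    priors$tau_rate * tau
  ll + lp_beta + lp_u + lp_tau
}

#' Potential scale reduction (R-hat) per scalar parameter
#'
#' With two or more chains, compares the pooled-draw variance with the mean
#' within-chain variance: `Rhat = sqrt(V_pooled / W)` (population-variance
#' convention, so identical chains give exactly 1). A single chain is split
#' into two halves first (split-chain mode); a single chain of fewer than 4
#' draws is an error.
#'
#' @param samples a `car_posterior`.
#' @return named numeric vector of R-hat values (beta0, each covariate,
#'   sigma2_u, and each spatial effect).
#' @export
rhat <- function(samples) {
  split1 <- function(m) {  # draws x chains -> draws/2 x (2*chains)
    nk <- nrow(m)
    if (ncol(m) >= 2) return(m)
    if (nk < 4) stop("single short chain: cannot assess convergence")
    h <- nk %/% 2
    cbind(m[seq_len(h), 1], m[(nk - h + 1):nk, 1])
  }
  one <- function(m) {
    m <- split1(m)
    popvar <- function(x) mean((x - mean(x))^2)
    W <- mean(apply(m, 2, popvar))
    V <- popvar(as.vector(m))
    if (W == 0) return(if (V == 0) 1 else Inf)
    sqrt(V / W)
  }
  p <- dim(samples$beta)[2]; n <- dim(samples$u)[2]
  nk <- nrow(samples$beta0); m <- ncol(samples$beta0)
  as_mat <- function(a) matrix(a, nk, m)
  out <- c(beta0 = one(samples$beta0),
           vapply(seq_len(p), function(j) one(as_mat(samples$beta[, j, ])),
                  numeric(1)),
           sigma2_u = one(samples$sigma2_u),
           vapply(seq_len(n), function(i) one(as_mat(samples$u[, i, ])),
                  numeric(1)))
  names(out) <- c("beta0", samples$covariates, "sigma2_u",
                  paste0("u", seq_len(n)))
  out
}

#' Fixed-effect draws on the fully standardised scale
#'
#' Converts the fitted coefficients (fractions per +1.0 on \[0,1\],
#' continuous per +1 SD) to a uniform per-+1-SD scale by multiplying each
#' unstandardised coefficient by its covariate's population SD. This is the
#' scale on which the synthetic world defines its generative `beta_true`,
#' so parameter-recovery comparisons happen here.
#'
#' @param samples a `car_posterior`.
#' @return matrix of pooled draws (rows) by covariates (columns).
#' @export
standardized_coefficients <- function(samples) {
  p <- dim(samples$beta)[2]
  nk <- nrow(samples$beta0); m <- ncol(samples$beta0)
  out <- matrix(NA_real_, nk * m, p,
                dimnames = list(NULL, samples$covariates))
  for (j in seq_len(p)) {
    k <- match(samples$covariates[j], samples$scaling$covariate)
    fac <- if (samples$scaling$standardized[k]) 1 else samples$scaling$sd[k]
    out[, j] <- as.vector(samples$beta[, j, ]) * fac
  }
  out
}

#' Posterior draws of the smoothed annual incidence rate
#'
#' Rate draw for district i: `1e5 * E_i exp(eta_i) / (population_i *
#' n_years)` — annual cases per 100,000 inhabitants.
#'
#' @param samples a `car_posterior`.
#' @return matrix of draws (rows) by districts (columns).
#' @export
posterior_incidence <- function(samples) {
  d <- samples$data
  nk <- nrow(samples$beta0); m <- ncol(samples$beta0)
  n <- dim(samples$u)[2]
  p <- dim(samples$beta)[2]
  rates <- matrix(NA_real_, nk * m, n)
  row0 <- 0L
  for (k in seq_len(m)) {
    eta <- matrix(samples$beta0[, k], nk, n) +
      matrix(samples$beta[, , k], nk, p) %*% t(d$X) +
      matrix(samples$u[, , k], nk, n)
    rates[row0 + seq_len(nk), ] <-
      1e5 * sweep(exp(eta), 2, d$E, `*`) /
      matrix(d$population * d$n_years, nk, n, byrow = TRUE)
    row0 <- row0 + nk
  }
  colnames(rates) <- d$district_id
  rates
}

#' Posterior probability that the incidence exceeds a threshold
#'
#' Fraction of draws strictly above the threshold (the default 30 per
#' 100,000 per year is twice the national average incidence).
#'
#' @param rate_draws draws x districts matrix from [posterior_incidence()].
#' @param threshold annual incidence per 100,000.
#' @return numeric vector of per-district probabilities in \[0,1\].
#' @export
exceedance_probability <- function(rate_draws, threshold = 30) {
  if (nrow(rate_draws) < 1) stop("need at least one retained draw")
  colMeans(rate_draws > threshold)
}

#' Incidence-ratio table per natural covariate unit
#'
#' `IR = exp(beta_j)` summarised by the posterior median with a 95% credible
#' interval (2.5/97.5 percentiles). Standardised covariates are reported per
#' +1 SD in original units; fraction-valued covariates per +100 percentage
#' points.
#'
#' @param samples a `car_posterior`.
#' @return data frame: covariate, unit, IR, cri_low, cri_high.
#' @export
incidence_ratio_summary <- function(samples) {
  p <- dim(samples$beta)[2]
  sc <- samples$scaling
  rows <- lapply(seq_len(p), function(j) {
    draws <- exp(as.vector(samples$beta[, j, ]))
    cv <- samples$covariates[j]
    k <- match(cv, sc$covariate)
    unit <- if (sc$standardized[k]) {
      sprintf("per +%.4g (1 SD)", sc$scale[k])
    } else "per +100%-units"
    q <- stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(covariate = cv, unit = unit, IR = q[1], cri_low = q[2],
               cri_high = q[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
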