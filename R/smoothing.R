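#' Training/test period specification
#'
#' The study design: three one-year training windows (1994, 1998, 2002) and
#' three five-year training windows (1990-1994, 1994-1998, 1998-2002), each
#' paired with a five-year test window (1995-1999, 1999-2003, 2003-2007).
#' Overlap between consecutive five-year windows is intentional.
#'
#' @param train1 list of inclusive year ranges (length-2 vectors) for the
#'   one-year trainings.
#' @param train5 list of ranges for the five-year trainings.
#' @param test list of ranges for the paired test windows.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train1 = list(c(1994, 1994), c(1998, 1998),
                                     c(2002, 2002)),
                       train5 = list(c(1990, 1994), c(1994, 1998),
                                     c(1998, 2002)),
                       test = list(c(1995, 1999), c(1999, 2003),
                                   c(2003, 2007))) {
  stopifnot(length(train1) == length(test), length(train5) == length(test))
  ok <- function(w) length(w) == 2 && w[2] >= w[1]
  if (!all(vapply(c(train1, train5, test), ok, logical(1))))
    stop("every window must be an inclusive increasing year range")
  structure(list(train1 = train1, train5 = train5, test = test),
            class = "split_spec")
}

#' Aggregate yearly counts over a year window
#'
#' @param yearly district x year count matrix with calendar-year column
#'   names.
#' @param window inclusive year range `c(from, to)`.
#' @return integer vector of per-district counts summed over the window.
#' @export
window_counts <- function(yearly, window) {
  yrs <- as.integer(colnames(yearly))
  want <- seq(window[1], window[2])
  if (!all(want %in% yrs))
    stop(sprintf("window %d-%d outside the data range %d-%d",
                 window[1], window[2], min(yrs), max(yrs)))
  as.integer(rowSums(yearly[, as.character(want), drop = FALSE]))
}

#' Split yearly counts into training and test periods
#'
#' @param yearly district x year count matrix.
#' @param spec a [split_spec()].
#' @return a `period_split`: lists of per-district training counts (`train1`,
#'   `train5`) and test counts (`test`), plus per-window lengths in years.
#' @export
split_periods <- function(yearly, spec = split_spec()) {
  agg <- function(ws) lapply(ws, function(w) window_counts(yearly, w))
  yrs <- function(ws) vapply(ws, function(w) w[2] - w[1] + 1, numeric(1))
  structure(list(train1 = agg(spec$train1), train5 = agg(spec$train5),
                 test = agg(spec$test),
                 n_years = list(train1 = yrs(spec$train1),
                                train5 = yrs(spec$train5),
                                test = yrs(spec$test)),
                 spec = spec),
            class = "period_split")
}

#' Raw annual incidence per 100,000
#'
#' @param counts case counts over the period.
#' @param population persons at risk.
#' @param n_years period length in years.
#' @return `1e5 * counts / (population * n_years)`.
#' @export
raw_incidence <- function(counts, population, n_years) {
  if (any(population <= 0)) stop("population must be positive")
  1e5 * counts / (population * n_years)
}

#' Local empirical-Bayes rate smoothing (Marshall)
#'
#' Shrinks each district's raw rate towards its neighbourhood mean (self plus
#' queen neighbours), with a data-determined weight that grows with the
#' district's population. With neighbourhood `N+(i)` (including i), rates
#' `r_j = y_j / n_j` in cases per person-year:
#' `m_i = sum(y_j) / sum(n_j)`, `s2_i = sum(n_j (r_j - m_i)^2) / sum(n_j)`,
#' `A_i = max(0, s2_i - m_i |N+(i)| / sum(n_j))`,
#' `C_i = A_i / (A_i + m_i / n_i)`, smoothed rate `m_i + C_i (r_i - m_i)`.
#'
#' @param counts per-district case counts over the period.
#' @param population persons at risk.
#' @param adjacency an `adjacency_graph`.
#' @param n_years period length in years (rates are returned as annual
#'   incidence per 100,000).
#' @return numeric vector of smoothed annual rates per 100,000.
#' @export
local_eb_smooth <- function(counts, population, adjacency, n_years = 1) {
  stopifnot(length(counts) == adjacency$n,
            length(population) == adjacency$n)
  if (any(population <= 0)) stop("population must be positive")
  py <- population * n_years   # person-years
  r <- counts / py
  out <- numeric(adjacency$n)
  for (i in seq_len(adjacency$n)) {
    hood <- c(i, adjacency$nbr[[i]])
    sy <- sum(counts[hood]); sn <- sum(py[hood])
    m <- sy / sn
    s2 <- sum(py[hood] * (r[hood] - m)^2) / sn
    A <- max(0, s2 - m * length(hood) / sn)
    C <- if (A == 0 && m == 0) 0 else A / (A + m / py[i])
    out[i] <- m + C * (r[i] - m)
  }
  1e5 * out
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' AUC as the Mann-Whitney probability that a random positive outscores a
#' random negative, ties counting one half. The standard error follows
#' Hanley & McNeil (1982).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return an `auc_result`: list(auc, se, n_pos, n_neg).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute an ROC curve")
  # Mann-Whitney via midranks: AUC = (R_pos - n_pos(n_pos+1)/2) / (n_pos n_neg)
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  structure(list(auc = auc, se = se, n_pos = n_pos, n_neg = n_neg),
            class = "auc_result")
}

#' Mean AUC over period pairs with an empirical confidence interval
#'
#' Draws plausible AUC values for each training/test pair from
#' `Normal(auc, se)` truncated to \[0,1\], averages across pairs within each
#' simulation, and reports the mean with 2.5/97.5 percentiles.
#'
#' @param auc_results list of [roc_auc()] results (one per period pair).
#' @param n_sim number of simulations.
#' @param seed integer seed.
#' @return list(mean_auc, ci_low, ci_high).
#' @export
mean_auc_ci <- function(auc_results, n_sim = 10000, seed = 1L) {
  stopifnot(length(auc_results) >= 1)
  set.seed(as.integer(seed))
  draws <- vapply(auc_results, function(a) {
    if (a$se == 0) return(rep(a$auc, n_sim))
    # inverse-CDF truncated normal on [0, 1]
    plo <- stats::pnorm(0, a$auc, a$se)
    phi <- stats::pnorm(1, a$auc, a$se)
    stats::qnorm(plo + stats::runif(n_sim) * (phi - plo), a$auc, a$se)
  }, numeric(n_sim))
  means <- rowMeans(draws)
  list(mean_auc = mean(means),
       ci_low = unname(stats::quantile(means, 0.025)),
       ci_high = unname(stats::quantile(means, 0.975)))
}

#' Compare smoothing methods by future-period discrimination
#'
#' For each training length (1 and 5 years) and method (raw incidence;
#' method A = posterior probability that the smoothed incidence exceeds the
#' threshold, from the CAR Poisson model; method B = local empirical-Bayes
#' smoothed rate), scores every district on the training window and asks how
#' well the score ranks districts whose *test-window* annual incidence
#' exceeds 30 per 100,000 (strict). Reports the mean AUC over the three
#' period pairs with its empirical CI.
#'
#' @param yearly district x year count matrix.
#' @param table district covariate table (district_id, population,
#'   covariates).
#' @param adjacency an `adjacency_graph`.
#' @param spec a [split_spec()].
#' @param priors,mcmc model settings for method A fits.
#' @param threshold annual incidence threshold per 100,000.
#' @param n_sim,seed settings for [mean_auc_ci()].
#' @return list: `table` (data frame with training_years, method, mean_auc,
#'   ci_low, ci_high — six rows), `auc` (per-pair `auc_result`s), `scores`
#'   (per combination, the per-pair score vectors and labels).
#' @export
compare_methods <- function(yearly, table, adjacency, spec = split_spec(),
                            priors = model_priors(), mcmc = mcmc_config(),
                            threshold = 30, n_sim = 10000, seed = 1L) {
  splits <- split_periods(yearly, spec)
  n_pairs <- length(splits$test)
  labels <- lapply(seq_len(n_pairs), function(k) {
    raw_incidence(splits$test[[k]], table$population,
                  splits$n_years$test[k]) > threshold
  })
  score_one <- function(counts, n_years, method, k) {
    tab <- table
    tab$Y <- counts
    tab$n_years <- n_years
    switch(method,
      none = raw_incidence(counts, table$population, n_years),
      A = {
        tab$E <- compute_offsets(tab)
        m <- mcmc
        m$seed <- mcmc$seed + 97L * k
        fit <- fit_car_poisson(tab, adjacency, priors, m)
        exceedance_probability(posterior_incidence(fit), threshold)
      },
      B = local_eb_smooth(counts, table$population, adjacency, n_years))
  }
  rows <- list(); aucs <- list(); scores <- list()
  for (tl in c(1, 5)) {
    trains <- if (tl == 1) splits$train1 else splits$train5
    n_yrs <- if (tl == 1) splits$n_years$train1 else splits$n_years$train5
    for (method in c("none", "A", "B")) {
      per_pair <- lapply(seq_len(n_pairs), function(k) {
        s <- score_one(trains[[k]], n_yrs[k], method, k + 10L * tl)
        list(scores = s, labels = labels[[k]],
             auc = roc_auc(s, labels[[k]]))
      })
      ar <- lapply(per_pair, `[[`, "auc")
      ci <- mean_auc_ci(ar, n_sim = n_sim, seed = seed + tl)
      key <- sprintf("t%d_%s", tl, method)
      aucs[[key]] <- ar
      scores[[key]] <- per_pair
      rows[[key]] <- data.frame(training_years = tl, method = method,
                                mean_auc = ci$mean_auc, ci_low = ci$ci_low,
                                ci_high = ci$ci_high,
                                stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       auc = aucs, scores = scores)
}

#' Calibrate the exceedance-probability cutoff to a target sensitivity
#'
#' Per training/test pair, finds the largest cutoff `p*` such that flagging
#' districts with score `>= p*` captures at least the target fraction of the
#' pair's true positives; returns the mean over pairs. With target 0 the
#' cutoff is the maximum observed score.
#'
#' @param score_sets list of per-pair numeric score vectors (exceedance
#'   probabilities on the training window).
#' @param label_sets list of matching logical label vectors (future
#'   high-incidence districts).
#' @param target_sensitivity required sensitivity (default 0.9).
#' @return list(cutoff = mean over pairs, per_pair = individual cutoffs).
#' @export
calibrate_cutoff <- function(score_sets, label_sets,
                             target_sensitivity = 0.9) {
  stopifnot(length(score_sets) == length(label_sets))
  per_pair <- mapply(function(s, l) {
    l <- as.logical(l)
    if (!any(l) || all(l))
      stop("both classes must be present to calibrate a cutoff")
    if (target_sensitivity == 0) return(max(s))
    pos <- sort(s[l], decreasing = TRUE)
    k <- ceiling(target_sensitivity * length(pos))
    if (k > length(pos))
      stop("target sensitivity unreachable")
    pos[k]
  }, score_sets, label_sets)
  list(cutoff = mean(per_pair), per_pair = as.numeric(per_pair))
}
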