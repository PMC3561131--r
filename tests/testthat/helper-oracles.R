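# Independent oracles used across tests. These deliberately avoid the
# package's own implementations.

# Brute-force single-source shortest path on the 8-connected move graph with
# move cost (t_a + t_b)/2 * k (k = sqrt(2) on diagonals): Bellman-Ford style
# relaxation until no distance changes.
bellman_ford_time <- function(cost, sources_rc) {
  nr <- nrow(cost); nc <- ncol(cost)
  dist <- matrix(Inf, nr, nc)
  for (s in seq_len(nrow(sources_rc))) {
    r <- sources_rc[s, 1]; c <- sources_rc[s, 2]
    if (!is.na(cost[r, c])) dist[r, c] <- 0
  }
  moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  kk <- ifelse(abs(moves[, 1]) + abs(moves[, 2]) == 2, sqrt(2), 1)
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.infinite(dist[r, c]) || is.na(cost[r, c])) next
      for (m in seq_len(8)) {
        r2 <- r + moves[m, 1]; c2 <- c + moves[m, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(cost[r2, c2])) next
        nd <- dist[r, c] + 0.5 * (cost[r, c] + cost[r2, c2]) * kk[m]
        if (nd < dist[r2, c2] - 1e-12) { dist[r2, c2] <- nd; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  dist[is.infinite(dist)] <- NA_real_
  dist
}

# Exhaustive Mann-Whitney AUC: count positive-negative pairs, ties half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Small fast world configuration for tests that do not need the full scale.
tiny_world_config <- function(seed = 1L, ...) {
  args <- list(lattice_rows = 5, lattice_cols = 6,
               raster_rows = 60, raster_cols = 60,
               n_census_units = 60, n_facilities = 2, n_stations = 2,
               n_ebais = 3, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(world_config, args)
}

fast_mcmc <- function(seed = 1L, n_burn = 500, n_keep = 500) {
  mcmc_config(n_burn = n_burn, n_keep = n_keep, seed = seed)
}
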