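#' Queen-contiguity adjacency for a rectangular lattice
#'
#' Districts are numbered row-major over an `nr x nc` lattice. Two districts
#' are neighbours if their cells share an edge or a corner (queen
#' contiguity).
#'
#' @param nr,nc lattice dimensions, both at least 2 (a 1 x 1 lattice has no
#'   neighbour structure and is rejected).
#' @return an `adjacency_graph`: list with `nbr` (list of sorted integer
#'   neighbour vectors), `n_nbr` (integer counts) and `n`.
#' @export
lattice_adjacency <- function(nr, nc) {
  nr <- as.integer(nr); nc <- as.integer(nc)
  if (nr * nc < 2L)
    stop("degenerate 1x1 lattice: the CAR structure needs at least 2 districts")
  idx <- function(r, c) (r - 1L) * nc + c
  nbr <- vector("list", nr * nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, c - 1L):min(nc, c + 1L)
    cand <- as.vector(outer(rs, cs, idx))
    nbr[[idx(r, c)]] <- sort(setdiff(cand, idx(r, c)))
  }
  adjacency_graph(nbr)
}

#' Construct an adjacency graph from neighbour lists
#'
#' Validates symmetry and irreflexivity.
#'
#' @param nbr list of integer neighbour vectors (1-based district indices).
#' @return an `adjacency_graph` object.
#' @export
adjacency_graph <- function(nbr) {
  n <- length(nbr)
  nbr <- lapply(nbr, function(v) sort(as.integer(v)))
  for (i in seq_len(n)) {
    if (i %in% nbr[[i]]) stop("district ", i, " listed as its own neighbour")
    for (j in nbr[[i]])
      if (!(i %in% nbr[[j]]))
        stop(sprintf("adjacency not symmetric: %d -> %d but not %d -> %d",
                     i, j, j, i))
  }
  structure(list(nbr = nbr, n_nbr = lengths(nbr), n = n),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d districts, %d edges, degree %d-%d\n",
              x$n, sum(x$n_nbr) / 2, min(x$n_nbr), max(x$n_nbr)))
  invisible(x)
}

#' Dense adjacency matrix of a graph
#' @param adj an `adjacency_graph`.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @export
adjacency_matrix <- function(adj) {
  W <- matrix(0, adj$n, adj$n)
  for (i in seq_len(adj$n)) W[i, adj$nbr[[i]]] <- 1
  W
}

#' Connected components of an adjacency graph
#' @param adj an `adjacency_graph`.
#' @return integer vector of component labels (1-based).
#' @export
graph_components <- function(adj) {
  comp <- integer(adj$n)
  k <- 0L
  for (s in seq_len(adj$n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      new <- adj$nbr[[v]][comp[adj$nbr[[v]]] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

#' Require a connected graph
#' @param adj an `adjacency_graph`.
#' @return invisibly `TRUE`; errors naming the components otherwise.
#' @export
check_connected <- function(adj) {
  comp <- graph_components(adj)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop(sprintf(
      "adjacency graph is disconnected: %d components of sizes %s",
      max(comp), paste(sizes, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Queen-contiguity adjacency from district polygons
#'
#' Two polygons are adjacent if their boundaries touch anywhere — a shared
#' border segment or a single corner point both count. Contact is decided by
#' exact segment-segment intersection tests between boundary edges, with a
#' bounding-box prefilter.
#'
#' @param rings list of closed polygon rings (x/y matrices, last vertex equal
#'   to the first), assumed non-overlapping.
#' @return an `adjacency_graph`; errors if any polygon ends up with no
#'   neighbour (an island breaks the intrinsic CAR prior).
#' @export
build_adjacency <- function(rings) {
  n <- length(rings)
  if (n < 2L) stop("need at least 2 polygons")
  boxes <- t(vapply(rings, function(r)
    c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])), numeric(4)))
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer(0)
  tol <- 1e-9
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (boxes[i, 1] > boxes[j, 2] + tol || boxes[j, 1] > boxes[i, 2] + tol ||
        boxes[i, 3] > boxes[j, 4] + tol || boxes[j, 3] > boxes[i, 4] + tol)
      next
    if (rings_touch(rings[[i]], rings[[j]], tol)) {
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  isolated <- which(lengths(nbr) == 0L)
  if (length(isolated))
    stop("island district(s) with no neighbour: ",
         paste(isolated, collapse = ", "))
  adjacency_graph(nbr)
}

# Any contact between two polygon boundaries (segment intersection incl.
# endpoint touch and collinear overlap).
rings_touch <- function(a, b, tol = 1e-9) {
  na <- nrow(a) - 1L; nb <- nrow(b) - 1L
  for (p in seq_len(na)) {
    for (q in seq_len(nb)) {
      if (segments_intersect(a[p, 1], a[p, 2], a[p + 1L, 1], a[p + 1L, 2],
                             b[q, 1], b[q, 2], b[q + 1L, 1], b[q + 1L, 2],
                             tol))
        return(TRUE)
    }
  }
  FALSE
}

segments_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4, tol = 1e-9) {
  d1x <- x2 - x1; d1y <- y2 - y1
  d2x <- x4 - x3; d2y <- y4 - y3
  denom <- d1x * d2y - d1y * d2x
  ex <- x3 - x1; ey <- y3 - y1
  if (abs(denom) > tol) {
    t <- (ex * d2y - ey * d2x) / denom
    u <- (ex * d1y - ey * d1x) / denom
    return(t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol)
  }
  # parallel: collinear overlap or touch
  cross <- ex * d1y - ey * d1x
  if (abs(cross) > tol * max(1, abs(d1x), abs(d1y))) return(FALSE)
  # project onto the dominant axis of segment 1
  if (abs(d1x) >= abs(d1y)) {
    lo <- min(x1, x2) - tol; hi <- max(x1, x2) + tol
    min(x3, x4) <= hi && max(x3, x4) >= lo
  } else {
    lo <- min(y1, y2) - tol; hi <- max(y1, y2) + tol
    min(y3, y4) <= hi && max(y3, y4) >= lo
  }
}

#' Moran's I spatial autocorrelation statistic
#'
#' Binary queen weights from the adjacency graph; the usual
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#'
#' @param x numeric vector, one value per district.
#' @param adj an `adjacency_graph` over the same districts.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, adj) {
  stopifnot(length(x) == adj$n)
  z <- x - mean(x)
  s0 <- sum(adj$n_nbr)
  num <- sum(vapply(seq_len(adj$n),
                    function(i) z[i] * sum(z[adj$nbr[[i]]]), numeric(1)))
  (adj$n / s0) * num / sum(z^2)
}
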