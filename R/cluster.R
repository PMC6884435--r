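# Plaintext reference of the k-means variant used by the secure protocol:
# integer data points, exact rational centroids (integer numerators over one
# integer denominator), division-free integer-only distance comparisons,
# lowest-index tie-breaking, unconditional centroid-self-inclusion updates
# (which also absorb empty clusters), a fixed iteration count and a single
# post-hoc convergence check.  Only the membership matrix and the convergence
# flag are returned -- never centroids -- mirroring what the secure execution
# may reveal.

#' k-means configuration
#'
#' @param k number of clusters.
#' @param iterations fixed number of assign/update rounds (no early stop);
#'   the convergence flag compares the last two assignments and is reported
#'   as 0 when `iterations == 1`.
#' @param seed seed for the public initial-centroid draw.
#' @param mode `"paper_variant"` (centroid self-inclusion update, the secure
#'   protocol's rule) or `"strict_lloyd"` (plain cluster means, empty clusters
#'   keep their centroid; a testing aid with the classical monotonicity
#'   guarantee).
#' @return object of class `kmeans_config`.
#' @export
kmeans_config <- function(k = 5, iterations = 5, seed = 1,
                          mode = c("paper_variant", "strict_lloyd")) {
  mode <- match.arg(mode)
  k <- as.integer(k); iterations <- as.integer(iterations)
  if (k < 1L) stop("k must be >= 1")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(k = k, iterations = iterations, seed = as.integer(seed), mode = mode),
            class = "kmeans_config")
}

points_matrix <- function(x) {
  m <- if (inherits(x, "facing_table")) x$counts else as.matrix(x)
  if (!is.numeric(m) || any(m < 0) || any(m != trunc(m))) {
    stop("data points must be non-negative integers")
  }
  m
}

# the public initial-centroid index draw (made by the analyst party);
# shared verbatim by the plaintext and secure paths
draw_init_indices <- function(n, k, seed) {
  if (k > n) stop("configuration error: k must not exceed the number of points")
  set.seed(seed)
  sample.int(n, k)
}

new_centroids <- function(x, w) {
  structure(list(x = x, w = as_bn(w)), class = "rational_centroids")
}

#' Sample initial centroids among the data points
#'
#' Draws `k` distinct point indices uniformly without replacement
#' (deterministic given `seed`); centroid `j` is the drawn point with
#' denominator 1.  The indices are public: in the secure setting this choice
#' is made in the clear by the hospital.
#'
#' @param points integer matrix (rows = data points) or a `facing_table`.
#' @param k number of centroids.
#' @param seed integer seed.
#' @return `rational_centroids` (numerator matrix `x`, denominator vector
#'   `w`) with attribute `indices`.
#' @export
init_centroids <- function(points, k, seed) {
  pts <- points_matrix(points)
  idx <- draw_init_indices(nrow(pts), k, seed)
  x <- matrix(as_bn(pts[idx, , drop = FALSE]), nrow = k)
  cent <- new_centroids(x, rep("1", k))
  attr(cent, "indices") <- idx
  cent
}

#' Integer comparison score of a point against a rational centroid
#'
#' For a centroid `c = x / w` the squared Euclidean distance decomposes as
#' `d^2(y, c) = sum(y^2) + s(y, c) / w^2` with the integer score
#' `s(y, c) = sum(x_l^2 - 2 w x_l y_l)`; distance comparisons then reduce to
#' integer comparisons of cross-scaled scores.
#'
#' @param y integer vector (one point) or matrix (rows = points).
#' @param centroids a `rational_centroids` object.
#' @return character matrix `n x k` of exact integer scores.
#' @export
centroid_score <- function(y, centroids) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  k <- length(centroids$w)
  m <- ncol(centroids$x)
  if (ncol(y) != m) stop("dimension mismatch between points and centroids")
  n <- nrow(y)
  yc <- matrix(as_bn(y), nrow = n)
  out <- matrix("0", n, k)
  for (j in seq_len(k)) {
    xj <- centroids$x[j, ]
    a_j <- bn_sum(bn_mul(xj, xj))                       # sum x^2
    wx <- bn_mul(centroids$w[j], xj)                    # w * x, length m
    prod <- bn_mul(yc, rep(wx, each = n))               # column-major alignment
    b_i <- bn_grouped_sum(prod, rep(seq_len(n), m), n)  # sum_l w x_l y_l
    out[, j] <- bn_sub(a_j, bn_mul("2", b_i))
  }
  out
}

#' Division-free distance comparison
#'
#' Returns whether `d^2(y, ca) <= d^2(y, cb)` using only exact integer
#' arithmetic via the identity
#' `d^2(y,ca) <= d^2(y,cb)  <=>  wb^2 * s(y,ca) <= wa^2 * s(y,cb)`.
#'
#' @param y point vector, or matrix of points (rows).
#' @param ca,cb `rational_centroids`; single centroids compare against all
#'   rows of `y`.  With `pairwise = TRUE`, `ca` and `cb` must have one
#'   centroid per row of `y` and row `i` is compared against pair `i`.
#' @param pairwise compare row-by-row instead of point-vs-single-centroid.
#' @return logical vector.
#' @export
closer_or_equal <- function(y, ca, cb, pairwise = FALSE) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  if (pairwise) {
    stopifnot(length(ca$w) == nrow(y), length(cb$w) == nrow(y))
    sa <- score_pairwise(y, ca)
    sb <- score_pairwise(y, cb)
    wa2 <- bn_mul(ca$w, ca$w)
    wb2 <- bn_mul(cb$w, cb$w)
    return(bn_cmp(bn_mul(wb2, sa), bn_mul(wa2, sb)) <= 0)
  }
  stopifnot(length(ca$w) == 1, length(cb$w) == 1)
  sa <- centroid_score(y, ca)[, 1]
  sb <- centroid_score(y, cb)[, 1]
  wa2 <- bn_mul(ca$w, ca$w)
  wb2 <- bn_mul(cb$w, cb$w)
  bn_cmp(bn_mul(wb2, sa), bn_mul(wa2, sb)) <= 0
}

# score of point i against centroid i (row-matched)
score_pairwise <- function(y, cent) {
  n <- nrow(y)
  m <- ncol(y)
  yc <- matrix(as_bn(y), nrow = n)
  x2 <- bn_mul(cent$x, cent$x)
  a <- bn_grouped_sum(x2, rep(seq_len(n), m), n)
  wx <- bn_mul(rep(cent$w, m), cent$x)
  b <- bn_grouped_sum(bn_mul(yc, wx), rep(seq_len(n), m), n)
  bn_sub(a, bn_mul("2", b))
}

#' Assign points to clusters (membership matrix)
#'
#' Point `i` joins cluster `j` iff centroid `j` is closer-or-equal to every
#' centroid (the product of pairwise comparison bits), followed by a
#' uniqueness pass that keeps only the lowest-indexed minimiser, so each row
#' of the returned matrix sums to exactly 1.
#'
#' @param points integer matrix or `facing_table`.
#' @param centroids `rational_centroids`.
#' @return binary integer matrix `n x k`.
#' @export
assign_points <- function(points, centroids) {
  pts <- points_matrix(points)
  n <- nrow(pts)
  k <- length(centroids$w)
  s <- centroid_score(pts, centroids)
  w2 <- bn_mul(centroids$w, centroids$w)
  raw <- matrix(TRUE, n, k)
  if (k >= 2) {
    for (j in seq_len(k)) {
      for (jp in seq_len(k)) {
        if (jp == j) next
        xi <- bn_cmp(bn_mul(w2[jp], s[, j]), bn_mul(w2[j], s[, jp])) <= 0
        raw[, j] <- raw[, j] & xi
      }
    }
  }
  M <- matrix(0L, n, k)
  first <- apply(raw, 1, function(r) which(r)[1])
  if (anyNA(first)) stop("internal error: no nearest centroid found")
  M[cbind(seq_len(n), first)] <- 1L
  M
}

#' Update rational centroids from a membership matrix
#'
#' In `paper_variant` mode each centroid is unconditionally added to its own
#' cluster: with cluster size `n_j`, the new centroid is the exact mean of
#' the member points plus the old centroid, computed division-free as
#' `x' = w * sum(M_ij y_i) + x`, `w' = w * (n_j + 1)`.  Empty clusters thus
#' keep their centroid unchanged and no division by zero can occur.  In
#' `strict_lloyd` mode the new centroid is the plain mean and empty clusters
#' retain their previous centroid.  Fractions are reduced by their gcd after
#' every update (plaintext only; shares cannot be reduced).
#'
#' @param points integer matrix or `facing_table`.
#' @param M binary membership matrix with unit row sums.
#' @param centroids current `rational_centroids`.
#' @param mode update rule, as in [kmeans_config()].
#' @return updated `rational_centroids`.
#' @export
update_centroids <- function(points, M, centroids, mode = "paper_variant") {
  pts <- points_matrix(points)
  if (!all(rowSums(M) == 1)) stop("invariant violation: membership rows must sum to 1")
  k <- length(centroids$w)
  m <- ncol(pts)
  xo <- matrix("0", k, m)
  wo <- character(k)
  for (j in seq_len(k)) {
    members <- M[, j] == 1
    nj <- sum(members)
    sy <- as_bn(colSums(pts[members, , drop = FALSE]))
    if (mode == "paper_variant") {
      xn <- bn_add(bn_mul(centroids$w[j], sy), centroids$x[j, ])
      wn <- bn_mul(centroids$w[j], as_bn(nj + 1))
    } else if (nj == 0) {
      xn <- centroids$x[j, ]
      wn <- centroids$w[j]
    } else {
      xn <- sy
      wn <- as_bn(nj)
    }
    g <- bn_gcd_reduce(c(wn, xn))
    if (g != "1" && g != "0") {
      xn <- bn_div(xn, g)
      wn <- bn_div(wn, g)
    }
    xo[j, ] <- xn
    wo[j] <- wn
  }
  new_centroids(xo, wo)
}

# full trace (per-iteration assignments and centroids) for tests
kmeans_engine <- function(pts, config) {
  cent <- init_centroids(pts, config$k, config$seed)
  init_idx <- attr(cent, "indices")
  ms <- vector("list", config$iterations)
  cents <- vector("list", config$iterations)
  for (r in seq_len(config$iterations)) {
    ms[[r]] <- assign_points(pts, cent)
    cent <- update_centroids(pts, ms[[r]], cent, mode = config$mode)
    cents[[r]] <- cent
  }
  converged <- if (config$iterations >= 2) {
    as.integer(identical(ms[[config$iterations]], ms[[config$iterations - 1]]))
  } else 0L
  list(membership = ms[[config$iterations]], converged = converged,
       assignments = max.col(ms[[config$iterations]], "first"),
       init_indices = init_idx,
       history = ms, centroid_history = cents)
}

#' Cluster nurses on their facing-time profiles
#'
#' Runs the configured number of assign/update rounds from the seeded initial
#' centroids and returns only the final membership matrix and the convergence
#' flag (1 iff the last two assignments were identical); centroid values are
#' never part of the output.  A pure function of `(points, config)`.
#'
#' @param points integer matrix (rows = data points) or a `facing_table`.
#' @param config a [kmeans_config()].
#' @return list with `membership` (binary `n x k` matrix), `converged` (0/1),
#'   `assignments` (cluster index per point) and `init_indices`.
#' @export
facing_kmeans <- function(points, config) {
  pts <- points_matrix(points)
  if (config$k > nrow(pts)) stop("configuration error: k must not exceed the number of points")
  res <- kmeans_engine(pts, config)
  res$history <- NULL
  res$centroid_history <- NULL
  res
}

# exact within-cluster sum of squares as a rational number (internal)
wss_exact <- function(pts, M, centroids) {
  n <- nrow(pts)
  total <- rat("0")
  for (i in seq_len(n)) {
    j <- which(M[i, ] == 1)
    d <- bn_sub(bn_mul(centroids$w[j], as_bn(pts[i, ])), centroids$x[j, ])
    num <- bn_sum(bn_mul(d, d))
    total <- rat_add(total, rat(num, bn_mul(centroids$w[j], centroids$w[j])))
  }
  total
}
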