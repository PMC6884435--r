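test_that("the integer score satisfies the distance decomposition", {
  c1 <- new_centroids(matrix(c("2", "2"), 1), "1")
  expect_equal(centroid_score(c(1, 2), c1)[1, 1], "-4")
  # sum(y^2) + s/w^2 = d^2: 5 - 4 = 1
  zero <- new_centroids(matrix(c("0", "0", "0"), 1), "7")
  expect_equal(centroid_score(c(5, 1, 9), zero)[1, 1], "0")
  # random check against exact rational d^2 via the direct form
  set.seed(21)
  n <- 2000
  y <- matrix(sample(0:30, n * 2, TRUE), n)
  cx <- matrix(as.character(sample(0:60, n * 2, TRUE)), n)
  cw <- as.character(sample(1:9, n, TRUE))
  cc <- new_centroids(cx, cw)
  s <- score_pairwise(y, cc)
  # w^2 * sum(y^2) + s*1 == sum((w y - x)^2) exactly
  lhs <- bn_add(bn_mul(bn_mul(cw, cw),
                       bn_grouped_sum(bn_mul(as.character(y), as.character(y)),
                                      rep(seq_len(n), 2), n)), s)
  d <- bn_sub(bn_mul(rep(cw, 2), as.character(y)), cx)
  rhs <- bn_grouped_sum(bn_mul(d, d), rep(seq_len(n), 2), n)
  expect_identical(lhs, rhs)
})

test_that("closer_or_equal agrees with the exact rational oracle", {
  # worked example: c = (2,2)/1 vs ct = (5,1)/2 for y = (1,2): d^2 = 1 vs 4.5
  c1 <- new_centroids(matrix(c("2", "2"), 1), "1")
  ct <- new_centroids(matrix(c("5", "1"), 1), "2")
  expect_true(closer_or_equal(c(1, 2), c1, ct))
  expect_false(closer_or_equal(c(1, 2), ct, c1))
  expect_true(closer_or_equal(c(1, 2), c1, c1))   # ties compare true
  # totality of <= on random triples
  set.seed(22)
  n <- 5000
  y <- matrix(sample(0:40, n * 3, TRUE), n)
  ca <- new_centroids(matrix(as.character(sample(0:99, n * 3, TRUE)), n),
                      as.character(sample(1:25, n, TRUE)))
  cb <- new_centroids(matrix(as.character(sample(0:99, n * 3, TRUE)), n),
                      as.character(sample(1:25, n, TRUE)))
  ab <- closer_or_equal(y, ca, cb, pairwise = TRUE)
  ba <- closer_or_equal(y, cb, ca, pairwise = TRUE)
  expect_true(all(ab | ba))
  expect_identical(ab, rational_d2_leq(y, ca, cb))
})

test_that("initial centroids are data points drawn without replacement", {
  set.seed(30)
  pts <- matrix(sample(0:9, 24, TRUE), 6)
  cent <- init_centroids(pts, 6, seed = 4)
  idx <- attr(cent, "indices")
  expect_equal(sort(idx), 1:6)  # k = n: a permutation
  expect_identical(cent$x, matrix(as.character(pts[idx, ]), 6))
  expect_true(all(cent$w == "1"))
  expect_identical(attr(init_centroids(pts, 3, seed = 9), "indices"),
                   attr(init_centroids(pts, 3, seed = 9), "indices"))
  expect_error(init_centroids(pts, 7, 1), "k must not exceed")
})

test_that("assignment matches the exhaustive nearest-centroid oracle", {
  pts <- rbind(c(0, 0), c(0, 2), c(10, 10), c(10, 12))
  cent <- new_centroids(matrix(as.character(rbind(c(0, 0), c(10, 10))), 2),
                        c("1", "1"))
  M <- assign_points(pts, cent)
  expect_equal(unname(M), rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L)))
  # identical centroids: everything to the lowest index
  cent2 <- new_centroids(matrix(c("5", "5", "5", "5"), 2), c("1", "1"))
  expect_true(all(assign_points(pts, cent2)[, 1] == 1))
  set.seed(31)
  for (i in 1:15) {
    n <- sample(4:9, 1); m <- sample(2:4, 1); k <- sample(2:4, 1)
    P <- matrix(sample(0:15, n * m, TRUE), n)
    cc <- init_centroids(P, k, seed = i)
    # push the centroids off the data points with one update round
    cc <- update_centroids(P, assign_points(P, cc), cc)
    expect_identical(unname(assign_points(P, cc)), oracle_assign(P, cc))
  }
})

test_that("the update rule is mean-plus-own-centroid, gcd-reduced", {
  pts <- rbind(c(0, 0), c(2, 2))
  old <- new_centroids(matrix(c("1", "3"), 1), "1")
  up <- update_centroids(pts, rbind(1L, 1L), old)
  expect_identical(up$x[1, ], c("3", "5"))   # mean of {(0,0),(2,2),(1,3)} = (1, 5/3)
  expect_equal(up$w, "3")
  # empty cluster: centroid carried over exactly
  M <- cbind(c(1L, 1L), c(0L, 0L))
  old2 <- new_centroids(rbind(c("1", "3"), c("7", "9")), c("1", "2"))
  up2 <- update_centroids(pts, M, old2)
  expect_identical(up2$x[2, ], c("7", "9"))
  expect_equal(up2$w[2], "2")
  # singleton cluster at its own centroid stays put
  up3 <- update_centroids(matrix(c(4, 6), 1), matrix(1L),
                          new_centroids(matrix(c("4", "6"), 1), "1"))
  expect_identical(up3$x[1, ], c("4", "6"))
  expect_equal(up3$w, "1")
  expect_error(update_centroids(pts, cbind(c(1L, 1L), c(1L, 0L)), old2),
               "sum to 1")
})

test_that("k-means on the four-point instance recovers the two pairs", {
  pts <- rbind(c(0, 0), c(0, 2), c(10, 10), c(10, 12))
  s <- seed_for_init(4, 2, c(1, 3))
  km <- facing_kmeans(pts, kmeans_config(k = 2, iterations = 2, seed = s))
  expect_equal(unname(km$membership),
               rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L)))
  expect_equal(km$converged, 1L)
  expect_equal(km$assignments, c(1L, 1L, 2L, 2L))
})

test_that("k = 1 and degenerate instances behave per the tie rule", {
  pts <- rbind(c(1, 2), c(3, 4), c(5, 6))
  km <- facing_kmeans(pts, kmeans_config(k = 1, iterations = 2, seed = 1))
  expect_true(all(km$membership == 1))
  expect_equal(km$converged, 1L)
  same <- rbind(c(3, 3), c(3, 3), c(3, 3))
  km2 <- facing_kmeans(same, kmeans_config(k = 2, iterations = 2, seed = 1))
  expect_true(all(km2$membership[, 1] == 1))
  # equidistant point goes to the lower-indexed cluster
  pts3 <- rbind(c(0, 0), c(4, 0), c(2, 0))
  s13 <- seed_for_init(3, 2, c(1, 2))
  km3 <- facing_kmeans(pts3, kmeans_config(k = 2, iterations = 1, seed = s13))
  expect_equal(km3$membership[3, ], c(1L, 0L))
})

test_that("membership rows always sum to one and runs are reproducible", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    P <- matrix(sample(0:20, n * 3, TRUE), n)
    cf <- kmeans_config(k = sample(2:3, 1), iterations = 3, seed = i)
    r1 <- facing_kmeans(P, cf)
    r2 <- facing_kmeans(P, cf)
    expect_true(all(rowSums(r1$membership) == 1))
    expect_identical(r1, r2)
  }
})

test_that("strict Lloyd mode never increases the within-cluster sum of squares", {
  set.seed(34)
  for (i in 1:10) {
    n <- sample(5:10, 1); m <- sample(2:4, 1); k <- sample(2:3, 1)
    P <- matrix(sample(0:20, n * m, TRUE), n)
    cf <- kmeans_config(k = k, iterations = 4, seed = i, mode = "strict_lloyd")
    eng <- kmeans_engine(P, cf)
    ws <- lapply(1:4, function(r) wss_exact(P, eng$history[[r]],
                                            eng$centroid_history[[r]]))
    for (r in 2:4) expect_lte(rat_cmp(ws[[r]], ws[[r - 1]]), 0)
  }
})
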