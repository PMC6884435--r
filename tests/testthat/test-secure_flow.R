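# Secure protocol vs its plaintext reference, budget accounting, and
# obliviousness of the gate sequence.

TB4 <- time_bins(c(10, 30, 60))

share_instance <- function(ctx, inst, addressing = "public") {
  list(
    n = share_period_table(ctx, inst$nurse_periods, nurse_ids = inst$nurse_ids,
                           addressing = addressing),
    p = share_period_table(ctx, inst$patient_periods,
                           type_labels = inst$type_labels,
                           addressing = addressing)
  )
}

test_that("the single-pair fixture survives the secure translation", {
  np <- data.frame(tagID = "n1", st = 100L, et = 140L, zID = 3L,
                   tagRole = "nurse", stringsAsFactors = FALSE)
  pp <- data.frame(tagID = "p1", st = 120L, et = 200L, zID = 3L,
                   tagRole = "patient:A", stringsAsFactors = FALSE)
  ft <- build_facing_table(np, pp, TB4, "n1", c("A", "B"))
  ctx <- mpc_session(field_mersenne127(), seed = 1)
  sn <- share_period_table(ctx, np, nurse_ids = "n1")
  sp <- share_period_table(ctx, pp, type_labels = c("A", "B"))
  sft <- secure_build_table(ctx, sn, sp, TB4, n_zones = 5, max_time = 200)
  expect_identical(reveal_facing_table(ctx, sft)$counts, ft$counts)
})

test_that("zero periods on either side give the all-zero shared table", {
  ctx <- mpc_session(field_mersenne127(), seed = 2)
  empty <- data.frame(tagID = character(), st = integer(), et = integer(),
                      zID = integer(), tagRole = character())
  attr(empty, "role_scope") <- "nurses_only"
  sn <- share_period_table(ctx, empty, nurse_ids = c("n1", "n2"))
  pp <- data.frame(tagID = "p1", st = 0L, et = 40L, zID = 1L,
                   tagRole = "patient:A", stringsAsFactors = FALSE)
  sp <- share_period_table(ctx, pp, type_labels = "A")
  sft <- secure_build_table(ctx, sn, sp, TB4, n_zones = 2, max_time = 40)
  expect_true(all(reveal_facing_table(ctx, sft)$counts == 0))
})

test_that("secure table construction equals the plaintext table on random instances", {
  set.seed(41)
  for (i in 1:8) {
    inst <- random_instance(sample(3:5, 1), sample(2:3, 1))
    ft <- build_facing_table(inst$nurse_periods, inst$patient_periods, TB4,
                             inst$nurse_ids, inst$type_labels)
    ctx <- mpc_session(field_mersenne127(), seed = i)
    sh <- share_instance(ctx, inst)
    sft <- secure_build_table(ctx, sh$n, sh$p, TB4, n_zones = inst$n_zones,
                              max_time = inst$max_time)
    expect_identical(reveal_facing_table(ctx, sft)$counts, ft$counts)
  }
})

test_that("oblivious one-hot addressing produces the same table", {
  set.seed(42)
  inst <- random_instance(4, 2, max_periods_side = 5)
  ft <- build_facing_table(inst$nurse_periods, inst$patient_periods, TB4,
                           inst$nurse_ids, inst$type_labels)
  ctx <- mpc_session(field_mersenne127(), seed = 5)
  sh <- share_instance(ctx, inst, addressing = "oblivious")
  sft <- secure_build_table(ctx, sh$n, sh$p, TB4, n_zones = inst$n_zones,
                            max_time = inst$max_time)
  expect_identical(reveal_facing_table(ctx, sft)$counts, ft$counts)
  # mixing addressed and oblivious tables is refused
  ctx2 <- mpc_session(field_mersenne127(), seed = 6)
  shp <- share_period_table(ctx2, inst$nurse_periods, nurse_ids = inst$nurse_ids)
  sho <- share_period_table(ctx2, inst$patient_periods,
                            type_labels = inst$type_labels,
                            addressing = "oblivious")
  expect_error(secure_build_table(ctx2, shp, sho, TB4), "oblivious")
})

test_that("secure k-means reveals exactly the plaintext membership and flag", {
  pts <- rbind(c(0, 0), c(0, 2), c(10, 10), c(10, 12))
  s <- seed_for_init(4, 2, c(1, 3))
  cf <- kmeans_config(k = 2, iterations = 2, seed = s)
  km <- facing_kmeans(pts, cf)
  ctx <- mpc_session(field_mersenne127(), seed = 11)
  sft <- list(cells = mpc_share(ctx, as.vector(t(pts))), Nn = 4, m = 2,
              nurse_ids = paste0("n", 1:4), type_labels = "A",
              bins = time_bins(10))
  class(sft) <- "shared_facing_table"
  skm <- secure_kmeans(ctx, sft, cf, y_bound = 12)
  expect_equal(unname(skm$membership),
               rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L)))
  expect_equal(skm$converged, 1L)
  expect_identical(unname(skm$membership), unname(km$membership))
  # k = 1: the all-ones column
  cf1 <- kmeans_config(k = 1, iterations = 2, seed = 1)
  ctx1 <- mpc_session(field_mersenne127(), seed = 12)
  sft1 <- sft
  sft1$cells <- mpc_share(ctx1, as.vector(t(pts)))
  skm1 <- secure_kmeans(ctx1, sft1, cf1, y_bound = 12)
  expect_true(all(skm1$membership == 1))
  expect_equal(skm1$converged, 1L)
})

test_that("full secure pipeline equals plaintext on random instances", {
  set.seed(43)
  for (i in 1:6) {
    inst <- random_instance(sample(4:6, 1), sample(2:3, 1))
    k <- sample(2:3, 1)
    cf <- kmeans_config(k = k, iterations = 2, seed = i + 100)
    ft <- build_facing_table(inst$nurse_periods, inst$patient_periods, TB4,
                             inst$nurse_ids, inst$type_labels)
    km <- facing_kmeans(ft, cf)
    ctx <- mpc_session(field_mersenne127(), seed = i)
    sh <- share_instance(ctx, inst)
    sft <- secure_build_table(ctx, sh$n, sh$p, TB4, n_zones = inst$n_zones,
                              max_time = inst$max_time)
    skm <- secure_kmeans(ctx, sft, cf,
                         y_bound = nrow(inst$nurse_periods) * nrow(inst$patient_periods))
    expect_identical(unname(skm$membership), unname(km$membership))
    expect_equal(skm$converged, km$converged)
  }
})

test_that("the budget planner predicts dealer consumption exactly", {
  set.seed(44)
  inst <- random_instance(5, 2)
  cf <- kmeans_config(k = 2, iterations = 3, seed = 7)
  ctx <- mpc_session(field_mersenne127(), seed = 7)
  sh <- share_instance(ctx, inst)
  sft <- secure_build_table(ctx, sh$n, sh$p, TB4, n_zones = inst$n_zones,
                            max_time = inst$max_time)
  invisible(secure_kmeans(ctx, sft, cf,
                          y_bound = nrow(inst$nurse_periods) * nrow(inst$patient_periods)))
  bud <- plan_budget(list(Nn = 5, Nptype = 2, Ntimebins = 4,
                          nP = nrow(inst$nurse_periods),
                          pP = nrow(inst$patient_periods),
                          k = 2, iterations = 3, n_zones = inst$n_zones,
                          max_time = inst$max_time), field_mersenne127())
  got <- dealer_stats(ctx)
  expect_equal(got$triples, bud$counts$total$triples)
  expect_equal(got$rand_bits, bud$counts$total$rand_bits)
  expect_equal(got$pow2_masks, bud$counts$total$pow2_masks)
  expect_equal(got$nonzero_masks, bud$counts$total$nonzero_masks)
})

test_that("denominator growth bounds and field rejection behave as designed", {
  kb <- kmeans_bounds(4, 2, 10, 2)
  expect_equal(kb$w[2], "25")      # (Nn + 1)^2 with Nn = 4
  # the 64-bit preset cannot host the full-size clustering circuit
  bud <- plan_budget(list(Nn = 120, Nptype = 5, Ntimebins = 4, nP = 7000,
                          pP = 90, k = 5, iterations = 5), field_paper64())
  expect_false(bud$ok)
  expect_true(any(grepl("score", bud$reasons)))
  # and secure_kmeans refuses to run on it
  ctx <- mpc_session(field_paper64(), seed = 1)
  sft <- list(cells = mpc_share(ctx, rep(0, 8)), Nn = 4, m = 2,
              nurse_ids = paste0("n", 1:4), type_labels = "A",
              bins = time_bins(10))
  class(sft) <- "shared_facing_table"
  expect_error(secure_kmeans(ctx, sft, kmeans_config(k = 2, iterations = 5, seed = 1),
                             y_bound = 1e6), "budget")
  # the default field hosts five iterations at small-cohort scale
  bud2 <- plan_budget(list(Nn = 7, Nptype = 3, Ntimebins = 4, nP = 420,
                           pP = 50, k = 2, iterations = 5), field_mersenne127())
  expect_true(bud2$ok)
  # but not the full-ward clustering circuit under the coarse public bound
  bud3 <- plan_budget(list(Nn = 120, Nptype = 5, Ntimebins = 4, nP = 7000,
                           pP = 90, k = 5, iterations = 5), field_mersenne127())
  expect_false(bud3$ok)
})

test_that("gate sequence depends only on public shape, not on secrets", {
  set.seed(45)
  base <- random_instance(4, 2)
  # same shape, different secret times/zones
  other <- base
  other$nurse_periods$st <- base$nurse_periods$st + 4L
  other$nurse_periods$et <- base$nurse_periods$et + 4L
  other$nurse_periods$zID <- sample(base$n_zones, nrow(base$nurse_periods), TRUE)
  other$patient_periods$zID <- sample(base$n_zones, nrow(base$patient_periods), TRUE)
  cf <- kmeans_config(k = 2, iterations = 2, seed = 3)
  run <- function(inst, seed) {
    ctx <- mpc_session(field_mersenne127(), seed = seed)
    sh <- share_instance(ctx, inst)
    sft <- secure_build_table(ctx, sh$n, sh$p, TB4, n_zones = inst$n_zones,
                              max_time = base$max_time + 8)
    invisible(secure_kmeans(ctx, sft, cf,
                            y_bound = nrow(inst$nurse_periods) * nrow(inst$patient_periods)))
    ctx
  }
  c1 <- run(base, 1)
  c2 <- run(other, 2)
  expect_identical(gate_trace(c1), gate_trace(c2))
  # the only reveals: masked openings, the zero test, and the final M
  rl <- reveal_log(c1)
  expect_true(all(rl$purpose %in% c("masked", "zero_test", "output")))
  expect_equal(sum(rl$n[rl$purpose == "output"]), 4 * 2) # the membership matrix
  expect_equal(sum(rl$purpose == "zero_test"), 1)        # the convergence bit
})
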