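# Gate semantics of the secret-sharing layer: exhaustive over a toy field,
# random at production size, plus the hiding properties of the transcript.

toy <- field_spec("101", kappa = 1, ell = 3)

test_that("share/reveal round-trips across the signed range", {
  ctx <- mpc_session(toy, seed = 5)
  x <- -50:50
  expect_identical(mpc_reveal(ctx, mpc_share(ctx, x)), as.numeric(x))
  expect_error(mpc_share(ctx, 51), "signed range")
  expect_equal(mpc_reveal(ctx, mpc_constant(ctx, c(-3, 0, 7))), c(-3, 0, 7))
  # all-zero shares reveal 0
  z <- new_sv(matrix(0, 1, 1), matrix(0, 1, 1), toy)
  expect_equal(mpc_reveal(ctx, z), 0)
})

test_that("linear and multiplicative gates are exhaustive over p = 101", {
  ctx <- mpc_session(toy, seed = 5)
  g <- expand.grid(a = -50:50, b = -50:50)
  # addition over the full signed range (results reduced mod p, signed)
  small <- g[abs(g$a + g$b) <= 50, ]
  s <- mpc_reveal(ctx, mpc_add(mpc_share(ctx, small$a), mpc_share(ctx, small$b)))
  expect_identical(s, as.numeric(small$a + small$b))
  d <- mpc_reveal(ctx, mpc_sub(mpc_share(ctx, small$a), mpc_share(ctx, small$b)),
                  as_numeric = FALSE)
  expect_identical(d, fp_to_signed(as.character(small$a - small$b), "101"))
  # multiplication: compare in the field (products wrap into the signed range)
  pr <- mpc_reveal(ctx, mpc_mul(ctx, mpc_share(ctx, g$a), mpc_share(ctx, g$b)),
                   as_numeric = FALSE)
  expect_identical(pr, fp_to_signed(fp_norm(as.character(g$a * g$b), "101"), "101"))
  # constants
  expect_identical(mpc_reveal(ctx, mpc_add_const(mpc_share(ctx, 0), 9)), 9)
  expect_identical(mpc_reveal(ctx, mpc_mul_const(mpc_share(ctx, -50:50), 0)),
                   rep(0, 101))
})

test_that("comparison gates are exhaustive over their legal toy-field range", {
  # at p = 101, masking headroom admits ell = 3: secrets in [-4, 4)
  ctx <- mpc_session(toy, seed = 5)
  g <- expand.grid(a = -4:3, b = -4:3)
  sa <- mpc_share(ctx, g$a); sb <- mpc_share(ctx, g$b)
  expect_identical(mpc_reveal(ctx, mpc_lt(ctx, sa, sb, 3)), as.numeric(g$a < g$b))
  expect_identical(mpc_reveal(ctx, mpc_ge(ctx, sa, sb, 3)), as.numeric(g$a >= g$b))
  expect_identical(mpc_reveal(ctx, mpc_eq(ctx, sa, sb, 3)), as.numeric(g$a == g$b))
  expect_identical(mpc_reveal(ctx, mpc_smin(ctx, sa, sb, 3)),
                   as.numeric(pmin(g$a, g$b)))
  expect_identical(mpc_reveal(ctx, mpc_smax(ctx, sa, sb, 3)),
                   as.numeric(pmax(g$a, g$b)))
  expect_error(mpc_lt(ctx, sa, sb, 5), "headroom")
})

test_that("gates agree with plaintext operators in the production field", {
  fp <- field_mersenne127()
  ctx <- mpc_session(fp, seed = 9)
  set.seed(2)
  n <- 4000
  rnd83 <- function() {
    bn_sub(bn_from_bits(matrix(sample(0:1, n * 83, TRUE), n)), two_pow_chr(82L))
  }
  a <- rnd83(); b <- rnd83()
  b[1:50] <- a[1:50]  # force equality cases
  sa <- mpc_share(ctx, a); sb <- mpc_share(ctx, b)
  cmp <- bn_cmp(a, b)
  expect_identical(mpc_reveal(ctx, mpc_lt(ctx, sa, sb, 84)), as.numeric(cmp < 0))
  expect_identical(mpc_reveal(ctx, mpc_eq(ctx, sa, sb, 84)), as.numeric(cmp == 0))
  mn <- mpc_reveal(ctx, mpc_smin(ctx, sa, sb, 84), as_numeric = FALSE)
  expect_identical(mn, ifelse(cmp <= 0, a, b))
  pr <- mpc_reveal(ctx, mpc_mul(ctx, sa, sb), as_numeric = FALSE)
  expect_identical(pr, fp_to_signed(fp_mul(fp_norm(a, fp$p), fp_norm(b, fp$p), fp$p), fp$p))
  su <- mpc_reveal(ctx, mpc_add(sa, sb), as_numeric = FALSE)
  expect_identical(su, bn_add(a, b))
})

test_that("the randomised zero test reveals exactly zero-ness", {
  ctx <- mpc_session(field_mersenne127(), seed = 3)
  x <- c(0, 5, 0, -3, 0)
  expect_identical(mpc_is_zero(ctx, mpc_share(ctx, x)), x == 0)
  # the opened values for nonzero secrets differ run to run (masked)
  ctx2 <- mpc_session(field_mersenne127(), seed = 4)
  invisible(mpc_is_zero(ctx2, mpc_share(ctx2, x)))
  expect_equal(dealer_stats(ctx)$nonzero_masks, 5)
})

test_that("party-0 shares of a fixed secret are uniform (chi-square)", {
  ctx <- mpc_session(toy, seed = 17)
  s <- mpc_share(ctx, rep(42, 20000))
  tab <- table(factor(as.vector(s$s0), levels = as.character(0:100)))
  pval <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(pval, 0.01)
})

test_that("masked multiplication openings are indistinguishable across inputs", {
  # run the same circuit shape on two fixed, distinct input pairs and compare
  # the distribution of the opened d = u - a values
  open_d <- function(x, y, seed) {
    ctx <- mpc_session(toy, seed = seed)
    u <- mpc_share(ctx, rep(x, 3000))
    v <- mpc_share(ctx, rep(y, 3000))
    tr <- draw_triples(ctx, 3000)
    d <- fx_to_str(fx_add(fx_sub(u$s0, tr$a0, "101"), fx_sub(u$s1, tr$a1, "101"), "101"))
    table(factor(d, levels = as.character(0:100)))
  }
  t1 <- open_d(3, 4, 23)
  t2 <- open_d(-7, 9, 24)
  p1 <- suppressWarnings(stats::chisq.test(t1)$p.value)
  p2 <- suppressWarnings(stats::chisq.test(t2)$p.value)
  ph <- suppressWarnings(stats::chisq.test(rbind(t1, t2))$p.value)
  expect_gt(p1, 0.001)  # uniform on its own
  expect_gt(p2, 0.001)
  expect_gt(ph, 0.001)  # and indistinguishable between the two inputs
})

test_that("dealer material is deterministic in the seed and counted exactly", {
  f <- field_mersenne127()
  c1 <- mpc_session(f, seed = 7)
  c2 <- mpc_session(f, seed = 7)
  r1 <- mpc_mul(c1, mpc_share(c1, 1:10), mpc_share(c1, 11:20))
  r2 <- mpc_mul(c2, mpc_share(c2, 1:10), mpc_share(c2, 11:20))
  expect_identical(r1$s0, r2$s0)
  expect_identical(dealer_stats(c1), dealer_stats(c2))
  expect_equal(dealer_stats(c1)$triples, 10)
  # a different seed yields different shares for the same secrets
  c3 <- mpc_session(f, seed = 8)
  r3 <- mpc_mul(c3, mpc_share(c3, 1:10), mpc_share(c3, 11:20))
  expect_false(identical(r1$s0, r3$s0))
  # one lt at b bits costs exactly 2b-1 triples, b bits, one mask block
  c4 <- mpc_session(f, seed = 9)
  invisible(mpc_lt(c4, mpc_share(c4, 5), mpc_share(c4, 9), bits = 20))
  expect_equal(dealer_stats(c4)$triples, 2 * 20 - 1)
  expect_equal(dealer_stats(c4)$rand_bits, 20)
  expect_equal(dealer_stats(c4)$pow2_masks, 1)
  # smin = a*eps + b*(1-eps): the lt cost plus exactly two products
  c5 <- mpc_session(f, seed = 10)
  invisible(mpc_smin(c5, mpc_share(c5, 3), mpc_share(c5, 7), bits = 20))
  expect_equal(dealer_stats(c5)$triples, (2 * 20 - 1) + 2)
})

test_that("field specs enforce masking headroom", {
  expect_error(field_spec("101", kappa = 40, ell = 10), "headroom")
  expect_silent(field_spec("101", kappa = 1, ell = 3))
  f64 <- field_paper64()
  expect_equal(f64$ell, 21L)
  expect_equal(field_mersenne127()$bitlen, 127L)
})
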