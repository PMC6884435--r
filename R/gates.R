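# Shared values and the gate set of the two-party layer.
#
# A shared value is a pair of parallel share matrices (one per party) over
# the session's prime field; the secret is their sum mod p, read in the
# symmetric signed range.  Field elements are stored as base-1e9 limb rows
# of a numeric matrix (exact; one R object per vector, so the million-share
# volumes of a secure run do not stress the garbage collector).  Linear
# gates are local; multiplication consumes one Beaver triple per element;
# comparisons run a statistically masked bit-decomposition subprotocol.
# All gates are vectorised: a shared value of length n is n independent
# wires processed in one batch.

new_sv <- function(s0, s1, field) {
  structure(list(s0 = s0, s1 = s1, field = field), class = "shared_value")
}

#' @export
length.shared_value <- function(x) nrow(x$s0)

#' @export
print.shared_value <- function(x, ...) {
  cat("<shared_value> length", length(x), "over", x$field$bitlen, "-bit field\n")
  invisible(x)
}

sv_check2 <- function(u, v) {
  if (!identical(u$field$p, v$field$p)) stop("shared values from different fields")
}

sv_slice <- function(v, idx) {
  new_sv(v$s0[idx, , drop = FALSE], v$s1[idx, , drop = FALSE], v$field)
}

sv_cat <- function(...) {
  vs <- list(...)
  new_sv(do.call(rbind, lapply(vs, `[[`, "s0")),
         do.call(rbind, lapply(vs, `[[`, "s1")), vs[[1]]$field)
}

sv_rep <- function(v, times = NULL, each = NULL, length.out = NULL) {
  idx <- if (!is.null(length.out)) rep(seq_len(nrow(v$s0)), length.out = length.out)
  else if (!is.null(each)) rep(seq_len(nrow(v$s0)), each = each)
  else rep(seq_len(nrow(v$s0)), times = times)
  sv_slice(v, idx)
}

#' Secret-share a vector of integers
#'
#' Party 0's share is uniformly random in the field; party 1 holds the
#' difference.  Each share alone is statistically independent of the secret.
#'
#' @param ctx an [mpc_session()].
#' @param x integer-valued numeric or decimal character vector; each value
#'   must lie in the field's signed range `[-M, M]`.
#' @return a `shared_value` of the same length.
#' @export
mpc_share <- function(ctx, x) {
  x <- as_bn(x)
  M <- ctx$field$signed_bound
  bad <- bn_cmp(x, M) > 0 | bn_cmp(x, bn_neg(M)) < 0
  if (any(bad)) stop("secret out of the signed range [-M, M]")
  n <- length(x)
  s0 <- draw_share0(ctx, n)
  bump(ctx, "input_shares", n)
  s1 <- fx_sub(fx_from_str(x, ctx$field$p), s0, ctx$field$p)
  new_sv(s0, s1, ctx$field)
}

#' Share a public constant
#'
#' Public values need no hiding: party 0 holds the value, party 1 holds zero.
#' Consumes no randomness.
#' @param ctx an [mpc_session()] (or a `field_spec`).
#' @param x integer-valued numeric or decimal character vector.
#' @param n optional length to recycle to.
#' @export
mpc_constant <- function(ctx, x, n = NULL) {
  field <- if (inherits(ctx, "field_spec")) ctx else ctx$field
  x <- as_bn(x)
  if (!is.null(n)) x <- rep_len(x, n)
  s0 <- fx_from_str(x, field$p)
  new_sv(s0, matrix(0, nrow(s0), ncol(s0)), field)
}

# joint reconstruction; returns field residues as a limb matrix
open_raw <- function(ctx, v, purpose) {
  log_reveal(ctx, purpose, length(v))
  fx_add(v$s0, v$s1, ctx$field$p)
}

#' Reveal a shared value
#'
#' Jointly reconstructs the secrets and maps them to the signed range.  Every
#' reveal is recorded in the session transcript under its purpose.
#'
#' @param ctx an [mpc_session()].
#' @param v a `shared_value`.
#' @param purpose transcript label; designated outputs use `"output"`.
#' @param as_numeric return numerics (errors if a value exceeds 2^53)?
#' @return numeric (default) or character vector of the secrets.
#' @export
mpc_reveal <- function(ctx, v, purpose = "output", as_numeric = TRUE) {
  out <- fx_to_signed_str(open_raw(ctx, v, purpose), ctx$field$p)
  if (as_numeric) bn_as_numeric(out) else out
}

#' Linear gates: addition, subtraction, constants
#'
#' Local operations on shares; no interaction, no preprocessing.
#' @param u,v `shared_value`s over the same field.
#' @param c public integer constant(s) (numeric or decimal character).
#' @return a `shared_value`.
#' @export
mpc_add <- function(u, v) {
  sv_check2(u, v)
  new_sv(fx_add(u$s0, v$s0, u$field$p), fx_add(u$s1, v$s1, u$field$p), u$field)
}

#' @rdname mpc_add
#' @export
mpc_sub <- function(u, v) {
  sv_check2(u, v)
  new_sv(fx_sub(u$s0, v$s0, u$field$p), fx_sub(u$s1, v$s1, u$field$p), u$field)
}

#' @rdname mpc_add
#' @export
mpc_add_const <- function(u, c) {
  new_sv(fx_addc(u$s0, as_bn(c), u$field$p), u$s1, u$field)
}

#' @rdname mpc_add
#' @export
mpc_mul_const <- function(u, c) {
  c <- as_bn(c)
  new_sv(fx_mulc(u$s0, c, u$field$p), fx_mulc(u$s1, c, u$field$p), u$field)
}

#' @rdname mpc_add
#' @export
mpc_neg <- function(u) {
  new_sv(fx_rsubc("0", u$s0, u$field$p), fx_rsubc("0", u$s1, u$field$p), u$field)
}

# 1 - u, local
one_minus <- function(u) {
  new_sv(fx_rsubc("1", u$s0, u$field$p), fx_rsubc("0", u$s1, u$field$p), u$field)
}

# add a public limb matrix (already a residue matrix) to party 0's share
add_pub <- function(u, pub) {
  new_sv(fx_add(u$s0, pub, u$field$p), u$s1, u$field)
}

#' Secure multiplication (Beaver triple)
#'
#' Consumes one preprocessed triple per element.  The parties open the two
#' uniformly masked differences `d = u - a` and `e = v - b` (recorded in the
#' transcript as `masked`) and locally assemble shares of the product.
#'
#' @param ctx an [mpc_session()].
#' @param u,v `shared_value`s of equal length (or length 1, recycled).
#' @return a `shared_value` with `reveal(out) = reveal(u) * reveal(v) mod p`.
#' @export
mpc_mul <- function(ctx, u, v) {
  sv_check2(u, v)
  n <- max(length(u), length(v))
  if (length(u) != n) u <- sv_rep(u, length.out = n)
  if (length(v) != n) v <- sv_rep(v, length.out = n)
  p <- ctx$field$p
  tr <- draw_triples(ctx, n)
  trace_event(ctx, "mul", n)
  a <- new_sv(tr$a0, tr$a1, ctx$field)
  b <- new_sv(tr$b0, tr$b1, ctx$field)
  d <- open_raw(ctx, mpc_sub(u, a), "masked")
  e <- open_raw(ctx, mpc_sub(v, b), "masked")
  de <- fx_mul(d, e, p)
  s0 <- fx_add(fx_add(tr$c0, fx_mul(d, tr$b0, p), p),
               fx_add(fx_mul(e, tr$a0, p), de, p), p)
  s1 <- fx_add(fx_add(tr$c1, fx_mul(d, tr$b1, p), p),
               fx_mul(e, tr$a1, p), p)
  new_sv(s0, s1, ctx$field)
}

# public-bits vs shared-bits comparison: shared bit (c < r) where c is a
# public n x bits 0/1 matrix and rbits the n*bits-row shared bit block
bitlt_pub_shared <- function(ctx, cbits, rb_s0, rb_s1) {
  p <- ctx$field$p
  field <- ctx$field
  bits <- ncol(cbits)
  n <- nrow(cbits)
  # d_i = c_i XOR r_i, local since c is public
  d <- vector("list", bits)
  rbit <- function(i) {
    idx <- ((i - 1L) * n + 1L):(i * n)
    new_sv(rb_s0[idx, , drop = FALSE], rb_s1[idx, , drop = FALSE], field)
  }
  for (i in seq_len(bits)) {
    ci <- cbits[, i]
    r <- rbit(i)
    d[[i]] <- new_sv(fx_select_csub(ci, r$s0, "1", p),
                     fx_select_csub(ci, r$s1, "0", p), field)
  }
  # prefix OR from the most significant bit; g marks the first difference
  g <- vector("list", bits)
  f <- d[[bits]]
  g[[bits]] <- d[[bits]]
  if (bits >= 2) {
    for (i in seq(bits - 1L, 1L)) {
      fd <- mpc_mul(ctx, f, d[[i]])
      fnew <- mpc_sub(mpc_add(f, d[[i]]), fd)
      g[[i]] <- mpc_sub(fnew, f)
      f <- fnew
    }
  }
  # result = sum_i g_i * r_i  (r_i > c_i at the first differing index)
  gall <- do.call(sv_cat, g)
  rall <- new_sv(rb_s0, rb_s1, field)
  prod <- mpc_mul(ctx, gall, rall)
  grp <- rep(seq_len(n), bits)
  new_sv(fx_grouped_sum(prod$s0, grp, n, p), fx_grouped_sum(prod$s1, grp, n, p), field)
}

#' Secure comparison: shared bit for `u < v`
#'
#' Both secrets must lie in \eqn{[-2^{bits-1}, 2^{bits-1})}; this is a caller
#' contract (the circuit planner supplies per-wire bounds).  The difference is
#' shifted to \eqn{z = u - v + 2^{bits} \in (0, 2^{bits+1})} and the bit at
#' position `bits` of `z` is extracted: the parties open the statistically
#' masked value \eqn{z + r' + 2^{bits} r''} (dealer-supplied \eqn{r'} with
#' shared bit decomposition, \eqn{r''} uniform with `kappa` bits), reduce the
#' public part mod \eqn{2^{bits}}, and resolve the borrow with a shared-bit
#' less-than circuit.  Costs `2*bits - 1` Beaver triples, `bits` shared random
#' bits and one masking block per element.
#'
#' @param ctx an [mpc_session()].
#' @param u,v `shared_value`s (equal length or length 1).
#' @param bits comparison bit-length; defaults to the field's `ell`.
#'   Requires `2^(bits + kappa + 2) <= p`.
#' @return a `shared_value` holding 0/1 secrets.
#' @export
mpc_lt <- function(ctx, u, v, bits = ctx$field$ell) {
  sv_check2(u, v)
  bits <- as.integer(bits)
  field <- ctx$field
  if (bits < 1L) stop("bits must be >= 1")
  if (bits + field$kappa + 2L > field$bitlen ||
      bn_cmp(two_pow_chr(bits + field$kappa + 2L), field$p) > 0) {
    stop(sprintf("comparison bit-length %d exceeds field headroom", bits))
  }
  n <- max(length(u), length(v))
  if (length(u) != n) u <- sv_rep(u, length.out = n)
  if (length(v) != n) v <- sv_rep(v, length.out = n)
  trace_event(ctx, "lt", n, bits)
  p <- field$p
  pow_m <- two_pow_chr(bits)
  z <- mpc_add_const(mpc_sub(u, v), pow_m)
  # dealer material: bit-decomposed r' and kappa-bit r''
  bs <- draw_bit_shares(ctx, n * bits)
  rp <- new_sv(fx_wsum_pow2(bs$s0, n, bits, p), fx_wsum_pow2(bs$s1, n, bits, p), field)
  rpp <- draw_pow2_shares(ctx, n, field$kappa)
  mask <- mpc_add(mpc_add(z, rp), mpc_mul_const(new_sv(rpp$s0, rpp$s1, field), pow_m))
  cpub <- open_raw(ctx, mask, "masked") # true integer: no wrap by headroom
  low <- fx_lowbits(cpub, bits)
  borrow <- bitlt_pub_shared(ctx, low$bits, bs$s0, bs$s1)
  # z mod 2^bits = c' - r' + 2^bits * borrow
  zmod <- add_pub(mpc_sub(mpc_mul_const(borrow, pow_m), rp), low$low)
  bit <- mpc_mul_const(mpc_sub(z, zmod), inv_two_pow(ctx, bits))
  one_minus(bit) # u < v  <=>  z < 2^bits  <=>  high bit 0
}

#' Derived comparison gates
#'
#' `mpc_ge` is `1 - lt(u, v)`; `mpc_eq` composes two comparisons and one
#' multiplication; `mpc_smin`/`mpc_smax` compute `a*eps + b*(1-eps)` (and its
#' mirror) from a single comparison bit `eps = (a < b)`.
#' @inheritParams mpc_lt
#' @param a,b `shared_value`s (equal length or length 1).
#' @return a `shared_value`.
#' @export
mpc_ge <- function(ctx, u, v, bits = ctx$field$ell) {
  one_minus(mpc_lt(ctx, u, v, bits))
}

#' @rdname mpc_ge
#' @export
mpc_eq <- function(ctx, u, v, bits = ctx$field$ell) {
  n <- max(length(u), length(v))
  if (length(u) != n) u <- sv_rep(u, length.out = n)
  if (length(v) != n) v <- sv_rep(v, length.out = n)
  both <- mpc_lt(ctx, sv_cat(u, v), sv_cat(v, u), bits)
  lt_uv <- sv_slice(both, seq_len(n))
  lt_vu <- sv_slice(both, n + seq_len(n))
  mpc_mul(ctx, one_minus(lt_uv), one_minus(lt_vu))
}

#' @rdname mpc_ge
#' @export
mpc_smin <- function(ctx, a, b, bits = ctx$field$ell) {
  n <- max(length(a), length(b))
  if (length(a) != n) a <- sv_rep(a, length.out = n)
  if (length(b) != n) b <- sv_rep(b, length.out = n)
  eps <- mpc_lt(ctx, a, b, bits)
  prods <- mpc_mul(ctx, sv_cat(a, b), sv_cat(eps, one_minus(eps)))
  mpc_add(sv_slice(prods, seq_len(n)), sv_slice(prods, n + seq_len(n)))
}

#' @rdname mpc_ge
#' @export
mpc_smax <- function(ctx, a, b, bits = ctx$field$ell) {
  n <- max(length(a), length(b))
  if (length(a) != n) a <- sv_rep(a, length.out = n)
  if (length(b) != n) b <- sv_rep(b, length.out = n)
  eps <- mpc_lt(ctx, a, b, bits)
  prods <- mpc_mul(ctx, sv_cat(b, a), sv_cat(eps, one_minus(eps)))
  mpc_add(sv_slice(prods, seq_len(n)), sv_slice(prods, n + seq_len(n)))
}

#' Randomised zero test
#'
#' Multiplies the shared value by a dealer-supplied uniform nonzero element
#' and opens the product: the opening is 0 iff the secret is 0, and uniform
#' on the nonzero field elements otherwise, so exactly one bit is revealed.
#' @param ctx an [mpc_session()].
#' @param v a `shared_value`.
#' @return logical vector: secret equal to zero?
#' @export
mpc_is_zero <- function(ctx, v) {
  n <- length(v)
  nz <- draw_nonzero_shares(ctx, n)
  t <- mpc_mul(ctx, v, new_sv(nz$s0, nz$s1, ctx$field))
  fx_is_zero(open_raw(ctx, t, "zero_test"))
}
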