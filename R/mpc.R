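#' Open a two-party computation session
#'
#' A session bundles the field, the trusted dealer's deterministic randomness
#' stream, consumption counters for preprocessed material (Beaver triples,
#' bit-decomposed comparison masks), a gate-invocation trace, and a log of
#' every opened value.  The two parties are simulated in-process: shares are
#' held in parallel vectors and the *only* way information crosses between
#' them is through [mpc_reveal()] / the internal masked openings, all of which
#' are recorded in the transcript.  The model is semi-honest with a trusted
#' dealer; it reproduces share-compute-reveal semantics and gate contracts,
#' not the MAC-checked malicious security of a full SPDZ deployment.
#'
#' @param field a [field_spec()].
#' @param seed integer seed; all dealer and sharing randomness is a
#'   deterministic function of it (counter-mode PRNG, independent of R's RNG).
#' @return an environment of class `mpc_session`.
#' @export
mpc_session <- function(field = field_mersenne127(), seed = 1) {
  stopifnot(inherits(field, "field_spec"))
  ctx <- new.env(parent = emptyenv())
  ctx$field <- field
  ctx$key <- as.numeric(seed) %% 2^53
  ctx$ctr <- 0
  ctx$counters <- list(
    triples = 0, rand_bits = 0, pow2_masks = 0, nonzero_masks = 0,
    input_shares = 0
  )
  ctx$trace <- list()
  ctx$reveals <- list()
  ctx$inv2_cache <- list()
  class(ctx) <- c("mpc_session", "environment")
  ctx
}

#' @export
print.mpc_session <- function(x, ...) {
  cat("<mpc_session> field:", x$field$bitlen, "bits;",
      "triples used:", x$counters$triples,
      "| mask bits:", x$counters$rand_bits,
      "| gate events:", length(x$trace), "\n")
  invisible(x)
}

bump <- function(ctx, what, n) {
  ctx$counters[[what]] <- ctx$counters[[what]] + n
  invisible(NULL)
}

trace_event <- function(ctx, op, n, bits = NA_integer_) {
  ctx$trace[[length(ctx$trace) + 1L]] <- list(op = op, n = as.integer(n),
                                              bits = as.integer(bits))
  invisible(NULL)
}

log_reveal <- function(ctx, purpose, n) {
  ctx$reveals[[length(ctx$reveals) + 1L]] <- list(purpose = purpose, n = as.integer(n))
  invisible(NULL)
}

# advance the dealer counter and return its previous value
take_ctr <- function(ctx, n) {
  c0 <- ctx$ctr
  ctx$ctr <- ctx$ctr + n
  c0
}

#' Gate-invocation trace of a session
#'
#' The sequence of gate kinds and batch sizes executed so far.  For an
#' oblivious circuit this sequence is a function of public shape parameters
#' only, never of secret values.
#' @param ctx an `mpc_session`.
#' @return data.frame with columns `op`, `n`, `bits`.
#' @export
gate_trace <- function(ctx) {
  if (length(ctx$trace) == 0) {
    return(data.frame(op = character(), n = integer(), bits = integer()))
  }
  data.frame(
    op = vapply(ctx$trace, `[[`, "", "op"),
    n = vapply(ctx$trace, `[[`, 0L, "n"),
    bits = vapply(ctx$trace, `[[`, 0L, "bits")
  )
}

#' Log of opened (revealed) values
#'
#' Every reconstruction performed during the session: uniformly masked
#' openings inside multiplication/comparison subprotocols (`masked`), the
#' randomised zero-test opening of the convergence check (`zero_test`), and
#' designated outputs (`output`).
#' @param ctx an `mpc_session`.
#' @return data.frame with columns `purpose`, `n`.
#' @export
reveal_log <- function(ctx) {
  if (length(ctx$reveals) == 0) {
    return(data.frame(purpose = character(), n = integer()))
  }
  data.frame(
    purpose = vapply(ctx$reveals, `[[`, "", "purpose"),
    n = vapply(ctx$reveals, `[[`, 0L, "n")
  )
}

#' Preprocessing consumption counters
#'
#' @param ctx an `mpc_session`.
#' @return named list: Beaver `triples`, shared random `rand_bits`,
#'   `pow2_masks` (statistical masks for comparisons), `nonzero_masks`
#'   (zero-test masks) and `input_shares`.
#' @export
dealer_stats <- function(ctx) ctx$counters

# ---- dealer draws (all deterministic in (key, ctr)) -----------------------

draw_triples <- function(ctx, n) {
  c0 <- take_ctr(ctx, n)
  bump(ctx, "triples", n)
  dealer2_triples(ctx$key, c0, as.integer(n), ctx$field$p)
}

draw_bit_shares <- function(ctx, n) {
  c0 <- take_ctr(ctx, n)
  bump(ctx, "rand_bits", n)
  dealer2_bits(ctx$key, c0, as.integer(n), ctx$field$p)
}

draw_pow2_shares <- function(ctx, n, bits) {
  c0 <- take_ctr(ctx, n)
  bump(ctx, "pow2_masks", n)
  dealer2_pow2(ctx$key, c0, as.integer(n), as.integer(bits), ctx$field$p)
}

draw_nonzero_shares <- function(ctx, n) {
  c0 <- take_ctr(ctx, n)
  bump(ctx, "nonzero_masks", n)
  dealer2_nonzero(ctx$key, c0, as.integer(n), ctx$field$p)
}

draw_share0 <- function(ctx, n) {
  c0 <- take_ctr(ctx, n)
  rng2_field(ctx$key, c0, as.integer(n), ctx$field$p)
}

# modular inverse of 2^bits (cached); p odd so inv(2) = (p+1)/2
inv_two_pow <- function(ctx, bits) {
  key <- as.character(bits)
  if (is.null(ctx$inv2_cache[[key]])) {
    inv2 <- bn_div(bn_add(ctx$field$p, "1"), "2")
    ctx$inv2_cache[[key]] <- fp_pow_ui(inv2, as.integer(bits), ctx$field$p)
  }
  ctx$inv2_cache[[key]]
}
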