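#' Prime-field parameters for the secret-sharing layer
#'
#' Secrets are integers in the symmetric range \eqn{[-M, M]} embedded into the
#' field \eqn{F_p} (with \eqn{2M < p}) as residues; negative values map to the
#' upper half of the field.  Comparison gates additionally require statistical
#' masking headroom: with comparison bit-length \eqn{\ell} and statistical
#' security \eqn{\kappa}, the masked opening must not wrap, which needs
#' \eqn{\ell + \kappa + 2 \le} bitlength(p).
#'
#' @param p prime modulus, as a decimal character string (or exact numeric).
#' @param kappa statistical security parameter in bits (masking slack of the
#'   comparison protocol).
#' @param ell default comparison bit-length: callers of comparison gates must
#'   guarantee their secrets lie in \eqn{[-2^{\ell-1}, 2^{\ell-1})}.
#' @param signed_bound bound \eqn{M} of the signed embedding; defaults to
#'   \eqn{(p-1)/2} (the full symmetric range).
#' @return an object of class `field_spec`.
#' @examples
#' f <- field_spec(p = "101", kappa = 1, ell = 3)
#' f$bitlen
#' @export
field_spec <- function(p, kappa = 40, ell = NULL, signed_bound = NULL) {
  p <- as_bn(p)
  if (bn_cmp(p, "3") < 0) stop("modulus too small")
  bitlen <- bn_bitlen(p)
  if (is.null(ell)) ell <- max(2L, bitlen - as.integer(kappa) - 2L)
  ell <- as.integer(ell)
  kappa <- as.integer(kappa)
  if (ell < 1L || kappa < 0L) stop("invalid comparison parameters")
  if (ell + kappa + 2L > bitlen || bn_cmp(two_pow_chr(ell + kappa + 2L), p) > 0) {
    stop(sprintf(
      "field headroom violated: need 2^(ell + kappa + 2) <= p, got ell = %d, kappa = %d, bitlength(p) = %d",
      ell, kappa, bitlen
    ))
  }
  half <- bn_div(bn_sub(p, "1"), "2")
  if (is.null(signed_bound)) signed_bound <- half
  signed_bound <- as_bn(signed_bound)
  if (bn_cmp(bn_mul("2", signed_bound), p) >= 0) stop("signed bound must satisfy 2M < p")
  structure(
    list(p = p, kappa = kappa, ell = ell, bitlen = bitlen,
         signed_bound = signed_bound, half = half),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> p with", x$bitlen, "bits; kappa =", x$kappa,
      "; comparison bits ell =", x$ell, "\n")
  invisible(x)
}

#' Default production field: the Mersenne prime 2^127 - 1
#'
#' Leaves 84 bits of comparison range at 40-bit statistical security, enough
#' for several k-means rounds of denominator growth without any in-protocol
#' fraction reduction.
#' @export
field_mersenne127 <- function() {
  field_spec(p = "170141183460469231731687303715884105727", kappa = 40, ell = 84)
}

#' 64-bit field preset (p = 2^64 - 59)
#'
#' Matches the field size used in the original two-party deployment this
#' package models.  At 40-bit statistical security only 21 bits remain for
#' comparison inputs, so realistic clustering circuits are rejected by
#' [plan_budget()]; the preset is retained for small demonstrations and for
#' documenting that limitation.
#' @export
field_paper64 <- function() {
  field_spec(p = "18446744073709551557", kappa = 40, ell = 21)
}
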