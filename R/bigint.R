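# R-side conveniences over the exact-integer kernel in src/bignum.cpp.
# Big integers travel as decimal character vectors; numerics are accepted
# anywhere provided they are exact integers below 2^53.

#' Coerce to exact-integer (decimal string) representation
#'
#' @param x character vector of decimal integers, or numeric vector of exact
#'   integer values (|x| < 2^53).
#' @return character vector.
#' @keywords internal
as_bn <- function(x) {
  if (is.character(x)) return(x)
  if (!is.numeric(x)) stop("cannot coerce to big integer: ", class(x)[1])
  if (any(!is.finite(x)) || any(x != trunc(x)) || any(abs(x) >= 2^53)) {
    stop("numeric values must be exact integers below 2^53")
  }
  out <- sprintf("%.0f", x)
  out[x == 0] <- "0"
  out
}

#' Convert small big integers back to numeric
#'
#' Errors if any value does not fit exactly in a double.
#' @keywords internal
bn_as_numeric <- function(x) {
  big <- nchar(sub("^-", "", x)) > 15
  if (any(big)) stop("value too large for exact numeric conversion: ", x[which(big)[1]])
  as.numeric(x)
}

# 2^k as a decimal string (memoised)
two_pow_chr <- local({
  cache <- new.env(parent = emptyenv())
  function(k) {
    k <- as.integer(k)
    key <- as.character(k)
    if (is.null(cache[[key]])) cache[[key]] <- bn_two_pow(k)
    cache[[key]]
  }
})

# smallest l such that values with |v| <= maxabs satisfy |v| < 2^(l-1)
bits_for <- function(maxabs) {
  maxabs <- as_bn(maxabs)
  if (bn_cmp(maxabs, "0") < 0) stop("bound must be non-negative")
  if (maxabs == "0") return(2L)
  bn_bitlen(maxabs) + 1L
}

# exact gcd of a vector of big integers
bn_gcd_reduce <- function(x) {
  Reduce(function(a, b) bn_gcd(a, b), x, accumulate = FALSE)
}

# ---- exact rationals (num/den pairs of decimal strings), internal ---------

rat <- function(num, den = "1") {
  den <- as_bn(den)
  if (any(bn_cmp(den, "0") <= 0)) stop("rational denominator must be positive")
  list(num = as_bn(num), den = den)
}

rat_add <- function(a, b) {
  rat(bn_add(bn_mul(a$num, b$den), bn_mul(b$num, a$den)), bn_mul(a$den, b$den))
}

# sign of a - b
rat_cmp <- function(a, b) {
  bn_cmp(bn_mul(a$num, b$den), bn_mul(b$num, a$den))
}
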