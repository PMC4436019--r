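#' Order-of-magnitude-marker encoding
#'
#' Decomposes a non-negative magnitude v into scientific notation
#' A x 10^B with the mantissa A (a real) and the exponent B (an integer),
#' both displayed on linear 0-10 scales: the exponent on a wide bar, the
#' mantissa on a narrow bar. 99 encodes as 9.9 x 10^1: wide bar at 1,
#' narrow bar at 9.9, so both large and small magnitudes stay legible on
#' one pair of short bars.
#'
#' Values in (0, 1) keep exponent 0 with the mantissa equal to the value
#' (negative exponents are not representable on the 0-10 scale but the
#' round trip is preserved). Values at or above 10^11 saturate: both bars
#' clamp to 10 and the encoding is flagged, rather than silently decoding
#' to a wrong magnitude.
#'
#' @param v Numeric vector of non-negative finite values.
#' @return A tibble with columns `mantissa` (in \[0, 10\]), `exponent`
#'   (integer in \[0, 10\]) and `saturated` (logical).
#' @examples
#' oomm_encode(99) # mantissa 9.9, exponent 1
#' @export
oomm_encode <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
    value_abort("OOMM values must be finite and non-negative")
  }
  mantissa <- numeric(length(v))
  exponent <- integer(length(v))
  sub1 <- v > 0 & v < 1
  mantissa[sub1] <- v[sub1]
  big <- v >= 1
  if (any(big)) {
    b <- floor(log10(v[big]))
    a <- v[big] / 10^b
    # guard floating-point log10 at power boundaries
    roll <- a >= 10
    b[roll] <- b[roll] + 1
    a[roll] <- a[roll] / 10
    under <- a < 1
    b[under] <- b[under] - 1
    a[under] <- a[under] * 10
    mantissa[big] <- a
    exponent[big] <- as.integer(b)
  }
  saturated <- exponent > 10L
  mantissa[saturated] <- 10
  exponent[saturated] <- 10L
  tibble(mantissa = mantissa, exponent = exponent, saturated = saturated)
}

#' Decode an OOMM encoding back to its magnitude
#'
#' @param e A tibble from [oomm_encode()]. Saturated encodings cannot be
#'   decoded (the magnitude was clamped away) and raise an error.
#' @return Numeric vector of magnitudes `mantissa * 10^exponent`.
#' @export
oomm_decode <- function(e) {
  if (any(e$saturated)) {
    value_abort("cannot decode a saturated OOMM encoding (information lost)")
  }
  e$mantissa * 10^e$exponent
}

#' Bar lengths for an OOMM encoding
#'
#' The exponent is drawn on the wide bar and the mantissa on the narrow bar,
#' both scaled linearly by `unit`; neither exceeds `10 * unit`.
#'
#' @inheritParams oomm_decode
#' @param unit Positive length of one scale unit.
#' @return A tibble with columns `wide` and `narrow`.
#' @examples
#' oomm_bar_lengths(oomm_encode(99), unit = 1) # wide 1, narrow 9.9
#' @export
oomm_bar_lengths <- function(e, unit = 1) {
  if (!is.numeric(unit) || length(unit) != 1L || unit <= 0) {
    value_abort("unit must be a single positive number")
  }
  tibble(wide = e$exponent * unit, narrow = e$mantissa * unit)
}
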