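#' Hill activation kernel
#'
#' Shared saturating kernel for every regulatory link in the feedback circuit:
#' `hill(x, K, n) = x^n / (x^n + K^n)`, a fraction in `[0, 1]` that is
#' monotone increasing in `x` with half-maximum at `x = K` and steepness `n`.
#'
#' The kernel is evaluated as `1 / (1 + (K/x)^n)`, which is safe against
#' intermediate overflow when `x` and `K` differ by many orders of magnitude
#' (important for the steep oxygen sensor, where `n` can be large).
#'
#' @param x Non-negative input (scalar or vector).
#' @param K Positive half-maximum constant.
#' @param n Positive Hill coefficient.
#' @return Fraction(s) in `[0, 1]`.
#' @examples
#' hill(2, 2, 4)        # 0.5 at the half-max point
#' hill(0, 1, 2)        # 0 at zero input
#' @export
hill <- function(x, K, n) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a single positive number", call. = FALSE)
  if (any(x < 0, na.rm = TRUE))
    stop("'x' must be non-negative", call. = FALSE)
  ifelse(x > 0, 1 / (1 + (K / x)^n), 0)
}

#' Epo-dependent net proliferation rate of erythroid progenitors
#'
#' `gmin + delta_g * hill(E, Ka, na)`: an Epo-independent floor plus a
#' saturable Epo-dependent increment, bounded in
#' `[gmin, gmin + delta_g]` per day.
#'
#' @param E Epo level (non-negative).
#' @param params An [erythro_params()] object.
#' @return Net proliferation rate, per day.
#' @export
proliferation_rate <- function(E, params) {
  params <- as_erythro_params(params)
  if (any(E < 0, na.rm = TRUE)) stop("'E' must be non-negative", call. = FALSE)
  params$gmin + params$delta_g * hill(E, params$Ka, params$na)
}

#' Epo-dependent ProE survival fraction
#'
#' Fraction of the ProE flux that escapes apoptosis and matures into red
#' blood cells: `hill(E, Ks, ns)`. At low Epo most ProE die; at saturating
#' Epo essentially all survive. Its reciprocal at the normoxic steady state
#' is the over-production cost of the circuit.
#'
#' @inheritParams proliferation_rate
#' @return Survival fraction in `[0, 1]`.
#' @export
proe_survival <- function(E, params) {
  params <- as_erythro_params(params)
  if (any(E < 0, na.rm = TRUE)) stop("'E' must be non-negative", call. = FALSE)
  hill(E, params$Ks, params$ns)
}
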