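#' Polynomial rate functions
#'
#' Every state-dependent rate in a structured model (`r`, `rho`, `d`, `e`,
#' `b`, `w`) is a polynomial in the state index `j`, represented as a plain
#' numeric vector of coefficients ascending in power: `coeffs[alpha + 1]`
#' multiplies `j^alpha`.  The zero polynomial is the empty vector
#' (`numeric(0)`) and has no degree (`poly_degree()` returns `NA`).
#' Evaluation uses the convention `0^0 = 1`, so that a constant polynomial
#' takes its constant value at `j = 0`.
#'
#' @param coeffs Numeric vector of coefficients, ascending in power of `j`.
#' @param j Integer (or numeric) state indices at which to evaluate.
#' @return `poly_eval()` returns the values of the polynomial at `j`;
#'   `poly_degree()` the degree (index of the last nonzero coefficient), or
#'   `NA_integer_` for the zero polynomial; `poly_trim()` the coefficient
#'   vector with trailing zeros removed; `poly_is_zero()` a logical.
#' @examples
#' poly_eval(c(3, 5), 0)      # 3: the constant term, via 0^0 = 1
#' poly_eval(c(0, 0, 1), 4)   # 16: j^2
#' poly_degree(numeric(0))    # NA: the zero polynomial
#' @export
poly_eval <- function(coeffs, j) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) == 0L) {
    return(rep(0, length(j)))
  }
  powers <- seq_along(coeffs) - 1
  # R evaluates 0^0 as 1, matching the convention used for moments
  vapply(j, function(jj) sum(coeffs * jj^powers), numeric(1))
}

#' @rdname poly_eval
#' @export
poly_degree <- function(coeffs) {
  coeffs <- poly_trim(coeffs)
  if (length(coeffs) == 0L) {
    return(NA_integer_)
  }
  length(coeffs) - 1L
}

#' @rdname poly_eval
#' @export
poly_trim <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  nz <- which(coeffs != 0)
  if (length(nz) == 0L) {
    return(numeric(0))
  }
  coeffs[seq_len(max(nz))]
}

#' @rdname poly_eval
#' @export
poly_is_zero <- function(coeffs) {
  length(poly_trim(coeffs)) == 0L
}

#' Multiply two coefficient vectors (polynomial product)
#'
#' @param a,b Numeric coefficient vectors, ascending in power.
#' @return The coefficient vector of the product polynomial.
#' @export
poly_mul <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    return(numeric(0))
  }
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}
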