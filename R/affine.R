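#' Affine expressions in the population moments
#'
#' The coefficients that appear in the derived moment equations are not
#' always plain numbers: when the burden weighting `b` is state-dependent,
#' the kinetic coefficients carry terms proportional to the moments
#' `mu_0, ..., mu_deg(b)`.  An affine moment expression represents
#' `const + sum_m linear[m] * mu_m` with finitely many nonzero linear
#' coefficients.  Products of such coefficients with the moment they
#' multiply make the derived moment equations at most bilinear, which is
#' sufficient for every polynomial-kinetics model handled here.
#'
#' @param const Numeric scalar, the moment-independent part.
#' @param linear Named numeric vector; names are moment indices (as
#'   integers coerced to character), values the coefficients on those
#'   moments.
#' @return An object of class `moment_affine`.
#' @examples
#' a <- affine_expr(2, c("1" = -0.5)) # 2 - 0.5 * mu_1
#' affine_eval(a, c(1, 4))            # evaluated at mu_0 = 1, mu_1 = 4
#' @export
affine_expr <- function(const = 0, linear = numeric(0)) {
  stopifnot(is.numeric(const), length(const) == 1L)
  linear <- affine_normalise_linear(linear)
  structure(list(const = as.numeric(const), linear = linear),
            class = "moment_affine")
}

affine_normalise_linear <- function(linear) {
  if (length(linear) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stopifnot(is.numeric(linear), !is.null(names(linear)))
  idx <- as.integer(names(linear))
  agg <- tapply(as.numeric(linear), idx, sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out <- out[out != 0]
  ord <- order(as.integer(names(out)))
  out[ord]
}

#' @rdname affine_expr
#' @param x A `moment_affine` object or a numeric scalar to promote.
#' @export
as_affine <- function(x) {
  if (inherits(x, "moment_affine")) {
    return(x)
  }
  affine_expr(const = x)
}

affine_add <- function(a, b) {
  a <- as_affine(a)
  b <- as_affine(b)
  affine_expr(a$const + b$const, c(a$linear, b$linear))
}

affine_scale <- function(a, s) {
  a <- as_affine(a)
  affine_expr(a$const * s, a$linear * s)
}

#' @rdname affine_expr
#' @param a A `moment_affine` object (or numeric scalar).
#' @param mu Numeric vector of moments, `mu[m + 1]` holding the moment of
#'   order `m`.
#' @export
affine_eval <- function(a, mu) {
  a <- as_affine(a)
  if (length(a$linear) == 0L) {
    return(a$const)
  }
  idx <- as.integer(names(a$linear))
  if (max(idx) + 1L > length(mu)) {
    stop("affine expression references moment index ", max(idx),
         " but only moments up to order ", length(mu) - 1L,
         " were supplied", call. = FALSE)
  }
  a$const + sum(a$linear * mu[idx + 1L])
}

affine_magnitude <- function(a) {
  a <- as_affine(a)
  abs(a$const) + sum(abs(a$linear))
}

affine_is_zero <- function(a, tol = 0) {
  affine_magnitude(a) <= tol
}

#' @export
format.moment_affine <- function(x, digits = 6, ...) {
  pieces <- character(0)
  if (x$const != 0 || length(x$linear) == 0L) {
    pieces <- format(x$const, digits = digits)
  }
  for (i in seq_along(x$linear)) {
    co <- x$linear[i]
    term <- paste0(format(abs(co), digits = digits), "*mu", names(x$linear)[i])
    pieces <- c(pieces, if (co < 0) paste0("- ", term) else
      if (length(pieces)) paste0("+ ", term) else term)
  }
  paste(pieces, collapse = " ")
}

#' @export
print.moment_affine <- function(x, ...) {
  cat("<moment-affine> ", format(x, ...), "\n", sep = "")
  invisible(x)
}

affine_to_list <- function(a) {
  a <- as_affine(a)
  list(const = a$const, linear = as.list(a$linear))
}
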