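#' Moments of a population state
#'
#' The moment of order `k` is `mu_k = sum_j j^k u_j` (with `0^0 = 1`, so
#' `mu_0` counts every individual including those in state 0).  `mu_0` is
#' the total population and `mu_1 / mu_0` the mean state.
#'
#' @param u Numeric state vector, `u[j + 1]` the subpopulation in state `j`.
#' @param K Highest moment order to compute (`K >= 0`).
#' @return Numeric vector `mu` of length `K + 1`, `mu[k + 1] = mu_k`.
#' @examples
#' moments_from_state(c(1, 2, 3), K = 2)  # c(6, 8, 14)
#' @export
moments_from_state <- function(u, K) {
  u <- as.numeric(u)
  K <- as.integer(K)
  if (is.na(K) || K < 0L) {
    stop("K must be a non-negative integer", call. = FALSE)
  }
  grid <- seq_along(u) - 1
  vapply(0:K, function(k) sum(grid^k * u), numeric(1))
}

#' Invert the moment map (trivial closure)
#'
#' The moments of order `0..N` determine the state uniquely through the
#' Vandermonde relation `V^T u = mu` with `V[a, b] = a^b` on the nodes
#' `a = 0, ..., N`.  Because this matrix is notoriously ill-conditioned,
#' the solve uses the Björck–Pereyra recurrences for transposed
#' Vandermonde systems, which exploit the node structure and deliver far
#' better componentwise accuracy than a generic LU solve (round-trip error
#' below 1e-8 up to `N = 10`; by `N = 12` the double-precision moments
#' themselves limit any solver to about 1e-7).
#'
#' @param mu Numeric vector of all `N + 1` moments of order `0..N`.
#' @param N Integer; number of states minus one.
#' @return The unique state vector `u` with these moments.
#' @examples
#' state_from_moments(c(6, 8, 14), N = 2)  # c(1, 2, 3)
#' @export
state_from_moments <- function(mu, N) {
  mu <- as.numeric(mu)
  N <- as.integer(N)
  if (length(mu) != N + 1L) {
    stop("the trivial closure needs all ", N + 1L,
         " moments of order 0..", N, "; received ", length(mu),
         call. = FALSE)
  }
  u <- vandermonde_dual_solve(0:N, mu)
  err_bound <- vandermonde_error_bound(N, mu)
  if (err_bound > 1e-3 * max(1e-300, max(abs(u)))) {
    stop("conditioning failure: the moment-to-state map at N = ", N,
         " amplifies rounding in the moments beyond usable accuracy ",
         "(estimated relative error ",
         format(err_bound / max(1e-300, max(abs(u))), digits = 3), ")",
         call. = FALSE)
  }
  u
}

# Björck–Pereyra solve of sum_a x_a^beta u_a = f_beta for u, nodes x.
vandermonde_dual_solve <- function(x, f) {
  n <- length(f) - 1L
  b <- as.numeric(f)
  if (n == 0L) {
    return(b)
  }
  for (k in 0:(n - 1L)) {
    for (i in n:(k + 1L)) {
      b[i + 1L] <- b[i + 1L] - x[k + 1L] * b[i]
    }
  }
  for (k in (n - 1L):0) {
    for (i in (k + 1L):n) {
      b[i + 1L] <- b[i + 1L] / (x[i + 1L] - x[i - k])
    }
    for (i in k:(n - 1L)) {
      b[i + 1L] <- b[i + 1L] - b[i + 2L]
    }
  }
  b
}

# Componentwise error amplification of the inverse map: the solution is
# u_a = sum_g c_{a g} mu_g with c the Lagrange-basis coefficients on the
# nodes 0..N, so rounding |dmu| <= eps |mu| yields |du| <= eps |c| |mu|.
vandermonde_error_bound <- function(N, mu) {
  amp <- 0
  for (a in 0:N) {
    num <- 1
    denom <- 1
    for (m in 0:N) {
      if (m != a) {
        num <- poly_mul(num, c(-m, 1))
        denom <- denom * (a - m)
      }
    }
    amp <- max(amp, sum(abs(num / denom) * abs(mu)))
  }
  .Machine$double.eps * amp
}

#' Flux contribution coefficients for the moment equations
#'
#' Shifting the summation index in `sum_j j^k J_j` (legitimate because
#' `w(-1) = w(N) = 0`) turns the flux contribution to the `k`-th moment
#' equation into `sum_j [(j+1)^k - j^k] w(j) u_j`.  The coefficients of
#' the polynomial `[(j+1)^k - j^k] w(j)` are the convolution
#' `phi_{k, beta} = sum_{g1 + g2 = beta} omega_{g1} choose(k, g2)` with
#' `g1 <= deg(w)` and `g2 <= k - 1`.  Identities:
#' `phi_{k, 0} = omega_0`, `phi_{1, i} = omega_i`, and the leading
#' coefficient `phi_{k, k - 1 + deg(w)} = k * omega_{deg(w)}`.
#'
#' @param w Flux polynomial coefficients (ascending; must not be the zero
#'   polynomial).
#' @param k Moment order, `k >= 1` (at `k = 0` the flux contribution
#'   vanishes identically and no coefficients exist).
#' @return Numeric vector of length `k + deg(w)`, entry `beta + 1` holding
#'   `phi_{k, beta}` for `beta = 0, ..., k - 1 + deg(w)`.
#' @examples
#' phi_coefficients(c(3, 5), 2)  # c(3, 11, 10): expand (2j + 1)(3 + 5j)
#' @export
phi_coefficients <- function(w, k) {
  w <- poly_trim(w)
  if (length(w) == 0L) {
    stop("phi coefficients are undefined for the zero flux polynomial",
         call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) {
    stop("phi coefficients require k >= 1; the flux contribution to the ",
         "zeroth moment vanishes identically", call. = FALSE)
  }
  binom <- choose(k, 0:(k - 1L))  # coefficients of (j+1)^k - j^k
  poly_mul(w, binom)
}

# The kinetic coefficients nu_alpha of n(j, u) as affine expressions in
# the moments: nu_alpha = g0 * delta_{alpha 0} + rho_alpha - d_alpha
#                         - e_alpha * sum_m b_m mu_m.
nu_expressions <- function(model) {
  len <- max(1L, length(model$rho), length(model$d), length(model$e))
  pad <- function(p) c(p, numeric(len - length(p)))
  rho <- pad(model$rho)
  d <- pad(model$d)
  e <- pad(model$e)
  b <- model$b
  out <- vector("list", len)
  for (alpha in seq_len(len) - 1L) {
    const <- rho[alpha + 1L] - d[alpha + 1L] + if (alpha == 0L) model$g0 else 0
    linear <- numeric(0)
    if (e[alpha + 1L] != 0 && length(b) > 0L) {
      linear <- stats::setNames(-e[alpha + 1L] * b,
                                as.character(seq_along(b) - 1L))
    }
    out[[alpha + 1L]] <- affine_expr(const, linear)
  }
  # drop trailing identically-zero coefficients
  while (length(out) > 1L && affine_is_zero(out[[length(out)]])) {
    out[[length(out)]] <- NULL
  }
  if (length(out) == 1L && affine_is_zero(out[[1L]])) {
    out <- list()
  }
  out
}

# Promote a flux specification (numeric coefficients or list of affine
# expressions) to a list of affine expressions.
flux_as_affine <- function(w) {
  if (is.numeric(w)) {
    lapply(as.numeric(w), as_affine)
  } else if (is.list(w)) {
    lapply(w, as_affine)
  } else {
    stop("flux must be a numeric coefficient vector or a list of affine ",
         "expressions", call. = FALSE)
  }
}

affine_flux_is_zero <- function(w_aff) {
  length(w_aff) == 0L || all(vapply(w_aff, affine_is_zero, logical(1)))
}

# phi convolution for affine flux coefficients; returns list of affine
# expressions of length k + length(w_aff) - 1.
phi_affine <- function(w_aff, k) {
  binom <- choose(k, 0:(k - 1L))
  out_len <- length(w_aff) + k - 1L
  out <- replicate(out_len, as_affine(0), simplify = FALSE)
  for (g1 in seq_along(w_aff) - 1L) {
    for (g2 in 0:(k - 1L)) {
      beta <- g1 + g2
      out[[beta + 1L]] <- affine_add(out[[beta + 1L]],
                                     affine_scale(w_aff[[g1 + 1L]],
                                                  binom[g2 + 1L]))
    }
  }
  out
}

#' Exact evolution equation of a single moment
#'
#' Derives `d mu_k / dt` symbolically for the given model.  For `k >= 1`
#' the row is
#' `sum_alpha nu_alpha mu_{k + alpha} + sum_beta phi_{k, beta} mu_beta`,
#' where the `nu_alpha` are the (possibly moment-dependent) kinetic
#' coefficients and the `phi` terms collect the flux contribution; the
#' state-resetting rate `r` does not appear because its contribution is
#' weighted by `j = 0`.  For `k = 0` the flux sums away and the row is
#' `sum_alpha nu_alpha mu_alpha + sum_beta r_beta mu_beta`.
#'
#' @inheritParams validate_model
#' @param k Moment order.
#' @param flux Optional flux override: numeric coefficients or a list of
#'   `moment_affine` coefficients (a candidate flux whose coefficients
#'   depend on moments).  Defaults to the model's own `w`.
#' @return A named list mapping moment index `m` (as character) to the
#'   `moment_affine` coefficient multiplying `mu_m`.
#' @examples
#' m <- load_preset("model_A")
#' moment_ode_row(m, 1)
#' @export
moment_ode_row <- function(model, k, flux = NULL) {
  stopifnot(inherits(model, "structured_model"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  w_aff <- if (is.null(flux)) flux_as_affine(model$w) else flux_as_affine(flux)
  nu <- nu_expressions(model)
  row <- list()
  add_term <- function(row, m, coeff) {
    key <- as.character(m)
    row[[key]] <- if (is.null(row[[key]])) as_affine(coeff) else
      affine_add(row[[key]], coeff)
    row
  }
  if (k == 0L) {
    for (alpha in seq_along(nu) - 1L) {
      row <- add_term(row, alpha, nu[[alpha + 1L]])
    }
    for (beta in seq_along(model$r) - 1L) {
      if (model$r[beta + 1L] != 0) {
        row <- add_term(row, beta, model$r[beta + 1L])
      }
    }
  } else {
    if (!affine_flux_is_zero(w_aff)) {
      if (is.null(flux) && !flux_vanishes_at_N(model$w, model$N)) {
        stop("closure machinery unavailable: w(N) != 0 as a polynomial ",
             "identity, so the index-shift step behind the moment ",
             "equations does not apply", call. = FALSE)
      }
      phi <- phi_affine(w_aff, k)
      for (beta in seq_along(phi) - 1L) {
        row <- add_term(row, beta, phi[[beta + 1L]])
      }
    }
    for (alpha in seq_along(nu) - 1L) {
      row <- add_term(row, k + alpha, nu[[alpha + 1L]])
    }
  }
  row_drop_negligible(row)
}

# Drop coefficients that are zero up to round-off relative to the row scale.
row_drop_negligible <- function(row) {
  if (length(row) == 0L) {
    return(row)
  }
  mags <- vapply(row, affine_magnitude, numeric(1))
  tol <- 1e-10 * max(1, mags)
  row <- row[mags > tol]
  row[order(as.integer(names(row)))]
}

#' Evaluate a derived moment row at a moment vector
#'
#' Computes `sum_m coeff_m(mu) * mu_m` for a row produced by
#' [moment_ode_row()]; this is the exact time derivative of the
#' corresponding moment when `mu` holds all referenced moments.
#'
#' @param row A row as returned by [moment_ode_row()].
#' @param mu Numeric vector of moments, `mu[m + 1] = mu_m`, long enough to
#'   cover every index the row references.
#' @return A scalar.
#' @export
evaluate_moment_row <- function(row, mu) {
  if (length(row) == 0L) {
    return(0)
  }
  idx <- as.integer(names(row))
  if (max(idx) + 1L > length(mu)) {
    stop("row references moment index ", max(idx), " but only moments up ",
         "to order ", length(mu) - 1L, " were supplied", call. = FALSE)
  }
  sum(vapply(seq_along(row), function(i) {
    affine_eval(row[[i]], mu) * mu[idx[i] + 1L]
  }, numeric(1)))
}

#' Assemble the moment-evolution system up to a requested order
#'
#' Builds the rows `d mu_k / dt` for `k = 0, ..., K` and records every
#' nonzero coefficient on a moment of order above `K` as a residual.  An
#' empty residual set means the system is exactly closed at order `K`:
#' the `K + 1` equations involve no information beyond `mu_0, ..., mu_K`.
#' Because any closure must carry the moments that the burden and
#' state-resetting terms inject (`mu_{deg(b)}` and `mu_{deg(r)}`), the
#' requested order must satisfy `K >= max(deg(b), deg(r))`.
#'
#' @inheritParams moment_ode_row
#' @param K Requested closure order.
#' @return An object of class `moment_system` with elements `K`, `N`,
#'   `rows` (list of rows indexed `k + 1`), and `residuals` (list of
#'   `list(k, m, coeff)` witnesses).
#' @examples
#' sys <- assemble_moment_system(load_preset("model_A"), K = 2)
#' length(sys$residuals)  # 0: exactly closed
#' @export
assemble_moment_system <- function(model, K, flux = NULL) {
  stopifnot(inherits(model, "structured_model"))
  K <- as.integer(K)
  lower <- max(0L, poly_degree(model$b), poly_degree(model$r), na.rm = TRUE)
  if (is.na(K) || K < lower) {
    stop("closure order K must be at least max(deg(b), deg(r)) = ", lower,
         ": the burden and state-resetting terms inject these moments ",
         "into every subpopulation equation", call. = FALSE)
  }
  rows <- lapply(0:K, function(k) moment_ode_row(model, k, flux = flux))
  residuals <- list()
  for (k in 0:K) {
    row <- rows[[k + 1L]]
    for (m in as.integer(names(row))) {
      if (m > K) {
        residuals[[length(residuals) + 1L]] <-
          list(k = k, m = m, coeff = row[[as.character(m)]])
      }
    }
  }
  structure(list(K = K, N = model$N, rows = rows, residuals = residuals),
            class = "moment_system")
}

#' @export
print.moment_system <- function(x, ...) {
  cat("<moment_system> order K =", x$K, " (N =", x$N, ")\n")
  for (k in 0:x$K) {
    row <- x$rows[[k + 1L]]
    terms <- vapply(seq_along(row), function(i) {
      paste0("(", format(row[[i]]), ")*mu", names(row)[i])
    }, character(1))
    cat("  dmu", k, "/dt = ",
        if (length(terms)) paste(terms, collapse = " + ") else "0",
        "\n", sep = "")
  }
  if (length(x$residuals) == 0L) {
    cat("  exactly closed: no residual dependence above order", x$K, "\n")
  } else {
    cat("  NOT closed; residual terms:\n")
    for (res in x$residuals) {
      cat("    row k=", res$k, " depends on mu", res$m,
          " with coefficient ", format(res$coeff), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialise a moment system to JSON
#'
#' @param system A `moment_system` from [assemble_moment_system()].
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
moment_system_json <- function(system, path = NULL) {
  stopifnot(inherits(system, "moment_system"))
  rows <- lapply(seq_along(system$rows), function(i) {
    row <- system$rows[[i]]
    lapply(seq_along(row), function(j) {
      a <- row[[j]]
      list(m = as.integer(names(row)[j]), const = a$const,
           linear = as.list(a$linear))
    })
  })
  residuals <- lapply(system$residuals, function(res) {
    list(res$k, res$m, affine_to_list(res$coeff))
  })
  txt <- jsonlite::toJSON(list(K = system$K, N = system$N, rows = rows,
                               residuals = residuals),
                          auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
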