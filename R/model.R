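#' Discretely structured logistic growth model
#'
#' A population stratified over discrete states `j = 0, ..., N` in which
#' each subpopulation `u_j` evolves by
#' `du_j/dt = n(j, u) u_j + J_j + delta_{0j} sum_i r(i) u_i`, where
#' `n(j, u) = g0 + rho(j) - d(j) - e(j) * sum_i b(i) u_i` collects
#' state-preserving reproduction (`rho`), death (`d`) and the
#' environmental-burden response (`e` times the aggregate burden
#' `sum_i b(i) u_i`), `J_j = w(j-1) u_{j-1} - w(j) u_j` is the
#' uni-directional net flux between adjacent states (with boundary
#' conventions `w(-1) = w(N) = 0`), and `r` is the state-resetting
#' reproduction rate whose offspring all enter state 0.
#'
#' All six rates are polynomials in `j`, supplied as ascending coefficient
#' vectors (see [poly_eval()]).  `g0` is a signed baseline net growth rate
#' added uniformly to `n(j, .)`; it exists so that a state-independent net
#' rate (`rho - d` constant) can be expressed without violating the
#' convention `rho(0) = 0`, which reserves `r(0)` as the sole reproduction
#' rate of the `j = 0` subpopulation.
#'
#' @param N Integer; states run `j = 0, ..., N`, so the model has `N + 1`
#'   compartments.  Must be at least 1.
#' @param rho State-preserving (in-place) reproduction rate polynomial,
#'   per unit time; must satisfy `rho(0) = 0`.
#' @param d Death rate polynomial, per unit time.
#' @param e Burden-response polynomial, per unit time per unit burden.
#' @param b Burden-weight polynomial, burden per individual.
#' @param w Flux rate polynomial, per unit time; must be non-negative on
#'   `j = 0, ..., N - 1`.  The polynomial identity `w(N) = 0` is not
#'   enforced at construction (simulation masks the boundary), but the
#'   moment-closure machinery requires it.
#' @param r State-resetting reproduction rate polynomial, per unit time.
#' @param g0 Signed baseline net growth rate (scalar, per unit time),
#'   exempt from non-negativity checks.
#' @return An object of class `structured_model`.
#' @seealso [validate_model()], [kinetics_rhs()], [simulate_full()],
#'   [load_preset()]
#' @examples
#' # state-independent logistic kinetics, linearly decreasing flux
#' m <- structured_model(N = 10, e = 0.5, b = 1, g0 = 1,
#'                       w = c(10, -1) / 5.5)
#' validate_model(m)
#' @export
structured_model <- function(N, rho = numeric(0), d = numeric(0),
                             e = numeric(0), b = numeric(0),
                             w = numeric(0), r = numeric(0), g0 = 0) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L) {
    stop("N must be a single integer >= 1", call. = FALSE)
  }
  stopifnot(is.numeric(g0), length(g0) == 1L, is.finite(g0))
  model <- structure(
    list(N = N,
         rho = poly_trim(rho), d = poly_trim(d), e = poly_trim(e),
         b = poly_trim(b), w = poly_trim(w), r = poly_trim(r),
         g0 = as.numeric(g0)),
    class = "structured_model")
  model
}

#' @export
print.structured_model <- function(x, ...) {
  fmt <- function(p) {
    if (length(p) == 0L) "0" else paste0("[", paste(signif(p, 6), collapse = ", "), "]")
  }
  cat("<structured_model> N =", x$N, "\n")
  cat("  rho:", fmt(x$rho), " d:", fmt(x$d), " e:", fmt(x$e), "\n")
  cat("  b:  ", fmt(x$b), " w:", fmt(x$w), " r:", fmt(x$r),
      " g0:", signif(x$g0, 6), "\n")
  mech <- attr(x, "mechanism")
  if (!is.null(mech)) cat("  mechanism:", mech, "\n")
  invisible(x)
}

check_state <- function(model, u) {
  u <- as.numeric(u)
  if (length(u) != model$N + 1L) {
    stop("state vector has length ", length(u), " but the model has ",
         model$N + 1L, " compartments (states 0..", model$N, ")",
         call. = FALSE)
  }
  u
}

#' Validate a structured model
#'
#' Checks the structural assumptions of the model class.  Hard violations
#' break the model's interpretation or the moment algebra: `rho(0) != 0`
#' (the state-preserving rate must vanish at state 0 so that `r(0)` is the
#' sole reproduction rate there) and `w(j) < 0` for some grid point
#' `j = 0, ..., N - 1` (a negative transfer rate).  Warn-level findings do
#' not stop any computation: negative values of `r`, `rho`, `d`, `e` or
#' `b` on the grid (the analysis is insensitive to this, but the terms
#' lose their physical reading), and `w(N) != 0` as a polynomial identity,
#' which leaves simulation intact but makes the moment-closure machinery
#' unavailable.  The baseline rate `g0` is exempt from sign checks.
#'
#' @param model A [structured_model()].
#' @return An object of class `model_validation` with elements `hard`
#'   (character vector of violations), `warnings`, and `ok`
#'   (`TRUE` when there are no hard violations).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "structured_model"))
  hard <- character(0)
  warns <- character(0)
  N <- model$N
  grid <- 0:N
  if (poly_eval(model$rho, 0) != 0) {
    hard <- c(hard, "rho(0) must be 0")
  }
  w_grid <- poly_eval(model$w, 0:(N - 1))
  if (any(w_grid < 0)) {
    hard <- c(hard, paste0("w is negative on the grid (first at j = ",
                           (0:(N - 1))[which(w_grid < 0)[1]], ")"))
  }
  for (nm in c("r", "rho", "d", "e", "b")) {
    vals <- poly_eval(model[[nm]], grid)
    if (any(vals < 0)) {
      warns <- c(warns, paste0(nm, " takes negative values on the grid ",
                               "(first at j = ", grid[which(vals < 0)[1]], ")"))
    }
  }
  if (!poly_is_zero(model$w) && !flux_vanishes_at_N(model$w, N)) {
    warns <- c(warns, paste0("w(N) != 0 as a polynomial identity: ",
                             "closure machinery unavailable"))
  }
  structure(list(hard = hard, warnings = warns, ok = length(hard) == 0L),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  if (x$ok) {
    cat("model valid: no hard violations\n")
  } else {
    cat("model INVALID:\n")
    for (h in x$hard) cat("  [hard] ", h, "\n", sep = "")
  }
  for (w in x$warnings) cat("  [warn] ", w, "\n", sep = "")
  invisible(x)
}

# Polynomial identity w(N) = 0, up to round-off in the coefficients.
flux_vanishes_at_N <- function(w, N) {
  if (poly_is_zero(w)) {
    return(TRUE)
  }
  scale <- max(abs(w) * N^(seq_along(w) - 1))
  abs(poly_eval(w, N)) <= 1e-9 * max(1, scale)
}

#' Aggregate burden of a population state
#'
#' The total load `sum_i b(i) u_i` that the population places on its
#' environment; the self-limiting term of the kinetics is `e(j)` times
#' this aggregate.
#'
#' @inheritParams validate_model
#' @param u Numeric state vector of length `N + 1` (`u[j + 1]` is the
#'   subpopulation in state `j`).
#' @return A scalar.
#' @export
burden_total <- function(model, u) {
  u <- check_state(model, u)
  if (poly_is_zero(model$b)) {
    return(0)
  }
  sum(poly_eval(model$b, 0:model$N) * u)
}

#' Net flux between adjacent states
#'
#' `J_j = w(j - 1) u_{j - 1} - w(j) u_j`, with the boundary conventions
#' `w(-1) = w(N) = 0` applied regardless of the formal values of the flux
#' polynomial, so that no mass enters from below state 0 or leaves above
#' state `N` and `sum_j J_j = 0` exactly (up to floating round-off).
#'
#' @inheritParams burden_total
#' @return Numeric vector of length `N + 1`.
#' @export
net_flux <- function(model, u) {
  u <- check_state(model, u)
  N <- model$N
  w_vals <- poly_eval(model$w, 0:N)
  w_vals[N + 1L] <- 0   # boundary: w(N) = 0
  outflow <- w_vals * u
  inflow <- c(0, outflow[1:N])  # boundary: w(-1) = 0
  inflow - outflow
}

#' Right-hand side of the structured model
#'
#' Evaluates `du/dt` exactly: entry `j` is
#' `n(j, u) u_j + J_j + delta_{0j} sum_i r(i) u_i` with
#' `n(j, u) = g0 + rho(j) - d(j) - e(j) * sum_i b(i) u_i`.
#'
#' @inheritParams burden_total
#' @return Numeric vector of length `N + 1`.
#' @export
kinetics_rhs <- function(model, u) {
  u <- check_state(model, u)
  grid <- 0:model$N
  n_vals <- model$g0 +
    poly_eval(model$rho, grid) -
    poly_eval(model$d, grid) -
    poly_eval(model$e, grid) * burden_total(model, u)
  rhs <- n_vals * u + net_flux(model, u)
  if (!poly_is_zero(model$r)) {
    rhs[1] <- rhs[1] + sum(poly_eval(model$r, grid) * u)
  }
  rhs
}
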