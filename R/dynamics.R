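#' Trajectory container
#'
#' @param times Strictly increasing numeric time grid.
#' @param states Matrix with one row per time point; columns are
#'   subpopulations `u_0..u_N` (kind `"full"`) or moments `mu_0..mu_K`
#'   (kind `"moments"`).
#' @param kind `"full"` or `"moments"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, states, kind = c("full", "moments")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  states <- as.matrix(states)
  if (length(times) != nrow(states)) {
    stop("times and states disagree in length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  prefix <- if (kind == "full") "u_" else "mu_"
  colnames(states) <- paste0(prefix, seq_len(ncol(states)) - 1L)
  structure(list(times = times, states = states, kind = kind),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> kind =", x$kind, ":", length(x$times), "times in [",
      min(x$times), ",", max(x$times), "],", ncol(x$states), "components\n")
  invisible(x)
}

default_grid <- function(t_max, n = 400L) {
  seq(0, t_max, length.out = n)
}

#' Integrate the full structured system
#'
#' Solves the `N + 1` coupled subpopulation equations with an adaptive
#' implicit-capable integrator (`deSolve::ode`, method `lsoda`).  Default
#' tolerances are tight (`rtol = 1e-9`, `atol = 1e-12`) because the
#' closure checks compare trajectories at the `1e-6` level.  Small
#' negative undershoots (within `10 * atol`) are clamped to zero in the
#' returned states only, never inside the solver.
#'
#' @inheritParams validate_model
#' @param u0 Non-negative initial state of length `N + 1`.
#' @param t_max Final time (used with a 400-point uniform grid when
#'   `t_grid` is not given).
#' @param t_grid Explicit output time grid (overrides `t_max`).
#' @param rtol,atol Integrator tolerances.
#' @return A [trajectory()] of kind `"full"`.
#' @examples
#' m <- load_preset("model_A")
#' traj <- simulate_full(m, c(1, rep(0, 10)), t_max = 20)
#' tail(rowSums(traj$states), 1)  # approaches the carrying capacity 2
#' @export
simulate_full <- function(model, u0, t_max = NULL, t_grid = NULL,
                          rtol = 1e-9, atol = 1e-12) {
  u0 <- check_state(model, u0)
  if (any(u0 < 0)) {
    stop("u0 must be non-negative", call. = FALSE)
  }
  if (is.null(t_grid)) {
    if (is.null(t_max)) {
      stop("supply t_max or t_grid", call. = FALSE)
    }
    t_grid <- default_grid(t_max)
  }
  sol <- deSolve::ode(y = u0, times = t_grid,
                      func = function(t, y, parms) list(kinetics_rhs(model, y)),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("full-system integration failed (istate = ",
         attr(sol, "istate")[1], ") for the supplied model and u0",
         call. = FALSE)
  }
  states <- unname(sol[, -1, drop = FALSE])
  states[states < 0 & states > -10 * atol] <- 0
  trajectory(sol[, 1], states, kind = "full")
}

#' Integrate a closed moment system
#'
#' Solves `d mu_k / dt = sum_m coeff_{k,m}(mu) mu_m` for
#' `k = 0, ..., K`.  Refuses to run when the system's residual set is
#' nonempty (the right-hand sides would reference moments that the state
#' does not carry).
#'
#' @param system A `moment_system` from [assemble_moment_system()] with
#'   an empty residual set.
#' @param mu_init Initial moments `mu_0..mu_K`.
#' @inheritParams simulate_full
#' @return A [trajectory()] of kind `"moments"`.
#' @export
simulate_closed <- function(system, mu_init, t_max = NULL, t_grid = NULL,
                            rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(system, "moment_system"))
  if (length(system$residuals) > 0L) {
    stop("moment system is not closed: residual dependence on moments ",
         "above order ", system$K, " (run the closure decision first)",
         call. = FALSE)
  }
  mu_init <- as.numeric(mu_init)
  if (length(mu_init) != system$K + 1L) {
    stop("mu_init must have length K + 1 = ", system$K + 1L, call. = FALSE)
  }
  if (is.null(t_grid)) {
    if (is.null(t_max)) {
      stop("supply t_max or t_grid", call. = FALSE)
    }
    t_grid <- default_grid(t_max)
  }
  rows <- system$rows
  rhs <- function(t, mu, parms) {
    list(vapply(rows, evaluate_moment_row, numeric(1), mu = mu))
  }
  sol <- deSolve::ode(y = mu_init, times = t_grid, func = rhs,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("moment-system integration failed (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  trajectory(sol[, 1], unname(sol[, -1, drop = FALSE]), kind = "moments")
}

#' Integrate to a steady state
#'
#' Integrates the full system in chunks until the right-hand side drops
#' below `tol` in the supremum norm, or the horizon is reached.
#' Non-convergence is reported through the flag, not an error.
#'
#' @inheritParams simulate_full
#' @param horizon Maximum integration time (default 100 time units).
#' @param tol Convergence threshold on `||du/dt||_inf` (default `1e-8`).
#' @return A list with `state`, `converged`, `time`, and `total`
#'   (the total population `mu_0` of the final state).
#' @export
steady_state <- function(model, u0, horizon = 100, tol = 1e-8,
                         rtol = 1e-9, atol = 1e-12) {
  u0 <- check_state(model, u0)
  chunk <- max(horizon / 20, 1)
  t_now <- 0
  u <- u0
  repeat {
    if (max(abs(kinetics_rhs(model, u))) < tol) {
      return(list(state = u, converged = TRUE, time = t_now, total = sum(u)))
    }
    if (t_now >= horizon) {
      return(list(state = u, converged = FALSE, time = t_now, total = sum(u)))
    }
    t_end <- min(t_now + chunk, horizon)
    traj <- simulate_full(model, pmax(u, 0), t_grid = c(t_now, t_end),
                          rtol = rtol, atol = atol)
    u <- traj$states[nrow(traj$states), ]
    t_now <- t_end
  }
}

#' Feasibility of a moment trajectory
#'
#' A moment vector is attainable from a non-negative population on states
#' `0..N` only inside the cone `mu_k >= 0`, `mu_{k+1} <= N mu_k`.  Exact
#' closures preserve this cone (on the boundary `mu_1 = N mu_0` the
#' derived equations satisfy `d mu_1/dt = N d mu_0/dt`, so feasible
#' states remain feasible); violations indicate an incorrect closure or
#' integrator failure.  Checks are applied with slack
#' `eps = 1e-6 * max(1, mu_0)` per time point (`mu_k >= -eps * N^k` and
#' `mu_{k+1} <= N mu_k + eps`).
#'
#' @param traj A [trajectory()].  Full trajectories are converted to
#'   moments (order `N`) before checking.
#' @param N State count minus one.
#' @return An object of class `feasibility_report`: `ok`, and
#'   `violations` (data frame with columns `time`, `constraint`,
#'   `excess`).
#' @export
feasibility_check <- function(traj, N) {
  stopifnot(inherits(traj, "trajectory"))
  mu <- if (traj$kind == "full") {
    t(apply(traj$states, 1, moments_from_state, K = N))
  } else {
    traj$states
  }
  K <- ncol(mu) - 1L
  viol <- list()
  for (i in seq_along(traj$times)) {
    eps <- 1e-6 * max(1, abs(mu[i, 1]))
    for (k in 0:K) {
      if (mu[i, k + 1L] < -eps * N^k) {
        viol[[length(viol) + 1L]] <- data.frame(
          time = traj$times[i], constraint = paste0("mu_", k, " >= 0"),
          excess = -mu[i, k + 1L])
      }
      if (k < K && mu[i, k + 2L] > N * mu[i, k + 1L] + eps) {
        viol[[length(viol) + 1L]] <- data.frame(
          time = traj$times[i],
          constraint = paste0("mu_", k + 1L, " <= N*mu_", k),
          excess = mu[i, k + 2L] - N * mu[i, k + 1L])
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(time = numeric(0), constraint = character(0),
               excess = numeric(0))
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  if (x$ok) {
    cat("feasible: all moment-cone constraints satisfied\n")
  } else {
    cat("INFEASIBLE at", nrow(x$violations), "grid points; first:\n")
    print(utils::head(x$violations, 3))
  }
  invisible(x)
}

#' Closed-form logistic solution
#'
#' `u(t) = L / (1 + (L/u0 - 1) exp(-g t))`: the total population of any
#' structured model with state-independent kinetics follows this curve
#' exactly, independent of the flux.
#'
#' @param t Time(s).
#' @param g Net growth rate.
#' @param L Carrying capacity.
#' @param u0 Initial total population.
#' @return Numeric vector of the same length as `t`.
#' @export
logistic_growth <- function(t, g, L, u0) {
  if (u0 == 0) {
    return(rep(0, length(t)))
  }
  L / (1 + (L / u0 - 1) * exp(-g * t))
}
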