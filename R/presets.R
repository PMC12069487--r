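#' Built-in model presets
#'
#' Six fully parameterised reference models used throughout the package:
#' \describe{
#'   \item{`model_A`}{Essentially unstructured logistic kinetics
#'     (`N = 10`, net growth rate 1, carrying capacity 2 via `e = 1/2`,
#'     `b = 1`) with linearly decreasing flux `w(j) = (N - j)/W`,
#'     `W = (N + 1)/2` (which fixes the grid-average flux rate to one).
#'     Admits exact closures at every order below `N`.}
#'   \item{`model_B`}{Same kinetics as `model_A` but constant flux
#'     `w(j) = 1` on `j = 0..N-1`.  Because interpolating that flux as a
#'     polynomial with `w(N) = 0` needs degree at least `N`, only the
#'     order-0 and the trivial closures exist.}
#'   \item{`exponential`}{Linear kinetics `n(j) = beta - j` with
#'     `beta = (N + 1)/2` (constant birth rate, death rate `d(j) = j`, no
#'     burden) and flux `w(j) = N - j`; the population grows and then
#'     collapses as mass drifts to high-death states.  Closable at any
#'     order by a quadratic flux family.}
#'   \item{`nonlinear`}{Quadratic kinetics
#'     `n(j) = 2(N - j)^2/N - (1 + (N - j)/N) mu_1` (burden weight
#'     `b(j) = j`, response `e(j) = 1 + (N - j)/N`, growth falling with
#'     state), flux `w(j) = N - j`.  The state-dependent net growth is
#'     stored as baseline `g0 = 2N` plus `d(j) = 4j - 2j^2/N`
#'     (non-negative on the grid), which leaves the convention
#'     `rho(0) = 0` intact.  No exact closure exists at any order.}
#'   \item{`mechanism_P`, `mechanism_R`}{The matched state-preserving /
#'     state-resetting pair (`N = 10`, rate 1, `d = 0`, `e = 1/2`,
#'     `b = 1`, `w(j) = (N - j)/10`) used by the mechanism-identification
#'     experiment.}
#' }
#'
#' @param name One of `"model_A"`, `"model_B"`, `"exponential"`,
#'   `"nonlinear"`, `"mechanism_P"`, `"mechanism_R"`.
#' @return A [structured_model()] (with a `provenance` attribute
#'   describing what the preset encodes).
#' @examples
#' load_preset("model_A")
#' preset_names()
#' @export
load_preset <- function(name) {
  N <- 10L
  W <- (N + 1) / 2
  model <- switch(
    name,
    model_A = {
      m <- structured_model(N, e = 0.5, b = 1, w = c(N, -1) / W, g0 = 1)
      attr(m, "provenance") <- paste(
        "state-independent logistic kinetics (growth 1, capacity 2)",
        "with linearly decreasing flux (N - j)/W, W = (N + 1)/2")
      m
    },
    model_B = {
      m <- structured_model(N, e = 0.5, b = 1, w = 1, g0 = 1)
      attr(m, "provenance") <- paste(
        "state-independent logistic kinetics with constant unit flux;",
        "no polynomial flux of degree < N matches it, so only the",
        "order-0 closure survives")
      m
    },
    exponential = {
      m <- structured_model(N, d = c(0, 1), w = c(N, -1), g0 = (N + 1) / 2)
      attr(m, "provenance") <- paste(
        "linear kinetics n(j) = beta - j with beta = (N + 1)/2 and",
        "flux w(j) = N - j: transient growth followed by collapse")
      m
    },
    nonlinear = {
      m <- structured_model(N, d = c(0, 4, -2 / N), e = c(2, -1 / N),
                            b = c(0, 1), w = c(N, -1), g0 = 2 * N)
      attr(m, "provenance") <- paste(
        "quadratic kinetics n(j) = 2(N - j)^2/N - (1 + (N - j)/N) mu_1,",
        "encoded as g0 = 2N with d(j) = 4j - 2j^2/N; closure is",
        "impossible at every order")
      m
    },
    mechanism_P = ,
    mechanism_R = {
      pair <- build_mechanism_pair(N, rate = 1, e = 0.5, b = 1,
                                   w = c(N, -1) / 10)
      m <- if (name == "mechanism_P") pair$preserving else pair$resetting
      attr(m, "provenance") <- paste(
        "member of the matched reproduction-mechanism pair (rate 1,",
        "e = 1/2, b = 1, w(j) = (N - j)/10):",
        if (name == "mechanism_P") "offspring keep their parent's state"
        else "offspring enter state 0")
      m
    },
    stop("unknown preset '", name, "'; available presets: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)
  )
  model
}

#' @rdname load_preset
#' @export
preset_names <- function() {
  c("model_A", "model_B", "exponential", "nonlinear",
    "mechanism_P", "mechanism_R")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Seeded random structured models
#'
#' Property-test input generator.  Coefficients are drawn uniformly from
#' `[0, 2]`; `rho(0)` is forced to zero; the flux is a random
#' non-negative polynomial multiplied by `(N - j)/N`, which guarantees
#' `w(N) = 0` as a polynomial identity and non-negativity on the grid.
#' Every output passes [validate_model()] with no hard violations, and
#' the same seed always returns the same model.
#'
#' When `deg_n_target` is given, the state-dependent part of the
#' kinetics is a single monomial of that degree placed in either the
#' death channel (making the leading kinetic coefficient negative) or
#' the state-preserving channel (positive), chosen by one random
#' sign-flip slot — both sign branches of the linear-kinetics flux
#' family are thereby exercised.
#'
#' @param seed Integer seed (local to the call; the caller's RNG state is
#'   restored on exit).
#' @param N State count minus one (`N >= 2`).
#' @param deg_n_target Optional exact degree for the kinetics polynomial
#'   (`>= 1`); `NULL` draws generic degrees up to `max_degree`.
#' @param max_degree Cap on the drawn degrees of `rho`, `d` and the flux
#'   base polynomial.
#' @param with_burden Include a burden term (`e`, `b` constant-to-linear)
#'   with probability 1/2 when `NA` (default); set `TRUE`/`FALSE` to
#'   force.
#' @return A [structured_model()].
#' @export
random_model <- function(seed, N = 6, deg_n_target = NULL, max_degree = 3,
                         with_burden = NA) {
  stopifnot(N >= 2)
  with_local_seed(seed, {
    g0 <- stats::runif(1, 0, 2)
    if (is.na(with_burden)) {
      with_burden <- stats::runif(1) < 0.5
    }
    e <- if (with_burden) stats::runif(1, 0.1, 1) else numeric(0)
    b <- if (with_burden) stats::runif(sample(1:2, 1), 0, 1) else numeric(0)
    r <- if (stats::runif(1) < 0.5) stats::runif(1, 0, 1) else numeric(0)
    if (is.null(deg_n_target)) {
      dr <- sample(0:max_degree, 1)
      rho <- if (dr > 0) c(0, stats::runif(dr, 0, 2)) else numeric(0)
      dd <- sample(0:max_degree, 1)
      d <- stats::runif(dd + 1, 0, 2)
    } else {
      stopifnot(deg_n_target >= 1)
      s <- stats::runif(1, 0.3, 2)
      mono <- c(numeric(deg_n_target), s)
      if (stats::runif(1) < 0.5) {   # sign-flip slot: nu_deg < 0 branch
        d <- mono
        rho <- numeric(0)
      } else {                       # nu_deg > 0 branch (rho(0) = 0 kept)
        rho <- mono
        d <- stats::runif(1, 0, 1)
      }
      if (with_burden) {             # keep the burden from raising deg(n)
        e <- e[1]
      }
    }
    w_base <- stats::runif(sample(1:max(1, max_degree - 1), 1) + 1, 0, 2)
    w <- poly_mul(w_base, c(1, -1 / N))  # times (N - j)/N: w(N) = 0
    structured_model(N, rho = rho, d = d, e = e, b = b, w = w, r = r,
                     g0 = g0)
  })
}

#' @rdname random_model
#' @param scale Upper bound of the uniform draw for subpopulation sizes.
#' @return `random_state()` returns a non-negative state vector of length
#'   `N + 1`.
#' @export
random_state <- function(seed, N, scale = 2) {
  with_local_seed(seed, stats::runif(N + 1, 0, scale))
}
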