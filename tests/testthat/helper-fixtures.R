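# Shared fixtures and independent oracles for the test suite.

unit_mass <- function(N, at = 0) {
  u <- numeric(N + 1)
  u[at + 1] <- 1
  u
}

# Brute-force oracle for the k-th moment derivative: differentiate the
# full system and aggregate, sum_j j^k * (du_j/dt).  Independent of the
# symbolic moment-equation machinery.
moment_deriv_oracle <- function(model, u, k) {
  grid <- 0:model$N
  sum(grid^k * kinetics_rhs(model, u))
}

# Highest moment index referenced by a derived row, including moments
# carried inside the affine coefficients (burden terms).
row_max_index <- function(row) {
  if (length(row) == 0L) {
    return(0L)
  }
  idx <- as.integer(names(row))
  for (a in row) {
    if (length(a$linear)) idx <- c(idx, as.integer(names(a$linear)))
  }
  max(idx)
}

# Random mechanism-trial parameters: rate perturbation of at least 0.1
# and an initial condition with mu_1(0) >= 0.5.
with_seed_draws <- function(seed) {
  set.seed(seed)
  u0 <- runif(9, 0, 1)
  while (sum((0:8) * u0) < 0.5) u0 <- u0 + 0.1
  list(rate = runif(1, 0.5, 2),
       delta = runif(1, 0.1, 0.5),
       d = runif(1, 0, 0.3),
       e = runif(1, 0.2, 1),
       b = runif(1, 0.5, 1.5),
       C = runif(1, 0.05, 0.5),
       u0 = u0)
}

# A model with linear kinetics and its order-K constructed flux filled in.
closed_linear_model <- function(seed, N = 5, K = 1) {
  m <- random_model(seed, N = N, deg_n_target = 1)
  fam <- construct_flux_family(m, K = K)
  C <- if (!is.null(fam$bounds) && is.finite(fam$bounds[1])) 2 * N else -N
  m$w <- flux_polynomial(fam, C = C)
  m
}
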