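test_that("moments of a state follow mu_k = sum_j j^k u_j", {
  expect_equal(moments_from_state(unit_mass(2), 2), c(1, 0, 0))
  expect_equal(moments_from_state(c(1, 2, 3), 2), c(6, 8, 14))
  expect_equal(moments_from_state(c(1, 1, 1), 2), c(3, 3, 5))
  expect_error(moments_from_state(c(1, 2), -1), "non-negative")
})

test_that("the trivial closure inverts the moment map", {
  expect_equal(state_from_moments(c(1, 0, 0), 2), unit_mass(2))
  expect_equal(state_from_moments(c(6, 8, 14), 2), c(1, 2, 3))
  expect_equal(state_from_moments(c(3, 3, 5), 2), c(1, 1, 1))
  expect_error(state_from_moments(c(1, 2), 2), "moments")
})

test_that("moment round trip is accurate up to the conditioning limit", {
  for (N in c(3, 6, 8, 10)) {
    u <- random_state(N, N, scale = 3)
    back <- state_from_moments(moments_from_state(u, N), N)
    expect_lt(max(abs(back - u)) / max(abs(u)), 1e-8)
  }
  # at N = 12 the double-precision moments themselves limit accuracy
  u12 <- random_state(12, 12, scale = 3)
  back12 <- state_from_moments(moments_from_state(u12, 12), 12)
  expect_lt(max(abs(back12 - u12)) / max(abs(u12)), 1e-6)
  # far beyond that, the solve refuses rather than returning noise
  u25 <- random_state(25, 25)
  expect_error(state_from_moments(moments_from_state(u25, 25), 25),
               "conditioning")
})

test_that("phi coefficients equal the expansion of [(j+1)^k - j^k] w(j)", {
  expect_equal(phi_coefficients(c(3, 5), 2), c(3, 11, 10))
  # identities: phi_{k,0} = omega_0; phi_{1,i} = omega_i;
  # leading phi_{k,k-1+deg(w)} = k * omega_deg(w)
  for (seed in 1:10) {
    w <- random_state(seed, sample(0:3, 1) + 1, scale = 2) + 0.1
    for (k in 1:5) {
      phi <- phi_coefficients(w, k)
      expect_length(phi, k + length(w) - 1)
      expect_equal(phi[1], w[1])
      expect_equal(phi[length(phi)], k * w[length(w)])
      if (k == 1) expect_equal(phi, w)
      # value-level oracle on the grid, independent of the convolution
      j <- 0:10
      expect_equal(poly_eval(phi, j),
                   ((j + 1)^k - j^k) * poly_eval(w, j), tolerance = 1e-12)
    }
  }
  expect_error(phi_coefficients(numeric(0), 2), "zero flux")
  expect_error(phi_coefficients(c(1, 1), 0), "k >= 1")
})

test_that("derived moment rows reproduce the closed equations of the presets", {
  mA <- load_preset("model_A")
  W <- 5.5
  # d mu1/dt = g mu1 (1 - mu0/L) + (N mu0 - mu1)/W
  r1 <- moment_ode_row(mA, 1)
  expect_equal(r1[["0"]]$const, 10 / W)
  expect_equal(r1[["1"]]$const, 1 - 1 / W)
  expect_equal(r1[["1"]]$linear, c("0" = -0.5))
  # d mu2/dt = g mu2 (1 - mu0/L) + (N mu0 + (2N - 1) mu1 - 2 mu2)/W
  r2 <- moment_ode_row(mA, 2)
  expect_equal(r2[["0"]]$const, 10 / W)
  expect_equal(r2[["1"]]$const, 19 / W)
  expect_equal(r2[["2"]]$const, 1 - 2 / W)
  expect_equal(r2[["2"]]$linear, c("0" = -0.5))
  # exponential kinetics with the quadratic flux w = (j-N)(j-C), K = 1:
  # d mu1/dt = C N mu0 + (beta - C - N) mu1, the mu2 term cancelled
  me <- load_preset("exponential")
  C <- 20
  me$w <- poly_mul(c(-10, 1), c(-C, 1))
  rexp <- moment_ode_row(me, 1)
  expect_equal(rexp[["0"]]$const, C * 10)
  expect_equal(rexp[["1"]]$const, 5.5 - C - 10)
  expect_null(rexp[["2"]])
})

test_that("the state-resetting term enters only the zeroth row", {
  m <- structured_model(5, r = c(0.5, 0.2), w = c(5, -1), e = 1, b = 1)
  r0 <- moment_ode_row(m, 0)
  expect_equal(r0[["1"]]$const, 0.2)
  m_nor <- m
  m_nor$r <- numeric(0)
  for (k in 1:3) {
    expect_identical(moment_ode_row(m, k), moment_ode_row(m_nor, k))
  }
})

test_that("symbolic rows agree with the brute-force aggregation oracle", {
  for (seed in 1:30) {
    m <- random_model(seed, N = 6)
    u <- random_state(seed + 500, 6)
    for (k in 0:3) {
      row <- moment_ode_row(m, k)
      mu <- moments_from_state(u, max(k, row_max_index(row)))
      expect_equal(evaluate_moment_row(row, mu),
                   moment_deriv_oracle(m, u, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("rows above zero reject fluxes that do not vanish at N", {
  mB <- load_preset("model_B")
  expect_error(moment_ode_row(mB, 1), "closure machinery unavailable")
  expect_silent(moment_ode_row(mB, 0))
})

test_that("assembled systems report residual dependence above the order", {
  expect_length(assemble_moment_system(load_preset("model_A"), 2)$residuals, 0)
  # nonlinear kinetics under the order-2 candidate flux leave mu3, coeff 1/N
  mn <- load_preset("nonlinear")
  cand <- flux_candidate_coefficients(construct_flux_family(mn, 2), C = 0)
  res <- assemble_moment_system(mn, 2, flux = cand)$residuals
  expect_length(res, 1)
  expect_equal(res[[1]]$k, 1)
  expect_equal(res[[1]]$m, 3)
  expect_equal(res[[1]]$coeff$const, 1 / 10, tolerance = 1e-12)
  # the order bound: burden weight of degree 1 forbids K = 0
  expect_error(assemble_moment_system(mn, 0), "max\\(deg\\(b\\), deg\\(r\\)\\)")
})

test_that("moment systems serialise to JSON and back-reference their order", {
  sys <- assemble_moment_system(load_preset("model_A"), 1)
  txt <- moment_system_json(sys)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_equal(parsed$K, 1)
  expect_length(parsed$rows, 2)
  expect_length(parsed$residuals, 0)
})
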