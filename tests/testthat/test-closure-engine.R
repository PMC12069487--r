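test_that("the structural kinetics degree reflects all kinetic channels", {
  expect_equal(structural_degree_n(load_preset("exponential")), 1L)
  expect_equal(structural_degree_n(load_preset("nonlinear")), 2L)
  expect_equal(structural_degree_n(load_preset("model_A")), 0L)
  # vanishing kinetics have no degree
  expect_identical(structural_degree_n(structured_model(3, w = c(3, -1))),
                   NA_integer_)
  # burden channel counts only when both e and b are nonzero
  expect_equal(structural_degree_n(structured_model(3, e = c(0, 1), b = 1)), 1L)
  expect_identical(structural_degree_n(structured_model(3, e = c(0, 1))),
                   NA_integer_)
})

test_that("the degree rule forces deg(w) = deg(n) + 1", {
  expect_equal(required_flux_degree(1), 2L)
  expect_equal(required_flux_degree(0), 1L)
  expect_equal(required_flux_degree(2), 3L)
  expect_identical(required_flux_degree(NA), NA_integer_)
  expect_error(required_flux_degree(-1), "non-negative")
})

test_that("closure decisions match the theory on the reference models", {
  mA <- load_preset("model_A")
  for (K in 0:2) {
    expect_equal(closure_decision(mA, K)$exists, "yes")
  }
  decB <- closure_decision(load_preset("model_B"), 1)
  expect_equal(decB$exists, "no")
  expect_match(decB$reason, "degree >= N")
  expect_equal(closure_decision(load_preset("model_B"), 0)$exists, "yes")
  # the exponential preset's own linear flux cannot close (deg(w) must be 2)
  dec_e <- closure_decision(load_preset("exponential"), 1)
  expect_equal(dec_e$exists, "no")
  expect_match(dec_e$reason, "deg\\(w\\) = 2")
  # quadratic kinetics: impossible at every order, witness nu_2 / K
  mn <- load_preset("nonlinear")
  for (K in 1:4) {
    dec <- closure_decision(mn, K)
    expect_equal(dec$exists, "no")
    expect_equal(dec$witness$coeff$const, (2 / 10) / K, tolerance = 1e-12)
    expect_equal(dec$witness$row, K - 1)
    expect_equal(dec$witness$moment, K + 1)
  }
  expect_error(closure_decision(mA, 10), "trivial")
  expect_error(closure_decision(mn, 0), "deg\\(b\\)")
})

test_that("constructed flux families reproduce the closed-form family", {
  me <- load_preset("exponential")   # nu_1 = -1
  fam1 <- construct_flux_family(me, K = 1)
  # w(j) = (1/K)(j - N)(j - C): leading coefficient 1/K, C >= N
  expect_equal(affine_eval(fam1$coeffs[[3]], numeric(0)), 1)
  expect_equal(fam1$bounds, c(10, Inf))
  w <- flux_polynomial(fam1, C = 20)
  expect_equal(poly_eval(w, 0), 200)
  expect_equal(poly_eval(w, 10), 0)
  # closure at higher orders requires reduced fluxes: leading halves as K doubles
  fam2 <- construct_flux_family(me, K = 2)
  expect_equal(affine_eval(fam2$coeffs[[3]], numeric(0)), 0.5)
  # positive nu_1 flips the admissible parameter range to C <= 0
  m_pos <- structured_model(6, rho = c(0, 0.8), d = 0.1, g0 = 1)
  fam_pos <- construct_flux_family(m_pos, K = 1)
  expect_equal(fam_pos$bounds, c(-Inf, 0))
  w_pos <- flux_polynomial(fam_pos, C = -3)
  expect_true(all(poly_eval(w_pos, 0:5) >= 0))
  # an out-of-range parameter would make the flux negative on the grid
  expect_error(flux_polynomial(fam1, C = 5), "admissible")
  # order-2 candidate for the quadratic model: omega_3 = -nu_2 / 2 = -1/N
  fam_nl <- construct_flux_family(load_preset("nonlinear"), K = 2)
  expect_false(fam_nl$closing)
  expect_equal(affine_eval(fam_nl$coeffs[[4]], numeric(0)), -1 / 10)
})

test_that("symbolic verification certifies exactly the constructed closures", {
  me <- load_preset("exponential")
  me$w <- flux_polynomial(construct_flux_family(me, K = 1), C = 20)
  expect_length(verify_closure_symbolic(me, 1), 0)
  # K-specificity: the order-1 flux does not close the system at order 2
  expect_gt(length(verify_closure_symbolic(me, 2)), 0)
  # essentially unstructured model with w = C(N - j): closed at any order
  mA <- load_preset("model_A")
  for (K in 1:4) {
    expect_length(verify_closure_symbolic(mA, K), 0)
  }
  # quadratic kinetics: the candidate leaves mu3 in the mu1 row
  mn <- load_preset("nonlinear")
  cand <- flux_candidate_coefficients(construct_flux_family(mn, 2), C = 0)
  res <- verify_closure_symbolic(mn, 2, flux = cand)
  expect_length(res, 1)
  expect_equal(res[[1]]$m, 3)
})

test_that("numerical certification agrees with symbolic exactness", {
  v <- verify_closure_numeric(load_preset("model_A"), 1, unit_mass(10),
                              horizon = 15)
  expect_lt(v$discrepancy, 1e-6)
  # exponential model with beta = N/2 and the C = 2N flux, closed at K = 1
  me <- structured_model(10, d = c(0, 1), g0 = 5)
  me$w <- flux_polynomial(construct_flux_family(me, K = 1), C = 20)
  v2 <- verify_closure_numeric(me, 1, unit_mass(10, at = 2), horizon = 10)
  expect_lt(v2$discrepancy, 1e-6)
  # zero initial condition: both systems stay at zero
  v0 <- verify_closure_numeric(load_preset("model_A"), 1, rep(0, 11),
                               horizon = 5, n_grid = 50)
  expect_equal(v0$discrepancy, 0)
  # refuses to certify when residuals are nonempty
  expect_error(verify_closure_numeric(load_preset("exponential"), 1,
                                      unit_mass(10)),
               "not exactly closed")
})

test_that("closure is impossible for superlinear kinetics (random ensemble)", {
  for (seed in 1:40) {
    deg <- 2 + seed %% 2
    m <- random_model(seed, N = 6, deg_n_target = deg)
    lower <- max(1, poly_degree(m$b), poly_degree(m$r), na.rm = TRUE)
    for (K in lower:(m$N - 1)) {
      dec <- closure_decision(m, K)
      expect_equal(dec$exists, "no")
      expect_gt(abs(dec$witness$coeff$const) +
                  sum(abs(dec$witness$coeff$linear)), 0)
    }
  }
})

test_that("constructed fluxes close linear-kinetics models (random ensemble)", {
  for (seed in 1:40) {
    K <- 1 + seed %% 3
    m <- closed_linear_model(seed, N = 5, K = K)
    expect_length(verify_closure_symbolic(m, K), 0)
  }
  # numeric certification on a subset
  for (seed in 1:8) {
    K <- 1 + seed %% 2
    m <- closed_linear_model(seed, N = 5, K = K)
    u0 <- random_state(seed + 2000, 5, scale = 0.5)
    v <- verify_closure_numeric(m, K, u0, horizon = 1, n_grid = 80)
    expect_lt(v$discrepancy, 1e-6)
  }
})
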