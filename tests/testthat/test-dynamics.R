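test_that("the total of a state-independent model follows the logistic curve", {
  mA <- load_preset("model_A")
  traj <- simulate_full(mA, unit_mass(10), t_max = 20)
  mu0 <- rowSums(traj$states)
  expect_lt(max(abs(mu0 - logistic_growth(traj$times, 1, 2, 1))), 1e-6)
  # the flux does not affect the total: constant-flux variant agrees
  mB <- load_preset("model_B")
  mu0_B <- rowSums(simulate_full(mB, unit_mass(10), t_grid = traj$times)$states)
  expect_lt(max(abs(mu0_B - mu0)), 1e-6)
})

test_that("the structured exponential model grows then collapses", {
  me <- load_preset("exponential")
  traj <- simulate_full(me, unit_mass(10), t_max = 30)
  mu0 <- rowSums(traj$states)
  expect_gt(max(mu0), 1.05 * mu0[1])   # initial growth phase
  expect_lt(mu0[length(mu0)], 1e-3)    # eventual extinction
})

test_that("zero initial conditions stay at extinction", {
  traj <- simulate_full(load_preset("model_A"), rep(0, 11), t_max = 5)
  expect_true(all(traj$states == 0))
})

test_that("steady states match the fixed points of the closed totals", {
  ssA <- steady_state(load_preset("model_A"), unit_mass(10),
                      horizon = 200, tol = 1e-7)
  expect_equal(ssA$total, 2, tolerance = 1e-6)
  # constant rho = 1, d = 0, e = 1/2: total settles at rho / e = 2
  ssP <- steady_state(load_preset("mechanism_P"), unit_mass(10),
                      horizon = 200, tol = 1e-7)
  expect_equal(ssP$total, 2, tolerance = 1e-6)
  # exponential model: extinction
  ssE <- steady_state(load_preset("exponential"), unit_mass(10),
                      horizon = 200, tol = 1e-7)
  expect_true(ssE$converged)
  expect_lt(ssE$total, 1e-6)
})

test_that("closed moment systems respect their invariant structures", {
  # beta = N: trajectories starting on mu_1 = N mu_0 stay on it
  m_marg <- structured_model(10, d = c(0, 1), g0 = 10)
  m_marg$w <- flux_polynomial(construct_flux_family(m_marg, K = 1), C = 20)
  sys <- assemble_moment_system(m_marg, 1)
  traj <- simulate_closed(sys, c(1, 10), t_max = 5)
  expect_lt(max(abs(traj$states[, 2] - 10 * traj$states[, 1])),
            1e-6 * max(traj$states[, 1]))
  expect_true(feasibility_check(traj, 10)$ok)
  # beta = N/2 < N: extinction is linearly stable
  m_sub <- structured_model(10, d = c(0, 1), g0 = 5)
  m_sub$w <- flux_polynomial(construct_flux_family(m_sub, K = 1), C = 20)
  sys_sub <- assemble_moment_system(m_sub, 1)
  traj_sub <- simulate_closed(sys_sub, c(1, 2), t_max = 40)
  expect_lt(max(abs(traj_sub$states[nrow(traj_sub$states), ])), 1e-4)
  # zero initial moments stay at zero
  traj0 <- simulate_closed(sys, c(0, 0), t_max = 5, t_grid = NULL)
  expect_true(all(traj0$states == 0))
  # refuses a system with residuals
  sys_bad <- assemble_moment_system(load_preset("exponential"), 1)
  expect_error(simulate_closed(sys_bad, c(1, 0), t_max = 1), "not closed")
})

test_that("feasibility checks flag states outside the moment cone", {
  # any full simulation of a validated model is feasible
  traj <- simulate_full(load_preset("model_A"), unit_mass(10), t_max = 10)
  expect_true(feasibility_check(traj, 10)$ok)
  # a fabricated moment trajectory with mu_1 > N mu_0 is flagged
  bad <- trajectory(c(0, 1), rbind(c(1, 20), c(1, 20)), kind = "moments")
  rep_bad <- feasibility_check(bad, 10)
  expect_false(rep_bad$ok)
  expect_match(rep_bad$violations$constraint, "mu_1 <= N\\*mu_0", all = FALSE)
})

test_that("trajectories round-trip through CSV losslessly", {
  traj <- simulate_full(load_preset("model_A"), unit_mass(10),
                        t_grid = seq(0, 2, length.out = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(back$kind, "full")
  expect_equal(back$times, traj$times, tolerance = 0)
  expect_equal(back$states, traj$states, tolerance = 0)
  # moments kind is recovered from the header
  sysA <- assemble_moment_system(load_preset("model_A"), 1)
  trajm <- simulate_closed(sysA, c(1, 0), t_grid = seq(0, 1, length.out = 5))
  write_trajectory(trajm, path)
  expect_identical(read_trajectory(path)$kind, "moments")
  # a ragged row is reported with its position
  lines <- readLines(path)
  lines[3] <- paste0(lines[3], ",99")
  writeLines(lines, path)
  expect_error(read_trajectory(path), "ragged trajectory row 3")
})
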