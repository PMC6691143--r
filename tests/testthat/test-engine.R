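test_that("boost energy follows the closed form with a hard threshold", {
  expect_equal(boost_energy(100, 100, 20), 0)
  expect_equal(boost_energy(80, 100, 20), 10)
  expect_equal(boost_energy(120, 100, 20), 0)
  expect_true(all(boost_energy(seq(-500, 500, by = 7), 100, 20) >= 0))
  expect_error(boost_energy(80, 100, 0), "alpha")
})

test_that("force scale is the analytic dV'/dV: matches finite differences, monotone, in (0,1]", {
  expect_equal(boost_force_scale(100, 100, 20), 1)
  expect_equal(boost_force_scale(80, 100, 20), 0.25)
  grid <- seq(-200, 150, by = 2.5)
  s <- boost_force_scale(grid, 100, 20)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) >= 0))       # monotone increase toward V = E
  # central differences away from the V = E kink
  grid_fd <- grid[abs(grid - 100) > 0.1]
  h <- 1e-3
  fd <- 1 + (boost_energy(grid_fd + h, 100, 20) -
             boost_energy(grid_fd - h, 100, 20)) / (2 * h)
  expect_lt(max(abs(boost_force_scale(grid_fd, 100, 20) - fd)), 1e-8)
  expect_error(boost_force_scale(80, 100, -1), "alpha")
})

test_that("dual_boost composes the two bias terms additively", {
  expect_equal(dual_boost(50, 5, NULL, "none")$deltaV, 0)
  bp <- boost_params(E_P = 100, alpha_P = 20, E_D = 10, alpha_D = 4)
  above <- dual_boost(150, 20, bp, "dual")
  expect_equal(above$deltaV, 0)
  expect_equal(above$scale_total, 1)
  expect_equal(above$scale_dihedral, 1)
  d <- dual_boost(80, 8, bp, "dual")
  expect_equal(d$deltaV, 10 + 4 / 6)
  expect_error(dual_boost(80, 8, boost_params(E_P = 1, alpha_P = 1), "dual"),
               "alpha_D")
})

test_that("modified force equals the analytic gradient of V' = V + deltaV", {
  set.seed(31)
  hx <- make_cg_helix(8)
  bp <- boost_params(E_P = 50, alpha_P = 10, E_D = 8, alpha_D = 4)
  for (comp in c("additive", "nested")) {
    x <- hx$reference + matrix(rnorm(24, sd = 0.3), 8)
    bg <- boosted_gradient(hx, x, bp, mode = "dual", composition = comp)
    vprime <- function(xx) {
      b <- boosted_gradient(hx, xx, bp, mode = "dual", composition = comp)
      b$V + b$deltaV
    }
    fd <- x * 0
    h <- 1e-6
    for (i in 1:8) for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      fd[i, k] <- (vprime(xp) - vprime(xm)) / (2 * h)
    }
    expect_lt(max(abs(bg$gradient - fd)) / max(abs(fd)), 1e-5)
    expect_gte(bg$deltaV, 0)
  }
})

test_that("NVE integration conserves energy to <1% at dt = period/100", {
  k <- 10; m <- 12
  h <- make_harmonic(k, mass = m)
  omega <- sqrt(418.4 * k / m)
  dt <- (2 * pi / omega) / 100
  cfg <- simulation_config(timestep = dt, temperature = 300,
                           collision_frequency = 0, n_steps = 10000,
                           save_interval = 10, seed = 3)
  tr <- run_simulation(h, cfg, coords = matrix(0.8, 1, 1),
                       velocities = matrix(0, 1, 1))
  E <- tr$scalars$V + 0.5 * KB_KCALMOL * tr$scalars$T_inst  # KE = ndof*kB*T/2
  E0 <- E[1]
  expect_gt(E0, 0)
  expect_lt(max(abs(E - E0)) / E0, 0.01)
})

test_that("thermostatted dynamics satisfies equipartition at the target T", {
  h <- make_harmonic(10, mass = 12)
  cfg <- simulation_config(timestep = 0.002, temperature = 300,
                           collision_frequency = 5, n_steps = 400000,
                           save_interval = 100, seed = 17)
  tr <- run_simulation(h, cfg)
  Ts <- tr$scalars$T_inst[-(1:200)]             # drop equilibration
  blocks <- split(Ts, cut(seq_along(Ts), 40))
  bm <- vapply(blocks, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(bm) - 300), 3 * se + 10)
})

test_that("boost with thresholds below all sampled energies is bit-for-bit inert", {
  d <- dwell_test_traj(seed = 21)
  vmin <- min(d$traj$scalars$V)
  bp <- boost_params(E_P = vmin - 50, alpha_P = 5,
                     E_D = -1, alpha_D = 1)     # V_D = 0 >= E_D: inactive
  cfg_b <- d$config
  cfg_b$boost_mode <- "dual"
  tr_b <- run_simulation(d$system, cfg_b, bp)
  expect_identical(tr_b$coords, d$traj$coords)
  expect_identical(tr_b$scalars$V, d$traj$scalars$V)
  expect_true(all(tr_b$scalars$deltaV == 0))
})

test_that("the trajectory is a pure function of (seed, config, system)", {
  a <- dwell_test_traj(seed = 9)$traj
  b <- dwell_test_traj(seed = 9)$traj
  expect_identical(a$coords, b$coords)
  expect_identical(a$scalars, b$scalars)
  c <- dwell_test_traj(seed = 10)$traj
  expect_false(identical(a$coords, c$coords))
  expect_true(all(diff(a$scalars$time_ps) > 0))
  expect_true(all(a$scalars$deltaV == 0))
})

test_that("heat ramp warms the system from 0 K to the target", {
  h <- make_harmonic(10, mass = 12)
  cfg <- simulation_config(timestep = 0.002, temperature = 300,
                           collision_frequency = 5, n_steps = 200000,
                           save_interval = 100, heat_ramp_steps = 100000,
                           seed = 4)
  tr <- run_simulation(h, cfg)
  Ts <- tr$scalars$T_inst
  n <- length(Ts)
  expect_lt(mean(Ts[2:100]), mean(Ts[(n - 500):n]))  # early cold, late warm
  expect_lt(abs(mean(Ts[(n - 800):n]) - 300), 60)
  expect_equal(Ts[1], 0)                              # starts at rest
})

test_that("divergent runs are truncated and reported", {
  dw <- make_double_well(6, 2)
  cfg <- simulation_config(timestep = 5, temperature = 300, n_steps = 5000,
                           save_interval = 10, seed = 2, energy_ceiling = 1e6)
  expect_warning(tr <- run_simulation(dw, cfg), "diverged")
  expect_identical(tr$status, "diverged")
  expect_lt(n_frames(tr), 501)
})

test_that("a single gamma=0 langevin_step is one velocity-Verlet update", {
  k <- 10; m <- 12
  h <- make_harmonic(k, mass = m)
  dt <- 0.002
  cfg <- simulation_config(timestep = dt, temperature = 300,
                           collision_frequency = 0, n_steps = 1, seed = 1)
  x0 <- 0.7; v0 <- 3.1
  st <- langevin_step(h, list(positions = matrix(x0, 1, 1),
                              velocities = matrix(v0, 1, 1)), cfg)
  vh <- v0 + 0.5 * dt * 418.4 * (-k * x0) / m
  x1 <- x0 + dt * vh
  v1 <- vh + 0.5 * dt * 418.4 * (-k * x1) / m
  expect_equal(st$positions[1, 1], x1, tolerance = 1e-12)
  expect_equal(st$velocities[1, 1], v1, tolerance = 1e-12)
})

test_that("minimization descends to the correct basin", {
  h <- make_harmonic(10)
  m <- minimize(h, matrix(3.2, 1, 1))
  expect_true(m$converged)
  expect_lt(abs(m$coords[1, 1]), 1e-4)
  dw <- make_double_well(6, 2)
  expect_gt(minimize(dw, matrix(0.1, 1, 1))$coords[1, 1], 1.9)
  expect_lt(minimize(dw, matrix(-0.1, 1, 1))$coords[1, 1], -1.9)
  hx <- make_cg_helix(8)
  start <- hx$reference
  res <- minimize(hx, start)
  expect_lte(res$energy, potential_energy(hx, start))
})

test_that("boosted runs record a non-negative bias on every frame", {
  dw <- make_double_well(6, 2)
  cfg0 <- simulation_config(n_steps = 20000, save_interval = 10, seed = 6,
                            temperature = 300, timestep = 0.002)
  bp <- calibrate_boost(dw, cfg0, n_res = 5, n_atom = 25)
  cfg <- simulation_config(n_steps = 20000, save_interval = 10, seed = 6,
                           temperature = 300, timestep = 0.002,
                           boost_mode = "total")
  tr <- run_simulation(dw, cfg, bp)
  expect_true(all(tr$scalars$deltaV >= 0))
  expect_gt(max(tr$scalars$deltaV), 0)
  expect_error(run_simulation(dw, cfg), "requires boost")
})
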