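# Shared oracles and fixture builders, independent of the code paths they
# check.

# central finite-difference gradient of the total (or dihedral) energy
fd_gradient <- function(system, coords, component = "total", h = 1e-6) {
  fn <- if (component == "total") potential_energy else dihedral_energy
  g <- coords * 0
  for (i in seq_len(nrow(coords))) for (k in seq_len(ncol(coords))) {
    xp <- coords; xp[i, k] <- xp[i, k] + h
    xm <- coords; xm[i, k] <- xm[i, k] - h
    g[i, k] <- (fn(system, xp) - fn(system, xm)) / (2 * h)
  }
  g
}

# quaternion -> rotation matrix
quat_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force minimum RMSD over rotations: quaternion grid + local refine.
# Deliberately independent of the Kabsch implementation.
brute_force_rmsd <- function(mobile, reference, n_grid = 3000) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best_q <- c(1, 0, 0, 0)
  best <- obj(best_q)
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  for (i in seq_len(n_grid)) {
    v <- obj(qs[i, ])
    if (v < best) { best <- v; best_q <- qs[i, ] }
  }
  opt <- stats::optim(best_q, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value, opt2$value)
}

random_rotation <- function() quat_rot(rnorm(4))

# short double-well MD trajectory shared by several tests
dwell_test_traj <- function(seed = 5, n_steps = 5000) {
  dw <- make_double_well(6, 2, mass = 12)
  cfg <- simulation_config(n_steps = n_steps, save_interval = 10, seed = seed,
                           temperature = 300, timestep = 0.002)
  list(system = dw, config = cfg, traj = run_simulation(dw, cfg))
}

# planted conformer mixture: frames drawn from rigidly transformed copies of
# distinct conformers plus per-bead Gaussian jitter
planted_mixture <- function(counts, jitter = 0.1, n_res = 12, seed = 42) {
  set.seed(seed)
  confs <- list(ideal_helix_coords(n_res), extended_coords(n_res, 3.8))
  if (length(counts) > 2) {
    half <- rbind(ideal_helix_coords(ceiling(n_res / 2)),
                  extended_coords(floor(n_res / 2), 3.8) +
                    matrix(rep(c(0, 8, 0), each = floor(n_res / 2)),
                           ncol = 3))
    confs[[3]] <- half[seq_len(n_res), ]
  }
  labels <- rep(seq_along(counts), counts)
  frames <- array(NA_real_, c(length(labels), n_res, 3))
  for (f in seq_along(labels)) {
    base <- confs[[labels[f]]]
    R <- random_rotation()
    frames[f, , ] <- base %*% t(R) +
      matrix(rnorm(length(base), sd = jitter), nrow(base)) +
      matrix(rep(rnorm(3, sd = 5), each = n_res), ncol = 3)
  }
  list(frames = frames, labels = labels, conformers = confs)
}
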