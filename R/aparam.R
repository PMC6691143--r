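# Boost-threshold parameterization from a short unbiased pre-run.
#
#   E_D = E_D' + a1 * N_res / 5      alpha_D = a1 * N_res / 5
#   E_P = E_P' + a2 * N_atom         alpha_P = a2 * N_atom
#
# E_P' and E_D' are the mean total and dihedral energies of the pre-run;
# a1 = 3.5 and a2 = 0.2 kcal/mol are the conventional defaults.

#' Mean energies of an unbiased pre-run
#'
#' Arithmetic means of the per-frame total and dihedral potential energy
#' over an equilibrated window. The default discards the first half of the
#' frames as burn-in; a run that follows a heating ramp needs some
#' equilibration before its averages are meaningful.
#'
#' @param traj a `trajectory_record` produced with `boost_mode = "none"`
#' @param burn_in_frac fraction of initial frames discarded (in \[0, 1))
#' @return list with `E_P_prime` and `E_D_prime` (kcal/mol)
#' @export
average_energies <- function(traj, burn_in_frac = 0.5) {
  if (!inherits(traj, "trajectory_record")) stop("traj must be a trajectory_record")
  if (traj$config$boost_mode != "none")
    stop("pre-run averages require an unbiased (boost_mode = 'none') trajectory")
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  if (burn_in_frac < 0 || burn_in_frac >= 1) stop("burn_in_frac must be in [0, 1)")
  keep <- seq.int(floor(nf * burn_in_frac) + 1, nf)
  list(E_P_prime = mean(traj$scalars$V[keep]),
       E_D_prime = mean(traj$scalars$V_D[keep]))
}

#' Estimate dual-boost thresholds and strengths
#'
#' Scales the pre-run averages up by per-residue (`a1 * N_res / 5`) and
#' per-atom (`a2 * N_atom`) increments. By construction
#' `alpha_D = E_D - E_D_prime` and `alpha_P = E_P - E_P_prime`, so both
#' thresholds sit above the sampled means and the boost is active in the
#' typical region.
#'
#' @param E_P_prime,E_D_prime pre-run mean total / dihedral energy (kcal/mol)
#' @param a1 dihedral increment per 5 residues (kcal/mol), default 3.5
#' @param a2 total-potential increment per atom (kcal/mol), default 0.2
#' @param n_res,n_atom residue and atom counts (for 1-particle analytic
#'   systems supply effective counts; see the methods vignette)
#' @return a [boost_params()] with provenance fields populated
#' @export
estimate_thresholds <- function(E_P_prime, E_D_prime, a1 = 3.5, a2 = 0.2,
                                n_res, n_atom) {
  if (a1 <= 0 || a2 <= 0) stop("a1 and a2 must be > 0")
  if (n_res < 1 || n_atom < 1) stop("n_res and n_atom must be >= 1")
  alpha_D <- a1 * n_res / 5
  alpha_P <- a2 * n_atom
  boost_params(E_P = E_P_prime + alpha_P, alpha_P = alpha_P,
               E_D = E_D_prime + alpha_D, alpha_D = alpha_D,
               E_P_prime = E_P_prime, E_D_prime = E_D_prime,
               a1 = a1, a2 = a2,
               N_res = as.integer(n_res), N_atom = as.integer(n_atom))
}

#' Pre-run + threshold estimation in one call
#'
#' Runs a short unbiased simulation and derives [boost_params()] from it.
#'
#' @param system a `model_system`
#' @param config a [simulation_config()] with `boost_mode = "none"`
#' @param a1,a2 increments (kcal/mol)
#' @param n_res,n_atom effective counts; default to the system's own
#' @param burn_in_frac see [average_energies()]
#' @return a [boost_params()]
#' @export
calibrate_boost <- function(system, config, a1 = 3.5, a2 = 0.2,
                            n_res = system$n_res, n_atom = system$n_atom,
                            burn_in_frac = 0.5) {
  if (config$boost_mode != "none") stop("calibration pre-run must be unbiased")
  pre <- run_simulation(system, config)
  av <- average_energies(pre, burn_in_frac = burn_in_frac)
  estimate_thresholds(av$E_P_prime, av$E_D_prime, a1 = a1, a2 = a2,
                      n_res = n_res, n_atom = n_atom)
}
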