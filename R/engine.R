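# Langevin dynamics with optional dual-boost aMD bias.
#
# The bias adds, wherever an energy falls below its threshold E, the term
#   deltaV = (E - V)^2 / (alpha + E - V)
# which raises basins and leaves everything at or above E untouched; alpha
# controls how aggressively the landscape is flattened beneath E.

#' Single-term aMD boost energy
#'
#' \eqn{\Delta V = (E - V)^2 / (\alpha + E - V)} for \eqn{V < E}, else 0.
#' The boost is non-negative everywhere.
#'
#' @param V instantaneous energy (kcal/mol); vectorized
#' @param E threshold energy (kcal/mol)
#' @param alpha acceleration strength (kcal/mol), > 0
#' @return boost energy (kcal/mol), >= 0
#' @export
boost_energy <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  u <- E - V
  ifelse(u > 0, u^2 / (alpha + u), 0)
}

#' Force scale factor of the boosted potential
#'
#' The derivative \eqn{dV'/dV = \alpha^2 / (\alpha + E - V)^2} for
#' \eqn{V < E}, else 1: the factor by which forces derived from the boosted
#' energy are damped below the threshold. Continuous at `V = E`, in (0, 1].
#'
#' @inheritParams boost_energy
#' @return dimensionless scale in (0, 1]
#' @export
boost_force_scale <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  u <- E - V
  ifelse(u > 0, alpha^2 / (alpha + u)^2, 1)
}

#' Dual-boost parameter set
#'
#' Thresholds and strengths for the total-potential boost (`E_P`, `alpha_P`)
#' and the dihedral boost (`E_D`, `alpha_D`), with the provenance of the
#' estimate (pre-run averages and the `a1`/`a2` proportionality constants).
#'
#' @param E_P,alpha_P total-potential threshold and strength (kcal/mol)
#' @param E_D,alpha_D dihedral threshold and strength (kcal/mol)
#' @param E_P_prime,E_D_prime pre-run mean total / dihedral energy (kcal/mol)
#' @param a1,a2 per-residue / per-atom increments used (kcal/mol)
#' @param N_res,N_atom counts the thresholds were scaled by
#' @return a `boost_params` object
#' @export
boost_params <- function(E_P = NA_real_, alpha_P = NA_real_,
                         E_D = NA_real_, alpha_D = NA_real_,
                         E_P_prime = NA_real_, E_D_prime = NA_real_,
                         a1 = NA_real_, a2 = NA_real_,
                         N_res = NA_integer_, N_atom = NA_integer_) {
  structure(list(E_P = E_P, alpha_P = alpha_P, E_D = E_D, alpha_D = alpha_D,
                 E_P_prime = E_P_prime, E_D_prime = E_D_prime,
                 a1 = a1, a2 = a2, N_res = N_res, N_atom = N_atom),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat(sprintf(
    "<boost_params: E_P=%.4g alpha_P=%.4g E_D=%.4g alpha_D=%.4g (kcal/mol)>\n",
    x$E_P, x$alpha_P, x$E_D, x$alpha_D))
  invisible(x)
}

.check_boost_mode <- function(boost, mode) {
  needs_P <- mode %in% c("total", "dual")
  needs_D <- mode %in% c("dihedral", "dual")
  if (mode != "none" && is.null(boost))
    stop(sprintf("boost_mode '%s' requires boost parameters", mode))
  if (needs_P && (!is.finite(boost$E_P) || !is.finite(boost$alpha_P) ||
                  boost$alpha_P <= 0))
    stop("total/dual boost requires finite E_P and alpha_P > 0")
  if (needs_D && (!is.finite(boost$E_D) || !is.finite(boost$alpha_D) ||
                  boost$alpha_D <= 0))
    stop("dihedral/dual boost requires finite E_D and alpha_D > 0")
  invisible(TRUE)
}

# boost parameters in the form the compiled code takes
.boost_cpp <- function(boost, mode, composition = "additive") {
  mode_int <- match(mode, c("none", "dihedral", "total", "dual")) - 1L
  if (is.na(mode_int)) stop("unknown boost_mode: ", mode)
  comp_int <- match(composition, c("additive", "nested")) - 1L
  if (is.na(comp_int)) stop("unknown dual_composition: ", composition)
  list(mode_int = mode_int, composition_int = comp_int,
       E_P = if (is.null(boost)) 0 else boost$E_P,
       alpha_P = if (is.null(boost)) 1 else boost$alpha_P,
       E_D = if (is.null(boost)) 0 else boost$E_D,
       alpha_D = if (is.null(boost)) 1 else boost$alpha_D)
}

#' Dual-boost bias energy and force-composition rule
#'
#' Evaluates the additive two-term bias
#' \eqn{\Delta V = \Delta V_P(V) + \Delta V_D(V_D)} for the requested mode
#' and returns the scale factors that compose the modified force: the
#' gradient of \eqn{V' = V + \Delta V} is
#' `scale_total * grad(V) + (scale_dihedral - 1) * grad(V_D)`.
#'
#' @param V total potential energy (kcal/mol)
#' @param V_D dihedral energy (kcal/mol)
#' @param params a [boost_params()] object (may be `NULL` for mode "none")
#' @param mode one of `"none"`, `"dihedral"`, `"total"`, `"dual"`
#' @return list with `deltaV`, `scale_total`, `scale_dihedral`
#' @export
dual_boost <- function(V, V_D, params, mode = c("dual", "none", "dihedral", "total")) {
  mode <- match.arg(mode)
  if (mode == "none")
    return(list(deltaV = 0, scale_total = 1, scale_dihedral = 1))
  .check_boost_mode(params, mode)
  dV <- 0; sP <- 1; sD <- 1
  if (mode %in% c("total", "dual")) {
    dV <- dV + boost_energy(V, params$E_P, params$alpha_P)
    sP <- boost_force_scale(V, params$E_P, params$alpha_P)
  }
  if (mode %in% c("dihedral", "dual")) {
    dV <- dV + boost_energy(V_D, params$E_D, params$alpha_D)
    sD <- boost_force_scale(V_D, params$E_D, params$alpha_D)
  }
  list(deltaV = dV, scale_total = sP, scale_dihedral = sD)
}

#' Gradient of the boosted potential V' = V + deltaV
#'
#' @param system a `model_system`
#' @param coords coordinate matrix
#' @param boost a [boost_params()] object or `NULL`
#' @param mode boost mode
#' @param composition `"additive"` (the literal two-term bias) or `"nested"`
#'   (dihedral-boosted energy fed into the total boost)
#' @return list with `gradient` (matrix), `deltaV`, `V`, `V_D`
#' @export
boosted_gradient <- function(system, coords, boost = NULL, mode = "none",
                             composition = "additive") {
  coords <- .check_coords(system, coords)
  if (mode != "none") .check_boost_mode(boost, mode)
  r <- .cpp_boosted_gradient(unclass(system), .flat(coords),
                             .boost_cpp(boost, mode, composition))
  list(gradient = .unflat(r$gradient, system$dim), deltaV = r$deltaV,
       V = r$V, V_D = r$V_D)
}

#' Simulation configuration
#'
#' @param timestep integration timestep (ps)
#' @param temperature target temperature (K)
#' @param collision_frequency Langevin friction (1/ps); 0 gives
#'   velocity-Verlet (NVE) integration
#' @param n_steps number of integration steps
#' @param save_interval record a frame every this many steps
#' @param seed integer RNG seed; fully determines the trajectory
#' @param boost_mode `"none"`, `"dihedral"`, `"total"` or `"dual"`
#' @param heat_ramp_steps thermostat target ramped linearly from 0 K to
#'   `temperature` over this many initial steps (0 = start thermalized)
#' @param minimize_first run energy minimization before dynamics
#' @param dual_composition `"additive"` or `"nested"` (see [boosted_gradient()])
#' @param energy_ceiling abort threshold on |V| (kcal/mol)
#' @return a `simulation_config` object
#' @export
simulation_config <- function(timestep = 0.002, temperature = 300,
                              collision_frequency = 1.0, n_steps = 1000L,
                              save_interval = 10L, seed = 1L,
                              boost_mode = c("none", "dihedral", "total", "dual"),
                              heat_ramp_steps = 0L, minimize_first = FALSE,
                              dual_composition = c("additive", "nested"),
                              energy_ceiling = 1e8) {
  boost_mode <- match.arg(boost_mode)
  dual_composition <- match.arg(dual_composition)
  stopifnot(timestep > 0, temperature >= 0, collision_frequency >= 0,
            n_steps >= 1, save_interval >= 1, energy_ceiling > 0,
            heat_ramp_steps >= 0)
  structure(list(timestep = timestep, temperature = temperature,
                 collision_frequency = collision_frequency,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed), boost_mode = boost_mode,
                 heat_ramp_steps = as.integer(heat_ramp_steps),
                 minimize_first = minimize_first,
                 dual_composition = dual_composition,
                 energy_ceiling = energy_ceiling),
            class = "simulation_config")
}

# Maxwell-Boltzmann velocities (A/ps)
.mb_velocities <- function(system, temperature) {
  n <- system$n_particles * system$dim
  m <- rep(system$masses, each = system$dim)
  rnorm(n) * sqrt(.KFAC * KB_KCALMOL * temperature / m)
}

.default_start <- function(system) {
  switch(system$kind,
         double_well = matrix(-system$params$half_separation, 1, 1),
         harmonic = matrix(0, 1, 1),
         cg_helix = system$reference,
         stop("no default start for kind ", system$kind))
}

#' One BAOAB Langevin step
#'
#' Building-block single update with the (possibly boosted) forces. Consumes
#' the R random number stream; seed control is the caller's responsibility.
#' With `collision_frequency = 0` and boost off this is one velocity-Verlet
#' step.
#'
#' @param system a `model_system`
#' @param state list with `positions` (matrix) and `velocities` (matrix, A/ps)
#' @param config a [simulation_config()]
#' @param boost a [boost_params()] or `NULL`
#' @return updated state list
#' @export
langevin_step <- function(system, state, config, boost = NULL) {
  if (config$boost_mode != "none") .check_boost_mode(boost, config$boost_mode)
  x <- .check_coords(system, state$positions)
  r <- .cpp_langevin_run(unclass(system), .flat(x), .flat(state$velocities),
                         system$masses, config$timestep, 1L, 1L,
                         config$collision_frequency, config$temperature, 0L,
                         .boost_cpp(boost, config$boost_mode,
                                    config$dual_composition),
                         config$energy_ceiling)
  list(positions = .unflat(r$final_x, system$dim),
       velocities = .unflat(r$final_v, system$dim))
}

#' Run a Langevin MD / aMD simulation
#'
#' Integrates the system with the BAOAB Langevin scheme, recording a frame
#' every `save_interval` steps (the initial configuration is frame 1). With
#' `boost_mode = "none"` this is plain ("traditional") MD; otherwise the
#' requested aMD bias modifies the forces and the per-frame bias energy
#' `deltaV` is recorded for reweighting. The seed in `config` fully
#' determines the output.
#'
#' @param system a `model_system`
#' @param config a [simulation_config()]
#' @param boost a [boost_params()]; required unless `boost_mode = "none"`
#' @param coords starting coordinates (default: the system's reference or
#'   minimum)
#' @param velocities starting velocities; default Maxwell-Boltzmann at the
#'   target temperature, or zero when a heat ramp is requested
#' @return a `trajectory_record`
#' @export
run_simulation <- function(system, config, boost = NULL, coords = NULL,
                           velocities = NULL) {
  if (config$boost_mode != "none") .check_boost_mode(boost, config$boost_mode)
  if (is.null(coords)) coords <- .default_start(system)
  coords <- .check_coords(system, coords)
  set.seed(config$seed)
  if (config$minimize_first)
    coords <- minimize(system, coords)$coords
  if (is.null(velocities)) {
    velocities <- if (config$heat_ramp_steps > 0)
      matrix(0, system$n_particles, system$dim)
    else .unflat(.mb_velocities(system, config$temperature), system$dim)
  }
  r <- .cpp_langevin_run(unclass(system), .flat(coords), .flat(velocities),
                         system$masses, config$timestep, config$n_steps,
                         config$save_interval, config$collision_frequency,
                         config$temperature, config$heat_ramp_steps,
                         .boost_cpp(boost, config$boost_mode,
                                    config$dual_composition),
                         config$energy_ceiling)
  if (r$status != 0)
    warning(sprintf("simulation diverged at step %d; trajectory truncated",
                    r$fail_step))
  nf <- length(r$time_ps)
  coords_arr <- array(NA_real_, c(nf, system$n_particles, system$dim))
  for (f in seq_len(nf))
    coords_arr[f, , ] <- .unflat(r$coords[f, ], system$dim)
  structure(list(
    coords = coords_arr,
    scalars = data.frame(time_ps = r$time_ps, V = r$V, V_D = r$V_D,
                         deltaV = r$deltaV, T_inst = r$T_inst),
    config = config, boost = boost,
    system_kind = system$kind,
    final_state = list(positions = .unflat(r$final_x, system$dim),
                       velocities = .unflat(r$final_v, system$dim)),
    status = if (r$status == 0) "ok" else "diverged"),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf(
    "<trajectory_record: %d frames, %s, boost_mode=%s, T=%g K, status=%s>\n",
    nrow(x$scalars), x$system_kind, x$config$boost_mode,
    x$config$temperature, x$status))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory_record`
#' @return integer frame count
#' @export
n_frames <- function(traj) nrow(traj$scalars)

#' Energy minimization: steepest descent then conjugate gradient
#'
#' A backtracking steepest-descent phase takes the structure into the local
#' basin; a conjugate-gradient phase (via [stats::optim()]) then converges
#' it. The energy is non-increasing across accepted steps.
#'
#' @param system a `model_system`
#' @param coords starting coordinates
#' @param max_iter total iteration budget
#' @param gtol convergence threshold on the gradient max-norm (kcal/mol/A)
#' @param sd_iter iterations of the steepest-descent phase
#' @return list with `coords`, `energy`, `grad_norm`, `converged`, `n_eval`
#' @export
minimize <- function(system, coords, max_iter = 500L, gtol = 1e-4,
                     sd_iter = 50L) {
  coords <- .check_coords(system, coords)
  x <- .flat(coords)
  fn <- function(v) .cpp_energy(unclass(system), v)$V
  gr <- function(v) .cpp_energy(unclass(system), v)$gradient
  e <- fn(x)
  step <- 0.1
  for (it in seq_len(sd_iter)) {
    g <- gr(x)
    gn <- max(abs(g))
    if (gn <= gtol) break
    repeat { # backtracking line search along -g
      xn <- x - step * g / max(gn, 1e-12)
      en <- fn(xn)
      if (is.finite(en) && en <= e) break
      step <- step / 2
      if (step < 1e-12) { xn <- x; en <- e; break }
    }
    x <- xn; e <- en
    step <- min(step * 1.5, 1.0)
  }
  gn <- max(abs(gr(x)))
  if (gn > gtol) {
    opt <- stats::optim(x, fn, gr, method = "CG",
                        control = list(maxit = max(max_iter - sd_iter, 1L)))
    if (opt$value <= e) { x <- opt$par; e <- opt$value }
    gn <- max(abs(gr(x)))
    # CG stops on function decrease; polish with BFGS if gradient still large
    if (gn > gtol) {
      opt <- stats::optim(x, fn, gr, method = "BFGS",
                          control = list(maxit = max_iter))
      if (opt$value <= e) { x <- opt$par; e <- opt$value }
      gn <- max(abs(gr(x)))
    }
  }
  list(coords = .unflat(x, system$dim), energy = e, grad_norm = gn,
       converged = gn <= gtol, n_eval = NA_integer_)
}
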