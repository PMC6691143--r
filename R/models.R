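# Desk-scale model systems: analytic low-dimensional potentials with known
# Boltzmann distributions, and a coarse-grained Go-like helical peptide.

#' Construct a one-dimensional double-well system
#'
#' \eqn{V(x) = h\,((x/w)^2 - 1)^2}: minima at \eqn{x = \pm w} with
#' \eqn{V = 0} and a barrier of height \eqn{h} at \eqn{x = 0}. The dihedral
#' component \eqn{V_D} is identically zero.
#'
#' @param barrier_height barrier height `h` (kcal/mol), > 0
#' @param half_separation half-distance `w` between the minima (Angstrom), > 0
#' @param mass particle mass (amu)
#' @return a `model_system` object
#' @export
make_double_well <- function(barrier_height, half_separation, mass = 12) {
  if (!is.numeric(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be > 0")
  if (!is.numeric(half_separation) || half_separation <= 0)
    stop("half_separation must be > 0")
  if (mass <= 0) stop("mass must be > 0")
  new_model_system(
    kind = "double_well", n_particles = 1L, dim = 1L, masses = mass,
    n_res = 1L, n_atom = 1L,
    params = list(barrier_height = barrier_height,
                  half_separation = half_separation),
    term_names = "well")
}

#' Construct a one-dimensional harmonic oscillator
#'
#' \eqn{V(x) = \tfrac12 k x^2}; its canonical distribution is Gaussian with
#' variance \eqn{k_B T / k}, which makes it the reference case for
#' integrator-accuracy and reweighting checks.
#'
#' @param force_constant spring constant `k` (kcal/mol/A^2), > 0
#' @param mass particle mass (amu)
#' @return a `model_system` object
#' @export
make_harmonic <- function(force_constant, mass = 12) {
  if (force_constant <= 0) stop("force_constant must be > 0")
  if (mass <= 0) stop("mass must be > 0")
  new_model_system(
    kind = "harmonic", n_particles = 1L, dim = 1L, masses = mass,
    n_res = 1L, n_atom = 1L,
    params = list(force_constant = force_constant),
    term_names = "well")
}

#' Ideal alpha-helix C-alpha trace
#'
#' Beads on a helix of radius 2.3 A, rise 1.5 A per residue, 100 degrees of
#' twist per residue -- the standard C-alpha geometry of an alpha-helix.
#' Serves as the synthetic "native structure" of the coarse-grained model.
#'
#' @param n_res number of residues (>= 1)
#' @param radius,rise,twist_deg helix geometry (A, A per residue, degrees
#'   per residue)
#' @return an `n_res x 3` coordinate matrix (A)
#' @export
ideal_helix_coords <- function(n_res, radius = 2.3, rise = 1.5,
                               twist_deg = 100) {
  if (n_res < 1) stop("n_res must be >= 1")
  i <- seq_len(n_res) - 1
  ang <- i * twist_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * i)
}

#' Extended (linear) chain coordinates
#'
#' Collinear beads at uniform spacing along x, the desk-scale analog of an
#' unfolded starting structure.
#'
#' @param n_res number of residues (>= 1)
#' @param spacing inter-bead distance (A), > 0
#' @return an `n_res x 3` coordinate matrix (A)
#' @export
extended_coords <- function(n_res, spacing = 3.8) {
  if (n_res < 1) stop("n_res must be >= 1")
  if (spacing <= 0) stop("spacing must be > 0")
  i <- seq_len(n_res) - 1
  cbind(spacing * i, 0, 0)
}

#' Construct the coarse-grained Go-like helical peptide
#'
#' One bead per residue. The energy decomposes into harmonic bonds
#' (`bond_k (r - r0)^2`), harmonic pseudo-angles, periodic pseudo-dihedral
#' terms with minimum at the ideal-helix dihedral (these torsion terms
#' constitute the dihedral component \eqn{V_D}), attractive 12-10 wells on
#' the native-contact pairs of the ideal-helix reference (minimum `-contact_eps`
#' at the native distance), and inverse-12 excluded-volume repulsion on all
#' other non-adjacent pairs. Attraction only at native contacts biases the
#' model toward the helical fold, in the spirit of Go models.
#'
#' @param n_res number of residues (>= 5, so at least one dihedral exists)
#' @param bond_k bond force coefficient (kcal/mol/A^2)
#' @param angle_k pseudo-angle coefficient (kcal/mol/rad^2)
#' @param torsion_k pseudo-dihedral amplitude (kcal/mol); term is
#'   `torsion_k * (1 - cos(phi - phi0))`
#' @param contact_eps native-contact well depth (kcal/mol)
#' @param repulsion_sigma excluded-volume length scale (A)
#' @param bond_r0 equilibrium bond length (A)
#' @param repulsion_eps excluded-volume prefactor (kcal/mol)
#' @param mass bead mass (amu); the mass of an average residue by default
#' @param contact_cutoff,contact_min_seq_sep native-contact definition applied
#'   to the ideal-helix reference (A; residue separation)
#' @return a `model_system` object with `n_res = n_atom =` number of beads
#' @export
make_cg_helix <- function(n_res, bond_k = 100, angle_k = 20, torsion_k = 2.0,
                          contact_eps = 3.0, repulsion_sigma = 4.0,
                          bond_r0 = 3.8, repulsion_eps = 1.0, mass = 110,
                          contact_cutoff = 7.0, contact_min_seq_sep = 2L) {
  if (n_res < 5)
    stop("n_res must be >= 5 (no pseudo-dihedral is defined below 5 residues)")
  stopifnot(bond_k > 0, angle_k > 0, torsion_k > 0, contact_eps > 0,
            repulsion_sigma > 0, mass > 0)
  ref <- ideal_helix_coords(n_res)

  # reference internal geometry
  theta0 <- .bead_angle(ref[1, ], ref[2, ], ref[3, ])
  phi0 <- .bead_dihedral(ref[1, ], ref[2, ], ref[3, ], ref[4, ])

  # native contacts of the reference, same rule as the analysis module
  cs <- native_contacts(ref, cutoff = contact_cutoff,
                        min_seq_sep = contact_min_seq_sep)
  if (nrow(cs$pairs) == 0) stop("reference has no native contacts")
  csig <- sqrt(rowSums((ref[cs$pairs[, 1], , drop = FALSE] -
                        ref[cs$pairs[, 2], , drop = FALSE])^2))

  # all remaining non-adjacent pairs are purely repulsive
  all_pairs <- which(upper.tri(matrix(0, n_res, n_res)), arr.ind = TRUE)
  all_pairs <- all_pairs[all_pairs[, 2] - all_pairs[, 1] >= contact_min_seq_sep, ,
                         drop = FALSE]
  key <- function(p) paste(p[, 1], p[, 2])
  rep_pairs <- all_pairs[!(key(all_pairs) %in% key(cs$pairs)), , drop = FALSE]

  new_model_system(
    kind = "cg_helix", n_particles = as.integer(n_res), dim = 3L,
    masses = rep(mass, n_res), n_res = as.integer(n_res),
    n_atom = as.integer(n_res),
    params = list(
      bond_k = bond_k, r0 = bond_r0, angle_k = angle_k, theta0 = theta0,
      torsion_k = torsion_k, phi0 = phi0, contact_eps = contact_eps,
      repulsion_eps = repulsion_eps, repulsion_sigma = repulsion_sigma,
      contact_pairs = unname(as.matrix(cs$pairs)) - 1L,   # 0-based for C++
      contact_sigma = csig,
      repulsive_pairs = unname(as.matrix(rep_pairs)) - 1L,
      contact_cutoff = contact_cutoff,
      contact_min_seq_sep = contact_min_seq_sep),
    term_names = c("bond", "angle", "torsion", "contact", "repulsion"),
    reference = ref)
}

new_model_system <- function(kind, n_particles, dim, masses, n_res, n_atom,
                             params, term_names, reference = NULL) {
  stopifnot(n_res >= 1, n_atom >= 1, all(masses > 0))
  structure(list(kind = kind, n_particles = n_particles, dim = dim,
                 masses = masses, n_res = n_res, n_atom = n_atom,
                 params = params, term_names = term_names,
                 reference = reference),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf("<model_system '%s': %d particle(s), dim %d, N_res=%d, N_atom=%d>\n",
              x$kind, x$n_particles, x$dim, x$n_res, x$n_atom))
  invisible(x)
}

.check_coords <- function(system, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = system$dim)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (nrow(coords) != system$n_particles || ncol(coords) != system$dim)
    stop(sprintf("coordinates must be %d x %d", system$n_particles, system$dim))
  coords
}

#' Total potential energy of a model system
#' @param system a `model_system`
#' @param coords coordinate matrix (n_particles x dim, A)
#' @return energy in kcal/mol
#' @export
potential_energy <- function(system, coords) {
  coords <- .check_coords(system, coords)
  .cpp_energy(unclass(system), .flat(coords))$V
}

#' Named energy components
#'
#' The total potential equals the sum of the named components exactly.
#' @inheritParams potential_energy
#' @return named numeric vector (kcal/mol)
#' @export
energy_terms <- function(system, coords) {
  coords <- .check_coords(system, coords)
  .cpp_energy(unclass(system), .flat(coords))$terms
}

#' Dihedral energy component V_D
#' @inheritParams potential_energy
#' @return kcal/mol (0 for systems without torsion terms)
#' @export
dihedral_energy <- function(system, coords) {
  coords <- .check_coords(system, coords)
  .cpp_energy(unclass(system), .flat(coords))$V_D
}

#' Analytic gradient of the potential
#' @inheritParams potential_energy
#' @param component `"total"` for the gradient of V, `"dihedral"` for the
#'   gradient of V_D
#' @return gradient matrix (n_particles x dim, kcal/mol/A)
#' @export
energy_gradient <- function(system, coords, component = c("total", "dihedral")) {
  component <- match.arg(component)
  coords <- .check_coords(system, coords)
  e <- .cpp_energy(unclass(system), .flat(coords))
  g <- if (component == "total") e$gradient else e$gradient_D
  .unflat(g, system$dim)
}

# internal geometry helpers (R side, used at model construction and in the
# analysis module)
.bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cs)))
}

.bead_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
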