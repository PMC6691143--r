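test_that("double well has the constructed minima, barrier and symmetry", {
  dw <- make_double_well(5, 2)
  expect_equal(potential_energy(dw, matrix(2, 1, 1)), 0)
  expect_equal(potential_energy(dw, matrix(-2, 1, 1)), 0)
  expect_equal(potential_energy(dw, matrix(0, 1, 1)), 5)
  expect_equal(energy_gradient(dw, matrix(0, 1, 1))[1, 1], 0)
  expect_equal(dihedral_energy(dw, matrix(1.3, 1, 1)), 0)
  expect_error(make_double_well(-1, 2), "barrier_height")
  expect_error(make_double_well(5, 0), "half_separation")
})

test_that("analytic gradients match finite differences on random configurations", {
  set.seed(101)
  systems <- list(dwell = make_double_well(6, 2),
                  harm = make_harmonic(10),
                  helix = make_cg_helix(8))
  for (nm in names(systems)) {
    sys <- systems[[nm]]
    base <- if (sys$kind == "cg_helix") sys$reference
            else matrix(0, sys$n_particles, sys$dim)
    n_cfg <- if (sys$kind == "cg_helix") 40 else 100
    for (rep in seq_len(n_cfg)) {
      x <- base + matrix(rnorm(length(base), sd = runif(1, 0.05, 0.5)),
                         nrow(base))
      g <- energy_gradient(sys, x)
      fd <- fd_gradient(sys, x)
      expect_lt(max(abs(g - fd)) / max(max(abs(fd)), 1e-8), 1e-5)
      if (sys$kind == "cg_helix") {
        gD <- energy_gradient(sys, x, "dihedral")
        fdD <- fd_gradient(sys, x, "dihedral")
        expect_lt(max(abs(gD - fdD)) / max(max(abs(fdD)), 1e-8), 1e-5)
      }
    }
  }
})

test_that("energy decomposes exactly into named components with V_D = torsion", {
  hx <- make_cg_helix(10)
  set.seed(7)
  for (rep in 1:20) {
    x <- hx$reference + matrix(rnorm(30, sd = 0.4), 10)
    terms <- energy_terms(hx, x)
    expect_identical(names(terms),
                     c("bond", "angle", "torsion", "contact", "repulsion"))
    expect_equal(potential_energy(hx, x), sum(terms))
    expect_equal(dihedral_energy(hx, x), unname(terms["torsion"]))
  }
})

test_that("cg helix has n_res - 3 pseudo-dihedral terms with the 1-cos form", {
  hx <- make_cg_helix(10, torsion_k = 2)
  set.seed(8)
  x <- hx$reference + matrix(rnorm(30, sd = 0.3), 10)
  phis <- vapply(1:7, function(i)
    boostmd:::.bead_dihedral(x[i, ], x[i + 1, ], x[i + 2, ], x[i + 3, ]),
    numeric(1))
  expected <- sum(2 * (1 - cos(phis - hx$params$phi0)))
  expect_equal(dihedral_energy(hx, x), expected, tolerance = 1e-10)
  expect_error(make_cg_helix(4), "n_res")
})

test_that("ideal helix geometry: chord length, single residue, angular period", {
  h2 <- ideal_helix_coords(2)
  chord <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  expect_equal(sqrt(sum((h2[2, ] - h2[1, ])^2)), chord, tolerance = 1e-12)
  h1 <- ideal_helix_coords(1)
  expect_equal(sqrt(sum(h1[1, 1:2]^2)), 2.3)
  # 18 residues x 100 deg = 5 full turns: bead 19 sits directly above bead 1
  h <- ideal_helix_coords(19)
  expect_equal(h[19, 1:2], h[1, 1:2], tolerance = 1e-9)
})

test_that("extended chain matches the closed-form Rg of a uniform linear chain", {
  expect_equal(radius_of_gyration(extended_coords(2, 3.8)), 1.9)
  expect_equal(radius_of_gyration(extended_coords(1, 3.8)), 0)
  for (n in c(5, 12, 30)) {
    d <- 3.8
    expect_equal(radius_of_gyration(extended_coords(n, d)),
                 sqrt(d^2 * (n^2 - 1) / 12), tolerance = 1e-12)
  }
})

test_that("ideal-helix reference is a near-minimum and beats the extended chain", {
  hx <- make_cg_helix(12)
  expect_lt(potential_energy(hx, hx$reference),
            potential_energy(hx, extended_coords(12)))
  m <- minimize(hx, hx$reference, gtol = 1e-4)
  expect_true(m$converged)
  expect_lte(m$grad_norm, 1e-4)
  # the minimized structure stays essentially at the reference
  expect_lt(superpose_rmsd(m$coords, hx$reference)$rmsd, 0.2)
})

test_that("model constructors validate their inputs", {
  expect_error(make_harmonic(0), "force_constant")
  expect_error(make_cg_helix(10, bond_k = -5))
  expect_error(extended_coords(3, spacing = -1), "spacing")
  expect_error(ideal_helix_coords(0), "n_res")
  dw <- make_double_well(5, 2)
  expect_error(potential_energy(dw, matrix(NaN, 1, 1)), "finite")
  expect_error(potential_energy(dw, matrix(0, 2, 1)), "1 x 1")
})
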