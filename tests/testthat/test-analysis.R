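test_that("superposition RMSD is zero for identical and rigidly moved structures", {
  set.seed(61)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(A, A)$rmsd, 0)
  for (rep in 1:20) {
    R <- random_rotation()
    B <- A %*% t(R) + matrix(rep(rnorm(3, sd = 10), each = 10), ncol = 3)
    expect_lt(superpose_rmsd(B, A)$rmsd, 1e-9)
    expect_lt(superpose_rmsd(A, B)$rmsd, 1e-9)
  }
})

test_that("Kabsch equals the brute-force rotational minimum on random point sets", {
  set.seed(62)
  for (rep in 1:5) {
    A <- matrix(rnorm(24, sd = 2), 8, 3)
    B <- matrix(rnorm(24, sd = 2), 8, 3)
    expect_equal(superpose_rmsd(A, B)$rmsd, brute_force_rmsd(A, B),
                 tolerance = 1e-6)
  }
})

test_that("superposition is symmetric, returns a proper rotation, flags degeneracy", {
  set.seed(63)
  A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(15), 5, 3)
  expect_equal(superpose_rmsd(A, B)$rmsd, superpose_rmsd(B, A)$rmsd,
               tolerance = 1e-12)
  expect_equal(det(superpose_rmsd(A, B)$rotation), 1, tolerance = 1e-10)
  # mirror images need the det = +1 branch: rmsd must stay > 0
  M <- A; M[, 3] <- -M[, 3]
  expect_gt(superpose_rmsd(M, A)$rmsd, 0.1)
  expect_warning(superpose_rmsd(extended_coords(5), extended_coords(5)),
                 "collinear")
  expect_error(superpose_rmsd(A, B[1:4, ]), "differ")
})

test_that("radius of gyration matches closed forms, mass weighting included", {
  expect_equal(radius_of_gyration(matrix(c(5, 2, 1), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 2)
  # unequal masses {1, 3} at distance d: Rg = d*sqrt(3)/4
  expect_equal(radius_of_gyration(two, masses = c(1, 3)), 4 * sqrt(3) / 4)
  expect_equal(radius_of_gyration(extended_coords(11, 2.5)),
               sqrt(2.5^2 * (11^2 - 1) / 12))
  expect_error(radius_of_gyration(two, selection = integer(0)), "empty")
  expect_error(radius_of_gyration(two, masses = c(1, -1)), "masses")
})

test_that("native contacts apply the strict cutoff to non-adjacent pairs", {
  # 3 collinear beads at 3.8 A: the only |i-j|>=2 distance is 7.6 > 7.0
  expect_equal(nrow(native_contacts(extended_coords(3, 3.8))$pairs), 0)
  cs <- native_contacts(extended_coords(3, 3.0))
  expect_equal(unname(cs$pairs[1, ]), c(1L, 3L))
  # exact boundary: distance == cutoff is NOT a contact
  expect_equal(nrow(native_contacts(extended_coords(3, 3.5), cutoff = 7.0)$pairs), 0)
  # ideal 10-residue helix: every (i, i+3) pair is in contact
  h <- ideal_helix_coords(10)
  cs10 <- native_contacts(h)
  key <- paste(cs10$pairs[, 1], cs10$pairs[, 2])
  expect_true(all(paste(1:7, 4:10) %in% key))
  # stricter sequence separation removes the (i, i+2) band
  cs3 <- native_contacts(h, min_seq_sep = 3)
  expect_true(all(cs3$pairs[, 2] - cs3$pairs[, 1] >= 3))
  # too-short trace: empty set
  expect_equal(nrow(native_contacts(matrix(0, 2, 3))$pairs), 0)
})

test_that("fraction of native contacts is exact on constructed frames", {
  h <- ideal_helix_coords(10)
  cs <- native_contacts(h)
  expect_equal(fraction_native(h, cs), 1)
  expect_equal(fraction_native(extended_coords(10), cs), 0)
  # frame with exactly half the pairs formed: pull a two-bead segment away
  two <- matrix(c(0, 0, 0, 3, 0, 0, 100, 0, 0, 103, 0, 0), 4, 3, byrow = TRUE)
  ref <- matrix(c(0, 0, 0, 3, 0, 0, 6, 0, 0, 9, 0, 0), 4, 3, byrow = TRUE)
  cs4 <- native_contacts(ref, cutoff = 7.0)   # pairs (1,3) and (2,4)
  expect_equal(nrow(cs4$pairs), 2)
  frame_half <- matrix(c(0, 0, 0, 3, 0, 0, 6, 0, 0, 100, 0, 0), 4, 3,
                       byrow = TRUE)          # (1,3) formed, (2,4) broken
  expect_equal(fraction_native(frame_half, cs4), 0.5)
  expect_error(fraction_native(h, native_contacts(extended_coords(3, 3.8))),
               "empty contact set")
})

test_that("helix content counts pseudo-dihedrals inside the ideal window", {
  expect_equal(helix_content(ideal_helix_coords(12)), 1)
  expect_equal(helix_content(extended_coords(12)), 0)
  # half-helix / half-extended 12-mer lands mid-range
  hx <- ideal_helix_coords(6)
  ext <- cbind(seq(3.8, by = 3.8, length.out = 6) + hx[6, 1], hx[6, 2], hx[6, 3])
  mixed <- rbind(hx, ext)
  val <- helix_content(mixed)
  expect_gt(val, 0.3); expect_lt(val, 0.7)
  expect_error(helix_content(ideal_helix_coords(3)), "4 residues")
})

test_that("clustering recovers planted conformer mixtures", {
  pm <- planted_mixture(c(50, 50), jitter = 0.1, seed = 71)
  cl <- cluster_trajectory(pm$frames, n_clusters = 2,
                           reference = pm$conformers[[1]])
  expect_equal(sort(cl$populations), c(0.5, 0.5))
  expect_equal(sum(cl$populations), 1)
  # representatives sit within jitter RMSD of the planted conformers
  reps <- cl$representatives
  rep_rmsds <- vapply(reps, function(f)
    min(superpose_rmsd(pm$frames[f, , ], pm$conformers[[1]])$rmsd,
        superpose_rmsd(pm$frames[f, , ], pm$conformers[[2]])$rmsd), numeric(1))
  expect_true(all(rep_rmsds < 0.2))
  expect_true(all(cl$labels[reps] == seq_along(reps)))
})

test_that("clustering handles the degenerate one-cluster case and is deterministic", {
  frames <- array(rep(ideal_helix_coords(8), each = 10), c(10, 8, 3))
  cl <- cluster_trajectory(frames, n_clusters = 1)
  expect_equal(cl$populations, 1)
  expect_equal(cl$representatives, 1L)
  pm <- planted_mixture(c(30, 20), jitter = 0.2, seed = 72)
  c1 <- cluster_trajectory(pm$frames, n_clusters = 2)
  c2 <- cluster_trajectory(pm$frames, n_clusters = 2)
  expect_identical(c1$labels, c2$labels)
  expect_error(cluster_trajectory(pm$frames), "n_clusters or rmsd_cutoff")
  expect_error(cluster_trajectory(pm$frames[1:3, , , drop = FALSE],
                                  n_clusters = 5), "at least")
})

test_that("an 80/15/5 planted mixture is recovered within 3 points", {
  pm <- planted_mixture(c(80, 15, 5), jitter = 0.15, seed = 73)
  cl <- cluster_trajectory(pm$frames, n_clusters = 3)
  expect_true(all(abs(sort(cl$populations, decreasing = TRUE) -
                      c(0.80, 0.15, 0.05)) <= 0.03))
})

test_that("trajectory metric table carries the four folding diagnostics", {
  hx <- make_cg_helix(8)
  cfg <- simulation_config(n_steps = 2000, save_interval = 100, seed = 5,
                           temperature = 300, timestep = 0.005)
  tr <- run_simulation(hx, cfg)
  met <- trajectory_metrics(tr, hx$reference, masses = hx$masses)
  expect_identical(names(met), c("time_ps", "rmsd", "rg", "q_native",
                                 "helix_frac"))
  expect_equal(nrow(met), n_frames(tr))
  expect_true(all(met$q_native >= 0 & met$q_native <= 1))
  expect_true(all(met$helix_frac >= 0 & met$helix_frac <= 1))
  expect_true(all(met$rg > 0))
})
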