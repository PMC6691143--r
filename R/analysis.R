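# Folding metrics: optimal-superposition RMSD (Kabsch), radius of gyration,
# native contacts, helix content, and trajectory clustering.

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares optimal rigid superposition of `mobile` onto `reference`
#' over a selection, with a proper rotation enforced (det = +1). Returns the
#' minimized RMSD and the transform.
#'
#' @param mobile,reference coordinate matrices (n x dim) with matching
#'   selections
#' @param selection row indices used for the fit (default: all)
#' @return list with `rmsd` (A), `rotation` (dim x dim), `translation`
#'   (applied after rotation of the centered mobile)
#' @export
superpose_rmsd <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference))
    stop("selection lengths differ between mobile and reference")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (!all(is.finite(A)) || !all(is.finite(B))) stop("coordinates must be finite")
  d <- ncol(A)
  if (d == 3 && nrow(A) >= 3) {
    # effective rank check: near-collinear point sets make the rotation
    # ill-determined (RMSD itself is still well-defined)
    sv <- svd(scale(A, scale = FALSE))$d
    if (sv[2] < 1e-8 * max(sv[1], 1))
      warning("selection is (near-)collinear; superposition is degenerate")
  }
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)           # covariance, mobile -> reference
  s <- svd(H)
  sgn <- diag(c(rep(1, d - 1), sign(det(s$v %*% t(s$u)))), d)
  R <- s$v %*% sgn %*% t(s$u)      # proper rotation: B0 ~ A0 %*% t(R)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  list(rmsd = rmsd, rotation = R, translation = cb)
}

#' RMSD time series of a trajectory against a reference
#'
#' @param traj a `trajectory_record` or a 3D coordinate array
#'   (frames x particles x dim)
#' @param reference coordinate matrix
#' @param selection fit selection
#' @return numeric vector, one RMSD (A) per frame
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  arr <- if (inherits(traj, "trajectory_record")) traj$coords else traj
  vapply(seq_len(dim(arr)[1]), function(f)
    superpose_rmsd(arr[f, , , drop = TRUE], reference, selection)$rmsd,
    numeric(1))
}

#' Mass-weighted radius of gyration
#'
#' RMS distance of the selected particles from their center of mass,
#' weighted by mass.
#'
#' @param coords coordinate matrix (n x dim, A)
#' @param masses per-particle masses (amu); equal masses by default
#' @param selection row indices (default: all); must be non-empty
#' @return Rg in A
#' @export
radius_of_gyration <- function(coords, masses = NULL, selection = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  if (is.null(selection)) selection <- seq_len(nrow(coords))
  if (length(selection) == 0) stop("empty selection")
  x <- coords[selection, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, nrow(x)) else masses[selection]
  if (any(m <= 0)) stop("masses must be > 0")
  com <- colSums(x * m) / sum(m)
  sq <- rowSums(sweep(x, 2, com)^2)
  sqrt(sum(m * sq) / sum(m))
}

#' Rg time series of a trajectory
#' @inheritParams rmsd_series
#' @param masses per-particle masses
#' @return numeric vector, one Rg (A) per frame
#' @export
rg_series <- function(traj, masses = NULL, selection = NULL) {
  arr <- if (inherits(traj, "trajectory_record")) traj$coords else traj
  vapply(seq_len(dim(arr)[1]), function(f)
    radius_of_gyration(arr[f, , , drop = TRUE], masses, selection), numeric(1))
}

#' Native contacts of a reference structure
#'
#' All residue pairs (i, j) with `j - i >= min_seq_sep` whose inter-residue
#' distance is strictly below the cutoff. The 7.0 A / non-adjacent
#' convention (`min_seq_sep = 2`: only sequence neighbors excluded) is the
#' default; stricter separations (>= 3, >= 4) are selectable.
#'
#' @param reference residue-trace coordinate matrix (one row per residue)
#' @param cutoff distance cutoff (A), strict `<`
#' @param min_seq_sep minimum residue separation
#' @return a `contact_set`: list with `pairs` (2-column matrix, i < j),
#'   `cutoff`, `min_seq_sep`, `n_res`
#' @export
native_contacts <- function(reference, cutoff = 7.0, min_seq_sep = 2L) {
  n <- nrow(reference)
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (n >= min_seq_sep + 1) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] >= min_seq_sep, , drop = FALSE]
    if (nrow(idx) > 0) {
      d <- sqrt(rowSums((reference[idx[, 1], , drop = FALSE] -
                         reference[idx[, 2], , drop = FALSE])^2))
      keep <- d < cutoff
      pairs <- idx[keep, , drop = FALSE]
      colnames(pairs) <- c("i", "j")
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    }
  }
  structure(list(pairs = pairs, cutoff = cutoff,
                 min_seq_sep = as.integer(min_seq_sep), n_res = n),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set: %d pairs, cutoff %.1f A, |i-j| >= %d, %d residues>\n",
              nrow(x$pairs), x$cutoff, x$min_seq_sep, x$n_res))
  invisible(x)
}

#' Fraction of native contacts formed in a frame
#'
#' Number of native pairs within the same cutoff in the frame, divided by
#' the native pair count.
#'
#' @param frame residue-trace coordinate matrix
#' @param contacts a [native_contacts()] result
#' @return fraction in \[0, 1\]
#' @export
fraction_native <- function(frame, contacts) {
  if (nrow(contacts$pairs) == 0)
    stop("empty contact set: fraction of native contacts is undefined")
  if (nrow(frame) < max(contacts$pairs))
    stop("frame has fewer residues than the contact indices require")
  d <- sqrt(rowSums((frame[contacts$pairs[, 1], , drop = FALSE] -
                     frame[contacts$pairs[, 2], , drop = FALSE])^2))
  mean(d < contacts$cutoff)
}

#' Q time series of a trajectory
#' @inheritParams rmsd_series
#' @param contacts a [native_contacts()] result
#' @return numeric vector, fraction of native contacts per frame
#' @export
q_native_series <- function(traj, contacts) {
  arr <- if (inherits(traj, "trajectory_record")) traj$coords else traj
  vapply(seq_len(dim(arr)[1]), function(f)
    fraction_native(arr[f, , , drop = TRUE], contacts), numeric(1))
}

#' Fractional helix content of a residue trace
#'
#' Fraction of consecutive-quadruple pseudo-dihedrals lying within an
#' angular window of the ideal-helix pseudo-dihedral (default +-30 deg,
#' circular difference). This is an operational trace-level criterion, not a
#' hydrogen-bond secondary-structure assignment.
#'
#' @param frame residue-trace coordinate matrix (>= 4 residues, 3-D)
#' @param window_deg half-width of the acceptance window (degrees)
#' @param phi0 reference pseudo-dihedral (radians); ideal-helix value by
#'   default
#' @return fraction in \[0, 1\]
#' @export
helix_content <- function(frame, window_deg = 30,
                          phi0 = .ideal_helix_phi0()) {
  n <- nrow(frame)
  if (n < 4) stop("helix content needs >= 4 residues")
  phis <- vapply(seq_len(n - 3), function(i)
    .bead_dihedral(frame[i, ], frame[i + 1, ], frame[i + 2, ], frame[i + 3, ]),
    numeric(1))
  dphi <- atan2(sin(phis - phi0), cos(phis - phi0)) # wrapped difference
  mean(abs(dphi) <= window_deg * pi / 180)
}

.ideal_helix_phi0 <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      h <- ideal_helix_coords(4)
      val <<- .bead_dihedral(h[1, ], h[2, ], h[3, ], h[4, ])
    }
    val
  }
})

#' Pairwise superposed-RMSD matrix of trajectory frames
#'
#' @inheritParams rmsd_series
#' @param selection fit selection
#' @return symmetric matrix of RMSDs (A)
#' @export
pairwise_rmsd <- function(traj, selection = NULL) {
  arr <- if (inherits(traj, "trajectory_record")) traj$coords else traj
  nf <- dim(arr)[1]
  M <- matrix(0, nf, nf)
  for (a in seq_len(nf - 1)) {
    xa <- arr[a, , , drop = TRUE]
    for (b in seq.int(a + 1, nf)) {
      M[a, b] <- M[b, a] <- superpose_rmsd(arr[b, , , drop = TRUE], xa,
                                           selection)$rmsd
    }
  }
  M
}

#' Cluster trajectory frames by structural similarity
#'
#' Average-linkage agglomerative clustering on the pairwise superposed-RMSD
#' matrix. Populations are reported sorted descending; each cluster's
#' representative is the member frame minimizing the mean RMSD to the other
#' members (ties broken by the earliest frame). Deterministic given the
#' frame order.
#'
#' @inheritParams rmsd_series
#' @param selection fit selection
#' @param n_clusters desired cluster count (mutually exclusive with
#'   `rmsd_cutoff`)
#' @param rmsd_cutoff tree-cut height in A instead of a fixed count
#' @param reference optional native structure; if given, the representative
#'   RMSD-to-native is reported per cluster
#' @return a `cluster_result`: list with `labels`, `populations`,
#'   `representatives`, `rmsd_of_representative_to_native`, `linkage`
#' @export
cluster_trajectory <- function(traj, selection = NULL, n_clusters = NULL,
                               rmsd_cutoff = NULL, reference = NULL) {
  arr <- if (inherits(traj, "trajectory_record")) traj$coords else traj
  nf <- dim(arr)[1]
  if (is.null(n_clusters) && is.null(rmsd_cutoff))
    stop("supply n_clusters or rmsd_cutoff")
  if (!is.null(n_clusters) && nf < n_clusters)
    stop("need at least n_clusters frames")
  M <- pairwise_rmsd(arr, selection)
  if (any(!is.finite(M))) stop("pairwise RMSD matrix contains non-finite values")
  if (!is.null(n_clusters) && n_clusters == 1L) {
    raw <- rep(1L, nf)
  } else {
    hc <- stats::hclust(stats::as.dist(M), method = "average")
    raw <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters)
           else stats::cutree(hc, h = rmsd_cutoff)
  }
  sizes <- table(raw)
  # relabel clusters 1..k by descending population (ties: first appearance)
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(relabel[as.character(raw)])
  k <- length(ord)
  reps <- integer(k)
  rep_rmsd <- rep(NA_real_, k)
  for (cl in seq_len(k)) {
    members <- which(labels == cl)
    mean_r <- if (length(members) == 1) 0 else
      rowMeans(M[members, members, drop = FALSE])
    reps[cl] <- members[which.min(mean_r)]   # which.min takes the earliest tie
    if (!is.null(reference))
      rep_rmsd[cl] <- superpose_rmsd(arr[reps[cl], , , drop = TRUE],
                                     reference, selection)$rmsd
  }
  structure(list(labels = labels,
                 populations = as.numeric(table(labels)) / nf,
                 representatives = reps,
                 rmsd_of_representative_to_native = rep_rmsd,
                 linkage = "average"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d clusters (%s linkage); top populations %s>\n",
              length(x$populations), x$linkage,
              paste(sprintf("%.1f%%", 100 * head(x$populations, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-frame folding metrics of a trajectory
#'
#' Convenience table of the standard convergence diagnostics: RMSD to the
#' native reference, Rg, fraction of native contacts and helix content.
#'
#' @param traj a `trajectory_record`
#' @param reference native coordinate matrix
#' @param contacts optional precomputed [native_contacts()]; derived from
#'   the reference by default
#' @param masses per-particle masses for Rg (equal by default)
#' @param selection fit/Rg selection
#' @return data.frame with columns `time_ps`, `rmsd`, `rg`, `q_native`,
#'   `helix_frac`
#' @export
trajectory_metrics <- function(traj, reference, contacts = NULL,
                               masses = NULL, selection = NULL) {
  if (is.null(contacts)) contacts <- native_contacts(reference)
  arr <- traj$coords
  hx <- if (dim(arr)[3] == 3 && dim(arr)[2] >= 4)
    vapply(seq_len(dim(arr)[1]), function(f)
      helix_content(arr[f, , , drop = TRUE]), numeric(1))
  else rep(NA_real_, dim(arr)[1])
  data.frame(time_ps = traj$scalars$time_ps,
             rmsd = rmsd_series(traj, reference, selection),
             rg = rg_series(traj, masses, selection),
             q_native = q_native_series(traj, contacts),
             helix_frac = hx)
}
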