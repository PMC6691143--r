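# File formats: CA-trace PDB reading (via bio3d), a minimal fixed-column
# multi-model PDB writer, trajectory persistence, and fixture generation.

#' Read a C-alpha residue trace from a PDB file
#'
#' Reads the first MODEL only and extracts one atom per residue, in residue
#' order, using an atom-name filter (C-alpha by default). Residues missing
#' the requested atom are skipped with a warning; chain breaks (consecutive
#' CA-CA distance > 4.5 A) are reported.
#'
#' @param path PDB file with ATOM records
#' @param atom_name atom-name filter (default `"CA"`)
#' @return coordinate matrix (n_res x 3) with attributes `resno`, `resid`,
#'   `chain`, `n_skipped`, `chain_breaks`
#' @export
read_pdb_trace <- function(path, atom_name = "CA") {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  # residue identity = (chain, resno, insert)
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_order <- unique(rid)
  ca <- at[at$elety == atom_name, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "|")), ,
           drop = FALSE]
  have <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  n_skipped <- sum(!(res_order %in% have))
  if (n_skipped > 0)
    warning(sprintf("%d residue(s) missing atom '%s'; skipped", n_skipped,
                    atom_name))
  ca <- ca[match(res_order[res_order %in% have], have), , drop = FALSE]
  xyz <- cbind(ca$x, ca$y, ca$z)
  breaks <- integer(0)
  if (nrow(xyz) > 1) {
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
    breaks <- which(d > 4.5)
  }
  structure(xyz, resno = ca$resno, resid = ca$resid, chain = ca$chain,
            n_skipped = n_skipped, chain_breaks = breaks)
}

# fixed-column ATOM record for a CA bead
.pdb_atom_line <- function(serial, resno, x, y, z, resid = "ALA",
                           chain = "A") {
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, resid, chain, resno, x, y, z)
}

#' Write a multi-model CA-trace PDB
#'
#' Minimal fixed-column dialect: MODEL/ATOM/ENDMDL/END, beads as CA atoms of
#' ALA, occupancy 1.00, B-factor 0.00. Coordinates are written at format
#' precision (3 decimals).
#'
#' @param frames 3D array (frames x residues x 3) or a single matrix
#' @param path output file
#' @return the path, invisibly
#' @export
write_pdb_frames <- function(frames, path) {
  if (is.matrix(frames)) frames <- array(frames, c(1, nrow(frames), ncol(frames)))
  nf <- dim(frames)[1]; n <- dim(frames)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(n))
      writeLines(.pdb_atom_line(i, i, frames[f, i, 1], frames[f, i, 2],
                                frames[f, i, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Persist a trajectory as multi-model PDB plus scalar CSV
#'
#' Writes `<prefix>.pdb` (one MODEL per frame, CA beads) and `<prefix>.csv`
#' with columns `time_ps`, `V`, `V_D`, `deltaV`, `T_inst` at full precision,
#' so the scalars round-trip bit-exactly and the coordinates to format
#' precision (5e-4 A). Only 3-D systems have a PDB representation; 1-D
#' trajectories write the CSV plus a coordinate CSV.
#'
#' @param traj a `trajectory_record`
#' @param path_prefix output path prefix
#' @return invisible character vector of files written
#' @export
write_trajectory <- function(traj, path_prefix) {
  if (n_frames(traj) == 0) stop("empty trajectory")
  csv <- paste0(path_prefix, ".csv")
  sc <- traj$scalars
  out <- data.frame(lapply(sc, function(col) sprintf("%.17g", col)))
  names(out) <- names(sc)
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)
  files <- csv
  if (dim(traj$coords)[3] == 3) {
    pdb <- paste0(path_prefix, ".pdb")
    write_pdb_frames(traj$coords, pdb)
    files <- c(files, pdb)
  } else {
    cc <- paste0(path_prefix, "_coords.csv")
    flat <- apply(traj$coords, 1, function(m) sprintf("%.17g", as.numeric(m)))
    flat <- if (is.null(dim(flat))) matrix(flat, ncol = 1) else t(flat)
    utils::write.table(flat, cc, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    files <- c(files, cc)
  }
  invisible(files)
}

#' Read back a persisted trajectory
#'
#' @param path_prefix prefix used in [write_trajectory()]
#' @return list with `coords` (3D array) and `scalars` (data.frame)
#' @export
read_trajectory <- function(path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  sc <- utils::read.csv(csv)
  sc[] <- lapply(sc, as.numeric)
  pdb <- paste0(path_prefix, ".pdb")
  if (file.exists(pdb)) {
    mm <- suppressWarnings(bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE))
    xyz <- mm$xyz
    nf <- nrow(xyz); n <- ncol(xyz) / 3
    coords <- array(NA_real_, c(nf, n, 3))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  } else {
    flat <- as.matrix(utils::read.table(paste0(path_prefix, "_coords.csv"),
                                        sep = ","))
    coords <- array(flat, c(nrow(flat), ncol(flat), 1))
  }
  if (dim(coords)[1] != nrow(sc))
    warning("frame count mismatch between PDB and CSV")
  list(coords = coords, scalars = sc)
}

#' Generate deterministic structural fixtures
#'
#' Seed-stamped CA-trace PDB fixtures for tests and demos:
#' `ideal_helix` (the analytic native), `extended` (linear chain),
#' `decoy_set` (helix with per-bead Gaussian noise at the given sigma
#' levels), `two_conformer_mix` (interleaved helix/extended frames).
#' Decoy `sigma` is the RMS per-bead displacement in A (per-coordinate
#' standard deviation `sigma/sqrt(3)`).
#'
#' @param kind one of `"ideal_helix"`, `"extended"`, `"decoy_set"`,
#'   `"two_conformer_mix"`
#' @param n_res residue count
#' @param seed RNG seed (used by the noisy kinds)
#' @param dir output directory
#' @param sigma noise levels in A for `decoy_set`
#' @return character vector of files written
#' @export
make_fixtures <- function(kind = c("ideal_helix", "extended", "decoy_set",
                                   "two_conformer_mix"),
                          n_res = 15, seed = 1, dir = ".",
                          sigma = c(0, 0.5, 1.0)) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  path <- function(nm) file.path(dir, nm)
  switch(kind,
    ideal_helix = {
      f <- path(sprintf("ideal_helix_n%d.pdb", n_res))
      write_pdb_frames(ideal_helix_coords(n_res), f)
      f
    },
    extended = {
      f <- path(sprintf("extended_n%d.pdb", n_res))
      write_pdb_frames(extended_coords(n_res), f)
      f
    },
    decoy_set = {
      ref <- ideal_helix_coords(n_res)
      vapply(sigma, function(s) {
        f <- path(sprintf("decoy_n%d_sigma%.2f_seed%d.pdb", n_res, s, seed))
        write_pdb_frames(ref + matrix(rnorm(length(ref), sd = s / sqrt(3)),
                                      nrow(ref)), f)
        f
      }, character(1))
    },
    two_conformer_mix = {
      a <- ideal_helix_coords(n_res); b <- extended_coords(n_res)
      frames <- array(NA_real_, c(10, n_res, 3))
      for (f in 1:10)
        frames[f, , ] <- (if (f %% 2) a else b) +
          matrix(rnorm(length(a), sd = 0.05), nrow(a))
      f <- path(sprintf("two_conformer_n%d_seed%d.pdb", n_res, seed))
      write_pdb_frames(frames, f)
      f
    })
}
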