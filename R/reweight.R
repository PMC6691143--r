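# Boltzmann reweighting of boosted trajectories and 2D free-energy surfaces
# over two collective variables (canonically RMSD and Rg).

#' Canonical frame weights from the bias energy
#'
#' Each boosted frame is reweighted by the Boltzmann factor of its bias,
#' \eqn{w_i \propto \exp(\Delta V_i / k_B T)}, normalized to sum to one.
#' Computed in log space with max-subtraction, so any finite bias series is
#' safe from overflow.
#'
#' @param deltaV_series per-frame bias energies (kcal/mol, >= 0)
#' @param temperature simulation temperature (K), > 0
#' @return normalized weights summing to 1
#' @export
frame_weights <- function(deltaV_series, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (any(!is.finite(deltaV_series))) stop("deltaV must be finite")
  if (any(deltaV_series < 0))
    stop("negative deltaV violates the boost contract (deltaV >= 0)")
  lw <- deltaV_series / (KB_KCALMOL * temperature)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Effective sample size of a weight vector
#'
#' Kish's \eqn{n_{eff} = (\sum w)^2 / \sum w^2}; equals the frame count for
#' uniform weights and collapses toward 1 as a few frames dominate.
#'
#' @param weights (not necessarily normalized) non-negative weights
#' @return effective sample size
#' @export
effective_sample_size <- function(weights) sum(weights)^2 / sum(weights^2)

.make_edges <- function(x, bins) {
  if (length(bins) > 1) return(bins)         # caller-supplied edges
  r <- range(x)
  pad <- 0.05 * max(diff(r), .Machine$double.eps)
  seq(r[1] - pad, r[2] + pad, length.out = bins + 1)
}

#' Reweighted 2D free-energy surface
#'
#' Weighted 2D histogram over two collective-variable series using
#' [frame_weights()]; for a single boosted trajectory the weighted-histogram
#' estimator reduces to exactly this. Free energy is
#' \eqn{F = -k_B T \ln p}, shifted so the occupied minimum is 0; empty bins
#' carry `NA` (distinct from merely high-energy bins). Multiple trajectories
#' may be combined by concatenating their series and bias energies.
#'
#' @param traj a `trajectory_record`, or `NULL` if `deltaV` is given directly
#' @param cv1_series,cv2_series per-frame collective variables (same length)
#' @param bins bin count per axis (default 50) or a list of two edge vectors
#' @param temperature K; defaults to the trajectory's configured temperature
#' @param deltaV per-frame bias energies; defaults to the trajectory's
#' @return an `fes_grid` object
#' @export
weighted_fes <- function(traj = NULL, cv1_series, cv2_series, bins = 50,
                         temperature = NULL, deltaV = NULL) {
  if (is.null(deltaV)) {
    if (is.null(traj)) stop("supply either traj or deltaV")
    deltaV <- traj$scalars$deltaV
  }
  if (is.null(temperature)) {
    if (is.null(traj)) stop("supply temperature when traj is NULL")
    temperature <- traj$config$temperature
  }
  n <- length(cv1_series)
  if (length(cv2_series) != n || length(deltaV) != n)
    stop("cv1, cv2 and deltaV series must have equal length")
  w <- frame_weights(deltaV, temperature)

  if (is.list(bins)) {
    e1 <- bins[[1]]; e2 <- bins[[2]]
  } else {
    e1 <- .make_edges(cv1_series, bins)
    e2 <- .make_edges(cv2_series, bins)
  }
  i1 <- findInterval(cv1_series, e1, rightmost.closed = TRUE, all.inside = TRUE)
  i2 <- findInterval(cv2_series, e2, rightmost.closed = TRUE, all.inside = TRUE)
  n1 <- length(e1) - 1; n2 <- length(e2) - 1
  prob <- matrix(0, n1, n2)
  cnt <- matrix(0L, n1, n2)
  wsq <- matrix(0, n1, n2)
  for (f in seq_len(n)) {
    prob[i1[f], i2[f]] <- prob[i1[f], i2[f]] + w[f]
    wsq[i1[f], i2[f]] <- wsq[i1[f], i2[f]] + w[f]^2
    cnt[i1[f], i2[f]] <- cnt[i1[f], i2[f]] + 1L
  }
  if (sum(cnt > 0) == 1)
    warning("all frames fall in a single bin; surface is a single point")
  fe <- matrix(NA_real_, n1, n2)
  occ <- prob > 0
  fe[occ] <- -KB_KCALMOL * temperature * log(prob[occ])
  fe <- fe - min(fe, na.rm = TRUE)
  neff <- matrix(NA_real_, n1, n2)
  neff[occ] <- prob[occ]^2 / wsq[occ]
  structure(list(cv1_edges = e1, cv2_edges = e2, probability = prob,
                 free_energy = fe, count = cnt, n_eff = neff,
                 temperature = temperature,
                 frame_bin = cbind(i1, i2), weights = w),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("<fes_grid: %d x %d bins, %d occupied, T=%g K, n_eff=%.1f>\n",
              nrow(x$probability), ncol(x$probability), sum(x$count > 0),
              x$temperature, effective_sample_size(x$weights)))
  invisible(x)
}

#' Bin centers of an FES axis
#' @param fes an `fes_grid`
#' @param axis 1 or 2
#' @return numeric vector of bin centers
#' @export
fes_centers <- function(fes, axis = 1) {
  e <- if (axis == 1) fes$cv1_edges else fes$cv2_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Lowest-free-energy state of a surface
#'
#' Bin-center coordinates of the occupied minimum and a representative frame
#' (the highest-weight frame within that bin; ties broken by the earliest
#' frame).
#'
#' @param fes an `fes_grid`
#' @return list with `cv1`, `cv2`, `free_energy`, `bin` (i, j), and
#'   `representative` frame index
#' @export
lowest_free_energy_state <- function(fes) {
  if (!any(fes$count > 0)) stop("empty free-energy surface")
  idx <- which(fes$free_energy == min(fes$free_energy, na.rm = TRUE),
               arr.ind = TRUE)[1, , drop = TRUE]
  inbin <- which(fes$frame_bin[, 1] == idx[1] & fes$frame_bin[, 2] == idx[2])
  rep_frame <- inbin[which.max(fes$weights[inbin])]
  list(cv1 = fes_centers(fes, 1)[idx[1]], cv2 = fes_centers(fes, 2)[idx[2]],
       free_energy = fes$free_energy[idx[1], idx[2]],
       bin = unname(idx), representative = rep_frame)
}

#' Second-order cumulant reweighting weights
#'
#' Alternative estimator for high-variance bias series: per-bin averages use
#' \eqn{\exp(\beta \langle\Delta V\rangle + \tfrac{\beta^2}{2}
#' \mathrm{Var}(\Delta V))} per bin rather than per-frame exponentials. Not
#' part of the source method; offered for high-variance cases. Returns
#' per-frame weights built from the bin-level cumulant expansion of the
#' supplied binned bias series.
#'
#' @param deltaV_series per-frame bias energies (kcal/mol)
#' @param bin_index integer bin assignment per frame
#' @param temperature K
#' @return normalized per-frame weights
#' @export
cumulant_weights <- function(deltaV_series, bin_index, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  beta <- 1 / (KB_KCALMOL * temperature)
  bins <- split(seq_along(deltaV_series), bin_index)
  lw <- numeric(length(deltaV_series))
  for (idx in bins) {
    g <- deltaV_series[idx]
    v <- if (length(g) > 1) stats::var(g) else 0
    # bin mass ~ exp(cumulant), spread evenly over the bin's frames
    lw[idx] <- beta * mean(g) + beta^2 * v / 2 - log(length(g))
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Write a free-energy surface as long-format CSV
#'
#' Columns: `cv1_center`, `cv2_center`, `probability`, `free_energy`,
#' `count`.
#'
#' @param fes an `fes_grid`
#' @param path output file
#' @return the path, invisibly
#' @export
write_fes <- function(fes, path) {
  c1 <- fes_centers(fes, 1); c2 <- fes_centers(fes, 2)
  df <- expand.grid(cv1_center = c1, cv2_center = c2)
  df$probability <- as.vector(fes$probability)
  df$free_energy <- as.vector(fes$free_energy)
  df$count <- as.vector(fes$count)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
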