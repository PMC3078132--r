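## Rigid-body superposition (Kabsch), RMS deviation time series, and
## per-residue RMS fluctuation profiles.

#' Optimal rigid superposition of two matched point sets
#'
#' Kabsch algorithm via singular value decomposition: finds the proper
#' rotation and translation minimizing the least-squares distance between
#' index-matched point sets (reflections corrected by sign-flipping the
#' smallest singular direction). The aligned mobile set is
#' `mobile %*% t(rotation) + translation` (rows).
#'
#' @param mobile,reference `M x 3` matrices of matched points, `M >= 3`,
#'   non-collinear.
#' @return object of class `SuperpositionResult`: list with `rotation`
#'   (3x3, determinant +1), `translation` (3-vector), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L)
    pd_stop("mobile and reference must be index-matched M x 3 matrices",
            "contract_violation")
  if (nrow(mobile) < 3L)
    pd_stop("superposition needs at least 3 point pairs", "geometry_error")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  s <- svd(crossprod(p, q))
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    pd_stop("degenerate (collinear) point sets", "geometry_error")
  sgn <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, sgn)) %*% t(s$u)
  aligned <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((aligned - q)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd),
            class = "SuperpositionResult")
}

#' Apply a superposition to coordinates
#' @param coords `N x 3` matrix.
#' @param sup a `SuperpositionResult`.
#' @return transformed `N x 3` matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(rbind(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

resolve_ca <- function(traj, indices) {
  if (is.null(indices)) select_atoms(traj, atom_name = "CA") else indices
}

#' RMS deviation time series after per-frame superposition
#'
#' Each frame is superposed onto the reference over `fit_indices`; the RMSD
#' is then reported over `measure_indices` (defaults: all C-alpha atoms for
#' both). The reference defaults to the trajectory's first frame, the usual
#' "deviation from the initial structure" convention; pass an external
#' `Structure` to use a deposited model instead.
#'
#' @param traj a `Trajectory`.
#' @param reference a `Structure` with matching topology, or `NULL` for the
#'   first frame.
#' @param fit_indices,measure_indices atom indices; `NULL` means all
#'   C-alpha atoms.
#' @return data frame with columns `time_ps`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference = NULL, fit_indices = NULL,
                        measure_indices = NULL) {
  fit <- resolve_ca(traj, fit_indices)
  meas <- if (is.null(measure_indices)) fit else measure_indices
  ref_xyz <- if (is.null(reference)) traj$coords[, , 1]
  else coords_matrix(reference)
  if (nrow(ref_xyz) < max(c(fit, meas)))
    pd_stop("reference does not cover the requested atom indices",
            "contract_violation")
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (m in seq_len(nf)) {
    xyz <- traj$coords[, , m]
    sup <- tryCatch(kabsch_superpose(xyz[fit, , drop = FALSE],
                                     ref_xyz[fit, , drop = FALSE]),
                    error = function(e)
                      pd_stop(sprintf("frame %d: %s", m, conditionMessage(e)),
                              "geometry_error"))
    aligned <- apply_superposition(xyz[meas, , drop = FALSE], sup)
    out[m] <- sqrt(mean(rowSums((aligned - ref_xyz[meas, , drop = FALSE])^2)))
  }
  data.frame(time_ps = traj$times, rmsd = out)
}

#' Per-residue RMS fluctuation profile
#'
#' Frames (after an optional equilibration skip) are superposed onto the
#' iteratively refined time-average structure: superpose onto the current
#' mean, re-average, and repeat until the mean structure drifts by less than
#' `tol` (default 1e-6 Angstrom, max 20 iterations). The RMSF of atom i is
#' the root-mean-square distance of its aligned positions from its mean
#' position.
#'
#' @param traj a `Trajectory`.
#' @param ca_indices atom indices to profile; `NULL` means all C-alpha atoms.
#' @param equilibration_skip number of leading frames to drop (default 0).
#' @param tol convergence threshold on mean-structure drift (Angstrom).
#' @param max_iter iteration cap.
#' @return object of class `FluctuationProfile`: data frame with columns
#'   `chain_id`, `residue_number`, `rmsf`.
#' @export
rmsf_profile <- function(traj, ca_indices = NULL, equilibration_skip = 0L,
                         tol = 1e-6, max_iter = 20L) {
  idx <- resolve_ca(traj, ca_indices)
  keep <- seq_len(n_frames(traj))
  if (equilibration_skip > 0L) keep <- keep[-seq_len(equilibration_skip)]
  if (length(keep) < 2L)
    pd_stop("RMSF needs at least 2 frames after the equilibration skip",
            "insufficient_data_error")
  nk <- length(keep)
  stack <- array(traj$coords[idx, , keep], dim = c(length(idx), 3L, nk))
  mean_xyz <- stack[, , 1]
  for (it in seq_len(max_iter)) {
    aligned <- stack
    for (m in seq_len(nk)) {
      sup <- kabsch_superpose(stack[, , m], mean_xyz)
      aligned[, , m] <- apply_superposition(stack[, , m], sup)
    }
    new_mean <- apply(aligned, c(1, 2), mean)
    drift <- sqrt(max(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (drift < tol) break
  }
  dev2 <- sapply(seq_len(nk), function(m)
    rowSums((aligned[, , m] - mean_xyz)^2))
  rmsf <- sqrt(rowMeans(dev2))
  out <- data.frame(chain_id = traj$topology$chain_id[idx],
                    residue_number = traj$topology$residue_number[idx],
                    rmsf = rmsf)
  class(out) <- c("FluctuationProfile", class(out))
  out
}

#' Write RMSD series / RMSF profile as TSV
#' @param x data frame from [rmsd_series()] or [rmsf_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
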