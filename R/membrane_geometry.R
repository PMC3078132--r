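## Bilayer reference frame and the two cytoplasmic-domain descriptors:
## tilt angle theta (degrees, measured against the bilayer PLANE) and
## membrane distance d (Angstrom, centroid to midplane along the normal).

#' Construct a membrane reference frame
#'
#' @param midplane_point 3-vector on the bilayer midplane (Angstrom).
#' @param normal bilayer normal; normalized internally, must be non-zero.
#' @param leaflet_half_thickness optional positive half-distance between the
#'   leaflet planes (Angstrom).
#' @return object of class `MembraneFrame`.
#' @export
membrane_frame <- function(midplane_point = c(0, 0, 0),
                           normal = c(0, 0, 1),
                           leaflet_half_thickness = NULL) {
  normal <- unit3(as.numeric(normal))
  if (!is.null(leaflet_half_thickness) && leaflet_half_thickness <= 0)
    pd_stop("leaflet_half_thickness must be positive", "geometry_error")
  structure(list(midplane_point = as.numeric(midplane_point),
                 normal = normal,
                 leaflet_half_thickness = leaflet_half_thickness),
            class = "MembraneFrame")
}

#' @export
print.MembraneFrame <- function(x, ...) {
  cat(sprintf("<MembraneFrame> midplane (%.2f, %.2f, %.2f), normal (%.3f, %.3f, %.3f)%s\n",
              x$midplane_point[1], x$midplane_point[2], x$midplane_point[3],
              x$normal[1], x$normal[2], x$normal[3],
              if (is.null(x$leaflet_half_thickness)) ""
              else sprintf(", half-thickness %.2f A", x$leaflet_half_thickness)))
  invisible(x)
}

## Least-squares plane through a point set: returns centroid and unit normal
## (smallest principal axis). Errors on (near-)collinear input, where the
## plane is not identifiable.
fit_plane <- function(pts) {
  if (nrow(pts) < 3L)
    pd_stop("plane fit needs at least 3 points", "geometry_error")
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    pd_stop("degenerate (collinear) reference atoms", "geometry_error")
  list(centroid = ctr, normal = unit3(s$v[, 3]))
}

## Deterministic 1-D two-means split (initialized at the range endpoints),
## used to separate the two leaflets along a candidate axis. No RNG.
split_two_means <- function(v) {
  c1 <- min(v); c2 <- max(v)
  grp <- rep(1L, length(v))
  for (it in 1:50) {
    grp_new <- ifelse(abs(v - c1) <= abs(v - c2), 1L, 2L)
    if (identical(grp_new, grp) && it > 1L) break
    grp <- grp_new
    if (!any(grp == 1L) || !any(grp == 2L)) break
    c1 <- mean(v[grp == 1L]); c2 <- mean(v[grp == 2L])
  }
  within <- sqrt(mean(c(v[grp == 1L] - c1, v[grp == 2L] - c2)^2))
  list(group = grp, separation = abs(c2 - c1) / (within + 1e-9))
}

#' Estimate the bilayer frame from lipid reference atoms
#'
#' With lipid reference atoms (e.g. the phosphate positions of both
#' leaflets), the two leaflet planes are fitted by least squares; the normal
#' is the unit vector minimizing in-plane variance of the two fitted planes
#' (their sign-aligned mean normal), the midplane point is the mean of the
#' leaflet centroids, and the half-thickness is half their separation along
#' the normal. Leaflet membership is found by a deterministic two-means split
#' along the best-separating principal axis, then refined once along the
#' fitted normal. Without lipid references, the declared fallback convention
#' is used: normal +z, midplane through the origin.
#'
#' @param coords `N x 3` coordinate matrix for one frame.
#' @param lipid_ref_indices row indices of lipid reference atoms spanning
#'   both leaflets (at least 6), or `NULL` for the fallback frame.
#' @return a `MembraneFrame`.
#' @export
estimate_membrane_frame <- function(coords, lipid_ref_indices = NULL) {
  if (is.null(lipid_ref_indices) || length(lipid_ref_indices) == 0L)
    return(membrane_frame())
  pts <- coords[lipid_ref_indices, , drop = FALSE]
  if (nrow(pts) < 6L)
    pd_stop("need at least 6 lipid reference atoms spanning both leaflets",
            "geometry_error")
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)$vectors
  ## pick the axis along which the points split most cleanly into two groups
  best <- NULL
  for (k in 1:3) {
    sp <- split_two_means(drop(centered %*% ev[, k]))
    if (is.null(best) || sp$separation > best$separation) {
      best <- sp
      best$axis <- ev[, k]
    }
  }
  for (pass in 1:2) {
    g1 <- best$group == 1L
    if (sum(g1) < 3L || sum(!g1) < 3L)
      pd_stop("could not separate two leaflets among reference atoms",
              "geometry_error")
    p1 <- fit_plane(pts[g1, , drop = FALSE])
    p2 <- fit_plane(pts[!g1, , drop = FALSE])
    n2 <- if (sum(p1$normal * p2$normal) < 0) -p2$normal else p2$normal
    normal <- unit3(p1$normal + n2)
    if (pass == 1L) {
      ## refine membership along the fitted normal
      proj <- drop(sweep(pts, 2, ctr) %*% normal)
      best$group <- ifelse(proj <= mean(range(proj)), 1L, 2L)
    }
  }
  midpoint <- (p1$centroid + p2$centroid) / 2
  half <- abs(sum(normal * (p1$centroid - p2$centroid))) / 2
  if (half <= 1e-6)
    pd_stop("leaflet centroids coincide; cannot define a bilayer",
            "geometry_error")
  membrane_frame(midpoint, normal, half)
}

#' Cytoplasmic-domain axis from two C-alpha atoms
#'
#' The line through the first and last residues of the cytoplasmic domain
#' (residues 1 and 16 by default numbering) defines the domain direction.
#'
#' @param coords `N x 3` frame coordinate matrix.
#' @param ca_index_first,ca_index_last row indices of the first and last
#'   C-alpha atoms of the domain.
#' @return unit 3-vector pointing from the first toward the last residue.
#' @export
cp_axis <- function(coords, ca_index_first, ca_index_last) {
  v <- coords[ca_index_last, ] - coords[ca_index_first, ]
  if (sqrt(sum(v^2)) < 1e-6)
    pd_stop("coincident end-point atoms: domain axis undefined", "geometry_error")
  unit3(v)
}

## Least-squares alternative: first principal axis of the domain C-alpha
## cloud, sign-oriented from the first toward the last residue.
lsq_axis <- function(coords, ca_indices) {
  pts <- coords[ca_indices, , drop = FALSE]
  s <- svd(sweep(pts, 2, colMeans(pts)))
  ax <- s$v[, 1]
  ref <- pts[nrow(pts), ] - pts[1, ]
  if (sum(ax * ref) < 0) ax <- -ax
  unit3(ax)
}

#' Tilt angle of a domain axis relative to the bilayer plane
#'
#' `theta = 90 - acos(|axis . normal|)` in degrees: 0 for an axis lying in
#' the bilayer plane, 90 for an axis along the normal. The absolute value
#' makes the angle independent of the orientation of both the axis and the
#' normal.
#'
#' @param axis unit 3-vector (checked to within 1e-6).
#' @param frame a `MembraneFrame`.
#' @return angle in degrees, in `[0, 90]`.
#' @export
theta_angle <- function(axis, frame) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    pd_stop("axis must be a unit vector", "contract_violation")
  cosang <- min(1, abs(sum(axis * frame$normal)))
  90 - acos(cosang) * 180 / pi
}

#' Distance of a domain from the bilayer midplane
#'
#' The absolute projection of the domain centroid onto the membrane normal,
#' measured from the midplane point.
#'
#' @param cp_coords `M x 3` matrix of domain atom coordinates (M >= 1).
#' @param frame a `MembraneFrame`.
#' @return distance in Angstrom (non-negative).
#' @export
distance_d <- function(cp_coords, frame) {
  cp_coords <- rbind(cp_coords)
  if (nrow(cp_coords) < 1L || ncol(cp_coords) != 3L)
    pd_stop("cp_coords must be a non-empty M x 3 matrix", "contract_violation")
  abs(sum(frame$normal * (colMeans(cp_coords) - frame$midplane_point)))
}

#' Per-frame orientation descriptors for one chain
#'
#' Computes the tilt angle `theta` and midplane distance `d` of the
#' cytoplasmic domain (C-alpha atoms of `domain`, default residues 1-16) for
#' every frame of a trajectory.
#'
#' @param traj a `Trajectory`.
#' @param chain chain identifier.
#' @param lipid_ref indices of lipid reference atoms, or `NULL` for the
#'   fallback frame (normal +z, midplane through the origin).
#' @param domain inclusive residue range of the cytoplasmic domain.
#' @param axis_mode `"endpoints"` (line through the first and last residues)
#'   or `"lsq"` (principal axis of the domain C-alphas), for sensitivity
#'   analysis.
#' @param per_frame_membrane when `TRUE` (default) the membrane frame is
#'   re-estimated each frame; `FALSE` reuses the first frame's estimate
#'   (appropriate when the reference atoms are static).
#' @return object of class `OrientationSeries`: a list with `chain_id`,
#'   `times` (ps), `theta` (degrees), `d` (Angstrom).
#' @export
orientation_series <- function(traj, chain, lipid_ref = NULL,
                               domain = c(1L, 16L),
                               axis_mode = c("endpoints", "lsq"),
                               per_frame_membrane = TRUE) {
  axis_mode <- match.arg(axis_mode)
  ca <- select_atoms(traj, chain = chain, domain = domain, atom_name = "CA")
  resno <- traj$topology$residue_number[ca]
  if (!all(domain[1]:domain[2] %in% resno))
    pd_stop(sprintf("chain %s is missing C-alpha atoms for residues %s",
                    chain,
                    paste(setdiff(domain[1]:domain[2], resno), collapse = ",")),
            "selection_error")
  i_first <- ca[which(resno == domain[1])]
  i_last <- ca[which(resno == domain[2])]
  nf <- n_frames(traj)
  theta <- numeric(nf)
  d <- numeric(nf)
  mf <- NULL
  for (m in seq_len(nf)) {
    xyz <- traj$coords[, , m]
    if (is.null(mf) || per_frame_membrane) {
      mf <- tryCatch(estimate_membrane_frame(xyz, lipid_ref),
                     error = function(e)
                       pd_stop(sprintf("frame %d: %s", m, conditionMessage(e)),
                               "geometry_error"))
    }
    ax <- if (axis_mode == "endpoints") cp_axis(xyz, i_first, i_last)
    else lsq_axis(xyz, ca)
    theta[m] <- theta_angle(ax, mf)
    d[m] <- distance_d(xyz[ca, , drop = FALSE], mf)
  }
  structure(list(chain_id = chain, times = traj$times, theta = theta, d = d),
            class = "OrientationSeries")
}

#' @export
print.OrientationSeries <- function(x, ...) {
  cat(sprintf("<OrientationSeries> chain %s, %d frames: theta %.2f +/- %.2f deg, d %.2f +/- %.2f A\n",
              x$chain_id, length(x$times), mean(x$theta), stats::sd(x$theta),
              mean(x$d), stats::sd(x$d)))
  invisible(x)
}

#' Average orientation series over chains
#'
#' Pentamer-level summary: the per-frame mean of theta and d across chains.
#'
#' @param series_list list of `OrientationSeries` with identical time bases.
#' @return an `OrientationSeries` with `chain_id = "mean"`.
#' @export
aggregate_orientation <- function(series_list) {
  if (length(series_list) < 1L)
    pd_stop("need at least one series", "contract_violation")
  t0 <- series_list[[1]]$times
  for (s in series_list)
    if (!isTRUE(all.equal(s$times, t0)))
      pd_stop("series have different time bases", "contract_violation")
  structure(list(
    chain_id = "mean",
    times = t0,
    theta = rowMeans(sapply(series_list, function(s) s$theta)),
    d = rowMeans(sapply(series_list, function(s) s$d))
  ), class = "OrientationSeries")
}

#' Write orientation series as tidy TSV
#' @param series_list list of `OrientationSeries` (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orientation_tsv <- function(series_list, path) {
  if (inherits(series_list, "OrientationSeries"))
    series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(chain = s$chain_id, time_ps = s$times,
               theta_deg = s$theta, d_angstrom = s$d)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
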