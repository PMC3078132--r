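# Independent oracles and small fixture builders shared across test files.

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_rotation <- function() quat_to_rot(rnorm(4))

# Brute-force minimum RMSD over rotations: coarse random quaternion grid
# followed by Nelder-Mead refinement of the quaternion. Independent of the
# SVD route used by the implementation.
brute_force_min_rmsd <- function(mobile, reference, n_coarse = 400) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  f <- function(qt) {
    R <- quat_to_rot(qt)
    sqrt(mean(rowSums((p %*% t(R) - q)^2)))
  }
  qs <- rbind(c(1, 0, 0, 0), matrix(rnorm(4 * n_coarse), ncol = 4))
  vals <- apply(qs, 1, f)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  opt$value
}

# toy topology/trajectory builders --------------------------------------

toy_topology <- function(n, chain = "A") {
  data.frame(serial = seq_len(n), atom_name = "CA", residue_name = "ALA",
             chain_id = chain, residue_number = seq_len(n),
             stringsAsFactors = FALSE)
}

toy_trajectory <- function(frames, dt_ps = 1, chain = "A") {
  n <- nrow(frames[[1]])
  coords <- array(unlist(frames), dim = c(n, 3L, length(frames)))
  trajectory(toy_topology(n, chain), coords,
             (seq_along(frames) - 1) * dt_ps)
}

# small synthetic pentamer used by several files
quick_sim <- function(n_frames = 100, dt_ps = 10, seed = 1, ...) {
  generate_synthetic(synthetic_config(n_frames = n_frames, dt_ps = dt_ps,
                                      seed = seed, ...))
}

chain_series <- function(sim, per_frame = FALSE) {
  lip <- lipid_reference_indices(sim$trajectory)
  lapply(sim$truth$chains, function(ch)
    orientation_series(sim$trajectory, ch, lipid_ref = lip,
                       per_frame_membrane = per_frame))
}

mean_series <- function(sim, ...) aggregate_orientation(chain_series(sim, ...))

# write a minimal PDB from explicit lines
write_lines_tmp <- function(lines) {
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  p
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          icode = " ", altloc = " ") {
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name_f, altloc, resname, chain, resno, icode, x, y, z)
}
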