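## Synthetic coarse-grained pentamer trajectories with planted ground truth.
##
## Each chain carries a C-alpha-only model of the 52-residue monomer: a rigid
## transmembrane helix (residues 23-52) centred on the bilayer midplane, a
## hinge (17-22) interpolated between the segments, and a cytoplasmic helix
## (1-16) whose end-to-end line is re-oriented every frame so that its tilt
## angle and midplane distance follow a two-state Markov-switching
## Ornstein-Uhlenbeck process. Lipid reference pseudo-atoms (one phosphate
## stand-in per grid node, both leaflets) define the virtual bilayer. The
## planted per-frame state, theta and d are returned as ground truth, so
## every analysis stage can be validated closed-loop.

#' Configuration for the synthetic pentamer generator
#'
#' Defaults reproduce the study conditions this package targets: a
#' five-chain 52-residue pentamer in a POPC-like bilayer (half-thickness
#' 19 Angstrom), 40 ns of frames saved every 1 ps, and two orientation
#' states for the cytoplasmic domain — extended (theta 41.19 +/- 8.46 deg,
#' d 30.00 +/- 1.19 A) and bent (theta 23.40 +/- 7.46 deg,
#' d 33.72 +/- 2.40 A). The `"phosphorylated"` regime instead uses the
#' near-degenerate wells seen after Ser16 phosphorylation (theta
#' 30.87 +/- 9.93 and 27.37 +/- 9.05 deg; d 32 and 37 A).
#'
#' @param n_chains number of chains (default 5).
#' @param residues_per_chain residues per chain (default 52).
#' @param domains domain-definition table ([domain_definitions()]).
#' @param bilayer_half_thickness leaflet half-separation, Angstrom
#'   (default 19, typical for POPC).
#' @param theta_means,theta_sds per-state well means / stationary SDs of the
#'   tilt angle, degrees, named `extended` and `bent`.
#' @param d_means,d_sds per-state well means / stationary SDs of the
#'   midplane distance, Angstrom.
#' @param switch_rates per-ns transition rates
#'   `c(extended_to_bent, bent_to_extended)` (default 0.05 each, i.e. mean
#'   dwell 20 ns, the scale of the transitions the method is built to
#'   detect).
#' @param ou_relaxation_ns Ornstein-Uhlenbeck relaxation time of theta and d
#'   within a well, ns (default 0.2, a sub-nanosecond orientational
#'   correlation time).
#' @param positional_noise_sd isotropic Gaussian noise added per atom
#'   coordinate, Angstrom (default 0.5).
#' @param n_frames number of frames (default 40000).
#' @param dt_ps frame spacing, ps (default 1).
#' @param seed integer RNG seed.
#' @param regime `"unphosphorylated"` (default) or `"phosphorylated"`;
#'   the latter re-centres both wells near 30 degrees unless the well
#'   parameters are given explicitly.
#' @param start_state `"extended"` or `"bent"`.
#' @param forced_switch_ns optional vector of times (ns) at which every
#'   chain deterministically toggles state (stochastic switching is then
#'   disabled); used to plant transitions at known times.
#' @return object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_chains = 5L,
                             residues_per_chain = 52L,
                             domains = domain_definitions(),
                             bilayer_half_thickness = 19,
                             theta_means = c(extended = 41.19, bent = 23.40),
                             theta_sds = c(extended = 8.46, bent = 7.46),
                             d_means = c(extended = 30.00, bent = 33.72),
                             d_sds = c(extended = 1.19, bent = 2.40),
                             switch_rates = c(extended_to_bent = 0.05,
                                              bent_to_extended = 0.05),
                             ou_relaxation_ns = 0.2,
                             positional_noise_sd = 0.5,
                             n_frames = 40000L,
                             dt_ps = 1,
                             seed = 1L,
                             regime = c("unphosphorylated", "phosphorylated"),
                             start_state = c("extended", "bent"),
                             forced_switch_ns = NULL) {
  regime <- match.arg(regime)
  start_state <- match.arg(start_state)
  if (regime == "phosphorylated") {
    ## phosphorylation collapses the two wells onto a common orientation
    ## near 30 degrees and pushes the domain outward
    if (missing(theta_means)) theta_means <- c(extended = 30.87, bent = 27.37)
    if (missing(theta_sds)) theta_sds <- c(extended = 9.93, bent = 9.05)
    if (missing(d_means)) d_means <- c(extended = 32, bent = 37)
  }
  cfg <- list(n_chains = as.integer(n_chains),
              residues_per_chain = as.integer(residues_per_chain),
              domains = domains,
              bilayer_half_thickness = bilayer_half_thickness,
              theta_means = theta_means, theta_sds = theta_sds,
              d_means = d_means, d_sds = d_sds,
              switch_rates = switch_rates,
              ou_relaxation_ns = ou_relaxation_ns,
              positional_noise_sd = positional_noise_sd,
              n_frames = as.integer(n_frames), dt_ps = dt_ps,
              seed = as.integer(seed), regime = regime,
              start_state = start_state,
              forced_switch_ns = forced_switch_ns)
  validate_synthetic_config(cfg)
  structure(cfg, class = "SyntheticConfig")
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) pd_stop(msg, "configuration_error")
  chk(cfg$n_chains >= 1L, "n_chains must be >= 1")
  chk(cfg$residues_per_chain >= 17L, "residues_per_chain must cover the hinge")
  chk(cfg$bilayer_half_thickness > 0, "bilayer_half_thickness must be positive")
  chk(length(cfg$theta_means) == 2L && all(cfg$theta_means > 0) &&
        all(cfg$theta_means < 90), "theta_means must lie in (0, 90)")
  chk(all(cfg$theta_sds >= 0) && all(cfg$d_sds >= 0),
      "state SDs must be non-negative")
  chk(all(cfg$d_means > 0), "d_means must be positive")
  chk(all(cfg$switch_rates >= 0), "switch rates must be non-negative")
  chk(cfg$ou_relaxation_ns > 0, "ou_relaxation_ns must be positive")
  chk(cfg$positional_noise_sd >= 0, "positional_noise_sd must be non-negative")
  chk(cfg$n_frames >= 1L && cfg$dt_ps > 0, "need n_frames >= 1 and dt_ps > 0")
  invisible(cfg)
}

## ideal C-alpha helix: 100 deg/residue about the axis, rise 1.5 A/residue,
## radius 2.3 A; returned centred at the origin with axis +z
ideal_helix <- function(n_res, radius = 2.3, rise = 1.5, turn_deg = 100) {
  ang <- (seq_len(n_res) - 1L) * turn_deg * pi / 180
  xyz <- cbind(radius * cos(ang), radius * sin(ang),
               (seq_len(n_res) - 1L) * rise)
  sweep(xyz, 2, colMeans(xyz))
}

## rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    ## antiparallel: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) unit3(c(a[2] * 0 - a[3] * 0 + 0,
                                         a[3] * 1 - a[1] * 0,
                                         a[1] * 0 - a[2] * 1)) else unit3(c(0, a[3], -a[2]))
    perp <- unit3(perp - sum(perp * a) * a)
    K <- matrix(c(0, -perp[3], perp[2], perp[3], 0, -perp[1],
                  -perp[2], perp[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

## continuous-time two-state Markov path sampled at frame times.
## Returns integer state per frame (1 = extended, 2 = bent) and the exact
## continuous transition times (ps).
simulate_state_path <- function(n_frames, dt_ps, rates_per_ns, start_state,
                                forced_switch_ns = NULL) {
  total_ps <- (n_frames - 1L) * dt_ps
  s0 <- if (start_state == "extended") 1L else 2L
  if (!is.null(forced_switch_ns)) {
    ev <- sort(forced_switch_ns) * 1000
    ev <- ev[ev > 0 & ev <= total_ps]
  } else {
    rates_ps <- rates_per_ns / 1000
    ev <- numeric(0)
    t <- 0; s <- s0
    repeat {
      r <- rates_ps[s]
      if (r <= 0) break
      t <- t + stats::rexp(1L, r)
      if (t > total_ps) break
      ev <- c(ev, t)
      s <- 3L - s
    }
  }
  times <- (seq_len(n_frames) - 1L) * dt_ps
  states <- rep(s0, n_frames)
  if (length(ev)) {
    n_before <- findInterval(times, ev)    # switches completed by each frame
    states <- ifelse(n_before %% 2L == 0L, s0, 3L - s0)
  }
  list(states = as.integer(states), transition_times_ps = ev)
}

## OU recursion toward the active well of a Markov-switching target
simulate_switching_ou <- function(states, dt_ps, tau_ns, means, sds) {
  n <- length(states)
  a <- exp(-(dt_ps / 1000) / tau_ns)
  innov_scale <- sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- means[states[1]] + sds[states[1]] * stats::rnorm(1L)
  z <- stats::rnorm(n)
  if (n < 2L) return(x)
  for (i in 2:n) {
    mu <- means[states[i]]
    sdv <- sds[states[i]]
    x[i] <- mu + (x[i - 1] - mu) * a + sdv * innov_scale * z[i]
  }
  x
}

## geometry layout constants (Angstrom)
CP_RADIAL_OFFSET <- 14   # lateral distance of the cytoplasmic-helix centroid
TM_RADIAL_OFFSET <- 9    # lateral distance of the TM-helix axis
LIPID_GRID_N <- 8        # lipid pseudo-atoms per leaflet edge
LIPID_GRID_SPACING <- 9  # Angstrom between grid nodes

synthetic_topology <- function(cfg) {
  chains <- LETTERS[seq_len(cfg$n_chains)]
  prot <- do.call(rbind, lapply(chains, function(ch)
    data.frame(atom_name = "CA", residue_name = "ALA", chain_id = ch,
               residue_number = seq_len(cfg$residues_per_chain),
               stringsAsFactors = FALSE)))
  nl <- LIPID_GRID_N^2 * 2L
  lip <- data.frame(atom_name = "P", residue_name = "POP", chain_id = "X",
                    residue_number = seq_len(nl), stringsAsFactors = FALSE)
  top <- rbind(prot, lip)
  top <- cbind(serial = seq_len(nrow(top)), top)
  top
}

lipid_coords <- function(cfg) {
  g <- (seq_len(LIPID_GRID_N) - (LIPID_GRID_N + 1) / 2) * LIPID_GRID_SPACING
  grid <- as.matrix(expand.grid(x = g, y = g))
  h <- cfg$bilayer_half_thickness
  rbind(cbind(grid, z = h), cbind(grid, z = -h))
}

#' Generate a synthetic pentamer trajectory with ground truth
#'
#' See [synthetic_config()] for the model. The construction is exact by
#' design: before positional noise, the end-to-end line of each chain's
#' cytoplasmic C-alphas has precisely the planted tilt, and the domain
#' centroid sits precisely at the planted midplane distance, so
#' `analysis(generate(config))` returns the planted series up to noise (and
#' exactly for a noise-free configuration). Deterministic for a fixed seed.
#'
#' @param config a `SyntheticConfig`.
#' @return list with elements `trajectory` (a [trajectory()] including lipid
#'   reference pseudo-atoms on chain `"X"`) and `truth` (per-chain planted
#'   `theta` and `d` matrices (frames x chains), per-chain state labels,
#'   per-chain transition times in ps, and the config echo).
#' @export
generate_synthetic <- function(config) {
  cfg <- validate_synthetic_config(config)
  with_seed(cfg$seed, {
    nf <- cfg$n_frames
    nc <- cfg$n_chains
    nres <- cfg$residues_per_chain
    top <- synthetic_topology(cfg)
    n_atoms <- nrow(top)
    coords <- array(0, dim = c(n_atoms, 3L, nf))

    ## static pieces -----------------------------------------------------
    cp_res <- 1:16
    tm_res <- 23:nres
    hinge_res <- 17:22
    tm_local <- ideal_helix(length(tm_res))
    ## TM helix held rigid, centred on the midplane, standing along z
    tm_base <- sweep(tm_local, 2, c(TM_RADIAL_OFFSET, 0, 0), "+")
    lip <- lipid_coords(cfg)
    lip_rows <- which(top$chain_id == "X")
    for (m in seq_len(nf)) coords[lip_rows, , m] <- lip

    ## cytoplasmic template: centred, pre-rotated so its end-to-end
    ## (residue 1 -> 16) vector lies along +x
    cp_local <- ideal_helix(length(cp_res))
    e2e <- cp_local[nrow(cp_local), ] - cp_local[1, ]
    cp_local <- cp_local %*% t(rotation_between(e2e, c(1, 0, 0)))

    theta_truth <- matrix(NA_real_, nf, nc)
    d_truth <- matrix(NA_real_, nf, nc)
    state_truth <- matrix(NA_integer_, nf, nc)
    transition_times <- vector("list", nc)

    for (ci in seq_len(nc)) {
      path <- simulate_state_path(nf, cfg$dt_ps, cfg$switch_rates,
                                  cfg$start_state, cfg$forced_switch_ns)
      st <- path$states
      theta <- simulate_switching_ou(st, cfg$dt_ps, cfg$ou_relaxation_ns,
                                     cfg$theta_means, cfg$theta_sds)
      theta <- pmin(pmax(theta, 0.5), 89.5)   # keep within the descriptor range
      dd <- simulate_switching_ou(st, cfg$dt_ps, cfg$ou_relaxation_ns,
                                  cfg$d_means, cfg$d_sds)
      dd <- pmax(dd, 1)
      theta_truth[, ci] <- theta
      d_truth[, ci] <- dd
      state_truth[, ci] <- st
      transition_times[[ci]] <- path$transition_times_ps

      ## frame-by-frame placement, fully vectorized over frames:
      ## tilt the template about y so +x maps to (cos theta, 0, sin theta),
      ## then translate the centroid to (CP_RADIAL_OFFSET, 0, d)
      th <- theta * pi / 180
      ct <- cos(th); stn <- sin(th)
      X0 <- cp_local[, 1]; Y0 <- cp_local[, 2]; Z0 <- cp_local[, 3]
      cp_x <- outer(X0, ct) - outer(Z0, stn) + CP_RADIAL_OFFSET  # 16 x nf
      cp_y <- matrix(Y0, length(Y0), nf)
      cp_z <- outer(X0, stn) + outer(Z0, ct) + rep(dd, each = length(X0))

      ## chain azimuth: rotate the whole chain about z
      phi <- 2 * pi * (ci - 1) / nc
      cphi <- cos(phi); sphi <- sin(phi)
      rows_cp <- which(top$chain_id == LETTERS[ci] &
                         top$residue_number %in% cp_res)
      rows_tm <- which(top$chain_id == LETTERS[ci] &
                         top$residue_number %in% tm_res)
      rows_h <- which(top$chain_id == LETTERS[ci] &
                        top$residue_number %in% hinge_res)

      coords[rows_cp, 1, ] <- cp_x * cphi - cp_y * sphi
      coords[rows_cp, 2, ] <- cp_x * sphi + cp_y * cphi
      coords[rows_cp, 3, ] <- cp_z

      tm_rot <- cbind(tm_base[, 1] * cphi - tm_base[, 2] * sphi,
                      tm_base[, 1] * sphi + tm_base[, 2] * cphi,
                      tm_base[, 3])
      coords[rows_tm, , ] <- array(rep(tm_rot, nf),
                                   dim = c(length(tm_res), 3L, nf))

      ## hinge: linear interpolation between residue 16 and residue 23
      p16 <- rbind(coords[rows_cp[length(rows_cp)], 1, ],
                   coords[rows_cp[length(rows_cp)], 2, ],
                   coords[rows_cp[length(rows_cp)], 3, ])   # 3 x nf
      p23 <- tm_rot[1, ]
      for (k in seq_along(hinge_res)) {
        w <- k / (length(hinge_res) + 1)
        coords[rows_h[k], , ] <- p16 * (1 - w) + p23 * w
      }
    }

    if (cfg$positional_noise_sd > 0) {
      prot_rows <- which(top$chain_id != "X")
      coords[prot_rows, , ] <- coords[prot_rows, , ] +
        stats::rnorm(length(prot_rows) * 3L * nf, sd = cfg$positional_noise_sd)
    }

    state_names <- c(STATE_EXTENDED, STATE_BENT)
    truth <- list(
      theta = theta_truth,
      d = d_truth,
      states = matrix(state_names[state_truth], nf, nc),
      transition_times_ps = transition_times,
      chains = LETTERS[seq_len(nc)],
      config = cfg
    )
    list(trajectory = trajectory(top, coords,
                                 (seq_len(nf) - 1L) * cfg$dt_ps),
         truth = truth)
  })
}

#' Indices of the lipid reference pseudo-atoms in a synthetic trajectory
#' @param traj a `Trajectory` from [generate_synthetic()] (lipids on chain
#'   `"X"`, atom name `"P"`).
#' @return integer atom indices.
#' @export
lipid_reference_indices <- function(traj) {
  select_atoms(traj, chain = "X", atom_name = "P")
}

#' Write a synthetic trajectory fixture to disk
#'
#' Emits a multi-model PDB (`trajectory.pdb`), the planted ground truth
#' (`truth.json`), and a config echo (`config.json`). Re-reading the PDB
#' reproduces the trajectory to the format's 3-decimal precision. Files are
#' byte-identical for a fixed seed.
#'
#' @param sim output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @param format `"pdb"` (default) or `"xyz"`.
#' @return named character vector of the files written.
#' @export
write_fixture <- function(sim, dir, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  traj_path <- file.path(dir, paste0("trajectory.", format))
  if (format == "pdb") write_pdb_trajectory(sim$trajectory, traj_path)
  else write_xyz_trajectory(sim$trajectory, traj_path)
  truth_path <- file.path(dir, "truth.json")
  truth <- sim$truth
  jsonlite::write_json(
    list(theta = truth$theta, d = truth$d, states = truth$states,
         transition_times_ps = truth$transition_times_ps,
         chains = truth$chains),
    truth_path, digits = 6, pretty = TRUE)
  cfg_path <- file.path(dir, "config.json")
  cfg <- unclass(truth$config)
  cfg$domains <- NULL
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  c(trajectory = traj_path, truth = truth_path, config = cfg_path)
}
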