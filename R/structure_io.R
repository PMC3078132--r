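## Structure and trajectory containers, PDB/XYZ/DCD readers and writers,
## atom selection, and the four-domain architecture of the 52-residue
## phospholamban monomer.

#' Standard structural domains of the phospholamban monomer
#'
#' Returns the four-domain decomposition used throughout the package:
#' cytoplasmic helix Ia (residues 1-16), the type-III beta-turn hinge
#' (17-22), and the transmembrane domains Ib (23-30) and II (31-52).
#'
#' @param custom optional data frame with columns `name`, `start`, `end`
#'   overriding the defaults; ranges must be 1-based, inclusive, ordered and
#'   non-overlapping.
#' @return data frame with columns `name`, `start`, `end`.
#' @export
#' @examples
#' domain_definitions()
domain_definitions <- function(custom = NULL) {
  if (is.null(custom)) {
    defs <- data.frame(
      name  = c("Ia", "hinge", "Ib", "II"),
      start = c(1L, 17L, 23L, 31L),
      end   = c(16L, 22L, 30L, 52L),
      stringsAsFactors = FALSE
    )
    return(defs)
  }
  defs <- as.data.frame(custom, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(defs)))
    pd_stop("domain definitions need columns name, start, end", "configuration_error")
  defs$start <- as.integer(defs$start)
  defs$end <- as.integer(defs$end)
  if (any(defs$start < 1L) || any(defs$end < defs$start))
    pd_stop("domain ranges must be 1-based with start <= end", "configuration_error")
  o <- order(defs$start)
  defs <- defs[o, , drop = FALSE]
  if (nrow(defs) > 1L && any(defs$start[-1L] <= defs$end[-nrow(defs)]))
    pd_stop("domain ranges overlap", "configuration_error")
  rownames(defs) <- NULL
  defs
}

new_structure <- function(atoms, model_index = 0L) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "atom_name", "residue_name", "chain_id",
              "residue_number", "x", "y", "z")
  if (!all(needed %in% names(atoms)))
    pd_stop("atom table missing required columns", "parse_error")
  if (nrow(atoms) == 0L)
    pd_stop("structure contains zero atoms", "empty_input_error")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    pd_stop("non-finite atom coordinates", "parse_error")
  if (any(atoms$residue_number < 1L))
    pd_stop("residue numbers must be >= 1", "parse_error")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    pd_stop("duplicate (chain, residue, atom name) within a model", "parse_error")
  structure(list(atoms = atoms, model_index = as.integer(model_index)),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure> model %d: %d atoms, chains %s\n",
              x$model_index, nrow(x$atoms),
              paste(unique(x$atoms$chain_id), collapse = "")))
  invisible(x)
}

coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Construct a Trajectory object
#'
#' A trajectory is a fixed atom topology plus an ordered stack of coordinate
#' frames with strictly increasing timestamps (picoseconds).
#'
#' @param topology data frame of atom records (`serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_number`); coordinate columns, if
#'   present, are ignored.
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`.
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, times) {
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  needed <- c("serial", "atom_name", "residue_name", "chain_id", "residue_number")
  if (!all(needed %in% names(topology)))
    pd_stop("topology missing required atom-record columns", "parse_error")
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    pd_stop("coords must be an n_atoms x 3 x n_frames array", "format_error")
  if (dim(coords)[1] != nrow(topology))
    pd_stop(sprintf("coordinate rows (%d) do not match topology size (%d)",
                    dim(coords)[1], nrow(topology)), "format_error")
  times <- as.numeric(times)
  if (length(times) != dim(coords)[3])
    pd_stop("one timestamp per frame required", "format_error")
  if (any(times < 0) || (length(times) > 1L && any(diff(times) <= 0)))
    pd_stop("frame times must be non-negative and strictly increasing",
            "format_error")
  structure(list(topology = topology[, needed], coords = coords, times = times),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d atoms x %d frames (%.1f-%.1f ps), chains %s\n",
              nrow(x$topology), n_frames(x), x$times[1],
              x$times[length(x$times)],
              paste(unique(x$topology$chain_id), collapse = "")))
  invisible(x)
}

#' @export
n_frames <- function(traj) UseMethod("n_frames")

#' @export
n_frames.Trajectory <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj))
    pd_stop(sprintf("frame index %d out of range", i), "format_error")
  traj$coords[, , i, drop = TRUE]
}

## ---- PDB reading --------------------------------------------------------

## Fixed-width PDB v3 ATOM/HETATM columns, parsed vectorized over all record
## lines at once; validation reports the first offending physical line number.
## Insertion codes are rejected; altloc other than ' '/'A' is dropped.
## bio3d::read.pdb serves as an independent cross-check of this reader in the
## test suite.
parse_atom_block <- function(lines, linenos) {
  short <- which(nchar(lines) < 54)
  if (length(short))
    pd_stop(sprintf("malformed ATOM record at line %d: fewer than 54 columns",
                    linenos[short[1]]), "parse_error")
  icode <- substr(lines, 27, 27)
  bad_ic <- which(icode != " ")
  if (length(bad_ic))
    pd_stop(sprintf("insertion code '%s' at line %d not supported",
                    icode[bad_ic[1]], linenos[bad_ic[1]]), "parse_error")
  num <- function(a, b) suppressWarnings(as.numeric(substr(lines, a, b)))
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  bad <- which(is.na(serial) | is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    pd_stop(sprintf("malformed ATOM record at line %d: non-numeric field",
                    linenos[bad[1]]), "parse_error")
  df <- data.frame(
    serial = serial,
    atom_name = trimws(substr(lines, 13, 16)),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    residue_number = resno,
    x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )
  df[substr(lines, 17, 17) %in% c(" ", "A"), , drop = FALSE]
}

#' Read a (possibly multi-model) PDB file
#'
#' Parses ATOM/HETATM records into one `Structure` per MODEL block (a single
#' structure when the file has no MODEL records). Only alternate-location
#' indicators `' '` and `'A'` are kept, giving a deterministic
#' single-conformer view; insertion codes are rejected. Residue numbering is
#' taken verbatim from the file.
#'
#' @param path path to a PDB file.
#' @return list of `Structure` objects in file order.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path))
    pd_stop(sprintf("file not found: %s", path), "validation_error")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom))
    pd_stop(sprintf("no atoms found in %s", path), "empty_input_error")
  ## model id per line: cumulative count of MODEL records (0 if none seen yet)
  model_of_line <- cumsum(rec == "MODEL ")
  atom_lines <- which(is_atom)
  atoms <- parse_atom_block(lines[atom_lines], atom_lines)
  model_ids <- model_of_line[atom_lines][substr(lines[atom_lines], 17, 17) %in%
                                           c(" ", "A")]
  split_idx <- split(seq_len(nrow(atoms)), model_ids)
  models <- lapply(names(split_idx), function(mid) {
    new_structure(atoms[split_idx[[mid]], , drop = FALSE],
                  model_index = as.integer(mid))
  })
  if (length(models) == 0L)
    pd_stop(sprintf("no atoms found in %s", path), "empty_input_error")
  models
}

topology_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$atom_name, sep = "|")
}

## ---- trajectory reading -------------------------------------------------

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fidx <- fidx + 1L
    if (is.na(n) || n < 1L)
      pd_stop(sprintf("bad atom count header at frame %d (line %d)", fidx, i),
              "format_error")
    if (i + 1L + n > length(lines))
      pd_stop(sprintf("truncated frame %d: expected %d atom lines", fidx, n),
              "format_error")
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad))
      pd_stop(sprintf("malformed atom line in frame %d (line %d)",
                      fidx, i + 1L + bad[1]), "format_error")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      pd_stop(sprintf("non-numeric coordinate in frame %d", fidx), "format_error")
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    frames[[fidx]] <- list(
      n = n, xyz = xyz,
      time = if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    )
    i <- i + 2L + n
  }
  if (length(frames) == 0L)
    pd_stop(sprintf("no frames found in %s", path), "empty_input_error")
  frames
}

#' Read a coordinate trajectory
#'
#' Supports multi-model PDB (topology taken from the first model), XYZ
#' (requires a separate `topology`), and binary DCD via [bio3d::read.dcd]
#' (requires a `topology`; available when the file was written by an engine
#' bio3d understands). Timestamps come from file metadata when present (`t=`
#' tags in XYZ comment lines), otherwise `index * dt_ps`.
#'
#' @param path trajectory file.
#' @param format one of `"pdb"`, `"xyz"`, `"dcd"`.
#' @param topology a `Structure` supplying the atom records for xyz/dcd input.
#' @param dt_ps frame spacing in ps used when the file carries no timestamps
#'   (default 1 ps).
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz", "dcd"),
                            topology = NULL, dt_ps = 1) {
  format <- match.arg(format)
  if (!file.exists(path))
    pd_stop(sprintf("file not found: %s", path), "validation_error")
  if (format == "pdb") {
    models <- read_pdb(path)
    key0 <- topology_key(models[[1]]$atoms)
    coords <- array(NA_real_, dim = c(length(key0), 3L, length(models)))
    for (m in seq_along(models)) {
      at <- models[[m]]$atoms
      if (nrow(at) != length(key0) || !identical(topology_key(at), key0))
        pd_stop(sprintf("frame %d atom records differ from frame 1", m),
                "format_error")
      coords[, , m] <- as.matrix(at[, c("x", "y", "z")])
    }
    return(trajectory(models[[1]]$atoms, coords,
                      (seq_along(models) - 1) * dt_ps))
  }
  if (is.null(topology))
    pd_stop(sprintf("%s input requires a topology Structure", format),
            "validation_error")
  if (format == "xyz") {
    frames <- read_xyz_frames(path)
    n0 <- frames[[1]]$n
    bad <- which(vapply(frames, function(f) f$n, 1L) != n0)
    if (length(bad))
      pd_stop(sprintf("frame %d atom count (%d) differs from frame 1 (%d)",
                      bad[1], frames[[bad[1]]]$n, n0), "format_error")
    if (n0 != nrow(topology$atoms))
      pd_stop("xyz atom count does not match topology", "format_error")
    coords <- array(NA_real_, dim = c(n0, 3L, length(frames)))
    for (m in seq_along(frames)) coords[, , m] <- frames[[m]]$xyz
    tm <- vapply(frames, function(f) f$time, numeric(1))
    times <- if (all(is.finite(tm))) tm else (seq_along(frames) - 1) * dt_ps
    return(trajectory(topology$atoms, coords, times))
  }
  ## DCD: delegate the binary format to bio3d
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n0 <- ncol(xyz) / 3L
  if (n0 != nrow(topology$atoms))
    pd_stop("dcd atom count does not match topology", "format_error")
  coords <- array(NA_real_, dim = c(n0, 3L, nrow(xyz)))
  for (m in seq_len(nrow(xyz)))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
  trajectory(topology$atoms, coords, (seq_len(nrow(xyz)) - 1) * dt_ps)
}

## ---- writers ------------------------------------------------------------

format_atom_line <- function(serial, name, resname, chain, resno, x, y, z) {
  name_f <- ifelse(nchar(name) < 4L, sprintf(" %-3s", name),
                   substr(name, 1, 4))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, name_f, substr(resname, 1, 3), chain,
          resno %% 10000L, x, y, z)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written with the PDB's three decimal places, the format's
#' stated precision for round-trips.
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  top <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , m]
    lines <- format_atom_line(top$serial, top$atom_name, top$residue_name,
                              top$chain_id, top$residue_number,
                              xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(sprintf("MODEL     %4d", m), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in XYZ format
#'
#' One block per frame: atom count, a comment line carrying `t= <ps>`, then
#' element/x/y/z lines at five decimal places.
#'
#' @inheritParams write_pdb_trajectory
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  top <- traj$topology
  el <- substr(top$atom_name, 1, 1)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , m]
    writeLines(c(sprintf("%d", nrow(top)),
                 sprintf("frame %d t= %.6f", m, traj$times[m]),
                 sprintf("%-2s %12.5f %12.5f %12.5f",
                         el, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Write an atom table as TSV
#' @param x a `Structure` or `Trajectory` (topology plus first frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atom_table <- function(x, path) {
  atoms <- if (inherits(x, "Structure")) x$atoms
  else cbind(x$topology,
             as.data.frame(x$coords[, , 1, drop = TRUE]) |>
               stats::setNames(c("x", "y", "z")))
  utils::write.table(atoms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- selection ----------------------------------------------------------

#' Select atom indices by chain, residue range, and atom name
#'
#' Indices are returned in topology order and are stable across frames, so
#' selecting once and reusing the indices on every frame is the intended
#' pattern.
#'
#' @param x a `Trajectory`, `Structure`, or atom-record data frame.
#' @param chain chain identifier, or `"all"`.
#' @param domain `NULL` (all residues), a domain name from
#'   [domain_definitions()] (e.g. `"Ia"`), or an inclusive 1-based
#'   `c(start, end)` pair.
#' @param atom_name atom name to match (default `"CA"`); `"all"` keeps every
#'   atom name.
#' @param domains domain-definition table used to resolve domain names.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(x, chain = "all", domain = NULL, atom_name = "CA",
                         domains = domain_definitions()) {
  atoms <- if (is.data.frame(x)) x
  else if (inherits(x, "Structure")) x$atoms
  else if (inherits(x, "Trajectory")) x$topology
  else pd_stop("cannot select from this object", "selection_error")
  keep <- rep(TRUE, nrow(atoms))
  pred <- character(0)
  if (!identical(chain, "all")) {
    keep <- keep & atoms$chain_id %in% chain
    pred <- c(pred, sprintf("chain=%s", paste(chain, collapse = ",")))
  }
  if (!is.null(domain)) {
    rng <- if (is.character(domain)) {
      hit <- domains[domains$name == domain, ]
      if (nrow(hit) != 1L)
        pd_stop(sprintf("unknown domain '%s'", domain), "selection_error")
      c(hit$start, hit$end)
    } else as.integer(domain)
    if (length(rng) != 2L || rng[1] > rng[2])
      pd_stop("residue range must be an ordered pair", "selection_error")
    keep <- keep & atoms$residue_number >= rng[1] & atoms$residue_number <= rng[2]
    pred <- c(pred, sprintf("residues=%d-%d", rng[1], rng[2]))
  }
  if (!identical(atom_name, "all")) {
    keep <- keep & atoms$atom_name %in% atom_name
    pred <- c(pred, sprintf("atom=%s", paste(atom_name, collapse = ",")))
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    pd_stop(sprintf("empty selection for predicate {%s}",
                    paste(pred, collapse = "; ")), "selection_error")
  idx
}
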