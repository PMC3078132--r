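test_that("single-model PDB parsing preserves atom count and order", {
  lines <- sapply(1:5, function(i)
    pdb_atom_line(i, "CA", "ALA", "A", i, i * 1.5, 0, 0))
  p <- write_lines_tmp(c(lines, "END"))
  models <- read_pdb(p)
  expect_length(models, 1L)
  expect_equal(nrow(models[[1]]$atoms), 5L)
  expect_equal(models[[1]]$atoms$residue_number, 1:5)
  expect_equal(models[[1]]$atoms$x, (1:5) * 1.5)
})

test_that("multi-model PDB yields one Structure per MODEL with shared topology", {
  block <- function(shift) sapply(1:4, function(i)
    pdb_atom_line(i, "CA", "GLY", "B", i, i + shift, 0, 0))
  p <- write_lines_tmp(c("MODEL        1", block(0), "ENDMDL",
                         "MODEL        2", block(10), "ENDMDL", "END"))
  models <- read_pdb(p)
  expect_length(models, 2L)
  key <- function(s) paste(s$atoms$chain_id, s$atoms$residue_number,
                           s$atoms$atom_name)
  expect_identical(key(models[[1]]), key(models[[2]]))
  expect_equal(models[[2]]$atoms$x, models[[1]]$atoms$x + 10)
})

test_that("PDB parse errors carry line numbers; insertion codes are rejected", {
  good <- pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0)
  bad_short <- "ATOM      2  CA  ALA A   2"
  p <- write_lines_tmp(c(good, bad_short))
  expect_error(read_pdb(p), "line 2", class = "parse_error")

  with_icode <- pdb_atom_line(2, "CA", "ALA", "A", 2, 1, 1, 1, icode = "B")
  p2 <- write_lines_tmp(c(good, with_icode))
  expect_error(read_pdb(p2), "insertion code", class = "parse_error")

  bad_num <- pdb_atom_line(2, "CA", "ALA", "A", 2, 1, 1, 1)
  substr(bad_num, 31, 38) <- "  xx.xxx"
  p3 <- write_lines_tmp(c(good, bad_num))
  expect_error(read_pdb(p3), "line 2", class = "parse_error")

  p4 <- write_lines_tmp(c("HEADER junk", "END"))
  expect_error(read_pdb(p4), "no atoms", class = "empty_input_error")
})

test_that("altloc handling keeps blank and 'A' conformers only", {
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, altloc = "A"),
             pdb_atom_line(2, "CA", "ALA", "A", 2, 1, 0, 0, altloc = "B"),
             pdb_atom_line(3, "CA", "ALA", "A", 3, 2, 0, 0))
  models <- read_pdb(write_lines_tmp(lines))
  expect_equal(models[[1]]$atoms$residue_number, c(1L, 3L))
})

test_that("multi-model PDB trajectory gets default 1 ps frame spacing", {
  block <- function(shift) pdb_atom_line(1, "CA", "ALA", "A", 1, shift, 0, 0)
  p <- write_lines_tmp(c("MODEL        1", block(0), "ENDMDL",
                         "MODEL        2", block(1), "ENDMDL",
                         "MODEL        3", block(2), "ENDMDL"))
  tr <- read_trajectory(p, "pdb")
  expect_equal(tr$times, c(0, 1, 2))
  expect_equal(n_frames(tr), 3L)
})

test_that("xyz reader flags a frame with deviant atom count", {
  xyz <- c("2", "frame 1 t= 0", "C 0 0 0", "C 1 0 0",
           "3", "frame 2 t= 1", "C 0 0 0", "C 1 0 0", "C 2 0 0")
  p <- tempfile(fileext = ".xyz")
  writeLines(xyz, p)
  top <- new_top <- read_pdb(write_lines_tmp(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 0, 0, 0))))[[1]]
  expect_error(read_trajectory(p, "xyz", topology = top), "frame 2",
               class = "format_error")
})

test_that("trajectory constructor enforces frame/topology consistency", {
  top <- toy_topology(4)
  coords <- array(0, dim = c(3, 3, 2))
  expect_error(trajectory(top, coords, c(0, 1)), class = "format_error")
  coords <- array(0, dim = c(4, 3, 2))
  expect_error(trajectory(top, coords, c(1, 1)), class = "format_error")
  expect_s3_class(trajectory(top, coords, c(0, 1)), "Trajectory")
})

test_that("PDB round-trip preserves counts, order, and 3-decimal coordinates", {
  set.seed(7)
  frames <- lapply(1:3, function(i) matrix(rnorm(30, sd = 20), 10, 3))
  tr <- toy_trajectory(frames)
  p <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(tr, p)
  back <- read_trajectory(p, "pdb")
  expect_equal(n_frames(back), 3L)
  expect_identical(back$topology$residue_number, tr$topology$residue_number)
  expect_equal(back$coords, round(tr$coords, 3), tolerance = 1e-12)
})

test_that("our PDB reader agrees with bio3d on a written trajectory", {
  sim <- quick_sim(n_frames = 3, seed = 9)
  p <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(sim$trajectory, p)
  ours <- read_trajectory(p, "pdb")
  ref <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(ref$atom), nrow(ours$topology))
  for (m in 1:3)
    expect_equal(matrix(ref$xyz[m, ], ncol = 3, byrow = TRUE),
                 ours$coords[, , m], tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("selection returns ordered stable indices and errors usefully", {
  sim <- quick_sim(n_frames = 2, seed = 3)
  tr <- sim$trajectory
  ia <- select_atoms(tr, chain = "A", domain = "Ia", atom_name = "CA")
  expect_length(ia, 16L)
  all_ca <- select_atoms(tr, chain = LETTERS[1:5], atom_name = "CA")
  expect_length(all_ca, 5L * 52L)
  expect_false(is.unsorted(all_ca))
  expect_error(select_atoms(tr, atom_name = "XX"), "XX",
               class = "selection_error")
  # idempotence on the topology subset
  sub <- tr$topology[ia, ]
  again <- select_atoms(sub, chain = "A", domain = c(1, 16), atom_name = "CA")
  expect_identical(sub[again, ], sub)
})

test_that("default domain table matches the monomer architecture", {
  d <- domain_definitions()
  expect_equal(d$name, c("Ia", "hinge", "Ib", "II"))
  expect_equal(d$start, c(1L, 17L, 23L, 31L))
  expect_equal(d$end, c(16L, 22L, 30L, 52L))
  expect_error(domain_definitions(data.frame(name = c("a", "b"),
                                             start = c(1, 5),
                                             end = c(6, 8))),
               "overlap", class = "configuration_error")
})
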