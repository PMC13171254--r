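# structure/trajectory I/O, selections and glycan assignment

test_that("PDB coordinates are converted from Angstrom to nm on read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CA  ALA A   1      10.000   2.500",
                      "  -3.000  1.00  0.00           C"),
               "END"), f)
  s <- read_structure(f)
  expect_equal(n_atoms(s), 1)
  expect_equal(s$xyz[1, ], c(1.0, 0.25, -0.3))
  expect_equal(s$atoms$atom_name, "CA")
  expect_equal(s$atoms$element, "C")
})

test_that("write/read round-trip preserves atoms, numbering and coordinates", {
  m <- build_toy_mechanomodule()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m$structure, f)
  s2 <- read_structure(f)
  expect_equal(n_atoms(s2), n_atoms(m$structure))
  expect_equal(s2$atoms$atom_name, m$structure$atoms$atom_name)
  expect_equal(s2$atoms$resnum, m$structure$atoms$resnum)
  expect_equal(s2$atoms$resname, m$structure$atoms$resname)
  # PDB precision is 3 decimals in Angstrom = 1e-4 nm
  expect_equal(s2$xyz, m$structure$xyz, tolerance = 1e-12)
  # HETATM glycan atoms survive
  expect_true(any(s2$atoms$het))
})

test_that("multi-model PDB trajectories round-trip with frame counts", {
  s <- make_structure(rep("CA", 5), rep("C", 5), rep("ALA", 5), 1:5,
                      matrix(rnorm(15), 5, 3))
  frames <- list(s$xyz, s$xyz + 0.1, s$xyz + 0.2)
  traj <- make_trajectory(s, lapply(frames, round, digits = 4), dt_ns = 0.5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  t2 <- read_trajectory(s, f, dt_ns = 0.5)
  expect_equal(n_frames(t2), 3)
  expect_equal(dim(t2$coords), c(3, 5, 3))
  expect_equal(t2$times, c(0, 0.5, 1.0))
  expect_equal(frame_coords(t2, 2), frame_coords(traj, 2), tolerance = 1e-12)
  # single-model file read as trajectory equals read_structure coordinates
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f1)
  t1 <- read_trajectory(s, f1)
  expect_equal(n_frames(t1), 1)
  expect_equal(frame_coords(t1, 1), read_structure(f1)$xyz)
})

test_that("topology mismatch on trajectory read is a clear error", {
  s <- make_structure(rep("CA", 5), rep("C", 5), rep("ALA", 5), 1:5,
                      matrix(0, 5, 3))
  small <- make_structure(rep("CA", 4), rep("C", 4), rep("ALA", 4), 1:4,
                          matrix(0, 4, 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(make_trajectory(s, list(s$xyz)), f)
  expect_error(read_trajectory(small, f), "topology mismatch.*4.*5")
})

test_that("duplicate (chain, resnum, atom_name) triplets are rejected", {
  expect_error(
    make_structure(c("CA", "CA"), c("C", "C"), c("ALA", "ALA"), c(1, 1),
                   matrix(0:5, 2, 3)),
    "duplicate atom")
})

test_that("altloc conformers keep highest occupancy, ties by letter", {
  line <- function(serial, alt, occ, x) {
    sprintf("ATOM  %5d  CA %1sALA A   1    %8.3f   0.000   0.000%6.2f  0.00           C",
            serial, alt, x, occ)
  }
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(line(1, "A", 0.4, 1), line(2, "B", 0.6, 2), "END"), f)
  s <- read_structure(f)
  expect_equal(n_atoms(s), 1)
  expect_equal(s$xyz[1, 1], 0.2)  # the 0.6-occupancy B conformer
  writeLines(c(line(1, "B", 0.5, 1), line(2, "A", 0.5, 2), "END"), f)
  s <- read_structure(f)
  expect_equal(s$xyz[1, 1], 0.2)  # tie broken by altloc letter: A wins
})

test_that("region selection respects ranges, chains and heavy-only", {
  m <- build_toy_mechanomodule()
  s <- m$structure
  idx <- select_atoms(s, region_spec("naim", c(1238, 1271)))
  expect_true(all(s$atoms$resnum[idx] >= 1238 & s$atoms$resnum[idx] <= 1271))
  expect_true(all(s$atoms$element[idx] != "H"))
  # hydrogens included when heavy_only = FALSE
  idx_all <- select_atoms(s, region_spec("naim", c(1238, 1271),
                                         heavy_only = FALSE))
  expect_gt(length(idx_all), length(idx))
  expect_equal(sum(s$atoms$element[idx_all] == "H"),
               length(idx_all) - length(idx))
  # idempotent and order-stable
  expect_identical(idx, sort(idx))
  # union of disjoint specs equals the merged spec
  r1 <- region_spec("a", c(1238, 1250))
  r2 <- region_spec("b", c(1251, 1271))
  merged <- merge_regions("ab", r1, r2)
  expect_identical(sort(union(select_atoms(s, r1), select_atoms(s, r2))),
                   select_atoms(s, merged))
  # empty selection warns and returns empty
  expect_warning(idx0 <- select_atoms(s, region_spec("none", c(5000, 5001))),
                 "selects no atoms")
  expect_length(idx0, 0)
})

test_that("mechanomodule span covers 1110 residue positions", {
  expect_equal(region_n_residues(region_spec("span", c(764, 1873))), 1110)
  regs <- default_regions()
  expect_equal(region_n_residues(regs$mechanomodule), 1110)
  expect_equal(region_n_residues(regs$naim), 34)
  expect_equal(region_n_residues(regs$caim), 35)
})

test_that("glycan assignment follows the inclusive 0.5 nm rule", {
  s <- make_structure(c("CA", "C1", "C1"), c("C", "C", "C"),
                      c("ALA", "NAG", "NAG"), c(10, 2001, 2002),
                      rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.6, 0)))
  g1 <- glycan_annotation("near", c("A", 10), "N", 2)
  g2 <- glycan_annotation("far", c("A", 10), "O", 3)
  reg <- region_spec("r", c(10, 10))
  got <- assign_glycans_to_region(s, list(g1, g2), reg)
  expect_identical(got, "near")
  # boundary inclusive
  s$xyz[3, ] <- c(0, 0.5, 0)
  got <- assign_glycans_to_region(s, list(g1, g2), reg)
  expect_identical(got, c("near", "far"))
})

test_that("glycan assignment matches the brute-force distance oracle", {
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 8, seed = 11))
  s <- m$structure
  heavy <- which(s$atoms$element != "H")
  for (fr in c(1, 5, 8)) {
    x <- frame_coords(sim$trajectory, fr)
    for (rg_name in c("naim", "caim", "d_d3")) {
      rg <- m$regions[[rg_name]]
      got <- assign_glycans_to_region(s, m$glycans, rg, coords = x)
      ridx <- intersect(select_atoms(s, rg, quiet = TRUE), heavy)
      exp_ids <- Filter(function(id) {
        g <- m$glycans[[which(vapply(m$glycans, `[[`, "", "glycan_id") == id)]]
        gi <- match(g$atom_serials, s$atoms$serial)
        oracle_min_dist(x[gi, , drop = FALSE], x[ridx, , drop = FALSE]) <= 0.5
      }, vapply(m$glycans, `[[`, "", "glycan_id"))
      expect_identical(sort(got), sort(unlist(exp_ids)))
    }
  }
})

test_that("region config YAML round-trips", {
  m <- build_toy_mechanomodule()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_region_config(m$regions, m$glycans, f)
  cfg <- read_region_config(f)
  expect_setequal(names(cfg$regions), names(m$regions))
  expect_equal(cfg$regions$naim$ranges, m$regions$naim$ranges)
  expect_length(cfg$glycans, length(m$glycans))
  expect_equal(cfg$glycans[[1]]$atom_serials, m$glycans[[1]]$atom_serials)
})
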