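# superposition and structural descriptors

test_that("Kabsch superposition handles identity, rigid motions and errors", {
  set.seed(42)
  x <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation about z plus translation recovers exactly
  y <- sweep(x %*% rot_z(90), 2, c(1, 2, 3), "+")
  sp <- kabsch_superpose(x, y)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_superposition(sp, x), y, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "degenerate")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD agrees with the quaternion oracle on perturbed sets", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tgt <- pts
  tgt[4, ] <- tgt[4, ] + c(0, 0, 0.04)
  sp <- kabsch_superpose(pts, tgt)
  expect_equal(sp$rmsd, oracle_rmsd_quaternion(pts, tgt), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- sweep(a %*% rot_z(33 * i), 2, rnorm(3), "+") +
      matrix(rnorm(24, sd = 0.05), 8, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_rmsd_quaternion(a, b),
                 tolerance = 1e-9)
    # invariance under rigid pre-transform of the mobile set
    a2 <- sweep(a %*% rot_z(120), 2, c(5, -2, 1), "+")
    expect_equal(kabsch_superpose(a2, b)$rmsd,
                 kabsch_superpose(a, b)$rmsd, tolerance = 1e-9)
    # agreement with bio3d's least-squares fit as a second external check
    fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(b)),
                                              as.vector(t(a))))
    b3 <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
    expect_equal(kabsch_superpose(a, b)$rmsd, b3, tolerance = 1e-9)
  }
})

test_that("RMSD series is zero for rigid motions and matches brute force", {
  s <- make_structure(rep("CA", 6), rep("C", 6), rep("ALA", 6), 1:6,
                      matrix(rnorm(18), 6, 3))
  frames <- list(s$xyz,
                 sweep(s$xyz %*% rot_z(45), 2, c(1, 0, 0), "+"),
                 sweep(s$xyz %*% rot_z(170), 2, c(0, 2, -1), "+"))
  traj <- make_trajectory(s, frames)
  out <- rmsd_series(traj)
  expect_equal(out$value, rep(0, 3), tolerance = 1e-9)
  # one-frame trajectory equal to the reference gives [0]
  t1 <- make_trajectory(s, list(s$xyz))
  expect_equal(rmsd_series(t1)$value, 0, tolerance = 1e-12)
  # synthetic uncoiling frames match a direct-formula oracle
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 10, seed = 5))
  out <- rmsd_series(sim$trajectory)
  top <- sim$trajectory$topology
  ca <- which(top$atoms$atom_name %in% c("N", "CA", "C", "O") &
                top$atoms$element != "H")
  ref <- frame_coords(sim$trajectory, 1)[ca, ]
  for (fr in c(2, 6, 10)) {
    x <- frame_coords(sim$trajectory, fr)[ca, ]
    # oracle: quaternion optimal RMSD over the same selection, to 1e-9 nm
    expect_lt(abs(out$value[fr] - oracle_rmsd_quaternion(x, ref)), 1e-9)
  }
})

test_that("RMSF recovers closed-form amplitudes and arm/core contrast", {
  # residue 1 alternates +/- d along x; fitting on the fixed residues
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1))
  s <- make_structure(rep("CA", 6), rep("C", 6), rep("ALA", 6), 1:6, base)
  d <- 0.3
  up <- base; up[1, 1] <- up[1, 1] + d
  dn <- base; dn[1, 1] <- dn[1, 1] - d
  traj <- make_trajectory(s, list(up, dn, up, dn))
  out <- rmsf_per_residue(traj, fit_region = region_spec("fixed", c(2, 6)))
  expect_equal(out$rmsf[out$resnum == 1], d, tolerance = 1e-9)
  expect_equal(out$rmsf[out$resnum == 5], 0, tolerance = 1e-9)
  # static trajectory: all zeros
  st <- make_trajectory(s, list(base, base, base))
  expect_equal(rmsf_per_residue(st)$rmsf, rep(0, 6), tolerance = 1e-12)
  # arms fluctuate more than the restrained core in the free ensemble
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("free", n_frames = 40, seed = 2))
  rf <- rmsf_per_residue(sim$trajectory,
                         fit_region = region_spec("anchor", c(1290, 1430)))
  arm <- rf$rmsf[rf$resnum >= 1238 & rf$resnum <= 1271]
  core <- rf$rmsf[rf$resnum >= 1290 & rf$resnum <= 1430]
  expect_gt(min(arm), max(core))
})

test_that("radius of gyration matches closed forms and the oracle", {
  expect_equal(radius_of_gyration(matrix(c(5, 5, 5), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(radius_of_gyration(cube), sqrt(0.75), tolerance = 1e-12)
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "zero total mass")
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  w <- runif(20, 1, 16)
  expect_equal(radius_of_gyration(x, w), oracle_rg(x, w), tolerance = 1e-12)
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 6, seed = 9))
  rg <- rg_series(sim$trajectory)
  top <- sim$trajectory$topology
  heavy <- which(top$atoms$element != "H")
  for (fr in c(1, 6)) {
    x <- frame_coords(sim$trajectory, fr)[heavy, ]
    expect_equal(rg$value[fr],
                 oracle_rg(x, element_masses(top$atoms$element[heavy])),
                 tolerance = 1e-9)
  }
})

test_that("Shrake-Rupley SASA matches sphere closed forms", {
  # isolated carbon: 4*pi*(0.17 + 0.14)^2
  one <- sasa_shrake_rupley(matrix(0, 1, 3), "C")
  expect_equal(one$total, 4 * pi * 0.31^2, tolerance = 0.01 * 4 * pi * 0.31^2)
  # far-apart atoms are additive
  two <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "N"))
  iso <- 4 * pi * (c(0.17, 0.155) + 0.14)^2
  expect_equal(two$per_atom, iso, tolerance = 0.02 * max(iso))
  expect_equal(two$total, sum(two$per_atom))
  # an atom caged by a tight shell is fully buried
  shell <- .sphere_points_for_test(60) * 0.25
  caged <- sasa_shrake_rupley(rbind(c(0, 0, 0), shell),
                              rep("C", 61))
  expect_lt(caged$per_atom[1], 1e-6)
  # quadrature refines toward the analytic sphere area
  err <- vapply(c(60, 240, 960), function(np) {
    abs(sasa_shrake_rupley(matrix(0, 1, 3), "C", n_points = np)$total -
          4 * pi * 0.31^2)
  }, 0)
  expect_lt(err[3], err[1] + 1e-9)
  expect_error(sasa_shrake_rupley(matrix(0, 1, 3), "XX", default_radius = NA),
               "XX")
})

test_that("window statistics follow the half-open convention", {
  s <- data.frame(time_ns = c(0, 1, 2, 3), value = c(1, 2, 3, 4))
  w <- analysis_window("w", 0, 2)
  st <- window_stats(s, w)
  expect_equal(st$mean, 1.5)
  expect_equal(st$n_frames, 2)
  cst <- window_stats(data.frame(time_ns = 0:9, value = rep(7, 10)),
                      analysis_window("c", 0, 10))
  expect_equal(cst$mean, 7)
  expect_equal(cst$sd, 0)
  expect_error(window_stats(s, analysis_window("z", 10, 20)), "no frames")
  # translation equivariance of window means
  s2 <- s; s2$value <- s2$value + 11
  expect_equal(window_stats(s2, w)$mean, st$mean + 11)
  expect_error(analysis_window("bad", 5, 5))
})

test_that("probability densities integrate to one", {
  set.seed(1)
  x <- rnorm(1e5)
  d <- probability_density(x, "gaussian_kde")
  integral <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_lt(abs(d$x[which.max(d$density)]), 0.1)
  h <- probability_density(rep(3, 10), "histogram", n_bins = 4)
  expect_equal(sum(h$density > 0), 1)
  h2 <- probability_density(c(0, 1), "histogram", n_bins = 2)
  expect_equal(h2$density, c(1, 1))  # each bin holds mass 0.5 over width 0.5
})

test_that("Savitzky-Golay smoothing reproduces polynomials and denoises", {
  expect_equal(savgol_smooth(rep(4, 100), 21, 3), rep(4, 100),
               tolerance = 1e-9)
  t <- seq(0, 1, length.out = 101)
  cubic <- 2 - t + 3 * t^2 - 0.5 * t^3
  expect_equal(savgol_smooth(cubic, 31, 3), cubic, tolerance = 1e-9)
  set.seed(5)
  clean <- sin(2 * pi * t)
  noisy <- clean + rnorm(101, sd = 0.2)
  sm <- savgol_smooth(noisy, 31, 3)
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
  expect_error(savgol_smooth(1:10, 4, 3), "odd")
  expect_error(savgol_smooth(1:10, 11, 3), "length")
  expect_equal(clamp_savgol_window(10, 51, 3), 9)
  expect_true(is.na(clamp_savgol_window(3, 51, 3)))
})
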