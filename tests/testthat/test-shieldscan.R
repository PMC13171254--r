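# steric-clash scoring against the superposed receptor reference

test_that("clash counting is strict, symmetric and cutoff-monotone", {
  a <- rbind(c(0, 0, 0), c(5, 0, 0))
  b <- rbind(c(0.25, 0, 0))
  expect_equal(count_clashes(a, b), 1L)
  # exactly 0.30 nm is NOT a clash (strict inequality)
  expect_equal(count_clashes(matrix(0, 1, 3), matrix(c(0.30, 0, 0), 1, 3)), 0L)
  expect_equal(count_clashes(matrix(0, 1, 3), matrix(c(0.30, 0, 0), 1, 3),
                             inclusive = TRUE), 1L)
  # symmetry and empty sets
  expect_equal(count_clashes(a, b), count_clashes(b, a))
  expect_equal(count_clashes(matrix(0, 0, 3), b), 0L)
  # an atom farther than cutoff from everything never changes the count
  expect_equal(count_clashes(rbind(a, c(99, 99, 99)), b), count_clashes(a, b))
  # counts are non-decreasing in the cutoff
  set.seed(8)
  x <- matrix(rnorm(60, sd = 0.3), 20, 3)
  y <- matrix(rnorm(30, sd = 0.3), 10, 3)
  cuts <- c(0.1, 0.2, 0.3, 0.5, 1)
  counts <- vapply(cuts, function(ct) count_clashes(x, y, ct), 0L)
  expect_true(all(diff(counts) >= 0))
  # brute-force parity on random sets
  expect_equal(count_clashes(x, y, 0.4), oracle_count_clashes(x, y, 0.4))
})

test_that("clash_scan reproduces planted per-region counts on frame 0", {
  m <- build_toy_mechanomodule()
  traj <- make_trajectory(m$structure, list(m$structure$xyz), dt_ns = 0.1)
  cfg <- clash_config(shield_regions = m$regions[c("d_d3", "nfp", "naim",
                                                   "naim_proximal", "caim")],
                      smooth_window = NA)
  cs <- clash_scan(traj, m$reference, cfg, m$glycans)
  probes <- m$planted$probes
  planted <- function(seg) sum(probes$segment == seg & probes$dist < 0.30)
  expect_equal(unname(cs$per_region[1, "d_d3"]), planted("d_d3"))
  expect_equal(unname(cs$per_region[1, "nfp"]), planted("nfp"))
  expect_equal(unname(cs$per_region[1, "caim"]), planted("caim"))
  expect_equal(unname(cs$per_region[1, "naim_proximal"]), planted("naim_proximal"))
  # naim spans nfp plus proximal
  expect_equal(unname(cs$per_region[1, "naim"]),
               planted("nfp") + planted("naim_proximal"))
  # mid-band (0.30-0.50) and far probes contribute nothing
  expect_gt(sum(probes$dist >= 0.30), 0)
  expect_equal(cs$total[1], sum(cs$per_region[1, ]))
  expect_equal(cs$align_rmsd[1], 0, tolerance = 1e-9)
})

test_that("requested planted clash counts are honoured by the builder", {
  m2 <- build_toy_mechanomodule(n_clash = c(d_d3 = 3, nfp = 5,
                                            naim_proximal = 1, caim = 2))
  traj <- make_trajectory(m2$structure, list(m2$structure$xyz))
  cfg <- clash_config(shield_regions = m2$regions[c("nfp", "naim_proximal",
                                                    "caim")])
  cs <- clash_scan(traj, m2$reference, cfg, list())  # without glycans
  expect_equal(as.integer(cs$per_region[1, ]), c(5L, 1L, 2L))
  expect_error(build_toy_mechanomodule(n_clash = c(d_d3 = 3, nfp = 50,
                                                   naim_proximal = 1,
                                                   caim = 2)),
               "infeasible")
})

test_that("clash totals are invariant under global rigid motion of the frame", {
  m <- build_toy_mechanomodule()
  x2 <- sweep(m$structure$xyz %*% rot_z(63), 2, c(2, 1, -3), "+")
  traj <- make_trajectory(m$structure, list(m$structure$xyz, x2))
  cfg <- clash_config(shield_regions = m$regions[c("naim", "caim")])
  cs <- clash_scan(traj, m$reference, cfg, m$glycans)
  expect_equal(cs$per_region[2, ], cs$per_region[1, ])
})

test_that("retracted arms score zero and scans match the end-to-end oracle", {
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 30, seed = 13))
  cfg <- clash_config(shield_regions = m$regions[c("naim", "caim")],
                      smooth_window = NA)
  cs <- clash_scan(sim$trajectory, m$reference, cfg, m$glycans)
  expect_equal(unname(cs$per_region[, "naim"]),
               unname(sim$log$clash_counts[, "naim"]))
  expect_equal(unname(cs$per_region[, "caim"]),
               unname(sim$log$clash_counts[, "caim"]))
  # late flow frames: fully retracted C-terminal arm scores zero
  late <- simulate_uncoiling(m, sim_config("flow", n_frames = 160, seed = 13))
  cs2 <- clash_scan(late$trajectory, m$reference, cfg, m$glycans)
  expect_equal(max(cs2$per_region[150:160, "caim"]), 0)
})

test_that("alignment floor and missing regions raise clear errors", {
  m <- build_toy_mechanomodule()
  traj <- make_trajectory(m$structure, list(m$structure$xyz))
  cfg <- clash_config(align_region = region_spec("bad", c(4000, 4100)),
                      shield_regions = m$regions["naim"])
  expect_error(clash_scan(traj, m$reference, cfg), "alignment region")
  cfg2 <- clash_config(min_matched_atoms = 1e5,
                       shield_regions = m$regions["naim"])
  expect_error(clash_scan(traj, m$reference, cfg2), "matched anchor atoms")
})

test_that("normalisation maps counts to [0,1] and keeps zero regions zero", {
  fake <- structure(list(per_region = cbind(a = c(0, 2, 4), b = c(0, 0, 0)),
                         total = c(0, 2, 4), times = 0:2),
                    class = "clash_series")
  nc <- normalized_clash(fake)
  expect_equal(unname(nc$per_region[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nc$per_region[, "b"]), c(0, 0, 0))
  expect_equal(unname(nc$means), c(0.5, 0))
  fake$per_region[1, "a"] <- 2
  ni <- normalized_clash(fake, "initial")
  expect_equal(unname(ni$per_region[, "a"]), c(1, 1, 2))
})

test_that("construct comparison is monotone under added shielding regions", {
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 40, seed = 17))
  p_small <- construct_preset("small", m$regions["caim"])
  p_big <- construct_preset("big", m$regions[c("caim", "naim")])
  out <- construct_compare(sim$trajectory, m$reference,
                           list(p_small, p_big), clash_config(), m$glycans)
  expect_gt(out$mean_normalized[out$construct == "big"],
            out$mean_normalized[out$construct == "small"])
  # empty preset regions mean full accessibility
  p_empty <- construct_preset("empty",
                              list(region_spec("gap", c(1900, 1950))))
  out2 <- suppressWarnings(
    construct_compare(sim$trajectory, m$reference, list(p_empty, p_big),
                      clash_config(), m$glycans))
  expect_equal(out2$mean_normalized[out2$construct == "empty"], 0)
})

test_that("construct ranking recovers the planted shielding order", {
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 200, seed = 29))
  cc <- construct_compare(sim$trajectory, m$reference,
                          default_construct_presets(), clash_config(),
                          m$glycans)
  expect_equal(cc$construct[order(cc$rank)], sim$log$construct_order)
  expect_equal(sim$log$construct_order[1], "dPro")
})
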