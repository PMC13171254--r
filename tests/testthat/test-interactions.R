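# hydrogen-bond and salt-bridge geometric criteria

hb_toy <- function(acceptor_xyz) {
  make_structure(c("N", "H1", "O"), c("N", "H", "O"),
                 c("ALA", "ALA", "ALA"), c(1, 1, 5),
                 rbind(c(0, 0, 0), c(0.1, 0, 0), acceptor_xyz))
}

test_that("hydrogen bonds require both the 0.35 nm and 150 degree criteria", {
  g_a <- region_spec("a", c(1, 1))
  g_b <- region_spec("b", c(5, 5))
  # collinear donor-H-acceptor at 0.29 nm: one bond
  rec <- detect_hbonds(hb_toy(c(0.29, 0, 0)), g_a, g_b)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$angle, 180)
  expect_false(rec$approximate)
  # acceptor at 0.36 nm: distance fails
  expect_equal(nrow(detect_hbonds(hb_toy(c(0.36, 0, 0)), g_a, g_b)), 0)
  # boundary: exactly 0.35 nm is inclusive
  expect_equal(nrow(detect_hbonds(hb_toy(c(0.35, 0, 0)), g_a, g_b)), 1)
  # acceptor placed by trigonometry for a target D-H-A angle at 0.30 nm
  place <- function(theta_deg) {
    f <- function(phi) {
      a <- 0.30 * c(cos(phi), sin(phi), 0)
      h <- c(0.1, 0, 0)
      v1 <- -h - (a - h) * 0  # placeholder to keep expressions clear
      v1 <- c(0, 0, 0) - h
      v2 <- a - h
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi - theta_deg
    }
    phi <- uniroot(f, c(1e-6, pi - 1e-6))$root
    0.30 * c(cos(phi), sin(phi), 0)
  }
  a140 <- place(140)
  expect_equal(nrow(detect_hbonds(hb_toy(a140), g_a, g_b)), 0)
  a151 <- place(151)
  rec <- detect_hbonds(hb_toy(a151), g_a, g_b)
  expect_equal(nrow(rec), 1)
  expect_gte(rec$angle, 150)
})

test_that("hydrogen-stripped structures fall back to the flagged donor-antecedent angle", {
  s <- make_structure(c("CA", "N", "O"), c("C", "N", "O"),
                      c("ALA", "ALA", "ALA"), c(1, 1, 5),
                      rbind(c(-0.11, 0, 0), c(0, 0, 0), c(0.30, 0, 0)))
  rec <- detect_hbonds(s, region_spec("a", c(1, 1)), region_spec("b", c(5, 5)))
  expect_equal(nrow(rec), 1)
  expect_true(rec$approximate)
  expect_equal(rec$angle, 180)
})

test_that("salt bridges use the inclusive 0.35 nm cutoff on charged atom pairs", {
  sb_toy <- function(d, cat_res = "LYS", cat_atom = "NZ",
                     ani_res = "GLU", ani_atom = "OE1") {
    make_structure(c(cat_atom, ani_atom), c("N", "O"),
                   c(cat_res, ani_res), c(1, 5),
                   rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  g_a <- region_spec("a", c(1, 1))
  g_b <- region_spec("b", c(5, 5))
  expect_equal(nrow(detect_salt_bridges(sb_toy(0.34), g_a, g_b)), 1)
  # boundary inclusive
  expect_equal(nrow(detect_salt_bridges(sb_toy(0.35, "ARG", "NH1",
                                               "ASP", "OD2"), g_a, g_b)), 1)
  expect_equal(nrow(detect_salt_bridges(sb_toy(0.351), g_a, g_b)), 0)
  # non-charged residue names never qualify
  expect_equal(nrow(detect_salt_bridges(sb_toy(0.2, "SER", "NZ"),
                                        g_a, g_b)), 0)
})

test_that("detectors agree with brute-force oracles on planted frames", {
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 12, seed = 21))
  s <- m$structure
  arm_res <- c(1238:1271, 1459:1493)
  core_res <- 1272:1458
  arms <- merge_regions("aim", m$regions$naim, m$regions$caim)
  for (fr in c(1, 7, 12)) {
    x <- frame_coords(sim$trajectory, fr)
    hb <- detect_hbonds(s, arms, m$regions$a1_core, coords = x)
    ohb <- oracle_hbonds(s, x, arm_res, core_res)
    expect_equal(nrow(hb), nrow(ohb))
    expect_setequal(paste(hb$resnum_a, hb$resnum_b),
                    paste(ohb[, "don"], ohb[, "acc"]))
    sb <- detect_salt_bridges(s, arms, m$regions$a1_core, coords = x)
    osb <- oracle_salt_bridges(s, x)
    expect_equal(nrow(sb), nrow(osb))
  }
})

test_that("detector output is invariant under global rigid transforms", {
  m <- build_toy_mechanomodule()
  s <- m$structure
  arms <- merge_regions("aim", m$regions$naim, m$regions$caim)
  base_hb <- detect_hbonds(s, arms, m$regions$a1_core)
  base_sb <- detect_salt_bridges(s, arms, m$regions$a1_core)
  x2 <- sweep(s$xyz %*% rot_z(77), 2, c(3, -4, 5), "+")
  hb2 <- detect_hbonds(s, arms, m$regions$a1_core, coords = x2)
  sb2 <- detect_salt_bridges(s, arms, m$regions$a1_core, coords = x2)
  expect_equal(nrow(hb2), nrow(base_hb))
  expect_equal(nrow(sb2), nrow(base_sb))
  expect_equal(sort(hb2$distance), sort(base_hb$distance), tolerance = 1e-9)
})

test_that("planted contacts are recovered exactly and decoys rejected", {
  m <- build_toy_mechanomodule()
  s <- m$structure
  arms <- merge_regions("aim", m$regions$naim, m$regions$caim)
  hb <- detect_hbonds(s, arms, m$regions$a1_core)
  expect_setequal(paste(hb$resnum_a, hb$resnum_b),
                  paste(m$planted$hb$don_res, m$planted$hb$acc_res))
  sb <- detect_salt_bridges(s, arms, m$regions$a1_core)
  planted_sb <- m$planted$sb[m$planted$sb$dist <= 0.35, ]
  expect_setequal(paste(sb$resnum_a, sb$resnum_b),
                  paste(planted_sb$cat_res, planted_sb$ani_res))
  # decoy residues never appear
  decoys <- c(m$planted$plant$hb_dist_decoy, m$planted$plant$hb_angle_decoy,
              m$planted$plant$sb_decoy)
  expect_false(any(hb$resnum_a %in% decoys))
  expect_false(any(sb$resnum_a %in% decoys))
  # hydrogen-stripped variant recovers the same bonds via the approximation
  s2 <- strip_hydrogens(s)
  hb2 <- detect_hbonds(s2, arms, m$regions$a1_core)
  expect_true(all(hb2$approximate))
  expect_true(all(paste(hb$resnum_a, hb$resnum_b) %in%
                    paste(hb2$resnum_a, hb2$resnum_b)))
})

test_that("intramolecular counting excludes near-sequence neighbours", {
  s <- make_structure(c("N", "H1", "O", "O"), c("N", "H", "O", "O"),
                      rep("ALA", 4), c(1, 1, 2, 5),
                      rbind(c(0, 0, 0), c(0.1, 0, 0),
                            c(0.29, 0, 0), c(0.29, 0.001, 0)))
  whole <- seq_len(4)
  rec <- detect_hbonds(s, whole, whole, min_residue_separation = 2)
  # the residue-2 acceptor is excluded (|1 - 2| < 2), residue 5 retained
  expect_equal(nrow(rec), 1)
  expect_equal(rec$resnum_b, 5)
})

test_that("replicate concatenation reindexes frames with provenance", {
  m <- build_toy_mechanomodule()
  reps <- lapply(1:3, function(sd) {
    simulate_uncoiling(m, sim_config("flow", n_frames = 10, seed = sd))
  })
  arms <- merge_regions("aim", m$regions$naim, m$regions$caim)
  recs <- lapply(reps, function(r) {
    collect_contacts(r$trajectory, arms, m$regions$a1_core)
  })
  comb <- concatenate_replicates(recs, c(10, 10, 10))
  expect_equal(comb$n_frames_total, 30)
  expect_setequal(unique(comb$records$replicate), 1:3)
  expect_true(all(comb$records$frame[comb$records$replicate == 2] > 10))
  expect_true(all(comb$records$frame <= 30))
  # single replicate is the identity
  one <- concatenate_replicates(recs[1], 10)
  expect_equal(one$records$frame, recs[[1]]$frame)
  # presence counting across replicates: planted pairs present everywhere
  expect_equal(nrow(comb$records),
               sum(vapply(recs, nrow, 0L)))
})

test_that("contact frequencies apply the inclusive 10 percent filter", {
  rec_at <- function(frames) {
    data.frame(kind = "HB", chain_a = "A", resnum_a = 1L, resname_a = "ALA",
               atom_a = "N", chain_b = "A", resnum_b = 9L, resname_b = "ALA",
               atom_b = "O", distance = 0.3, angle = 170,
               approximate = FALSE, frame = frames, time_ns = frames)
  }
  fm <- contact_frequency_map(rec_at(c(2, 5, 7)), 10)
  expect_equal(fm$frequency, 0.30)
  expect_equal(fm$n_frames, 3L)
  # 1 of 20 frames = 0.05: filtered out
  expect_equal(nrow(contact_frequency_map(rec_at(4), 20)), 0)
  # exactly 10 percent retained (boundary inclusive)
  expect_equal(nrow(contact_frequency_map(rec_at(c(1, 2)), 20)), 1)
  # duplicate atom pairs within one frame count once at residue level
  fm <- contact_frequency_map(rbind(rec_at(1), rec_at(1)), 10)
  expect_equal(fm$n_frames, 1L)
  # matrix export is symmetric with sorted residue labels
  mtx <- frequency_matrix(contact_frequency_map(rec_at(1:5), 10))
  expect_equal(rownames(mtx), c("ALA1", "ALA9"))
  expect_equal(mtx["ALA1", "ALA9"], 0.5)
  expect_equal(mtx, t(mtx))
})

test_that("interaction time series count planted contacts per frame", {
  m <- build_toy_mechanomodule()
  sim <- simulate_uncoiling(m, sim_config("flow", n_frames = 15, seed = 4))
  arms <- merge_regions("aim", m$regions$naim, m$regions$caim)
  ts <- interaction_timeseries(sim$trajectory, arms, m$regions$a1_core)
  truth <- sim$log$contacts
  for (fr in seq_len(15)) {
    expect_equal(ts$hb[fr], sum(truth$frame == fr & truth$kind == "HB"))
    expect_equal(ts$sb[fr], sum(truth$frame == fr & truth$kind == "SB"))
  }
  # empty groups give an all-zero series
  ts0 <- interaction_timeseries(sim$trajectory,
                                region_spec("d", c(764, 823)),
                                region_spec("rec", c(900, 950)))
  expect_equal(ts0$total, rep(0L, 15))
  # averaging identical replicates gives zero sd
  avg <- average_series(list(ts, ts, ts), "total")
  expect_equal(avg$mean, as.numeric(ts$total))
  expect_equal(avg$sd, rep(0, 15))
})
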