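#' Coarse-grained synthetic mechanomodule and uncoiling simulator
#'
#' A desk-scale bead model standing in for an atomistic mechanomodule: a
#' static core ("A1", residues 1272-1458, with the 1290-1430 alignment
#' anchor), two autoinhibitory arms (1238-1271 and 1459-1493), a restrained
#' D'D3 stub (764-823), glycan pseudo-atoms on arm residues, and a
#' pseudo-receptor reference (residues 1-265) whose probe atoms are planted
#' at known distances (below, inside and beyond the clash and glycan
#' cutoffs) from arm and glycan atoms. Planted donor-hydrogen-acceptor
#' triplets and cation-anion pairs exercise the hydrogen-bond and
#' salt-bridge detectors, including near-miss decoys that fail exactly one
#' criterion. The simulator performs seeded overdamped updates in which arm
#' beads are harmonically tethered to targets that switch from docked to
#' retracted positions on a schedule (flow mode) or when the pulling spring
#' force crosses a planted threshold (steered mode), and logs complete
#' per-frame ground truth measured by direct arithmetic over all candidate
#' pairs. It is an analysis test-bed, not a physical MD engine: drag, noise
#' and stiffness are dimensionless knobs tuned only so the detectors'
#' geometric thresholds are meaningfully exercised.
#'
#' @name synthetic
NULL

.toy_const <- list(
  z_arm = 0.15, z_rec = -1.2, bead_gap = 0.6,
  x_naim = -1.2, x_caim = 1.2, x_dd3 = -2.4,
  clash_d = 0.25, mid_d = 0.40, far_d = 0.60,
  hb_d = 0.29, hb_h = 0.10, sb_d = 0.30, side_lift = 0.11,
  gly_near = 0.35, gly_far = 0.65
)

# solve acceptor direction giving a requested donor-hydrogen-acceptor angle
.hb_decoy_direction <- function(target_angle, dist, h_len) {
  f <- function(psi) {
    o <- dist * c(sin(psi), 0, cos(psi))
    h <- c(0, 0, h_len)
    v1 <- -h
    v2 <- o - h
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    ang - target_angle
  }
  psi <- stats::uniroot(f, c(1e-6, pi - 1e-6))$root
  c(sin(psi), 0, cos(psi))
}

#' Build the toy mechanomodule and its receptor reference
#'
#' Deterministic given `seed`: same seed, bit-identical structures.
#'
#' @param seed integer seed (layout jitter of planted schedules lives in
#'   [simulate_uncoiling()]; the builder itself is deterministic and the
#'   seed is recorded for provenance).
#' @param n_clash planted sub-cutoff receptor pairs per segment
#'   (`d_d3`, `nfp`, `naim_proximal`, `caim`).
#' @param n_hbond planted hydrogen-bond sites per arm (`naim`, `caim`).
#' @param n_saltbridge planted salt-bridge sites per arm.
#' @return a `toy_mechanomodule`: list with `structure`, `reference`,
#'   `glycans`, `regions`, `beads`, `offsets`, `h_owner`, `planted`,
#'   `seed`.
#' @export
build_toy_mechanomodule <- function(seed = 1,
                                    n_clash = c(d_d3 = 6, nfp = 4,
                                                naim_proximal = 2, caim = 3),
                                    n_hbond = c(naim = 6, caim = 4),
                                    n_saltbridge = c(naim = 4, caim = 2)) {
  k <- .toy_const
  if (n_clash[["nfp"]] > 6 || n_clash[["naim_proximal"]] > 2 ||
      n_clash[["caim"]] > 8 || n_hbond[["naim"]] > 6 ||
      n_hbond[["caim"]] > 7 || n_saltbridge[["naim"]] > 4 ||
      n_saltbridge[["caim"]] > 4 || n_clash[["d_d3"]] > 15) {
    stop("infeasible geometry request: planted counts exceed the toy layout")
  }
  lane <- function(n, x) {
    y <- (seq_len(n) - (n + 1) / 2) * k$bead_gap
    cbind(x, y, k$z_arm)
  }
  beads <- list()
  add_bead <- function(resnum, pos, segment, arm) {
    beads[[length(beads) + 1]] <<- data.frame(
      resnum = resnum, x = pos[1], y = pos[2], z = pos[3],
      segment = segment, arm = arm, stringsAsFactors = FALSE)
  }
  dd3_res <- 764:823
  dd3_pos <- lane(length(dd3_res), k$x_dd3)
  for (i in seq_along(dd3_res)) add_bead(dd3_res[i], dd3_pos[i, ], "d_d3", "d_d3")
  naim_res <- 1238:1271
  naim_pos <- lane(length(naim_res), k$x_naim)
  for (i in seq_along(naim_res)) {
    seg <- if (naim_res[i] <= 1267) "nfp" else "naim_proximal"
    add_bead(naim_res[i], naim_pos[i, ], seg, "naim")
  }
  core_res <- 1272:1458
  nc <- length(core_res)
  th <- (seq_len(nc) - 1) * 0.6
  core_pos <- cbind(1.4 * cos(th), 1.4 * sin(th),
                    1.6 + 1.8 * (seq_len(nc) - 1) / (nc - 1))
  for (i in seq_len(nc)) add_bead(core_res[i], core_pos[i, ], "core", "core")
  caim_res <- 1459:1493
  caim_pos <- lane(length(caim_res), k$x_caim)
  for (i in seq_along(caim_res)) add_bead(caim_res[i], caim_pos[i, ], "caim", "caim")
  beads <- do.call(rbind, beads)
  rownames(beads) <- NULL
  bead_row <- function(res) which(beads$resnum == res)
  bead_pos <- function(res) unlist(beads[bead_row(res), c("x", "y", "z")])

  atoms <- list()
  offsets <- list()
  parent <- integer(0)
  add_atom <- function(res, name, element, resname, offset, het = FALSE) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      atom_name = name, element = element, resname = resname, resnum = res,
      chain = "A", het = het, stringsAsFactors = FALSE)
    offsets[[length(offsets) + 1]] <<- offset
    parent[length(parent) + 1] <<- bead_row(res)
  }
  resname_of <- new.env()
  set_resname <- function(res, nm) assign(as.character(res), nm, resname_of)
  get_resname <- function(res) {
    key <- as.character(res)
    if (exists(key, resname_of)) get(key, resname_of) else "ALA"
  }

  # planted feature residues: disjoint mod-4 classes per arm keep every
  # planted site on its own residue (no cross-talk between features)
  plant <- list(
    clash = list(d_d3 = seq(766, by = 4, length.out = n_clash[["d_d3"]]),
                 nfp = seq(1240, by = 4, length.out = n_clash[["nfp"]]),
                 naim_proximal = c(1268, 1270)[seq_len(n_clash[["naim_proximal"]])],
                 caim = seq(1460, by = 4, length.out = n_clash[["caim"]])),
    mid = c(1242, 1478), far = c(1246),
    hb = list(naim = seq(1241, by = 4, length.out = n_hbond[["naim"]]),
              caim = seq(1461, by = 4, length.out = n_hbond[["caim"]])),
    sb = list(naim = seq(1243, by = 4, length.out = n_saltbridge[["naim"]]),
              caim = seq(1463, by = 4, length.out = n_saltbridge[["caim"]])),
    hb_dist_decoy = 1254, hb_angle_decoy = 1258, sb_decoy = 1262
  )
  # acceptor hosts on the core, outside the 1290-1430 anchor
  acc_hosts_n <- 1272 + seq_len(n_hbond[["naim"]]) - 1
  anion_hosts_n <- 1280 + seq_len(n_saltbridge[["naim"]]) - 1
  decoy_hosts <- c(dist = 1285, angle = 1286, sb = 1287)
  acc_hosts_c <- 1431 + seq_len(n_hbond[["caim"]]) - 1
  anion_hosts_c <- 1440 + seq_len(n_saltbridge[["caim"]]) - 1
  for (r in c(anion_hosts_n, anion_hosts_c, decoy_hosts[["sb"]])) set_resname(r, "GLU")
  for (r in c(plant$sb$naim, plant$sb$caim, plant$sb_decoy)) set_resname(r, "LYS")

  # protein atoms in residue order: CA first, then planted side atoms
  up <- c(0, 0, 1)
  hb_pairs <- list()
  sb_pairs <- list()
  all_res <- sort(beads$resnum)
  side_of <- list()  # res -> list of (name, element, resname_override, offset)
  add_side <- function(res, name, element, offset) {
    key <- as.character(res)
    side_of[[key]] <<- c(side_of[[key]], list(list(name = name,
                                                   element = element,
                                                   offset = offset)))
  }
  hb_site <- function(don_res, acc_res) {
    p <- bead_pos(don_res)
    nq <- c(0, 0, k$side_lift)
    add_side(don_res, "N", "N", nq)
    add_side(don_res, "H1", "H", nq + k$hb_h * up)
    o_abs <- p + nq + k$hb_d * up
    add_side(acc_res, "O", "O", o_abs - bead_pos(acc_res))
    hb_pairs[[length(hb_pairs) + 1]] <<- data.frame(
      don_res = don_res, acc_res = acc_res)
  }
  sb_site <- function(cat_res, ani_res, dist) {
    p <- bead_pos(cat_res)
    nq <- c(0, 0, k$side_lift)
    add_side(cat_res, "NZ", "N", nq)
    o_abs <- p + nq + dist * up
    add_side(ani_res, "OE1", "O", o_abs - bead_pos(ani_res))
    sb_pairs[[length(sb_pairs) + 1]] <<- data.frame(
      cat_res = cat_res, ani_res = ani_res, dist = dist)
  }
  for (i in seq_len(n_hbond[["naim"]])) hb_site(plant$hb$naim[i], acc_hosts_n[i])
  for (i in seq_len(n_hbond[["caim"]])) hb_site(plant$hb$caim[i], acc_hosts_c[i])
  for (i in seq_len(n_saltbridge[["naim"]])) sb_site(plant$sb$naim[i], anion_hosts_n[i], k$sb_d)
  for (i in seq_len(n_saltbridge[["caim"]])) sb_site(plant$sb$caim[i], anion_hosts_c[i], k$sb_d)
  # decoys: distance fail (0.40 nm), angle fail (140 deg at 0.30 nm),
  # salt-bridge distance fail (0.40 nm)
  {
    p <- bead_pos(plant$hb_dist_decoy)
    nq <- c(0, 0, k$side_lift)
    add_side(plant$hb_dist_decoy, "N", "N", nq)
    add_side(plant$hb_dist_decoy, "H1", "H", nq + k$hb_h * up)
    add_side(decoy_hosts[["dist"]], "O", "O",
             p + nq + 0.40 * up - bead_pos(decoy_hosts[["dist"]]))
    p <- bead_pos(plant$hb_angle_decoy)
    add_side(plant$hb_angle_decoy, "N", "N", nq)
    add_side(plant$hb_angle_decoy, "H1", "H", nq + k$hb_h * up)
    dirv <- .hb_decoy_direction(140, 0.30, k$hb_h)
    add_side(decoy_hosts[["angle"]], "O", "O",
             p + nq + 0.30 * dirv - bead_pos(decoy_hosts[["angle"]]))
    sb_site(plant$sb_decoy, decoy_hosts[["sb"]], 0.40)
  }
  for (res in all_res) {
    add_atom(res, "CA", "C", get_resname(res), c(0, 0, 0))
    for (s in side_of[[as.character(res)]]) {
      add_atom(res, s$name, s$element, get_resname(res), s$offset)
    }
  }
  # glycan pseudo-atoms (residue numbers outside the protein span)
  gly_specs <- list(
    list(id = "glyN1", link = "N", res = 1250, off = c(k$gly_near, 0, 0)),
    list(id = "glyN2", link = "N", res = 770, off = c(k$gly_near, 0, 0)),
    list(id = "glyO1", link = "O", res = 1269, off = c(k$gly_near, 0, 0)),
    list(id = "glyO2", link = "O", res = 1470, off = c(-k$gly_near, 0, 0)),
    list(id = "glyO3", link = "O", res = 1490, off = c(0, 0, k$gly_far))
  )
  gly_resnum <- 2000
  gly_atoms <- list()
  for (g in gly_specs) {
    gly_resnum <- gly_resnum + 1
    atoms[[length(atoms) + 1]] <- data.frame(
      atom_name = "C1", element = "C", resname = "NAG", resnum = gly_resnum,
      chain = "A", het = TRUE, stringsAsFactors = FALSE)
    offsets[[length(offsets) + 1]] <- g$off
    parent[length(parent) + 1] <- bead_row(g$res)
    gly_atoms[[g$id]] <- list(link = g$link, res = g$res,
                              atom_index = length(atoms))
  }
  atoms <- do.call(rbind, atoms)
  atoms$serial <- seq_len(nrow(atoms))
  offsets <- do.call(rbind, offsets)
  # quantise to PDB precision (1e-4 nm) so fixtures round-trip exactly
  xyz <- round(as.matrix(beads[parent, c("x", "y", "z")]) + offsets, 4)
  structure_ <- new_structure(
    atoms[, c("serial", "atom_name", "element", "resname", "resnum",
              "chain", "het")], xyz, name = "toy_mechanomodule")
  glycans <- lapply(names(gly_atoms), function(id) {
    g <- gly_atoms[[id]]
    glycan_annotation(id, c("A", g$res), g$link,
                      structure_$atoms$serial[g$atom_index])
  })

  # receptor reference: grid residues 1-250 plus probe atoms on 251-265,
  # placed at planted distances straight below dynamic atoms
  gx <- seq(-6, 6, by = 0.5)
  gy <- seq(-2.5, 2, by = 0.5)
  grid <- expand.grid(x = gx, y = gy)[seq_len(250), ]
  rec_atoms <- data.frame(atom_name = "CA", element = "C", resname = "GLY",
                          resnum = seq_len(250), chain = "G", het = FALSE,
                          stringsAsFactors = FALSE)
  rec_xyz <- cbind(grid$x, grid$y, k$z_rec)
  probe_targets <- list()
  add_probe <- function(dyn_res_or_idx, dist, segment, via_glycan = NA) {
    probe_targets[[length(probe_targets) + 1]] <<- list(
      idx = dyn_res_or_idx, dist = dist, segment = segment,
      via_glycan = via_glycan)
  }
  for (seg in names(plant$clash)) {
    for (res in plant$clash[[seg]]) {
      add_probe(which(structure_$atoms$resnum == res &
                        structure_$atoms$atom_name == "CA"),
                k$clash_d, seg)
    }
  }
  for (res in plant$mid) {
    add_probe(which(structure_$atoms$resnum == res &
                      structure_$atoms$atom_name == "CA"), k$mid_d, "mid")
  }
  for (res in plant$far) {
    add_probe(which(structure_$atoms$resnum == res &
                      structure_$atoms$atom_name == "CA"), k$far_d, "far")
  }
  add_probe(gly_atoms[["glyO1"]]$atom_index, k$clash_d, "naim_proximal", "glyO1")
  add_probe(gly_atoms[["glyO2"]]$atom_index, k$clash_d, "caim", "glyO2")
  probe_names <- c("CB", "CG", "CD", "CE")
  probe_tab <- list()
  for (i in seq_along(probe_targets)) {
    pt <- probe_targets[[i]]
    pos <- structure_$xyz[pt$idx, ] - c(0, 0, pt$dist)
    resnum <- 250 + ceiling(i / 4)
    nm <- probe_names[((i - 1) %% 4) + 1]
    rec_atoms <- rbind(rec_atoms,
                       data.frame(atom_name = nm, element = "C",
                                  resname = "GLY", resnum = resnum,
                                  chain = "G", het = FALSE,
                                  stringsAsFactors = FALSE))
    rec_xyz <- rbind(rec_xyz, pos)
    probe_tab[[i]] <- data.frame(probe = i, segment = pt$segment,
                                 dyn_serial = structure_$atoms$serial[pt$idx],
                                 dist = pt$dist,
                                 via_glycan = pt$via_glycan,
                                 stringsAsFactors = FALSE)
  }
  # anchor copy: CA atoms of 1290-1430 at docked coordinates
  anchor_sel <- which(structure_$atoms$resnum >= 1290 &
                        structure_$atoms$resnum <= 1430 &
                        structure_$atoms$atom_name == "CA")
  ref_atoms <- rbind(rec_atoms,
                     structure_$atoms[anchor_sel,
                                      c("atom_name", "element", "resname",
                                        "resnum", "chain", "het")])
  ref_xyz <- rbind(rec_xyz, structure_$xyz[anchor_sel, ])
  ref_atoms$serial <- seq_len(nrow(ref_atoms))
  reference <- new_structure(
    ref_atoms[, c("serial", "atom_name", "element", "resname", "resnum",
                  "chain", "het")], round(ref_xyz, 4),
    name = "toy_receptor_reference")

  regions <- list(
    d_d3 = region_spec("d_d3", c(764, 1237)),
    nfp = region_spec("nfp", c(1238, 1267)),
    naim = region_spec("naim", c(1238, 1271)),
    naim_proximal = region_spec("naim_proximal", c(1268, 1271)),
    a1_core = region_spec("a1_core", c(1272, 1458)),
    align_anchor = region_spec("align_anchor", c(1290, 1430)),
    caim = region_spec("caim", c(1459, 1493)),
    receptor = region_spec("receptor", c(1, 265))
  )
  h_owner <- rep(NA_integer_, nrow(structure_$atoms))
  hyd <- which(structure_$atoms$element == "H")
  for (hi in hyd) {
    same_res <- which(structure_$atoms$resnum == structure_$atoms$resnum[hi] &
                        structure_$atoms$atom_name == "N")
    h_owner[hi] <- same_res[1]
  }
  out <- list(structure = structure_, reference = reference,
              glycans = glycans, regions = regions, beads = beads,
              parent = parent, offsets = offsets, h_owner = h_owner,
              planted = list(hb = do.call(rbind, hb_pairs),
                             sb = do.call(rbind, sb_pairs),
                             probes = do.call(rbind, probe_tab),
                             plant = plant),
              seed = seed)
  class(out) <- "toy_mechanomodule"
  out
}

#' @export
print.toy_mechanomodule <- function(x, ...) {
  cat("<toy_mechanomodule>", n_atoms(x$structure), "atoms /",
      nrow(x$beads), "pseudo-residues;", length(x$glycans), "glycans;",
      nrow(x$planted$probes), "receptor probes\n")
  invisible(x)
}

#' Simulation configuration for the toy mechanomodule
#'
#' @param mode `"free"`, `"flow"` or `"steered"`.
#' @param n_frames frames to simulate (>= 2).
#' @param dt_ns time per frame, ns (default 2.5 in free mode, so 200
#'   frames emulate a 500-ns run with early/late analysis windows; 0.1
#'   otherwise).
#' @param seed seed fixing all randomness.
#' @param flow_strength dimensionless drag scale; release schedules
#'   accelerate and drift speeds grow proportionally; 0 disables uncoiling.
#' @param noise_sd_arm,noise_sd_core per-step Gaussian jitter, nm
#'   (defaults: free 0.02/0.002, flow/steered 0.004/0).
#' @param drift_speed retraction speed of released beads, nm per frame at
#'   `flow_strength = 1`.
#' @param drift_cap maximum retraction distance per bead, nm.
#' @param pull steered-mode spring: list with `k_spring`
#'   (kJ mol^-1 nm^-2), `v` (nm/ps), `site_a`, `site_b` (residue numbers
#'   of the pulled C-alpha atoms).
#' @param release_threshold steered-mode spring force (kJ mol^-1 nm^-1) at
#'   which the C-terminal arm lets go (`Inf` = unbreakable).
#' @param glycosylated steered-mode drag contrast: planted glycan drag
#'   raises the release threshold by `glycan_drag_factor`.
#' @param glycan_drag_factor threshold multiplier when glycosylated.
#' @export
sim_config <- function(mode = c("flow", "free", "steered"), n_frames = 200,
                       dt_ns = NULL, seed = 1, flow_strength = 1,
                       noise_sd_arm = NULL, noise_sd_core = NULL,
                       drift_speed = 0.08, drift_cap = 8,
                       pull = list(k_spring = 1000, v = 1e-4,
                                   site_a = 1238, site_b = 1493),
                       release_threshold = 400, glycosylated = FALSE,
                       glycan_drag_factor = 1.3) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 2)
  if (is.null(dt_ns)) dt_ns <- if (mode == "free") 2.5 else 0.1
  if (is.null(noise_sd_arm)) noise_sd_arm <- if (mode == "free") 0.02 else 0.004
  if (is.null(noise_sd_core)) noise_sd_core <- if (mode == "free") 0.002 else 0
  structure(list(mode = mode, n_frames = n_frames, dt_ns = dt_ns,
                 seed = seed, flow_strength = flow_strength,
                 noise_sd_arm = noise_sd_arm, noise_sd_core = noise_sd_core,
                 drift_speed = drift_speed, drift_cap = drift_cap,
                 pull = pull, release_threshold = release_threshold,
                 glycosylated = glycosylated,
                 glycan_drag_factor = glycan_drag_factor),
            class = "sim_config")
}

# --- independent ground-truth measurement (direct arithmetic over all
# candidate pairs; deliberately not the analysis-path detectors) ---------

.truth_prep <- function(model) {
  a <- model$structure$atoms
  donor_names <- c("N", "NE", "ND1", "NE2", "NH1", "NH2", "OG", "OG1", "OH")
  acc_names <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH")
  don <- which(a$atom_name %in% donor_names & a$element %in% c("N", "O"))
  acc <- which(a$atom_name %in% acc_names & a$element == "O")
  key <- paste(a$resname, a$atom_name, sep = ":")
  cat_idx <- which(key %in% c("LYS:NZ", "ARG:NE", "ARG:NH1", "ARG:NH2"))
  ani_idx <- which(key %in% c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2"))
  don_h <- lapply(don, function(d) which(model$h_owner == d))
  heavy <- !(a$element %in% c("H", "D"))
  reg_atoms <- lapply(model$regions[c("d_d3", "nfp", "naim",
                                      "naim_proximal", "caim")],
                      function(rg) {
    sel <- rep(FALSE, nrow(a))
    for (r in rg$ranges) sel <- sel | (a$resnum >= r[1] & a$resnum <= r[2])
    which(sel & heavy)
  })
  gly_idx <- lapply(model$glycans, function(g) {
    match(g$atom_serials, a$serial)
  })
  names(gly_idx) <- vapply(model$glycans, `[[`, "", "glycan_id")
  gly_link <- vapply(model$glycans, `[[`, "", "linkage")
  names(gly_link) <- names(gly_idx)
  rec_heavy <- which(!(model$reference$atoms$element %in% c("H", "D")) &
                       model$reference$atoms$resnum <= 265 &
                       model$reference$atoms$chain == "G")
  list(don = don, acc = acc, don_h = don_h, cat_idx = cat_idx,
       ani_idx = ani_idx, reg_atoms = reg_atoms, gly_idx = gly_idx,
       gly_link = gly_link, rec_xyz = model$reference$xyz[rec_heavy, ,
                                                          drop = FALSE],
       resnum = a$resnum)
}

.truth_frame <- function(prep, xyz) {
  contacts <- list()
  if (length(prep$don) && length(prep$acc)) {
    d <- sqrt(crossdist2(xyz[prep$don, , drop = FALSE],
                         xyz[prep$acc, , drop = FALSE]))
    hits <- which(d <= 0.35, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      di <- prep$don[hits[h, 1]]
      ai <- prep$acc[hits[h, 2]]
      if (prep$resnum[di] == prep$resnum[ai]) next
      hs <- prep$don_h[[hits[h, 1]]]
      ok <- FALSE
      for (hi in hs) {
        v1 <- xyz[di, ] - xyz[hi, ]
        v2 <- xyz[ai, ] - xyz[hi, ]
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= 150) { ok <- TRUE; break }
      }
      if (ok) {
        contacts[[length(contacts) + 1]] <-
          data.frame(kind = "HB", resnum_don = prep$resnum[di],
                     resnum_acc = prep$resnum[ai])
      }
    }
  }
  if (length(prep$cat_idx) && length(prep$ani_idx)) {
    d <- sqrt(crossdist2(xyz[prep$cat_idx, , drop = FALSE],
                         xyz[prep$ani_idx, , drop = FALSE]))
    hits <- which(d <= 0.35, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      contacts[[length(contacts) + 1]] <-
        data.frame(kind = "SB",
                   resnum_don = prep$resnum[prep$cat_idx[hits[h, 1]]],
                   resnum_acc = prep$resnum[prep$ani_idx[hits[h, 2]]])
    }
  }
  assign_gly <- function(reg_idx, drop_o) {
    ok <- character(0)
    for (id in names(prep$gly_idx)) {
      if (drop_o && prep$gly_link[[id]] == "O") next
      d2 <- crossdist2(xyz[prep$gly_idx[[id]], , drop = FALSE],
                       xyz[reg_idx, , drop = FALSE])
      if (sqrt(min(d2)) <= 0.5) ok <- c(ok, id)
    }
    ok
  }
  clash <- numeric(length(prep$reg_atoms))
  clash_no_o <- numeric(length(prep$reg_atoms))
  names(clash) <- names(clash_no_o) <- names(prep$reg_atoms)
  gly_assign <- list()
  for (rn in names(prep$reg_atoms)) {
    ridx <- prep$reg_atoms[[rn]]
    ids <- assign_gly(ridx, drop_o = FALSE)
    ids_no_o <- assign_gly(ridx, drop_o = TRUE)
    gly_assign[[rn]] <- ids
    dyn <- c(ridx, unlist(prep$gly_idx[ids]))
    d2 <- crossdist2(prep$rec_xyz, xyz[dyn, , drop = FALSE])
    clash[rn] <- sum(d2 < 0.30^2)
    dyn2 <- c(ridx, unlist(prep$gly_idx[ids_no_o]))
    d2b <- crossdist2(prep$rec_xyz, xyz[dyn2, , drop = FALSE])
    clash_no_o[rn] <- sum(d2b < 0.30^2)
  }
  list(contacts = if (length(contacts)) do.call(rbind, contacts) else NULL,
       clash = clash, clash_no_o = clash_no_o, gly_assign = gly_assign)
}

#' Simulate seeded uncoiling of the toy mechanomodule
#'
#' Overdamped updates: every bead relaxes toward a target position plus
#' seeded Gaussian noise. In flow mode arm targets switch from docked to
#' retracted on a planted schedule (the C-terminal arm releases first, the
#' distal/N-terminal-flanking part of the N-terminal arm next, and its
#' proximal part last) scaled by `flow_strength`; in steered mode the
#' C-terminal arm releases when the pulling spring force crosses the
#' planted threshold; in free mode nothing releases and the arms only
#' fluctuate. The core and the D'D3 stub are restrained throughout.
#' Coordinates are quantised to PDB precision (1e-4 nm) before logging so
#' that exported fixtures reproduce the log exactly.
#'
#' @param model a [build_toy_mechanomodule()] result.
#' @param config a [sim_config()].
#' @return list with `trajectory` (a `vwf_trajectory`) and `log`
#'   (a `ground_truth_log`): per-frame contact table, per-region clash
#'   counts (with and without O-linked glycans), glycan assignments, pull
#'   force (kJ mol^-1 nm^-1), end-to-end extension, release events, and
#'   the planted orderings (`arm_order`, `construct_order`).
#' @export
simulate_uncoiling <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "toy_mechanomodule"))
  withr::with_seed(config$seed, .simulate_uncoiling_impl(model, config))
}

.simulate_uncoiling_impl <- function(model, config) {
  beads <- model$beads
  nb <- nrow(beads)
  nf <- config$n_frames
  dock <- as.matrix(beads[, c("x", "y", "z")])
  seg <- beads$segment
  arm <- beads$arm
  # planted release schedule (frames), jittered per bead then scaled
  base <- rep(Inf, nb)
  sched <- list(caim = c(30, 70), nfp = c(90, 140),
                naim_proximal = c(155, 185))
  for (sn in names(sched)) {
    idx <- which(seg == sn)
    if (length(idx)) {
      base[idx] <- seq(sched[[sn]][1], sched[[sn]][2],
                       length.out = length(idx)) +
        stats::runif(length(idx), -5, 5)
    }
  }
  strength <- config$flow_strength
  release <- switch(config$mode,
    free = rep(Inf, nb),
    flow = if (strength > 0) base / strength else rep(Inf, nb),
    steered = rep(Inf, nb))
  dirs <- matrix(0, nb, 3)
  ux <- ifelse(arm == "naim", -1, ifelse(arm == "caim", 1, 0))
  for (b in seq_len(nb)) {
    if (ux[b] != 0) dirs[b, ] <- c(ux[b], 0, 0.6) / sqrt(1 + 0.36)
  }
  noise_sd <- ifelse(arm %in% c("naim", "caim"),
                     config$noise_sd_arm, config$noise_sd_core)
  threshold <- config$release_threshold *
    if (config$glycosylated) config$glycan_drag_factor else 1
  site_a <- which(model$structure$atoms$resnum == config$pull$site_a &
                    model$structure$atoms$atom_name == "CA")
  site_b <- which(model$structure$atoms$resnum == config$pull$site_b &
                    model$structure$atoms$atom_name == "CA")
  bead_a <- model$parent[site_a]
  bead_b <- model$parent[site_b]
  pull_dir <- dock[bead_b, ] - dock[bead_a, ]
  ext0 <- sqrt(sum(pull_dir^2))
  pull_dir <- pull_dir / ext0
  rate <- config$pull$v * 1000 * config$dt_ns  # nm per frame
  k_spring <- config$pull$k_spring

  prep <- .truth_prep(model)
  pos <- dock
  coords <- array(NA_real_, c(nf, n_atoms(model$structure), 3))
  pull_force <- numeric(nf)
  extension <- numeric(nf)
  contacts <- list()
  clash <- matrix(0, nf, length(prep$reg_atoms),
                  dimnames = list(NULL, names(prep$reg_atoms)))
  clash_no_o <- clash
  gly_assign <- vector("list", nf)
  events <- list()
  caim_released_at <- NA_integer_
  drift_v <- config$drift_speed * max(strength, if (config$mode == "steered") 1 else 0)
  for (t in seq_len(nf)) {
    ext <- sqrt(sum((pos[bead_b, ] - pos[bead_a, ])^2))
    restraint <- ext0 + rate * (t - 1)
    force <- if (config$mode == "steered") {
      max(0, k_spring * (restraint - ext))
    } else 0
    if (config$mode == "steered" && is.na(caim_released_at) &&
        force >= threshold) {
      caim_released_at <- t
      cidx <- which(arm == "caim")
      release[cidx] <- t + seq_along(cidx) %% 5 +
        stats::runif(length(cidx), 0, 2)
      events[[length(events) + 1]] <- data.frame(event = "caim_release",
                                                 frame = t, force = force)
    }
    # overdamped relaxation toward (possibly retracted) targets
    target <- dock
    rel <- which(t >= release)
    if (length(rel)) {
      disp <- pmin((t - release[rel]) * drift_v, config$drift_cap)
      target[rel, ] <- dock[rel, ] + dirs[rel, ] * disp
    }
    if (config$mode == "steered" && !is.na(caim_released_at)) {
      # the pulled terminus tracks the moving restraint along the pull line
      target[bead_b, ] <- dock[bead_b, ] +
        pull_dir * (restraint - ext0)
    }
    pos <- pos + 0.5 * (target - pos) +
      matrix(stats::rnorm(nb * 3, 0, 1), nb, 3) * noise_sd
    if (any(abs(pos) > 1e4)) {
      stop("numerical blow-up at frame ", t, ": max displacement ",
           max(abs(pos)))
    }
    xyz <- round(pos[model$parent, , drop = FALSE] + model$offsets, 4)
    coords[t, , ] <- xyz
    extension[t] <- sqrt(sum((xyz[site_b, ] - xyz[site_a, ])^2))
    pull_force[t] <- force
    truth <- .truth_frame(prep, xyz)
    if (!is.null(truth$contacts)) {
      truth$contacts$frame <- t
      contacts[[length(contacts) + 1]] <- truth$contacts
    }
    clash[t, ] <- truth$clash
    clash_no_o[t, ] <- truth$clash_no_o
    gly_assign[[t]] <- truth$gly_assign
  }
  traj <- new_trajectory(model$structure, coords, dt_ns = config$dt_ns)
  contacts <- if (length(contacts)) do.call(rbind, contacts) else
    data.frame(kind = character(), resnum_don = integer(),
               resnum_acc = integer(), frame = integer())
  construct_tot <- cbind(
    dPro = clash[, "d_d3"] + clash[, "naim"] + clash[, "caim"],
    dD_D3 = clash[, "naim"] + clash[, "caim"],
    `dD_D3NFP-` = clash[, "naim_proximal"] + clash[, "caim"],
    `dD_D3OG-` = clash_no_o[, "naim"] + clash_no_o[, "caim"])
  log <- structure(list(
    mode = config$mode, seed = config$seed, n_frames = nf,
    times = traj$times, contacts = contacts, clash_counts = clash,
    clash_counts_no_o = clash_no_o, glycan_assignments = gly_assign,
    pull_force_kj = pull_force, extension = extension,
    events = if (length(events)) do.call(rbind, events) else NULL,
    release_frames = release,
    construct_totals = construct_tot,
    arm_order = c("naim", "caim"),
    construct_order = names(sort(colMeans(construct_tot),
                                 decreasing = TRUE))),
    class = "ground_truth_log")
  list(trajectory = traj, log = log)
}

#' Remove hydrogens from a structure or trajectory
#'
#' Used to exercise the heavy-atom angle approximation of the
#' hydrogen-bond detector on hydrogen-stripped fixtures.
#'
#' @param x a `vwf_structure` or `vwf_trajectory`.
#' @export
strip_hydrogens <- function(x) {
  if (inherits(x, "vwf_trajectory")) {
    keep <- which(is_heavy(x$topology))
    top <- strip_hydrogens(x$topology)
    new_trajectory(top, x$coords[, keep, , drop = FALSE], times = x$times)
  } else {
    keep <- which(is_heavy(x))
    new_structure(x$atoms[keep, , drop = FALSE],
                  x$xyz[keep, , drop = FALSE], name = x$name)
  }
}

#' Export a synthetic fixture to disk
#'
#' Writes a multi-model PDB trajectory, a frame-0 topology PDB, the
#' receptor reference PDB, a region/glycan YAML config, the ground-truth
#' log as JSON and a manifest. Re-reading the fixture and re-running the
#' pipeline reproduces the log exactly (coordinates are quantised to PDB
#' precision during simulation).
#'
#' @param traj trajectory from [simulate_uncoiling()].
#' @param log matching `ground_truth_log`.
#' @param model the `toy_mechanomodule`.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
export_fixture <- function(traj, log, model, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(traj, file.path(out_dir, "trajectory.pdb"))
  top0 <- new_structure(traj$topology$atoms, frame_coords(traj, 1),
                        name = "frame0")
  write_structure(top0, file.path(out_dir, "topology.pdb"))
  write_structure(model$reference, file.path(out_dir, "reference.pdb"))
  write_region_config(model$regions, model$glycans,
                      file.path(out_dir, "config.yaml"))
  log_json <- list(
    mode = log$mode, seed = log$seed, n_frames = log$n_frames,
    times = log$times, contacts = log$contacts,
    clash_counts = as.data.frame(log$clash_counts),
    clash_counts_no_o = as.data.frame(log$clash_counts_no_o),
    pull_force_kj = log$pull_force_kj, extension = log$extension,
    release_frames = unname(log$release_frames),
    arm_order = log$arm_order, construct_order = log$construct_order)
  jsonlite::write_json(log_json, file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  manifest <- list(n_atoms = n_atoms(traj$topology),
                   n_frames = n_frames(traj),
                   files = c("trajectory.pdb", "topology.pdb",
                             "reference.pdb", "config.yaml",
                             "ground_truth.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
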