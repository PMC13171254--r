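#' Steric-clash epitope-shielding analysis
#'
#' The mechano-presentation score: a static receptor complex (GPIb-alpha
#' bound to the A1 domain) is superposed onto every trajectory frame via a
#' rigid A1 anchor (heavy atoms of residues 1290-1430), and heavy-atom
#' pairs closer than 3.0 Angstrom between the transformed receptor
#' (residues 1-265) and each dynamic shielding region (autoinhibitory arms
#' plus any glycans within 5 Angstrom of the region) are counted per frame.
#' A shielded epitope clashes with the receptor footprint; force-induced
#' uncoiling removes the clashes and exposes the epitope.
#'
#' @name shieldscan
NULL

#' Count steric clashes between two heavy-atom sets
#'
#' Counts unordered atom pairs with distance strictly below `cutoff`
#' (default < 3.0 Angstrom; set `inclusive = TRUE` for a closed cutoff,
#' which differs only on measure-zero geometries).
#'
#' @param static_xyz,dynamic_xyz coordinate matrices (nm); empty sets give 0.
#' @param cutoff nm.
#' @param inclusive use `<=` instead of `<`.
#' @return integer pair count.
#' @export
count_clashes <- function(static_xyz, dynamic_xyz, cutoff = 0.30,
                          inclusive = FALSE) {
  if (length(static_xyz) == 0 || length(dynamic_xyz) == 0) return(0L)
  d2 <- crossdist2(static_xyz, dynamic_xyz)
  if (inclusive) sum(d2 <= cutoff^2) else sum(d2 < cutoff^2)
}

#' Configuration for a clash scan
#'
#' @param align_region anchor used to superpose the reference onto each
#'   frame (default: heavy atoms of residues 1290-1430).
#' @param receptor_region static receptor atoms in the reference (default:
#'   residues 1-265).
#' @param shield_regions named list of `region_spec`s scored against the
#'   receptor.
#' @param glycan_cutoff glycan-to-region assignment distance, nm.
#' @param clash_cutoff clash distance, nm (strict `<` by default).
#' @param glycan_assignment `"per_frame"` (default) or `"initial_frame"`.
#' @param inclusive closed clash cutoff (see [count_clashes()]).
#' @param min_matched_atoms floor on anchor atoms matched between reference
#'   and topology.
#' @param rmsd_warn warn when the per-frame anchor fit RMSD exceeds this
#'   (nm).
#' @param smooth_window,smooth_poly Savitzky-Golay parameters for the
#'   smoothed series.
#' @export
clash_config <- function(align_region = region_spec("align_anchor",
                                                    c(1290, 1430)),
                         receptor_region = region_spec("receptor",
                                                       c(1, 265)),
                         shield_regions = list(
                           naim = region_spec("naim", c(1238, 1271)),
                           caim = region_spec("caim", c(1459, 1493))),
                         glycan_cutoff = 0.5, clash_cutoff = 0.30,
                         glycan_assignment = c("per_frame", "initial_frame"),
                         inclusive = FALSE, min_matched_atoms = 100,
                         rmsd_warn = 0.5, smooth_window = 51,
                         smooth_poly = 3) {
  glycan_assignment <- match.arg(glycan_assignment)
  stopifnot(clash_cutoff < glycan_cutoff)
  if (is.null(names(shield_regions))) {
    names(shield_regions) <- vapply(shield_regions, `[[`, "", "name")
  }
  structure(list(align_region = align_region,
                 receptor_region = receptor_region,
                 shield_regions = shield_regions,
                 glycan_cutoff = glycan_cutoff, clash_cutoff = clash_cutoff,
                 glycan_assignment = glycan_assignment,
                 inclusive = inclusive,
                 min_matched_atoms = min_matched_atoms,
                 rmsd_warn = rmsd_warn, smooth_window = smooth_window,
                 smooth_poly = smooth_poly),
            class = "clash_config")
}

# match anchor atoms between reference and topology by (resnum, atom_name)
.match_anchor <- function(reference, topology, align_region, floor_atoms) {
  ridx <- select_atoms(reference, align_region, quiet = TRUE)
  tidx <- select_atoms(topology, align_region, quiet = TRUE)
  if (length(ridx) == 0 || length(tidx) == 0) {
    stop("alignment region '", align_region$name,
         "' resolves no atoms in reference or topology")
  }
  rkey <- paste(reference$atoms$resnum[ridx], reference$atoms$atom_name[ridx])
  tkey <- paste(topology$atoms$resnum[tidx], topology$atoms$atom_name[tidx])
  common <- intersect(rkey, tkey)
  if (length(common) < floor_atoms) {
    stop("only ", length(common), " matched anchor atoms (need >= ",
         floor_atoms, "); missing residues in alignment region")
  }
  list(ref = ridx[match(common, rkey)], top = tidx[match(common, tkey)])
}

#' Scan a trajectory for per-region steric clashes
#'
#' Per frame: (i) the reference is superposed onto the frame via the
#' anchor; (ii) its receptor atoms are transformed; (iii) each shielding
#' region contributes its heavy atoms plus the atoms of glycans assigned
#' to it at `glycan_cutoff`; (iv) clash pairs below `clash_cutoff` are
#' counted per region and in total. Savitzky-Golay smoothed series are
#' attached when the run is long enough.
#'
#' @param traj a `vwf_trajectory`.
#' @param reference a `vwf_structure` holding the receptor and the anchor
#'   residues (e.g. a receptor-complex crystal structure).
#' @param config a [clash_config()].
#' @param glycans list of `glycan_annotation` on the trajectory topology.
#' @return a `clash_series`: list with `per_region` (frames x regions
#'   integer matrix), `total`, `smoothed`, `times`, `align_rmsd`, and
#'   `glycan_assignments` (per-region list of per-frame id vectors).
#' @export
clash_scan <- function(traj, reference, config = clash_config(),
                       glycans = list()) {
  top <- traj$topology
  anchor <- .match_anchor(reference, top, config$align_region,
                          config$min_matched_atoms)
  rec_idx <- select_atoms(reference, config$receptor_region, quiet = TRUE)
  if (length(rec_idx) == 0) stop("receptor region resolves no atoms")
  regions <- config$shield_regions
  reg_idx <- lapply(regions, select_atoms, structure = top, quiet = TRUE)
  heavy <- is_heavy(top)
  nf <- n_frames(traj)
  counts <- matrix(0L, nf, length(regions),
                   dimnames = list(NULL, names(regions)))
  align_rmsd <- numeric(nf)
  assignments <- rep(list(vector("list", nf)), length(regions))
  names(assignments) <- names(regions)
  init_assign <- NULL
  if (config$glycan_assignment == "initial_frame" && length(glycans)) {
    x0 <- frame_coords(traj, 1)
    init_assign <- lapply(regions, function(rg) {
      assign_glycans_to_region(top, glycans, rg, coords = x0,
                               cutoff = config$glycan_cutoff)
    })
  }
  gly_ids <- vapply(glycans, `[[`, "", "glycan_id")
  for (i in seq_len(nf)) {
    x <- frame_coords(traj, i)
    sp <- kabsch_superpose(reference$xyz[anchor$ref, , drop = FALSE],
                           x[anchor$top, , drop = FALSE])
    align_rmsd[i] <- sp$rmsd
    if (sp$rmsd > config$rmsd_warn) {
      warning("frame ", i, ": anchor fit RMSD ", round(sp$rmsd, 3),
              " nm exceeds ", config$rmsd_warn, " nm")
    }
    rec_xyz <- apply_superposition(sp, reference$xyz[rec_idx, , drop = FALSE])
    for (r in seq_along(regions)) {
      ids <- if (length(glycans)) {
        if (config$glycan_assignment == "per_frame") {
          assign_glycans_to_region(top, glycans, regions[[r]], coords = x,
                                   cutoff = config$glycan_cutoff)
        } else init_assign[[r]]
      } else character(0)
      assignments[[r]][[i]] <- ids
      idx <- reg_idx[[r]]
      if (length(ids)) {
        gsel <- unlist(lapply(glycans[match(ids, gly_ids)], function(g) {
          gi <- .glycan_atom_indices(top, g)
          gi[!is.na(gi)]
        }))
        idx <- union(idx, gsel[heavy[gsel]])
      }
      counts[i, r] <- count_clashes(rec_xyz, x[idx, , drop = FALSE],
                                    config$clash_cutoff, config$inclusive)
    }
  }
  w <- clamp_savgol_window(nf, config$smooth_window, config$smooth_poly)
  smoothed <- if (is.na(w)) NULL else {
    apply(counts, 2, savgol_smooth, window_length = w,
          polyorder = config$smooth_poly)
  }
  structure(list(per_region = counts, total = as.integer(rowSums(counts)),
                 smoothed = smoothed, times = traj$times,
                 align_rmsd = align_rmsd,
                 glycan_assignments = assignments),
            class = "clash_series")
}

#' @export
print.clash_series <- function(x, ...) {
  cat("<clash_series>", nrow(x$per_region), "frames x",
      ncol(x$per_region), "regions; mean total",
      round(mean(x$total), 2), "\n")
  invisible(x)
}

#' Normalise a clash series per region
#'
#' Each region's counts are scaled to `[0, 1]` by its maximum (`"max"`,
#' default) or its initial value (`"initial"`); an all-zero region stays
#' all-zero. Per-region means over all frames are attached.
#'
#' @param series a `clash_series`.
#' @param mode `"max"` or `"initial"`.
#' @return list with `per_region` (frames x regions, in `[0, 1]`), `means`
#'   (named per-region vector), `mode` and `times`.
#' @export
normalized_clash <- function(series, mode = c("max", "initial")) {
  mode <- match.arg(mode)
  counts <- series$per_region
  norm <- apply(counts, 2, function(v) {
    ref <- if (mode == "max") max(v) else v[1]
    if (ref > 0) v / ref else rep(0, length(v))
  })
  norm <- matrix(norm, nrow = nrow(counts), dimnames = dimnames(counts))
  list(per_region = norm, means = colMeans(norm), mode = mode,
       times = series$times)
}

#' Define a construct preset
#'
#' A construct is evaluated as the set of shielding regions it retains
#' (deletion constructs simply omit regions); optionally its O-linked
#' glycans are removed.
#'
#' @param name construct label (e.g. `"dPro"`, `"dD_D3"`, `"dD_D3NFP-"`,
#'   `"dD_D3OG-"`).
#' @param regions named list of `region_spec`s the construct retains.
#' @param omit_o_glycans drop O-linked glycan annotations.
#' @export
construct_preset <- function(name, regions, omit_o_glycans = FALSE) {
  if (is.null(names(regions))) {
    names(regions) <- vapply(regions, `[[`, "", "name")
  }
  structure(list(name = name, regions = regions,
                 omit_o_glycans = isTRUE(omit_o_glycans)),
            class = "construct_preset")
}

#' Default deletion-construct presets
#'
#' The four constructs used to compare simulated accessibility with
#' measured receptor-binding affinities: full shielding (`dPro`), D'D3
#' deleted (`dD_D3`), D'D3 plus the N-terminal flanking peptide up to
#' residue 1267 deleted (`dD_D3NFP-`), and D'D3 deleted with O-linked
#' glycans removed (`dD_D3OG-`).
#'
#' @return list of `construct_preset`.
#' @export
default_construct_presets <- function() {
  d_d3 <- region_spec("d_d3", c(764, 1237))
  naim <- region_spec("naim", c(1238, 1271))
  prox <- region_spec("naim_proximal", c(1268, 1271))
  caim <- region_spec("caim", c(1459, 1493))
  list(
    construct_preset("dPro", list(d_d3 = d_d3, naim = naim, caim = caim)),
    construct_preset("dD_D3", list(naim = naim, caim = caim)),
    construct_preset("dD_D3NFP-", list(naim_proximal = prox, caim = caim)),
    construct_preset("dD_D3OG-", list(naim = naim, caim = caim),
                     omit_o_glycans = TRUE)
  )
}

#' Compare receptor accessibility across constructs
#'
#' Each construct's retained regions (and glycans) are clash-scanned; the
#' per-frame totals are normalised by the maximum total observed across
#' all constructs (one common scale, so the ranking equals the raw-mean
#' ranking) and summarised as mean and sd. Rank 1 has the most shielding
#' (largest mean normalised clash); the most accessible construct ranks
#' last.
#'
#' @param traj a `vwf_trajectory`.
#' @param reference receptor-complex reference structure.
#' @param presets list of [construct_preset()]s.
#' @param config a [clash_config()] (its `shield_regions` are replaced per
#'   preset).
#' @param glycans glycan annotations on the topology.
#' @return data.frame `(construct, mean_clash, sd_clash, mean_normalized,
#'   sd_normalized, rank)`.
#' @export
construct_compare <- function(traj, reference, presets,
                              config = clash_config(), glycans = list()) {
  totals <- lapply(presets, function(p) {
    cfg <- config
    cfg$shield_regions <- p$regions
    gl <- glycans
    if (p$omit_o_glycans && length(gl)) {
      gl <- gl[vapply(gl, `[[`, "", "linkage") != "O"]
    }
    clash_scan(traj, reference, cfg, gl)$total
  })
  scale_max <- max(1, unlist(totals))
  out <- data.frame(
    construct = vapply(presets, `[[`, "", "name"),
    mean_clash = vapply(totals, mean, 0),
    sd_clash = vapply(totals, stats::sd, 0),
    mean_normalized = vapply(totals, function(v) mean(v / scale_max), 0),
    sd_normalized = vapply(totals, function(v) stats::sd(v / scale_max), 0),
    stringsAsFactors = FALSE
  )
  out$rank <- rank(-out$mean_normalized, ties.method = "first")
  out
}
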