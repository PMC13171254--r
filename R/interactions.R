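#' Hydrogen-bond and salt-bridge detection
#'
#' Geometric contact criteria: a hydrogen bond requires a donor-acceptor
#' distance of at most 3.5 Angstrom (0.35 nm) and a donor-hydrogen-acceptor
#' angle of at least 150 degrees; a salt bridge requires a cation-nitrogen
#' to anion-oxygen distance of at most 3.5 Angstrom between Lys/Arg and
#' Asp/Glu side chains. Frequencies across concatenated replicates are
#' filtered at 10 percent persistence.
#'
#' @name interactions
NULL

#' Hydrogen-bond criteria
#'
#' @param max_distance donor-acceptor cutoff, nm (inclusive).
#' @param min_angle donor-hydrogen-acceptor cutoff, degrees (inclusive).
#' @param donor_atom_names,acceptor_atom_names PDB atom-name sets; the
#'   defaults are the side-chain/backbone N and O names conventionally
#'   treated as donors and acceptors (OG/OG1/OH appear in both sets).
#' @param h_attach_distance hydrogens are assigned to the nearest
#'   donor-capable heavy atom within this distance, nm.
#' @export
hbond_criteria <- function(max_distance = 0.35, min_angle = 150,
                           donor_atom_names = c("N", "NE", "ND1", "NE2",
                                                "NH1", "NH2", "OG", "OG1",
                                                "OH"),
                           acceptor_atom_names = c("O", "OD1", "OD2", "OE1",
                                                   "OE2", "OG", "OG1", "OH"),
                           h_attach_distance = 0.12) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 donor_atom_names = donor_atom_names,
                 acceptor_atom_names = acceptor_atom_names,
                 h_attach_distance = h_attach_distance),
            class = "hbond_criteria")
}

#' Salt-bridge criteria
#'
#' @param max_distance cutoff, nm (inclusive).
#' @param cation_atoms,anion_atoms `"RESNAME:ATOM"` strings.
#' @export
salt_bridge_criteria <- function(max_distance = 0.35,
                                 cation_atoms = c("LYS:NZ", "ARG:NE",
                                                  "ARG:NH1", "ARG:NH2"),
                                 anion_atoms = c("ASP:OD1", "ASP:OD2",
                                                 "GLU:OE1", "GLU:OE2")) {
  stopifnot(max_distance > 0)
  structure(list(max_distance = max_distance, cation_atoms = cation_atoms,
                 anion_atoms = anion_atoms),
            class = "salt_bridge_criteria")
}

.angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.group_indices <- function(structure, group) {
  if (inherits(group, "region_spec")) select_atoms(structure, group, quiet = TRUE)
  else as.integer(group)
}

.empty_records <- function() {
  data.frame(kind = character(), chain_a = character(), resnum_a = integer(),
             resname_a = character(), atom_a = character(),
             chain_b = character(), resnum_b = integer(),
             resname_b = character(), atom_b = character(),
             distance = numeric(), angle = numeric(), approximate = logical(),
             stringsAsFactors = FALSE)
}

.record_rows <- function(structure, kind, ia, ib, dist, angle, approx) {
  a <- structure$atoms
  data.frame(kind = kind,
             chain_a = a$chain[ia], resnum_a = a$resnum[ia],
             resname_a = a$resname[ia], atom_a = a$atom_name[ia],
             chain_b = a$chain[ib], resnum_b = a$resnum[ib],
             resname_b = a$resname[ib], atom_b = a$atom_name[ib],
             distance = dist, angle = angle, approximate = approx,
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds in one frame
#'
#' A bond is recorded for each (donor, acceptor) atom pair meeting both the
#' distance and the angle criterion; the donor may lie in either group.
#' When hydrogens exist they define the true donor-hydrogen-acceptor angle
#' (the best hydrogen counts); when a donor carries no hydrogen the angle
#' at the donor formed by its nearest heavy-atom antecedent, the donor and
#' the acceptor is used instead and the record is flagged `approximate`.
#' Pairs are deduplicated by unordered atom pair.
#'
#' @param structure topology (`vwf_structure`).
#' @param group_a,group_b `region_spec`s or atom index vectors; the groups
#'   must be disjoint at residue level unless `min_residue_separation > 0`.
#' @param coords frame coordinates (default: the structure's own).
#' @param criteria an [hbond_criteria()].
#' @param min_residue_separation require `|resnum_a - resnum_b| >=` this
#'   value (use 2 for intramolecular counting).
#' @return data.frame of contact records.
#' @export
detect_hbonds <- function(structure, group_a, group_b, coords = NULL,
                          criteria = hbond_criteria(),
                          min_residue_separation = 0) {
  if (is.null(coords)) coords <- structure$xyz
  a <- structure$atoms
  idx_a <- .group_indices(structure, group_a)
  idx_b <- .group_indices(structure, group_b)
  res_a <- unique(paste(a$chain, a$resnum)[idx_a])
  res_b <- unique(paste(a$chain, a$resnum)[idx_b])
  donor_capable <- which(a$atom_name %in% criteria$donor_atom_names &
                           toupper(a$element) %in% c("N", "O"))
  acc_all <- which(a$atom_name %in% criteria$acceptor_atom_names &
                     toupper(a$element) == "O")
  hyd <- which(!is_heavy(structure))
  # hydrogen -> donor attachment by nearest donor-capable heavy atom
  h_owner <- integer(0)
  if (length(hyd) && length(donor_capable)) {
    d2 <- crossdist2(coords[hyd, , drop = FALSE],
                     coords[donor_capable, , drop = FALSE])
    nearest <- max.col(-d2)
    ok <- sqrt(d2[cbind(seq_along(hyd), nearest)]) <= criteria$h_attach_distance
    h_owner <- ifelse(ok, donor_capable[nearest], NA_integer_)
  }
  res_of <- paste(a$chain, a$resnum)
  out <- list()
  for (dir in 1:2) {
    don_res <- if (dir == 1) res_a else res_b
    acc_res <- if (dir == 1) res_b else res_a
    don <- donor_capable[res_of[donor_capable] %in% don_res]
    acc <- acc_all[res_of[acc_all] %in% acc_res]
    if (!length(don) || !length(acc)) next
    d <- sqrt(crossdist2(coords[don, , drop = FALSE],
                         coords[acc, , drop = FALSE]))
    hits <- which(d <= criteria$max_distance, arr.ind = TRUE)
    if (!nrow(hits)) next
    for (h in seq_len(nrow(hits))) {
      di <- don[hits[h, 1]]
      ai <- acc[hits[h, 2]]
      if (di == ai) next
      if (abs(a$resnum[di] - a$resnum[ai]) < min_residue_separation) next
      if (res_of[di] == res_of[ai]) next
      my_h <- hyd[which(h_owner == di)]
      if (length(my_h)) {
        angs <- vapply(my_h, function(hi) {
          .angle_deg(coords[di, ], coords[hi, ], coords[ai, ])
        }, 0)
        ang <- max(angs)
        approx <- FALSE
      } else {
        heavy_idx <- which(is_heavy(structure))
        heavy_idx <- heavy_idx[heavy_idx != di]
        d2a <- crossdist2(coords[di, , drop = FALSE],
                          coords[heavy_idx, , drop = FALSE])
        ante <- heavy_idx[which.min(d2a)]
        ang <- .angle_deg(coords[ante, ], coords[di, ], coords[ai, ])
        approx <- TRUE
      }
      if (ang >= criteria$min_angle) {
        out[[length(out) + 1]] <- .record_rows(structure, "HB", di, ai,
                                               d[hits[h, 1], hits[h, 2]],
                                               ang, approx)
        attr(out[[length(out)]], "pair") <- paste(sort(c(di, ai)),
                                                  collapse = "-")
      }
    }
  }
  if (!length(out)) return(.empty_records())
  pairs <- vapply(out, attr, character(1), "pair")
  rec <- do.call(rbind, out[!duplicated(pairs)])
  rownames(rec) <- NULL
  rec
}

#' Detect salt bridges in one frame
#'
#' One record per qualifying cation-nitrogen / anion-oxygen atom pair at or
#' below the distance cutoff (inclusive).
#'
#' @inheritParams detect_hbonds
#' @param criteria a [salt_bridge_criteria()].
#' @return data.frame of contact records (`angle` is `NA`).
#' @export
detect_salt_bridges <- function(structure, group_a, group_b, coords = NULL,
                                criteria = salt_bridge_criteria(),
                                min_residue_separation = 0) {
  if (is.null(coords)) coords <- structure$xyz
  a <- structure$atoms
  key <- paste(a$resname, a$atom_name, sep = ":")
  cat_all <- which(key %in% criteria$cation_atoms)
  ani_all <- which(key %in% criteria$anion_atoms)
  idx_a <- .group_indices(structure, group_a)
  idx_b <- .group_indices(structure, group_b)
  res_of <- paste(a$chain, a$resnum)
  res_a <- unique(res_of[idx_a])
  res_b <- unique(res_of[idx_b])
  out <- list()
  for (dir in 1:2) {
    cat_res <- if (dir == 1) res_a else res_b
    ani_res <- if (dir == 1) res_b else res_a
    cats <- cat_all[res_of[cat_all] %in% cat_res]
    anis <- ani_all[res_of[ani_all] %in% ani_res]
    if (!length(cats) || !length(anis)) next
    d <- sqrt(crossdist2(coords[cats, , drop = FALSE],
                         coords[anis, , drop = FALSE]))
    hits <- which(d <= criteria$max_distance, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      ci <- cats[hits[h, 1]]
      ai <- anis[hits[h, 2]]
      if (abs(a$resnum[ci] - a$resnum[ai]) < min_residue_separation) next
      out[[length(out) + 1]] <- .record_rows(structure, "SB", ci, ai,
                                             d[hits[h, 1], hits[h, 2]],
                                             NA_real_, FALSE)
      attr(out[[length(out)]], "pair") <- paste(sort(c(ci, ai)),
                                                collapse = "-")
    }
  }
  if (!length(out)) return(.empty_records())
  pairs <- vapply(out, attr, character(1), "pair")
  rec <- do.call(rbind, out[!duplicated(pairs)])
  rownames(rec) <- NULL
  rec
}

#' Collect contact records over a trajectory
#'
#' @param traj a `vwf_trajectory`.
#' @param group_a,group_b groups as in [detect_hbonds()].
#' @param hb_criteria,sb_criteria criteria objects; set either to `NULL`
#'   to skip that contact kind.
#' @param min_residue_separation see [detect_hbonds()].
#' @return data.frame of records with `frame` (1-based) and `time_ns`.
#' @export
collect_contacts <- function(traj, group_a, group_b,
                             hb_criteria = hbond_criteria(),
                             sb_criteria = salt_bridge_criteria(),
                             min_residue_separation = 0) {
  top <- traj$topology
  recs <- lapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    r <- .empty_records()
    if (!is.null(hb_criteria)) {
      r <- rbind(r, detect_hbonds(top, group_a, group_b, x, hb_criteria,
                                  min_residue_separation))
    }
    if (!is.null(sb_criteria)) {
      r <- rbind(r, detect_salt_bridges(top, group_a, group_b, x, sb_criteria,
                                        min_residue_separation))
    }
    if (nrow(r)) {
      r$frame <- i
      r$time_ns <- traj$times[i]
    }
    r
  })
  out <- do.call(rbind, recs)
  if (is.null(out$frame)) {
    out$frame <- integer(0)
    out$time_ns <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Per-frame interaction counts
#'
#' @inheritParams collect_contacts
#' @param kinds which contact kinds to count.
#' @return data.frame `(frame, time_ns, hb, sb, total)`.
#' @export
interaction_timeseries <- function(traj, group_a, group_b,
                                   hb_criteria = hbond_criteria(),
                                   sb_criteria = salt_bridge_criteria(),
                                   kinds = c("HB", "SB"),
                                   min_residue_separation = 0) {
  if (!"HB" %in% kinds) hb_criteria <- NULL
  if (!"SB" %in% kinds) sb_criteria <- NULL
  rec <- collect_contacts(traj, group_a, group_b, hb_criteria, sb_criteria,
                          min_residue_separation)
  nf <- n_frames(traj)
  hb <- tabulate(rec$frame[rec$kind == "HB"], nbins = nf)
  sb <- tabulate(rec$frame[rec$kind == "SB"], nbins = nf)
  data.frame(frame = seq_len(nf), time_ns = traj$times,
             hb = hb, sb = sb, total = hb + sb)
}

#' Mean and standard deviation across replicate series
#'
#' Replicates are expected on a common time grid (the usual case for
#' equal-length runs); otherwise each is linearly interpolated onto the
#' first replicate's grid before averaging.
#'
#' @param series_list list of data.frames with `time_ns` and a value column.
#' @param column value column name.
#' @return data.frame `(time_ns, mean, sd)`.
#' @export
average_series <- function(series_list, column = "total") {
  grid <- series_list[[1]]$time_ns
  vals <- vapply(series_list, function(s) {
    if (length(s$time_ns) == length(grid) && all(s$time_ns == grid)) {
      s[[column]]
    } else {
      stats::approx(s$time_ns, s[[column]], xout = grid, rule = 2)$y
    }
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  data.frame(time_ns = grid,
             mean = rowMeans(vals),
             sd = apply(vals, 1, function(v) {
               if (length(v) > 1) stats::sd(v) else 0
             }))
}

#' Concatenate replicate contact records
#'
#' Frames are reindexed into one continuous dataset (replicate 2 starts
#' after replicate 1, and so on); replicate provenance is retained.
#'
#' @param records_list list of per-replicate record data.frames (from
#'   [collect_contacts()]).
#' @param n_frames_each integer vector of per-replicate frame counts.
#' @return list with `records` (with `replicate` and global `frame`) and
#'   `n_frames_total`.
#' @export
concatenate_replicates <- function(records_list, n_frames_each) {
  if (length(records_list) != length(n_frames_each)) {
    stop("records_list and n_frames_each lengths differ")
  }
  offset <- c(0, cumsum(n_frames_each))[seq_along(records_list)]
  recs <- lapply(seq_along(records_list), function(k) {
    r <- records_list[[k]]
    if (nrow(r)) {
      r$replicate <- k
      r$frame <- r$frame + offset[k]
    } else {
      r$replicate <- integer(0)
    }
    r
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  list(records = out, n_frames_total = sum(n_frames_each))
}

.residue_pair_key <- function(rec) {
  a <- paste(rec$chain_a, rec$resnum_a, rec$resname_a, sep = "|")
  b <- paste(rec$chain_b, rec$resnum_b, rec$resname_b, sep = "|")
  swap <- rec$resnum_b < rec$resnum_a |
    (rec$resnum_b == rec$resnum_a & b < a)
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  paste(first, second, sep = "||")
}

#' Contact-frequency map with persistence filter
#'
#' The frequency of a residue pair is the fraction of frames in which it
#' forms a hydrogen bond or salt bridge; pairs below the persistence
#' threshold (default: present in at least 10 percent of the combined
#' frames, boundary inclusive) are dropped.
#'
#' @param records combined contact records (see
#'   [concatenate_replicates()]).
#' @param n_frames_total total frame count of the combined dataset.
#' @param threshold persistence fraction, inclusive.
#' @return data.frame `(chain_a, resnum_a, resname_a, chain_b, resnum_b,
#'   resname_b, n_frames, frequency)` sorted by decreasing frequency, with
#'   attributes `n_frames_total` and `threshold`.
#' @export
contact_frequency_map <- function(records, n_frames_total, threshold = 0.10) {
  stopifnot(n_frames_total > 0)
  if (nrow(records) == 0) {
    out <- data.frame(chain_a = character(), resnum_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resnum_b = integer(), resname_b = character(),
                      n_frames = integer(), frequency = numeric())
  } else {
    key <- .residue_pair_key(records)
    present <- unique(data.frame(key = key, frame = records$frame,
                                 stringsAsFactors = FALSE))
    counts <- table(present$key)
    parts <- do.call(rbind, strsplit(names(counts), "||", fixed = TRUE))
    pa <- do.call(rbind, strsplit(parts[, 1], "|", fixed = TRUE))
    pb <- do.call(rbind, strsplit(parts[, 2], "|", fixed = TRUE))
    out <- data.frame(chain_a = pa[, 1], resnum_a = as.integer(pa[, 2]),
                      resname_a = pa[, 3],
                      chain_b = pb[, 1], resnum_b = as.integer(pb[, 2]),
                      resname_b = pb[, 3],
                      n_frames = as.integer(counts),
                      frequency = as.integer(counts) / n_frames_total,
                      stringsAsFactors = FALSE)
    out <- out[out$frequency >= threshold, , drop = FALSE]
    out <- out[order(-out$frequency, out$resnum_a, out$resnum_b), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_frames_total") <- n_frames_total
  attr(out, "threshold") <- threshold
  out
}

#' Dense matrix form of a contact-frequency map
#'
#' Rows/columns are labelled `RESNAME+resnum` and sorted by residue
#' number, ready for heatmap plotting (brighter = more persistent).
#'
#' @param fmap output of [contact_frequency_map()].
#' @return symmetric numeric matrix of frequencies.
#' @export
frequency_matrix <- function(fmap) {
  lab_a <- paste0(fmap$resname_a, fmap$resnum_a)
  lab_b <- paste0(fmap$resname_b, fmap$resnum_b)
  labs <- unique(data.frame(lab = c(lab_a, lab_b),
                            num = c(fmap$resnum_a, fmap$resnum_b)))
  labs <- labs[order(labs$num), ]
  m <- matrix(0, nrow(labs), nrow(labs),
              dimnames = list(labs$lab, labs$lab))
  for (i in seq_len(nrow(fmap))) {
    m[lab_a[i], lab_b[i]] <- fmap$frequency[i]
    m[lab_b[i], lab_a[i]] <- fmap$frequency[i]
  }
  m
}
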