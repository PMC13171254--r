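#' Rigid-body superposition and structural descriptors
#'
#' Kabsch least-squares superposition plus the per-frame descriptors used
#' to characterise compact-to-extended transitions: RMSD, per-residue RMSF,
#' radius of gyration, Shrake-Rupley SASA, analysis-window statistics,
#' probability densities and Savitzky-Golay smoothing.
#'
#' @name geometry
NULL

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' matched coordinate rows; `mobile` is mapped onto `target`.
#'
#' @param mobile,target matched coordinate matrices (n x 3, nm), n >= 3 and
#'   non-collinear.
#' @return a `superposition`: list with `rotation` (3x3, det = +1),
#'   `translation` (length-3, nm) and `rmsd` (nm) over the matched rows.
#'   The fitted point for row x is `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- matrix(mobile, ncol = 3)
  target <- matrix(target, ncol = 3)
  if (nrow(mobile) != nrow(target)) stop("matched sets differ in size")
  if (nrow(mobile) < 3) stop("degenerate superposition: fewer than 3 pairs")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  for (M in list(P, Q)) {
    sv <- svd(M)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12)) {
      stop("degenerate superposition: collinear selection")
    }
  }
  H <- crossprod(P, Q)           # 3x3
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = ct - drop(cm %*% R), rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition`.
#' @param coords n x 3 matrix, nm.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(matrix(coords, ncol = 3) %*% sp$rotation, 2, sp$translation, "+")
}

.rmsd_direct <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series
#'
#' Each frame is superposed onto the reference using `fit_region`, then the
#' RMSD is measured over `measure_region`. The reference defaults to the
#' first frame; fit and measure selections default to backbone heavy atoms
#' if those names exist, otherwise to all heavy atoms.
#'
#' @param traj a `vwf_trajectory`.
#' @param reference reference coordinates (atoms x 3 matrix matching the
#'   topology) or `NULL` for frame 1.
#' @param fit_region,measure_region `region_spec`s resolved on the topology;
#'   `NULL` selects backbone (N, CA, C, O) heavy atoms of the whole
#'   topology.
#' @return data.frame `(time_ns, value)` with attribute `metric = "rmsd"`,
#'   units nm.
#' @export
rmsd_series <- function(traj, reference = NULL, fit_region = NULL,
                        measure_region = NULL) {
  top <- traj$topology
  default_idx <- .backbone_indices(top)
  fit_idx <- if (is.null(fit_region)) default_idx else select_atoms(top, fit_region)
  mea_idx <- if (is.null(measure_region)) default_idx else select_atoms(top, measure_region)
  if (length(fit_idx) < 3) stop("fit selection too small")
  ref <- if (is.null(reference)) frame_coords(traj, 1) else as.matrix(reference)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    sp <- tryCatch(kabsch_superpose(x[fit_idx, , drop = FALSE],
                                    ref[fit_idx, , drop = FALSE]),
                   error = function(e) stop("frame ", i, ": ",
                                            conditionMessage(e)))
    xf <- apply_superposition(sp, x)
    .rmsd_direct(xf[mea_idx, , drop = FALSE], ref[mea_idx, , drop = FALSE])
  }, 0)
  .descriptor(vals, traj$times, "rmsd")
}

.backbone_indices <- function(top) {
  idx <- which(top$atoms$atom_name %in% c("N", "CA", "C", "O") & is_heavy(top))
  if (length(idx) >= 3) idx else which(is_heavy(top))
}

.descriptor <- function(values, times, metric) {
  out <- data.frame(time_ns = times, value = values)
  attr(out, "metric") <- metric
  out
}

#' Per-residue RMSF of C-alpha atoms
#'
#' Frames are first fitted to frame 1 on `fit_region`, the time-average
#' structure is computed, frames are re-fitted to that average, and the
#' fluctuation of each C-alpha about its mean position is reported.
#'
#' @param traj a `vwf_trajectory`.
#' @param selection `region_spec` whose C-alpha atoms are measured
#'   (`NULL` = all residues).
#' @param fit_region `region_spec` used for fitting (`NULL` = the measured
#'   C-alpha set).
#' @return data.frame `(chain, resnum, rmsf)`, nm.
#' @export
rmsf_per_residue <- function(traj, selection = NULL, fit_region = NULL) {
  top <- traj$topology
  ca <- which(top$atoms$atom_name == "CA" & is_heavy(top))
  if (!is.null(selection)) ca <- intersect(ca, select_atoms(top, selection))
  if (length(ca) == 0) stop("no C-alpha atoms in selection")
  fit_idx <- if (is.null(fit_region)) ca else select_atoms(top, fit_region)
  nf <- n_frames(traj)
  fitted <- array(NA_real_, c(nf, n_atoms(top), 3))
  ref <- frame_coords(traj, 1)
  for (i in seq_len(nf)) {
    x <- frame_coords(traj, i)
    sp <- kabsch_superpose(x[fit_idx, , drop = FALSE],
                           ref[fit_idx, , drop = FALSE])
    fitted[i, , ] <- apply_superposition(sp, x)
  }
  avg <- apply(fitted, c(2, 3), mean)
  for (i in seq_len(nf)) {
    x <- matrix(fitted[i, , ], ncol = 3)
    sp <- kabsch_superpose(x[fit_idx, , drop = FALSE],
                           avg[fit_idx, , drop = FALSE])
    fitted[i, , ] <- apply_superposition(sp, x)
  }
  avg <- apply(fitted, c(2, 3), mean)
  msf <- vapply(ca, function(j) {
    dx <- sweep(matrix(fitted[, j, ], ncol = 3), 2, avg[j, ])
    mean(rowSums(dx^2))
  }, 0)
  data.frame(chain = top$atoms$chain[ca], resnum = top$atoms$resnum[ca],
             rmsf = sqrt(msf))
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of atoms from their centre of
#' mass (set `masses = 1` for the unweighted variant).
#'
#' @param coords atoms x 3 matrix, nm.
#' @param masses per-atom masses (amu), recycled; must not sum to zero.
#' @return nm.
#' @export
radius_of_gyration <- function(coords, masses = 1) {
  coords <- matrix(coords, ncol = 3)
  if (nrow(coords) < 1) stop("radius of gyration of an empty set")
  m <- rep_len(masses, nrow(coords))
  M <- sum(m)
  if (M <= 0) stop("zero total mass")
  com <- colSums(coords * m) / M
  dx <- sweep(coords, 2, com)
  sqrt(sum(m * rowSums(dx^2)) / M)
}

#' Radius-of-gyration series over a trajectory
#'
#' @param traj a `vwf_trajectory`.
#' @param region `region_spec` (`NULL` = all heavy atoms).
#' @param mass_weighted use element masses (default) or unit weights.
#' @return data.frame `(time_ns, value)`, metric `"rg"`, nm.
#' @export
rg_series <- function(traj, region = NULL, mass_weighted = TRUE) {
  top <- traj$topology
  idx <- if (is.null(region)) which(is_heavy(top)) else select_atoms(top, region)
  m <- if (mass_weighted) element_masses(top$atoms$element[idx]) else 1
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    radius_of_gyration(frame_coords(traj, i)[idx, , drop = FALSE], m)
  }, 0)
  .descriptor(vals, traj$times, "rg")
}

# deterministic golden-spiral quadrature points on the unit sphere
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic rolling-probe quadrature: each atom's accessible area is the
#' fraction of points on its probe-expanded sphere not occluded by any
#' neighbour's expanded sphere, times `4*pi*(r + probe)^2`.
#'
#' @param coords atoms x 3 matrix, nm.
#' @param elements element symbols (for Bondi radii).
#' @param probe_radius probe radius, nm (water: 0.14).
#' @param n_points quadrature points per atom.
#' @param radii optional explicit per-atom radii (nm), overriding elements.
#' @param default_radius fallback for unknown elements (`NA` = error).
#' @return list with `total` (nm^2) and `per_atom` (nm^2 vector).
#' @export
sasa_shrake_rupley <- function(coords, elements, probe_radius = 0.14,
                               n_points = 960, radii = NULL,
                               default_radius = 0.170) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(radii)) radii <- vdw_radii(elements, default = default_radius)
  radii <- rep_len(radii, n)
  rx <- radii + probe_radius
  pts <- .sphere_points(n_points)
  d2 <- crossdist2(coords, coords)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rx[i] + rx)^2)
    nb <- nb[nb != i]
    surf <- sweep(pts * rx[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(surf, 2, coords[j, ])
      free <- free & (rowSums(dj * dj) >= rx[j]^2)
      if (!any(free)) break
    }
    per_atom[i] <- 4 * pi * rx[i]^2 * mean(free)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' SASA series over a trajectory
#'
#' @param traj a `vwf_trajectory`.
#' @param region `region_spec` (`NULL` = all heavy atoms).
#' @param stride evaluate every `stride`-th frame (SASA is the one
#'   quadratic-cost descriptor; the default keeps long runs fast).
#' @param ... passed to [sasa_shrake_rupley()].
#' @return data.frame `(time_ns, value)`, metric `"sasa"`, nm^2.
#' @export
sasa_series <- function(traj, region = NULL, stride = 1, ...) {
  top <- traj$topology
  idx <- if (is.null(region)) which(is_heavy(top)) else select_atoms(top, region)
  frames <- seq(1, n_frames(traj), by = stride)
  vals <- vapply(frames, function(i) {
    sasa_shrake_rupley(frame_coords(traj, i)[idx, , drop = FALSE],
                       top$atoms$element[idx], ...)$total
  }, 0)
  .descriptor(vals, traj$times[frames], "sasa")
}

#' Define an analysis window
#'
#' Half-open time window `[t_start, t_end)` in ns, e.g. the early
#' (0-100 ns) and late (400-500 ns) stages of a 500-ns run.
#'
#' @param name label.
#' @param t_start,t_end ns, `t_start < t_end`.
#' @export
analysis_window <- function(name, t_start, t_end) {
  if (!(t_start < t_end)) stop("t_start must be < t_end")
  structure(list(name = name, t_start = t_start, t_end = t_end),
            class = "analysis_window")
}

#' Statistics of a descriptor series over a time window
#'
#' @param series data.frame `(time_ns, value)`.
#' @param window an `analysis_window`.
#' @return list `mean`, `sd` (0 when n = 1), `n_frames`.
#' @export
window_stats <- function(series, window) {
  sel <- series$time_ns >= window$t_start & series$time_ns < window$t_end
  if (!any(sel)) stop("window '", window$name, "' contains no frames")
  v <- series$value[sel]
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n_frames = length(v))
}

#' Probability density of a descriptor
#'
#' @param values numeric sample.
#' @param method `"histogram"` or `"gaussian_kde"`.
#' @param n_bins histogram bin count.
#' @return data.frame `(x, density)`; the density integrates to 1 over the
#'   grid (trapezoid rule for the KDE, exact for the histogram).
#' @export
probability_density <- function(values, method = c("histogram", "gaussian_kde"),
                                n_bins = 50) {
  method <- match.arg(method)
  if (method == "histogram") {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    h <- graphics::hist(values, breaks = br, plot = FALSE)
    data.frame(x = h$mids, density = h$density)
  } else {
    if (length(values) < 2) stop("KDE needs at least 2 values")
    d <- stats::density(values)
    data.frame(x = d$x, density = d$y)
  }
}

#' Savitzky-Golay smoothing
#'
#' Output has the input length; the ends are handled with the asymmetric
#' end-window polynomial fits of the classic filter, so polynomials up to
#' `polyorder` are reproduced exactly everywhere.
#'
#' @param values numeric series.
#' @param window_length odd integer, `> polyorder`, `<= length(values)`.
#' @param polyorder polynomial order.
#' @return smoothed series.
#' @export
savgol_smooth <- function(values, window_length = 51, polyorder = 3) {
  n <- length(values)
  if (window_length %% 2 == 0 || window_length <= polyorder ||
      window_length > n) {
    stop("window_length must be odd, > polyorder and <= series length")
  }
  as.numeric(signal::sgolayfilt(values, p = polyorder, n = window_length))
}

#' Largest valid Savitzky-Golay window for a series
#'
#' @param n series length.
#' @param preferred preferred (odd) window.
#' @param polyorder polynomial order.
#' @return an odd window length usable with [savgol_smooth()], or `NA` when
#'   the series is too short to smooth at this order.
#' @export
clamp_savgol_window <- function(n, preferred = 51, polyorder = 3) {
  if (is.na(preferred)) return(NA_integer_)
  w <- min(preferred, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  if (w <= polyorder) return(NA_integer_)
  w
}
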