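#' Flow calibration and steered-pull force analysis
#'
#' Maps pull velocities onto physiological shear via the Newtonian
#' relation tau = mu * gamma_dot and the nominal-rate definition
#' gamma_dot = v / L, and analyses force-extension profiles from
#' constant-velocity pulls (rupture force = peak force prior to
#' detachment).
#'
#' @name pullstats
NULL

#' Force unit conversion: 1 kJ mol^-1 nm^-1 in pN
#' @export
PN_PER_KJ_MOL_NM <- 1.66054

#' Convert shear stress between dyn/cm^2 and Pa
#' @param tau_dyn_cm2 shear stress in dyn/cm^2.
#' @export
dyn_cm2_to_pa <- function(tau_dyn_cm2) tau_dyn_cm2 * 0.1

#' Convert force between kJ mol^-1 nm^-1 and pN
#' @param f force in kJ mol^-1 nm^-1.
#' @export
kj_mol_nm_to_pn <- function(f) f * PN_PER_KJ_MOL_NM

#' @rdname kj_mol_nm_to_pn
#' @param f_pn force in pN.
#' @export
pn_to_kj_mol_nm <- function(f_pn) f_pn / PN_PER_KJ_MOL_NM

#' Flow-calibration parameters
#'
#' Defaults: dynamic viscosity of water at 310 K (6.93e-4 Pa s),
#' solvent box length 150 nm, pull velocity 0.01 nm/ps, spring constant
#' 1000 kJ mol^-1 nm^-2.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param box_length characteristic solvent box length, nm.
#' @param v_pull pull velocity, nm/ps.
#' @param k_spring spring constant, kJ mol^-1 nm^-2.
#' @export
flow_params <- function(mu = 6.93e-4, box_length = 150, v_pull = 0.01,
                        k_spring = 1000) {
  stopifnot(mu > 0, box_length > 0)
  structure(list(mu = mu, box_length = box_length, v_pull = v_pull,
                 k_spring = k_spring), class = "flow_params")
}

#' Shear rate from shear stress (Newtonian fluid)
#'
#' @param tau shear stress, Pa.
#' @param mu dynamic viscosity, Pa s.
#' @return shear rate, 1/s.
#' @export
shear_rate_from_stress <- function(tau, mu = 6.93e-4) {
  if (any(mu <= 0)) stop("viscosity must be positive")
  tau / mu
}

#' Shear stress from shear rate (Newtonian fluid)
#'
#' @param gamma_dot shear rate, 1/s.
#' @param mu dynamic viscosity, Pa s.
#' @return shear stress, Pa.
#' @export
stress_from_shear_rate <- function(gamma_dot, mu = 6.93e-4) {
  if (any(mu <= 0)) stop("viscosity must be positive")
  gamma_dot * mu
}

#' Nominal shear rate of a constant-velocity pull
#'
#' `gamma_dot = v / L` with the velocity in m/s and the box length in m
#' (1 nm/ps = 1000 m/s).
#'
#' @param v_pull pull velocity, nm/ps.
#' @param box_length solvent box length, nm.
#' @return shear rate, 1/s.
#' @export
nominal_shear_rate <- function(v_pull, box_length = 150) {
  if (any(box_length <= 0)) stop("box length must be positive")
  (v_pull * 1000) / (box_length * 1e-9)
}

#' Acceleration factor of the simulated flow regime
#'
#' Ratio of the nominal pull shear rate to a reference physiological
#' shear rate `tau_ref / mu`.
#'
#' @param v_pull pull velocity, nm/ps.
#' @param box_length solvent box length, nm.
#' @param tau_ref reference shear stress, Pa.
#' @param mu dynamic viscosity, Pa s.
#' @return dimensionless factor.
#' @export
acceleration_factor <- function(v_pull = 0.01, box_length = 150,
                                tau_ref = 128, mu = 6.93e-4) {
  ref <- shear_rate_from_stress(tau_ref, mu)
  if (any(ref == 0)) stop("reference shear rate is zero")
  nominal_shear_rate(v_pull, box_length) / ref
}

#' Read a two-column pull log
#'
#' Accepts the xvg dialect (lines starting with `#` or `@` skipped) and
#' plain CSV/whitespace tables of (time, force).
#'
#' @param path file path.
#' @return data.frame `(time, force)` in the file's units.
#' @export
read_pull_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines))) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE)
  stats::setNames(tab[, 1:2], c("time", "force"))
}

#' Force-extension profile of a steered pull
#'
#' Extension is the distance between the two pulled sites per frame; force
#' is taken from a spring log (kJ mol^-1 nm^-1) when given, otherwise
#' computed from the spring law `F = k * (restraint separation - site
#' separation along the pull axis)` with the restraint moving at `v_pull`.
#' Forces are reported in pN.
#'
#' @param traj a `vwf_trajectory`.
#' @param site_a,site_b atom serial numbers of the pulled sites.
#' @param force_log optional per-frame force vector, kJ mol^-1 nm^-1
#'   (length = frames).
#' @param k_spring spring constant, kJ mol^-1 nm^-2.
#' @param v_pull restraint velocity, nm/ps.
#' @param axis pull axis (1 = x, 2 = y, 3 = z) for the spring-law path.
#' @return a `force_extension_profile`: data.frame `(time_ns,
#'   extension_nm, force_pN)`.
#' @export
force_extension_profile <- function(traj, site_a, site_b, force_log = NULL,
                                    k_spring = 1000, v_pull = 0.01,
                                    axis = 2) {
  ia <- match(site_a, traj$topology$atoms$serial)
  ib <- match(site_b, traj$topology$atoms$serial)
  if (is.na(ia) || is.na(ib)) stop("pull site serial not found in topology")
  nf <- n_frames(traj)
  ext <- vapply(seq_len(nf), function(i) {
    x <- frame_coords(traj, i)
    sqrt(sum((x[ia, ] - x[ib, ])^2))
  }, 0)
  if (!is.null(force_log)) {
    if (length(force_log) != nf) {
      stop("force log length ", length(force_log),
           " does not match ", nf, " frames")
    }
    force_pn <- kj_mol_nm_to_pn(force_log)
  } else {
    sep_axis <- vapply(seq_len(nf), function(i) {
      x <- frame_coords(traj, i)
      abs(x[ia, axis] - x[ib, axis])
    }, 0)
    restraint <- sep_axis[1] + v_pull * 1000 * (traj$times - traj$times[1])
    force_pn <- kj_mol_nm_to_pn(k_spring * (restraint - sep_axis))
  }
  out <- data.frame(time_ns = traj$times, extension_nm = ext,
                    force_pN = force_pn)
  class(out) <- c("force_extension_profile", class(out))
  out
}

#' Rupture events in a force-extension profile
#'
#' Detachment is the first frame where the force falls below
#' `drop_fraction` times the running peak and stays below it for
#' `sustain_frames` consecutive frames; the rupture force is the maximum
#' force before that frame. With `all_events = TRUE` the scan restarts
#' after each detachment.
#'
#' @param profile data.frame with `force_pN` (and optionally `time_ns`,
#'   `extension_nm`).
#' @param drop_fraction force-collapse fraction of the running peak.
#' @param sustain_frames frames the collapse must persist.
#' @param all_events return every event instead of the first.
#' @return `NULL` when no detachment is found; otherwise a data.frame
#'   `(peak_force, peak_time, peak_extension, drop_fraction)` with one row
#'   per event.
#' @export
rupture_force <- function(profile, drop_fraction = 0.5, sustain_frames = 10,
                          all_events = FALSE) {
  f <- profile$force_pN
  n <- length(f)
  if (n == 0) stop("empty profile")
  times <- if (!is.null(profile$time_ns)) profile$time_ns else seq_len(n)
  ext <- if (!is.null(profile$extension_nm)) profile$extension_nm else
    rep(NA_real_, n)
  events <- list()
  start <- 1
  repeat {
    peak <- -Inf
    peak_i <- start
    detach <- NA_integer_
    i <- start
    while (i <= n) {
      if (f[i] > peak) {
        peak <- f[i]
        peak_i <- i
      }
      if (peak > 0 && f[i] < drop_fraction * peak) {
        run_end <- min(n, i + sustain_frames - 1)
        if (run_end - i + 1 >= sustain_frames &&
            all(f[i:run_end] < drop_fraction * peak)) {
          detach <- i
          break
        }
      }
      i <- i + 1
    }
    if (is.na(detach)) break
    events[[length(events) + 1]] <- data.frame(
      peak_force = peak, peak_time = times[peak_i],
      peak_extension = ext[peak_i], drop_fraction = drop_fraction)
    if (!all_events) break
    start <- detach + sustain_frames
    if (start > n) break
  }
  if (!length(events)) return(NULL)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
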