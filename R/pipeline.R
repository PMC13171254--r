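#' Analysis pipelines
#'
#' Orchestration of the three analyses run on mechanomodule trajectories:
#' equilibrium ("free") descriptor analysis, flow-conditioned uncoiling
#' analysis with replicate-concatenated contact maps, and steered-pull
#' force analysis. Each run writes tidy CSV/JSON artifacts plus a manifest;
#' CSV/JSON are the contract (plots are optional extras).
#'
#' @name pipeline
NULL

.write_manifest <- function(out_dir, stage, config, warnings = character(0),
                            wall_time = NA_real_) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("vwfshield")),
    config = config,
    wall_time_s = wall_time,
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

.tidy_descriptors <- function(series_list) {
  do.call(rbind, lapply(names(series_list), function(m) {
    s <- series_list[[m]]
    data.frame(metric = m, time_ns = s$time_ns, value = s$value)
  }))
}

#' Equilibrium (free) descriptor analysis
#'
#' Computes the descriptor suite used to characterise compact ensembles:
#' backbone RMSD, radius of gyration, SASA, intramolecular hydrogen-bond
#' count, per-residue C-alpha RMSF, arm-to-core interaction counts and
#' (when a receptor reference is given) the steric-clash series, plus
#' early/late window statistics and probability densities.
#'
#' @param traj a `vwf_trajectory`.
#' @param reference receptor-complex `vwf_structure`, or `NULL` to skip
#'   clash analysis.
#' @param regions named list of `region_spec`s; needs `naim`, `caim` and
#'   `a1_core` entries for the interaction analysis (missing entries skip
#'   that stage).
#' @param glycans glycan annotations.
#' @param out_dir output directory.
#' @param windows list of `analysis_window`s (default: early 0-100 ns and
#'   late 400-500 ns).
#' @param sasa_stride frame stride for the SASA series.
#' @param clash_cfg a [clash_config()] used when `reference` is given.
#' @param label run label recorded in outputs.
#' @return (invisibly) list with `descriptors`, `window_stats`, `rmsf`,
#'   `interactions`, `clash`, `densities`.
#' @export
run_free_analysis <- function(traj, reference = NULL, regions = list(),
                              glycans = list(), out_dir,
                              windows = list(analysis_window("R1", 0, 100),
                                             analysis_window("R5", 400, 500)),
                              sasa_stride = 5, clash_cfg = NULL,
                              label = "free") {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warn <- character(0)
  series <- list(
    rmsd = rmsd_series(traj),
    rg = rg_series(traj),
    sasa = sasa_series(traj, stride = sasa_stride)
  )
  hb_intra <- interaction_timeseries(traj, seq_len(n_atoms(traj$topology)),
                                     seq_len(n_atoms(traj$topology)),
                                     sb_criteria = NULL,
                                     min_residue_separation = 2)
  series$hbond_count <- data.frame(time_ns = hb_intra$time_ns,
                                   value = hb_intra$hb)
  desc <- .tidy_descriptors(series)
  desc$label <- label
  utils::write.csv(desc, file.path(out_dir, "descriptors.csv"),
                   row.names = FALSE)

  ws <- list()
  for (w in windows) {
    for (m in names(series)) {
      st <- tryCatch(window_stats(series[[m]], w), error = function(e) NULL)
      if (is.null(st)) {
        warn <- c(warn, paste0("window ", w$name, " empty for ", m))
        next
      }
      ws[[length(ws) + 1]] <- data.frame(window = w$name, metric = m,
                                         mean = st$mean, sd = st$sd,
                                         n_frames = st$n_frames)
    }
  }
  ws <- do.call(rbind, ws)
  utils::write.csv(ws, file.path(out_dir, "window_stats.csv"),
                   row.names = FALSE)

  dens <- do.call(rbind, lapply(names(series), function(m) {
    d <- probability_density(series[[m]]$value, "histogram")
    data.frame(metric = m, x = d$x, density = d$density)
  }))
  utils::write.csv(dens, file.path(out_dir, "densities.csv"),
                   row.names = FALSE)

  rmsf <- rmsf_per_residue(traj)
  utils::write.csv(rmsf, file.path(out_dir, "rmsf.csv"), row.names = FALSE)

  inter <- NULL
  if (all(c("naim", "caim", "a1_core") %in% names(regions))) {
    arms <- merge_regions("aim", regions$naim, regions$caim)
    inter <- interaction_timeseries(traj, arms, regions$a1_core)
    utils::write.csv(inter, file.path(out_dir, "interactions_aim_a1.csv"),
                     row.names = FALSE)
  }

  clash <- NULL
  if (!is.null(reference)) {
    cfg <- if (is.null(clash_cfg)) clash_config() else clash_cfg
    clash <- clash_scan(traj, reference, cfg, glycans)
    .write_clash_csv(clash, file.path(out_dir, "clash.csv"))
  }
  .write_manifest(out_dir, "free",
                  list(label = label, n_frames = n_frames(traj),
                       n_atoms = n_atoms(traj$topology),
                       sasa_stride = sasa_stride,
                       windows = vapply(windows, `[[`, "", "name")),
                  warn, proc.time()[["elapsed"]] - t0)
  invisible(list(descriptors = series, window_stats = ws, rmsf = rmsf,
                 interactions = inter, clash = clash, densities = dens))
}

.write_clash_csv <- function(clash, path) {
  long <- do.call(rbind, lapply(colnames(clash$per_region), function(rn) {
    data.frame(time_ns = clash$times, region = rn,
               count = clash$per_region[, rn],
               smoothed = if (is.null(clash$smoothed)) NA_real_ else
                 clash$smoothed[, rn])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Flow-conditioned uncoiling analysis
#'
#' Per-replicate arm-to-core interaction time series (reported as mean and
#' sd across replicates), replicate-concatenated contact records filtered
#' at the persistence threshold into a contact-frequency map, and the
#' per-region steric-clash series with Savitzky-Golay smoothing.
#'
#' @param replicates list of `vwf_trajectory` replicates (same topology).
#' @param reference receptor-complex reference structure.
#' @param regions named list with `naim`, `caim`, `a1_core`.
#' @param glycans glycan annotations.
#' @param out_dir output directory.
#' @param threshold persistence threshold for the frequency map.
#' @param clash_cfg a [clash_config()]; defaults to arm shield regions.
#' @return (invisibly) list with `interaction_mean`, `interaction_series`,
#'   `records`, `frequency_map`, `clash` (per replicate), `clash_mean`.
#' @export
run_flow_analysis <- function(replicates, reference, regions,
                              glycans = list(), out_dir, threshold = 0.10,
                              clash_cfg = NULL) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(length(replicates) >= 1)
  arms <- merge_regions("aim", regions$naim, regions$caim)
  inter <- lapply(replicates, interaction_timeseries, group_a = arms,
                  group_b = regions$a1_core)
  inter_mean <- average_series(inter, "total")
  utils::write.csv(inter_mean, file.path(out_dir, "interactions_mean.csv"),
                   row.names = FALSE)
  records <- lapply(replicates, collect_contacts, group_a = arms,
                    group_b = regions$a1_core)
  combined <- concatenate_replicates(records,
                                     vapply(replicates, n_frames, 0L))
  utils::write.csv(combined$records, file.path(out_dir, "contacts.csv"),
                   row.names = FALSE)
  fmap <- contact_frequency_map(combined$records, combined$n_frames_total,
                                threshold)
  utils::write.csv(fmap, file.path(out_dir, "contact_frequency.csv"),
                   row.names = FALSE)
  if (nrow(fmap)) {
    utils::write.csv(frequency_matrix(fmap),
                     file.path(out_dir, "contact_frequency_matrix.csv"))
  }
  cfg <- if (is.null(clash_cfg)) {
    clash_config(shield_regions = list(naim = regions$naim,
                                       caim = regions$caim))
  } else clash_cfg
  clash <- lapply(replicates, clash_scan, reference = reference,
                  config = cfg, glycans = glycans)
  for (i in seq_along(clash)) {
    .write_clash_csv(clash[[i]],
                     file.path(out_dir, sprintf("clash_rep%d.csv", i)))
  }
  clash_mean <- average_series(lapply(clash, function(cs) {
    data.frame(time_ns = cs$times, total = cs$total)
  }), "total")
  utils::write.csv(clash_mean, file.path(out_dir, "clash_mean.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "flow",
                  list(n_replicates = length(replicates),
                       n_frames_total = combined$n_frames_total,
                       threshold = threshold),
                  character(0), proc.time()[["elapsed"]] - t0)
  invisible(list(interaction_mean = inter_mean, interaction_series = inter,
                 records = combined, frequency_map = fmap, clash = clash,
                 clash_mean = clash_mean))
}

#' Steered-pull force analysis
#'
#' Force-extension profiles per run (triplicate runs averaged on the
#' common time grid), rupture events, and optional interaction/clash
#' series for the first run.
#'
#' @param runs list of runs; each a list with `traj` and optionally
#'   `force_log` (per-frame force, kJ mol^-1 nm^-1).
#' @param site_a,site_b pulled-site atom serial numbers.
#' @param out_dir output directory.
#' @param k_spring,v_pull spring law parameters when no force log exists.
#' @param reference,regions,glycans optional; when all given, clash and
#'   interaction series of run 1 are emitted as in the flow analysis.
#' @param drop_fraction,sustain_frames rupture detection parameters.
#' @return (invisibly) list with `profiles`, `profile_mean`, `events`,
#'   `clash`, `interactions`.
#' @export
run_steered_analysis <- function(runs, site_a, site_b, out_dir,
                                 k_spring = 1000, v_pull = 1e-4,
                                 reference = NULL, regions = NULL,
                                 glycans = list(), drop_fraction = 0.5,
                                 sustain_frames = 10) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- lapply(runs, function(r) {
    force_extension_profile(r$traj, site_a, site_b,
                            force_log = r$force_log,
                            k_spring = k_spring, v_pull = v_pull)
  })
  for (i in seq_along(profiles)) {
    utils::write.csv(profiles[[i]],
                     file.path(out_dir, sprintf("force_extension_run%d.csv",
                                                i)),
                     row.names = FALSE)
  }
  prof_mean <- average_series(lapply(profiles, function(p) {
    data.frame(time_ns = p$time_ns, force_pN = p$force_pN)
  }), "force_pN")
  utils::write.csv(prof_mean, file.path(out_dir, "force_mean.csv"),
                   row.names = FALSE)
  events <- lapply(seq_along(profiles), function(i) {
    ev <- rupture_force(profiles[[i]], drop_fraction, sustain_frames)
    if (is.null(ev)) NULL else cbind(run = i, ev)
  })
  events <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  jsonlite::write_json(
    if (is.null(events)) list() else events,
    file.path(out_dir, "rupture_events.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  clash <- NULL
  inter <- NULL
  if (!is.null(reference) && !is.null(regions)) {
    cfg <- clash_config(shield_regions = list(naim = regions$naim,
                                              caim = regions$caim))
    clash <- clash_scan(runs[[1]]$traj, reference, cfg, glycans)
    .write_clash_csv(clash, file.path(out_dir, "clash_run1.csv"))
    arms <- merge_regions("aim", regions$naim, regions$caim)
    inter <- interaction_timeseries(runs[[1]]$traj, arms, regions$a1_core)
    utils::write.csv(inter, file.path(out_dir, "interactions_run1.csv"),
                     row.names = FALSE)
  }
  .write_manifest(out_dir, "steered",
                  list(n_runs = length(runs), k_spring = k_spring,
                       v_pull = v_pull, drop_fraction = drop_fraction,
                       sustain_frames = sustain_frames),
                  character(0), proc.time()[["elapsed"]] - t0)
  invisible(list(profiles = profiles, profile_mean = prof_mean,
                 events = events, clash = clash, interactions = inter))
}

#' Flow-calibration report
#'
#' Maps shear stresses to shear rates via the Newtonian relation and
#' reports the nominal pull shear rate and its acceleration factor over
#' the reference (pathological) stress.
#'
#' @param taus_dyn_cm2 shear stresses to tabulate, dyn/cm^2.
#' @param params a [flow_params()].
#' @param tau_ref_dyn_cm2 reference stress for the acceleration factor.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list with `table` (data.frame of stress/rate rows),
#'   `nominal_rate`, `acceleration`.
#' @export
run_flowcalc <- function(taus_dyn_cm2 = c(70, 1280), params = flow_params(),
                         tau_ref_dyn_cm2 = 1280, out_dir = NULL) {
  tau_pa <- dyn_cm2_to_pa(taus_dyn_cm2)
  tab <- data.frame(
    tau_dyn_cm2 = taus_dyn_cm2,
    tau_pa = tau_pa,
    shear_rate_s1 = shear_rate_from_stress(tau_pa, params$mu)
  )
  nominal <- nominal_shear_rate(params$v_pull, params$box_length)
  accel <- acceleration_factor(params$v_pull, params$box_length,
                               dyn_cm2_to_pa(tau_ref_dyn_cm2), params$mu)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "shear_calibration.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(nominal_shear_rate_s1 = nominal,
                              acceleration_factor = accel,
                              mu_pa_s = params$mu,
                              box_length_nm = params$box_length,
                              v_pull_nm_ps = params$v_pull),
                         file.path(out_dir, "flowcalc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = tab, nominal_rate = nominal, acceleration = accel)
}

#' Compare descriptor summaries against a deposited-data summary
#'
#' Long atomistic trajectories (hundreds of ns) are required to reproduce
#' published descriptor values; when a directory containing a
#' `descriptor_summary.csv` (columns `metric`, `value`) derived from such
#' deposited data is available locally, this compares the pipeline's
#' window means against it. Without the deposit the function reports the
#' comparison as unavailable rather than failing.
#'
#' @param window_stats data.frame from [run_free_analysis()]
#'   (`window_stats` element).
#' @param deposit_dir directory with `descriptor_summary.csv`, or `NULL`.
#' @param window window name to compare (default the late window).
#' @return list with `available`, and when available a `comparison`
#'   data.frame `(metric, value, reference, rel_diff)`.
#' @export
reference_summary_comparison <- function(window_stats, deposit_dir = NULL,
                                         window = "R5") {
  path <- if (is.null(deposit_dir)) "" else
    file.path(deposit_dir, "descriptor_summary.csv")
  if (!nzchar(path) || !file.exists(path)) {
    return(list(available = FALSE,
                message = "no deposited-data summary available"))
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  ours <- window_stats[window_stats$window == window, c("metric", "mean")]
  m <- merge(ours, ref, by = "metric")
  m$rel_diff <- (m$mean - m$value) / m$value
  list(available = TRUE,
       comparison = data.frame(metric = m$metric, value = m$mean,
                               reference = m$value, rel_diff = m$rel_diff))
}
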