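# Scripted experiment harness: the two simulation designs probing motion
# tracking (tracking accuracy vs motion scale; 1D vs 3D binning under
# thoracoabdominal asynchrony) and the end-to-end phantom study.

#' Ground-truth displacement per beat, relative to a reference beat
#'
#' @param phantom a `cardio_phantom`.
#' @param beats a `beat_index` (midpoint times are used).
#' @param reference row index of the reference beat.
#' @return matrix (n_beats x 3) of true displacements, mm.
#' @export
true_beat_displacement <- function(phantom, beats, reference = 1) {
  tm <- (beats$trigger_ms + beats$next_trigger_ms) / 2
  d <- phantom$displacement(tm)
  sweep(d, 2, d[reference, ])
}

# truth bins by the SI displacement: EE = top quartile, EI = bottom quartile
truth_quartile_bins <- function(dx) {
  q <- stats::quantile(dx, c(0.25, 0.75), names = FALSE)
  list(EE = which(dx >= q[2]), EI = which(dx <= q[1]))
}

#' Tracking accuracy versus motion scale (4 mm tracking resolution)
#'
#' Renders per-beat phantom volumes at 1 mm-class in-plane resolution,
#' low-passes them to the 4 mm tracking grid (block averaging), runs the 3D
#' motion tracker and reports the per-beat displacement RMSE against the
#' known sinusoidal motion, for small and large superior-inferior ranges.
#'
#' @param motion_ranges_mm half-ranges of SI motion to test (mm); a range of
#'   `r` means motion spanning -r..r.
#' @param tracking_res_mm tracking resolution (mm).
#' @param n_beats heartbeats per configuration.
#' @param seed integer seed.
#' @param noise_sigma image-domain noise added to the rendered volumes.
#' @return data.frame (range_mm, rmse_mm, rmse_si_mm, corr_si, n_beats).
#' @export
benchmark_tracking_scale <- function(motion_ranges_mm = c(2, 8), tracking_res_mm = 4,
                             n_beats = 40, seed = 1, noise_sigma = 0.01) {
  rows <- lapply(motion_ranges_mm, function(rg) {
    cfg <- phantom_config(matrix_size = c(256, 256, 30),
                          fov_mm = c(256, 256, 120),
                          n_coils = 1,
                          resp_depth_mm = 2 * rg,
                          resp_asymmetry = 1,       # sinusoidal SI motion
                          resp_jitter_frac = 0,
                          rsa_amplitude = 0,
                          noise_sigma = 0,
                          seed = seed)
    ph <- make_phantom(cfg)
    bt <- ph$beat_times_ms
    tm <- (bt[seq_len(n_beats)] + bt[seq_len(n_beats) + 1]) / 2
    fac <- round(tracking_res_mm / ph$spacing)
    fac[fac < 1] <- 1
    dims <- ceiling(cfg$matrix_size / fac)
    vols <- array(0, c(dims, n_beats))
    noise <- with_local_seed(seed + 11L, stats::rnorm(prod(dims) * n_beats, 0, noise_sigma))
    dim(noise) <- c(dims, n_beats)
    for (b in seq_len(n_beats)) {
      d <- ph$displacement(tm[b])[1, ]
      fine <- ph$render_state(0, d)          # diastolic anatomy: respiratory-only
      vols[, , , b] <- downsample3(fine, fac) + noise[, , , b]
    }
    trace <- track_motion(vols, ph$spacing * fac, reference = 1)
    truth <- ph$displacement(tm)
    truth <- sweep(truth, 2, truth[1, ])
    est <- as.matrix(trace[, c("dx_mm", "dy_mm", "dz_mm")])
    err <- est - truth
    data.frame(range_mm = rg,
               rmse_mm = sqrt(mean(rowSums(err^2))),
               rmse_si_mm = sqrt(mean(err[, 1]^2)),
               corr_si = if (stats::sd(truth[, 1]) > 0)
                 stats::cor(est[, 1], truth[, 1]) else NA_real_,
               n_beats = n_beats)
  })
  do.call(rbind, rows)
}

# shared small-scan simulation used by the asynchrony benchmark
asynchrony_scan <- function(asynchrony_rad, seed, duration_s = 60) {
  cfg <- phantom_config(matrix_size = c(48, 48, 16),
                        fov_mm = c(192, 192, 96),
                        n_coils = 4,
                        asynchrony_phase_rad = asynchrony_rad,
                        seed = seed)
  ph <- make_phantom(cfg)
  sch <- circus_schedule(cfg$matrix_size[2:3])
  bundle <- simulate_acquisition(ph, sch, duration_s)
  beats <- sort_beats(bundle)
  low <- lowres_beat_volumes(bundle, beats)
  trace3 <- track_motion(low$volumes, low$spacing)
  trace1 <- self_gating_1d(bundle, beats)
  truth <- true_beat_displacement(ph, beats)
  list(phantom = ph, bundle = bundle, beats = beats,
       trace3 = trace3, trace1 = trace1, truth = truth)
}

bin_dice_vs_truth <- function(values, truth_bins, seed) {
  b <- kmeans4(values, restarts = 10, seed = seed)
  mean(c(dice_coefficient(which(b$labels == which(b$phase_names == "EE")), truth_bins$EE),
         dice_coefficient(which(b$labels == which(b$phase_names == "EI")), truth_bins$EI)))
}

#' 1D versus 3D respiratory binning under thoracoabdominal asynchrony
#'
#' Simulates small free-breathing scans in which the chest wall (which
#' drives the 1D self-gating projection signal) lags the heart by a
#' configurable phase. Both the 3D motion-tracking trace and the 1D
#' self-gating trace are k-means binned into four phases; the Dice overlap
#' of the predicted EE/EI bins against ground-truth bins (quartiles of the
#' true SI heart displacement) is reported per method.
#'
#' @param seeds integer seeds (>= 3) for replicate scans.
#' @param asynchrony_levels phase lags in radians (0 = synchronous).
#' @param duration_s scan length per replicate.
#' @return data.frame (asynchrony_rad, seed, dice_3d, dice_1d); attribute
#'   `summary` holds per-level means.
#' @export
benchmark_asynchrony <- function(seeds = 1:3, asynchrony_levels = c(0, pi / 2),
                             duration_s = 60) {
  if (length(seeds) < 3) stop("need at least 3 seeds")
  rows <- list()
  for (a in asynchrony_levels) {
    for (s in seeds) {
      scan <- asynchrony_scan(a, s, duration_s)
      dx <- scan$truth[, 1]
      if (stats::sd(dx) < 1e-6) {
        rows[[length(rows) + 1]] <- data.frame(asynchrony_rad = a, seed = s,
                                               dice_3d = NaN, dice_1d = NaN,
                                               flag = "no-respiration")
        next
      }
      tb <- truth_quartile_bins(dx)
      d3 <- bin_dice_vs_truth(scan$trace3, tb, seed = s)
      d1 <- bin_dice_vs_truth(matrix(scan$trace1$value_mm, ncol = 1), tb, seed = s)
      rows[[length(rows) + 1]] <- data.frame(asynchrony_rad = a, seed = s,
                                             dice_3d = d3, dice_1d = d1,
                                             flag = "")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(cbind(dice_3d, dice_1d) ~ asynchrony_rad,
                                           out[out$flag == "", ], mean)
  out
}

#' Manual-style RV seed circles derived from the phantom geometry
#'
#' Stands in for the operator's covering circle: centred on the RV cavity
#' and large enough to cover it, on the slices the RV spans.
#'
#' @param phantom a `cardio_phantom`.
#' @param margin_mm extra covering radius.
#' @return data.frame (slice, cx, cy, r_mm, ok).
#' @export
make_rv_seed <- function(phantom, margin_mm = 6) {
  cfg <- phantom$config
  rv <- cfg$rv_geometry
  n <- cfg$matrix_size; sp <- phantom$spacing
  c0 <- phantom$center_voxel0
  cx <- c0[1] + 1 + rv$center[1] / sp[1]
  cy <- c0[2] + 1 + rv$center[2] / sp[2]
  zmm <- (seq_len(n[3]) - 1 - c0[3]) * sp[3]
  slices <- which(abs(zmm - rv$center[3]) <= rv$radii_ed[3] * 0.9)
  data.frame(slice = slices, cx = cx, cy = cy,
             r_mm = max(rv$radii_ed[1:2]) + rv$wall_mm + margin_mm, ok = TRUE)
}

#' End-to-end phantom study
#'
#' Runs the full chain — simulate, sample, gate, track, bin, reconstruct,
#' segment, report — on the digital phantom and compares the recovered
#' ventricular function and respiratory metrics with the phantom's ground
#' truth.
#'
#' @param config a [phantom_config()]; its seed is replaced by `seed`.
#' @param seed integer seed for the run.
#' @param duration_s scan duration (s).
#' @param tr_ms repetition time (ms).
#' @param views_per_segment cardiac views per segment (10 -> 40 ms bins).
#' @param resp_phases respiratory phases to reconstruct and analyse.
#' @param recon_iter iteration cap of the CS solver.
#' @param lambda_frac TV-weight heuristic fraction.
#' @param verbose log stage progress to stderr.
#' @return list: `report` (a `function_report`), `truth` (ground-truth
#'   comparison: EF errors, respiratory-depth oracle and error, per-phase
#'   HR, portions, 1D/3D correlation, EE-bin Dice), `binning`, `trace`,
#'   `metrics`, `timings_s`, `flags`.
#' @export
run_end_to_end <- function(config = phantom_config(), seed = 1,
                           duration_s = 90, tr_ms = 4,
                           views_per_segment = 10,
                           resp_phases = c("EE", "EI"),
                           recon_iter = 30, lambda_frac = 0.02,
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  flags <- character(0)
  config$seed <- as.integer(seed)

  t0 <- tic()
  phantom <- make_phantom(config)
  schedule <- circus_schedule(config$matrix_size[2:3])
  bundle <- simulate_acquisition(phantom, schedule, duration_s, tr_ms)
  timings["simulate"] <- tic() - t0
  say("simulated %d lines over %d beats [%.1f s]",
      nrow(bundle$lines), length(bundle$ecg_ms), timings["simulate"])

  t0 <- tic()
  beats <- sort_beats(bundle)
  low <- lowres_beat_volumes(bundle, beats)
  trace <- track_motion(low$volumes, low$spacing)
  if (any(!trace$converged)) flags <- c(flags, "registration-nonconvergence")
  sg1 <- self_gating_1d(bundle, beats)
  timings["track"] <- tic() - t0
  say("tracked %d beats (low-res R=%.1f) [%.1f s]", nrow(beats),
      low$undersampling_R, timings["track"])

  t0 <- tic()
  binning <- kmeans4(trace, restarts = 10, seed = seed + 1L)
  metrics <- resp_metrics(binning, trace, hr_bpm = beats$hr_bpm,
                          beat_t_ms = (beats$trigger_ms + beats$next_trigger_ms) / 2,
                          bellows = bundle$bellows)
  timings["bin"] <- tic() - t0

  t0 <- tic()
  maps <- estimate_coil_maps(bundle)
  pa <- cardiac_phase_assign(bundle, beats, views_per_segment)
  recons <- list()
  for (ph in resp_phases) {
    cell <- bin_kspace(bundle, beats, binning, pa, ph)
    recons[[ph]] <- ktss_reconstruct(cell, maps, max_iter = recon_iter,
                                     lambda_frac = lambda_frac)
    if (recons[[ph]]$diverged) flags <- c(flags, paste0("recon-diverged-", ph))
    say("reconstructed %s: %d cardiac phases, %d iters, lambda %.3g",
        ph, cell$n_card, recons[[ph]]$iterations, recons[[ph]]$lambda_t)
  }
  timings["recon"] <- tic() - t0

  t0 <- tic()
  rv_seed <- make_rv_seed(phantom)
  per_phase <- list()
  for (ph in resp_phases) {
    cine <- cine_magnitude(recons[[ph]])
    lv_masks <- segment_cine(cine, phantom$spacing, "LV",
                             radius_range_mm = c(12, 30))
    rv_masks <- segment_cine(cine, phantom$spacing, "RV", seeds = rv_seed,
                             lv_masks = lv_masks)
    if (any(vapply(lv_masks, function(m) any(m$slice_flags == "leak"), TRUE)))
      flags <- c(flags, paste0("lv-leak-", ph))
    per_phase[[ph]] <- list(lv = chamber_volumes(lv_masks),
                            rv = chamber_volumes(rv_masks))
  }
  timings["segment"] <- tic() - t0
  say("segmented %d respiratory phases [%.1f s]", length(resp_phases), timings["segment"])

  report <- function_report(per_phase, metrics)

  # ground-truth comparison
  tf <- phantom_true_function(phantom)
  truth_disp <- true_beat_displacement(phantom, beats)
  oracle_bin <- kmeans4(truth_disp, restarts = 10, seed = seed + 1L)
  dd_oracle <- respiratory_depth(oracle_bin)
  tb <- truth_quartile_bins(truth_disp[, 1])
  dice_ee <- dice_coefficient(which(binning$labels == which(binning$phase_names == "EE")),
                              tb$EE)
  truth <- list(
    lv_ef_true = unname(tf$lv["EF_pct"]),
    rv_ef_true = unname(tf$rv["EF_pct"]),
    lv_ef_error_points = if ("EE" %in% names(per_phase))
      per_phase$EE$lv$EF_pct - tf$lv["EF_pct"] else NA,
    resp_depth_oracle_mm = dd_oracle,
    resp_depth_error_pct = (metrics$resp_depth_mm - dd_oracle) / dd_oracle * 100,
    corr_1d_3d = stats::cor(trace$dx_mm, sg1$value_mm),
    dice_ee = dice_ee,
    trace_rmse_mm = sqrt(mean(rowSums(
      (as.matrix(trace[, c("dx_mm", "dy_mm", "dz_mm")]) - truth_disp)^2)))
  )
  list(report = report, truth = truth, metrics = metrics, binning = binning,
       trace = trace, self_gating = sg1, beats = beats, recons = recons,
       timings_s = timings, flags = flags)
}
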