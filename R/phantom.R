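# Digital cardiorespiratory phantom: a beating two-ventricle heart inside a
# torso, displaced quasi-periodically by respiration, imaged by a multi-coil
# Cartesian MR acquisition simulator.

#' Configuration of the digital cardiorespiratory phantom
#'
#' Builds and validates the parameter set describing the phantom anatomy, its
#' cardiac and respiratory dynamics, and the simulated receive chain. Defaults
#' describe a healthy adult heart at a desk-scale matrix (4 x 4 x 5 mm voxels
#' over a 256 x 256 x 120 mm field of view).
#'
#' Coordinate convention: array axis `x` (the first dimension, also the
#' readout) is the vertical axis of the short-axis plane; positive `x` means
#' the heart moves up. Respiration displaces the heart mainly along `x`, with
#' smaller in-plane components scaled by `resp_inplane_fraction`. All
#' displacements are in mm.
#'
#' The respiratory waveform is `-depth * sin(pi*t/T)^(2n)` with
#' `n = resp_asymmetry`: for `n = 1` a pure sinusoid, for `n >= 2` an
#' asymmetric curve that dwells near end-expiration (displacement 0, the most
#' positive `x` position) and makes comparatively brief excursions to
#' end-inspiration, so more heartbeats fall at end-expiration. Heart rate is
#' modulated by respiratory sinus arrhythmia: instantaneous HR equals
#' `heart_rate_base - rsa_amplitude` at end-expiration and
#' `heart_rate_base + rsa_amplitude` at end-inspiration.
#'
#' @param matrix_size integer triple (Nx, Ny, Nz).
#' @param fov_mm field of view in mm per axis.
#' @param n_coils number of receive coils (8-channel cardiac array by default).
#' @param heart_rate_base baseline heart rate, beats/min.
#' @param rsa_amplitude depth of respiratory-sinus-arrhythmia HR modulation,
#'   beats/min; must satisfy `0 <= rsa_amplitude < heart_rate_base`.
#' @param resp_rate respiratory rate, breaths/min.
#' @param resp_depth_mm peak-to-peak superior-inferior displacement, mm.
#' @param resp_inplane_fraction scale of the in-plane (y, z) displacement
#'   components relative to the SI component.
#' @param resp_asymmetry waveform exponent `n` (see Details); 1 = sinusoid.
#' @param resp_jitter_frac fractional slow modulation of the breathing depth
#'   (cycle-to-cycle variability), seeded deterministically.
#' @param asynchrony_phase_rad phase lag (radians, of the full respiratory
#'   cycle) between chest-wall and heart displacement; 0 = synchronous.
#' @param drift_mm_per_min linear baseline drift of the heart along `x`.
#' @param lv_radii_ed,lv_radii_es LV cavity semi-axes (mm) at end-diastole and
#'   end-systole.
#' @param lv_wall_ed,lv_wall_es LV wall thickness (mm) at ED and ES.
#' @param rv_geometry list with `center` (mm offset of the RV cavity ellipsoid
#'   from the LV center), `radii_ed`, `radii_es` (semi-axes, mm) and
#'   `wall_mm`. The RV cavity is the ellipsoid minus the LV epicardium, giving
#'   the crescent cross-section.
#' @param noise_sigma complex-noise standard deviation relative to the peak
#'   tissue signal (blood = 1).
#' @param seed integer seed governing noise and waveform jitter.
#' @param max_duration_s longest simulated scan supported by the beat table.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(matrix_size = c(64, 64, 24),
                           fov_mm = c(256, 256, 120),
                           n_coils = 8,
                           heart_rate_base = 60,
                           rsa_amplitude = 6,
                           resp_rate = 14.5,
                           resp_depth_mm = 8,
                           resp_inplane_fraction = 0.3,
                           resp_asymmetry = 2,
                           resp_jitter_frac = 0.05,
                           asynchrony_phase_rad = 0,
                           drift_mm_per_min = 0,
                           lv_radii_ed = c(25, 25, 35),
                           lv_radii_es = c(18, 18, 26),
                           lv_wall_ed = 9,
                           lv_wall_es = 13,
                           rv_geometry = list(center = c(0, -42, 0),
                                              radii_ed = c(28, 18, 30),
                                              radii_es = c(23, 15, 25),
                                              wall_mm = 4),
                           noise_sigma = 0.02,
                           seed = 1,
                           max_duration_s = 600) {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 3 || any(matrix_size < 2))
    stop("matrix_size must be three integers >= 2")
  if (length(fov_mm) != 3 || any(fov_mm <= 0))
    stop("fov_mm must be three positive extents")
  if (n_coils < 1) stop("n_coils must be >= 1")
  if (heart_rate_base <= 0) stop("heart_rate_base must be positive")
  if (rsa_amplitude < 0 || rsa_amplitude >= heart_rate_base)
    stop("rsa_amplitude must satisfy 0 <= rsa_amplitude < heart_rate_base")
  if (resp_rate <= 0) stop("resp_rate must be positive")
  if (resp_depth_mm < 0) stop("resp_depth_mm must be >= 0")
  if (resp_asymmetry < 1) stop("resp_asymmetry must be >= 1")
  if (any(lv_radii_ed <= 0) || any(lv_radii_es <= 0))
    stop("LV semi-axes must be positive")
  if (prod(lv_radii_es) >= prod(lv_radii_ed))
    stop("end-systolic LV cavity volume must be smaller than end-diastolic (contraction)")
  if (prod(rv_geometry$radii_es) >= prod(rv_geometry$radii_ed))
    stop("end-systolic RV cavity volume must be smaller than end-diastolic (contraction)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  cfg <- list(matrix_size = matrix_size, fov_mm = fov_mm, n_coils = as.integer(n_coils),
              heart_rate_base = heart_rate_base, rsa_amplitude = rsa_amplitude,
              resp_rate = resp_rate, resp_depth_mm = resp_depth_mm,
              resp_inplane_fraction = resp_inplane_fraction,
              resp_asymmetry = resp_asymmetry, resp_jitter_frac = resp_jitter_frac,
              asynchrony_phase_rad = asynchrony_phase_rad,
              drift_mm_per_min = drift_mm_per_min,
              lv_radii_ed = lv_radii_ed, lv_radii_es = lv_radii_es,
              lv_wall_ed = lv_wall_ed, lv_wall_es = lv_wall_es,
              rv_geometry = rv_geometry,
              noise_sigma = noise_sigma, seed = as.integer(seed),
              max_duration_s = max_duration_s)
  class(cfg) <- "phantom_config"
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> ", paste(x$matrix_size, collapse = "x"),
      " over ", paste(x$fov_mm, collapse = "x"), " mm, ",
      x$n_coils, " coils\n", sep = "")
  cat("  HR ", x$heart_rate_base, " bpm (RSA +/-", x$rsa_amplitude,
      "), resp ", x$resp_rate, " brpm, SI depth ", x$resp_depth_mm, " mm\n", sep = "")
  invisible(x)
}

# Depth-modulation envelope (cycle-to-cycle variability), deterministic in the
# config seed; two slow incommensurate sinusoids.
resp_jitter_fn <- function(config) {
  j <- config$resp_jitter_frac
  if (j <= 0) return(function(t) rep(1, length(t)))
  ph <- with_local_seed(config$seed + 101L, stats::runif(2, 0, 2 * pi))
  t_resp <- 60000 / config$resp_rate
  function(t) 1 + j * (0.6 * sin(2 * pi * t / (7.3 * t_resp) + ph[1]) +
                       0.4 * sin(2 * pi * t / (3.1 * t_resp) + ph[2]))
}

#' Build the digital cardiorespiratory phantom
#'
#' Instantiates the dynamic phantom: ground-truth motion, beat table, coil
#' sensitivity maps, and a renderer mapping time (or a cardiac phase /
#' displacement state) to a 3D intensity volume. The rendered volume is the
#' reference anatomy with the cardiac shape interpolated by cardiac phase and
#' rigidly displaced by the true respiratory displacement; the chest-wall
#' layer follows its own (possibly lagged) waveform.
#'
#' @param config a [phantom_config()].
#' @return an object of class `cardio_phantom` with elements
#'   `config`, `spacing` (mm/voxel), `beat_times_ms`, functions
#'   `displacement(t)`, `chest_displacement(t)`, `hr_inst(t)`,
#'   `cardiac_phase(t)`, `render(t)`, `render_state(p, d, wall_d)`,
#'   `coil_maps` (complex array Nx x Ny x Nz x n_coils), and
#'   `true_volumes_ml(phases)`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$matrix_size
  fov <- config$fov_mm
  spacing <- fov / n
  cvox <- floor(n / 2)          # 0-based center voxel = mm origin
  xs <- (seq_len(n[1]) - 1 - cvox[1]) * spacing[1]
  ys <- (seq_len(n[2]) - 1 - cvox[2]) * spacing[2]
  zs <- (seq_len(n[3]) - 1 - cvox[3]) * spacing[3]

  t_resp <- 60000 / config$resp_rate     # ms per breath
  nexp <- config$resp_asymmetry
  jit <- resp_jitter_fn(config)
  depth <- config$resp_depth_mm
  inpl <- config$resp_inplane_fraction

  resp_si <- function(t, phase_rad = 0) {
    -depth * jit(t) * sin(pi * t / t_resp + phase_rad / 2)^(2 * nexp)
  }
  displacement <- function(t) {
    s <- resp_si(t)
    cbind(dx = s + config$drift_mm_per_min * t / 60000,
          dy = inpl * s,
          dz = 0.6 * inpl * s)
  }
  chest_displacement <- function(t) resp_si(t, config$asynchrony_phase_rad)
  insp_level <- function(t) sin(pi * t / t_resp)^(2 * nexp)
  hr_inst <- function(t) {
    config$heart_rate_base - config$rsa_amplitude +
      2 * config$rsa_amplitude * insp_level(t)
  }

  # beat table: next R-wave follows from the instantaneous HR at the current one
  beat_times <- numeric(0)
  t <- 0
  tmax <- config$max_duration_s * 1000
  while (t <= tmax) {
    beat_times <- c(beat_times, t)
    t <- t + 60000 / hr_inst(t)
  }
  cardiac_phase <- function(t) {
    i <- findInterval(t, beat_times)
    i <- clamp(i, 1L, length(beat_times) - 1L)
    p <- (t - beat_times[i]) / (beat_times[i + 1] - beat_times[i])
    clamp(p, 0, 1 - 1e-9)
  }

  # coil sensitivities: Gaussian magnitude lobes on a ring around the torso,
  # distinct smooth phase per coil
  nc <- config$n_coils
  coil_maps <- array(0i, c(n, nc))
  grid_x <- array(rep(xs, times = n[2] * n[3]), n)
  grid_y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  grid_z <- array(rep(zs, each = n[1] * n[2]), n)
  for (c in seq_len(nc)) {
    th <- 2 * pi * (c - 1) / nc
    px <- 150 * cos(th); py <- 150 * sin(th)
    mag <- exp(-((grid_x - px)^2 + (grid_y - py)^2) / (2 * 120^2) -
                 grid_z^2 / (2 * 220^2))
    ph <- 0.004 * (grid_x * cos(th) + grid_y * sin(th)) + th / 3
    coil_maps[, , , c] <- mag * exp(1i * ph)
  }

  # cardiac activation: 0 at end-diastole (R-wave), 1 at end-systole (p = 0.5)
  activation <- function(p) sin(pi * p)^2
  geom_at <- function(p) {
    a <- activation(p)
    lv_cav <- config$lv_radii_ed + a * (config$lv_radii_es - config$lv_radii_ed)
    lv_wall <- config$lv_wall_ed + a * (config$lv_wall_es - config$lv_wall_ed)
    rv <- config$rv_geometry
    rv_cav <- rv$radii_ed + a * (rv$radii_es - rv$radii_ed)
    list(lv_cav = lv_cav, lv_epi = lv_cav + lv_wall,
         rv_cav = rv_cav, rv_epi = rv_cav + rv$wall_mm,
         rv_center = rv$center)
  }

  soft <- function(q, width = 0.12) clamp((1 - q) / width + 0.5, 0, 1)
  ell_q <- function(cx, cy, cz, r) {
    ((grid_x - cx) / r[1])^2 + ((grid_y - cy) / r[2])^2 + ((grid_z - cz) / r[3])^2
  }

  # paint order encodes anatomy priority: torso < chest wall < RV < LV.
  # Torso and chest-wall extents scale with the FOV so smaller test FOVs
  # stay alias-free; the heart geometry is absolute (mm).
  torso_a <- 0.43 * fov[1]; torso_b <- 0.47 * fov[2]
  slab_lo <- 0.27 * fov[1]; slab_hi <- 0.36 * fov[1]; slab_w <- 0.33 * fov[2]
  render_state <- function(p, d, wall_d = 0) {
    g <- geom_at(p)
    vol <- array(0, n)
    torso <- (grid_x / torso_a)^2 + (grid_y / torso_b)^2 <= 1
    vol[torso] <- 0.25
    slab <- torso & (grid_x - wall_d) > slab_lo & (grid_x - wall_d) < slab_hi &
      abs(grid_y) < slab_w
    vol[slab] <- 0.8
    w_rvw <- soft(ell_q(d[1] + g$rv_center[1], d[2] + g$rv_center[2],
                        d[3] + g$rv_center[3], g$rv_epi))
    vol <- vol * (1 - w_rvw) + 0.45 * w_rvw
    w_rvc <- soft(ell_q(d[1] + g$rv_center[1], d[2] + g$rv_center[2],
                        d[3] + g$rv_center[3], g$rv_cav))
    vol <- vol * (1 - w_rvc) + 1.0 * w_rvc
    w_epi <- soft(ell_q(d[1], d[2], d[3], g$lv_epi))
    vol <- vol * (1 - w_epi) + 0.45 * w_epi
    w_cav <- soft(ell_q(d[1], d[2], d[3], g$lv_cav))
    vol <- vol * (1 - w_cav) + 1.0 * w_cav
    vol
  }
  render <- function(t) {
    d <- displacement(t)[1, ]
    render_state(cardiac_phase(t), d, chest_displacement(t))
  }

  # true cavity volumes (mL) at the reference respiratory position: LV closed
  # form; RV (crescent = ellipsoid minus LV epicardium) by fine voxelization
  true_volumes_ml <- function(phases, rv_grid_mm = 1) {
    vapply(phases, function(p) {
      g <- geom_at(p)
      lv <- 4 / 3 * pi * prod(g$lv_cav) / 1000
      rv <- rv_crescent_volume_ml(g, rv_grid_mm)
      c(lv = lv, rv = rv)
    }, numeric(2)) -> v
    data.frame(phase = phases, lv_ml = v["lv", ], rv_ml = v["rv", ])
  }

  ph <- list(config = config, spacing = spacing, center_voxel0 = cvox,
             beat_times_ms = beat_times,
             displacement = displacement,
             chest_displacement = chest_displacement,
             hr_inst = hr_inst, cardiac_phase = cardiac_phase,
             insp_level = insp_level,
             coil_maps = coil_maps,
             render = render, render_state = render_state,
             geom_at = geom_at, activation = activation,
             true_volumes_ml = true_volumes_ml)
  class(ph) <- "cardio_phantom"
  ph
}

# RV crescent volume on a fine grid restricted to the RV bounding box.
rv_crescent_volume_ml <- function(g, grid_mm = 1) {
  rc <- g$rv_center; rr <- g$rv_cav
  xs <- seq(rc[1] - rr[1], rc[1] + rr[1], by = grid_mm)
  ys <- seq(rc[2] - rr[2], rc[2] + rr[2], by = grid_mm)
  zs <- seq(rc[3] - rr[3], rc[3] + rr[3], by = grid_mm)
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  inside_rv <- ((gx - rc[1]) / rr[1])^2 + ((gy - rc[2]) / rr[2])^2 +
    ((gz - rc[3]) / rr[3])^2 <= 1
  inside_lv_epi <- (gx / g$lv_epi[1])^2 + (gy / g$lv_epi[2])^2 +
    (gz / g$lv_epi[3])^2 <= 1
  sum(inside_rv & !inside_lv_epi) * grid_mm^3 / 1000
}

#' Analytic ventricular function of the phantom
#'
#' Ground-truth ESV/EDV/SV/EF over a dense cardiac-phase grid at the reference
#' respiratory position (LV closed-form; RV by fine voxelization).
#'
#' @param phantom a `cardio_phantom`.
#' @param n_phases number of cardiac phases on the evaluation grid.
#' @return list with `lv` and `rv`, each `(ESV_mL, EDV_mL, SV_mL, EF_pct)`.
#' @export
phantom_true_function <- function(phantom, n_phases = 40) {
  tv <- phantom$true_volumes_ml(seq(0, 1 - 1 / n_phases, length.out = n_phases))
  f <- function(v) {
    edv <- max(v); esv <- min(v)
    c(ESV_mL = esv, EDV_mL = edv, SV_mL = edv - esv, EF_pct = (edv - esv) / edv * 100)
  }
  list(lv = f(tv$lv_ml), rv = f(tv$rv_ml))
}

#' @export
print.cardio_phantom <- function(x, ...) {
  cat("<cardio_phantom> ", paste(x$config$matrix_size, collapse = "x"),
      " grid, spacing ", paste(round(x$spacing, 2), collapse = "x"), " mm, ",
      x$config$n_coils, " coils, ", length(x$beat_times_ms), " beats tabled\n", sep = "")
  tf <- phantom_true_function(x, 20)
  cat(sprintf("  true LV EF %.1f%%, RV EF %.1f%%\n", tf$lv["EF_pct"], tf$rv["EF_pct"]))
  invisible(x)
}

#' Simulate a continuous multi-coil Cartesian acquisition
#'
#' Plays a CIRCUS sampling schedule against the dynamic phantom: each readout
#' line is one kx column of the DC-centered unitary 3D DFT of (coil map x
#' instantaneous phantom volume) at the line's timestamp, plus complex
#' Gaussian noise. ECG triggers are the phantom beat times; the bellows trace
#' samples the chest-wall displacement (which may lag the heart by the
#' configured asynchrony phase).
#'
#' Time is quantised into simulation states (cardiac phase bins x displacement
#' quanta) so each distinct instantaneous volume is rendered and transformed
#' once; `cardiac_states` and `disp_quant_mm` bound the quantisation error.
#'
#' @param phantom a `cardio_phantom`.
#' @param schedule a `circus_schedule` on the (Ny, Nz) phase-encode grid;
#'   recycled cyclically over the scan.
#' @param duration_s scan duration, seconds (must cover >= 10 heartbeats).
#' @param tr_ms repetition time per readout line, ms.
#' @param noise_sigma overrides the config value when non-NULL.
#' @param cardiac_states number of cardiac-phase quantisation bins.
#' @param disp_quant_mm displacement quantisation step, mm.
#' @param readout_partial_fourier partial-Fourier fraction applied along kx as
#'   asymmetric truncation (zero-filled on reconstruction); NULL takes the
#'   schedule's fraction.
#' @return an object of class `kspace_bundle`: `kdata` (complex array
#'   Nx x n_lines x n_coils), `lines` (data.frame: line_id, ky, kz, t_ms,
#'   interleave, ring; ky/kz 0-based with DC at floor(N/2)), `ecg_ms`,
#'   `bellows` (data.frame t_ms, value), plus the acquisition geometry.
#' @export
simulate_acquisition <- function(phantom, schedule, duration_s, tr_ms = 4,
                                 noise_sigma = NULL,
                                 cardiac_states = 20, disp_quant_mm = 0.25,
                                 readout_partial_fourier = NULL) {
  stopifnot(inherits(phantom, "cardio_phantom"), inherits(schedule, "circus_schedule"))
  cfg <- phantom$config
  n <- cfg$matrix_size
  if (!all(attr(schedule, "grid") == n[2:3]))
    stop("schedule grid does not match the phantom phase-encode grid")
  if (nrow(schedule) == 0) stop("schedule is empty")
  bad <- which(schedule$ky < 0 | schedule$ky >= n[2] | schedule$kz < 0 | schedule$kz >= n[3])
  if (length(bad))
    stop("schedule line ", bad[1], " has (ky,kz)=(", schedule$ky[bad[1]], ",",
         schedule$kz[bad[1]], ") outside the ", n[2], "x", n[3], " grid")
  if (duration_s * 1000 > cfg$max_duration_s * 1000)
    stop("duration exceeds the phantom's max_duration_s")
  n_lines <- floor(duration_s * 1000 / tr_ms)
  t_ms <- (seq_len(n_lines) - 1) * tr_ms
  ecg <- phantom$beat_times_ms[phantom$beat_times_ms <= duration_s * 1000]
  if (length(ecg) < 10) stop("duration must cover at least 10 heartbeats")

  sched_idx <- ((seq_len(n_lines) - 1) %% nrow(schedule)) + 1L
  lines <- data.frame(line_id = seq_len(n_lines),
                      ky = schedule$ky[sched_idx], kz = schedule$kz[sched_idx],
                      t_ms = t_ms,
                      interleave = schedule$interleave[sched_idx],
                      ring = schedule$ring[sched_idx])

  # quantised state per line
  p <- phantom$cardiac_phase(t_ms)
  pstate <- pmin(floor(p * cardiac_states), cardiac_states - 1L)
  d <- phantom$displacement(t_ms)
  wd <- phantom$chest_displacement(t_ms)
  q <- disp_quant_mm
  dq <- round(d / q); wq <- round(wd / q)
  key <- paste(pstate, dq[, 1], dq[, 2], dq[, 3], wq, sep = "|")

  pf_x <- if (is.null(readout_partial_fourier)) attr(schedule, "partial_fourier") else readout_partial_fourier
  keep_x <- pf_indices0(n[1], pf_x) + 1L

  kdata <- array(0i, c(n[1], n_lines, cfg$n_coils))
  groups <- split(seq_len(n_lines), key)
  for (ids in groups) {
    i0 <- ids[1]
    vol <- phantom$render_state((pstate[i0] + 0.5) / cardiac_states,
                                dq[i0, ] * q, wq[i0] * q)
    cols <- lines$ky[ids] + 1L + n[2] * lines$kz[ids]
    for (c in seq_len(cfg$n_coils)) {
      K <- fftc(vol * phantom$coil_maps[, , , c])
      dim(K) <- c(n[1], n[2] * n[3])
      kdata[, ids, c] <- K[, cols]
    }
  }
  # readout partial Fourier: asymmetric truncation, zero-filled
  if (length(keep_x) < n[1]) {
    drop_x <- setdiff(seq_len(n[1]), keep_x)
    kdata[drop_x, , ] <- 0i
  }
  sigma <- if (is.null(noise_sigma)) cfg$noise_sigma else noise_sigma
  if (sigma > 0) {
    kdata <- kdata + with_local_seed(cfg$seed + 7L, {
      nn <- length(kdata)
      complex(real = stats::rnorm(nn, 0, sigma / sqrt(2)),
              imaginary = stats::rnorm(nn, 0, sigma / sqrt(2)))
    })
  }
  bt <- seq(0, duration_s * 1000, by = 40)   # 25 Hz bellows sampling
  bell <- data.frame(t_ms = bt,
                     value = phantom$chest_displacement(bt) +
                       with_local_seed(cfg$seed + 8L, stats::rnorm(length(bt), 0, 0.02 * max(cfg$resp_depth_mm, 1))))
  out <- list(kdata = kdata, lines = lines, ecg_ms = ecg, bellows = bell,
              tr_ms = tr_ms, grid = n, fov_mm = cfg$fov_mm,
              spacing = phantom$spacing, n_coils = cfg$n_coils,
              partial_fourier = attr(schedule, "partial_fourier"),
              readout_keep0 = keep_x - 1L,
              config = cfg)
  class(out) <- "kspace_bundle"
  out
}

#' @export
print.kspace_bundle <- function(x, ...) {
  cat("<kspace_bundle> ", nrow(x$lines), " lines, TR ", x$tr_ms, " ms, ",
      x$n_coils, " coils, grid ", paste(x$grid, collapse = "x"), ", ",
      length(x$ecg_ms), " ECG triggers\n", sep = "")
  invisible(x)
}
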