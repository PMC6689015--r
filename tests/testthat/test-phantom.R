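test_that("configuration invariants are enforced", {
  expect_error(phantom_config(matrix_size = c(0, 16, 16)), "matrix_size")
  expect_error(phantom_config(rsa_amplitude = 70, heart_rate_base = 60), "rsa")
  expect_error(phantom_config(lv_radii_es = c(26, 26, 36)), "contraction")
  expect_error(phantom_config(resp_depth_mm = -1), "resp_depth")
})

test_that("LV cavity volume matches the closed-form ellipsoid, cross-checked by voxel counting", {
  ph <- make_phantom(phantom_config())
  tv <- ph$true_volumes_ml(0)
  expect_equal(tv$lv_ml, 4 / 3 * pi * 25 * 25 * 35 / 1000, tolerance = 1e-10)
  # independent oracle: count 1 mm voxels inside the ED cavity ellipsoid
  xs <- seq(-25.5, 25.5, by = 1); zs <- seq(-35.5, 35.5, by = 1)
  cnt <- 0
  for (z in zs) {
    q <- 1 - (z / 35)^2
    if (q <= 0) next
    inside <- outer(xs^2, xs^2, `+`) <= q * 25^2
    cnt <- cnt + sum(inside)
  }
  expect_lt(abs(cnt / 1000 - tv$lv_ml) / tv$lv_ml, 0.02)
  # contraction: ES volumes below ED for both ventricles
  tves <- ph$true_volumes_ml(0.5)
  expect_lt(tves$lv_ml, tv$lv_ml)
  expect_lt(tves$rv_ml, tv$rv_ml)
})

test_that("no respiration means zero displacement; no RSA means equal beat intervals", {
  cfg <- phantom_config(resp_depth_mm = 0, drift_mm_per_min = 0, rsa_amplitude = 0)
  ph <- make_phantom(cfg)
  t <- seq(0, 60000, by = 500)
  expect_true(all(abs(ph$displacement(t)) < 1e-12))
  expect_equal(unique(round(diff(ph$beat_times_ms), 9)), 60000 / cfg$heart_rate_base)
  expect_true(all(abs(ph$displacement(0)) == 0))
})

test_that("respiratory sinus arrhythmia keeps HR in band and slowest at end-expiration", {
  cfg <- phantom_config()
  ph <- make_phantom(cfg)
  t <- seq(0, 120000, by = 100)
  hr <- ph$hr_inst(t)
  expect_true(all(hr >= cfg$heart_rate_base - cfg$rsa_amplitude - 1e-9))
  expect_true(all(hr <= cfg$heart_rate_base + cfg$rsa_amplitude + 1e-9))
  # end-expiration (displacement ~ 0, the most positive x) has the lowest HR
  d <- ph$displacement(t)[, 1]
  expect_lt(mean(hr[d > quantile(d, 0.75)]), mean(hr[d < quantile(d, 0.25)]))
  rr <- diff(ph$beat_times_ms)
  expect_gt(max(rr) / min(rr), 1.05)
})

test_that("peak-to-peak SI excursion grows strictly with configured depth", {
  t <- seq(0, 60000, by = 50)
  p2p <- vapply(c(2, 5, 8, 12), function(dep) {
    ph <- make_phantom(phantom_config(resp_depth_mm = dep, resp_jitter_frac = 0))
    diff(range(ph$displacement(t)[, 1]))
  }, 1)
  expect_true(all(diff(p2p) > 0))
  expect_equal(p2p, c(2, 5, 8, 12), tolerance = 1e-6)
})

test_that("bellows is anti-phase with heart SI displacement at a pi lag", {
  t <- seq(0, 120000, by = 100)
  # sinusoidal waveform: exact anti-phase
  ph <- make_phantom(phantom_config(resp_asymmetry = 1, resp_jitter_frac = 0,
                                    asynchrony_phase_rad = pi))
  r <- cor(ph$chest_displacement(t), ph$displacement(t)[, 1])
  expect_equal(r, -1, tolerance = 1e-6)
  # default asymmetric waveform: strongly negative
  ph2 <- make_phantom(phantom_config(resp_jitter_frac = 0,
                                     asynchrony_phase_rad = pi))
  r2 <- cor(ph2$chest_displacement(t), ph2$displacement(t)[, 1])
  expect_lt(r2, -0.8)
  # synchronous: identical waveforms
  ph3 <- make_phantom(phantom_config(resp_jitter_frac = 0))
  expect_equal(cor(ph3$chest_displacement(t), ph3$displacement(t)[, 1]), 1,
               tolerance = 1e-9)
})

test_that("simulated lines equal the brute-force DFT and satisfy Parseval", {
  cfg <- static_config()
  ph <- make_phantom(cfg)
  sch <- circus_schedule(c(16, 16), partial_fourier = 1)
  b <- simulate_acquisition(ph, sch, duration_s = 15, cardiac_states = 1)
  vol <- ph$render_state(0.5, c(0, 0, 0)) * ph$coil_maps[, , , 1]
  for (i in c(3, 57, 411)) {
    expect_equal(b$kdata[, i, 1],
                 brute_dft_line(vol, b$lines$ky[i], b$lines$kz[i]),
                 tolerance = 1e-10)
  }
  # assemble the fully sampled k-space volume from the collected lines
  K <- array(0i, dim(vol))
  for (i in seq_len(nrow(b$lines)))
    K[, b$lines$ky[i] + 1, b$lines$kz[i] + 1] <- b$kdata[, i, 1]
  expect_true(all(Mod(K[1 + floor(8), , ]) >= 0))  # grid filled
  expect_lt(abs(sum(Mod(K)^2) - sum(Mod(vol)^2)) / sum(Mod(vol)^2), 1e-6)
  img <- cine5d:::ifftc(K)
  expect_lt(max(Mod(img - vol)), 1e-10)
})

test_that("line timestamps advance by TR and triggers mirror the beat table", {
  s <- small_scan()
  expect_equal(unique(diff(s$bundle$lines$t_ms)), s$bundle$tr_ms)
  expect_equal(s$bundle$ecg_ms,
               s$phantom$beat_times_ms[s$phantom$beat_times_ms <= 45 * 1000])
  # every phase encode lies inside the partial-Fourier region
  pfy <- cine5d:::pf_indices0(48, 0.75)
  pfz <- cine5d:::pf_indices0(16, 0.75)
  expect_true(all(s$bundle$lines$ky %in% pfy))
  expect_true(all(s$bundle$lines$kz %in% pfz))
})

test_that("acquisition rejects mismatched schedules and too-short scans", {
  ph <- make_phantom(static_config())
  sch_bad <- circus_schedule(c(12, 12))
  expect_error(simulate_acquisition(ph, sch_bad, 15), "grid")
  sch <- circus_schedule(c(16, 16))
  expect_error(simulate_acquisition(ph, sch, duration_s = 5), "10 heartbeats")
})

test_that("bundle round-trips through its on-disk serialization", {
  s <- small_scan()
  d <- withr::local_tempdir()
  write_bundle(s$bundle, d)
  b2 <- read_bundle(d)
  expect_equal(b2$kdata[, 1:20, ], s$bundle$kdata[, 1:20, ])
  expect_equal(b2$lines$ky, s$bundle$lines$ky)
  expect_equal(b2$ecg_ms, s$bundle$ecg_ms)
  expect_equal(b2$spacing, s$bundle$spacing)
})
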