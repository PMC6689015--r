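# minimal hand-built bundle for trigger arithmetic tests
toy_bundle <- function(trigger_ms, n_lines, tr_ms = 4) {
  structure(list(
    kdata = array(0i, c(4, n_lines, 1)),
    lines = data.frame(line_id = seq_len(n_lines), ky = 0, kz = 0,
                       t_ms = (seq_len(n_lines) - 1) * tr_ms),
    ecg_ms = trigger_ms, bellows = data.frame(t_ms = 0, value = 0),
    tr_ms = tr_ms, grid = c(4, 4, 4), fov_mm = c(16, 16, 16),
    spacing = c(4, 4, 4), n_coils = 1, partial_fourier = 1,
    readout_keep0 = 0:3), class = "kspace_bundle")
}

test_that("beats partition lines by trigger intervals with correct rates", {
  b <- toy_bundle(c(0, 1000), 300)
  beats <- sort_beats(b)
  expect_equal(beats$n_lines, 250)           # 1 s beat at TR 4 ms
  expect_equal(beats$hr_bpm, 60)
  expect_equal(attr(beats, "discarded"), 50)
  b2 <- toy_bundle(c(0, 800, 1800), 500)
  beats2 <- sort_beats(b2)
  expect_equal(beats2$hr_bpm, c(75, 60))
  expect_error(sort_beats(toy_bundle(0, 10)), "at least 2")
  expect_error(sort_beats(toy_bundle(c(100, 50), 50)), "increasing")
})

test_that("lines are conserved across beats, discards and QC rejections", {
  s <- small_scan()
  beats <- s$beats
  n_assigned <- sum(vapply(attr(beats, "line_ids"), length, 1L))
  expect_equal(n_assigned + attr(beats, "discarded"), nrow(s$bundle$lines))
  expect_true(all(beats$rr_ms >= 300 & beats$rr_ms <= 2000))
  expect_equal(beats$hr_bpm, 60000 / beats$rr_ms)
  # overly short beats are rejected as trigger artifacts
  b3 <- toy_bundle(c(0, 100, 1100), 300)
  expect_equal(attr(sort_beats(b3), "rejected_beats"), 1)
})

test_that("the low-resolution band matches FOV / resolution", {
  expect_equal(cine5d:::lowres_band(c(256, 255, 120), c(256, 144, 30), 4),
               c(64, 64, 30))
  expect_equal(cine5d:::lowres_band(c(192, 192, 96), c(48, 48, 16), 4),
               c(48, 48, 16))
})

test_that("static phantom gives identical per-beat volumes; rigid shifts move the correlation peak", {
  cfg <- static_config()
  ph <- make_phantom(cfg)
  sch <- circus_schedule(c(16, 16), partial_fourier = 1)
  b <- simulate_acquisition(ph, sch, duration_s = 15, cardiac_states = 1)
  beats <- sort_beats(b)
  low <- lowres_beat_volumes(b, beats, target_resolution_mm = 10)
  v <- low$volumes
  expect_gt(dim(v)[4], 5)
  ref <- v[, , , 1]
  for (ib in 2:dim(v)[4])
    expect_lt(max(abs(v[, , , ib] - ref)) / max(ref), 1e-8)
  expect_equal(unname(low$share_counts[, "missing"]), rep(0L, dim(v)[4]))

  # pure rigid 8 mm SI shift between two rendered states: xcorr peak at
  # 2 voxels for 4 mm voxels (shift theorem oracle on the rendered grid)
  cfg2 <- static_config(n = c(32, 32, 8), fov = c(128, 128, 64))
  ph2 <- make_phantom(cfg2)
  a <- ph2$render_state(0.5, c(0, 0, 0))
  bb <- ph2$render_state(0.5, c(8, 0, 0))
  # correlate over the heart-covering central region (the torso is static)
  ctr <- 9:24
  cc <- vapply(-4:4, function(s) {
    i <- ctr; j <- pmin(pmax(i + s, 1), 32)
    sum(bb[j, ctr, ] * a[i, ctr, ])
  }, 1)
  expect_equal((-4:4)[which.max(cc)], 2)
})

test_that("1D self-gating tracks synchronous SI motion", {
  s <- small_scan()
  sg <- self_gating_1d(s$bundle, s$beats)
  expect_false(any(sg$interpolated))
  expect_gt(abs(cor(sg$value_mm, s$truth[, 1])), 0.95)
  # no respiration: flat trace
  cfg <- static_config()
  ph <- make_phantom(cfg)
  b <- simulate_acquisition(ph, circus_schedule(c(16, 16), partial_fourier = 1),
                            duration_s = 15, cardiac_states = 1)
  beats <- sort_beats(b)
  sg0 <- self_gating_1d(b, beats)
  expect_lt(sd(sg0$value_mm), 0.1)
})

test_that("cardiac phases bin lines at views_per_segment x TR resolution", {
  b <- toy_bundle(c(0, 1000, 2000), 600)
  beats <- sort_beats(b)
  pa <- cardiac_phase_assign(b, beats, views_per_segment = 10)
  expect_equal(pa$temporal_resolution_ms, 40)
  expect_equal(pa$n_phases, 25)              # 1000 ms beat, 40 ms bins
  expect_equal(pa$phase[1], 0)               # line at t = trigger
  expect_equal(pa$phase[1 + 250], 0)         # first line of beat 2
  expect_equal(pa$phase[45], floor(44 * 4 / 40))
  expect_true(all(pa$phase[!is.na(pa$phase)] < 25))
})
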