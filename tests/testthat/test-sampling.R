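test_that("square rings partition the phase-encode grid", {
  r4 <- ring_partition(4, 4)
  expect_equal(sort(unique(as.vector(r4))), c(0, 1))
  expect_true(all(r4[2:3, 2:3] == 0))        # center 2x2 block is ring 0
  r8 <- ring_partition(8, 8)
  expect_equal(as.vector(table(r8)), c(4, 12, 20, 28))  # sizes sum to 64
  expect_equal(sum(table(r8)), 64)
  expect_equal(max(ring_partition(144, 30)), ceiling(max(144, 30) / 2) - 1)
  # every point belongs to exactly one ring by construction; spot-check corners
  expect_equal(r8[1, 1], 3); expect_equal(r8[8, 8], 3)
})

test_that("c = 0 degenerates to a radial-like spoke within an interleave", {
  s <- circus_schedule(c(32, 32), circus_c = 0, partial_fourier = 1,
                       n_interleaves = 1)
  rings <- ring_partition(32, 32)
  cy <- 16; cz <- 16
  # fractional perimeter position of each selected point within its ring
  fracs <- vapply(seq_len(nrow(s)), function(i) {
    r <- s$ring[i]
    pts <- which(rings == r, arr.ind = TRUE)
    ky <- pts[, 1] - 1; kz <- pts[, 2] - 1
    o <- order(atan2(kz - cz + 0.5, ky - cy + 0.5))
    pos <- which(ky[o] == s$ky[i] & kz[o] == s$kz[i])
    (pos - 1) / length(o)
  }, 1)
  big <- s$ring >= 4                         # rings with fine angular quantisation
  expect_lt(diff(range(fracs[big])), 0.1)    # same fractional position = spoke
})

test_that("full-Fourier schedule covers the grid; outer ring sampled once per cycle", {
  s <- circus_schedule(c(16, 16), partial_fourier = 1)
  m <- sampling_mask(s)
  expect_true(all(m))                        # every grid point sampled
  rings <- ring_partition(16, 16)
  outer_pts <- s[s$ring == max(rings), ]
  expect_false(any(duplicated(outer_pts[, c("ky", "kz")])))
})

test_that("75% partial Fourier spans 75% of each phase-encode axis", {
  s <- circus_schedule(c(64, 64), partial_fourier = 0.75)
  expect_equal(diff(range(s$ky)) + 1, 48, tolerance = 1)
  expect_equal(diff(range(s$kz)) + 1, 48, tolerance = 1)
})

test_that("each interleave holds exactly one unique entry per intersecting ring", {
  s <- circus_schedule(c(24, 16), n_interleaves = 12, seed = 3)
  for (t in unique(s$interleave)) {
    it <- s[s$interleave == t, ]
    expect_false(any(duplicated(it$ring)))
    expect_false(any(duplicated(it[, c("ky", "kz")])))
  }
  # within one cycle of any ring, no position repeats
  for (r in unique(s$ring)) {
    sr <- s[s$ring == r, ]
    cap <- nrow(unique(sr[, c("ky", "kz")]))
    first_cycle <- sr[seq_len(min(cap, nrow(sr))), ]
    expect_false(any(duplicated(first_cycle[, c("ky", "kz")])))
  }
})

test_that("schedules are deterministic and over-long requests truncate with a warning", {
  s1 <- circus_schedule(c(32, 16), seed = 7)
  s2 <- circus_schedule(c(32, 16), seed = 7)
  expect_identical(s1, s2)
  expect_warning(circus_schedule(c(8, 8), n_interleaves = 1000), "truncat")
})

test_that("undersampling factor follows R = Ny*Nz / lines", {
  expect_equal(round(undersampling_factor(c(144, 30), 250)), 17)
  expect_equal(undersampling_factor(c(144, 30), 250), 17.28)
  expect_equal(undersampling_factor(c(8, 8), 64), 1)
  expect_equal(undersampling_factor(c(8, 8), 16), 4)
  expect_error(undersampling_factor(c(8, 8), 0))
})

test_that("view sharing keeps own lines and fills from the temporally nearest beat", {
  beat <- data.frame(line_id = 1:3, ky = c(0, 1, 2), kz = 0, t_ms = c(100, 104, 108))
  all <- rbind(beat,
               data.frame(line_id = 4, ky = 3, kz = 0, t_ms = 20),    # beat i-1
               data.frame(line_id = 5, ky = 3, kz = 0, t_ms = 400))   # beat i+2
  pos <- cbind(ky = 0:3, kz = 0)
  f <- view_share_fill(beat, all, pos)
  expect_equal(f$source, c("self", "self", "self", "shared"))
  expect_equal(f$line_id[4], 4)              # nearer in time than line 5
  # all positions acquired within the beat: identical, zero shared
  f2 <- view_share_fill(beat, beat, cbind(ky = 0:2, kz = 0))
  expect_equal(unname(attr(f2, "counts")[c("shared", "missing")]), c(0L, 0L))
  # never-acquired position stays missing and is counted
  f3 <- view_share_fill(beat, all, cbind(ky = 9, kz = 9))
  expect_equal(f3$source, "missing")
  expect_true(is.na(f3$line_id))
})

test_that("shared-line count equals the brute-force set difference on a toy stream", {
  s <- circus_schedule(c(12, 12), n_interleaves = 8)
  n_per_beat <- nrow(s) / 2
  lines <- data.frame(line_id = seq_len(nrow(s)), ky = s$ky, kz = s$kz,
                      t_ms = (seq_len(nrow(s)) - 1) * 4)
  beat1 <- lines[seq_len(n_per_beat), ]
  pos_all <- unique(lines[, c("ky", "kz")])
  f <- view_share_fill(beat1, lines, as.matrix(pos_all))
  in_beat1 <- paste(beat1$ky, beat1$kz) |> unique()
  brute_missing <- sum(!(paste(pos_all$ky, pos_all$kz) %in% in_beat1))
  expect_equal(unname(attr(f, "counts")["shared"]), brute_missing)
})

test_that("PSF incoherence grows and density stays center-weighted", {
  s <- cached_fixture("sched64", circus_schedule(c(64, 64)))
  ratios <- vapply(c(1, 2, 4, 8), function(m)
    psf_peak_sidelobe(sampling_mask(s, 0:(m - 1))), 1)
  # monotone non-decreasing up to the sidelobe estimation tolerance
  expect_true(all(ratios[-1] >= ratios[-length(ratios)] * 0.98))
  expect_gt(ratios[4], ratios[1])
  # contiguous window shorter than the cycle: center denser than periphery
  m <- sampling_mask(s, 0:7)
  rings <- ring_partition(64, 64)
  dens <- tapply(as.vector(m), as.vector(rings), mean)
  inner <- mean(dens[as.integer(names(dens)) <= 4])
  outer <- mean(dens[as.integer(names(dens)) >= 24])
  expect_gt(inner, outer)
})

test_that("schedules export as CSV", {
  s <- circus_schedule(c(8, 8), n_interleaves = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(s))
  expect_named(df, c("index", "ky", "kz", "interleave", "ring"))
})
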