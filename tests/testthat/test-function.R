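sp2 <- c(2, 2, 8)

test_that("Hough initialisation finds disks within the radius range", {
  disk <- image_stack(c(96, 96, 3), function(X, Y, s)
    0.2 + 0.8 * ((X - 48)^2 + (Y - 48)^2 <= 10^2))     # radius 20 mm at 2 mm voxels
  h <- hough_lv_init(disk, sp2, radius_range_mm = c(10, 30))
  expect_true(all(h$ok))
  expect_equal(h$r_mm, rep(20, 3), tolerance = 2)
  expect_equal(h$cx, rep(48, 3), tolerance = 1.01)
  # blank image: flagged, no crash
  hb <- hough_lv_init(array(0, c(96, 96, 2)), sp2)
  expect_false(any(hb$ok))
  # two disks, one inside the configured range: the in-range disk wins
  two <- image_stack(c(96, 96, 1), function(X, Y, s)
    0.2 + 0.8 * pmax((X - 30)^2 + (Y - 30)^2 <= 6^2,
                     (X - 64)^2 + (Y - 64)^2 <= 20^2))
  h2 <- hough_lv_init(two, sp2, radius_range_mm = c(8, 20))
  expect_equal(h2$r_mm[1], 12, tolerance = 2)
  expect_equal(c(h2$cx[1], h2$cy[1]), c(30, 30), tolerance = 1.01)
})

test_that("the level set fits disks and ellipses beyond circularity", {
  disk <- image_stack(c(96, 96, 1), function(X, Y, s)
    0.2 + 0.8 * ((X - 48)^2 + (Y - 48)^2 <= 10^2))
  h <- hough_lv_init(disk, sp2, radius_range_mm = c(10, 30))
  seg <- levelset_segment(disk, h, sp2)
  truth <- image_stack(c(96, 96, 1), function(X, Y, s)
    (X - 48)^2 + (Y - 48)^2 <= 10^2)[, , 1] > 0
  expect_gt(dice_masks(seg$mask[, , 1], truth), 0.95)
  expect_equal(unname(seg$slice_flags), "converged")

  ell <- image_stack(c(96, 96, 1), function(X, Y, s)
    0.2 + 0.8 * (((X - 48) / 15)^2 + ((Y - 48) / 10)^2 <= 1))
  h2 <- hough_lv_init(ell, sp2, radius_range_mm = c(10, 40))
  seg2 <- levelset_segment(ell, h2, sp2)
  te <- image_stack(c(96, 96, 1), function(X, Y, s)
    ((X - 48) / 15)^2 + ((Y - 48) / 10)^2 <= 1)[, , 1] > 0
  expect_gt(dice_masks(seg2$mask[, , 1], te), 0.9)
})

test_that("degenerate initialisations are flagged, and reruns are deterministic", {
  img <- image_stack(c(96, 96, 1), function(X, Y, s)
    0.2 + 0.8 * ((X - 70)^2 + (Y - 70)^2 <= 8^2))
  # init far outside the bright region, window fully dark
  bad <- data.frame(slice = 1, cx = 20, cy = 20, r_mm = 10, ok = TRUE)
  segb <- levelset_segment(img, bad, sp2)
  expect_true(unname(segb$slice_flags) %in% c("leak", "collapsed", "degenerate-init"))
  # determinism: identical inputs give identical masks
  good <- data.frame(slice = 1, cx = 70, cy = 70, r_mm = 16, ok = TRUE)
  m1 <- rv_segment(img, good, sp2)
  m2 <- rv_segment(img, good, sp2)
  expect_identical(m1$mask, m2$mask)
  expect_equal(m1$provenance, "manual")
})

test_that("the crescent-shaped RV is segmented from a covering manual seed", {
  cfg <- static_config(n = c(96, 96, 8), fov = c(192, 192, 96), coils = 1)
  ph <- make_phantom(cfg)
  vol <- ph$render_state(0, c(0, 0, 0))
  seed <- make_rv_seed(ph)
  seed <- seed[seed$slice == 4, ]
  # LV-first workflow: the segmented LV (dilated) is excluded from the RV
  lv <- levelset_segment(vol, hough_lv_init(vol, ph$spacing, c(15, 35)), ph$spacing)
  excl <- cine5d:::dilate_mask_mm(lv$mask, ph$spacing, 6)
  seg <- rv_segment(vol, seed, ph$spacing, exclude = excl)
  # ground-truth crescent on that slice: RV ellipsoid minus LV epicardium
  n <- cfg$matrix_size; spn <- ph$spacing; c0 <- floor(n / 2)
  X <- (matrix(seq_len(n[1]), n[1], n[2]) - 1 - c0[1]) * spn[1]
  Y <- (matrix(seq_len(n[2]), n[1], n[2], byrow = TRUE) - 1 - c0[2]) * spn[2]
  z <- (seed$slice[1] - 1 - c0[3]) * spn[3]
  g <- ph$geom_at(0)
  rvc <- cfg$rv_geometry$center
  in_rv <- ((X - rvc[1]) / g$rv_cav[1])^2 + ((Y - rvc[2]) / g$rv_cav[2])^2 +
    ((z - rvc[3]) / g$rv_cav[3])^2 <= 1
  in_lv <- (X / g$lv_epi[1])^2 + (Y / g$lv_epi[2])^2 + (z / g$lv_epi[3])^2 <= 1
  truth <- in_rv & !in_lv
  expect_gt(dice_masks(seg$mask[, , seed$slice[1]], truth), 0.85)
})

test_that("chamber volumes implement the EF arithmetic", {
  m <- array(FALSE, c(10, 10, 4, 3))
  m[1:5, 1:5, , 1] <- TRUE   # 100 voxels/slice * 4 slices
  m[1:5, 1:2, , 2] <- TRUE
  m[1:5, 1:4, , 3] <- TRUE
  cv <- chamber_volumes(m, spacing = c(10, 10, 2.5))  # voxel 0.25 mL
  expect_equal(cv$EDV_mL, 25)
  expect_equal(cv$ESV_mL, 10)
  expect_equal(cv$SV_mL, 15)
  expect_equal(cv$EF_pct, 60)
  expect_equal(cv$ed_phase, 1); expect_equal(cv$es_phase, 2)
  # constant volume: SV = EF = 0
  mc <- array(rep(m[, , , 1], 2), c(10, 10, 4, 2))
  cvc <- chamber_volumes(mc, spacing = c(10, 10, 2.5))
  expect_equal(cvc$SV_mL, 0); expect_equal(cvc$EF_pct, 0)
  # empty masks: EF undefined
  cv0 <- chamber_volumes(array(FALSE, c(4, 4, 2, 2)), spacing = c(1, 1, 1))
  expect_true(is.nan(cv0$EF_pct))
})

test_that("EF is stable under a finer voxel grid", {
  efs <- vapply(list(c(48, 48, 12), c(96, 96, 24)), function(n) {
    cfg <- static_config(n = n, fov = c(192, 192, 96), coils = 1)
    ph <- make_phantom(cfg)
    cine <- array(0, c(n, 2))
    cine[, , , 1] <- ph$render_state(0, c(0, 0, 0))
    cine[, , , 2] <- ph$render_state(0.5, c(0, 0, 0))
    masks <- segment_cine(cine, ph$spacing, "LV", radius_range_mm = c(12, 30))
    chamber_volumes(masks)$EF_pct
  }, 1)
  expect_lt(abs(diff(efs)), 1)
})

test_that("phase comparisons compute paired statistics and percentage change", {
  # identical pairs: zero t statistic, p = 1
  ee <- c(10, 12, 14, 16); ei <- ee
  cp <- compare_phases(ee, ei)
  expect_equal(cp$t_test$statistic, 0)
  expect_equal(cp$t_test$p, 1)
  expect_equal(cp$change_pct_mean, 0)
  # hand oracle: mean of per-pair changes 10%, 8.333%, 7.143%
  cp2 <- compare_phases(c(10, 12, 14), c(11, 13, 15))
  expect_equal(cp2$change_pct_mean, mean(c(1 / 10, 1 / 12, 1 / 14)) * 100,
               tolerance = 1e-9)
  expect_equal(cp2$change_pct_mean, 8.492, tolerance = 1e-3)
  # perfectly correlated parameter pair
  cp3 <- compare_phases(c(1, 2, 3, 4), c(2, 3, 4, 5), correlate_with = c(2, 4, 6, 8))
  expect_equal(cp3$correlation$r, 1, tolerance = 1e-9)
  # too few pairs: tests skipped with a message
  expect_message(cp4 <- compare_phases(c(1, 2), c(2, 3)), "skipped")
  expect_null(cp4$t_test)
  # group comparison plumbs through Mann-Whitney
  set.seed(10)
  g <- rep(c("F", "M"), each = 4)
  cp5 <- compare_phases(c(1, 2, 3, 4, 11, 12, 13, 14), rep(1, 8), gender = g)
  expect_true(cp5$mann_whitney$p < 0.05)
})

test_that("function reports assemble and round-trip through JSON", {
  pp <- list(EE = list(lv = list(ESV_mL = 40, EDV_mL = 100, SV_mL = 60, EF_pct = 60),
                       rv = list(ESV_mL = 80, EDV_mL = 150, SV_mL = 70, EF_pct = 46.667)),
             EI = list(lv = list(ESV_mL = 42, EDV_mL = 99, SV_mL = 57, EF_pct = 57.576),
                       rv = list(ESV_mL = 88, EDV_mL = 170, SV_mL = 82, EF_pct = 48.235)))
  rep <- function_report(pp)
  expect_equal(nrow(rep$table), 4)
  expect_equal(rep$table$SV_mL, rep$table$EDV_mL - rep$table$ESV_mL)
  lv_chg <- rep$change_pct[rep$change_pct$ventricle == "LV", ]
  expect_equal(lv_chg$ESV, (42 - 40) / 40 * 100)
  f <- withr::local_tempfile(fileext = ".json")
  write_function_report_json(rep, f)
  rt <- read_function_report_json(f)
  expect_equal(rt$table$EF_pct, rep$table$EF_pct, tolerance = 1e-12)
  expect_equal(rt$change_pct$EDV, rep$change_pct$EDV, tolerance = 1e-12)
})
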