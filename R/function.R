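# Ventricular function: Hough-circle initialisation of the LV, elliptically
# refined level-set (Chan-Vese) segmentation of LV/RV on short-axis slices,
# chamber volumetry (ESV/EDV/SV/EF), and the paired statistics comparing
# respiratory phases.

# FFT cross-correlation of an image with a DC-centered kernel
xcorr2_centered <- function(img, kernel) {
  n <- prod(dim(img))
  Re(stats::fft(stats::fft(img) * Conj(stats::fft(ifftshift(kernel))), inverse = TRUE)) / n
}

#' Hough-transform initial LV circles
#'
#' Detects, per short-axis slice, the strongest circular edge response within
#' a radius range: gradient-magnitude edges are cross-correlated with
#' annulus kernels of increasing radius and the best (center, radius) vote
#' wins. Slices whose best score falls below `min_score`, or whose center
#' strays far from the stack consensus, are flagged for a manual seed.
#'
#' @param volume magnitude array (x, y, z); slices are the (x, y) planes.
#' @param spacing voxel spacing mm.
#' @param radius_range_mm circle radius search range.
#' @param slices slice indices to process (default all).
#' @param edge_quantile quantile of gradient magnitude defining edge pixels.
#' @param min_score minimum annulus edge coverage (0..1) to accept a slice.
#' @param consensus_mm maximum distance from the median detected center.
#' @return data.frame (slice, cx, cy, r_mm, score, ok); cx/cy are 1-based
#'   voxel coordinates along x and y.
#' @export
hough_lv_init <- function(volume, spacing, radius_range_mm = c(10, 32),
                          slices = NULL, edge_quantile = 0.9,
                          min_score = 0.2, consensus_mm = 25) {
  d <- dim(volume)
  if (is.null(slices)) slices <- seq_len(d[3])
  sp <- spacing[1:2]
  n1 <- d[1]; n2 <- d[2]
  gx <- (seq_len(n1) - 1 - floor(n1 / 2)) * sp[1]
  gy <- (seq_len(n2) - 1 - floor(n2 / 2)) * sp[2]
  DX <- matrix(gx, n1, n2); DY <- matrix(gy, n1, n2, byrow = TRUE)
  DD <- sqrt(DX^2 + DY^2)
  radii <- seq(radius_range_mm[1], radius_range_mm[2], by = max(1, mean(sp) / 2))
  kernels <- lapply(radii, function(r) {
    k <- abs(DD - r) <= 0.75 * mean(sp)
    k / max(1, sum(k))
  })
  res <- data.frame(slice = slices, cx = NA_real_, cy = NA_real_,
                    r_mm = NA_real_, score = 0, ok = FALSE)
  for (i in seq_along(slices)) {
    I <- volume[, , slices[i]]
    if (max(I) <= 0) next
    ex <- (I[c(2:n1, n1), ] - I[c(1, 1:(n1 - 1)), ]) / (2 * sp[1])
    ey <- (I[, c(2:n2, n2)] - I[, c(1, 1:(n2 - 1))]) / (2 * sp[2])
    mag <- sqrt(ex^2 + ey^2)
    if (max(mag) <= 0) next
    # edge set: the sharper of a global-quantile and a fraction-of-max cut,
    # so flat images with a single structure still yield its edges
    thr <- max(stats::quantile(mag, edge_quantile, names = FALSE), 0.25 * max(mag))
    E <- (mag >= thr) * 1
    best_score <- -Inf; best_cx <- NA; best_cy <- NA; best_r <- NA
    for (j in seq_along(radii)) {
      acc <- xcorr2_centered(E, kernels[[j]])
      w <- which.max(acc)
      if (acc[w] > best_score) {
        best_score <- acc[w]
        best_cx <- (w - 1) %% n1 + 1
        best_cy <- (w - 1) %/% n1 + 1
        best_r <- radii[j]
      }
    }
    res$cx[i] <- best_cx; res$cy[i] <- best_cy; res$r_mm[i] <- best_r
    res$score[i] <- best_score
    res$ok[i] <- best_score >= min_score
  }
  if (any(res$ok)) {
    # consensus center from the top-scoring slices only: spurious circles in
    # chamber-free slices score systematically lower than the true cavity
    strong <- res$ok & res$score >= 0.9 * max(res$score[res$ok])
    mx <- stats::median(res$cx[strong]); my <- stats::median(res$cy[strong])
    far <- sqrt(((res$cx - mx) * sp[1])^2 + ((res$cy - my) * sp[2])^2) > consensus_mm
    res$ok[which(far)] <- FALSE
  }
  res
}

#' Level-set parameters
#' @param iters iteration cap per slice.
#' @param dt time step.
#' @param mu curvature (smoothness) weight.
#' @param ellipse_weight blending weight of the best-fit-ellipse attraction.
#' @param ellipse_every iterations between ellipse refinements.
#' @param window_factor local background window radius, in initial radii.
#' @param smooth_every iterations between Gaussian re-regularisation.
#' @return list of class `levelset_params`.
#' @export
#' @param bound_factor hard containment: the contour may not grow beyond
#'   `bound_factor` times the initial radius from the initial center.
levelset_params <- function(iters = 150, dt = 1, mu = 0.25,
                            ellipse_weight = 0.25, ellipse_every = 25,
                            window_factor = 3, smooth_every = 15,
                            bound_factor = 1.6) {
  p <- list(iters = iters, dt = dt, mu = mu, ellipse_weight = ellipse_weight,
            ellipse_every = ellipse_every, window_factor = window_factor,
            smooth_every = smooth_every, bound_factor = bound_factor)
  class(p) <- "levelset_params"
  p
}

# connected component of `mask` containing (cx, cy); falls back to the
# largest component when the center pixel is off the mask
seed_component <- function(mask, cx, cy) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  l0 <- lab[round(cx), round(cy)]
  if (l0 == 0) {
    tab <- tabulate(lab[lab > 0])
    l0 <- which.max(tab)
  }
  lab == l0
}

smooth2 <- function(m, sigma) {
  a <- array(m, c(dim(m), 1))
  gauss_smooth3(a, c(sigma, sigma, 0))[, , 1]
}

# Chan-Vese evolution with periodic elliptical refinement on one slice.
# Returns mask, status flag and iteration count.
chan_vese_slice <- function(I, cx, cy, r_vox, params, aspect = 1,
                            exclude = NULL) {
  n1 <- nrow(I); n2 <- ncol(I)
  mx <- max(I)
  if (mx <= 0) return(list(mask = matrix(FALSE, n1, n2), flag = "empty", iters = 0L))
  I <- I / mx
  X <- matrix(seq_len(n1), n1, n2); Y <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  D <- sqrt((X - cx)^2 + ((Y - cy) * aspect)^2)
  phi <- r_vox - D
  W <- D < params$window_factor * r_vox
  out_of_bound <- D > params$bound_factor * r_vox
  if (!is.null(exclude)) out_of_bound <- out_of_bound | exclude
  phi[out_of_bound] <- pmin(phi[out_of_bound], -1)
  area0 <- sum(phi > 0)
  if (area0 < 4) return(list(mask = matrix(FALSE, n1, n2), flag = "degenerate-init", iters = 0L))
  eps <- 1.5
  flag <- "max-iters"
  last_area <- area0
  stable <- 0L
  it <- 0L
  for (it in seq_len(params$iters)) {
    inside <- phi > 0
    if (!any(inside & W) || all(inside | !W)) { flag <- "collapsed"; break }
    c1 <- mean(I[inside & W]); c2 <- mean(I[!inside & W])
    F <- (I - c2)^2 - (I - c1)^2
    F <- F / max(abs(F), 1e-9)
    px <- (phi[c(2:n1, n1), ] - phi[c(1, 1:(n1 - 1)), ]) / 2
    py <- (phi[, c(2:n2, n2)] - phi[, c(1, 1:(n2 - 1))]) / 2
    pxx <- phi[c(2:n1, n1), ] - 2 * phi + phi[c(1, 1:(n1 - 1)), ]
    pyy <- phi[, c(2:n2, n2)] - 2 * phi + phi[, c(1, 1:(n2 - 1))]
    pxy <- (phi[c(2:n1, n1), c(2:n2, n2)] - phi[c(2:n1, n1), c(1, 1:(n2 - 1))] -
              phi[c(1, 1:(n1 - 1)), c(2:n2, n2)] + phi[c(1, 1:(n1 - 1)), c(1, 1:(n2 - 1))]) / 4
    kappa <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
      ((px^2 + py^2)^1.5 + 1e-8)
    delta <- eps / (pi * (eps^2 + phi^2))
    phi <- phi + params$dt * delta * (F + params$mu * kappa) / max(delta)
    phi[out_of_bound] <- pmin(phi[out_of_bound], -1)  # containment
    if (it %% params$smooth_every == 0) phi <- smooth2(phi, 0.7)
    if (params$ellipse_weight > 0 && it %% params$ellipse_every == 0) {
      m <- phi > 0
      if (sum(m) > 10) {
        pts <- cbind(X[m], Y[m] * aspect)
        ctr <- colMeans(pts)
        C <- stats::cov(pts) * 4
        Ci <- tryCatch(solve(C), error = function(e) NULL)
        if (!is.null(Ci)) {
          dx <- X - ctr[1]; dy <- Y * aspect - ctr[2]
          q <- Ci[1, 1] * dx^2 + 2 * Ci[1, 2] * dx * dy + Ci[2, 2] * dy^2
          reff <- det(C)^(1 / 4)
          phi_e <- (1 - sqrt(pmax(q, 0))) * reff
          w <- params$ellipse_weight
          phi <- (1 - w) * phi + w * phi_e
        }
      }
    }
    area <- sum(phi > 0)
    if (area > 3 * area0) { flag <- "leak"; break }
    if (it %% 10 == 0) {
      if (abs(area - last_area) <= max(2, 0.005 * area)) stable <- stable + 1L
      else stable <- 0L
      last_area <- area
      if (stable >= 2L) { flag <- "converged"; break }
    }
  }
  if (flag == "max-iters") flag <- "converged"
  mask <- phi > 0
  if (any(mask)) mask <- seed_component(mask, cx, cy)
  list(mask = mask, flag = flag, iters = it)
}

#' Level-set segmentation of one chamber in a 3D volume
#'
#' Evolves a region-based (piecewise-constant) level set from an initial
#' circle on every included slice, with a soft attraction of the zero set
#' toward its best-fit ellipse, so the contour may deform beyond circularity
#' while staying chamber-like. A mask growing beyond 3x the initial circle
#' aborts that slice with a `"leak"` flag.
#'
#' @param volume magnitude array (x, y, z).
#' @param init data.frame (slice, cx, cy, r_mm, ok) as from
#'   [hough_lv_init()] or a manual seed table.
#' @param spacing voxel spacing mm.
#' @param params a [levelset_params()].
#' @param ventricle label stored in the result (`"LV"` / `"RV"`).
#' @param provenance `"auto"` or `"manual"`.
#' @return a `chamber_masks`: `mask` (logical x,y,z), `slice_flags`,
#'   `included_slices`, `ventricle`, `provenance`, `spacing`.
#' @export
levelset_segment <- function(volume, init, spacing, params = levelset_params(),
                             ventricle = "LV", provenance = "auto",
                             exclude = NULL) {
  d <- dim(volume)
  mask <- array(FALSE, d)
  flags <- character(0)
  inc <- integer(0)
  aspect <- spacing[2] / spacing[1]
  for (i in seq_len(nrow(init))) {
    if (!isTRUE(init$ok[i])) next
    s <- init$slice[i]
    r <- chan_vese_slice(volume[, , s], init$cx[i], init$cy[i],
                         init$r_mm[i] / spacing[1], params, aspect,
                         exclude = if (!is.null(exclude)) exclude[, , s])
    mask[, , s] <- r$mask
    flags <- c(flags, stats::setNames(r$flag, s))
    inc <- c(inc, s)
  }
  out <- list(mask = mask, slice_flags = flags, included_slices = inc,
              ventricle = ventricle, provenance = provenance, spacing = spacing)
  class(out) <- "chamber_masks"
  out
}

#' Segment the RV from a manual covering seed
#'
#' Same elliptically refined level-set evolution as [levelset_segment()],
#' started from operator-provided circles centred on and covering the RV.
#'
#' @inheritParams levelset_segment
#' @param seed_circles data.frame (slice, cx, cy, r_mm); `ok` defaults TRUE.
#' @param exclude optional logical volume the contour may not enter;
#'   typically the already-segmented LV chamber dilated to (part of) its
#'   wall, since the covering RV seed usually overlaps the nearby LV.
#' @export
rv_segment <- function(volume, seed_circles, spacing,
                       params = levelset_params(), exclude = NULL) {
  if (is.null(seed_circles$ok)) seed_circles$ok <- TRUE
  levelset_segment(volume, seed_circles, spacing, params,
                   ventricle = "RV", provenance = "manual", exclude = exclude)
}

# dilate a logical volume slice-wise by a disc of radius r_mm
dilate_mask_mm <- function(mask, spacing, r_mm) {
  r_vox <- max(1L, round(r_mm / spacing[1]))
  brush <- EBImage::makeBrush(2 * r_vox + 1, "disc")
  out <- mask
  for (s in seq_len(dim(mask)[3]))
    if (any(mask[, , s]))
      out[, , s] <- EBImage::dilate(mask[, , s] * 1, brush) > 0
  out
}

#' Chamber volumes and ejection fraction over a cine
#'
#' Per cardiac phase, the chamber volume is the mask voxel count times the
#' voxel volume over the included slices. EDV and ESV are the maximum and
#' minimum phase volumes; `SV = EDV - ESV`; `EF = (EDV - ESV) / EDV * 100`.
#'
#' @param masks list of `chamber_masks` (one per cardiac phase) or a logical
#'   4D array (x, y, z, phase).
#' @param spacing voxel spacing mm (taken from the masks when available).
#' @param slice_range optional slice indices included in the volume
#'   computation (basal-slice inclusion choice); default all.
#' @return list: `volumes_ml` (per phase), `ESV_mL`, `EDV_mL`, `SV_mL`,
#'   `EF_pct` (NaN-flagged when EDV is 0), `ed_phase`, `es_phase`.
#' @export
chamber_volumes <- function(masks, spacing = NULL, slice_range = NULL) {
  if (is.list(masks) && inherits(masks[[1]], "chamber_masks")) {
    if (is.null(spacing)) spacing <- masks[[1]]$spacing
    arrs <- lapply(masks, function(m) m$mask)
  } else if (is.array(masks) && length(dim(masks)) == 4) {
    arrs <- lapply(seq_len(dim(masks)[4]), function(p) masks[, , , p])
  } else stop("masks must be a list of chamber_masks or a 4D logical array")
  if (length(arrs) < 2) stop("need at least 2 cardiac phases")
  if (is.null(spacing)) stop("spacing required")
  vox_ml <- prod(spacing) / 1000
  vols <- vapply(arrs, function(m) {
    if (!is.null(slice_range)) m <- m[, , slice_range, drop = FALSE]
    sum(m) * vox_ml
  }, 1)
  # phases where segmentation found nothing are excluded (flagged), not
  # counted as zero-volume hearts
  usable <- vols > 0
  if (sum(usable) < 2) {
    return(list(volumes_ml = vols, ESV_mL = NaN, EDV_mL = NaN, SV_mL = NaN,
                EF_pct = NaN, ed_phase = NA, es_phase = NA,
                excluded_phases = which(!usable)))
  }
  edv <- max(vols[usable]); esv <- min(vols[usable])
  list(volumes_ml = vols,
       ESV_mL = esv, EDV_mL = edv, SV_mL = edv - esv,
       EF_pct = if (edv > 0) (edv - esv) / edv * 100 else NaN,
       ed_phase = which(vols == edv)[1], es_phase = which(vols == esv)[1],
       excluded_phases = which(!usable))
}

#' Segment a ventricle across all cardiac phases of a cine
#'
#' LV: Hough initialisation per phase; RV: the manual seed table reused for
#' every phase.
#'
#' @param cine magnitude array (x, y, z, cardiac phase).
#' @param spacing voxel spacing mm.
#' @param ventricle `"LV"` or `"RV"`.
#' @param seeds manual seed table (required for RV).
#' @param radius_range_mm Hough search range (LV).
#' @param params a [levelset_params()].
#' @param lv_masks for RV: the per-phase LV `chamber_masks`, used (dilated
#'   by `lv_margin_mm`) as an exclusion region so the covering RV seed does
#'   not capture the neighbouring LV chamber.
#' @param lv_margin_mm dilation of the LV exclusion, mm.
#' @return list of `chamber_masks`, one per cardiac phase.
#' @export
segment_cine <- function(cine, spacing, ventricle = c("LV", "RV"),
                         seeds = NULL, radius_range_mm = c(10, 32),
                         params = levelset_params(),
                         lv_masks = NULL, lv_margin_mm = 6) {
  ventricle <- match.arg(ventricle)
  np <- dim(cine)[4]
  excl <- NULL
  if (ventricle == "RV" && !is.null(lv_masks)) {
    # static exclusion: the LV chamber region over the whole cycle (the
    # cavity's largest extent), dilated toward the wall
    u <- lv_masks[[1]]$mask
    for (p in seq_len(np)[-1]) u <- u | lv_masks[[p]]$mask
    excl <- dilate_mask_mm(u, spacing, lv_margin_mm)
  }
  lapply(seq_len(np), function(p) {
    vol <- cine[, , , p]
    if (ventricle == "LV") {
      init <- hough_lv_init(vol, spacing, radius_range_mm)
      levelset_segment(vol, init, spacing, params, "LV", "auto")
    } else {
      if (is.null(seeds)) stop("RV segmentation requires a manual seed table")
      rv_segment(vol, seeds, spacing, params, exclude = excl)
    }
  })
}

#' Paired comparison of a measurement between respiratory phases
#'
#' Two-tailed paired t-test between end-expiration and end-inspiration
#' values, per-subject percentage change `(EI - EE) / EE * 100` (averaged),
#' an optional Mann-Whitney test between groups (e.g. genders), and an
#' optional Pearson correlation against a respiratory parameter. Tests are
#' skipped with a message when fewer than 3 pairs are available.
#'
#' @param ee,ei paired per-subject measurements at EE and EI.
#' @param gender optional factor (two levels) for the group comparison,
#'   applied to the EE values.
#' @param correlate_with optional numeric vector (e.g. respiratory depth)
#'   correlated with the EE values.
#' @param alpha significance level reported alongside (0.05).
#' @return list of class `phase_comparison`: `n`, `change_pct_mean`,
#'   `change_pct_sd`, `t_test`, `mann_whitney`, `correlation` (each a list
#'   with statistic and p, or NULL when skipped).
#' @export
compare_phases <- function(ee, ei, gender = NULL, correlate_with = NULL,
                           alpha = 0.05) {
  stopifnot(length(ee) == length(ei))
  n <- length(ee)
  chg <- (ei - ee) / ee * 100
  out <- list(n = n, alpha = alpha,
              change_pct_mean = mean(chg), change_pct_sd = stats::sd(chg),
              t_test = NULL, mann_whitney = NULL, correlation = NULL)
  if (n < 3) {
    message("fewer than 3 pairs; statistical tests skipped")
  } else {
    d <- ei - ee
    if (stats::sd(d) == 0) {
      # degenerate paired differences: the t statistic limit
      tt <- if (mean(d) == 0) list(statistic = 0, p.value = 1)
            else list(statistic = sign(mean(d)) * Inf, p.value = 0)
    } else {
      t0 <- stats::t.test(ei, ee, paired = TRUE)
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    }
    out$t_test <- list(statistic = tt$statistic, p = tt$p.value,
                       significant = tt$p.value < alpha)
    if (!is.null(gender)) {
      g <- factor(gender)
      if (nlevels(g) == 2 && all(table(g) >= 2)) {
        mw <- stats::wilcox.test(ee ~ g, exact = FALSE)
        out$mann_whitney <- list(statistic = unname(mw$statistic), p = mw$p.value,
                                 significant = mw$p.value < alpha)
      }
    }
    if (!is.null(correlate_with)) {
      ct <- stats::cor.test(ee, correlate_with)
      out$correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                              significant = ct$p.value < alpha)
    }
  }
  class(out) <- "phase_comparison"
  out
}

#' Assemble a ventricular function report
#'
#' @param per_phase named list (respiratory phase -> list(lv = , rv = ) of
#'   [chamber_volumes()] results).
#' @param resp_metrics a `resp_metrics`.
#' @param comparisons optional named list of `phase_comparison` objects.
#' @return a `function_report` with a tidy `table` (ventricle, phase,
#'   ESV_mL, EDV_mL, SV_mL, EF_pct) plus `change_pct` between EI and EE per
#'   ventricle when both phases are present.
#' @export
function_report <- function(per_phase, resp_metrics = NULL, comparisons = NULL) {
  rows <- list()
  for (ph in names(per_phase)) {
    for (v in names(per_phase[[ph]])) {
      cv <- per_phase[[ph]][[v]]
      rows[[length(rows) + 1]] <- data.frame(
        ventricle = toupper(v), phase = ph,
        ESV_mL = cv$ESV_mL, EDV_mL = cv$EDV_mL,
        SV_mL = cv$SV_mL, EF_pct = cv$EF_pct)
    }
  }
  tab <- do.call(rbind, rows)
  change <- NULL
  if (all(c("EE", "EI") %in% names(per_phase))) {
    change <- do.call(rbind, lapply(names(per_phase$EE), function(v) {
      ee <- per_phase$EE[[v]]; ei <- per_phase$EI[[v]]
      data.frame(ventricle = toupper(v),
                 ESV = (ei$ESV_mL - ee$ESV_mL) / ee$ESV_mL * 100,
                 EDV = (ei$EDV_mL - ee$EDV_mL) / ee$EDV_mL * 100,
                 SV = (ei$SV_mL - ee$SV_mL) / ee$SV_mL * 100,
                 EF = (ei$EF_pct - ee$EF_pct) / ee$EF_pct * 100)
    }))
  }
  out <- list(table = tab, change_pct = change, resp_metrics = resp_metrics,
              comparisons = comparisons)
  class(out) <- "function_report"
  out
}

#' @export
print.function_report <- function(x, ...) {
  cat("<function_report>\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$resp_metrics)) print(x$resp_metrics)
  invisible(x)
}

#' Serialise a function report to JSON (and back)
#' @param report a `function_report`.
#' @param path output `.json` path.
#' @export
write_function_report_json <- function(report, path) {
  obj <- list(table = report$table, change_pct = report$change_pct,
              resp_metrics = unclass(report$resp_metrics),
              comparisons = lapply(report$comparisons, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_function_report_json
#' @export
read_function_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(table = obj$table, change_pct = obj$change_pct,
              resp_metrics = obj$resp_metrics, comparisons = obj$comparisons)
  class(out) <- "function_report"
  out
}
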