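# ECG synchronisation: sort readout lines into heartbeats, reconstruct
# low-resolution per-beat volumes for motion tracking (with view sharing),
# derive the 1D self-gating respiratory surrogate, and assign cardiac phases.

#' Sort readout lines into heartbeats
#'
#' Lines with timestamps in `[trigger_i, trigger_{i+1})` belong to beat i.
#' Lines before the first or after the last trigger are discarded (counted).
#' Beats with RR interval outside `[min_rr_ms, max_rr_ms]` are rejected as
#' trigger artifacts and logged.
#'
#' @param bundle a `kspace_bundle`.
#' @param min_rr_ms,max_rr_ms RR-interval acceptance gate.
#' @return a `beat_index`: data.frame (beat_id, trigger_ms, next_trigger_ms,
#'   rr_ms, hr_bpm, n_lines) of accepted beats, with attributes `line_ids`
#'   (list of line ids per beat), `discarded` (lines outside the trigger
#'   span), `rejected_beats`.
#' @export
sort_beats <- function(bundle, min_rr_ms = 300, max_rr_ms = 2000) {
  trig <- bundle$ecg_ms
  if (length(trig) < 2) stop("need at least 2 ECG triggers")
  if (any(diff(trig) <= 0)) stop("ECG triggers must be strictly increasing")
  t <- bundle$lines$t_ms
  b <- findInterval(t, trig)
  inside <- b >= 1 & b <= length(trig) - 1 & t < trig[length(trig)]
  discarded <- sum(!inside)
  rr <- diff(trig)
  ok_rr <- rr >= min_rr_ms & rr <= max_rr_ms
  ids <- which(ok_rr)
  line_ids <- split(bundle$lines$line_id[inside], b[inside])
  line_ids <- line_ids[as.character(ids)]
  names(line_ids) <- NULL
  df <- data.frame(beat_id = ids,
                   trigger_ms = trig[ids],
                   next_trigger_ms = trig[ids + 1],
                   rr_ms = rr[ids],
                   hr_bpm = 60000 / rr[ids],
                   n_lines = vapply(line_ids, length, 1L))
  attr(df, "line_ids") <- line_ids
  attr(df, "discarded") <- discarded
  attr(df, "rejected_beats") <- sum(!ok_rr)
  class(df) <- c("beat_index", "data.frame")
  df
}

# central-band extents (lines kept per axis) for a target resolution
lowres_band <- function(fov_mm, grid, target_resolution_mm) {
  keep <- round(fov_mm / target_resolution_mm)
  keep <- keep + keep %% 2          # round to even
  pmin(as.integer(keep), as.integer(grid))
}

#' Low-resolution per-beat volumes for motion tracking
#'
#' For each accepted beat: retain only k-space samples inside the central
#' band whose extent corresponds to `target_resolution_mm` given the FOV,
#' fill missing in-band positions by nearest-in-time view sharing from other
#' beats ([view_share_fill()]), inverse Fourier transform, and combine coils
#' by root-sum-of-squares.
#'
#' @param bundle a `kspace_bundle`.
#' @param beats a `beat_index` from [sort_beats()].
#' @param target_resolution_mm nominal isotropic tracking resolution.
#' @param view_share logical; fill missing positions from neighbouring beats.
#' @return list with `volumes` (magnitude array bx x by x bz x n_beats),
#'   `spacing` (mm), `band` (kept extents), `share_counts` (per beat:
#'   self/shared/missing), and `undersampling_R` (band size over mean lines
#'   per beat).
#' @export
lowres_beat_volumes <- function(bundle, beats, target_resolution_mm = 4,
                                view_share = TRUE) {
  stopifnot(inherits(beats, "beat_index"))
  if (nrow(beats) == 0) stop("no accepted beats")
  n <- bundle$grid
  band <- lowres_band(bundle$fov_mm, n, target_resolution_mm)
  if (any(band < 2)) stop("empty central band for the requested resolution")
  bx <- band_indices0(n[1], band[1]) + 1L
  by0 <- band_indices0(n[2], band[2])
  bz0 <- band_indices0(n[3], band[3])
  in_band <- bundle$lines$ky %in% by0 & bundle$lines$kz %in% bz0
  all_lines <- bundle$lines[in_band, c("line_id", "ky", "kz", "t_ms")]
  positions <- as.matrix(expand.grid(ky = by0, kz = bz0))
  line_ids <- attr(beats, "line_ids")
  nb <- nrow(beats)
  vols <- array(0, c(band, nb))
  counts <- matrix(0L, nb, 3, dimnames = list(NULL, c("self", "shared", "missing")))
  nc <- bundle$n_coils
  for (ib in seq_len(nb)) {
    own <- all_lines[all_lines$line_id %in% line_ids[[ib]], , drop = FALSE]
    if (view_share) {
      fill <- view_share_fill(own, all_lines, positions,
                              t_ref = (beats$trigger_ms[ib] + beats$next_trigger_ms[ib]) / 2)
    } else {
      fill <- view_share_fill(own, own, positions)
    }
    counts[ib, ] <- attr(fill, "counts")[c("self", "shared", "missing")]
    got <- !is.na(fill$line_id)
    ky_i <- match(fill$ky[got], by0)
    kz_i <- match(fill$kz[got], bz0)
    acc <- array(0, band)
    for (c in seq_len(nc)) {
      # fill columns: K[, ky_i[j], kz_i[j]] <- kdata[bx, line, c]
      Km <- matrix(0i, band[1], band[2] * band[3])
      Km[, ky_i + band[2] * (kz_i - 1)] <- bundle$kdata[bx, fill$line_id[got], c]
      dim(Km) <- band
      img <- ifftc(Km)
      acc <- acc + Mod(img)^2
    }
    vols[, , , ib] <- sqrt(acc)
  }
  list(volumes = vols,
       spacing = bundle$fov_mm / band,
       band = band,
       share_counts = counts,
       undersampling_R = prod(band[2:3]) / mean(beats$n_lines))
}

#' 1D self-gating respiratory trace
#'
#' Per beat, the superior-inferior projection profile (inverse FFT along the
#' readout of the central phase-encode lines, ring 0 of the CIRCUS pattern)
#' is registered to a reference beat's profile by cross-correlation with
#' sub-voxel (parabolic) refinement; the 1D shift, converted to mm, is the
#' surrogate. Beats without a central line get an interpolated value and are
#' flagged.
#'
#' @param bundle a `kspace_bundle`.
#' @param beats a `beat_index`.
#' @param reference index (into `beats`) of the reference beat.
#' @param smooth_window odd integer; running-median smoothing (1 = none).
#' @return data.frame (beat_id, t_ms, value_mm, interpolated).
#' @export
self_gating_1d <- function(bundle, beats, reference = 1, smooth_window = 1) {
  n <- bundle$grid
  cy <- floor(n[2] / 2); cz <- floor(n[3] / 2)
  is_center <- bundle$lines$ky %in% c(cy - 1, cy) & bundle$lines$kz %in% c(cz - 1, cz)
  line_ids <- attr(beats, "line_ids")
  nb <- nrow(beats)
  profiles <- matrix(NA_real_, bundle$grid[1], nb)
  for (ib in seq_len(nb)) {
    sel <- intersect(line_ids[[ib]], bundle$lines$line_id[is_center])
    if (!length(sel)) next
    mags <- vapply(sel, function(l) {
      p <- 0
      for (c in seq_len(bundle$n_coils)) p <- p + Mod(ifftc(bundle$kdata[, l, c]))^2
      sqrt(p)
    }, numeric(n[1]))
    profiles[, ib] <- rowMeans(mags)
  }
  have <- which(!is.na(profiles[1, ]))
  if (!length(have)) stop("no central (ring 0) lines in any beat")
  ref <- profiles[, if (reference %in% have) reference else have[1]]
  shift_of <- function(p) {
    cc <- vapply(-8:8, function(s) {
      i <- seq_len(length(p))
      j <- clamp(i + s, 1, length(p))
      sum(p[j] * ref[i])
    }, 1)
    k <- which.max(cc)
    s <- (-8:8)[k]
    if (k > 1 && k < length(cc)) {   # parabolic sub-voxel refinement
      denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      if (denom < 0) s <- s - 0.5 * (cc[k + 1] - cc[k - 1]) / denom
    }
    s
  }
  val <- rep(NA_real_, nb)
  for (ib in have) val[ib] <- shift_of(profiles[, ib]) * bundle$spacing[1]
  interpolated <- is.na(val)
  if (any(interpolated)) {
    val[interpolated] <- stats::approx(which(!interpolated), val[!interpolated],
                                       xout = which(interpolated), rule = 2)$y
  }
  if (smooth_window > 1) val <- stats::runmed(val, smooth_window)
  data.frame(beat_id = beats$beat_id,
             t_ms = (beats$trigger_ms + beats$next_trigger_ms) / 2,
             value_mm = val, interpolated = interpolated)
}

#' Assign readout lines to cardiac phases
#'
#' Phase index of a line is `floor((t - trigger) / (views_per_segment * TR))`
#' within its beat; the number of reconstructed phases is the largest count
#' every accepted beat supports. Temporal resolution is
#' `views_per_segment * TR` ms.
#'
#' @param bundle a `kspace_bundle`.
#' @param beats a `beat_index`.
#' @param views_per_segment views per segment (protocol value 10).
#' @return list with `phase` (0-based per line, NA for lines outside accepted
#'   beats or beyond the common phase count), `beat` (accepted beat row per
#'   line, NA likewise), `n_phases`, `temporal_resolution_ms`, `n_dropped`.
#' @export
cardiac_phase_assign <- function(bundle, beats, views_per_segment = 10) {
  stopifnot(views_per_segment >= 1)
  seg_ms <- views_per_segment * bundle$tr_ms
  n_phases <- max(1L, floor(min(beats$rr_ms) / seg_ms))
  line_ids <- attr(beats, "line_ids")
  phase <- rep(NA_integer_, nrow(bundle$lines))
  beat_of <- rep(NA_integer_, nrow(bundle$lines))
  for (ib in seq_len(nrow(beats))) {
    ids <- line_ids[[ib]]
    ph <- floor((bundle$lines$t_ms[ids] - beats$trigger_ms[ib]) / seg_ms)
    phase[ids] <- ph
    beat_of[ids] <- ib
  }
  dropped <- sum(phase >= n_phases, na.rm = TRUE)
  phase[!is.na(phase) & phase >= n_phases] <- NA_integer_
  list(phase = phase, beat = beat_of, n_phases = n_phases,
       temporal_resolution_ms = seg_ms, n_dropped = dropped)
}
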