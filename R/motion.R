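# Absolute 3D respiratory motion tracking: multi-resolution demons-style
# deformable registration of low-resolution beat volumes to a reference beat,
# averaged over the central quarter-FOV region.

#' Registration parameters
#'
#' @param levels pyramid depth (>= 1); level k works at 1/2^k resolution.
#' @param iterations iterations per level, coarse to fine.
#' @param sigma_fluid_vox Gaussian smoothing (voxels) of each update field.
#' @param sigma_elastic_vox Gaussian smoothing (voxels) of the accumulated
#'   field after each update.
#' @param similarity convergence monitor: `"mi"` (mutual information, 32-bin
#'   joint histogram) or `"ssd"` (negative sum of squared differences).
#' @param mi_bins histogram bins for the MI monitor.
#' @param max_step_mm per-iteration cap on the update magnitude.
#' @param tol relative similarity improvement below which the level is
#'   declared converged.
#' @return list of class `register_params`.
#' @export
register_params <- function(levels = 3, iterations = c(20, 20, 15),
                            sigma_fluid_vox = 1.0, sigma_elastic_vox = 0.6,
                            similarity = c("mi", "ssd"), mi_bins = 32,
                            max_step_mm = NULL, tol = 1e-4) {
  similarity <- match.arg(similarity)
  p <- list(levels = as.integer(levels),
            iterations = rep_len(as.integer(iterations), levels),
            sigma_fluid_vox = sigma_fluid_vox,
            sigma_elastic_vox = sigma_elastic_vox,
            similarity = similarity, mi_bins = as.integer(mi_bins),
            max_step_mm = max_step_mm, tol = tol)
  class(p) <- "register_params"
  p
}

mutual_information <- function(a, b, bins = 32) {
  ia <- clamp(floor(a * bins) + 1L, 1L, bins)
  ib <- clamp(floor(b * bins) + 1L, 1L, bins)
  h <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(ia)
  dim(h) <- c(bins, bins)
  px <- rowSums(h); py <- colSums(h)
  nz <- h > 0
  sum(h[nz] * log(h[nz] / (px[row(h)[nz]] * py[col(h)[nz]])))
}

# warp a volume by a displacement field in mm (sampling arr at x + u/spacing)
.warp_cache <- new.env(parent = emptyenv())

warp3_mm <- function(arr, field, spacing) {
  d <- dim(arr)
  key <- paste(d, collapse = "|")
  base <- .warp_cache[[key]]
  if (is.null(base)) {
    base <- list(x = rep(seq_len(d[1]), times = d[2] * d[3]),
                 y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                 z = rep(seq_len(d[3]), each = d[1] * d[2]))
    .warp_cache[[key]] <- base
  }
  n <- prod(d)
  array(interp3(arr,
                base$x + field[seq_len(n)] / spacing[1],
                base$y + field[n + seq_len(n)] / spacing[2],
                base$z + field[2 * n + seq_len(n)] / spacing[3]), d)
}

gradient3_mm <- function(arr, spacing) {
  d <- dim(arr)
  g <- array(0, c(d, 3))
  g[, , , 1] <- (arr[c(2:d[1], d[1]), , ] - arr[c(1, 1:(d[1] - 1)), , ]) / (2 * spacing[1])
  g[, , , 2] <- (arr[, c(2:d[2], d[2]), ] - arr[, c(1, 1:(d[2] - 1)), ]) / (2 * spacing[2])
  g[, , , 3] <- (arr[, , c(2:d[3], d[3])] - arr[, , c(1, 1:(d[3] - 1))]) / (2 * spacing[3])
  g
}

#' Deformable registration of two 3D magnitude volumes
#'
#' Multi-resolution free-form displacement estimation: a Thirion-style demons
#' update (intensity-difference force normalised by the fixed-image gradient)
#' with Gaussian fluid/elastic regularisation, monitored by the configured
#' similarity (mutual information by default, SSD selectable). The returned
#' field maps the target (current beat) back to the reference: a target equal
#' to the reference rigidly shifted by `+d` yields a field whose central mean
#' is approximately `+d` (mm).
#'
#' @param target,reference magnitude volumes on the same grid.
#' @param spacing voxel spacing in mm (length 3).
#' @param params a [register_params()].
#' @param init_field optional initial displacement field (mm) for warm starts.
#' @return list of class `deformation_field`: `field` (array dims x 3, mm),
#'   `similarity` (final monitor value), `converged`, `iterations`, `spacing`.
#' @export
register3d <- function(target, reference, spacing, params = register_params(),
                       init_field = NULL) {
  stopifnot(all(dim(target) == dim(reference)), length(spacing) == 3)
  norm01 <- function(v) {
    hi <- stats::quantile(v, 0.995, names = FALSE); lo <- min(v)
    if (hi <= lo) return(array(0, dim(v)))
    clamp((v - lo) / (hi - lo), 0, 1)
  }
  tn <- norm01(target); rn <- norm01(reference)
  sim_fun <- function(a, b) {
    if (params$similarity == "mi") mutual_information(a, b, params$mi_bins)
    else -mean((a - b)^2)
  }
  levels <- params$levels
  field <- NULL
  total_iter <- 0L
  converged <- TRUE
  for (lev in seq(levels - 1, 0)) {
    f <- 2^lev
    tl <- if (f > 1) downsample3(tn, f) else tn
    rl <- if (f > 1) downsample3(rn, f) else rn
    sp <- spacing * f
    d <- dim(tl)
    if (is.null(field)) {
      field <- array(0, c(d, 3))
      if (!is.null(init_field)) {
        for (k in 1:3) field[, , , k] <- array(
          interp3(init_field[, , , k],
                  seq(1, dim(init_field)[1], length.out = d[1])[rep(seq_len(d[1]), times = d[2] * d[3])],
                  rep(rep(seq(1, dim(init_field)[2], length.out = d[2]), each = d[1]), times = d[3]),
                  rep(seq(1, dim(init_field)[3], length.out = d[3]), each = d[1] * d[2])), d)
      }
    } else if (any(dim(field)[1:3] != d)) {
      up <- array(0, c(d, 3))
      for (k in 1:3) up[, , , k] <- array(
        interp3(field[, , , k],
                seq(1, dim(field)[1], length.out = d[1])[rep(seq_len(d[1]), times = d[2] * d[3])],
                rep(rep(seq(1, dim(field)[2], length.out = d[2]), each = d[1]), times = d[3]),
                rep(seq(1, dim(field)[3], length.out = d[3]), each = d[1] * d[2])), d)
      field <- up
    }
    gF <- gradient3_mm(rl, sp)
    xi2 <- 1 / mean(sp)^2
    max_step <- if (is.null(params$max_step_mm)) 1.25 * mean(sp) else params$max_step_mm
    best_sim <- -Inf
    stalled <- 0L
    level_converged <- FALSE
    mean_upd <- Inf
    for (it in seq_len(params$iterations[levels - lev])) {
      warped <- warp3_mm(tl, field, sp)
      diffim <- rl - warped
      # symmetric demons force: average of fixed and warped-moving gradients
      gM <- gradient3_mm(warped, sp)
      g1 <- (gF[, , , 1] + gM[, , , 1]) / 2
      g2c <- (gF[, , , 2] + gM[, , , 2]) / 2
      g3 <- (gF[, , , 3] + gM[, , , 3]) / 2
      g2 <- g1^2 + g2c^2 + g3^2
      denom <- g2 + diffim^2 * xi2
      scale <- diffim / pmax(denom, 1e-8)
      scale[denom < 1e-8] <- 0
      upd <- array(0, c(d, 3))
      upd[, , , 1] <- gauss_smooth3(scale * g1, params$sigma_fluid_vox)
      upd[, , , 2] <- gauss_smooth3(scale * g2c, params$sigma_fluid_vox)
      upd[, , , 3] <- gauss_smooth3(scale * g3, params$sigma_fluid_vox)
      mag <- sqrt(upd[, , , 1]^2 + upd[, , , 2]^2 + upd[, , , 3]^2)
      over <- mag > max_step
      if (any(over)) {
        sc <- array(1, d); sc[over] <- max_step / mag[over]
        for (k in 1:3) upd[, , , k] <- upd[, , , k] * sc
      }
      field <- field + upd
      for (k in 1:3) field[, , , k] <- gauss_smooth3(field[, , , k], params$sigma_elastic_vox)
      mean_upd <- mean(mag)
      total_iter <- total_iter + 1L
      s <- sim_fun(warp3_mm(tl, field, sp), rl)
      if (s > best_sim * (1 + sign(best_sim) * params$tol) + ifelse(best_sim == 0, params$tol, 0)) {
        best_sim <- s
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
        if (stalled >= 3L) { level_converged <- TRUE; break }
      }
    }
    # convergence at the finest level: similarity plateau with a settled field
    if (lev == 0) converged <- level_converged && mean_upd < 0.25 * mean(sp)
    attr(field, "similarity") <- best_sim
  }
  out <- list(field = field, similarity = attr(field, "similarity"),
              converged = converged, iterations = total_iter, spacing = spacing)
  class(out) <- "deformation_field"
  out
}

#' Mean displacement over the central region
#'
#' Average of the deformation vectors over the centered box covering
#' `fraction` of the field of view per axis (the heart-covering region used
#' for absolute motion tracking).
#'
#' @param field a `deformation_field` or a raw dims x 3 array.
#' @param fraction box side as a fraction of FOV per axis (default 1/4).
#' @return numeric (dx, dy, dz) in mm.
#' @export
central_roi_mean <- function(field, fraction = 0.25) {
  if (inherits(field, "deformation_field")) field <- field$field
  stopifnot(fraction > 0, fraction <= 1)
  d <- dim(field)[1:3]
  idx <- lapply(d, function(n) {
    half <- max(1L, round(n * fraction / 2))
    c0 <- floor(n / 2) + 1L
    clamp((c0 - half):(c0 + half - 1L), 1L, n)
  })
  v <- vapply(1:3, function(k) mean(field[idx[[1]], idx[[2]], idx[[3]], k]), 1)
  names(v) <- c("dx", "dy", "dz")
  v
}

#' Track per-beat heart displacement
#'
#' Registers every beat volume to the reference beat and summarises each
#' deformation field by its central-region mean, giving the absolute 3D
#' displacement trace (mm; positive x = heart moves up). Consecutive beats
#' warm-start from the previous field.
#'
#' @param volumes magnitude array (x, y, z, beat) from
#'   [lowres_beat_volumes()].
#' @param spacing voxel spacing in mm.
#' @param reference beat index used as reference (default 1).
#' @param params a [register_params()].
#' @param roi_fraction central-region fraction for the mean.
#' @param beat_ids optional beat ids for labelling.
#' @param warm_start reuse the previous beat's field as initialisation.
#' @return a `motion_trace`: data.frame (beat_id, dx_mm, dy_mm, dz_mm,
#'   converged) with attributes `reference`, `spacing`.
#' @export
track_motion <- function(volumes, spacing, reference = 1,
                         params = register_params(), roi_fraction = 0.25,
                         beat_ids = NULL, warm_start = TRUE) {
  nb <- dim(volumes)[4]
  if (nb < 2) stop("need at least 2 beats to track motion")
  if (is.null(beat_ids)) beat_ids <- seq_len(nb)
  ref <- volumes[, , , reference]
  out <- matrix(0, nb, 3)
  conv <- rep(TRUE, nb)
  prev <- NULL
  for (ib in seq_len(nb)) {
    if (ib == reference) { prev <- NULL; next }
    r <- register3d(volumes[, , , ib], ref, spacing, params,
                    init_field = if (warm_start) prev else NULL)
    out[ib, ] <- central_roi_mean(r, roi_fraction)
    conv[ib] <- r$converged
    prev <- r$field
  }
  tr <- data.frame(beat_id = beat_ids, dx_mm = out[, 1], dy_mm = out[, 2],
                   dz_mm = out[, 3], converged = conv)
  attr(tr, "reference") <- reference
  attr(tr, "spacing") <- spacing
  class(tr) <- c("motion_trace", "data.frame")
  tr
}

#' @export
print.motion_trace <- function(x, ...) {
  cat("<motion_trace> ", nrow(x), " beats, reference beat ",
      attr(x, "reference"), "\n", sep = "")
  cat(sprintf("  SI (x) range [%.2f, %.2f] mm\n", min(x$dx_mm), max(x$dx_mm)))
  invisible(x)
}

#' @export
plot.motion_trace <- function(x, ...) {
  graphics::matplot(x$beat_id, cbind(x$dx_mm, x$dy_mm, x$dz_mm), type = "l",
                    lty = 1, col = c("black", "steelblue", "tomato"),
                    xlab = "heartbeat", ylab = "displacement (mm)", ...)
  graphics::legend("topright", c("x (SI)", "y", "z"), lty = 1,
                   col = c("black", "steelblue", "tomato"), bty = "n")
  invisible(x)
}

#' Export a motion trace as CSV
#' @param trace a `motion_trace`.
#' @param path output file.
#' @param hr_bpm optional per-beat heart rate column.
#' @export
write_motion_trace_csv <- function(trace, path, hr_bpm = NULL) {
  df <- as.data.frame(trace)
  if (!is.null(hr_bpm)) df$hr_bpm <- hr_bpm
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
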