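# Respiratory phase binning: k-means clustering of per-beat displacements
# into four phases, end-expiration / end-inspiration identification, and the
# respiration-related metrics (rate, depth, portions, EE:EI ratio, per-phase
# heart rate).

#' Cluster per-beat displacements into four respiratory phases
#'
#' Lloyd's k-means with random initial seeds, run `restarts` times keeping
#' the solution with the lowest total intra-cluster variance (inertia).
#' Deterministic given `seed`. Works on a 3D [track_motion()] trace or on a
#' 1D surrogate (e.g. the self-gating trace), in which case the single
#' column plays the role of the x displacement.
#'
#' @param trace a `motion_trace`, a numeric matrix of per-beat displacement
#'   vectors, or a numeric vector (1D surrogate).
#' @param restarts number of random restarts (protocol value 10).
#' @param seed integer seed for the restarts.
#' @param k number of clusters; fixed at 4 respiratory phases by default.
#' @return a `resp_binning`: `labels` (cluster id per beat), `centroids`
#'   (k x dims, mm), `inertia`, `phase_names` (set by [assign_phases()],
#'   which is called automatically), `beat_ids`.
#' @export
kmeans4 <- function(trace, restarts = 10, seed = NULL, k = 4) {
  if (inherits(trace, "motion_trace")) {
    X <- as.matrix(trace[, c("dx_mm", "dy_mm", "dz_mm")])
    beat_ids <- trace$beat_id
  } else {
    X <- as.matrix(trace)
    beat_ids <- seq_len(nrow(X))
  }
  colnames(X) <- c("dx_mm", "dy_mm", "dz_mm")[seq_len(ncol(X))]
  if (nrow(X) < 2 * k) stop("need at least ", 2 * k, " beats to bin")
  if (nrow(unique(X)) < k) stop("insufficient motion diversity: fewer than ",
                                k, " distinct displacement points")
  fits <- with_local_seed(seed, {
    lapply(seq_len(restarts), function(i) {
      tryCatch(stats::kmeans(X, centers = k, iter.max = 100,
                             algorithm = "Lloyd", nstart = 1),
               error = function(e) NULL, warning = function(w) {
                 tryCatch(suppressWarnings(stats::kmeans(X, centers = k,
                                                         iter.max = 200,
                                                         algorithm = "Lloyd")),
                          error = function(e) NULL)
               })
    })
  })
  fits <- Filter(Negate(is.null), fits)
  fits <- Filter(function(f) all(f$size > 0), fits)
  if (!length(fits)) stop("k-means failed on all restarts")
  inert <- vapply(fits, function(f) f$tot.withinss, 1)
  best <- fits[[which.min(inert)]]
  out <- list(labels = best$cluster, centroids = best$centers,
              inertia = best$tot.withinss, restart_inertias = inert,
              beat_ids = beat_ids, points = X, k = k)
  class(out) <- "resp_binning"
  assign_phases(out)
}

#' Name the respiratory phases of a clustering
#'
#' Orders clusters by the x (superior-inferior) component of their centroids:
#' the most positive is end-expiration (EE), the most negative
#' end-inspiration (EI), and the two in between are the mid phases, by x
#' order. Ties are broken by the within-cluster second moment along x (logged
#' via `message`).
#'
#' @param binning a `resp_binning`.
#' @return the binning with `phase_names` set: character vector mapping
#'   cluster id to one of `"EE"`, `"mid-expiration"`, `"mid-inspiration"`,
#'   `"EI"`.
#' @export
assign_phases <- function(binning) {
  cx <- binning$centroids[, 1]
  if (anyDuplicated(cx)) {
    # ties: order by the within-cluster second moment along SI
    m2 <- vapply(seq_len(binning$k), function(c) {
      sel <- binning$labels == c
      if (!any(sel) || is.null(binning$points)) return(0)
      mean((binning$points[sel, 1] - cx[c])^2)
    }, 1)
    message("tied centroid x components; breaking ties by SI second moment")
    ord <- order(cx, m2, decreasing = TRUE)
  } else {
    ord <- order(cx, decreasing = TRUE)
  }
  nm <- character(binning$k)
  labels4 <- c("EE", "mid-expiration", "mid-inspiration", "EI")
  if (binning$k == 4) {
    nm[ord] <- labels4
  } else {
    nm[ord] <- c("EE", paste0("mid-", seq_len(binning$k - 2)), "EI")[seq_len(binning$k)]
  }
  binning$phase_names <- nm
  binning
}

#' Beats belonging to a named respiratory phase
#' @param binning a `resp_binning`.
#' @param phase one of the names in `binning$phase_names` (e.g. `"EE"`).
#' @return the beat ids in that phase.
#' @export
phase_beats <- function(binning, phase) {
  cl <- which(binning$phase_names == phase)
  binning$beat_ids[binning$labels %in% cl]
}

#' Respiratory depth
#'
#' Euclidean distance (mm) between the end-expiration and end-inspiration
#' cluster centroids:
#' `sqrt((c1x-c2x)^2 + (c1y-c2y)^2 + (c1z-c2z)^2)`.
#'
#' @param binning a `resp_binning` with phases assigned.
#' @return depth in mm.
#' @export
respiratory_depth <- function(binning) {
  ee <- binning$centroids[which(binning$phase_names == "EE"), ]
  ei <- binning$centroids[which(binning$phase_names == "EI"), ]
  sqrt(sum((ee - ei)^2))
}

#' Respiration-related metrics of a binning
#'
#' Data portions (percentage of heartbeats per phase), average motion (mean
#' Euclidean distance of the phase's points from their centroid), the EE:EI
#' portion ratio, per-phase mean instantaneous heart rate, the respiratory
#' depth, and the respiratory rate from the dominant spectral peak of the SI
#' displacement trace (and of the bellows trace when given).
#'
#' @param binning a `resp_binning`.
#' @param trace the clustered trace (motion_trace / matrix / vector).
#' @param hr_bpm per-beat instantaneous heart rate (optional).
#' @param beat_t_ms per-beat times (ms) for the spectral rate estimate.
#' @param bellows optional data.frame (t_ms, value) for a bellows-based rate.
#' @return a `resp_metrics` list: `resp_rate_brpm`, `resp_rate_bellows_brpm`,
#'   `resp_depth_mm`, `data_portion_pct`, `average_motion_mm`,
#'   `ee_ei_ratio`, `hr_bpm` (per phase).
#' @export
resp_metrics <- function(binning, trace = NULL, hr_bpm = NULL,
                         beat_t_ms = NULL, bellows = NULL) {
  k <- binning$k
  counts <- tabulate(binning$labels, k)
  portions <- 100 * counts / sum(counts)
  names(portions) <- binning$phase_names
  X <- NULL
  if (!is.null(trace)) {
    X <- if (inherits(trace, "motion_trace"))
      as.matrix(trace[, c("dx_mm", "dy_mm", "dz_mm")]) else as.matrix(trace)
  }
  avg_motion <- rep(NA_real_, k)
  if (!is.null(X)) {
    for (c in seq_len(k)) {
      sel <- binning$labels == c
      if (any(sel)) {
        dif <- sweep(X[sel, , drop = FALSE], 2, binning$centroids[c, ])
        avg_motion[c] <- mean(sqrt(rowSums(dif^2)))
      } else avg_motion[c] <- NaN
    }
  }
  names(avg_motion) <- binning$phase_names
  ee <- which(binning$phase_names == "EE"); ei <- which(binning$phase_names == "EI")
  ratio <- if (counts[ei] > 0) portions[[ee]] / portions[[ei]] else NaN
  hr_phase <- rep(NA_real_, k); names(hr_phase) <- binning$phase_names
  if (!is.null(hr_bpm)) {
    for (c in seq_len(k)) {
      sel <- binning$labels == c
      hr_phase[c] <- if (any(sel)) mean(hr_bpm[sel]) else NaN
    }
  }
  rate <- NA_real_
  if (!is.null(X) && !is.null(beat_t_ms))
    rate <- spectral_resp_rate(beat_t_ms, X[, 1])
  rate_bell <- if (!is.null(bellows))
    spectral_resp_rate(bellows$t_ms, bellows$value) else NA_real_
  out <- list(resp_rate_brpm = rate,
              resp_rate_bellows_brpm = rate_bell,
              resp_depth_mm = respiratory_depth(binning),
              data_portion_pct = portions,
              average_motion_mm = avg_motion,
              ee_ei_ratio = ratio,
              hr_bpm = hr_phase)
  class(out) <- "resp_metrics"
  out
}

# dominant-frequency respiratory rate (breaths/min) of an irregularly sampled
# trace, via resampling to a uniform grid and an FFT periodogram
spectral_resp_rate <- function(t_ms, value, f_range_hz = c(0.05, 0.8)) {
  if (length(t_ms) < 8) return(NA_real_)
  dt <- 0.2  # s
  tt <- seq(min(t_ms), max(t_ms), by = dt * 1000)
  if (length(tt) < 16) return(NA_real_)
  v <- stats::approx(t_ms, value, xout = tt, rule = 2)$y
  v <- v - mean(v)
  v <- v * (0.5 - 0.5 * cos(2 * pi * seq_along(v) / length(v)))  # Hann
  sp <- Mod(stats::fft(v))^2
  f <- (seq_along(v) - 1) / (length(v) * dt)
  sel <- f >= f_range_hz[1] & f <= f_range_hz[2]
  if (!any(sel)) return(NA_real_)
  60 * f[sel][which.max(sp[sel])]
}

#' @export
print.resp_binning <- function(x, ...) {
  cat("<resp_binning> ", length(x$labels), " beats in ", x$k,
      " phases, inertia ", signif(x$inertia, 4), "\n", sep = "")
  lev <- intersect(c("EE", "mid-expiration", "mid-inspiration", "EI"), x$phase_names)
  print(table(factor(x$phase_names[x$labels], levels = lev)))
  invisible(x)
}

#' @export
print.resp_metrics <- function(x, ...) {
  cat("<resp_metrics>\n")
  cat(sprintf("  resp rate %.1f brpm, depth (Dd) %.2f mm, EE:EI ratio %.2f\n",
              x$resp_rate_brpm, x$resp_depth_mm, x$ee_ei_ratio))
  cat("  portions (%):", paste(sprintf("%s=%.1f", names(x$data_portion_pct),
                                       x$data_portion_pct), collapse = ", "), "\n")
  if (!all(is.na(x$hr_bpm)))
    cat("  HR (bpm):", paste(sprintf("%s=%.1f", names(x$hr_bpm), x$hr_bpm),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Export a binning as CSV
#' @param binning a `resp_binning`.
#' @param path output file.
#' @export
write_binning_csv <- function(binning, path) {
  df <- data.frame(beat_id = binning$beat_ids,
                   cluster = binning$labels,
                   phase = binning$phase_names[binning$labels])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dice coefficient of two index sets
#' @param a,b vectors of ids.
#' @return `2|a n b| / (|a| + |b|)`; NaN when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!length(a) && !length(b)) return(NaN)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
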