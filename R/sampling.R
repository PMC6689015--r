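# CIRCUS: pseudo-random variable-density interleaved Cartesian undersampling
# of the (ky, kz) phase-encode plane, organised in concentric square rings,
# with partial Fourier; plus the nearest-neighbour view-sharing fill policy.

#' Partition a phase-encode grid into concentric square rings
#'
#' Rings are centered on DC (0-based index `floor(N/2)` per axis). Ring 0 is
#' the central 2 x 2 block; ring r adds the square shell around ring r-1.
#' Every grid point belongs to exactly one ring.
#'
#' @param ny,nz grid extents (both >= 2).
#' @return integer matrix (ny x nz) of ring ids; rows index ky (0-based grid
#'   index = row - 1), columns kz.
#' @export
ring_partition <- function(ny, nz) {
  ny <- as.integer(ny); nz <- as.integer(nz)
  stopifnot(ny >= 2, nz >= 2)
  gy <- ring_offset_radius(0:(ny - 1) - floor(ny / 2))
  gz <- ring_offset_radius(0:(nz - 1) - floor(nz / 2))
  outer(gy, gz, pmax)
}

# radius of a 0-based offset from DC: offsets {-1, 0} -> 0, {-2, 1} -> 1, ...
ring_offset_radius <- function(d) ifelse(d >= 0, d, -d - 1L)

#' Generate a CIRCUS sampling schedule
#'
#' One interleave visits every ring once; within interleave `t` the position
#' along the perimeter of ring `r` is chosen at fractional arc
#' `u(r, t) = frac(t * phi + c * r / R_max)` with `phi` the golden-ratio
#' conjugate (~0.618) and `c` the spiral parameter: `c = 0` degenerates to a
#' radial-like spoke, larger `c` twists the selection across rings. Positions
#' falling outside the partial-Fourier region, or already used in the current
#' pass over the ring, are re-drawn at the nearest free perimeter slot, so
#' each ring exhausts all its in-region points before reusing any (the center
#' rings cycle faster than the periphery, which is what makes the density
#' variable). Ordering is interleave-major, so any contiguous time window is
#' a valid interleaved subset.
#'
#' @param grid integer pair (Ny, Nz).
#' @param circus_c spiral parameter (protocol value 1.5).
#' @param partial_fourier fraction kept per phase-encode axis in `[0.5, 1]`
#'   (protocol value 0.75); the kept band is the DC-centered positive half
#'   plus part of the negative half.
#' @param n_interleaves number of interleaves to generate; defaults to one
#'   full cycle of the largest ring. Values beyond the largest ring's
#'   capacity are truncated with a warning.
#' @param seed optional integer; jitters the golden-angle phase origin
#'   deterministically (NULL = canonical schedule).
#' @return a `circus_schedule`: data.frame (ky, kz, interleave, ring) with
#'   0-based indices, with attributes `grid`, `circus_c`, `partial_fourier`.
#' @export
circus_schedule <- function(grid, circus_c = 1.5, partial_fourier = 0.75,
                            n_interleaves = NULL, seed = NULL) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2, all(grid >= 2))
  if (partial_fourier < 0.5 || partial_fourier > 1)
    stop("partial_fourier must be in [0.5, 1]")
  ny <- grid[1]; nz <- grid[2]
  rings <- ring_partition(ny, nz)
  in_pf <- matrix(FALSE, ny, nz)
  in_pf[pf_indices0(ny, partial_fourier) + 1L, pf_indices0(nz, partial_fourier) + 1L] <- TRUE

  # perimeter ordering per ring: points sorted by angle about DC
  cy <- floor(ny / 2); cz <- floor(nz / 2)
  ring_ids <- sort(unique(rings[in_pf]))
  perims <- lapply(ring_ids, function(r) {
    sel <- which(rings == r & in_pf, arr.ind = TRUE)
    ky <- sel[, 1] - 1L; kz <- sel[, 2] - 1L
    ang <- atan2(kz - cz + 0.5, ky - cy + 0.5)
    o <- order(ang)
    cbind(ky = ky[o], kz = kz[o])
  })
  rmax <- max(ring_ids)
  phi <- (sqrt(5) - 1) / 2
  t0 <- if (is.null(seed)) 0 else with_local_seed(as.integer(seed), stats::runif(1))
  cap <- max(vapply(perims, nrow, 1L))
  if (is.null(n_interleaves)) n_interleaves <- cap
  if (n_interleaves > cap) {
    warning("n_interleaves exceeds the largest ring's unique points (", cap,
            "); truncating")
    n_interleaves <- cap
  }
  used <- lapply(perims, function(p) logical(nrow(p)))
  res <- vector("list", n_interleaves)
  for (t in seq_len(n_interleaves)) {
    ky <- integer(length(ring_ids)); kz <- integer(length(ring_ids))
    for (i in seq_along(ring_ids)) {
      p <- perims[[i]]
      np <- nrow(p)
      if (all(used[[i]])) used[[i]][] <- FALSE   # ring cycle restarts
      u <- ((t - 1) * phi + t0 + circus_c * ring_ids[i] / max(rmax, 1)) %% 1
      pos <- (floor(u * np)) %% np + 1L
      if (used[[i]][pos]) {                      # nearest free slot (cyclic)
        free <- which(!used[[i]])
        dist <- pmin((free - pos) %% np, (pos - free) %% np)
        pos <- free[which.min(dist)]
      }
      used[[i]][pos] <- TRUE
      ky[i] <- p[pos, 1]; kz[i] <- p[pos, 2]
    }
    res[[t]] <- data.frame(ky = ky, kz = kz, interleave = t - 1L, ring = ring_ids)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "circus_c") <- circus_c
  attr(out, "partial_fourier") <- partial_fourier
  class(out) <- c("circus_schedule", "data.frame")
  out
}

#' @export
print.circus_schedule <- function(x, ...) {
  cat("<circus_schedule> grid ", paste(attr(x, "grid"), collapse = "x"),
      ", c=", attr(x, "circus_c"), ", pf=", attr(x, "partial_fourier"),
      ", ", max(x$interleave) + 1L, " interleaves (", nrow(x), " entries)\n", sep = "")
  invisible(x)
}

#' Binary sampling mask of a set of interleaves
#'
#' @param schedule a `circus_schedule`.
#' @param interleaves which interleave ids (0-based) to include; NULL = all.
#' @return logical matrix (Ny x Nz).
#' @export
sampling_mask <- function(schedule, interleaves = NULL) {
  g <- attr(schedule, "grid")
  s <- if (is.null(interleaves)) schedule else schedule[schedule$interleave %in% interleaves, ]
  m <- matrix(FALSE, g[1], g[2])
  m[cbind(s$ky + 1L, s$kz + 1L)] <- TRUE
  m
}

#' Per-volume undersampling factor
#'
#' `R = Ny * Nz / lines_per_beat`: the full phase-encode grid size over the
#' number of lines actually collected in one heartbeat.
#'
#' @param grid integer pair (Ny, Nz).
#' @param lines_per_beat lines acquired in the beat (>= 1).
#' @return unitless acceleration factor.
#' @export
undersampling_factor <- function(grid, lines_per_beat) {
  stopifnot(lines_per_beat >= 1)
  prod(as.integer(grid)) / lines_per_beat
}

#' Nearest-neighbour view sharing for one heartbeat
#'
#' Fills phase-encode positions missing from a beat with the temporally
#' nearest acquisition of that position from other beats. Positions already
#' acquired within the beat are always taken from the beat itself (so the
#' densely revisited low-frequency center is dominated by the beat's own
#' data, and sharing happens mainly at high frequencies). Positions never
#' acquired anywhere remain unfilled and are counted.
#'
#' @param beat_lines data.frame with `line_id`, `ky`, `kz`, `t_ms` for the
#'   beat's own lines.
#' @param all_lines data.frame with the same columns for the whole scan.
#' @param positions integer matrix / data.frame of required (ky, kz)
#'   positions (0-based); defaults to every position present in `all_lines`.
#' @param t_ref reference time (ms) of the beat for the nearest rule;
#'   defaults to the midpoint of the beat's own line times.
#' @param policy only `"nearest"` is defined.
#' @return data.frame (ky, kz, line_id, source) where `source` is `"self"`,
#'   `"shared"` or `"missing"` (line_id NA); attribute `counts` with the
#'   three totals.
#' @export
view_share_fill <- function(beat_lines, all_lines, positions = NULL,
                            t_ref = NULL, policy = "nearest") {
  if (!identical(policy, "nearest")) stop("only the 'nearest' policy is defined")
  if (is.null(t_ref)) t_ref <- stats::median(beat_lines$t_ms)
  keyfun <- function(ky, kz) paste(ky, kz, sep = ",")
  if (is.null(positions)) {
    u <- !duplicated(keyfun(all_lines$ky, all_lines$kz))
    positions <- cbind(ky = all_lines$ky[u], kz = all_lines$kz[u])
  }
  positions <- as.matrix(positions)
  pk <- keyfun(positions[, 1], positions[, 2])
  self_map <- split(beat_lines$line_id, keyfun(beat_lines$ky, beat_lines$kz))
  other <- all_lines[!(all_lines$line_id %in% beat_lines$line_id), , drop = FALSE]
  other_map <- split(seq_len(nrow(other)), keyfun(other$ky, other$kz))
  line_id <- rep(NA_integer_, nrow(positions))
  source <- rep("missing", nrow(positions))
  for (i in seq_len(nrow(positions))) {
    k <- pk[i]
    if (!is.null(self_map[[k]])) {
      line_id[i] <- self_map[[k]][1]
      source[i] <- "self"
    } else if (!is.null(other_map[[k]])) {
      j <- other_map[[k]]
      line_id[i] <- other$line_id[j[which.min(abs(other$t_ms[j] - t_ref))]]
      source[i] <- "shared"
    }
  }
  out <- data.frame(ky = positions[, 1], kz = positions[, 2],
                    line_id = line_id, source = source)
  attr(out, "counts") <- c(self = sum(source == "self"),
                           shared = sum(source == "shared"),
                           missing = sum(source == "missing"))
  out
}

#' Point-spread-function incoherence of a mask
#'
#' Peak-to-largest-sidelobe magnitude ratio of the PSF (inverse DFT of the
#' sampling mask); larger is more incoherent aliasing.
#'
#' @param mask logical/numeric matrix.
#' @return scalar ratio.
#' @export
psf_peak_sidelobe <- function(mask) {
  psf <- Mod(stats::fft(ifftshift(mask * 1), inverse = TRUE))
  peak <- psf[1, 1]
  psf[1, 1] <- 0
  peak / max(psf)
}

#' Export a schedule as CSV
#' @param schedule a `circus_schedule`.
#' @param path output file.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- data.frame(index = seq_len(nrow(schedule)) - 1L,
                   ky = schedule$ky, kz = schedule$kz,
                   interleave = schedule$interleave, ring = schedule$ring)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
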