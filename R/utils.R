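# Internal numerical helpers: DC-centered unitary FFTs, resampling,
# Gaussian smoothing, local RNG scope.

#' @keywords internal
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    c <- floor(n / 2)
    ((seq_len(n) - 1 + (n - c)) %% n) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @keywords internal
ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    c <- floor(n / 2)
    ((seq_len(n) - 1 + c) %% n) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Unitary DC-centered n-dimensional FFT pair. DC sits at 0-based index
# floor(N/2) along every axis; spatial index 0 is the first voxel, so the
# forward transform matches the textbook DFT
#   K[k] = N^{-1/2} * sum_x V[x] exp(-2*pi*i * sum_d (k_d - c_d) x_d / N_d).
#' @keywords internal
fftc <- function(x) {
  n <- length(x)
  fftshift(stats::fft(x)) / sqrt(n)
}

#' @keywords internal
ifftc <- function(k) {
  n <- length(k)
  stats::fft(ifftshift(k), inverse = TRUE) / sqrt(n)
}

# Centered contiguous band of `keep` indices (0-based) around DC.
#' @keywords internal
band_indices0 <- function(n, keep) {
  keep <- max(1L, min(n, as.integer(keep)))
  c0 <- floor(n / 2)
  lo <- c0 - floor(keep / 2)
  lo:(lo + keep - 1L)
}

# Partial-Fourier keep range along one axis (0-based indices): the DC-centered
# positive half plus a fraction of the negative half, extent round(pf * n).
#' @keywords internal
pf_indices0 <- function(n, pf) {
  stopifnot(pf >= 0.5, pf <= 1)
  keep <- round(pf * n)
  (n - keep):(n - 1L)
}

#' @keywords internal
nrmse <- function(est, truth) {
  sqrt(sum(Mod(est - truth)^2)) / sqrt(sum(Mod(truth)^2))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL leaves the stream alone.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based), clamped at the borders.
#' @keywords internal
interp3 <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  if (any(d[1:3] < 2)) stop("interp3 needs extents >= 2 per axis")
  xi <- pmin.int(pmax.int(xi, 1), d[1])
  yi <- pmin.int(pmax.int(yi, 1), d[2])
  zi <- pmin.int(pmax.int(zi, 1), d[3])
  x0 <- floor(xi); x0[x0 > d[1] - 1] <- d[1] - 1
  y0 <- floor(yi); y0[y0 > d[2] - 1] <- d[2] - 1
  z0 <- floor(zi); z0[z0 > d[3] - 1] <- d[3] - 1
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  o2 <- d[1]; o3 <- d[1] * d[2]
  i000 <- x0 + o2 * (y0 - 1) + o3 * (z0 - 1)
  gx0 <- 1 - fx; gy0 <- 1 - fy; gz0 <- 1 - fz
  (arr[i000] * gx0 + arr[i000 + 1] * fx) * gy0 * gz0 +
    (arr[i000 + o2] * gx0 + arr[i000 + o2 + 1] * fx) * fy * gz0 +
    (arr[i000 + o3] * gx0 + arr[i000 + o3 + 1] * fx) * gy0 * fz +
    (arr[i000 + o2 + o3] * gx0 + arr[i000 + o2 + o3 + 1] * fx) * fy * fz
}

# Frequency-domain Gaussian smoothing of a 3D array; sigma in voxels per axis.
# Periodic boundaries (fields and magnitudes here vanish near the borders).
#' @keywords internal
.smooth_cache <- new.env(parent = emptyenv())

gauss_smooth3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  if (all(sigma <= 0)) return(arr)
  key <- paste(c(d, signif(sigma, 6)), collapse = "|")
  m <- .smooth_cache[[key]]
  if (is.null(m)) {
    mult <- lapply(seq_len(3L), function(ax) {
      n <- d[ax]
      f <- (seq_len(n) - 1)
      f <- ifelse(f > n / 2, f - n, f) / n
      exp(-2 * pi^2 * sigma[ax]^2 * f^2)
    })
    m <- outer(outer(mult[[1]], mult[[2]]), mult[[3]])
    .smooth_cache[[key]] <- m
  }
  out <- stats::fft(stats::fft(arr) * m, inverse = TRUE) / prod(d)
  if (is.complex(arr)) out else Re(out)
}

# Block-mean downsampling by an integer factor per axis (edge blocks padded by
# replication when the extent is not divisible).
#' @keywords internal
downsample3 <- function(arr, factor) {
  factor <- rep_len(as.integer(factor), 3L)
  d <- dim(arr)
  nd <- as.integer(ceiling(d / factor))
  xi <- pmin(seq_len(nd[1] * factor[1]), d[1])
  yi <- pmin(seq_len(nd[2] * factor[2]), d[2])
  zi <- pmin(seq_len(nd[3] * factor[3]), d[3])
  full <- arr[xi, yi, zi, drop = FALSE]
  dim(full) <- c(factor[1], nd[1], factor[2], nd[2], factor[3], nd[3])
  full <- aperm(full, c(1, 3, 5, 2, 4, 6))
  dim(full) <- c(prod(factor), prod(nd))
  array(colMeans(full), nd)
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# rowsum for complex matrices (groups sorted as in rowsum)
#' @keywords internal
rowsum_complex <- function(x, group) {
  re <- rowsum(Re(x), group)
  im <- rowsum(Im(x), group)
  out <- re + 1i * im
  rownames(out) <- rownames(re)
  out
}
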