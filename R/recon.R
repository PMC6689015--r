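# k-t SPARSE-SENSE reconstruction: multi-coil SENSE encoding with Cartesian
# undersampling, solved per respiratory phase with a temporal (cardiac)
# total-variation penalty by proximal gradient descent.

#' Estimate coil sensitivity maps from the scan
#'
#' Time-averages the central k-space region over the whole acquisition,
#' inverse transforms per coil and normalises by the root-sum-of-squares
#' image, giving smooth unit-norm maps on the signal support.
#'
#' @param bundle a `kspace_bundle`.
#' @param calib_res_mm resolution of the calibration band (mm); the band
#'   extent per axis is `FOV / calib_res_mm`.
#' @param support_frac RSS threshold (fraction of the RSS maximum) below
#'   which maps are set to zero.
#' @return complex array (Nx, Ny, Nz, n_coils) with attribute `support`.
#' @export
estimate_coil_maps <- function(bundle, calib_res_mm = 16, support_frac = 0.02) {
  n <- bundle$grid
  keep <- lowres_band(bundle$fov_mm, n, calib_res_mm)
  by0 <- band_indices0(n[2], keep[2]); bz0 <- band_indices0(n[3], keep[3])
  sel <- bundle$lines$ky %in% by0 & bundle$lines$kz %in% bz0
  if (!any(sel)) stop("no central k-space acquired for calibration")
  ky <- bundle$lines$ky[sel]; kz <- bundle$lines$kz[sel]
  pos <- ky + n[2] * kz
  nc <- bundle$n_coils
  imgs <- array(0i, c(n, nc))
  for (c in seq_len(nc)) {
    K <- matrix(0i, n[1], n[2] * n[3])
    cols <- bundle$kdata[, which(sel), c, drop = FALSE]
    dim(cols) <- c(n[1], sum(sel))
    # average duplicate acquisitions of the same position
    agg <- rowsum_complex(t(cols), pos)
    upos <- as.integer(rownames(agg))
    nrep <- as.vector(table(pos)[as.character(upos)])
    K[, upos + 1L] <- t(agg / nrep)
    dim(K) <- n
    imgs[, , , c] <- ifftc(K)
  }
  if (all(Mod(imgs) == 0)) stop("calibration region is all zero")
  rss <- array(sqrt(rowSums(matrix(Mod(imgs)^2, prod(n), nc))), n)
  support <- rss > support_frac * max(rss)
  maps <- array(0i, c(n, nc))
  for (c in seq_len(nc)) {
    m <- imgs[, , , c]
    m[support] <- m[support] / rss[support]
    m[!support] <- 0i
    maps[, , , c] <- m
  }
  attr(maps, "support") <- support
  maps
}

#' Bin k-space lines into a (respiratory phase, cardiac phase) cell set
#'
#' Places every line of the beats belonging to the requested respiratory
#' phase into its cardiac phase, averaging duplicate (ky, kz) acquisitions
#' within a cell. Readout samples outside the partial-Fourier band are
#' excluded from the sampled set (they were never acquired).
#'
#' @param bundle a `kspace_bundle`.
#' @param beats a `beat_index`.
#' @param binning a `resp_binning` over the accepted beats (beat ids must
#'   index rows of `beats`).
#' @param phase_assign result of [cardiac_phase_assign()].
#' @param resp_phase phase name (`"EE"`, `"EI"`, ...) or cluster id.
#' @return list of class `kt_cell`: `idx` (per cardiac phase, linear indices
#'   into the (Nx, Ny, Nz) k-grid), `y` (per cardiac phase, complex matrix
#'   n_idx x n_coils), `dims`, `n_card`, `n_lines`, `resp_phase`.
#' @export
bin_kspace <- function(bundle, beats, binning, phase_assign, resp_phase) {
  n <- bundle$grid
  nc <- bundle$n_coils
  n_card <- phase_assign$n_phases
  if (is.character(resp_phase)) {
    cl <- which(binning$phase_names == resp_phase)
    if (!length(cl)) stop("unknown respiratory phase: ", resp_phase)
  } else cl <- resp_phase
  beat_rows <- which(binning$labels %in% cl)
  beat_ids <- binning$beat_ids[beat_rows]
  keep_x <- bundle$readout_keep0 + 1L
  idx <- vector("list", n_card)
  y <- vector("list", n_card)
  sel_beat <- !is.na(phase_assign$beat) & phase_assign$beat %in% beat_ids
  total <- 0L
  for (p in seq_len(n_card) - 1L) {
    lid <- which(sel_beat & !is.na(phase_assign$phase) & phase_assign$phase == p)
    if (!length(lid)) { idx[[p + 1]] <- integer(0); y[[p + 1]] <- matrix(0i, 0, nc); next }
    total <- total + length(lid)
    pos <- bundle$lines$ky[lid] + n[2] * bundle$lines$kz[lid]
    A <- bundle$kdata[keep_x, lid, , drop = FALSE]        # (kx, line, coil)
    A <- aperm(A, c(2, 1, 3))
    dim(A) <- c(length(lid), length(keep_x) * nc)
    agg <- rowsum_complex(A, pos)
    upos <- as.integer(rownames(agg))
    nrep <- as.vector(table(pos)[as.character(upos)])
    agg <- agg / nrep
    dim(agg) <- c(length(upos), length(keep_x), nc)
    # linear indices: kx + Nx*(ky + Ny*kz)
    ii <- outer(keep_x, upos * n[1], `+`)                 # (kx, upos)
    yy <- matrix(0i, length(ii), nc)
    for (c in seq_len(nc)) yy[, c] <- as.vector(t(agg[, , c]))
    idx[[p + 1]] <- as.vector(ii)
    y[[p + 1]] <- yy
  }
  out <- list(idx = idx, y = y, dims = n, n_card = n_card, n_coils = nc,
              n_lines = total, resp_phase = resp_phase,
              n_beats = length(beat_ids))
  class(out) <- "kt_cell"
  out
}

#' SENSE encoding operator for a binned cell set
#'
#' Forward: coil multiplication, unitary DC-centered 3D FFT, sampling at the
#' cell's k-space locations, per cardiac phase. The adjoint embeds sampled
#' residuals, inverse transforms and combines with conjugate coil maps. With
#' unit-norm maps the operator norm is at most 1.
#'
#' @param maps complex coil maps (Nx, Ny, Nz, n_coils).
#' @param idx list (per cardiac phase) of sampled linear k-space indices.
#' @param dims grid dims.
#' @return list with `forward(x)` (x: complex array dims x n_card -> list of
#'   matrices) and `adjoint(ylist)`.
#' @export
make_encoding_operator <- function(maps, idx, dims) {
  nc <- dim(maps)[4]
  n_card <- length(idx)
  forward <- function(x) {
    out <- vector("list", n_card)
    for (p in seq_len(n_card)) {
      if (!length(idx[[p]])) { out[[p]] <- matrix(0i, 0, nc); next }
      yy <- matrix(0i, length(idx[[p]]), nc)
      xp <- array(x[, , , p], dims)
      for (c in seq_len(nc)) {
        K <- fftc(xp * maps[, , , c])
        yy[, c] <- K[idx[[p]]]
      }
      out[[p]] <- yy
    }
    out
  }
  adjoint <- function(ylist) {
    x <- array(0i, c(dims, n_card))
    for (p in seq_len(n_card)) {
      if (!length(idx[[p]])) next
      acc <- array(0i, dims)
      for (c in seq_len(nc)) {
        K <- array(0i, dims)
        K[idx[[p]]] <- ylist[[p]][, c]
        acc <- acc + Conj(maps[, , , c]) * ifftc(K)
      }
      x[, , , p] <- acc
    }
    x
  }
  list(forward = forward, adjoint = adjoint, dims = dims, n_card = n_card)
}

# proximal operator of lambda * cyclic 1D total variation along the last
# axis, applied per voxel to complex signals, via dual projected gradient
tv_prox_cyclic <- function(v, lambda, iters = 10) {
  d <- dim(v)
  t_ax <- length(d)
  nT <- d[t_ax]
  if (nT < 2 || lambda <= 0) return(v)
  V <- matrix(v, ncol = nT)
  P <- matrix(0i, nrow(V), nT)
  Dop <- function(z) z[, c(2:nT, 1), drop = FALSE] - z
  Dt <- function(p) p[, c(nT, 1:(nT - 1)), drop = FALSE] - p
  for (i in seq_len(iters)) {
    z <- V - Dt(P)
    P <- P + 0.25 * Dop(z)
    m <- Mod(P)
    over <- m > lambda
    P[over] <- P[over] * (lambda / m[over])
  }
  out <- V - Dt(P)
  array(out, d)
}

tv_cyclic_norm <- function(x) {
  d <- dim(x)
  nT <- d[length(d)]
  X <- matrix(x, ncol = nT)
  sum(Mod(X[, c(2:nT, 1), drop = FALSE] - X))
}

#' k-t SPARSE-SENSE reconstruction of one respiratory phase
#'
#' Solves `argmin_x 0.5 ||E x - y||^2 + lambda_t * TV_cardiac(x)` where `E`
#' is the SENSE encoding operator of the binned cell set and the total
#' variation uses cyclic finite differences along the cardiac dimension
#' (the cine loops). Proximal gradient descent (unit step; the operator norm
#' is <= 1 with unit-norm maps), with the exact per-voxel 1D TV proximal map
#' evaluated by dual projection. The objective is tracked and must be
#' non-increasing up to the proximal tolerance; a sustained increase aborts
#' with diagnostics.
#'
#' @param cell a `kt_cell` from [bin_kspace()], or a compatible list.
#' @param maps coil maps (Nx, Ny, Nz, n_coils).
#' @param lambda_t TV weight; `NULL` picks `lambda_frac` times the maximum
#'   temporal-difference magnitude of the zero-filled reconstruction.
#' @param lambda_frac heuristic fraction for the default `lambda_t`.
#' @param max_iter iteration cap.
#' @param tol relative objective change declaring convergence.
#' @param prox_iter inner dual iterations of the TV proximal map.
#' @return a `ktss_recon`: `cine` (complex array Nx x Ny x Nz x n_card),
#'   `objective` (per iteration), `lambda_t`, `iterations`, `residual`
#'   (final data-fidelity), `converged`, `diverged`.
#' @export
ktss_reconstruct <- function(cell, maps, lambda_t = NULL, lambda_frac = 0.02,
                             max_iter = 40, tol = 1e-5, prox_iter = 10) {
  nonempty <- sum(vapply(cell$idx, length, 1L) > 0)
  if (nonempty < 2) stop("need sampled data in at least 2 cardiac phases")
  E <- make_encoding_operator(maps, cell$idx, cell$dims)
  x <- E$adjoint(cell$y)            # zero-filled SENSE adjoint
  if (is.null(lambda_t)) {
    X <- matrix(x, ncol = dim(x)[4])
    lambda_t <- lambda_frac * max(Mod(X[, c(2:ncol(X), 1), drop = FALSE] - X))
  }
  obj <- numeric(0)
  bad <- 0L
  converged <- FALSE
  diverged <- FALSE
  for (it in seq_len(max_iter)) {
    fx <- E$forward(x)
    fid <- 0
    res <- vector("list", length(fx))
    for (p in seq_along(fx)) {
      res[[p]] <- fx[[p]] - cell$y[[p]]
      fid <- fid + 0.5 * sum(Mod(res[[p]])^2)
    }
    o <- fid + lambda_t * tv_cyclic_norm(x)
    obj <- c(obj, o)
    if (it > 1) {
      if (o > obj[it - 1] * (1 + 1e-8)) bad <- bad + 1L else bad <- 0L
      if (bad >= 5L) { diverged <- TRUE; break }
      if (abs(obj[it - 1] - o) <= tol * abs(obj[it - 1])) { converged <- TRUE; break }
    }
    g <- E$adjoint(res)
    x <- tv_prox_cyclic(x - g, lambda_t, prox_iter)
  }
  out <- list(cine = x, objective = obj, lambda_t = lambda_t,
              iterations = length(obj), residual = utils::tail(obj, 1),
              converged = converged, diverged = diverged,
              resp_phase = cell$resp_phase)
  class(out) <- "ktss_recon"
  if (diverged) warning("objective increased for 5 consecutive iterations; aborted")
  out
}

#' @export
print.ktss_recon <- function(x, ...) {
  cat("<ktss_recon> phase ", as.character(x$resp_phase), ", ",
      paste(dim(x$cine), collapse = "x"), ", ", x$iterations,
      " iterations, lambda_t ", signif(x$lambda_t, 3), "\n", sep = "")
  invisible(x)
}

#' Magnitude cine of a reconstruction
#' @param recon a `ktss_recon`.
#' @return numeric array (x, y, z, cardiac phase).
#' @export
cine_magnitude <- function(recon) Mod(recon$cine)

#' Write a 4D cine (x, y, z, cardiac) as NIfTI with a JSON sidecar
#'
#' @param cine numeric 4D array.
#' @param spacing voxel spacing mm.
#' @param path output `.nii` path; the sidecar replaces the extension with
#'   `.json`.
#' @param meta named list stored in the sidecar.
#' @export
write_cine_nifti <- function(cine, spacing, path, meta = list()) {
  img <- RNifti::asNifti(cine)
  RNifti::pixdim(img) <- c(spacing, 1)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
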