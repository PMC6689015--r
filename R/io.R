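# Serialization of the acquisition bundle and volume export.
#
# A bundle is written as a directory: raw complex k-space (interleaved
# re/im doubles, kx fastest, then line, then coil), a CSV line table
# (index, ky, kz, t_ms, interleave, ring), CSV ECG trigger and bellows
# tables, and a JSON manifest echoing the acquisition geometry.

#' Write / read a k-space bundle
#'
#' @param bundle a `kspace_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory (write) or a reconstructed `kspace_bundle` (read);
#'   the phantom config echo is not round-tripped.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- bundle$kdata
  con <- file(file.path(dir, "kspace.cplx"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rbind(Re(as.vector(k)), Im(as.vector(k)))), con, size = 8)
  df <- bundle$lines
  names(df)[names(df) == "line_id"] <- "index"
  utils::write.csv(df, file.path(dir, "lines.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t_ms = bundle$ecg_ms),
                   file.path(dir, "ecg.csv"), row.names = FALSE)
  utils::write.csv(bundle$bellows, file.path(dir, "bellows.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(dims = dim(k), grid = bundle$grid, fov_mm = bundle$fov_mm,
         spacing = bundle$spacing, tr_ms = bundle$tr_ms,
         n_coils = bundle$n_coils, partial_fourier = bundle$partial_fourier,
         readout_keep0 = bundle$readout_keep0),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "kspace.cplx"), "rb")
  on.exit(close(con))
  n <- prod(man$dims)
  raw <- readBin(con, "double", 2 * n, size = 8)
  k <- array(complex(real = raw[seq(1, 2 * n, 2)],
                     imaginary = raw[seq(2, 2 * n, 2)]), man$dims)
  lines <- utils::read.csv(file.path(dir, "lines.csv"))
  names(lines)[names(lines) == "index"] <- "line_id"
  out <- list(kdata = k, lines = lines,
              ecg_ms = utils::read.csv(file.path(dir, "ecg.csv"))$t_ms,
              bellows = utils::read.csv(file.path(dir, "bellows.csv")),
              tr_ms = man$tr_ms, grid = man$grid, fov_mm = man$fov_mm,
              spacing = man$spacing, n_coils = man$n_coils,
              partial_fourier = man$partial_fourier,
              readout_keep0 = man$readout_keep0, config = NULL)
  class(out) <- "kspace_bundle"
  out
}

#' Write a 3D/4D volume as NIfTI with voxel spacing
#' @param vol numeric array.
#' @param spacing voxel spacing mm (first 3 dims).
#' @param path output path.
#' @export
write_volume_nifti <- function(vol, spacing, path) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(vol)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
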