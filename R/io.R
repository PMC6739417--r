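# Disk I/O: 32-bit float TIFF for slices and sinograms with plain-text
# sidecar headers, and round-trippable CSV for scan curves.

.write_sidecar <- function(path, fields) {
  writeLines(sprintf("%s\t%s", names(fields),
                     vapply(fields, function(x) paste(format(x), collapse = ","),
                            character(1))),
             path)
}

.need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
}

#' Write / read a reconstructed slice as 32-bit float TIFF
#'
#' The attenuation map (1/cm) goes to `<path>`; geometry and provenance go
#' to a plain-text sidecar `<path>.txt`.
#'
#' @param slice a `bct_slice`.
#' @param path output TIFF path.
#' @export
write_slice_tiff <- function(slice, path) {
  .need_tiff()
  stopifnot(inherits(slice, "bct_slice"))
  # TIFF float storage is defined on [0, 1]; affine-rescale and record the
  # transform in the sidecar so readers can invert it exactly.
  off <- min(slice$image)
  scl <- max(max(slice$image) - off, .Machine$double.xmin)
  tiff::writeTIFF((slice$image - off) / scl, path, bits.per.sample = 32,
                  reduce = FALSE)
  .write_sidecar(paste0(path, ".txt"),
                 list(type = "bct_slice", units = "1/cm", dx_mm = slice$dx,
                      algorithm = slice$algorithm,
                      offset = sprintf("%.17g", off),
                      scale = sprintf("%.17g", scl)))
  invisible(path)
}

#' @rdname write_slice_tiff
#' @export
read_slice_tiff <- function(path) {
  .need_tiff()
  img <- tiff::readTIFF(path)
  hdr <- utils::read.table(paste0(path, ".txt"), sep = "\t",
                           stringsAsFactors = FALSE)
  meta <- stats::setNames(hdr$V2, hdr$V1)
  img <- img * as.numeric(meta[["scale"]]) + as.numeric(meta[["offset"]])
  .new_slice(img, as.numeric(meta[["dx_mm"]]), meta[["algorithm"]])
}

#' Write a sinogram as 32-bit float TIFF plus sidecar header
#'
#' @param sino a `bct_sinogram`.
#' @param path output TIFF path.
#' @export
write_sinogram_tiff <- function(sino, path) {
  .need_tiff()
  stopifnot(inherits(sino, "bct_sinogram"))
  m <- sino$data
  off <- min(m)
  scl <- max(max(m) - off, .Machine$double.xmin)
  tiff::writeTIFF((m - off) / scl, path, bits.per.sample = 32,
                  reduce = FALSE)
  .write_sidecar(paste0(path, ".txt"),
                 list(type = "bct_sinogram", kind = sino$kind,
                      n_proj = nrow(m), n_det = ncol(m), dx_mm = sino$dx,
                      flat = sino$flat, odd_cm = sino$odd_cm,
                      seed = sino$seed,
                      offset = sprintf("%.17g", off),
                      scale = sprintf("%.17g", scl),
                      angles_rad = c(sino$angles[1],
                                     sino$angles[length(sino$angles)])))
  invisible(path)
}

#' Write / read an analytic CNR curve as CSV
#'
#' Columns `E_keV, dgn, K_mGy, N_ph, sigma_center, cnr, cnr_normalized`.
#'
#' @param curve a `bct_cnr_curve` from [energy_scan()].
#' @param path CSV path.
#' @export
write_cnr_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnr_csv
#' @export
read_cnr_csv <- function(path) {
  utils::read.csv(path)
}
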