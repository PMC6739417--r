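# Parallel-beam reconstruction: FBP (Ram-Lak / Hamming), iterative
# SART/SIRT, and photon-starvation correction of counts sinograms.

.new_slice <- function(image, dx, algorithm, ...) {
  structure(list(image = image, dx = dx, algorithm = algorithm,
                 provenance = list(...)),
            class = "bct_slice")
}

#' @export
print.bct_slice <- function(x, ...) {
  cat(sprintf("<bct_slice> %d x %d px (dx = %g mm), %s\n",
              nrow(x$image), ncol(x$image), x$dx, x$algorithm))
  invisible(x)
}

# Discrete ramp kernel (band-limited inverse transform of |f|), sampled at
# the detector pitch: h(0) = 1/(4 dx^2), h(odd n) = -1/(pi n dx)^2, else 0.
# Its transfer function is the periodically replicated |f| band, which
# avoids the DC bias of naive frequency-domain |f| sampling.
.ramp_kernel <- function(n_pad, dx) {
  h <- numeric(n_pad)
  h[1] <- 1 / (4 * dx^2)
  k <- seq_len(n_pad - 1)
  kk <- pmin(k, n_pad - k)  # circulant: negative lags wrap around
  odd <- kk %% 2 == 1
  h[1 + k[odd]] <- -1 / (pi * kk[odd] * dx)^2
  h
}

#' Filtered back-projection
#'
#' Rows are filtered in the frequency domain with the discrete ramp kernel
#' (zero-padded to at least twice the next power of two), optionally
#' apodized by a Hamming window on the Nyquist band; backprojection uses
#' linear detector interpolation. Reconstructing noiseless data returns the
#' attenuation map in 1/cm.
#'
#' @param projections a `bct_sinogram` of kind `"lineint"`.
#' @param filter `"ramlak"` or `"hamming"`.
#' @return A `bct_slice` with the square attenuation image (1/cm).
#' @export
fbp <- function(projections, filter = c("ramlak", "hamming")) {
  filter <- match.arg(filter)
  stopifnot(inherits(projections, "bct_sinogram"))
  if (projections$kind != "lineint")
    stop("fbp needs a line-integral sinogram; see to_line_integrals()")
  p <- projections$data
  if (any(!is.finite(p))) stop("non-finite values in projections")
  n_det <- ncol(p)
  dx <- projections$dx
  n_pad <- 2 * 2^ceiling(log2(n_det))
  H <- Re(stats::fft(.ramp_kernel(n_pad, dx)))
  if (filter == "hamming") {
    f <- c(seq(0, n_pad / 2), seq(-n_pad / 2 + 1, -1)) / (n_pad * dx)
    f_nyq <- 1 / (2 * dx)
    H <- H * (0.54 + 0.46 * cos(pi * pmin(abs(f) / f_nyq, 1)))
  }
  # filter all rows at once; H is real, so two real projections can share
  # one complex transform (linearity keeps them in Re and Im parts)
  n_proj <- nrow(p)
  n_half <- ceiling(n_proj / 2)
  pp <- matrix(0 + 0i, n_pad, n_half)
  idx1 <- seq_len(n_half)
  idx2 <- pmin(idx1 + n_half, n_proj)
  pp[seq_len(n_det), ] <- t(p[idx1, , drop = FALSE] +
                              1i * p[idx2, , drop = FALSE])
  back <- stats::mvfft(stats::mvfft(pp) * H, inverse = TRUE) / n_pad
  filt <- matrix(0, n_proj, n_det)
  filt[idx1, ] <- t(Re(back[seq_len(n_det), , drop = FALSE]))
  filt[idx2, ] <- t(Im(back[seq_len(n_det), , drop = FALSE]))
  filt <- filt * dx
  img <- cpp_backproject(filt, projections$angles, dx)
  .new_slice(img * 10, dx, paste0("fbp-", filter),  # 1/mm -> 1/cm
             filter = filter, n_proj = nrow(p), seed = projections$seed)
}

.check_divergence <- function(rms) {
  if (length(rms) >= 51) {
    growing <- diff(rms) > 0
    run <- rle(growing)
    if (any(run$lengths[run$values] >= 50))
      stop("iterative reconstruction diverged: RMS update grew over 50 ",
           "consecutive iterations (max RMS ", signif(max(rms), 4), ")")
  }
}

#' SART reconstruction
#'
#' Simultaneous algebraic reconstruction technique: one iteration processes
#' one projection (sequential angle ordering) with relaxation `lambda`,
#' matching the per-projection iteration convention of common tomography
#' toolboxes, so `n_iter = n_proj` is one full sweep. Zero-initialized;
#' deterministic.
#'
#' @param projections a `bct_sinogram` of kind `"lineint"`.
#' @param n_iter number of projection updates (default 1200).
#' @param lambda relaxation factor.
#' @return A `bct_slice` (1/cm).
#' @export
sart <- function(projections, n_iter = 1200, lambda = 1) {
  stopifnot(inherits(projections, "bct_sinogram"),
            projections$kind == "lineint")
  res <- cpp_sart(projections$data, projections$angles, projections$dx,
                  as.integer(n_iter), lambda)
  .check_divergence(res$rms_update)
  .new_slice(res$image * 10, projections$dx, "sart",
             n_iter = n_iter, lambda = lambda, seed = projections$seed)
}

#' SIRT reconstruction
#'
#' Simultaneous iterative reconstruction technique with standard
#' row/column-sum normalization; one iteration uses all projections.
#'
#' @inheritParams sart
#' @param n_iter number of full iterations (default 500).
#' @return A `bct_slice` (1/cm).
#' @export
sirt <- function(projections, n_iter = 500, lambda = 1) {
  stopifnot(inherits(projections, "bct_sinogram"),
            projections$kind == "lineint")
  res <- cpp_sirt(projections$data, projections$angles, projections$dx,
                  as.integer(n_iter), lambda)
  .check_divergence(res$rms_update)
  .new_slice(res$image * 10, projections$dx, "sirt",
             n_iter = n_iter, lambda = lambda, seed = projections$seed)
}

#' Photon-starvation correction
#'
#' Replaces each zero-count bin by 1-D linear interpolation along its
#' detector row between the nearest nonzero neighbours; runs of zeros are
#' interpolated across the run and row-edge zeros take the nearest nonzero
#' value. The starvation mask is preserved in the output.
#'
#' @param sampled a `bct_sinogram` of kind `"counts"`.
#' @return A corrected `bct_sinogram` of kind `"counts"`.
#' @export
starvation_correct <- function(sampled) {
  stopifnot(inherits(sampled, "bct_sinogram"), sampled$kind == "counts")
  counts <- sampled$data
  mask <- counts == 0
  if (!any(mask)) {
    out <- sampled
    out$mask <- mask
    return(out)
  }
  for (i in which(rowSums(mask) > 0)) {
    row <- counts[i, ]
    nz <- which(row > 0)
    if (length(nz) == 0)
      stop("projection row ", i, " has no counts at all; cannot interpolate")
    counts[i, ] <- stats::approx(nz, row[nz], xout = seq_along(row),
                                 rule = 2)$y
  }
  .new_sinogram(counts, "counts", sampled$angles, sampled$dx, sampled$flat,
                sampled$odd_cm, seed = sampled$seed, mask = mask)
}
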