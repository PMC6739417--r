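# Analytic forward projection of the concentric-cylinder phantom and
# Poisson-sampled sinogram generation for an ideal photon-counting detector.

#' Concentric-cylinder breast phantom
#'
#' A homogeneous cylinder of diameter `d` and glandularity `G` containing a
#' central glandular disc of 1 cm diameter surrounded by a concentric
#' adipose ring of equal area (outer radius `0.5*sqrt(2)` cm).
#'
#' @param d_cm outer diameter in cm (>= 2 so detail and ring fit inside).
#' @param G background glandularity.
#' @return An object of class `bct_phantom`.
#' @export
concentric_phantom <- function(d_cm, G) {
  if (d_cm < 2) stop("phantom diameter must be >= 2 cm")
  r_detail <- 0.5
  r_ring <- 0.5 * sqrt(2)
  stopifnot(abs((r_ring^2 - r_detail^2) / r_detail^2 - 1) < 1e-12)
  structure(list(d_cm = d_cm, G = G,
                 background = mixture_composition(G),
                 detail = mixture_composition(1),
                 ring = mixture_composition(0),
                 r_detail_cm = r_detail, r_ring_cm = r_ring),
            class = "bct_phantom")
}

#' Per-material chord lengths through the phantom
#'
#' By concentricity all view angles are equivalent; the chord through each
#' nested disc at detector coordinate `s` is `2 sqrt(r^2 - s^2)`, and the
#' per-material path lengths follow by subtraction.
#'
#' @param phantom a [concentric_phantom()].
#' @param s_mm detector coordinate(s) in mm (0 at the rotation axis).
#' @return matrix with one row per `s` and columns `background`, `ring`,
#'   `detail`, path lengths in cm.
#' @export
path_lengths <- function(phantom, s_mm) {
  s <- s_mm / 10  # cm
  chord <- function(r) ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0)
  outer_c <- chord(phantom$d_cm / 2)
  ring_c <- chord(phantom$r_ring_cm)
  detail_c <- chord(phantom$r_detail_cm)
  cbind(background = outer_c - ring_c, ring = ring_c - detail_c,
        detail = detail_c)
}

.detector_n <- function(d_cm, dx_mm) {
  n <- ceiling(d_cm * 10 / dx_mm)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

.detector_s <- function(n_det, dx_mm) (seq_len(n_det) - 1 - (n_det - 1) / 2) * dx_mm

.new_sinogram <- function(data, kind, angles, dx, flat, odd_cm, seed = NA,
                          mask = NULL) {
  structure(list(data = data, kind = kind, angles = angles, dx = dx,
                 flat = flat, odd_cm = odd_cm, seed = seed, mask = mask),
            class = "bct_sinogram")
}

#' @export
print.bct_sinogram <- function(x, ...) {
  cat(sprintf("<bct_sinogram> %s, %d proj x %d det, dx = %g mm, flat = %.4g\n",
              x$kind, nrow(x$data), ncol(x$data), x$dx, x$flat))
  invisible(x)
}

#' Expected (noiseless) sinogram of the phantom
#'
#' Expected counts per detector pixel are `(N_ph/n_proj) *
#' exp(-sum_m mu_m L_m(s)) * exp(-mu_air ODD)`, one ray through each pixel
#' center; by symmetry all projection rows are identical. `N_ph` is the
#' per-scan photon budget per pixel, split evenly over the projections.
#'
#' @param phantom a [concentric_phantom()].
#' @param E photon energy, keV.
#' @param N_ph photons per pixel over the whole scan.
#' @param n_proj number of projections over 180 degrees.
#' @param dx detector pitch, mm.
#' @param odd_cm air path to the detector, cm.
#' @return A `bct_sinogram` of kind `"expected"`.
#' @export
expected_sinogram <- function(phantom, E, N_ph, n_proj = 1200, dx = 0.12,
                              odd_cm = 185) {
  if (N_ph <= 0 || n_proj < 1) stop("need N_ph > 0 and n_proj >= 1")
  n_det <- .detector_n(phantom$d_cm, dx)
  s <- .detector_s(n_det, dx)
  L <- path_lengths(phantom, s)
  mu <- c(background = linear_attenuation(phantom$background, E),
          ring = linear_attenuation(phantom$ring, E),
          detail = linear_attenuation(phantom$detail, E))
  atten <- exp(-(L %*% mu)) * exp(-air_linear_attenuation(E) * odd_cm)
  flat <- (N_ph / n_proj) * exp(-air_linear_attenuation(E) * odd_cm)
  row <- (N_ph / n_proj) * as.numeric(atten)
  data <- matrix(rep(row, each = n_proj), nrow = n_proj)
  angles <- (seq_len(n_proj) - 1) * pi / n_proj
  .new_sinogram(data, "expected", angles, dx, flat, odd_cm)
}

#' Poisson-sampled sinogram
#'
#' Independent Poisson draw per bin; each run is a single realization of
#' the counting process, deterministic given `seed`.
#'
#' @param expected a `bct_sinogram` of kind `"expected"`.
#' @param seed integer seed.
#' @return A `bct_sinogram` of kind `"counts"` with a starvation mask
#'   (`TRUE` where a bin recorded zero counts).
#' @export
sample_sinogram <- function(expected, seed) {
  stopifnot(inherits(expected, "bct_sinogram"), expected$kind == "expected")
  if (any(!is.finite(expected$data)) || any(expected$data < 0))
    stop("expected counts must be finite and >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(expected$data), expected$data),
                   nrow = nrow(expected$data))
  .new_sinogram(counts, "counts", expected$angles, expected$dx,
                expected$flat, expected$odd_cm, seed = as.integer(seed),
                mask = counts == 0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Log-normalize counts to line integrals
#'
#' `p = -ln(max(counts, eps) / flat)` with `flat` the noiseless expected
#' blank counts (including the air-path factor, which therefore divides
#' out). Zero-count bins are flagged in the starvation mask and given a
#' finite placeholder (`eps` counts), not silently repaired; the tiny
#' default keeps the placeholder faithful to what the raw logarithm does
#' to an empty bin, so uncorrected reconstructions exhibit the
#' characteristic photon-starvation streaks rather than hiding them
#' (repair belongs to [starvation_correct()], which acts on counts before
#' this step).
#'
#' @param sampled a `bct_sinogram` of kind `"counts"` (or `"expected"` for
#'   noiseless studies).
#' @param eps placeholder counts for empty bins (default `1e-6`).
#' @return A `bct_sinogram` of kind `"lineint"`.
#' @export
to_line_integrals <- function(sampled, eps = 1e-6) {
  stopifnot(inherits(sampled, "bct_sinogram"),
            sampled$kind %in% c("counts", "expected"))
  if (sampled$flat <= 0) stop("flat-field counts must be positive")
  mask <- sampled$data == 0
  p <- -log(pmax(sampled$data, eps) / sampled$flat)
  .new_sinogram(p, "lineint", sampled$angles, sampled$dx, sampled$flat,
                sampled$odd_cm, seed = sampled$seed, mask = mask)
}
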