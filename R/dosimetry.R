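# Dosimetry: mean glandular dose -> entrance air kerma -> photon fluence ->
# photons per pixel, with the normalized glandular dose coefficient DgN_CT
# estimated by Monte-Carlo photon transport in the homogeneous cylindrical
# breast.

#' Acquisition beam geometry
#'
#' @param mode `"full"` irradiates the whole cylinder (beam height equals
#'   the cylinder height, approximating a complete multi-slab exam);
#'   `"laminar"` uses a thin sheet beam of height `h_mm`.
#' @param h_mm laminar beam height in mm (default 3.5).
#' @param H_cm cylinder (breast) height in cm. The default `NA` with
#'   `mode = "full"` selects the translationally invariant infinite
#'   cylinder (a unit length is irradiated and all deposits are scored,
#'   which by symmetry equals the fully irradiated infinite breast and
#'   removes the free height parameter); a finite `H_cm` models axial
#'   escape from a cylinder of that height. `"laminar"` requires a finite
#'   `H_cm`.
#' @param odd_cm object-to-detector distance in cm (air path).
#' @return An object of class `bct_geometry`.
#' @export
beam_geometry <- function(mode = c("full", "laminar"), h_mm = 3.5,
                          H_cm = NA_real_, odd_cm = 185) {
  mode <- match.arg(mode)
  if (odd_cm < 0) stop("ODD must be >= 0")
  if (!is.na(H_cm) && (h_mm <= 0 || h_mm > H_cm * 10))
    stop("beam height must satisfy 0 < h <= 10*H")
  structure(list(mode = mode, h_mm = h_mm, H_cm = H_cm, odd_cm = odd_cm),
            class = "bct_geometry")
}

.resolve_H <- function(geometry, d_cm) {
  H <- geometry$H_cm
  if (is.na(H)) {
    if (geometry$mode == "laminar")
      stop("laminar geometry requires a finite cylinder height H_cm")
    H <- Inf  # full irradiation: infinite cylinder, unit irradiated length
  }
  h <- if (geometry$mode == "full") (if (is.finite(H)) H else 1)
       else geometry$h_mm / 10
  if (h <= 0 || h > H) stop("beam height must satisfy 0 < h <= H")
  list(H_cm = H, h_cm = h)
}

#' Air kerma at the isocenter from the mean glandular dose
#'
#' Inverts `MGD_t = K * DgN_CT`.
#'
#' @param mgd mean glandular dose in mGy.
#' @param dgn a `bct_dgn` object from [dgn_ct_monte_carlo()], or a bare
#'   positive number (mGy per mGy of isocenter air kerma).
#' @return air kerma at the isocenter, mGy.
#' @export
kerma_from_mgd <- function(mgd, dgn) {
  v <- if (inherits(dgn, "bct_dgn")) dgn$value else dgn
  if (!is.numeric(v) || v <= 0) stop("DgN_CT must be positive")
  if (any(mgd < 0)) stop("MGD must be >= 0")
  mgd / v
}

#' Photon fluence from air kerma
#'
#' At these energies kerma equals fluence times photon energy times the air
#' mass energy-absorption coefficient; this inverts that relation.
#'
#' @param K air kerma, mGy.
#' @param E photon energy, keV.
#' @return fluence in photons/mm^2.
#' @export
fluence_from_kerma <- function(K, E) {
  if (any(K < 0)) stop("kerma must be >= 0")
  mu_en_mm2_kg <- air_mass_energy_absorption(E) * 1e5  # cm^2/g -> mm^2/kg
  (K * 1e-3) / (mu_en_mm2_kg * E * .KEV_TO_J)
}

#' Photons per detector pixel over a full scan
#'
#' Chains `MGD -> K -> fluence -> counts`: `N_ph = phi * dx^2`.
#'
#' @param d breast diameter, cm (carried for provenance).
#' @param G glandularity.
#' @param mgd mean glandular dose, mGy.
#' @param dx detector pixel size, mm.
#' @param E photon energy, keV.
#' @param dgn DgN_CT coefficient (see [kerma_from_mgd()]).
#' @return expected photons entering one detector pixel over the whole scan.
#' @export
photons_per_pixel <- function(d, G, mgd, dx, E, dgn) {
  fluence_from_kerma(kerma_from_mgd(mgd, dgn), E) * dx^2
}

#' Monte-Carlo normalized glandular dose coefficient for breast CT
#'
#' Transports photons (photoelectric absorption, incoherent scattering by
#' Klein-Nishina sampling, optional coherent scattering) through a
#' homogeneous cylinder of diameter `d` and glandularity `G`, accumulating
#' the glandular-weighted deposited energy over the whole cylinder. Each
#' deposit of a photon of current energy E' is attributed to glandular
#' tissue with weight `(mu_en/rho)_g(E') / [G (mu_en/rho)_g(E') +
#' (1-G) (mu_en/rho)_a(E')]` relative to the total breast mass, the standard
#' homogeneous-mixture convention (finite for G = 0). The result is
#' normalized by the air kerma at the isocenter computed analytically from
#' the simulated fluence (zero-variance denominator).
#'
#' @param d cylinder diameter, cm.
#' @param G glandularity in `[0, 1]`.
#' @param E photon energy, keV (within the tabulated 10-50 keV band).
#' @param geometry a [beam_geometry()]; default full irradiation with
#'   cylinder height equal to `d`, ODD irrelevant here.
#' @param n_photons number of photon histories (>= 1e4).
#' @param seed integer seed; runs are deterministic given
#'   `(seed, n_photons, parameters)`.
#' @param coherent include coherent scattering (form-factor-free Thomson
#'   angular sampling; approximate). If `FALSE` the coherent channel is
#'   removed from the total cross section.
#' @return An object of class `bct_dgn`: fields `value` (mGy per mGy air
#'   kerma at isocenter), `stderr`, and the parameters it was computed for.
#' @export
dgn_ct_monte_carlo <- function(d, G, E, geometry = beam_geometry(),
                               n_photons = 1e6, seed = 1L,
                               coherent = TRUE) {
  if (n_photons < 1e4) stop("n_photons must be >= 1e4")
  if (E < 10 || E > 50) stop("E must be within 10-50 keV")
  gg <- .resolve_H(geometry, d)
  mix <- mixture_composition(G)
  gl <- mixture_composition(1)
  ad <- mixture_composition(0)
  rho <- mix$composition$density_g_cm3

  e_grid <- seq(1, E + 0.5, by = 0.25)
  mu_tot <- rho * .mixture_coef_extrap(mix, e_grid, "attenuation")
  ne <- .electrons_per_gram(mix)
  mu_inc <- rho * ne * .kn_total(e_grid)
  # photoelectric-like local absorption strength from the energy-absorption
  # table: mu_en minus the Compton energy-transfer part
  mu_abs <- rho * pmax(.mixture_coef_extrap(mix, e_grid, "absorption") -
                         ne * .kn_transfer(e_grid), 0)
  mu_coh <- pmax(mu_tot - mu_inc - mu_abs, 0)
  if (!coherent) {
    mu_tot <- mu_tot - mu_coh
    mu_coh <- mu_coh * 0
  }
  en_g <- .mixture_coef_extrap(gl, e_grid, "absorption")
  en_a <- .mixture_coef_extrap(ad, e_grid, "absorption")
  wgt <- en_g / (G * en_g + (1 - G) * en_a)

  R <- d / 2
  res <- cpp_mc_cylinder(R, gg$H_cm, gg$h_cm, E, n_photons, e_grid,
                         mu_tot, mu_abs, mu_inc, mu_coh, wgt,
                         as.double(seed %% 2147483647), as.double(seed))
  injected <- n_photons * E
  if (abs(res$deposited + res$escaped - injected) > 1e-6 * injected)
    stop("Monte-Carlo energy audit failed")

  # MGD per simulated photon batch: S1/M_total; isocenter kerma from the
  # analytic fluence N / (beam area): K = phi * E * (mu_en/rho)_air.
  # For the infinite fully irradiated cylinder the reference mass is that
  # of the unit irradiated slab (translational symmetry).
  M_total <- rho * pi * R^2 * (if (is.finite(gg$H_cm)) gg$H_cm else gg$h_cm)
  beam_area <- 2 * R * gg$h_cm
  kerma_unit <- E * air_mass_energy_absorption(E) / beam_area  # per photon
  value <- (res$mean_c / M_total) / kerma_unit
  se <- (sqrt(res$var_c / res$n) / M_total) / kerma_unit
  structure(list(value = value, stderr = se, E = E, d = d, G = G,
                 mode = geometry$mode, H_cm = gg$H_cm, h_cm = gg$h_cm,
                 n_photons = n_photons, seed = seed, coherent = coherent),
            class = "bct_dgn")
}

#' @export
print.bct_dgn <- function(x, ...) {
  cat(sprintf(
    "<bct_dgn> DgN_CT = %.4f +/- %.4f (E=%g keV, d=%g cm, G=%g, %s, H=%g cm)\n",
    x$value, x$stderr, x$E, x$d, x$G, x$mode, x$H_cm))
  invisible(x)
}

# ---- DgN cache ------------------------------------------------------------

.dgn_cache_key <- function(E, d, G, mode, H_cm) {
  sprintf("%.6g|%.6g|%.6g|%s|%.6g", E, d, G, mode, H_cm)
}

#' Cached DgN_CT lookup
#'
#' Memoizes [dgn_ct_monte_carlo()] per `(E, d, G, geometry)` in the session;
#' energy scans over a grid reuse coefficients across glandularities and
#' doses. The per-energy seed is derived from `seed` and the energy so a
#' scan is reproducible regardless of evaluation order.
#'
#' @inheritParams dgn_ct_monte_carlo
#' @export
dgn_ct <- function(d, G, E, geometry = beam_geometry(), n_photons = 1e6,
                   seed = 1L, coherent = TRUE) {
  if (is.null(.bct_data$dgn_cache))
    .bct_data$dgn_cache <- new.env(parent = emptyenv())
  gg <- .resolve_H(geometry, d)
  key <- .dgn_cache_key(E, d, G, geometry$mode, gg$H_cm)
  hit <- .bct_data$dgn_cache[[key]]
  if (!is.null(hit) && hit$n_photons >= n_photons) return(hit)
  run_seed <- (as.integer(seed) * 997L + as.integer(round(E * 8)) +
                 as.integer(round(d * 64)) +
                 as.integer(round(G * 1021))) %% 2147483647L
  val <- dgn_ct_monte_carlo(d, G, E, geometry, n_photons, run_seed, coherent)
  .bct_data$dgn_cache[[key]] <- val
  val
}

#' Clear the in-session DgN cache
#' @export
dgn_cache_clear <- function() {
  .bct_data$dgn_cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

#' Read / write a DgN_CT cache table
#'
#' Delimited text with columns `E_keV, d_cm, G, mode, H_cm, dgn, stderr,
#' n_photons, seed`; an external table in this format (for example
#' transcribed from a published Monte-Carlo study) can be loaded to
#' override the in-repo Monte Carlo.
#'
#' @param path file path.
#' @export
dgn_cache_write <- function(path) {
  cache <- .bct_data$dgn_cache
  if (is.null(cache)) stop("DgN cache is empty")
  rows <- lapply(ls(cache), function(k) {
    x <- cache[[k]]
    data.frame(E_keV = x$E, d_cm = x$d, G = x$G, mode = x$mode,
               H_cm = x$H_cm, dgn = x$value, stderr = x$stderr,
               n_photons = x$n_photons, seed = x$seed)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$d_cm, df$G, df$E_keV), ]
  out <- df
  for (col in c("dgn", "stderr"))  # full precision for exact round trips
    out[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' @rdname dgn_cache_write
#' @export
dgn_cache_read <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(.bct_data$dgn_cache))
    .bct_data$dgn_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) {
    x <- structure(list(value = df$dgn[i], stderr = df$stderr[i],
                        E = df$E_keV[i], d = df$d_cm[i], G = df$G[i],
                        mode = df$mode[i], H_cm = df$H_cm[i],
                        h_cm = if (df$mode[i] == "full") df$H_cm[i] else NA,
                        n_photons = df$n_photons[i], seed = df$seed[i],
                        coherent = NA), class = "bct_dgn")
    key <- .dgn_cache_key(x$E, x$d, x$G, x$mode, x$H_cm)
    .bct_data$dgn_cache[[key]] <- x
  }
  invisible(df)
}
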