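# Tissue and air X-ray coefficient data: elemental compositions, densities,
# and energy-dependent mass attenuation / mass energy-absorption coefficients,
# combined by the standard mixture rule with log-log interpolation in energy.

.bct_data <- new.env(parent = emptyenv())

.read_table <- function(file) {
  utils::read.table(system.file("extdata", file, package = "bctsim",
                                mustWork = TRUE),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# Coefficient tables as element x energy matrices, loaded once per session.
xray_tables <- function() {
  if (is.null(.bct_data$tables)) {
    att <- .read_table("element_mass_attenuation.tsv")
    en <- .read_table("element_mass_energy_absorption.tsv")
    air <- .read_table("air_coefficients.tsv")
    comp <- .read_table("tissue_compositions.tsv")
    to_mat <- function(df, val) {
      e <- sort(unique(df$energy_keV))
      els <- unique(df$element)
      m <- matrix(NA_real_, length(els), length(e),
                  dimnames = list(els, as.character(e)))
      for (i in seq_len(nrow(df)))
        m[df$element[i], as.character(df$energy_keV[i])] <- df[[val]][i]
      stopifnot(!anyNA(m), all(m > 0))
      list(energy = e, coef = m)
    }
    stopifnot(all(diff(air$energy_keV) > 0), all(air[-1] > 0))
    .bct_data$tables <- list(
      attenuation = to_mat(att, "mu_over_rho_cm2_g"),
      absorption = to_mat(en, "mu_en_over_rho_cm2_g"),
      air = air, compositions = comp)
  }
  .bct_data$tables
}

#' Elemental composition of a homogeneous material
#'
#' @param elements character vector of element symbols.
#' @param mass_fractions numeric vector of mass fractions; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param density_g_cm3 mass density in g/cm^3; must be positive.
#' @return An object of class `elemental_composition`.
#' @export
elemental_composition <- function(elements, mass_fractions, density_g_cm3) {
  stopifnot(length(elements) == length(mass_fractions))
  if (any(mass_fractions < 0) || abs(sum(mass_fractions) - 1) > 1e-9)
    stop("mass fractions must be >= 0 and sum to 1")
  if (!is.numeric(density_g_cm3) || density_g_cm3 <= 0)
    stop("density must be positive")
  structure(list(elements = as.character(elements),
                 mass_fractions = as.numeric(mass_fractions),
                 density_g_cm3 = as.numeric(density_g_cm3)),
            class = "elemental_composition")
}

.tissue_composition <- function(tissue) {
  comp <- xray_tables()$compositions
  rows <- comp[comp$tissue == tissue, ]
  stopifnot(nrow(rows) > 0)
  elemental_composition(rows$element,
                        rows$mass_fraction / sum(rows$mass_fraction),
                        rows$density_g_cm3[1])
}

#' Breast material of given glandularity
#'
#' Builds the homogeneous adipose/glandular mixture with glandular weight
#' fraction `G`. Elemental mass fractions are the G-weighted combination of
#' the two tissue compositions; the mixture density follows mass-fraction
#' mixing of specific volumes, 1/rho = G/rho_gland + (1-G)/rho_adipose.
#'
#' @param G glandularity, the glandular mass fraction in `[0, 1]`.
#' @return An object of class `bct_material` with fields `name`, `G` and
#'   `composition` (an [elemental_composition()]).
#' @export
mixture_composition <- function(G) {
  if (!is.numeric(G) || length(G) != 1 || is.na(G) || G < 0 || G > 1)
    stop("glandularity G must be a single value in [0, 1]")
  ad <- .tissue_composition("adipose")
  gl <- .tissue_composition("glandular")
  stopifnot(identical(ad$elements, gl$elements))
  w <- G * gl$mass_fractions + (1 - G) * ad$mass_fractions
  rho <- 1 / (G / gl$density_g_cm3 + (1 - G) / ad$density_g_cm3)
  name <- if (G == 0) "adipose" else if (G == 1) "glandular"
          else sprintf("breast G=%g", G)
  structure(list(name = name, G = G,
                 composition = elemental_composition(ad$elements, w / sum(w),
                                                     rho)),
            class = "bct_material")
}

#' @export
print.bct_material <- function(x, ...) {
  cat(sprintf("<bct_material> %s (G = %g, rho = %.4f g/cm^3)\n",
              x$name, x$G, x$composition$density_g_cm3))
  invisible(x)
}

# piecewise log-log (power-law) interpolation; errors outside the grid
.loglog_interp <- function(E, grid, values) {
  if (any(E < grid[1] - 1e-9) || any(E > grid[length(grid)] + 1e-9))
    stop(sprintf("energy outside the tabulated range [%g, %g] keV",
                 grid[1], grid[length(grid)]))
  exp(stats::approx(log(grid), log(values), xout = log(pmin(pmax(E, grid[1]),
                                                            grid[length(grid)])),
                    rule = 1)$y)
}

.mixture_coef <- function(material, E, which = c("attenuation", "absorption")) {
  which <- match.arg(which)
  tab <- xray_tables()[[which]]
  comp <- material$composition
  vals <- vapply(E, function(e) {
    per_el <- vapply(comp$elements, function(el)
      .loglog_interp(e, tab$energy, tab$coef[el, ]), numeric(1))
    sum(comp$mass_fractions * per_el)
  }, numeric(1))
  vals
}

#' Linear attenuation coefficient of a material
#'
#' `mu = rho * sum_i w_i (mu/rho)_i(E)` with log-log interpolation of the
#' packaged elemental tables.
#'
#' @param material a `bct_material` from [mixture_composition()].
#' @param E photon energy in keV (vectorized); must lie in the tabulated
#'   range.
#' @return linear attenuation coefficient(s) in 1/cm.
#' @export
linear_attenuation <- function(material, E) {
  stopifnot(inherits(material, "bct_material"))
  material$composition$density_g_cm3 * .mixture_coef(material, E, "attenuation")
}

#' Mass energy-absorption coefficient of a material (cm^2/g)
#' @inheritParams linear_attenuation
#' @export
mass_energy_absorption <- function(material, E) {
  stopifnot(inherits(material, "bct_material"))
  .mixture_coef(material, E, "absorption")
}

#' Mass energy-absorption coefficient of air (cm^2/g)
#' @param E photon energy in keV (vectorized).
#' @export
air_mass_energy_absorption <- function(E) {
  air <- xray_tables()$air
  .loglog_interp(E, air$energy_keV, air$mu_en_over_rho_cm2_g)
}

#' Linear attenuation coefficient of air (1/cm)
#'
#' Uses a dry-air density of 1.205e-3 g/cm^3 (20 C, sea level).
#' @param E photon energy in keV (vectorized).
#' @export
air_linear_attenuation <- function(E) {
  air <- xray_tables()$air
  1.205e-3 * .loglog_interp(E, air$energy_keV, air$mu_over_rho_cm2_g)
}
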