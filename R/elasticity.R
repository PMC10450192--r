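# Extensible worm-like-chain (WLC) elasticity: conversions between force,
# fractional extension and DNA contour length.

# Boltzmann constant in pN nm / K (exact SI value).
.kB <- 1.380649e-2

#' Elastic parameters for double-stranded DNA
#'
#' Bundles the constants of the extensible worm-like-chain (WLC) model used
#' to convert between tension, fractional extension and contour length.
#' Defaults are the literature-standard values for dsDNA in physiological
#' ionic conditions at room temperature.
#'
#' @param persistence_length Persistence length P in nm (default 50).
#' @param stretch_modulus Enthalpic stretch modulus K in pN (default 1200).
#' @param temperature Absolute temperature in K (default 296.15, ~23 C).
#' @param rise_per_bp Helical rise per base pair in nm (default 0.34).
#'
#' @return An object of class `elastic_params`.
#' @examples
#' p <- elastic_params()
#' thermal_energy(p) # ~4.09 pN nm
#' @export
elastic_params <- function(persistence_length = 50, stretch_modulus = 1200,
                           temperature = 296.15, rise_per_bp = 0.34) {
  vals <- c(persistence_length = persistence_length,
            stretch_modulus = stretch_modulus,
            temperature = temperature, rise_per_bp = rise_per_bp)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all elastic parameters must be finite and strictly positive")
  }
  structure(as.list(vals), class = "elastic_params")
}

#' Thermal energy kT
#'
#' @param params An [elastic_params()] object.
#' @return Thermal energy in pN nm.
#' @export
thermal_energy <- function(params = elastic_params()) {
  .kB * params$temperature
}

# Marko-Siggia interpolation force at relaxed (entropic) fractional
# extension z, in pN. Valid for z < 1.
.ms_force <- function(z, params) {
  (thermal_energy(params) / params$persistence_length) *
    (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' WLC force at a given fractional extension
#'
#' Solves the extensible Marko-Siggia relation self-consistently:
#' `F = (kT/P) * (1/(4(1-z)^2) - 1/4 + z)` with `z = x - F/K`, where `x` is
#' the measured extension divided by contour length. The enthalpic correction
#' enters through `z` rather than additively, keeping the relation monotone
#' and exactly invertible.
#'
#' @param frac_ext Fractional extension x (extension / contour length),
#'   `>= 0`. Values slightly above 1 are admitted at high force where the
#'   enthalpic stretch dominates.
#' @param params An [elastic_params()] object.
#' @return Force in pN, vectorised over `frac_ext`.
#' @examples
#' wlc_force(0.94) # ~5 pN
#' @export
wlc_force <- function(frac_ext, params = elastic_params()) {
  if (any(!is.finite(frac_ext)) || any(frac_ext < 0)) {
    rlang::abort("frac_ext must be finite and >= 0")
  }
  vapply(frac_ext, function(x) {
    if (x == 0) return(0)
    g <- function(f) .ms_force(x - f / params$stretch_modulus, params) - f
    # g(0) > 0 for x > 0 when z < 1; find an upper bracket where g < 0
    f_lo <- 0
    if (x - 0 / params$stretch_modulus >= 1) {
      # need F large enough that z < 1 before the force balance is defined
      f_lo <- params$stretch_modulus * (x - 1) * (1 + 1e-9) + 1e-9
    }
    f_hi <- max(2 * f_lo, 1)
    it <- 0
    while (g(f_hi) > 0) {
      f_hi <- f_hi * 2
      it <- it + 1
      if (it > 60) rlang::abort("no WLC force solution found (frac_ext out of range)")
    }
    stats::uniroot(g, c(f_lo, f_hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Fractional extension at a given force
#'
#' Exact inverse of [wlc_force()]: the relaxed extension `z` solving the
#' Marko-Siggia relation is found by bracketed root-finding on `z in [0, 1)`
#' and the enthalpic term `F/K` is added back.
#'
#' @param force Tension in pN, `>= 0`.
#' @param params An [elastic_params()] object.
#' @return Fractional extension, vectorised over `force`.
#' @examples
#' fractional_extension(5) # ~0.940
#' @export
fractional_extension <- function(force, params = elastic_params()) {
  if (any(!is.finite(force)) || any(force < 0)) {
    rlang::abort("force must be finite and >= 0")
  }
  vapply(force, function(f) {
    if (f == 0) return(0)
    g <- function(z) .ms_force(z, params) - f
    z <- stats::uniroot(g, c(0, 1 - 1e-9), tol = 1e-14)$root
    z + f / params$stretch_modulus
  }, numeric(1))
}

# Fast vectorised fractional extension: cubic-spline interpolant of the
# exact inverse over a force range. Used on per-sample force signals where
# calling uniroot per sample would dominate runtime.
.fractional_extension_fun <- function(force_range, params, n = 2048L) {
  lo <- max(min(force_range) - 0.5, 1e-4)
  hi <- max(force_range) + 0.5
  grid <- seq(lo, hi, length.out = n)
  stats::splinefun(grid, fractional_extension(grid, params), method = "natural")
}

#' DNA contour length from extension and force
#'
#' Converts a measured tether extension at known tension into contour length
#' in base pairs: `L = extension / (fractional_extension(F) * rise_per_bp)`.
#'
#' @param extension Extension in nm, `>= 0`.
#' @param force Tension in pN, `> 0` (fractional extension is zero at zero
#'   force, so the conversion is undefined there).
#' @param params An [elastic_params()] object.
#' @return Contour length in bp, vectorised (recycling extension/force).
#' @examples
#' contour_length_bp(3196, 5) # ~10 kb
#' @export
contour_length_bp <- function(extension, force, params = elastic_params()) {
  if (any(!is.finite(extension)) || any(extension < 0)) {
    rlang::abort("extension must be finite and >= 0")
  }
  if (any(!is.finite(force)) || any(force <= 0)) {
    rlang::abort("force must be finite and > 0")
  }
  extension / (fractional_extension(force, params) * params$rise_per_bp)
}
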