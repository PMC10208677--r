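#' Mechanical description of a muscular thin film cantilever
#'
#' Houses every symbol of the Stoney stress computation: the free length and
#' width of the cantilever, the elastic substrate's modulus, Poisson ratio
#' and thickness, the contractile film (tissue) thickness, and a pluggable
#' dimensionless correction factor for modified-Stoney variants.
#'
#' The defaults describe a micro-molded gelatin cantilever carrying a
#' neonatal rat ventricular myocyte monolayer; the gelatin modulus and the
#' two thicknesses are placeholders a user should override with measured
#' values for their chips.
#'
#' @param free_length_L Free (deflecting) cantilever length in m.
#' @param width Cantilever width in m.
#' @param substrate_modulus_Es Substrate Young's modulus in Pa.
#' @param substrate_poisson_nu Substrate Poisson ratio (0.5 = incompressible
#'   hydrogel).
#' @param substrate_thickness_hs Substrate thickness in m.
#' @param film_thickness_hf Tissue layer thickness in m.
#' @param correction_factor_C Dimensionless multiplicative correction to the
#'   classical Stoney relation (default 1, the classical thin-film limit);
#'   thickness-ratio corrections plug in here.
#' @return An object of class `mechanical_spec`.
#' @export
mechanical_spec <- function(free_length_L = 3e-3,
                            width = 4e-3,
                            substrate_modulus_Es = 50e3,
                            substrate_poisson_nu = 0.5,
                            substrate_thickness_hs = 100e-6,
                            film_thickness_hf = 18e-6,
                            correction_factor_C = 1) {
  stopifnot(free_length_L > 0, width > 0,
            substrate_modulus_Es > 0,
            substrate_thickness_hs > 0, film_thickness_hf > 0,
            correction_factor_C > 0)
  if (substrate_poisson_nu < 0 || substrate_poisson_nu > 0.5 + 1e-9) {
    stop("substrate_poisson_nu must lie in [0, 0.5]")
  }
  structure(
    list(
      free_length_L = free_length_L,
      width = width,
      substrate_modulus_Es = substrate_modulus_Es,
      substrate_poisson_nu = substrate_poisson_nu,
      substrate_thickness_hs = substrate_thickness_hs,
      film_thickness_hf = film_thickness_hf,
      correction_factor_C = correction_factor_C
    ),
    class = "mechanical_spec"
  )
}

#' @export
print.mechanical_spec <- function(x, ...) {
  cat(sprintf(
    paste0("mechanical_spec: L = %g mm, width = %g mm, Es = %g kPa, ",
           "nu = %g, hs = %g um, hf = %g um, C = %g\n"),
    1e3 * x$free_length_L, 1e3 * x$width, 1e-3 * x$substrate_modulus_Es,
    x$substrate_poisson_nu, 1e6 * x$substrate_thickness_hs,
    1e6 * x$film_thickness_hf, x$correction_factor_C
  ))
  invisible(x)
}

#' Read a mechanical spec from a YAML config file
#'
#' @param path Path to a YAML file whose top-level keys are any subset of
#'   the [mechanical_spec()] arguments; missing keys take the defaults.
#' @return A [mechanical_spec()].
#' @export
mechanical_spec_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  cfg <- yaml::read_yaml(path)
  known <- names(formals(mechanical_spec))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(mechanical_spec, cfg)
}

#' Film stress from substrate curvature (Stoney relation)
#'
#' The classical Stoney thin-film relation, with a pluggable multiplicative
#' correction factor `C` for modified variants:
#' \deqn{\sigma = C \, E_s h_s^2 \kappa / (6 h_f (1 - \nu_s))}
#' Linear in the curvature.
#'
#' @param kappa Curvature in 1/m (>= 0); vectorized.
#' @param spec A [mechanical_spec()].
#' @return Film stress in Pa, same length as `kappa`.
#' @examples
#' sp <- mechanical_spec(substrate_modulus_Es = 6e3,
#'                       substrate_thickness_hs = 1e-3,
#'                       film_thickness_hf = 1e-3)
#' stoney_stress(1, sp)  # 2 Pa
#' @export
stoney_stress <- function(kappa, spec) {
  stopifnot(inherits(spec, "mechanical_spec"), all(kappa >= 0))
  if (spec$substrate_poisson_nu >= 1) stop("Poisson ratio of 1 is unphysical")
  spec$correction_factor_C * spec$substrate_modulus_Es *
    spec$substrate_thickness_hs^2 * kappa /
    (6 * spec$film_thickness_hf * (1 - spec$substrate_poisson_nu))
}

#' Curvature from stress: the inverse Stoney relation
#'
#' @param sigma Film stress in Pa (vectorized).
#' @param spec A [mechanical_spec()].
#' @return Curvature in 1/m.
#' @export
stoney_curvature <- function(sigma, spec) {
  stopifnot(inherits(spec, "mechanical_spec"), all(sigma >= 0))
  6 * spec$film_thickness_hf * (1 - spec$substrate_poisson_nu) * sigma /
    (spec$correction_factor_C * spec$substrate_modulus_Es *
       spec$substrate_thickness_hs^2)
}

#' Horizontal projection of a uniformly curled cantilever
#'
#' A cantilever of free length `L` bending as a circular arc of curvature
#' `kappa`, base tangent to the substrate plane, presents a horizontal extent
#' \eqn{x = L \sin(\kappa L) / (\kappa L)} to a camera looking from above
#' (`x = L` for a flat film). Injective for `kappa * L` in `[0, pi)`.
#'
#' @param kappa Curvature in 1/m (vectorized, >= 0).
#' @param L Free length in m.
#' @return Projected length in m.
#' @export
projection_from_curvature <- function(kappa, L) {
  stopifnot(L > 0, all(kappa >= 0))
  theta <- kappa * L
  x <- ifelse(theta == 0, L, L * sin(theta) / theta)
  as.numeric(x)
}

#' Recover curvature from the x-projection of a curled cantilever
#'
#' Inverts \eqn{x = L \sin(\theta)/\theta} (with \eqn{\theta = \kappa L}) by
#' bisection on \eqn{\theta \in (0, \pi)}, where \eqn{\sin\theta/\theta} is
#' strictly decreasing, to an absolute tolerance of 1e-12 in \eqn{\theta}.
#'
#' @param x Projected length(s) in m; must satisfy `0 < x <= L`.
#' @param L Free length in m.
#' @return Curvature(s) `kappa` in 1/m, in `[0, pi/L)`; `x = L` maps to 0.
#' @examples
#' curvature_from_projection(3e-3 * 2 / pi, 3e-3) * 3e-3  # pi/2
#' @export
curvature_from_projection <- function(x, L) {
  stopifnot(L > 0)
  if (any(x <= 0)) stop("projected length must be positive")
  if (any(x > L)) {
    stop(sprintf("projected length %.6g m exceeds the free length %.6g m: impossible projection",
                 max(x), L))
  }
  rho <- x / L
  lo <- rep(0, length(x))
  hi <- rep(pi, length(x))
  # sin(theta)/theta is strictly decreasing on (0, pi): plain bisection,
  # vectorized over all frames at once
  for (i in seq_len(60)) {
    mid <- 0.5 * (lo + hi)
    f <- sin(mid) / mid
    high <- f > rho      # mid below the solution
    lo[high] <- mid[high]
    hi[!high] <- mid[!high]
    if (max(hi - lo) < 1e-12) break
  }
  theta <- 0.5 * (lo + hi)
  theta[rho >= 1] <- 0
  theta / L
}
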