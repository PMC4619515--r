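#' Suspending-medium properties
#'
#' Container for the physical properties of the suspending fluid (cell-culture
#' medium).  All values are strict SI.  The default is a water-like culture
#' medium at 22 degrees C (density 1005 kg m^-3, viscosity 9.55e-4 Pa s),
#' which is an assumption of this package, not a measured media property:
#' override it when media density/viscosity are known.
#'
#' @param density Medium density rho_m (kg m^-3).
#' @param viscosity Dynamic viscosity eta (kg m^-1 s^-1, i.e. Pa s).
#' @param temperature Absolute temperature T (K).
#' @param mean_free_path Mean free path lambda of the medium (m); about
#'   2.5e-10 m for water.  Enters only the Cunningham slip correction.
#' @return An object of class `dg_medium`.
#' @examples
#' medium()                       # water-like culture medium, 22 C
#' medium(temperature = 310.15)   # same medium at 37 C
#' @export
medium <- function(density = 1005, viscosity = 9.55e-4,
                   temperature = 295.15, mean_free_path = 2.5e-10) {
  .dg_check_num(density, "density", len = 1)
  .dg_check_num(viscosity, "viscosity", len = 1)
  .dg_check_num(temperature, "temperature", len = 1)
  .dg_check_num(mean_free_path, "mean_free_path", len = 1)
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature, mean_free_path = mean_free_path),
            class = "dg_medium")
}

#' Bulk nanomaterial properties
#'
#' @param name Material label.
#' @param density Bulk material density rho_NM (kg m^-3).
#' @param ssa Specific surface area (m^2 g^-1), optional; needed only for
#'   BET-equivalent diameters.
#' @param molar_mass Molar mass (g mol^-1), optional; needed only to convert
#'   molar dissolution data to mass fractions.
#' @return An object of class `dg_material`.
#' @export
enm_material <- function(name, density, ssa = NULL, molar_mass = NULL) {
  .dg_check_num(density, "density", len = 1)
  if (!is.null(ssa)) .dg_check_num(ssa, "ssa", len = 1)
  if (!is.null(molar_mass)) .dg_check_num(molar_mass, "molar_mass", len = 1)
  structure(list(name = as.character(name)[1], density = density,
                 ssa = ssa, molar_mass = molar_mass),
            class = "dg_material")
}

#' Agglomerate size species
#'
#' One size class of suspended agglomerates.  Polydisperse suspensions are
#' lists of these, with mass fractions summing to one (see
#' [species_from_distribution()]).
#'
#' @param d_H Hydrodynamic diameter (m).
#' @param rho_EV Effective (agglomerate) density including trapped medium
#'   (kg m^-3), e.g. from volumetric centrifugation.
#' @param fraction Fraction of total suspended ENM mass carried by this
#'   species (dimensionless, in `[0, 1]`).
#' @return An object of class `dg_species`.
#' @export
agglomerate_species <- function(d_H, rho_EV, fraction = 1) {
  .dg_check_num(d_H, "d_H", len = 1)
  .dg_check_num(rho_EV, "rho_EV", len = 1)
  .dg_check_num(fraction, "fraction", positive = FALSE, len = 1)
  if (fraction < 0 || fraction > 1) .dg_stop("'fraction' must be in [0, 1]")
  structure(list(d_H = d_H, rho_EV = rho_EV, fraction = fraction),
            class = "dg_species")
}

.dg_species_list <- function(species) {
  if (inherits(species, "dg_species")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "dg_species")))
    .dg_stop("'species' must be a dg_species or a list of them")
  f <- vapply(species, `[[`, 0, "fraction")
  if (abs(sum(f) - 1) > 1e-12)
    .dg_stop("species mass fractions must sum to 1 (got ", format(sum(f)), ")")
  species
}

#' Build a species list from a size distribution
#'
#' Converts a (volume/mass-weighted) size distribution into a list of
#' [agglomerate_species()] sharing one effective density.  Number-weighted
#' distributions are first converted with [number_to_volume_distribution()],
#' since mass fractions are volume fractions at a common effective density.
#'
#' @param dist A [size_distribution()].
#' @param rho_EV Effective density (kg m^-3) applied to every size class.
#' @return List of `dg_species`.
#' @export
species_from_distribution <- function(dist, rho_EV) {
  stopifnot(inherits(dist, "dg_size_distribution"))
  if (dist$weighting == "number") dist <- number_to_volume_distribution(dist)
  f <- dist$fraction / sum(dist$fraction)
  # guard the strict sum-to-one invariant against accumulated rounding
  f[length(f)] <- 1 - sum(f[-length(f)])
  mapply(function(d, fr) agglomerate_species(d, rho_EV, fr),
         dist$diameter, f, SIMPLIFY = FALSE)
}

#' Friction-correction specification
#'
#' Corrections to the ideal Stokes friction coefficient, expressed as the
#' ratio f/f0 by which diffusion coefficients and sedimentation velocities
#' are *divided* (see [friction_ratio()]).  The Cunningham slip correction is
#' applied by default; shape, solvation and roughness factors default to 1
#' (smooth unsolvated sphere).
#'
#' @param slip Apply the Cunningham slip correction (logical).
#' @param shape One of `"sphere"`, `"cube"`, `"prolate"`, `"oblate"`,
#'   `"cylinder"`, `"explicit"`.
#' @param aspect_ratio Major/minor axis ratio P = a/b (> 1), required for
#'   ellipsoids and cylinders.
#' @param shape_factor Explicit dynamic shape factor chi, required when
#'   `shape = "explicit"`.
#' @param solvation Solvation factor (> 0).
#' @param roughness Surface-roughness factor (> 0).
#' @return An object of class `dg_friction`.
#' @export
friction_correction <- function(slip = TRUE, shape = "sphere",
                                aspect_ratio = NULL, shape_factor = NULL,
                                solvation = 1, roughness = 1) {
  shape <- match.arg(shape, c("sphere", "cube", "prolate", "oblate",
                              "cylinder", "explicit"))
  if (shape %in% c("prolate", "oblate", "cylinder")) {
    if (is.null(aspect_ratio)) .dg_stop("'aspect_ratio' required for shape '", shape, "'")
    .dg_check_num(aspect_ratio, "aspect_ratio", len = 1)
  }
  if (shape == "explicit") {
    if (is.null(shape_factor)) .dg_stop("'shape_factor' required for shape 'explicit'")
    .dg_check_num(shape_factor, "shape_factor", len = 1)
  }
  .dg_check_num(solvation, "solvation", len = 1)
  .dg_check_num(roughness, "roughness", len = 1)
  structure(list(slip = isTRUE(slip), shape = shape,
                 aspect_ratio = aspect_ratio, shape_factor = shape_factor,
                 solvation = solvation, roughness = roughness),
            class = "dg_friction")
}

#' Transport-coefficient options
#'
#' @param k Concentration-dependence factor (inverse mass concentration,
#'   m^3 kg^-1).  Both transport coefficients are divided by (1 + k C)
#'   locally; the default 0 recovers concentration-independent transport.
#' @return An object of class `dg_coef_options`.
#' @export
coefficient_options <- function(k = 0) {
  .dg_check_num(k, "k", positive = FALSE, len = 1)
  if (k < 0) .dg_stop("'k' must be >= 0")
  structure(list(k = k), class = "dg_coef_options")
}

#' Stokes sedimentation velocity
#'
#' Terminal settling velocity of a spherical agglomerate under gravity,
#' v_s = g (rho_EV - rho_m) d_H^2 / (18 eta).  Negative for buoyant species
#' (effective density below the medium density).
#'
#' @param species An [agglomerate_species()].
#' @param medium A [medium()].
#' @return Velocity in m s^-1.
#' @export
sedimentation_velocity <- function(species, medium) {
  stopifnot(inherits(species, "dg_species"), inherits(medium, "dg_medium"))
  .dg_g * (species$rho_EV - medium$density) * species$d_H^2 /
    (18 * medium$viscosity)
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (3 pi eta d_H).
#'
#' @inheritParams sedimentation_velocity
#' @return Diffusion coefficient in m^2 s^-1 (strictly positive).
#' @export
diffusion_coefficient <- function(species, medium) {
  stopifnot(inherits(species, "dg_species"), inherits(medium, "dg_medium"))
  .dg_kB * medium$temperature / (3 * pi * medium$viscosity * species$d_H)
}

#' Sedimentation coefficient
#'
#' S = v_s / g: sedimentation velocity per unit applied acceleration
#' (units of seconds; the svedberg is 1e-13 s).
#'
#' @inheritParams sedimentation_velocity
#' @return Sedimentation coefficient in s; sign matches the velocity.
#' @export
sedimentation_coefficient <- function(species, medium) {
  sedimentation_velocity(species, medium) / .dg_g
}

#' Cunningham slip correction factor
#'
#' C_c = 1 + (lambda/d) (2.34 + 1.05 exp(-0.39 d / (2 lambda))).  Appreciable
#' only when the particle diameter approaches the medium mean free path
#' (C_c ~ 1.006 at 100 nm, ~ 1.12 at 5 nm in water).
#'
#' @param d Particle diameter (m).
#' @param mean_free_path Medium mean free path lambda (m).
#' @return Dimensionless factor > 1.
#' @export
cunningham_factor <- function(d, mean_free_path = 2.5e-10) {
  .dg_check_num(d, "d")
  .dg_check_num(mean_free_path, "mean_free_path", len = 1)
  1 + (mean_free_path / d) *
    (2.34 + 1.05 * exp(-0.39 * d / (2 * mean_free_path)))
}

#' Dynamic shape factor
#'
#' Ratio chi by which the friction of a non-spherical particle exceeds that
#' of the volume-equivalent sphere.  Closed forms are provided for prolate
#' and oblate ellipsoids and circular cylinders of axis ratio P = a/b > 1;
#' the cube value 1.08 is a tabulated constant.
#'
#' @param shape One of `"sphere"`, `"cube"`, `"prolate"`, `"oblate"`,
#'   `"cylinder"`, `"explicit"`.
#' @param P Axis ratio a/b (> 1), for the analytic non-spherical shapes.
#' @param chi Explicit user value, for `shape = "explicit"`.
#' @return Dimensionless dynamic shape factor.
#' @export
dynamic_shape_factor <- function(shape, P = NULL, chi = NULL) {
  shape <- match.arg(shape, c("sphere", "cube", "prolate", "oblate",
                              "cylinder", "explicit"))
  if (shape == "sphere") return(1)
  if (shape == "cube") return(1.08)
  if (shape == "explicit") {
    if (is.null(chi)) .dg_stop("'chi' required for shape 'explicit'")
    .dg_check_num(chi, "chi", len = 1)
    return(chi)
  }
  if (is.null(P) || !is.numeric(P) || length(P) != 1 || is.na(P) || P <= 1)
    .dg_stop("axis ratio 'P' must be a single number > 1 for shape '", shape, "'")
  q <- sqrt(P^2 - 1)
  switch(shape,
    prolate  = P^(-1/3) * q / log(P + q),
    oblate   = q / (P^(2/3) * atan(q)),
    cylinder = (2/3)^(1/3) * P^(2/3) / (log(2 * P) - 0.3))
}

#' Friction ratio f/f0
#'
#' Combined correction ratio of the actual to the ideal Stokes friction
#' coefficient.  Uncorrected diffusion coefficients and sedimentation
#' velocities are divided by this ratio: slip (C_c > 1) speeds transport up,
#' shape/solvation/roughness factors (>= 1) slow it down.  The factors are
#' composed multiplicatively: f/f0 = chi * solvation * roughness / C_c
#' (with C_c = 1 when slip is disabled).
#'
#' @param correction A [friction_correction()].
#' @param d Particle diameter (m), used by the slip term.
#' @param mean_free_path Medium mean free path (m).
#' @return Dimensionless ratio > 0.
#' @export
friction_ratio <- function(correction = friction_correction(), d,
                           mean_free_path = 2.5e-10) {
  stopifnot(inherits(correction, "dg_friction"))
  chi <- dynamic_shape_factor(correction$shape, P = correction$aspect_ratio,
                              chi = correction$shape_factor)
  ratio <- chi * correction$solvation * correction$roughness
  if (correction$slip) ratio <- ratio / cunningham_factor(d, mean_free_path)
  ratio
}

#' Concentration-dependent transport coefficient
#'
#' X' = X / (1 + k C): optional non-linear damping of a diffusion or
#' sedimentation coefficient by the local mass concentration.  Identity at
#' the default k = 0.
#'
#' @param X Coefficient value(s).
#' @param C Local mass concentration(s), kg m^-3 (>= 0).
#' @param k Concentration-dependence factor (m^3 kg^-1, >= 0).
#' @return Corrected coefficient, same shape as `X`.
#' @export
concentration_corrected_coefficient <- function(X, C, k = 0) {
  .dg_check_num(k, "k", positive = FALSE, len = 1)
  if (k < 0) .dg_stop("'k' must be >= 0")
  if (any(C < 0)) .dg_stop("'C' must be >= 0")
  X / (1 + k * C)
}

# Corrected transport coefficients for one species: divide ideal D and v_s
# by the friction ratio f/f0.
.dg_transport <- function(species, medium, correction = friction_correction()) {
  ratio <- friction_ratio(correction, species$d_H, medium$mean_free_path)
  list(D = diffusion_coefficient(species, medium) / ratio,
       S = sedimentation_coefficient(species, medium) / ratio)
}
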