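#' Nanomaterial volume fraction of an agglomerate
#'
#' From the mixing rule rho_EV = f rho_NM + (1 - f) rho_m:
#' f_V,NM = (rho_EV - rho_m) / (rho_NM - rho_m).  Values outside `[0, 1]`
#' indicate inconsistent measured densities and are clamped with a warning.
#'
#' @param rho_EV Agglomerate effective density (kg m^-3).
#' @param rho_NM Bulk nanomaterial density (kg m^-3).
#' @param rho_m Medium density (kg m^-3).
#' @return Volume fraction in `(0, 1]`.
#' @export
nm_volume_fraction <- function(rho_EV, rho_NM, rho_m) {
  if (rho_NM == rho_m) .dg_stop("rho_NM must differ from rho_m")
  f <- (rho_EV - rho_m) / (rho_NM - rho_m)
  if (f < 0 || f > 1) {
    warning("effective density outside [rho_m, rho_NM]; ",
            "volume fraction clamped to [0, 1]", call. = FALSE)
    f <- min(max(f, 0), 1)
  }
  f
}

#' Agglomerate number concentration
#'
#' C_N,agg = 6 C_NM / (pi d_H^3 rho_NM f_V,NM), assuming spherical
#' homogeneous agglomerates.  At f_V,NM = 1 this reduces to the solid-sphere
#' count 6 C / (pi d^3 rho).
#'
#' @param C_NM Nanomaterial mass concentration (kg m^-3).
#' @param d_H Agglomerate hydrodynamic diameter (m).
#' @param rho_NM Bulk nanomaterial density (kg m^-3).
#' @param f_V_NM Nanomaterial volume fraction of the agglomerate.
#' @return Number concentration (m^-3).
#' @export
number_concentration <- function(C_NM, d_H, rho_NM, f_V_NM) {
  if (any(f_V_NM <= 0)) .dg_stop("'f_V_NM' must be > 0 (no solid content)")
  .dg_check_num(d_H, "d_H")
  .dg_check_num(rho_NM, "rho_NM")
  6 * C_NM / (pi * d_H^3 * rho_NM * f_V_NM)
}

#' Agglomerate and nanomaterial surface-area concentrations
#'
#' C_S,agg = 6 C_NM / (d_H rho_NM f_V,NM) is the total agglomerate envelope
#' surface per volume; C_S,NM = C_S,agg f_V,NM = 6 C_NM / (d_H rho_NM) is the
#' nanomaterial surface exposed on that envelope (independent of f_V,NM).
#'
#' @inheritParams number_concentration
#' @return List with `agg` and `nm` surface concentrations (m^2 m^-3).
#' @export
surface_concentrations <- function(C_NM, d_H, rho_NM, f_V_NM) {
  if (any(f_V_NM <= 0)) .dg_stop("'f_V_NM' must be > 0 (no solid content)")
  .dg_check_num(d_H, "d_H")
  .dg_check_num(rho_NM, "rho_NM")
  nm <- 6 * C_NM / (d_H * rho_NM)
  list(agg = nm / f_V_NM, nm = nm)
}

#' BET-equivalent primary-particle diameter
#'
#' Diameter of the smooth sphere with the measured specific surface area:
#' d_BET = 6 / (SSA rho_p).
#'
#' @param ssa Specific surface area (m^2 g^-1).
#' @param rho_p Particle (bulk material) density (g cm^-3).
#' @return Diameter (m).
#' @export
bet_equivalent_diameter <- function(ssa, rho_p) {
  .dg_check_num(ssa, "ssa")
  .dg_check_num(rho_p, "rho_p")
  # SSA m^2 g^-1 -> m^2 kg^-1, rho g cm^-3 -> kg m^-3
  6 / ((ssa * 1e3) * (rho_p * 1e3))
}

#' Dose metrics for the bottom exposure slice
#'
#' Collapses a concentration profile into the dose metrics reported for the
#' cell microenvironment: mean mass concentration over the bottom slice
#' (default thickness 10 um), per-area deposition (concentration x
#' thickness, plus any cell-bound areal mass), deposited fraction f_D, and
#' per-species particle-number and nanomaterial-surface-area equivalents.
#'
#' f_D is the deposited mass per area divided by the *current* suspended +
#' bound mass per area, so complete deposition maps to f_D = 1 even when
#' part of the material has dissolved.
#'
#' @param C Concentration matrix (n compartments x J species, kg m^-3),
#'   row 1 at the top of the column.
#' @param h Compartment height (m).
#' @param slice_thickness Bottom-slice thickness (m); must span an integer
#'   number (>= 1) of compartments.
#' @param species List of [agglomerate_species()] (column order of `C`).
#' @param material [enm_material()] providing the bulk density.
#' @param medium [medium()] providing the medium density for f_V,NM.
#' @param bound Per-species cell-bound areal mass (kg m^-2); default zero.
#' @param dissolved Dissolved mass concentration over the column (kg m^-3).
#' @param d_current Per-species current diameters (m); defaults to the
#'   nominal species diameters (they differ only under dissolution).
#' @return One-row data.frame of SI dose metrics (see [run_simulation()]).
#' @export
bottom_slice_metrics <- function(C, h, slice_thickness, species, material,
                                 medium, bound = NULL, dissolved = 0,
                                 d_current = NULL) {
  species <- .dg_species_list(species)
  C <- as.matrix(C)
  n <- nrow(C); J <- ncol(C)
  if (J != length(species)) .dg_stop("ncol(C) must match length(species)")
  m <- slice_thickness / h
  if (abs(m - round(m)) > 1e-8 || round(m) < 1 || round(m) > n)
    .dg_stop("slice thickness must span an integer number (>= 1) of compartments")
  m <- round(m)
  if (is.null(bound)) bound <- numeric(J)
  if (is.null(d_current)) d_current <- vapply(species, `[[`, 0, "d_H")

  slice_conc_j <- colMeans(C[(n - m + 1):n, , drop = FALSE])  # kg m^-3
  dep_area_j <- slice_conc_j * slice_thickness + bound        # kg m^-2
  total_area <- sum(colSums(C) * h) + sum(bound)              # suspended + bound
  f_D <- if (total_area > 0) sum(dep_area_j) / total_area else 0

  f_V <- vapply(species, function(sp)
    nm_volume_fraction(sp$rho_EV, material$density, medium$density), 0)
  num_conc <- sum(number_concentration(slice_conc_j, d_current,
                                       material$density, f_V))
  num_area <- sum(number_concentration(dep_area_j, d_current,
                                       material$density, f_V))
  surf_conc <- sum(surface_concentrations(slice_conc_j, d_current,
                                          material$density, f_V)$nm)
  surf_area <- sum(surface_concentrations(dep_area_j, d_current,
                                          material$density, f_V)$nm)

  data.frame(bottom_conc = sum(slice_conc_j),
             deposited_per_area = sum(dep_area_j),
             fraction_deposited = f_D,
             number_conc = num_conc,
             number_per_area = num_area,
             surface_conc = surf_conc,
             surface_per_area = surf_area,
             bound_per_area = sum(bound),
             dissolved_conc = dissolved)
}
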