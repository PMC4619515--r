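# Characterized metal-oxide ENM suspensions shipped as presets: BET specific
# surface area, BET-equivalent primary diameter, suspending medium label
# (metadata only -- media density/viscosity must still be configured), DLS
# volume-weighted mean hydrodynamic diameter and polydispersity index, bulk
# material density and VCM effective agglomerate density.  Molar masses are
# standard formula weights, carried for dissolution unit conversions.
.dg_preset_table <- data.frame(
  name       = c("SiO2", "Fe2O3", "CeO2", "TiO2", "ZnO"),
  ssa_m2_g   = c(147, 41.5, 14, 50, 17),
  d_bet_nm   = c(18.6, 27.6, 45.4, 21, 63),
  media      = c("PBS + 0.1 % BSA", "RPMI + 10 % HS", "RPMI + 0.5 % BSA",
                 "RPMI + 10 % HS", "RPMI + 10 % FBS"),
  d_hv_nm    = c(149.9, 234.5, 982.1, 397.8, 307.0),
  pdi        = c(0.175, 0.755, 0.310, 0.233, 0.303),
  rho_enm_g_cm3 = c(2.648, 5.242, 7.215, 4.230, 5.606),
  rho_ev_g_cm3  = c(1.564, 1.335, 1.420, 1.251, 1.650),
  molar_mass_g_mol = c(60.08, 159.69, 172.11, 79.87, 81.38),
  stringsAsFactors = FALSE)

#' Material presets
#'
#' Table of the five characterized metal-oxide nanomaterial suspensions
#' bundled with the package (silica, iron oxide, ceria, titania, zinc
#' oxide), with BET surface areas, DLS volume-weighted mean diameters and
#' polydispersity indices, bulk and effective densities, and molar masses.
#' The polydispersity index and media label are metadata; the solver uses
#' `d_hv_nm` and `rho_ev_g_cm3`.
#'
#' @return data.frame, one row per material.
#' @export
dg_presets <- function() .dg_preset_table

#' Retrieve one material preset as model objects
#'
#' @param name Preset name (see [dg_presets()]); case-insensitive.
#' @return List with `material` ([enm_material()]), `species` (monodisperse
#'   [agglomerate_species()] at the volume-weighted mean diameter),
#'   `media_label`, `pdi` and `d_bet` (m).
#' @export
dg_preset <- function(name) {
  tab <- .dg_preset_table
  i <- match(tolower(name), tolower(tab$name))
  if (is.na(i))
    .dg_stop("unknown preset '", name, "'; available: ",
             paste(tab$name, collapse = ", "))
  row <- tab[i, ]
  list(material = enm_material(row$name, density = row$rho_enm_g_cm3 * 1e3,
                               ssa = row$ssa_m2_g,
                               molar_mass = row$molar_mass_g_mol),
       species = agglomerate_species(d_H = row$d_hv_nm * 1e-9,
                                     rho_EV = row$rho_ev_g_cm3 * 1e3,
                                     fraction = 1),
       media_label = row$media, pdi = row$pdi, d_bet = row$d_bet_nm * 1e-9)
}
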