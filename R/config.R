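# JSON run-configuration loader.  User-facing units are the conventional
# ones used on lab reports (mg ml^-1, nm, g cm^-3, mPa s, degrees C, mm, um,
# hours); everything is converted to strict SI here, at the boundary.

.dg_allowed_keys <- list(
  top        = c("material", "suspension", "medium", "simulation",
                 "dissolution", "corrections"),
  material   = c("preset", "name", "density_g_cm3", "ssa_m2_g",
                 "molar_mass_g_mol"),
  suspension = c("c0_mg_ml", "diameter_nm", "distribution_file", "weighting",
                 "effective_density_g_cm3"),
  medium     = c("density_g_cm3", "viscosity_mpa_s", "temperature_c",
                 "mean_free_path_nm"),
  simulation = c("column_height_mm", "compartment_height_um", "time_step_s",
                 "duration_h", "output_interval_h", "boundary", "kd_molar",
                 "bottom_slice_um", "area_cm2"),
  dissolution = c("mode", "initial_fraction", "rate_per_h", "ramp_end_h",
                  "max_fraction"),
  corrections = c("slip", "shape", "aspect_ratio", "shape_factor",
                  "solvation", "roughness", "k_conc"))

.dg_check_keys <- function(block, name) {
  extra <- setdiff(names(block), .dg_allowed_keys[[name]])
  if (length(extra))
    .dg_stop("unknown key(s) in '", name, "' block: ",
             paste(extra, collapse = ", "))
}

.dg_get <- function(block, key, default = NULL, required = FALSE, where = "") {
  if (!is.null(block[[key]])) return(block[[key]])
  if (required) .dg_stop("missing required key '", key, "' in '", where, "' block")
  default
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing material, suspension, medium,
#' simulation and (optionally) dissolution and friction-correction blocks,
#' validates it (unknown keys are rejected, required keys and ranges
#' checked), applies documented defaults and converts all quantities to SI.
#' A material `preset` fills in bulk/effective density, diameter, surface
#' area and molar mass, each overridable by explicit keys.
#'
#' @param path Path to a JSON configuration file, or a list with the same
#'   structure.
#' @return An object of class `dg_config`: the constructed model objects
#'   (`material`, `species`, `medium`, `settings`, `scenario`, `correction`,
#'   `options`, `C0`) plus `resolved`, the fully-defaulted configuration in
#'   file units (what [dump_config()] writes).
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) .dg_stop("config file not found: ", path)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .dg_check_keys(cfg, "top")
  mat <- cfg$material %||% list()
  sus <- cfg$suspension %||% list()
  med <- cfg$medium %||% list()
  sim <- cfg$simulation %||% list()
  dis <- cfg$dissolution %||% list()
  cor <- cfg$corrections %||% list()
  for (b in c("material", "suspension", "medium", "simulation",
              "dissolution", "corrections"))
    .dg_check_keys(get(substr(b, 1, 3)), b)

  preset <- NULL
  if (!is.null(mat$preset)) preset <- dg_preset(mat$preset)
  prow <- if (!is.null(preset)) {
    .dg_preset_table[match(tolower(mat$preset), tolower(.dg_preset_table$name)), ]
  } else NULL

  r_mat <- list(
    preset = mat$preset,
    name = .dg_get(mat, "name", if (!is.null(prow)) prow$name,
                   required = is.null(prow), where = "material"),
    density_g_cm3 = .dg_get(mat, "density_g_cm3",
                            if (!is.null(prow)) prow$rho_enm_g_cm3,
                            required = is.null(prow), where = "material"),
    ssa_m2_g = .dg_get(mat, "ssa_m2_g", if (!is.null(prow)) prow$ssa_m2_g),
    molar_mass_g_mol = .dg_get(mat, "molar_mass_g_mol",
                               if (!is.null(prow)) prow$molar_mass_g_mol))

  r_sus <- list(
    c0_mg_ml = .dg_get(sus, "c0_mg_ml", required = TRUE, where = "suspension"),
    diameter_nm = .dg_get(sus, "diameter_nm",
                          if (is.null(sus$distribution_file) && !is.null(prow))
                            prow$d_hv_nm),
    distribution_file = sus$distribution_file,
    weighting = .dg_get(sus, "weighting", "volume"),
    effective_density_g_cm3 = .dg_get(sus, "effective_density_g_cm3",
                                      if (!is.null(prow)) prow$rho_ev_g_cm3,
                                      required = is.null(prow),
                                      where = "suspension"))
  if (is.null(r_sus$diameter_nm) && is.null(r_sus$distribution_file))
    .dg_stop("'suspension' needs 'diameter_nm' or 'distribution_file'")
  if (!r_sus$weighting %in% c("volume", "number"))
    .dg_stop("'weighting' must be 'volume' or 'number'")

  r_med <- list(
    density_g_cm3 = .dg_get(med, "density_g_cm3", 1.005),
    viscosity_mpa_s = .dg_get(med, "viscosity_mpa_s", 0.955),
    temperature_c = .dg_get(med, "temperature_c", 22),
    mean_free_path_nm = .dg_get(med, "mean_free_path_nm", 0.25))
  if (r_med$viscosity_mpa_s < 0.1 || r_med$viscosity_mpa_s > 100)
    warning("viscosity ", r_med$viscosity_mpa_s,
            " mPa s is outside the plausible range for culture media",
            call. = FALSE)

  r_sim <- list(
    column_height_mm = .dg_get(sim, "column_height_mm", required = TRUE,
                               where = "simulation"),
    compartment_height_um = .dg_get(sim, "compartment_height_um", 5),
    time_step_s = .dg_get(sim, "time_step_s", 1),
    duration_h = .dg_get(sim, "duration_h", required = TRUE,
                         where = "simulation"),
    output_interval_h = .dg_get(sim, "output_interval_h",
                                min(.dg_get(sim, "duration_h", 1,
                                            required = TRUE,
                                            where = "simulation"), 1)),
    boundary = .dg_get(sim, "boundary", "reflective"),
    kd_molar = sim$kd_molar,
    bottom_slice_um = .dg_get(sim, "bottom_slice_um", 10),
    area_cm2 = sim$area_cm2)
  if (!r_sim$boundary %in% c("reflective", "langmuir"))
    .dg_stop("'boundary' must be 'reflective' or 'langmuir'")
  if (r_sim$boundary == "langmuir" && is.null(r_sim$kd_molar))
    .dg_stop("missing required key 'kd_molar' in 'simulation' block ",
             "(boundary = langmuir)")

  r_dis <- list(
    mode = .dg_get(dis, "mode", "none"),
    initial_fraction = .dg_get(dis, "initial_fraction", 0),
    rate_per_h = .dg_get(dis, "rate_per_h", 0),
    ramp_end_h = dis$ramp_end_h,
    max_fraction = dis$max_fraction)

  r_cor <- list(
    slip = .dg_get(cor, "slip", TRUE),
    shape = .dg_get(cor, "shape", "sphere"),
    aspect_ratio = cor$aspect_ratio,
    shape_factor = cor$shape_factor,
    solvation = .dg_get(cor, "solvation", 1),
    roughness = .dg_get(cor, "roughness", 1),
    k_conc = .dg_get(cor, "k_conc", 0))

  # ---- build SI model objects ----
  material <- enm_material(r_mat$name, density = r_mat$density_g_cm3 * 1e3,
                           ssa = r_mat$ssa_m2_g,
                           molar_mass = r_mat$molar_mass_g_mol)
  rho_EV <- r_sus$effective_density_g_cm3 * 1e3
  species <- if (!is.null(r_sus$distribution_file)) {
    dist <- read_size_distribution(r_sus$distribution_file, r_sus$weighting)
    species_from_distribution(dist, rho_EV)
  } else {
    list(agglomerate_species(r_sus$diameter_nm * 1e-9, rho_EV, 1))
  }
  medium_obj <- medium(density = r_med$density_g_cm3 * 1e3,
                       viscosity = r_med$viscosity_mpa_s * 1e-3,
                       temperature = r_med$temperature_c + 273.15,
                       mean_free_path = r_med$mean_free_path_nm * 1e-9)
  settings <- simulation_settings(
    height = r_sim$column_height_mm * 1e-3,
    compartment_height = r_sim$compartment_height_um * 1e-6,
    dt = r_sim$time_step_s,
    duration = r_sim$duration_h * 3600,
    output_interval = r_sim$output_interval_h * 3600,
    boundary = r_sim$boundary, K_D = r_sim$kd_molar,
    bottom_slice = r_sim$bottom_slice_um * 1e-6,
    area = if (!is.null(r_sim$area_cm2)) r_sim$area_cm2 * 1e-4)
  scenario <- dissolution_scenario(r_dis$mode,
                                   initial_fraction = r_dis$initial_fraction,
                                   rate = r_dis$rate_per_h,
                                   ramp_end = r_dis$ramp_end_h,
                                   max_fraction = r_dis$max_fraction)
  correction <- friction_correction(slip = r_cor$slip, shape = r_cor$shape,
                                    aspect_ratio = r_cor$aspect_ratio,
                                    shape_factor = r_cor$shape_factor,
                                    solvation = r_cor$solvation,
                                    roughness = r_cor$roughness)
  options <- coefficient_options(k = r_cor$k_conc)

  structure(list(material = material, species = species,
                 medium = medium_obj, settings = settings,
                 scenario = scenario, correction = correction,
                 options = options, C0 = r_sus$c0_mg_ml,
                 resolved = list(material = r_mat, suspension = r_sus,
                                 medium = r_med, simulation = r_sim,
                                 dissolution = r_dis, corrections = r_cor)),
            class = "dg_config")
}

#' Write a resolved configuration back to JSON
#'
#' Serializes the fully-defaulted configuration of a [load_config()] result;
#' loading the dumped file reproduces identical resolved settings
#' (round-trip property).
#'
#' @param config A `dg_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "dg_config"))
  out <- lapply(config$resolved, function(b) Filter(Negate(is.null), b))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' Convenience wrapper: `run_simulation()` with all pieces taken from a
#' loaded (or in-memory) configuration.
#'
#' @param config A `dg_config`, or a path passed to [load_config()].
#' @param ... Passed on to [run_simulation()] (e.g. `engine`, `quiet`).
#' @return A `dg_result`.
#' @export
run_config <- function(config, ...) {
  if (!inherits(config, "dg_config")) config <- load_config(config)
  run_simulation(config$settings, config$species, config$medium,
                 config$material, config$C0, config$scenario,
                 config$correction, config$options, ...)
}
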