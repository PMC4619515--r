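#' Read a size distribution from a two-column text file
#'
#' Accepts the common DLS export shape: two delimited columns (diameter in
#' nm, fractional or percent intensity), comma/semicolon/tab/whitespace
#' separated, with an optional header line.  Fractions are renormalized to
#' sum to 1; a renormalization away from 1 (e.g. percent input) is reported
#' with a message.
#'
#' @param path File path.
#' @param weighting Weighting of the file's fractions: `"volume"` (mass) or
#'   `"number"`.
#' @return A [size_distribution()] (diameters converted to metres).
#' @export
read_size_distribution <- function(path, weighting = c("volume", "number")) {
  weighting <- match.arg(weighting)
  if (!file.exists(path)) .dg_stop("distribution file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .dg_stop("empty distribution file: ", path)
  parse_line <- function(x) strsplit(trimws(x), "[,;\t ]+")[[1]]
  start <- 1
  first <- suppressWarnings(as.numeric(parse_line(lines[1])))
  if (anyNA(first)) start <- 2  # header line
  if (start > length(lines)) .dg_stop("no data rows in ", path)
  d <- f <- numeric(0)
  for (i in start:length(lines)) {
    v <- suppressWarnings(as.numeric(parse_line(lines[i])))
    if (length(v) < 2 || anyNA(v[1:2]))
      .dg_stop("cannot parse line ", i, " of ", path, ": '", lines[i], "'")
    if (v[1] <= 0 || v[2] < 0)
      .dg_stop("non-positive diameter or negative fraction at line ", i,
               " of ", path)
    d <- c(d, v[1]); f <- c(f, v[2])
  }
  s <- sum(f)
  if (abs(s - 1) > 1e-6)
    message(sprintf("size distribution fractions summed to %g; renormalized", s))
  size_distribution(d * 1e-9, f / s, weighting)
}

#' Write a size distribution to a two-column CSV
#'
#' Inverse of [read_size_distribution()]: `diameter_nm,fraction` with a
#' header line, full precision.
#'
#' @param dist A [size_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "dg_size_distribution"))
  lines <- c("diameter_nm,fraction",
             sprintf("%.17g,%.17g", dist$diameter * 1e9, dist$fraction))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulation outputs
#'
#' Serializes a [run_simulation()] result into an output directory:
#' \describe{
#'   \item{profile.csv}{`time_h, z_um, species_id, mass_conc_mg_ml` --
#'     per-species concentration over depth at each output time.}
#'   \item{timeseries.csv}{`time_h, bottom_conc_mg_ml, deposited_mg_cm2,
#'     fraction_deposited, number_conc_per_ml, number_per_cm2,
#'     surface_cm2_per_ml, surface_cm2_per_cm2, bound_mg_cm2,
#'     dissolved_mg_ml` -- bottom-slice dose metrics over time.  The
#'     deposited fraction is relative to the current suspended + bound
#'     mass (dissolved material excluded from the denominator).}
#'   \item{manifest.json}{resolved configuration (when the result came from
#'     one), software version, effective time step and mass-balance
#'     figures.}
#' }
#'
#' @param result A `dg_result`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional `dg_config` to embed in the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, out_dir, config = NULL) {
  stopifnot(inherits(result, "dg_result"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .dg_stop("cannot create output directory: ", out_dir)

  pr <- result$profiles
  profile <- data.frame(time_h = pr$time_s / 3600,
                        z_um = pr$z_m * 1e6,
                        species_id = pr$species,
                        mass_conc_mg_ml = pr$conc)   # kg m^-3 == mg ml^-1
  ts <- result$timeseries
  timeseries <- data.frame(
    time_h = ts$time_s / 3600,
    bottom_conc_mg_ml = ts$bottom_conc,
    deposited_mg_cm2 = ts$deposited_per_area * 100,   # kg m^-2 -> mg cm^-2
    fraction_deposited = ts$fraction_deposited,
    number_conc_per_ml = ts$number_conc * 1e-6,
    number_per_cm2 = ts$number_per_area * 1e-4,
    surface_cm2_per_ml = ts$surface_conc * 1e-2,      # m^2 m^-3 -> cm^2 ml^-1
    surface_cm2_per_cm2 = ts$surface_per_area,        # m^2 m^-2 == cm^2 cm^-2
    bound_mg_cm2 = ts$bound_per_area * 100,
    dissolved_mg_ml = ts$dissolved_conc)

  p_profile <- file.path(out_dir, "profile.csv")
  p_ts <- file.path(out_dir, "timeseries.csv")
  p_manifest <- file.path(out_dir, "manifest.json")
  write.csv(profile, p_profile, row.names = FALSE)
  write.csv(timeseries, p_ts, row.names = FALSE)

  manifest <- list(
    package = "dgdose",
    version = as.character(packageVersion("dgdose")),
    dt_effective_s = result$dt_effective,
    n_compartments = result$settings$n,
    compartment_height_m = result$settings$h,
    boundary = result$settings$boundary,
    c0_mg_ml = result$C0,
    initial_total_mass_per_area_kg_m2 = result$C0 * result$settings$height,
    final_total_mass_per_area_kg_m2 =
      ts$total_mass_per_area[nrow(ts)],
    config = if (!is.null(config)) {
      lapply(config$resolved, function(b) Filter(Negate(is.null), b))
    })
  manifest <- Filter(Negate(is.null), manifest)
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p_profile, p_ts, p_manifest))
}
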