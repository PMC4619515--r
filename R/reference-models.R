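#' Closed-form sedimentation-diffusion equilibrium profile
#'
#' Steady-state balance of gravitational settling and Brownian diffusion in
#' a closed column: an exponential (barometric) concentration profile with
#' scale height z0 = D / v_s measured up from the bottom,
#' C(z) = C0 H exp(-z/z0) / (z0 (1 - exp(-H/z0))), normalized so the
#' integral over the column equals the initial mass C0 H.  The friction
#' ratio cancels in z0, so corrections do not change the equilibrium.  Used
#' as an independent oracle for the long-time behaviour of the grid solver.
#'
#' @param species An [agglomerate_species()].
#' @param medium A [medium()].
#' @param H Column height (m).
#' @param C0 Initial mass concentration (kg m^-3).
#' @return Object of class `dg_equilibrium`: `z0` (m, `Inf` for non-settling
#'   species), `conc(z)` (concentration at height z above the bottom) and
#'   `mass_fraction_below(z)`.
#' @export
equilibrium_profile <- function(species, medium, H, C0 = 1) {
  .dg_check_num(H, "H", len = 1)
  .dg_check_num(C0, "C0", len = 1)
  v <- sedimentation_velocity(species, medium)
  D <- diffusion_coefficient(species, medium)
  if (v <= 0) {
    # pure diffusion (or buoyant) limit: uniform profile
    obj <- list(z0 = Inf, H = H, C0 = C0,
                conc = function(z) rep(C0, length(z)),
                mass_fraction_below = function(z) pmin(pmax(z / H, 0), 1))
    return(structure(obj, class = "dg_equilibrium"))
  }
  z0 <- D / v
  norm <- z0 * (1 - exp(-H / z0))
  obj <- list(
    z0 = z0, H = H, C0 = C0,
    conc = function(z) C0 * H * exp(-z / z0) / norm,
    mass_fraction_below = function(z)
      (1 - exp(-pmin(pmax(z, 0), H) / z0)) / (1 - exp(-H / z0)))
  structure(obj, class = "dg_equilibrium")
}

#' Settings for the Brownian-dynamics particle tracker
#'
#' @param n_particles Number of tracked particles (>= 1000 recommended for
#'   histogram comparisons).
#' @param dt Time step (s); choose it so the drift per step is well below
#'   one histogram bin.
#' @param duration Total tracked time (s).
#' @param height Column height (m).
#' @param seed RNG seed; the tracker is deterministic given the seed.
#' @return An object of class `dg_tracker_settings`.
#' @export
tracker_settings <- function(n_particles = 20000, dt = 30, duration,
                             height, seed = 42L) {
  n_particles <- as.integer(n_particles)
  if (is.na(n_particles) || n_particles < 1) .dg_stop("'n_particles' must be >= 1")
  .dg_check_num(dt, "dt", len = 1)
  .dg_check_num(duration, "duration", len = 1)
  .dg_check_num(height, "height", len = 1)
  structure(list(n_particles = n_particles, dt = dt, duration = duration,
                 height = height, seed = as.integer(seed)),
            class = "dg_tracker_settings")
}

#' Brownian-dynamics random-walk tracker
#'
#' Independent stochastic oracle for the grid solver: particles evolve by
#' the Euler-Maruyama step z <- z - v_s dt + sqrt(2 D dt) xi (z measured up
#' from the bottom, xi standard normal), with reflection at both walls.
#' Uses exactly the same (friction-corrected) v_s and D as the grid solver
#' so that discrepancies isolate the grid scheme.  The global RNG state is
#' saved and restored.
#'
#' @param species An [agglomerate_species()].
#' @param medium A [medium()].
#' @param settings A [tracker_settings()].
#' @param bin_width Histogram bin width (m); defaults to height / 50.  Use
#'   the grid solver's compartment height for direct comparison.
#' @param correction A [friction_correction()].
#' @return List with `breaks` (bin edges, m above bottom), `fraction`
#'   (number fraction per bin, bottom bin first), `counts`, and the `v`/`D`
#'   used.
#' @export
random_walk_tracker <- function(species, medium, settings,
                                bin_width = NULL,
                                correction = friction_correction()) {
  stopifnot(inherits(settings, "dg_tracker_settings"))
  H <- settings$height
  if (is.null(bin_width)) bin_width <- H / 50
  nbin <- round(H / bin_width)
  if (abs(nbin - H / bin_width) > 1e-8 || nbin < 1)
    .dg_stop("'bin_width' must divide the column height")

  tr <- .dg_transport(species, medium, correction)
  v <- tr$S * .dg_g
  D <- tr$D

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(settings$seed)

  # deterministic uniform start mirrors the solver's homogeneous initial state
  z <- H * (seq_len(settings$n_particles) - 0.5) / settings$n_particles
  nstep <- ceiling(settings$duration / settings$dt)
  dt <- settings$duration / nstep
  sig <- sqrt(2 * D * dt)
  for (s in seq_len(nstep)) {
    z <- z - v * dt + sig * rnorm(length(z))
    # reflect at both walls (repeat to catch rare double crossings)
    for (r in 1:2) {
      z <- ifelse(z < 0, -z, z)
      z <- ifelse(z > H, 2 * H - z, z)
    }
    z <- pmin(pmax(z, 0), H)
  }
  counts <- tabulate(pmin(floor(z / bin_width) + 1, nbin), nbins = nbin)
  list(breaks = seq(0, H, by = bin_width),
       fraction = counts / sum(counts),
       counts = counts, v = v, D = D)
}
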