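#' Simulation settings for the column solver
#'
#' Geometry, time stepping and boundary condition of the one-dimensional
#' suspension column.  Compartments are indexed top (1) to bottom (n); the
#' top and bottom of the well are the impermeable boundaries 1 and n + 1.
#'
#' @param height Column height H (m).
#' @param n_compartments Number of compartments, or `NULL` to derive it from
#'   `compartment_height`.
#' @param compartment_height Target compartment height h (m, default 5e-6);
#'   the actual height is H / n after rounding n to an integer.  Results are
#'   grid-independent for h below about 5 um.
#' @param dt Time step (s, default 1; the solver further caps it so the
#'   fastest-settling species moves at most h/2 per step and the explicit
#'   diffusion scheme stays stable).
#' @param duration Total simulated time (s).
#' @param output_interval Cadence of recorded profiles/metrics (s); defaults
#'   to `duration` (initial and final state only) or 1 h for long runs.
#' @param boundary `"reflective"` (particles at the bottom stay suspended)
#'   or `"langmuir"` (partial adsorption governed by `K_D`).
#' @param K_D Langmuir equilibrium dissociation constant (mol L^-1);
#'   required when `boundary = "langmuir"`.  Small values (~nM) mean sticky,
#'   large values recover the reflective limit.
#' @param bottom_slice Thickness of the exposure-reporting slice at the well
#'   bottom (m, default 10e-6); must be an integer multiple of h and at
#'   least one compartment.
#' @param area Well cross-sectional area (m^2), optional; transport is
#'   area-independent, this only enables absolute-mass reporting.
#' @return An object of class `dg_settings`.
#' @export
simulation_settings <- function(height, n_compartments = NULL,
                                compartment_height = 5e-6, dt = 1,
                                duration, output_interval = NULL,
                                boundary = c("reflective", "langmuir"),
                                K_D = NULL, bottom_slice = 10e-6,
                                area = NULL) {
  boundary <- match.arg(boundary)
  .dg_check_num(height, "height", len = 1)
  .dg_check_num(dt, "dt", len = 1)
  .dg_check_num(duration, "duration", positive = FALSE, len = 1)
  if (duration < 0) .dg_stop("'duration' must be >= 0")
  if (is.null(n_compartments)) {
    .dg_check_num(compartment_height, "compartment_height", len = 1)
    n_compartments <- max(2L, as.integer(round(height / compartment_height)))
  }
  n_compartments <- as.integer(n_compartments)
  if (is.na(n_compartments) || n_compartments < 2)
    .dg_stop("'n_compartments' must be >= 2")
  h <- height / n_compartments
  .dg_check_num(bottom_slice, "bottom_slice", len = 1)
  if (bottom_slice > height) .dg_stop("'bottom_slice' must be <= column height")
  m <- bottom_slice / h
  if (abs(m - round(m)) > 1e-8 || round(m) < 1)
    .dg_stop("bottom slice (", format(bottom_slice), " m) must span an integer ",
             "number >= 1 of compartments (h = ", format(h), " m)")
  if (boundary == "langmuir") {
    if (is.null(K_D)) .dg_stop("'K_D' is required for the langmuir boundary")
    .dg_check_num(K_D, "K_D", len = 1)
  }
  if (!is.null(area)) .dg_check_num(area, "area", len = 1)
  if (is.null(output_interval))
    output_interval <- if (duration > 0) min(duration, 3600) else 3600
  .dg_check_num(output_interval, "output_interval", len = 1)
  structure(list(height = height, n = n_compartments, h = h, dt = dt,
                 duration = duration, output_interval = output_interval,
                 boundary = boundary, K_D = K_D,
                 bottom_slice = bottom_slice, area = area),
            class = "dg_settings")
}

#' Langmuir adsorption parameters
#'
#' @param K_D Equilibrium dissociation constant (mol L^-1, > 0).
#' @return An object of class `dg_langmuir`.
#' @export
langmuir_params <- function(K_D) {
  .dg_check_num(K_D, "K_D", len = 1)
  structure(list(K_D = K_D), class = "dg_langmuir")
}

#' Dissolution scenario
#'
#' Time course of the dissolved fraction f_d(t) of the total initial
#' nanomaterial mass:
#' \describe{
#'   \item{none}{f_d = 0 throughout.}
#'   \item{initial_only}{f_d = f0 at t = 0 (dissolution completed before the
#'     suspension was characterized), no further dissolution.}
#'   \item{constant_rate}{f_d = f0 + r t, r in fraction per hour.}
#'   \item{linear_ramp}{f_d rises linearly from f0 to `max_fraction` at
#'     `ramp_end` hours and is constant afterwards.}
#' }
#' The cumulative fraction is clamped at 1.  Agglomerate diameters shrink so
#' that agglomerate volume tracks the remaining solid fraction:
#' d(t) = d0 ((1 - f_d(t)) / (1 - f0))^(1/3); the nominal (measured)
#' diameter corresponds to the state after any initial dissolution.
#'
#' @param mode One of `"none"`, `"initial_only"`, `"constant_rate"`,
#'   `"linear_ramp"`.
#' @param initial_fraction Initial dissolved fraction f0 of total mass.
#' @param rate Constant dissolution rate (fraction of initial mass per
#'   hour), for `"constant_rate"`.
#' @param ramp_end End of the linear ramp (hours), for `"linear_ramp"`.
#' @param max_fraction Total dissolved fraction reached at `ramp_end`.
#' @return An object of class `dg_dissolution`.
#' @export
dissolution_scenario <- function(mode = c("none", "initial_only",
                                          "constant_rate", "linear_ramp"),
                                 initial_fraction = 0, rate = 0,
                                 ramp_end = NULL, max_fraction = NULL) {
  mode <- match.arg(mode)
  .dg_check_num(initial_fraction, "initial_fraction", positive = FALSE, len = 1)
  if (initial_fraction < 0 || initial_fraction > 1)
    .dg_stop("'initial_fraction' must be in [0, 1]")
  .dg_check_num(rate, "rate", positive = FALSE, len = 1)
  if (rate < 0) .dg_stop("'rate' must be >= 0")
  if (mode == "linear_ramp") {
    if (is.null(ramp_end) || is.null(max_fraction))
      .dg_stop("'ramp_end' and 'max_fraction' are required for linear_ramp")
    .dg_check_num(ramp_end, "ramp_end", len = 1)
    .dg_check_num(max_fraction, "max_fraction", positive = FALSE, len = 1)
    if (max_fraction < initial_fraction || max_fraction > 1)
      .dg_stop("'max_fraction' must be in [initial_fraction, 1]")
  }
  structure(list(mode = mode, initial_fraction = initial_fraction,
                 rate = rate, ramp_end = ramp_end,
                 max_fraction = max_fraction),
            class = "dg_dissolution")
}

#' Dissolved mass fraction from a molar concentration
#'
#' Converts dissolved-phase measurements in molar units (e.g. ICP-MS data in
#' uM) into the fractions of total nanomaterial mass used by
#' [dissolution_scenario()]: fraction = conc_molar x molar mass / C0.
#'
#' @param conc_molar Dissolved concentration (mol L^-1); a rate in
#'   mol L^-1 h^-1 yields a fractional rate in h^-1.
#' @param molar_mass Molar mass of the material (g mol^-1).
#' @param C0 Total initial mass concentration (kg m^-3, = mg ml^-1).
#' @return Dimensionless mass fraction (or fractional rate).
#' @export
dissolved_fraction_from_molar <- function(conc_molar, molar_mass, C0) {
  .dg_check_num(molar_mass, "molar_mass", len = 1)
  .dg_check_num(C0, "C0", len = 1)
  # mol L^-1 * g mol^-1 = g L^-1 = kg m^-3
  conc_molar * molar_mass / C0
}

# cumulative dissolved fraction at time t (seconds), clamped to [f0, 1]
.dg_dissolved_fraction <- function(scenario, t) {
  f0 <- scenario$initial_fraction
  f <- switch(scenario$mode,
    none = 0,
    initial_only = f0,
    constant_rate = f0 + scenario$rate * t / 3600,
    linear_ramp = f0 + (scenario$max_fraction - f0) *
      pmin(t / (scenario$ramp_end * 3600), 1))
  pmin(f, 1)
}

#' Initialize the column grid
#'
#' Assigns the homogeneous initial state: every compartment holds
#' C0 f_j of species j.  Under a dissolution scenario with a non-zero
#' initial fraction f0, the solid concentrations are reduced to
#' (1 - f0) C0 f_j and the dissolved pool primed with f0 C0; nominal
#' diameters already describe the post-initial-dissolution agglomerates, so
#' they are unchanged at t = 0.
#'
#' @param settings A [simulation_settings()].
#' @param species A [agglomerate_species()] or list of them (fractions
#'   summing to 1).
#' @param C0 Total initial mass concentration (kg m^-3).
#' @param scenario A [dissolution_scenario()].
#' @return An object of class `dg_state`: fields `t`, `h`, `H`, `C`
#'   (n x J matrix, kg m^-3), `bound` (J, kg m^-2), `dissolved_areal`
#'   (kg m^-2), `d0` and `d_current` (m), `f0`.
#' @export
initialize_grid <- function(settings, species, C0,
                            scenario = dissolution_scenario("none")) {
  stopifnot(inherits(settings, "dg_settings"),
            inherits(scenario, "dg_dissolution"))
  species <- .dg_species_list(species)
  .dg_check_num(C0, "C0", positive = FALSE, len = 1)
  if (C0 < 0) .dg_stop("'C0' must be >= 0")
  n <- settings$n; J <- length(species)
  f <- vapply(species, `[[`, 0, "fraction")
  f0 <- .dg_dissolved_fraction(scenario, 0)
  C <- matrix(rep((1 - f0) * C0 * f, each = n), n, J)
  d0 <- vapply(species, `[[`, 0, "d_H")
  structure(list(t = 0, h = settings$h, H = settings$height, C = C,
                 bound = numeric(J), dissolved_areal = f0 * C0 * settings$height,
                 d0 = d0, d_current = d0, f0 = f0, C0 = C0,
                 rho_EV = vapply(species, `[[`, 0, "rho_EV"),
                 clamped = FALSE),
            class = "dg_state")
}

# total mass per unit well-bottom area (kg m^-2): suspended + bound + dissolved
.dg_total_mass_area <- function(state) {
  sum(colSums(state$C)) * state$h + sum(state$bound) + state$dissolved_areal
}

#' Explicit diffusion step
#'
#' Forward-Euler update of Fick diffusion on the compartment grid:
#' dC_i = (dt/h^2) (D_i (C_{i-1} - C_i) + D_{i+1} (C_{i+1} - C_i)), with the
#' flux terms across the impermeable walls (boundaries 1 and n + 1) absent.
#' Mass is conserved exactly up to floating point.  The caller is
#' responsible for the stability constraint D dt / h^2 <= 1/2 (enforced by
#' [cap_time_step()] inside [run_simulation()]).
#'
#' @param state A `dg_state`.
#' @param D Diffusion coefficients: length-J vector (one per species) or an
#'   (n + 1) x J matrix of per-boundary values (rows 1 and n + 1 unused).
#' @param dt Time step (s).
#' @param k Concentration-dependence factor; when > 0 the boundary-i
#'   coefficient is divided by (1 + k C_i).
#' @return Updated `dg_state` (time not advanced).
#' @export
diffusion_step <- function(state, D, dt, k = 0) {
  stopifnot(inherits(state, "dg_state"))
  C <- state$C
  n <- nrow(C); J <- ncol(C)
  if (is.matrix(D)) {
    if (!all(dim(D) == c(n + 1, J)))
      .dg_stop("per-boundary 'D' must be (n+1) x J")
    Db <- D[2:n, , drop = FALSE]              # interior boundaries 2..n
  } else {
    if (length(D) != J) .dg_stop("'D' must have length J or be (n+1) x J")
    Db <- matrix(rep(D, each = n - 1), n - 1, J)
  }
  if (k > 0)  # Eq.-style local damping, using the compartment sharing the boundary index
    Db <- Db / (1 + k * C[2:n, , drop = FALSE])
  # G[b-1, j]: downward transfer across interior boundary b = 2..n,
  # (C_{b-1} - C_b) D_b dt / h^2.  Compartment i gains G[i-1] from above and
  # loses G[i] to below; edge terms are absent (impermeable walls).
  G <- (C[1:(n - 1), , drop = FALSE] - C[2:n, , drop = FALSE]) * Db * (dt / state$h^2)
  state$C <- C + rbind(0, G) - rbind(G, 0)
  state
}

#' Explicit sedimentation step
#'
#' Inter-compartment mass transfer by settling: each compartment passes the
#' fraction dz/h = S g dt / h of its concentration to the compartment below
#' (Eq.-style upwind transfer).  The top compartment receives no inflow and
#' the bottom compartment has no outflow, so material accumulates at the
#' bottom without leaving the column; adsorption is handled separately by
#' [langmuir_partition()].  Buoyant species (S < 0) rise symmetrically.
#' Requires |S| g dt <= h (guaranteed with margin by [cap_time_step()]).
#'
#' @param state A `dg_state`.
#' @param S Sedimentation coefficients (s): length-J vector or n x J matrix
#'   of per-compartment-center values.
#' @param dt Time step (s).
#' @param k Concentration-dependence factor applied as S / (1 + k C).
#' @return Updated `dg_state` (time not advanced).
#' @export
sedimentation_step <- function(state, S, dt, k = 0) {
  stopifnot(inherits(state, "dg_state"))
  C <- state$C
  n <- nrow(C); J <- ncol(C)
  if (is.matrix(S)) {
    if (!all(dim(S) == c(n, J))) .dg_stop("per-compartment 'S' must be n x J")
    Sm <- S
  } else {
    if (length(S) != J) .dg_stop("'S' must have length J or be n x J")
    Sm <- matrix(rep(S, each = n), n, J)
  }
  if (k > 0) Sm <- Sm / (1 + k * C)
  frac <- Sm * (.dg_g * dt / state$h)
  if (any(abs(frac) > 1))
    .dg_stop("per-step displacement exceeds h; time-step cap logic failed")
  out <- C * abs(frac)
  newC <- C
  for (j in seq_len(J)) {
    if (all(frac[, j] >= 0)) {           # settling: bottom row keeps its mass
      newC[, j] <- C[, j] - c(out[-n, j], 0) + c(0, out[-n, j])
    } else if (all(frac[, j] <= 0)) {    # buoyant: mirrored, top row accumulates
      newC[, j] <- C[, j] - c(0, out[-1, j]) + c(out[-1, j], 0)
    } else {
      .dg_stop("mixed-sign sedimentation within one species is not supported")
    }
  }
  state$C <- newC
  state
}

#' Effective time step
#'
#' The solver time step is the user step reduced so that (a) the
#' fastest-settling species is displaced at most h/2 per step and (b) the
#' explicit diffusion scheme is stable (D dt / h^2 <= 1/2) for every
#' species.  Any reduction is reported with a message.
#'
#' @param settings A [simulation_settings()].
#' @param species Species list.
#' @param medium A [medium()].
#' @param correction A [friction_correction()].
#' @param quiet Suppress the reduction message.
#' @return Effective time step (s).
#' @export
cap_time_step <- function(settings, species, medium,
                          correction = friction_correction(), quiet = FALSE) {
  species <- .dg_species_list(species)
  tr <- lapply(species, .dg_transport, medium = medium, correction = correction)
  vmax <- max(abs(vapply(tr, `[[`, 0, "S"))) * .dg_g
  Dmax <- max(vapply(tr, `[[`, 0, "D"))
  h <- settings$h
  dt <- settings$dt
  dt_sed <- if (vmax > 0) h / (2 * vmax) else Inf
  dt_dif <- 0.5 * h^2 / Dmax
  dt_eff <- min(dt, dt_sed, dt_dif)
  if (!quiet && dt_eff < dt) {
    why <- if (dt_sed <= dt_dif) "h/2 settling displacement rule"
           else "explicit diffusion stability"
    message(sprintf("time step reduced from %g s to %g s (%s)", dt, dt_eff, why))
  }
  dt_eff
}

#' Langmuir adsorption partition at the bottom boundary
#'
#' Implements particle-cell binding as a Langmuir isotherm applied to the
#' bottom compartment at the end of each iteration.  Per species: the
#' agglomerate molar concentration is
#' `[P] = 1e-3 C_p / (N_A rho_EV (4/3) pi r^3)` (mol L^-1), the occupied
#' surface fraction theta = `[P]` / (K_D + `[P]`), the coverable fraction
#' theta_avail = h C_p A_m with A_m = 3 / (4 r rho_EV), and the bound
#' fraction F_b = min(theta / theta_avail, 1).
#'
#' The partition is an *equilibrium* split of the entire bottom-compartment
#' content (previously bound mass plus free suspension): each iteration the
#' bound areal mass is set to F_b C_p h and the free remainder
#' (1 - F_b) C_p stays in suspension, so the bound pool tracks the isotherm
#' as the local concentration evolves.  Bound mass is excluded from the
#' diffusion gradient (only the free concentration lives on the grid) and
#' from sedimentation.  In the sticky limit (K_D -> 0, F_b = 1) the bottom
#' compartment is fully sequestered each step and the boundary becomes
#' absorbing; for K_D far above the particle molar concentration F_b -> 0
#' and the reflective trajectory is recovered.
#'
#' @param state A `dg_state`.
#' @param params A [langmuir_params()] (or bare K_D value).
#' @return Updated `dg_state`.
#' @export
langmuir_partition <- function(state, params) {
  stopifnot(inherits(state, "dg_state"))
  if (!inherits(params, "dg_langmuir")) params <- langmuir_params(params)
  K_D <- params$K_D
  n <- nrow(state$C)
  for (j in seq_len(ncol(state$C))) {
    Cp <- state$C[n, j] + state$bound[j] / state$h   # total bottom content
    if (Cp <= 0) next
    r <- state$d_current[j] / 2
    rho <- state$rho_EV[j]
    P <- 1e-3 * Cp / (.dg_NA * rho * (4 / 3) * pi * r^3)
    theta <- P / (K_D + P)
    A_m <- 3 / (4 * r * rho)
    theta_avail <- state$h * Cp * A_m
    F_b <- min(theta / theta_avail, 1)
    state$bound[j] <- F_b * Cp * state$h
    state$C[n, j] <- (1 - F_b) * Cp
  }
  state
}

#' Apply a dissolution increment
#'
#' Advances the dissolution scenario from the state's current time over
#' `dt`: the newly dissolved mass is moved from the (well-mixed, spatially
#' uniform in proportion) solid phase into the single dissolved pool, and
#' agglomerate diameters shrink with the cube root of the remaining solid
#' fraction.  If the requested dissolved fraction exceeds the solid mass
#' still in suspension the removal is clamped (all solid gone) with a
#' warning.  Bound (cell-adsorbed) mass is not subject to dissolution.
#'
#' @param state A `dg_state`.
#' @param scenario A [dissolution_scenario()].
#' @param dt Time increment (s) over which to apply dissolution.
#' @return Updated `dg_state` (time not advanced).
#' @export
apply_dissolution <- function(state, scenario, dt) {
  stopifnot(inherits(state, "dg_state"), inherits(scenario, "dg_dissolution"))
  if (scenario$mode %in% c("none", "initial_only")) return(state)
  f_old <- .dg_dissolved_fraction(scenario, state$t)
  f_new <- .dg_dissolved_fraction(scenario, state$t + dt)
  dM <- (f_new - f_old) * state$C0 * state$H    # kg m^-2 to dissolve
  if (dM <= 0) return(state)
  total <- sum(colSums(state$C)) * state$h
  if (dM >= total) {
    if (!state$clamped)
      warning("dissolution exhausted the suspended solid phase; clamped",
              call. = FALSE)
    state$clamped <- TRUE
    dM <- total
    state$C[] <- 0
  } else {
    state$C <- state$C * (1 - dM / total)
  }
  state$dissolved_areal <- state$dissolved_areal + dM
  f_cum <- state$dissolved_areal / (state$C0 * state$H)
  state$d_current <- state$d0 * ((1 - f_cum) / (1 - state$f0))^(1 / 3)
  state
}
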