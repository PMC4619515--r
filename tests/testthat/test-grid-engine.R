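# Column solver: initialization, elementary steps (hand-computed cases),
# conservation, time-step capping, Langmuir partition, dissolution, and the
# full driver (superposition, determinism, engine equivalence).

toy_settings <- function(n = 3, H = n, dt = 1, duration = 0,
                         bottom = H / n, ...) {
  simulation_settings(height = H, n_compartments = n, dt = dt,
                      duration = duration, bottom_slice = bottom, ...)
}

toy_state <- function(C, H = nrow(as.matrix(C)), rho_EV = 1500, d = 2e-7) {
  C <- as.matrix(C)
  sets <- toy_settings(n = nrow(C), H = H)
  fr <- rep(1 / ncol(C), ncol(C))
  sp <- lapply(seq_len(ncol(C)), function(j)
    agglomerate_species(d, rho_EV, fr[j]))
  st <- initialize_grid(sets, sp, 1)
  st$C <- C
  st
}

test_that("grid initialization is homogeneous and partitions by fraction", {
  s <- simulation_settings(height = 3e-3, compartment_height = 5e-6,
                           duration = 0)
  expect_equal(s$n, 600)
  p <- agglomerate_species(1.499e-7, 1564)
  st <- initialize_grid(s, p, 0.1)
  expect_true(all(st$C == 0.1))
  expect_equal(dim(st$C), c(600L, 1L))
  sp2 <- list(agglomerate_species(1e-7, 1500, 0.25),
              agglomerate_species(2e-7, 1500, 0.75))
  st2 <- initialize_grid(s, sp2, 0.1)
  expect_equal(st2$C[, 1], rep(0.025, 600))
  expect_equal(st2$C[, 2], rep(0.075, 600))
  # bottom slice thinner than one compartment is a configuration error
  expect_error(simulation_settings(height = 3e-3, compartment_height = 2e-5,
                                   duration = 0, bottom_slice = 1e-5),
               "integer")
})

test_that("diffusion step: hand case, zero gradient, conservation", {
  st <- toy_state(c(1, 0, 0))
  out <- diffusion_step(st, D = 0.1, dt = 1)
  expect_equal(as.vector(out$C), c(0.9, 0.1, 0))
  # uniform concentration is stationary
  stu <- toy_state(c(0.4, 0.4, 0.4))
  expect_equal(diffusion_step(stu, 0.2, 1)$C, stu$C)
  # conservation for random states and per-boundary coefficient arrays
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    st <- toy_state(matrix(runif(2 * n), n, 2))
    Db <- matrix(runif(2 * (n + 1), 0, 0.2), n + 1, 2)
    out <- diffusion_step(st, Db, dt = 0.5)
    expect_equal(colSums(out$C), colSums(st$C), tolerance = 1e-14)
    expect_true(all(out$C >= -1e-15))
  }
  # scalar D equals a constant per-boundary array
  st <- toy_state(c(0.9, 0.1, 0.5))
  expect_equal(diffusion_step(st, 0.15, 1)$C,
               diffusion_step(st, matrix(0.15, 4, 1), 1)$C)
})

test_that("sedimentation step: hand case, mirror symmetry, conservation", {
  st <- toy_state(c(1, 1, 1))
  S <- 0.2 / 9.80665           # S g dt / h = 0.2
  out <- sedimentation_step(st, S, dt = 1)
  expect_equal(as.vector(out$C), c(0.8, 1.0, 1.2))
  expect_equal(sum(out$C), 3)
  # S = 0 leaves the state unchanged
  expect_equal(sedimentation_step(st, 0, 1)$C, st$C)
  # buoyant species mirrors the settling result top-to-bottom
  C0 <- c(0.9, 0.4, 0.7, 0.2)
  down <- sedimentation_step(toy_state(C0), S, 1)
  up <- sedimentation_step(toy_state(rev(C0)), -S, 1)
  expect_equal(as.vector(up$C), rev(as.vector(down$C)))
  # conservation under per-compartment arrays
  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    st <- toy_state(matrix(runif(n), n, 1))
    Sm <- matrix(runif(n, 0, 0.4 / 9.80665), n, 1)
    out <- sedimentation_step(st, Sm, 1)
    expect_equal(sum(out$C), sum(st$C), tolerance = 1e-14)
  }
  # displacement beyond h is an internal error
  expect_error(sedimentation_step(st, 1.5 / 9.80665, 1), "cap")
})

test_that("time-step cap: h/2 rule, stability rule, pass-through", {
  med <- medium()
  # large fast-settling species: settling displacement dominates
  big <- agglomerate_species(1e-5, 2000)
  s <- simulation_settings(height = 3e-3, compartment_height = 5e-6,
                           duration = 0)
  v <- sedimentation_velocity(big, med) /
    friction_ratio(friction_correction(), 1e-5)
  dt_half <- s$h / (2 * v)
  s1 <- simulation_settings(height = 3e-3, compartment_height = 5e-6,
                            dt = 2 * dt_half, duration = 0)
  expect_message(dt_eff <- cap_time_step(s1, big, med), "reduced")
  expect_equal(dt_eff, dt_half, tolerance = 1e-12)
  expect_equal(dt_eff, s1$dt / 2, tolerance = 1e-12)
  # slow species: user step passes through untouched
  slow <- agglomerate_species(1.5e-7, 1564)
  expect_equal(cap_time_step(s, slow, med, quiet = TRUE), s$dt)
  # the faster-settling species controls the cap
  both <- list(agglomerate_species(1e-5, 2000, 0.5),
               agglomerate_species(1e-7, 1500, 0.5))
  expect_equal(cap_time_step(s1, both, med, quiet = TRUE), dt_half,
               tolerance = 1e-12)
  # tiny species: diffusion stability controls
  tiny <- agglomerate_species(2e-9, 1200)
  Dc <- diffusion_coefficient(tiny, med) /
    friction_ratio(friction_correction(), 2e-9)
  expect_equal(cap_time_step(s, tiny, med, quiet = TRUE),
               min(s$dt, 0.5 * s$h^2 / Dc), tolerance = 1e-12)
})

test_that("Langmuir partition follows the isotherm", {
  d <- 2e-7; rho <- 1500; h <- 5e-6
  m_agg <- rho * (4 / 3) * pi * (d / 2)^3          # kg per agglomerate
  A_m <- 3 / (4 * (d / 2) * rho)
  expect_equal(3 / (4 * 1e-7 * 1500), 5000)        # worked A_m example
  sets <- simulation_settings(height = 3 * h, n_compartments = 3,
                              duration = 0, bottom_slice = h,
                              boundary = "langmuir", K_D = 1e-9)
  sp <- agglomerate_species(d, rho)
  st <- initialize_grid(sets, sp, 0.1)
  # choose Cp so that [P] = K_D, hence theta = 1/2
  K_D <- 1e-9
  Cp <- K_D * 6.02214076e23 * m_agg / 1e-3
  st$C[3, 1] <- Cp
  out <- langmuir_partition(st, langmuir_params(K_D))
  F_b <- min(0.5 / (h * Cp * A_m), 1)
  expect_equal(out$bound[1], F_b * Cp * h, tolerance = 1e-12)
  expect_equal(out$C[3, 1], (1 - F_b) * Cp, tolerance = 1e-12)
  # partition conserves bottom-compartment mass
  expect_equal(out$C[3, 1] * h + out$bound[1], Cp * h, tolerance = 1e-12)
  # weak-binding (uncapped) branch, full formula chain as oracle
  K_D2 <- 1e-6; Cp2 <- 0.5
  st$C[3, 1] <- Cp2; st$bound[1] <- 0
  out2 <- langmuir_partition(st, langmuir_params(K_D2))
  P2 <- 1e-3 * Cp2 / (6.02214076e23 * m_agg)
  F_b2 <- (P2 / (K_D2 + P2)) / (h * Cp2 * A_m)
  expect_lt(F_b2, 1)
  expect_equal(out2$bound[1], F_b2 * Cp2 * h, tolerance = 1e-12)
  expect_equal(out2$C[3, 1], (1 - F_b2) * Cp2, tolerance = 1e-12)
  # empty bottom compartment is a no-op
  st0 <- initialize_grid(sets, sp, 0)
  expect_equal(langmuir_partition(st0, 1e-9)$bound, 0)
  expect_error(langmuir_params(-1), "K_D")
})

test_that("huge K_D reproduces the reflective trajectory", {
  p <- dg_preset("SiO2")
  base <- simulation_settings(height = 5e-4, compartment_height = 1e-5,
                              duration = 2 * 3600, output_interval = 3600,
                              bottom_slice = 2e-5)
  lang <- simulation_settings(height = 5e-4, compartment_height = 1e-5,
                              duration = 2 * 3600, output_interval = 3600,
                              bottom_slice = 2e-5, boundary = "langmuir",
                              K_D = 1e3)
  r_ref <- run_simulation(base, p$species, medium(), p$material, 0.1,
                          quiet = TRUE)
  r_lng <- run_simulation(lang, p$species, medium(), p$material, 0.1,
                          quiet = TRUE)
  expect_lt(max(abs(r_lng$state$C - r_ref$state$C)) / 0.1, 1e-6)
  expect_lt(r_lng$state$bound[1] / (0.1 * 5e-4), 1e-6)
})

test_that("dissolution scenarios move mass between pools consistently", {
  p <- dg_preset("ZnO")
  # worked conversions: 20 uM initial and 2 uM/h for C0 = 0.01 mg/ml ZnO
  expect_equal(round(dissolved_fraction_from_molar(20e-6, 81.38, 0.01), 3),
               0.163)
  expect_equal(round(dissolved_fraction_from_molar(2e-6, 81.38, 0.01), 3),
               0.016)
  sets <- toy_settings(n = 4, H = 4)
  sp <- agglomerate_species(3.07e-7, 1650)
  # mode none: nothing happens
  st <- initialize_grid(sets, sp, 0.01, dissolution_scenario("none"))
  expect_identical(apply_dissolution(st, dissolution_scenario("none"), 60)$C,
                   st$C)
  expect_equal(st$dissolved_areal, 0)
  # initial_only: pools primed at t = 0, diameters nominal
  sc0 <- dissolution_scenario("initial_only", initial_fraction = 0.163)
  st0 <- initialize_grid(sets, sp, 0.01, sc0)
  expect_equal(st0$dissolved_areal / (0.01 * 4), 0.163)
  expect_true(all(st0$C == 0.01 * (1 - 0.163)))
  expect_equal(st0$d_current, st0$d0)
  # constant rate: cumulative fraction, proportional removal, diameter law
  sc <- dissolution_scenario("constant_rate", initial_fraction = 0.163,
                             rate = 0.016)
  st1 <- initialize_grid(sets, sp, 0.01, sc)
  st1$C[4, 1] <- st1$C[4, 1] * 2       # non-uniform: removal is proportional
  total0 <- sum(st1$C)
  st2 <- apply_dissolution(st1, sc, 3600)
  f_exp <- 0.163 + 0.016
  expect_equal(st2$dissolved_areal / (0.01 * 4), f_exp, tolerance = 1e-12)
  expect_equal(st2$C / st1$C, matrix(st2$C[1] / st1$C[1], 4, 1))
  expect_equal(st2$d_current,
               st2$d0 * ((1 - f_exp) / (1 - 0.163))^(1 / 3))
  # linear ramp reaches max at ramp end and stays there
  scr <- dissolution_scenario("linear_ramp", initial_fraction = 0.1,
                              ramp_end = 2, max_fraction = 0.5)
  expect_equal(dgdose:::.dg_dissolved_fraction(scr, 3600), 0.3)
  expect_equal(dgdose:::.dg_dissolved_fraction(scr, 4 * 3600), 0.5)
  # clamping when the solid phase runs out
  sch <- dissolution_scenario("constant_rate", rate = 10)
  sth <- initialize_grid(sets, sp, 0.01, sch)
  expect_warning(sth2 <- apply_dissolution(sth, sch, 3600), "clamped")
  expect_true(all(sth2$C == 0))
  expect_equal(sth2$dissolved_areal, 0.01 * 4, tolerance = 1e-12)
})

test_that("driver: zero duration, conservation, determinism", {
  p <- dg_preset("Fe2O3")
  s0 <- simulation_settings(height = 1e-3, compartment_height = 2e-5,
                            duration = 0, bottom_slice = 2e-5)
  r0 <- run_simulation(s0, p$species, medium(), p$material, 0.1, quiet = TRUE)
  expect_equal(nrow(r0$timeseries), 1)
  expect_true(all(r0$profiles$conc == 0.1))
  # conservation through a Langmuir + dissolution run
  s1 <- simulation_settings(height = 1e-3, compartment_height = 2e-5,
                            duration = 2 * 3600, output_interval = 1800,
                            bottom_slice = 2e-5, boundary = "langmuir",
                            K_D = 1e-9)
  sc <- dissolution_scenario("constant_rate", initial_fraction = 0.05,
                             rate = 0.01)
  zn <- dg_preset("ZnO")
  r1 <- run_simulation(s1, zn$species, medium(), zn$material, 0.1, sc,
                       quiet = TRUE)
  expect_lt(max(abs(r1$timeseries$total_mass_per_area / (0.1 * 1e-3) - 1)),
            1e-9)
  expect_true(all(r1$timeseries$dissolved_conc >= 0))
  # byte-level determinism
  r2 <- run_simulation(s1, zn$species, medium(), zn$material, 0.1, sc,
                       quiet = TRUE)
  expect_identical(r1$timeseries, r2$timeseries)
})

test_that("polydisperse run equals the fraction-weighted sum of mono runs", {
  med <- medium()
  mat <- enm_material("mix", 4000)
  s <- simulation_settings(height = 5e-4, compartment_height = 1e-5,
                           duration = 3600, output_interval = 3600,
                           bottom_slice = 2e-5)
  spA <- agglomerate_species(1.2e-7, 1400, 0.3)
  spB <- agglomerate_species(4e-7, 1800, 0.7)
  poly <- run_simulation(s, list(spA, spB), med, mat, 0.1, quiet = TRUE)
  monoA <- run_simulation(s, agglomerate_species(1.2e-7, 1400), med, mat,
                          0.1 * 0.3, quiet = TRUE)
  monoB <- run_simulation(s, agglomerate_species(4e-7, 1800), med, mat,
                          0.1 * 0.7, quiet = TRUE)
  expect_equal(poly$state$C[, 1], monoA$state$C[, 1], tolerance = 1e-12)
  expect_equal(poly$state$C[, 2], monoB$state$C[, 1], tolerance = 1e-12)
})

test_that("compiled and R engines agree", {
  zn <- dg_preset("ZnO")
  s <- simulation_settings(height = 4e-4, compartment_height = 2e-5,
                           duration = 1800, output_interval = 900,
                           bottom_slice = 2e-5, boundary = "langmuir",
                           K_D = 1e-8)
  sc <- dissolution_scenario("linear_ramp", initial_fraction = 0.1,
                             ramp_end = 1, max_fraction = 0.4)
  rc <- run_simulation(s, zn$species, medium(), zn$material, 0.05, sc,
                       engine = "compiled", quiet = TRUE)
  rr <- run_simulation(s, zn$species, medium(), zn$material, 0.05, sc,
                       engine = "r", quiet = TRUE)
  expect_equal(rc$state$C, rr$state$C, tolerance = 1e-12)
  expect_equal(rc$state$bound, rr$state$bound, tolerance = 1e-12)
  expect_equal(rc$state$dissolved_areal, rr$state$dissolved_areal,
               tolerance = 1e-12)
  expect_equal(rc$timeseries, rr$timeseries, tolerance = 1e-12)
})
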