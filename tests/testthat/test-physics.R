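# Transport coefficients and friction corrections.
# SiO2 worked case: d_H = 149.9 nm, rho_EV = 1564, rho_m = 1005 kg m^-3,
# eta = 9.55e-4 Pa s, T = 295.15 K.  Frozen oracles computed by direct hand
# evaluation of the defining formulas.

sio2_sp <- agglomerate_species(149.9e-9, 1564)
med <- medium()

test_that("sedimentation velocity: value, scalings, sign, errors", {
  expect_equal(sedimentation_velocity(sio2_sp, med), 7.165721e-9,
               tolerance = 1e-6)
  # zero buoyant density
  expect_equal(sedimentation_velocity(agglomerate_species(2e-7, 1005), med), 0)
  # exact d^2 and (rho_EV - rho_m) proportionality
  v1 <- sedimentation_velocity(agglomerate_species(1e-7, 1500), med)
  v2 <- sedimentation_velocity(agglomerate_species(2e-7, 1500), med)
  expect_equal(v2 / v1, 4)
  v3 <- sedimentation_velocity(agglomerate_species(1e-7, 1005 + 2 * 495), med)
  expect_equal(v3 / v1, 2)
  # buoyant species rise
  expect_lt(sedimentation_velocity(agglomerate_species(1e-7, 900), med), 0)
  expect_error(agglomerate_species(-1e-7, 1500), "d_H")
  expect_error(medium(viscosity = 0), "viscosity")
})

test_that("diffusion coefficient: value, scalings, positivity", {
  expect_equal(diffusion_coefficient(sio2_sp, med), 3.020299e-12,
               tolerance = 1e-6)
  D1 <- diffusion_coefficient(agglomerate_species(1e-7, 1500), med)
  D2 <- diffusion_coefficient(agglomerate_species(2e-7, 1500), med)
  expect_equal(D2, D1 / 2)
  hot <- medium(temperature = 2 * med$temperature)
  expect_equal(diffusion_coefficient(agglomerate_species(1e-7, 1500), hot),
               2 * D1)
  # positive for a spread of sizes
  for (d in c(1e-9, 1e-8, 1e-7, 1e-6))
    expect_gt(diffusion_coefficient(agglomerate_species(d, 1200), med), 0)
})

test_that("sedimentation coefficient is v_s/g and round-trips", {
  expect_equal(sedimentation_coefficient(sio2_sp, med), 7.307002e-10,
               tolerance = 1e-6)
  expect_equal(sedimentation_coefficient(sio2_sp, med) * 9.80665,
               sedimentation_velocity(sio2_sp, med))
  expect_equal(sedimentation_coefficient(agglomerate_species(1e-7, 1005), med), 0)
})

test_that("Cunningham factor reproduces printed values and limits", {
  expect_equal(round(cunningham_factor(100e-9), 3), 1.006)
  expect_equal(round(cunningham_factor(5e-9), 2), 1.12)
  # strictly decreasing in d, tending to 1
  d <- 10^seq(-9, -5, length.out = 40)
  cc <- cunningham_factor(d)
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc > 1))
  expect_equal(cunningham_factor(1), 1, tolerance = 1e-8)
})

test_that("dynamic shape factors: printed values, limits, errors", {
  expect_equal(dynamic_shape_factor("sphere"), 1)
  expect_equal(dynamic_shape_factor("cube"), 1.08)
  expect_equal(round(dynamic_shape_factor("prolate", 3), 2), 1.11)
  expect_equal(round(dynamic_shape_factor("oblate", 3), 2), 1.10)
  # cylinder formula as printed evaluates to 1.218 at P = 3 (independent
  # hand evaluation; the printed example 1.27 does not match the formula)
  expect_equal(dynamic_shape_factor("cylinder", 3), 1.218106,
               tolerance = 1e-6)
  # ellipsoids tend to the sphere as P -> 1+
  expect_equal(dynamic_shape_factor("prolate", 1.0001), 1, tolerance = 1e-3)
  expect_equal(dynamic_shape_factor("oblate", 1.0001), 1, tolerance = 1e-3)
  expect_equal(dynamic_shape_factor("explicit", chi = 1.7), 1.7)
  expect_error(dynamic_shape_factor("prolate", 1), "P")
  expect_error(dynamic_shape_factor("cylinder", 0.5), "P")
  expect_error(dynamic_shape_factor("explicit"), "chi")
})

test_that("friction ratio composes corrections and divides coefficients", {
  # defaults at large d: slip correction vanishes
  expect_equal(friction_ratio(friction_correction(), 1e-3), 1,
               tolerance = 1e-6)
  # 5 nm sphere with slip: ratio = 1/C_c(5 nm)
  expect_equal(friction_ratio(friction_correction(), 5e-9),
               1 / cunningham_factor(5e-9))
  # explicit chi = 2, slip off: corrected D exactly halved
  fc <- friction_correction(slip = FALSE, shape = "explicit", shape_factor = 2)
  expect_equal(friction_ratio(fc, 1e-7), 2)
  sp <- agglomerate_species(1e-7, 1500)
  tr <- dgdose:::.dg_transport(sp, med, fc)
  expect_equal(tr$D, diffusion_coefficient(sp, med) / 2)
  expect_equal(tr$S, sedimentation_coefficient(sp, med) / 2)
  # sphere, all factors 1, slip disabled: bit-for-bit uncorrected
  off <- friction_correction(slip = FALSE)
  tr0 <- dgdose:::.dg_transport(sp, med, off)
  expect_identical(tr0$D, diffusion_coefficient(sp, med))
  expect_identical(tr0$S, sedimentation_coefficient(sp, med))
  # multiplicative solvation/roughness
  fc2 <- friction_correction(slip = FALSE, solvation = 1.2, roughness = 1.5)
  expect_equal(friction_ratio(fc2, 1e-7), 1.8)
})

test_that("concentration-dependent coefficient damping", {
  expect_identical(concentration_corrected_coefficient(3.2e-12, 5, 0), 3.2e-12)
  expect_equal(concentration_corrected_coefficient(1, 2, 0.5), 0.5)
  C <- seq(0, 10, by = 0.5)
  out <- concentration_corrected_coefficient(1, C, 0.3)
  expect_true(all(diff(out) < 0))
  expect_error(concentration_corrected_coefficient(1, -1, 0.3), "C")
})

test_that("species fraction bookkeeping", {
  expect_error(agglomerate_species(1e-7, 1500, 1.5), "fraction")
  expect_error(
    dgdose:::.dg_species_list(list(agglomerate_species(1e-7, 1500, 0.6),
                                   agglomerate_species(2e-7, 1500, 0.5))),
    "sum to 1")
})
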