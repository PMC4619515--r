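# Shared fixtures.  Long simulations used by several acceptance criteria are
# memoized so the suite runs each paper-scale scenario once.

.dg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .dg_cache)) assign(key, force(expr), .dg_cache)
  get(key, .dg_cache)
}

# water-like culture medium at 22 C used throughout (package default)
test_medium <- function() medium()

# paper-conditions run: preset material at C0 = 0.1 mg/ml in a 3 mm column,
# h = 5 um, dt = 1 s
paper_settings <- function(duration_h, boundary = "reflective", K_D = NULL,
                           output_interval_h = 1, height_mm = 3,
                           compartment_um = 5, dt = 1) {
  simulation_settings(height = height_mm * 1e-3,
                      compartment_height = compartment_um * 1e-6,
                      dt = dt, duration = duration_h * 3600,
                      output_interval = output_interval_h * 3600,
                      boundary = boundary, K_D = K_D)
}

run_preset <- function(name, duration_h, ...) {
  p <- dg_preset(name)
  run_simulation(paper_settings(duration_h, ...), p$species, test_medium(),
                 p$material, C0 = 0.1, quiet = TRUE)
}

# Synthetic volume-weighted lognormal stand-in for a measured DLS volume
# distribution: volume-weighted arithmetic mean matched to the preset's
# <d_H>_v and geometric SD from the DLS polydispersity index,
# ln(gsd) = sqrt(ln(1 + PdI)).
synthetic_volume_distribution <- function(mean_d, pdi, bins = 15) {
  s <- sqrt(log(1 + pdi))
  mu <- log(mean_d) - s^2 / 2          # exp(mu + s^2/2) = mean_d
  centers <- seq(mu - 3 * s, mu + 3 * s, length.out = bins)
  w <- dnorm(centers, mu, s)
  d <- exp(centers)
  f <- w / sum(w)
  # rescale diameters so the discretized mean matches exactly
  d <- d * mean_d / sum(f * d)
  size_distribution(d, f, "volume")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
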