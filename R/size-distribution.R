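#' Agglomerate size distribution
#'
#' Paired arrays of hydrodynamic diameters and fractional contributions, as
#' exported by DLS.  Number-weighted fractions describe counts per size bin;
#' volume-weighted fractions describe volume (equivalently mass, at a common
#' effective density) per bin.
#'
#' @param diameter Bin diameters d_H (m), all > 0.
#' @param fraction Bin fractions (>= 0); renormalized to sum to 1 exactly.
#' @param weighting `"number"` or `"volume"`.
#' @return An object of class `dg_size_distribution`.
#' @export
size_distribution <- function(diameter, fraction,
                              weighting = c("volume", "number")) {
  weighting <- match.arg(weighting)
  .dg_check_num(diameter, "diameter")
  .dg_check_num(fraction, "fraction", positive = FALSE)
  if (length(diameter) != length(fraction))
    .dg_stop("'diameter' and 'fraction' must have the same length")
  if (any(fraction < 0)) .dg_stop("'fraction' must be >= 0")
  s <- sum(fraction)
  if (s <= 0) .dg_stop("'fraction' must have a positive sum")
  structure(list(diameter = as.numeric(diameter),
                 fraction = as.numeric(fraction) / s,
                 weighting = weighting),
            class = "dg_size_distribution")
}

#' Convert a number-weighted distribution to volume weighting
#'
#' f_V,i = f_N,i d_i^3 / sum_i f_N,i d_i^3.  Bin diameters are unchanged.
#'
#' @param dist A number-weighted [size_distribution()].
#' @return A volume-weighted `dg_size_distribution`.
#' @export
number_to_volume_distribution <- function(dist) {
  stopifnot(inherits(dist, "dg_size_distribution"))
  if (dist$weighting != "number")
    .dg_stop("'dist' is already volume-weighted")
  w <- dist$fraction * dist$diameter^3
  size_distribution(dist$diameter, w / sum(w), "volume")
}

#' Convert a volume-weighted distribution to number weighting
#'
#' Algebraic inverse of [number_to_volume_distribution()]:
#' f_N,i proportional to f_V,i / d_i^3.
#'
#' @param dist A volume-weighted [size_distribution()].
#' @return A number-weighted `dg_size_distribution`.
#' @export
volume_to_number_distribution <- function(dist) {
  stopifnot(inherits(dist, "dg_size_distribution"))
  if (dist$weighting != "volume")
    .dg_stop("'dist' is already number-weighted")
  w <- dist$fraction / dist$diameter^3
  size_distribution(dist$diameter, w / sum(w), "number")
}

#' Volume-weighted mean hydrodynamic diameter
#'
#' <d_H>_V = sum_i f_V,i d_i.  A number-weighted input is converted first.
#'
#' @param dist A [size_distribution()].
#' @return Mean diameter (m), between `min(diameter)` and `max(diameter)`.
#' @export
volume_weighted_mean <- function(dist) {
  stopifnot(inherits(dist, "dg_size_distribution"))
  if (dist$weighting == "number") dist <- number_to_volume_distribution(dist)
  sum(dist$fraction * dist$diameter)
}

#' Synthetic lognormal size distribution
#'
#' Deterministic stand-in for a DLS export: a number-weighted lognormal
#' discretized over +/- 3 geometric standard deviations.  Useful as a test
#' fixture and for exploring polydispersity effects when a measured
#' distribution is unavailable.
#'
#' @param gm Geometric mean diameter (m).
#' @param gsd Geometric standard deviation (> 1).
#' @param bins Number of bins (>= 1).
#' @param seed Accepted for interface stability; the discretization is
#'   deterministic and the seed is unused.
#' @return A number-weighted `dg_size_distribution`.
#' @export
synth_distribution <- function(gm, gsd, bins = 31, seed = NULL) {
  .dg_check_num(gm, "gm", len = 1)
  .dg_check_num(gsd, "gsd", len = 1)
  if (gsd <= 1) .dg_stop("'gsd' must be > 1")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1) .dg_stop("'bins' must be >= 1")
  lmu <- log(gm); lsd <- log(gsd)
  centers <- if (bins == 1) lmu else seq(lmu - 3 * lsd, lmu + 3 * lsd,
                                         length.out = bins)
  w <- dnorm(centers, mean = lmu, sd = lsd)
  size_distribution(exp(centers), w / sum(w), "number")
}
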