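# Phasor transform of TCSPC decays, lifetime calibration, and
# phasor <-> lifetime conversions.
#
# Conventions: first-harmonic phasors by default, angular frequency
# omega = 2*pi*rep_rate (rad/s); lifetimes in nanoseconds throughout.
# Time-bin centers (not edges) are used when transforming histograms.

omega_per_ns <- function(rep_rate_hz, harmonic = 1) {
  2 * pi * rep_rate_hz * 1e-9 * harmonic
}

#' Create a phasor point
#'
#' A phasor point holds the first-harmonic Fourier coordinates (g, s) of a
#' fluorescence decay. Mono-exponential decays lie on the universal
#' semicircle (g - 1/2)^2 + s^2 = 1/4; mixtures lie inside it.
#'
#' @param g cosine (real) coordinate.
#' @param s sine (imaginary) coordinate.
#' @return an object of class `phasor_point`.
#' @export
phasor_point <- function(g, s) {
  stopifnot(is.numeric(g), is.numeric(s), length(g) == length(s))
  structure(list(g = as.numeric(g), s = as.numeric(s)), class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> g = %.6g, s = %.6g\n", x$g[1], x$s[1]))
  if (length(x$g) > 1) cat(sprintf("  (%d points)\n", length(x$g)))
  invisible(x)
}

#' Phasor transform of a single decay histogram
#'
#' Transforms a photon arrival-time histogram into phasor coordinates at the
#' given harmonic of the laser repetition frequency:
#' \deqn{g = \sum_k h_k \cos(n \omega t_k) / \sum_k h_k, \quad
#'       s = \sum_k h_k \sin(n \omega t_k) / \sum_k h_k}
#' with \eqn{t_k} the bin centers, \eqn{n} the harmonic and
#' \eqn{\omega = 2\pi/\mathrm{period}}.
#'
#' @param histogram numeric vector of photon counts per time bin; bins
#'   uniformly cover `[0, period_ns)`.
#' @param period_ns laser period in ns (1e9 / repetition rate in Hz).
#' @param harmonic positive integer harmonic, default 1.
#' @return a [phasor_point()].
#' @export
decay_to_phasor <- function(histogram, period_ns, harmonic = 1) {
  stopifnot(is.numeric(histogram), length(histogram) >= 8,
            is.numeric(period_ns), period_ns > 0)
  if (any(histogram < 0)) stop("negative counts in decay histogram")
  total <- sum(histogram)
  if (total <= 0) stop("undefined phasor: decay histogram has zero total counts")
  T_ <- length(histogram)
  t_k <- (seq_len(T_) - 0.5) * period_ns / T_
  w <- 2 * pi / period_ns * harmonic
  phasor_point(sum(histogram * cos(w * t_k)) / total,
               sum(histogram * sin(w * t_k)) / total)
}

#' Closed-form phasor of a mono-exponential decay
#'
#' For lifetime `tau_ns` at repetition rate `rep_rate_hz` and harmonic `n`,
#' \eqn{g = 1/(1 + (n\omega\tau)^2)}, \eqn{s = n\omega\tau/(1 + (n\omega\tau)^2)}.
#' These points parameterise the universal semicircle.
#'
#' @param tau_ns lifetime in ns (>= 0).
#' @param rep_rate_hz pulse repetition rate in Hz.
#' @param harmonic positive integer harmonic, default 1.
#' @return a [phasor_point()].
#' @export
single_exp_phasor <- function(tau_ns, rep_rate_hz, harmonic = 1) {
  if (any(tau_ns < 0)) stop("lifetime must be non-negative")
  wt <- omega_per_ns(rep_rate_hz, harmonic) * tau_ns
  phasor_point(1 / (1 + wt^2), wt / (1 + wt^2))
}

#' Create a phasor bundle
#'
#' Per-pixel phasor coordinates with the accumulated intensity image and
#' acquisition metadata. Pixels with zero intensity carry `NA` coordinates
#' (no photons, undefined phasor).
#'
#' @param g,s numeric matrices of phasor coordinates.
#' @param intensity numeric matrix of per-pixel photon totals.
#' @param rep_rate_hz pulse repetition rate in Hz.
#' @param harmonic harmonic used in the transform.
#' @param calibrated logical flag; `TRUE` after [calibrate()].
#' @param reference_lifetime_ns lifetime of the calibration reference, or NA.
#' @return an object of class `phasor_bundle`.
#' @export
phasor_bundle <- function(g, s, intensity, rep_rate_hz, harmonic = 1,
                          calibrated = FALSE, reference_lifetime_ns = NA_real_) {
  stopifnot(is.matrix(g), is.matrix(s), is.matrix(intensity),
            all(dim(g) == dim(s)), all(dim(g) == dim(intensity)))
  structure(list(
    g = g, s = s, intensity = intensity,
    meta = list(rep_rate_hz = rep_rate_hz, harmonic = harmonic,
                calibrated = isTRUE(calibrated),
                reference_lifetime_ns = reference_lifetime_ns)
  ), class = "phasor_bundle")
}

#' @export
print.phasor_bundle <- function(x, ...) {
  cat(sprintf("<phasor_bundle> %d x %d px, %scalibrated, harmonic %d, rep rate %.4g MHz\n",
              nrow(x$g), ncol(x$g),
              if (x$meta$calibrated) "" else "un", x$meta$harmonic,
              x$meta$rep_rate_hz / 1e6))
  ok <- is.finite(x$g)
  cat(sprintf("  valid pixels: %d (%.1f%%); total photons: %.4g\n",
              sum(ok), 100 * mean(ok), sum(x$intensity)))
  invisible(x)
}

#' Per-pixel phasor transform of a TCSPC stack
#'
#' Applies [decay_to_phasor()] to every pixel of the accumulated decay
#' histogram. Pixels with zero photons are marked invalid (`NA` coordinates).
#'
#' @param stack a [tcspc_stack()].
#' @param harmonic positive integer harmonic, default 1.
#' @return a [phasor_bundle()] (uncalibrated).
#' @export
field_phasor <- function(stack, harmonic = 1) {
  stopifnot(inherits(stack, "tcspc_stack"))
  d <- stack$decay
  H <- dim(d)[1]; W <- dim(d)[2]; T_ <- dim(d)[3]
  t_k <- (seq_len(T_) - 0.5) * stack$period_ns / T_
  w <- 2 * pi / stack$period_ns * harmonic
  m <- matrix(d, nrow = H * W, ncol = T_)
  total <- rowSums(m)
  g <- as.numeric(m %*% cos(w * t_k))
  s <- as.numeric(m %*% sin(w * t_k))
  valid <- total > 0
  g <- ifelse(valid, g / total, NA_real_)
  s <- ifelse(valid, s / total, NA_real_)
  phasor_bundle(matrix(g, H, W), matrix(s, H, W), matrix(total, H, W),
                rep_rate_hz = stack$rep_rate_hz, harmonic = harmonic)
}

#' Intensity-weighted mean phasor of a bundle
#'
#' @param bundle a [phasor_bundle()].
#' @return a [phasor_point()].
#' @export
bundle_mean_phasor <- function(bundle) {
  stopifnot(inherits(bundle, "phasor_bundle"))
  ok <- is.finite(bundle$g) & is.finite(bundle$s) & bundle$intensity > 0
  if (!any(ok)) stop("bundle has no valid pixels")
  wsum <- sum(bundle$intensity[ok])
  phasor_point(sum(bundle$g[ok] * bundle$intensity[ok]) / wsum,
               sum(bundle$s[ok] * bundle$intensity[ok]) / wsum)
}

#' Calibration reference
#'
#' Describes a reference acquisition of a fluorophore with known
#' mono-exponential lifetime (e.g. Coumarin 6, 2.5 ns), used to remove the
#' instrument response from measured phasors.
#'
#' @param known_lifetime_ns the reference fluorophore's lifetime in ns (> 0).
#' @param measured the uncalibrated mean phasor of the reference acquisition:
#'   a [phasor_point()] or a [phasor_bundle()] (reduced with
#'   [bundle_mean_phasor()]).
#' @param rep_rate_hz pulse repetition rate in Hz.
#' @return an object of class `calibration_reference`.
#' @export
calibration_reference <- function(known_lifetime_ns, measured, rep_rate_hz) {
  stopifnot(is.numeric(known_lifetime_ns), known_lifetime_ns > 0)
  if (inherits(measured, "phasor_bundle")) measured <- bundle_mean_phasor(measured)
  stopifnot(inherits(measured, "phasor_point"))
  structure(list(known_lifetime_ns = known_lifetime_ns, measured = measured,
                 rep_rate_hz = rep_rate_hz),
            class = "calibration_reference")
}

#' Calibrate a phasor bundle against a known-lifetime reference
#'
#' Treats each pixel's phasor as a complex number z = g + i s and multiplies
#' by the single global factor c = z_expected / z_measured, where z_expected
#' is the closed-form phasor of the reference lifetime. Applying this to the
#' reference's own bundle maps its mean phasor exactly onto the universal
#' semicircle at the reference lifetime.
#'
#' @param bundle an uncalibrated [phasor_bundle()].
#' @param ref a [calibration_reference()].
#' @return a calibrated [phasor_bundle()].
#' @export
calibrate <- function(bundle, ref) {
  stopifnot(inherits(bundle, "phasor_bundle"), inherits(ref, "calibration_reference"))
  if (bundle$meta$calibrated) stop("bundle is already calibrated")
  z_meas <- complex(real = ref$measured$g, imaginary = ref$measured$s)
  if (Mod(z_meas) == 0) stop("calibration error: measured reference phasor has zero modulus")
  exp_p <- single_exp_phasor(ref$known_lifetime_ns, ref$rep_rate_hz,
                             bundle$meta$harmonic)
  cfac <- complex(real = exp_p$g, imaginary = exp_p$s) / z_meas
  z <- complex(real = bundle$g, imaginary = bundle$s) * cfac
  out <- phasor_bundle(matrix(Re(z), nrow(bundle$g)), matrix(Im(z), nrow(bundle$g)),
                       bundle$intensity, bundle$meta$rep_rate_hz,
                       harmonic = bundle$meta$harmonic, calibrated = TRUE,
                       reference_lifetime_ns = ref$known_lifetime_ns)
  out
}

#' Modulation and phase of a phasor point
#'
#' @param p a [phasor_point()].
#' @return list with `modulation` = sqrt(g^2 + s^2) and `phase_rad` =
#'   atan2(s, g).
#' @export
modulation_phase <- function(p) {
  stopifnot(inherits(p, "phasor_point"))
  list(modulation = sqrt(p$g^2 + p$s^2), phase_rad = atan2(p$s, p$g))
}

#' Phase lifetime of a phasor point
#'
#' Inverts the phase relation tan(phi) = n omega tau:
#' tau_phi = (s / g) / (n omega), in ns.
#'
#' @param p a [phasor_point()] with g > 0.
#' @param rep_rate_hz pulse repetition rate in Hz.
#' @param harmonic positive integer harmonic, default 1.
#' @return lifetime in ns.
#' @export
phase_lifetime <- function(p, rep_rate_hz, harmonic = 1) {
  stopifnot(inherits(p, "phasor_point"))
  if (any(p$g <= 0)) stop("phase lifetime undefined for g <= 0")
  (p$s / p$g) / omega_per_ns(rep_rate_hz, harmonic)
}

#' Modulation lifetime of a phasor point
#'
#' Inverts the modulation relation M = 1 / sqrt(1 + (n omega tau)^2):
#' tau_M = sqrt(1 / M^2 - 1) / (n omega), in ns. Equals the phase lifetime
#' exactly on the universal semicircle; exceeds it for multi-exponential
#' decays.
#'
#' @inheritParams phase_lifetime
#' @return lifetime in ns.
#' @export
modulation_lifetime <- function(p, rep_rate_hz, harmonic = 1) {
  stopifnot(inherits(p, "phasor_point"))
  m <- sqrt(p$g^2 + p$s^2)
  if (any(m == 0)) stop("modulation lifetime undefined for zero modulation")
  if (any(m > 1 + 1e-9)) stop("modulation > 1: not a physical decay phasor")
  m <- pmin(m, 1)
  sqrt(1 / m^2 - 1) / omega_per_ns(rep_rate_hz, harmonic)
}
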