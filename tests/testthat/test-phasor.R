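# Phasor transform, calibration and lifetime inversions.

test_that("decay_to_phasor matches the direct DFT oracle on random histograms", {
  set.seed(101)
  for (i in 1:100) {
    T_ <- sample(c(16, 64, 256), 1)
    h <- stats::rpois(T_, lambda = stats::runif(1, 1, 50))
    if (sum(h) == 0) h[1] <- 1
    p <- decay_to_phasor(h, 12.5)
    o <- oracle_phasor(h, 12.5)
    expect_equal(p$g, o["g"], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(p$s, o["s"], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("limiting decays: delta at t=0 gives (1,0), uniform gives (0,0)", {
  T_ <- 256
  delta <- c(1000, rep(0, T_ - 1))
  p <- decay_to_phasor(delta, 12.5)
  expect_equal(p$g, 1, tolerance = 2 * pi / T_)   # one-bin tolerance
  expect_equal(p$s, 0, tolerance = 2 * pi / T_)
  u <- decay_to_phasor(rep(7, T_), 12.5)
  expect_equal(u$g, 0, tolerance = 1e-12)
  expect_equal(u$s, 0, tolerance = 1e-12)
})

test_that("decay_to_phasor rejects invalid histograms", {
  expect_error(decay_to_phasor(rep(0, 64), 12.5), "zero total")
  expect_error(decay_to_phasor(c(-1, rep(1, 63)), 12.5), "negative")
})

test_that("phasor transform is linear in photon weights", {
  set.seed(7)
  for (i in 1:20) {
    h1 <- stats::rpois(128, 20); h2 <- stats::rpois(128, 5)
    h1[1] <- h1[1] + 1; h2[1] <- h2[1] + 1
    p1 <- decay_to_phasor(h1, 12.5); p2 <- decay_to_phasor(h2, 12.5)
    ps <- decay_to_phasor(h1 + h2, 12.5)
    w1 <- sum(h1) / sum(h1 + h2)
    expect_equal(ps$g, w1 * p1$g + (1 - w1) * p2$g, tolerance = 1e-12)
    expect_equal(ps$s, w1 * p1$s + (1 - w1) * p2$s, tolerance = 1e-12)
  }
})

test_that("single-exponential phasors lie on the universal semicircle", {
  taus <- c(0.05, 0.2, 0.4, 1, 2.5, 3.4, 8, 20)
  for (tau in taus) {
    p <- single_exp_phasor(tau, 8e7)
    expect_equal((p$g - 0.5)^2 + p$s^2, 0.25, tolerance = 1e-12)
    # discretized histogram version stays within 0.01 for T >= 64
    h <- decay_histogram(tau, 12.5, 64, total = 1e6)
    pd <- decay_to_phasor(h, 12.5)
    expect_lt(abs(sqrt((pd$g - 0.5)^2 + pd$s^2) - 0.5), 0.01)
  }
  expect_error(single_exp_phasor(-1, 8e7), "non-negative")
})

test_that("closed-form anchor points: tau = 0, apex, and 2.5 ns at 80 MHz", {
  p0 <- single_exp_phasor(0, 8e7)
  expect_equal(c(p0$g, p0$s), c(1, 0))
  w <- 2 * pi * 8e7 * 1e-9
  apex <- single_exp_phasor(1 / w, 8e7)
  expect_equal(c(apex$g, apex$s), c(0.5, 0.5), tolerance = 1e-12)
  # frozen from independent evaluation of 1/(1+x^2), x/(1+x^2) at
  # x = 2*pi*0.08*2.5 = 0.6283*... : (0.3877266, 0.4872317)
  p25 <- single_exp_phasor(2.5, 8e7)
  expect_equal(p25$g, 0.3877266, tolerance = 1e-3)
  expect_equal(p25$s, 0.4872317, tolerance = 1e-3)
  h <- decay_histogram(2.5, 12.5, 1024, total = 1)
  pd <- decay_to_phasor(h, 12.5)
  expect_lt(abs(pd$g - p25$g), 0.01)
  expect_lt(abs(pd$s - p25$s), 0.01)
})

test_that("convex mixtures of single-exponential decays fall inside the semicircle", {
  set.seed(11)
  for (i in 1:20) {
    fb <- stats::runif(1, 0.05, 0.95)
    h <- mixture_decay_histogram(fb, t_bins = 512, total = 1)
    p <- decay_to_phasor(h, 12.5)
    expect_lt((p$g - 0.5)^2 + p$s^2, 0.25)
  }
})

test_that("phase and modulation lifetimes invert single-exponential phasors", {
  for (tau in c(0.4, 1.7, 2.5, 3.4)) {
    p <- single_exp_phasor(tau, 8e7)
    expect_equal(phase_lifetime(p, 8e7), tau, tolerance = 1e-9)
    expect_equal(modulation_lifetime(p, 8e7), tau, tolerance = 1e-9)
  }
  expect_equal(phase_lifetime(phasor_point(0.5, 0.5), 8e7),
               1 / (2 * pi * 8e7 * 1e-9), tolerance = 1e-12)
  expect_equal(phase_lifetime(phasor_point(1, 0), 8e7), 0)
  expect_equal(modulation_lifetime(phasor_point(1, 0), 8e7), 0)
  expect_error(phase_lifetime(phasor_point(-0.1, 0.2), 8e7), "g <= 0")
  expect_error(modulation_lifetime(phasor_point(0, 0), 8e7), "zero modulation")
  expect_error(modulation_lifetime(phasor_point(1, 0.5), 8e7), "modulation > 1")
})

test_that("modulation lifetime exceeds phase lifetime for two-component mixtures", {
  for (fb in c(0.2, 0.5, 0.8)) {
    h <- mixture_decay_histogram(fb, t_bins = 1024, total = 1)
    p <- decay_to_phasor(h, 12.5)
    expect_gt(modulation_lifetime(p, 8e7), phase_lifetime(p, 8e7))
  }
})

test_that("field_phasor handles constant, empty and two-region stacks", {
  h <- round(decay_histogram(1.5, 12.5, 64, total = 400))
  stack <- uniform_histogram_stack(h, H = 6, W = 6)
  b <- field_phasor(stack)
  expect_true(all(abs(b$g - b$g[1, 1]) < 1e-12))
  expect_true(all(abs(b$s - b$s[1, 1]) < 1e-12))
  expect_equal(b$intensity[1, 1], sum(h))

  # all-zero stack: everything invalid, no crash
  z <- tcspc_stack(array(0L, c(2, 4, 4)), array(0L, c(4, 4, 16)), 8e7, 0.2)
  bz <- field_phasor(z)
  expect_true(all(is.na(bz$g)))
  expect_true(all(bz$intensity == 0))

  # two-region stack: free-only and bound-only halves
  T_ <- 128
  hf <- round(decay_histogram(0.4, 12.5, T_, total = 2e4))
  hb <- round(decay_histogram(3.4, 12.5, T_, total = 2e4))
  decay <- array(0L, c(4, 8, T_))
  for (k in seq_len(T_)) {
    decay[, 1:4, k] <- as.integer(hf[k])
    decay[, 5:8, k] <- as.integer(hb[k])
  }
  tot <- apply(decay, c(1, 2), sum)
  frames <- array(as.integer(tot), c(1, 4, 8))
  st2 <- tcspc_stack(frames, decay, 8e7, 0.2)
  b2 <- field_phasor(st2)
  pf <- single_exp_phasor(0.4, 8e7); pb <- single_exp_phasor(3.4, 8e7)
  expect_lt(abs(mean(b2$g[, 1:4]) - pf$g), 0.01)
  expect_lt(abs(mean(b2$s[, 1:4]) - pf$s), 0.01)
  expect_lt(abs(mean(b2$g[, 5:8]) - pb$g), 0.01)
  expect_lt(abs(mean(b2$s[, 5:8]) - pb$s), 0.01)
})

make_distorted_reference_bundle <- function(tau = 2.5, phase_off = 0.3,
                                            mod_scale = 0.8, H = 8, W = 8) {
  h <- decay_histogram(tau, 12.5, 256, total = 1e4)
  z <- decay_to_phasor(h, 12.5)
  zd <- complex(real = z$g, imaginary = z$s) * mod_scale * exp(1i * phase_off)
  phasor_bundle(matrix(Re(zd), H, W), matrix(Im(zd), H, W),
                matrix(1e4, H, W), 8e7)
}

test_that("self-calibration maps the reference onto its known lifetime exactly", {
  b <- make_distorted_reference_bundle()
  ref <- calibration_reference(2.5, bundle_mean_phasor(b), 8e7)
  cal <- calibrate(b, ref)
  mp <- bundle_mean_phasor(cal)
  exp_p <- single_exp_phasor(2.5, 8e7)
  expect_equal(mp$g, exp_p$g, tolerance = 1e-10)
  expect_equal(mp$s, exp_p$s, tolerance = 1e-10)
  expect_true(cal$meta$calibrated)
})

test_that("calibration with a correct reference is the identity", {
  h <- decay_histogram(1.2, 12.5, 256, total = 1e4)
  z <- decay_to_phasor(h, 12.5)
  b <- phasor_bundle(matrix(z$g, 4, 4), matrix(z$s, 4, 4), matrix(1e4, 4, 4), 8e7)
  # measured reference equals its expected phasor -> c = 1
  exp_p <- single_exp_phasor(2.5, 8e7)
  ref <- calibration_reference(2.5, phasor_point(exp_p$g, exp_p$s), 8e7)
  cal <- calibrate(b, ref)
  expect_equal(cal$g, b$g, tolerance = 1e-14)
  expect_equal(cal$s, b$s, tolerance = 1e-14)
})

test_that("instrument distortion is inverted: 0.4 ns recovered via a distorted 2.5 ns reference", {
  phase_off <- 0.3; mod_scale <- 0.8
  distort <- function(tau) {
    h <- decay_histogram(tau, 12.5, 1024, total = 1e6)
    z <- decay_to_phasor(h, 12.5)
    complex(real = z$g, imaginary = z$s) * mod_scale * exp(1i * phase_off)
  }
  z_s <- distort(0.4)
  sample_b <- phasor_bundle(matrix(Re(z_s), 4, 4), matrix(Im(z_s), 4, 4),
                            matrix(1e6, 4, 4), 8e7)
  z_r <- distort(2.5)
  ref <- calibration_reference(2.5, phasor_point(Re(z_r), Im(z_r)), 8e7)
  cal <- calibrate(sample_b, ref)
  tau_hat <- phase_lifetime(bundle_mean_phasor(cal), 8e7)
  expect_equal(tau_hat, 0.4, tolerance = 0.02)
})

test_that("calibration is invertible", {
  b <- make_distorted_reference_bundle(tau = 1.8)
  ref <- calibration_reference(2.5, phasor_point(0.31, 0.42), 8e7)
  cal <- calibrate(b, ref)
  # invert: reference whose expected phasor equals the measured one under c
  exp_p <- single_exp_phasor(2.5, 8e7)
  z_exp <- complex(real = exp_p$g, imaginary = exp_p$s)
  z_meas <- complex(real = 0.31, imaginary = 0.42)
  cfac <- z_exp / z_meas
  cal$meta$calibrated <- FALSE
  # a reference with measured = expected * cfac applies factor 1/cfac
  ref_inv <- calibration_reference(2.5, phasor_point(Re(z_exp * cfac),
                                                     Im(z_exp * cfac)), 8e7)
  back <- calibrate(cal, ref_inv)
  expect_equal(back$g, b$g, tolerance = 1e-12)
  expect_equal(back$s, b$s, tolerance = 1e-12)
})

test_that("calibrate guards its preconditions", {
  b <- make_distorted_reference_bundle()
  expect_error(calibrate(b, calibration_reference(2.5, phasor_point(0, 0), 8e7)),
               "zero modulus")
  ref <- calibration_reference(2.5, phasor_point(0.3, 0.4), 8e7)
  cal <- calibrate(b, ref)
  expect_error(calibrate(cal, ref), "already calibrated")
})
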