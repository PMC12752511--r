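# FIBIS segmentation: normalization, scan-noise suppression, thresholding,
# size-gated erosion and the assembled pipeline.

blob_image <- function(H = 64, W = 64, cy = 32, cx = 32, r = 9, level = 1) {
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  level * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * (r / 2)^2))
}

test_that("normalize_frames standardizes each frame before averaging", {
  set.seed(5)
  base <- matrix(stats::rpois(32 * 32, 10), 32, 32)
  # identical frames reduce to the single-frame result
  frames1 <- array(0, c(1, 32, 32)); frames1[1, , ] <- base
  frames3 <- array(0, c(3, 32, 32))
  for (f in 1:3) frames3[f, , ] <- base
  expect_equal(normalize_frames(frames3), normalize_frames(frames1))

  # constant frame contributes zeros without division errors
  framesc <- array(5, c(1, 8, 8))
  expect_true(all(normalize_frames(framesc) == 0))

  # a 10x brighter frame contributes equally after standardization
  fa <- matrix(stats::rpois(32 * 32, 10), 32, 32)
  fb <- 10 * matrix(stats::rpois(32 * 32, 10), 32, 32)
  two <- array(0, c(2, 32, 32)); two[1, , ] <- fa; two[2, , ] <- fb
  za <- (fa - mean(fa)) / stats::sd(fa)
  zb <- (fb - mean(fb)) / stats::sd(fb)
  expect_equal(sum(za^2), sum(zb^2), tolerance = 1e-9)  # equal contribution norms
  avg <- (za + zb) / 2
  expect_equal(normalize_frames(two),
               (avg - min(avg)) / (max(avg) - min(avg)), tolerance = 1e-12)
})

test_that("detect_scan_noise flags periodic stripes at the right frequency and not smooth content", {
  img <- blob_image()
  expect_false(detect_scan_noise(img)$flagged)

  period <- 8
  x0 <- matrix(seq_len(64) - 1, 64, 64, byrow = TRUE)
  striped <- img + 0.4 * sin(2 * pi * x0 / period)
  rep_s <- detect_scan_noise(striped)
  expect_true(rep_s$flagged)
  # stripe frequency index = W / period
  expect_true(any(abs(rep_s$peak_coords[, "kx"]) == 64 / period))
})

test_that("detect_scan_noise false-positive rate on white noise is below 5%", {
  set.seed(42)
  flags <- vapply(1:100, function(i) {
    detect_scan_noise(matrix(stats::rnorm(64 * 64), 64, 64))$flagged
  }, logical(1))
  expect_lte(sum(flags), 5)
})

test_that("fft_denoise removes stripes, preserves blobs, is identity when unflagged", {
  img <- blob_image()
  rep0 <- detect_scan_noise(img)
  expect_identical(fft_denoise(img, rep0), img)    # bit-identical

  period <- 8; amp <- 0.4
  x0 <- matrix(seq_len(64) - 1, 64, 64, byrow = TRUE)
  stripes <- amp * sin(2 * pi * x0 / period)
  striped <- img + stripes
  rep_s <- detect_scan_noise(striped)
  den <- fft_denoise(striped, rep_s)
  # stripe Fourier coefficient reduced >= 10x
  coef_at <- function(m) {
    A <- Mod(stats::fft(m)) / length(m)
    A[1, 1 + 64 / period]
  }
  expect_lt(coef_at(den - img), coef_at(striped - img) / 10)
  # blob mass changed <= 5%
  expect_lt(abs(sum(den) - sum(img)) / sum(img), 0.05)

  # denoising normalizes the histogram: a Gaussian field plus stripes is
  # platykurtic; removing the stripes brings excess kurtosis back toward 0
  set.seed(99)
  field <- matrix(0.5 + 0.05 * stats::rnorm(64 * 64), 64, 64)
  striped2 <- field + 0.2 * sin(2 * pi * x0 / period)
  rep2 <- detect_scan_noise(striped2)
  expect_true(rep2$flagged)
  den2 <- fft_denoise(striped2, rep2)
  kurt <- function(v) mean((v - mean(v))^4) / stats::var(v)^2 - 3
  expect_lt(abs(kurt(as.numeric(den2))), abs(kurt(as.numeric(striped2))))
})

test_that("otsu_threshold matches the brute-force between-class variance oracle", {
  # two-level histogram: 16 zeros, 16 at 255
  x <- c(rep(0, 16), rep(255, 16))
  thr <- otsu_threshold(x)
  expect_equal(thr, oracle_otsu(x))
  expect_true(thr > 0 && thr < 255)
  set.seed(13)
  for (i in 1:10) {
    x <- c(stats::rnorm(200, 40, 8), stats::rnorm(60, 160, 20))
    expect_equal(otsu_threshold(x), oracle_otsu(x), tolerance = 1e-12)
  }
  expect_error(otsu_threshold(rep(3, 10)), "fewer than 2 distinct")
})

test_that("iqr_otsu_threshold separates objects from diffuse background", {
  # noise-free two-level image
  img <- matrix(0.2, 32, 32); img[10:20, 10:20] <- 0.8
  bin <- iqr_otsu_threshold(img)
  thr <- attr(bin, "threshold")
  expect_true(thr > 0.2 && thr < 0.8)
  expect_true(all(bin == (img > 0.5)))

  # blob over diffuse background at 40% of blob intensity, with noise
  set.seed(21)
  H <- 64
  truth <- matrix(FALSE, H, H); truth[26:38, 26:38] <- TRUE
  img2 <- matrix(0.4, H, H) + matrix(stats::rnorm(H * H, 0, 0.03), H, H)
  img2[truth] <- 1 + stats::rnorm(sum(truth), 0, 0.03)
  img2 <- pmax(img2, 1e-6)
  bin2 <- iqr_otsu_threshold(img2)
  expect_gte(mean(bin2[truth]), 0.95)
  expect_lte(mean(bin2[!truth]), 0.05)
  expect_error(iqr_otsu_threshold(matrix(1, 4, 4)), "fewer than 2 distinct")
})

test_that("label_components uses 8-connectivity with raster-order ids", {
  m <- matrix(0, 5, 7)
  m[1, 1] <- 1; m[2, 2] <- 1           # diagonal touch: one object
  m[5, 6] <- 1                          # far speck: second object
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[5, 6], 2L)
  expect_equal(label_components(matrix(0, 3, 3)), matrix(0L, 3, 3))
})

test_that("size_filter_erode deletes specks, keeps in-range, splits bridged pairs", {
  cfg <- fibis_config(pixel_size_um = 0.2)

  # in-range component untouched, zero erosion iterations
  img <- matrix(0, 32, 32)
  img[10:18, 10:18] <- 1   # 9x9 px ~ 2 um
  m <- size_filter_erode(img > 0, img, cfg)
  expect_equal(nrow(m$objects), 1)
  expect_equal(m$objects$erosion_iters_applied, 0L)
  expect_equal(sum(m$labels > 0), sum(img > 0))

  # 2-px speck (0.3 um equivalent) deleted
  speck <- matrix(0, 16, 16); speck[4, 4:5] <- 1
  ms <- size_filter_erode(speck > 0, speck, cfg)
  expect_equal(nrow(ms$objects), 0)

  # two 1.5-um discs joined by a faint 1-px bridge -> eroded into two objects
  H <- 64
  yy <- matrix(seq_len(H), H, H); xx <- t(yy)
  d1 <- sqrt((yy - 32)^2 + (xx - 15)^2) <= 3.75
  d2 <- sqrt((yy - 32)^2 + (xx - 55)^2) <= 3.75
  bridge <- yy == 32 & xx > 15 & xx < 55
  inten <- matrix(0, H, H)
  inten[d1 | d2] <- 1; inten[bridge & !(d1 | d2)] <- 0.3
  mb <- size_filter_erode(inten > 0.1, inten, cfg)
  expect_equal(nrow(mb$objects), 2)
  expect_true(all(mb$objects$equiv_diameter_um >= 0.5 &
                  mb$objects$equiv_diameter_um <= 7))
  expect_true(all(mb$objects$erosion_iters_applied >= 1))
})

test_that("pipeline recovers clean scenes exactly and degraded scenes within one object", {
  r <- render_stack(make_scene("clean", seed = 21))
  m <- fibis_pipeline(r$stack)
  truth <- r$truth$per_object
  expect_equal(nrow(m$objects), nrow(truth))
  # per-object centroid error <= 1 px against the true mask
  tm <- fibis:::measure_objects(r$truth$mask, 0.2)
  for (i in seq_len(nrow(m$objects))) {
    d <- sqrt((tm$centroid_y - m$objects$centroid_y[i])^2 +
              (tm$centroid_x - m$objects$centroid_x[i])^2)
    expect_lte(min(d), 1)
  }

  rb <- render_stack(make_scene("paper_benchmark", seed = 12))
  mb <- fibis_pipeline(rb$stack)
  expect_lte(abs(nrow(mb$objects) - nrow(rb$truth$per_object)), 1)

  # empty scene
  sc <- make_scene(list(objects = list(), preset = "clean"), seed = 1)
  re <- render_stack(sc)
  expect_equal(nrow(fibis_pipeline(re$stack)$objects), 0)
})

test_that("pipeline is deterministic and masks stay inside observed photons", {
  r <- render_stack(make_scene("paper_benchmark", seed = 5))
  m1 <- fibis_pipeline(r$stack)
  m2 <- fibis_pipeline(r$stack)
  expect_identical(m1$labels, m2$labels)
  acc <- apply(r$stack$frames, c(2, 3), sum)
  expect_true(all(acc[m1$labels > 0] > 0))
  # structured log records each stage
  expect_named(m1$log, c("normalize", "noise", "threshold", "size_filter",
                         "config"))
  expect_true(m1$log$noise$flagged)
})

test_that("removing a true object never increases the recovered count", {
  sc <- make_scene("paper_benchmark", seed = 14)
  n_full <- nrow(fibis_pipeline(render_stack(sc)$stack)$objects)
  sc_minus <- sc
  sc_minus$objects <- sc$objects[-1]
  n_minus <- nrow(fibis_pipeline(render_stack(sc_minus)$stack)$objects)
  expect_lte(n_minus, n_full)
})

test_that("baseline resolves clean scenes but fails on blur and stripes", {
  # clean well-separated scene: baseline matches FIBIS
  r <- render_stack(make_scene("clean", seed = 22))
  m <- fibis_pipeline(r$stack)
  bl <- baseline_raw_threshold(r$stack)
  expect_equal(nrow(bl$objects), nrow(m$objects))

  # motion blur: baseline merges distinct true objects into one component
  merged <- 0
  for (seed in 31:40) {
    rb <- render_stack(make_scene("blurred", seed = seed))
    blb <- baseline_raw_threshold(rb$stack)
    sel <- blb$labels > 0 & rb$truth$mask > 0
    if (any(sel)) {
      tab <- table(blb$labels[sel], rb$truth$mask[sel])
      if (any(rowSums(tab > 0) >= 2)) merged <- merged + 1
    }
  }
  expect_gte(merged, 1)

  # stripes: baseline foreground includes stripe pixels, FIBIS excludes >= 90%
  rs <- render_stack(make_scene("striped", seed = 51))
  ms <- fibis_pipeline(rs$stack)
  bs <- baseline_raw_threshold(rs$stack)
  off_object <- rs$truth$mask == 0
  base_stripe_px <- sum(bs$labels > 0 & off_object)
  fibis_stripe_px <- sum(ms$labels > 0 & off_object)
  expect_gt(base_stripe_px, 0)
  expect_lte(fibis_stripe_px, 0.1 * base_stripe_px)
})
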