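# Image-quality metrics (MSE, PSNR, SSIM, multi-scale SSIM) and the
# FIBIS-vs-baseline benchmark harness.
#
# Masks are compared as 0/255 images so the PSNR peak value L = 255 is
# meaningful for binary masks.

check_pair <- function(reference, sample) {
  stopifnot(is.matrix(reference), is.matrix(sample))
  if (!all(dim(reference) == dim(sample)))
    stop("shape mismatch: reference is ", paste(dim(reference), collapse = "x"),
         ", sample is ", paste(dim(sample), collapse = "x"))
}

#' Mean squared error between two images
#'
#' `(1 / (M N)) * sum_ij (R(i,j) - F(i,j))^2` over images of dimensions
#' M x N on a common intensity scale.
#'
#' @param reference,sample numeric matrices of identical dimensions.
#' @return scalar MSE (>= 0).
#' @export
mse <- function(reference, sample) {
  check_pair(reference, sample)
  mean((reference - sample)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(L^2 / MSE)`; identical images (MSE = 0) report `Inf`.
#'
#' @inheritParams mse
#' @param L maximum pixel value of the intensity scale, default 255.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, sample, L = 255) {
  stopifnot(L > 0)
  m <- mse(reference, sample)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

# Sliding-window sums over all fully interior w x w windows via an integral
# image; returns an (H-w+1) x (W-w+1) matrix.
box_sums <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

# Per-window SSIM component maps with a uniform w x w window and population
# moments. Returns list(l = luminance map, cs = contrast-structure map).
ssim_maps <- function(reference, sample, window, k1, k2, L) {
  n <- window^2
  mu_x <- box_sums(reference, window) / n
  mu_y <- box_sums(sample, window) / n
  sxx <- box_sums(reference^2, window) / n - mu_x^2
  syy <- box_sums(sample^2, window) / n - mu_y^2
  sxy <- box_sums(reference * sample, window) / n - mu_x * mu_y
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  list(l = (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1),
       cs = (2 * sxy + C2) / (sxx + syy + C2))
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over all fully interior sliding windows (uniform `window` x
#' `window` weights, population moments), with the standard stabilizers
#' `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#'
#' @inheritParams psnr
#' @param window side of the square sliding window, default 7.
#' @param k1,k2 stabilizer constants, defaults 0.01 and 0.03.
#' @return scalar SSIM in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(reference, sample, window = 7, k1 = 0.01, k2 = 0.03, L = 255) {
  check_pair(reference, sample)
  if (any(dim(reference) < window))
    stop("window (", window, ") larger than image (",
         paste(dim(reference), collapse = "x"), ")")
  maps <- ssim_maps(reference, sample, window, k1, k2, L)
  mean(maps$l * maps$cs)
}

# 2x2 block average downsampling (floors odd dimensions)
downsample2 <- function(m) {
  H <- nrow(m) %/% 2; W <- ncol(m) %/% 2
  m <- m[seq_len(2 * H), seq_len(2 * W), drop = FALSE]
  (m[seq(1, 2 * H, 2), seq(1, 2 * W, 2)] + m[seq(2, 2 * H, 2), seq(1, 2 * W, 2)] +
   m[seq(1, 2 * H, 2), seq(2, 2 * W, 2)] + m[seq(2, 2 * H, 2), seq(2, 2 * W, 2)]) / 4
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Contrast/structure terms are evaluated at each dyadic downsampling (2x2
#' block average between scales) and the luminance term at the coarsest
#' scale, combined with the canonical exponent weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333). Negative term means are clamped
#' to zero so the result stays in `[0, 1]`. If the image is too small for
#' the requested number of scales, the scale count is reduced with a warning
#' (weights renormalized); `scales = 1` reduces exactly to [ssim()].
#'
#' @inheritParams ssim
#' @param scales number of dyadic scales, default 5.
#' @param weights per-scale exponent weights; default the canonical five.
#' @return scalar MS-SSIM in `[0, 1]`.
#' @export
ms_ssim <- function(reference, sample, scales = 5,
                    weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                    window = 7, k1 = 0.01, k2 = 0.03, L = 255) {
  check_pair(reference, sample)
  max_scales <- max(1, floor(log2(min(dim(reference)) / window)) + 1)
  if (scales > max_scales) {
    warning("image too small for ", scales, " scales; reducing to ", max_scales)
    scales <- max_scales
  }
  if (length(weights) < scales)
    stop("need at least ", scales, " weights")
  w <- weights[seq_len(scales)]
  w <- w / sum(w)
  if (scales == 1) return(ssim(reference, sample, window, k1, k2, L))
  r <- reference; s <- sample
  val <- 1
  for (j in seq_len(scales)) {
    maps <- ssim_maps(r, s, window, k1, k2, L)
    if (j < scales) {
      val <- val * max(mean(maps$cs), 0)^w[j]
      r <- downsample2(r); s <- downsample2(s)
    } else {
      val <- val * max(mean(maps$l * maps$cs), 0)^w[j]
    }
  }
  val
}

mask_to_image <- function(labels, L = 255) {
  (labels > 0) * L
}

#' Benchmark FIBIS against the raw-intensity baseline
#'
#' For each synthetic acquisition, segments with both [fibis_pipeline()] and
#' [baseline_raw_threshold()] and scores each mask against the ground-truth
#' mask with MSE, PSNR, SSIM and MS-SSIM (masks compared as 0/255 images).
#' Reports per-trial rows, per-method means with standard errors, and the
#' mean relative improvement of FIBIS over the baseline per metric
#' (sign-oriented so that positive always means FIBIS is better).
#'
#' @param trials a list as returned by [benchmark_set()]: each element has
#'   `stack` and `truth` (or, for real data, `truth` replaced by a
#'   `reference` binary matrix).
#' @param config a [fibis_config()] shared by all trials.
#' @param L intensity scale for the mask images, default 255.
#' @return object of class `fibis_benchmark` with `table` (per trial and
#'   method), `summary` (means +/- s.e.m.) and `improvement_pct`.
#' @export
benchmark_similarity <- function(trials, config = fibis_config(), L = 255) {
  stopifnot(is.list(trials), length(trials) >= 2)
  rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    ref <- if (!is.null(tr$truth)) tr$truth$mask else tr$reference
    if (is.null(ref)) stop("trial ", i, " has no ground-truth or reference mask")
    ref_img <- mask_to_image(ref, L)
    for (method in c("fibis", "baseline")) {
      mask <- if (method == "fibis") fibis_pipeline(tr$stack, config)
              else baseline_raw_threshold(tr$stack, config$baseline_quantile)
      img <- mask_to_image(mask$labels, L)
      rows[[length(rows) + 1]] <- data.frame(
        trial = i, method = method,
        mse = mse(ref_img, img),
        psnr_db = psnr(ref_img, img, L),
        ssim = ssim(ref_img, img, L = L),
        ms_ssim = ms_ssim(ref_img, img, L = L)
      )
    }
  }
  tab <- do.call(rbind, rows)
  metrics <- c("mse", "psnr_db", "ssim", "ms_ssim")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(c("fibis", "baseline"), function(meth) {
      v <- tab[[m]][tab$method == meth]
      data.frame(metric = m, method = meth, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)))
    }))
  }))
  improvement <- vapply(metrics, function(m) {
    f <- mean(tab[[m]][tab$method == "fibis"])
    b <- mean(tab[[m]][tab$method == "baseline"])
    if (!is.finite(f) || !is.finite(b) || b == 0) return(NA_real_)
    if (m == "mse") 100 * (b - f) / b else 100 * (f - b) / b
  }, numeric(1))
  structure(list(table = tab, summary = summ, improvement_pct = improvement,
                 n_trials = length(trials),
                 params = list(L = L, window = 7, k1 = 0.01, k2 = 0.03,
                               config = unclass(config))),
            class = "fibis_benchmark")
}

#' @export
print.fibis_benchmark <- function(x, ...) {
  cat(sprintf("<fibis_benchmark> %d trials\n", x$n_trials))
  s <- x$summary
  for (m in unique(s$metric)) {
    f <- s[s$metric == m & s$method == "fibis", ]
    b <- s[s$metric == m & s$method == "baseline", ]
    cat(sprintf("  %-8s FIBIS %8.4g +/- %.3g | baseline %8.4g +/- %.3g | improvement %+.1f%%\n",
                m, f$mean, f$sem, b$mean, b$sem, x$improvement_pct[[m]]))
  }
  invisible(x)
}
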