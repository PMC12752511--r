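# Independent oracles used across test files. These deliberately use naive
# direct formulations (loops, explicit DFT) so they stay independent of the
# package's vectorized implementations.

# Direct complex-exponential DFT phasor of a histogram (bin centers)
oracle_phasor <- function(h, period_ns, harmonic = 1) {
  T_ <- length(h)
  z <- 0i
  for (k in seq_len(T_)) {
    t_k <- (k - 0.5) * period_ns / T_
    z <- z + h[k] * exp(1i * 2 * pi * harmonic * t_k / period_ns)
  }
  z <- z / sum(h)
  c(g = Re(z), s = Im(z))
}

# Brute-force Otsu: try every cut on an nbins histogram, maximize
# omega0*omega1*(mu0-mu1)^2 computed from raw values
oracle_otsu <- function(x, nbins = 256, limits = range(x)) {
  bw <- (limits[2] - limits[1]) / nbins
  best <- -Inf; best_t <- NA
  for (t_ in 1:(nbins - 1)) {
    cut <- limits[1] + t_ * bw
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best + 1e-15) { best <- v; best_t <- cut }
  }
  best_t
}

# Double-loop MSE
oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / (nrow(a) * ncol(a))
}

# Double-loop windowed SSIM (uniform window, population moments)
oracle_ssim <- function(a, b, window = 7, k1 = 0.01, k2 = 0.03, L = 255) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - window + 1)) {
    for (j in seq_len(ncol(a) - window + 1)) {
      wa <- a[i:(i + window - 1), j:(j + window - 1)]
      wb <- b[i:(i + window - 1), j:(j + window - 1)]
      mx <- mean(wa); my <- mean(wb)
      vx <- mean((wa - mx)^2); vy <- mean((wb - my)^2)
      cxy <- mean((wa - mx) * (wb - my))
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# Exhaustive two-sample KS statistic: sup ECDF difference over all points
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(p) abs(mean(a <= p) - mean(b <= p)), numeric(1)))
}

# Small synthetic stack where every pixel carries a scaled copy of one
# histogram (intensity pattern x histogram outer product)
uniform_histogram_stack <- function(h, H = 8, W = 8, rep_rate_hz = 8e7,
                                    pixel_size_um = 0.2, frames_n = 2) {
  T_ <- length(h)
  decay <- array(0L, dim = c(H, W, T_))
  for (k in seq_len(T_)) decay[, , k] <- as.integer(h[k])
  tot <- apply(decay, c(1, 2), sum)
  frames <- array(0L, dim = c(frames_n, H, W))
  frames[1, , ] <- as.integer(tot %/% frames_n + tot %% frames_n)
  for (f in seq_len(frames_n)[-1]) frames[f, , ] <- as.integer(tot %/% frames_n)
  tcspc_stack(frames, decay, rep_rate_hz, pixel_size_um)
}
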