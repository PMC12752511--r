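# Synthetic TCSPC FLIM acquisition generator with ground truth.
#
# Emulates NADH autofluorescence acquisitions: 256x256 px scans, 15
# accumulated frames at 80 MHz repetition, mitochondria as
# ellipse/capsule objects with a two-lifetime (free 0.4 ns / bound 3.4 ns)
# NADH decay mixture, Poisson photon statistics, per-frame linear object
# drift (motion blur in the accumulated image), a diffuse cytosolic
# background, and periodic laser-scanning line noise as a multiplicative
# column gain. The renderer conserves photons exactly between the per-frame
# intensity images and the accumulated decay histogram.

#' Expected histogram of a periodically excited mono-exponential decay
#'
#' Bin-integrated probability mass of a mono-exponential decay folded into
#' one laser period (steady-state periodic excitation), scaled to
#' `total` counts. The folding avoids truncation bias for lifetimes that do
#' not extinguish within a period (e.g. 3.4 ns at 80 MHz).
#'
#' @param tau_ns lifetime in ns; `0` yields a delta in the first bin.
#' @param period_ns laser period in ns, default 12.5 (80 MHz).
#' @param t_bins number of uniform time bins covering `[0, period_ns)`.
#' @param total total counts the histogram sums to, default 1.
#' @return numeric vector of length `t_bins`.
#' @export
decay_histogram <- function(tau_ns, period_ns = 12.5, t_bins = 256, total = 1) {
  stopifnot(tau_ns >= 0, period_ns > 0, t_bins >= 8)
  if (tau_ns == 0) {
    h <- numeric(t_bins); h[1] <- total
    return(h)
  }
  edges <- seq(0, period_ns, length.out = t_bins + 1)
  cdf <- (1 - exp(-edges / tau_ns)) / (1 - exp(-period_ns / tau_ns))
  diff(cdf) * total
}

#' Expected histogram of a free/bound NADH decay mixture
#'
#' Photon-weighted mixture of two folded mono-exponential decays:
#' `fb` is the fraction of photons from the bound (long-lifetime) species,
#' optionally scaled by a relative quantum yield `q` of the free species.
#'
#' @param fb bound-photon fraction in `[0, 1]`.
#' @param tau_free_ns,tau_bound_ns mixture component lifetimes in ns.
#' @param period_ns laser period in ns.
#' @param t_bins number of time bins.
#' @param total total counts.
#' @param q relative photon yield of the free species, default 1.
#' @return numeric vector of length `t_bins`.
#' @export
mixture_decay_histogram <- function(fb, tau_free_ns = 0.4, tau_bound_ns = 3.4,
                                    period_ns = 12.5, t_bins = 256, total = 1,
                                    q = 1) {
  stopifnot(fb >= 0, fb <= 1)
  wb <- fb
  wf <- (1 - fb) * q
  h <- wb * decay_histogram(tau_bound_ns, period_ns, t_bins) +
       wf * decay_histogram(tau_free_ns, period_ns, t_bins)
  h / sum(h) * total
}

#' Specify a synthetic FLIM scene
#'
#' Builds a fully specified scene from a named preset or an explicit
#' parameter record. Presets (all 256x256 px, 15 frames, 256 time bins,
#' 80 MHz, 0.2 um/px):
#' \describe{
#'   \item{clean}{8-12 objects, zero drift, stripes disabled, no diffuse
#'     background (fully undegraded control).}
#'   \item{blurred}{motion drift 3-8 px total over the acquisition, no stripes.}
#'   \item{striped}{scan-line stripes (period 8 px, amplitude 0.3), no drift.}
#'   \item{blurred_striped}{both degradations.}
#'   \item{paper_benchmark}{8-12 objects of 0.8-4 um, drift 3-8 px total,
#'     stripes period 8 px amplitude 0.3, diffuse background 0.4 of object
#'     peak, >= 1e4 expected photons per object.}
#' }
#' Object bound-NADH fractions are drawn uniformly in `[0.1, 0.9]`; the
#' diffuse background sits at a free-dominated 0.2.
#'
#' @param preset preset name, or a list of overrides for any scene field
#'   (`objects`, `background`, `noise`, `acquisition`).
#' @param seed integer seed; fully determines the scene and, through
#'   [render_stack()], the rendered acquisition.
#' @return an object of class `synth_scene`.
#' @export
make_scene <- function(preset = "paper_benchmark", seed = 1) {
  presets <- c("clean", "blurred", "striped", "blurred_striped", "paper_benchmark")
  overrides <- NULL
  if (is.list(preset)) {
    overrides <- preset
    preset <- overrides$preset %||% "paper_benchmark"
  }
  preset <- sub("\\+", "_", preset)
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; choose one of ",
         paste(presets, collapse = ", "))

  acq <- list(H = 256L, W = 256L, F = 15L, T = 256L,
              rep_rate_hz = 8e7, pixel_size_um = 0.2, seed = as.integer(seed),
              psf_sigma_px = 0.7)
  # "clean" is fully undegraded: no drift, no stripes, no diffuse background
  bg <- list(diffuse_level = if (preset == "clean") 0 else 0.4,
             background_bound_fraction = 0.2)
  noise <- list(stripe_period_px = 8, stripe_amplitude = 0.3,
                enabled = preset %in% c("striped", "blurred_striped",
                                        "paper_benchmark"))
  drift_on <- preset %in% c("blurred", "blurred_striped", "paper_benchmark")

  if (!is.null(overrides)) {
    for (fld in c("acquisition", "background", "noise")) {
      if (!is.null(overrides[[fld]])) {
        tgt <- switch(fld, acquisition = "acq", background = "bg", noise = "noise")
        cur <- get(tgt)
        cur[names(overrides[[fld]])] <- overrides[[fld]]
        assign(tgt, cur)
      }
    }
  }

  objects <- overrides$objects %||% with_seed(acq$seed, {
    n <- sample(8:12, 1)
    # constant surface brightness: every object shares one per-pixel photon
    # rate, sized so the smallest allowed object (0.8 um equivalent
    # diameter) still collects >= 1e4 photons over the acquisition; totals
    # then scale with object area, as for a homogeneous fluorophore.
    min_area_px <- pi * (0.8 / 2)^2 / acq$pixel_size_um^2
    peak_rate <- 1.2e4 / (acq$F * min_area_px)
    objs <- vector("list", n)
    placed_y <- numeric(0); placed_x <- numeric(0); placed_r <- numeric(0)
    sep_margin <- 12  # px: max total drift (8) + blur tails, keeps objects distinct
    for (i in seq_len(n)) {
      shape <- sample(c("ellipse", "capsule"), 1)
      # equivalent diameter 0.8-4 um
      d_um <- stats::runif(1, 0.8, 4)
      max_extent_um <- 6  # longest axis: mitochondria stay inside the 0.5-7 um gate
      if (shape == "ellipse") {
        ecc <- stats::runif(1, 1, 2.5)        # axis ratio
        ecc <- min(ecc, (max_extent_um / d_um)^2)
        b <- d_um / 2 / sqrt(ecc)             # semi-axes: a*b = (d/2)^2
        a <- b * ecc
        ang <- stats::runif(1, 0, pi)
        extent_px <- a / acq$pixel_size_um
      } else {
        width_um <- min(d_um * stats::runif(1, 0.35, 0.6), d_um)
        # capsule area = L*w + pi*(w/2)^2 = pi*(d/2)^2  =>  L
        area_um2 <- pi * (d_um / 2)^2
        len_um <- max((area_um2 - pi * (width_um / 2)^2) / width_um, 0.1)
        if (len_um + width_um > max_extent_um) {
          # too elongated: thicken to preserve area at the capped length
          width_um <- stats::uniroot(function(w)
            (max_extent_um - w) * w + pi * (w / 2)^2 - area_um2,
            c(1e-3, max_extent_um))$root
          len_um <- max_extent_um - width_um
        }
        ang <- stats::runif(1, 0, pi)
        extent_px <- (len_um / 2 + width_um / 2) / acq$pixel_size_um
      }
      # rejection-sample a centre whose extent (plus drift margin) stays
      # inside the field and clear of previously placed objects
      margin <- extent_px + 6
      center <- NULL
      for (try in seq_len(200)) {
        cand <- c(y = stats::runif(1, margin, acq$H - margin),
                  x = stats::runif(1, margin, acq$W - margin))
        clear <- all(sqrt((placed_y - cand[1])^2 + (placed_x - cand[2])^2) >
                       placed_r + extent_px + sep_margin)
        if (clear) { center <- cand; break }
      }
      if (is.null(center)) center <- cand  # crowded field: accept the overlap
      placed_y <- c(placed_y, center[1]); placed_x <- c(placed_x, center[2])
      placed_r <- c(placed_r, extent_px)
      if (shape == "ellipse") {
        geom <- list(axes_um = c(a, b), angle = ang)
      } else {
        half <- c(sin(ang), cos(ang)) * len_um / 2 / acq$pixel_size_um
        geom <- list(endpoints = rbind(center + half, center - half),
                     width_um = width_um)
      }
      if (drift_on) {
        total_drift <- stats::runif(1, 3, 8)
        theta <- stats::runif(1, 0, 2 * pi)
        drift <- c(sin(theta), cos(theta)) * total_drift / (acq$F - 1)
      } else drift <- c(0, 0)
      objs[[i]] <- list(shape = shape, center = center, geom = geom,
                        true_bound_fraction = stats::runif(1, 0.1, 0.9),
                        peak_photon_rate = peak_rate,
                        drift_px_per_frame = drift,
                        size_um = d_um)
    }
    objs
  })

  structure(list(preset = preset, objects = objects, background = bg,
                 noise = noise, acquisition = acq),
            class = "synth_scene")
}

#' @export
print.synth_scene <- function(x, ...) {
  cat(sprintf("<synth_scene> preset '%s': %d objects, %dx%d px, %d frames, %d bins, seed %d\n",
              x$preset, length(x$objects), x$acquisition$H, x$acquisition$W,
              x$acquisition$F, x$acquisition$T, x$acquisition$seed))
  cat(sprintf("  stripes: %s; diffuse background: %.2f of object peak\n",
              if (x$noise$enabled) sprintf("period %g px, amplitude %g",
                                           x$noise$stripe_period_px,
                                           x$noise$stripe_amplitude) else "off",
              x$background$diffuse_level))
  invisible(x)
}

# Unblurred object support indicator (H x W in [0,1]) at a drifted position.
object_support <- function(obj, H, W, pixel_size_um, offset = c(0, 0)) {
  y <- matrix(seq_len(H) - 0.5, H, W)
  x <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  cy <- obj$center["y"] + offset[1]
  cx <- obj$center["x"] + offset[2]
  if (obj$shape == "ellipse") {
    a <- obj$geom$axes_um[1] / pixel_size_um
    b <- obj$geom$axes_um[2] / pixel_size_um
    th <- obj$geom$angle
    u <- (y - cy) * cos(th) + (x - cx) * sin(th)
    v <- -(y - cy) * sin(th) + (x - cx) * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  } else {
    p1 <- obj$geom$endpoints[1, ] + offset
    p2 <- obj$geom$endpoints[2, ] + offset
    r <- obj$geom$width_um / 2 / pixel_size_um
    d <- p2 - p1
    len2 <- sum(d^2)
    t_ <- if (len2 > 0) clamp(((y - p1[1]) * d[1] + (x - p1[2]) * d[2]) / len2, 0, 1) else 0
    dy <- y - (p1[1] + t_ * d[1])
    dx <- x - (p1[2] + t_ * d[2])
    dy^2 + dx^2 <= r^2
  }
}

# Exact multinomial sampling of per-pixel totals over time bins with a shared
# probability vector, via sequential conditional binomials (vectorized over
# pixels).
sample_decay_bins <- function(totals, probs) {
  n_px <- length(totals)
  T_ <- length(probs)
  out <- matrix(0L, n_px, T_)
  remaining <- as.integer(totals)
  p_rem <- 1
  for (k in seq_len(T_ - 1)) {
    if (p_rem <= 0 || all(remaining == 0L)) break
    p_k <- min(probs[k] / p_rem, 1)
    draw <- stats::rbinom(n_px, remaining, p_k)
    out[, k] <- draw
    remaining <- remaining - draw
    p_rem <- p_rem - probs[k]
  }
  out[, T_] <- remaining
  out
}

#' Render a synthetic scene into a TCSPC acquisition with ground truth
#'
#' Per frame, each object is drawn at its drifted position (sub-resolution
#' optics stand-in: Gaussian blur of the support); the per-pixel expected
#' photon rate is split into free- and bound-lifetime channels, scan-line
#' stripes multiply the rate column-wise, and counts are drawn Poisson.
#' The accumulated decay histogram is obtained by distributing each
#' channel's realized per-pixel photon total across time bins with the
#' folded-exponential bin probabilities, so photon conservation between
#' frames and decay is exact. Fully deterministic given the scene seed.
#'
#' @param scene a [make_scene()] scene.
#' @param tau_free_ns,tau_bound_ns decay endpoints in ns, defaults 0.4 / 3.4.
#' @return list with `stack` (a [tcspc_stack()]) and `truth` (class
#'   `synth_truth`: `mask` label image of the true objects at their
#'   mid-acquisition position and `per_object` table with id,
#'   true_bound_fraction, true_size_um, total_photons).
#' @export
render_stack <- function(scene, tau_free_ns = 0.4, tau_bound_ns = 3.4) {
  stopifnot(inherits(scene, "synth_scene"))
  acq <- scene$acquisition
  H <- acq$H; W <- acq$W; F_ <- acq$F; T_ <- acq$T
  period_ns <- 1e9 / acq$rep_rate_hz

  with_seed(acq$seed + 77000L, {
    peaks <- vapply(scene$objects, function(o) o$peak_photon_rate, numeric(1))
    bg_rate <- if (length(peaks)) scene$background$diffuse_level * mean(peaks) else 0

    gain <- rep(1, W)
    if (scene$noise$enabled) {
      x0 <- seq_len(W) - 1          # 0-based column index
      gain <- 1 + scene$noise$stripe_amplitude *
        sin(2 * pi * x0 / scene$noise$stripe_period_px)
    }

    frames <- array(0L, dim = c(F_, H, W))
    n_free <- matrix(0L, H, W)
    n_bound <- matrix(0L, H, W)
    fb_bg <- scene$background$background_bound_fraction

    for (f in seq_len(F_)) {
      rate_free <- matrix(bg_rate * (1 - fb_bg), H, W)
      rate_bound <- matrix(bg_rate * fb_bg, H, W)
      for (o in scene$objects) {
        off <- (f - (F_ + 1) / 2) * o$drift_px_per_frame
        sup <- object_support(o, H, W, acq$pixel_size_um, off)
        if (!any(sup)) next
        prof <- gauss_blur(sup * o$peak_photon_rate, acq$psf_sigma_px)
        rate_free <- rate_free + prof * (1 - o$true_bound_fraction)
        rate_bound <- rate_bound + prof * o$true_bound_fraction
      }
      rate_free <- sweep(rate_free, 2, gain, `*`)
      rate_bound <- sweep(rate_bound, 2, gain, `*`)
      cf <- matrix(stats::rpois(H * W, rate_free), H, W)
      cb <- matrix(stats::rpois(H * W, rate_bound), H, W)
      frames[f, , ] <- cf + cb
      n_free <- n_free + cf
      n_bound <- n_bound + cb
    }

    p_free <- decay_histogram(tau_free_ns, period_ns, T_)
    p_bound <- decay_histogram(tau_bound_ns, period_ns, T_)
    decay <- sample_decay_bins(as.vector(n_free), p_free) +
             sample_decay_bins(as.vector(n_bound), p_bound)
    decay <- array(as.integer(decay), dim = c(H, W, T_))

    stack <- tcspc_stack(frames, decay, rep_rate_hz = acq$rep_rate_hz,
                         pixel_size_um = acq$pixel_size_um)

    # ground truth at the mid-acquisition position
    mask <- matrix(0L, H, W)
    per_object <- data.frame(id = integer(0), true_bound_fraction = numeric(0),
                             true_size_um = numeric(0), total_photons = numeric(0))
    for (i in seq_along(scene$objects)) {
      o <- scene$objects[[i]]
      sup <- object_support(o, H, W, acq$pixel_size_um)
      mask[sup] <- i
      tot <- n_free + n_bound
      px <- sup
      per_object <- rbind(per_object, data.frame(
        id = i, true_bound_fraction = o$true_bound_fraction,
        true_size_um = o$size_um,
        total_photons = sum(tot[px])))
    }
    truth <- structure(list(mask = mask, per_object = per_object),
                       class = "synth_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a reproducible set of benchmark acquisitions
#'
#' Renders `n_trials` independent scenes from one preset; trial i uses seed
#' `seed + i`, so the whole set is reproducible from a single seed.
#'
#' @param n_trials number of acquisitions (>= 1).
#' @param preset preset name passed to [make_scene()].
#' @param seed base integer seed.
#' @return list of `n_trials` elements, each `list(stack, truth, scene)`;
#'   a manifest `data.frame` (trial, seed, n_objects, preset) is attached as
#'   attribute `"manifest"`.
#' @export
benchmark_set <- function(n_trials, preset = "paper_benchmark", seed = 7) {
  stopifnot(n_trials >= 1)
  trials <- lapply(seq_len(n_trials), function(i) {
    scene <- make_scene(preset, seed = seed + i)
    r <- render_stack(scene)
    list(stack = r$stack, truth = r$truth, scene = scene)
  })
  attr(trials, "manifest") <- data.frame(
    trial = seq_len(n_trials),
    seed = seed + seq_len(n_trials),
    n_objects = vapply(trials, function(t) nrow(t$truth$per_object), integer(1)),
    preset = preset
  )
  trials
}
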