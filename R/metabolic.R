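# Per-mitochondrion free/bound NADH metabolic index along the phasor
# trajectory, ellipse outlier gating, pseudocolor rendering and group
# comparison.

#' Free/bound NADH trajectory configuration
#'
#' The metabolic trajectory is the chord between the pure free-NADH and pure
#' bound-NADH phasors on the universal semicircle; a mitochondrion's position
#' along it indexes glycolytic vs oxidative metabolism.
#'
#' @param tau_free_ns free-NADH endpoint lifetime in ns, default 0.4.
#' @param tau_bound_ns bound-NADH endpoint lifetime in ns, default 3.4.
#' @param rep_rate_hz pulse repetition rate in Hz, default 8e7.
#' @return an object of class `trajectory_config`.
#' @export
trajectory_config <- function(tau_free_ns = 0.4, tau_bound_ns = 3.4,
                              rep_rate_hz = 8e7) {
  stopifnot(tau_free_ns > 0, tau_free_ns < tau_bound_ns, rep_rate_hz > 0)
  structure(list(tau_free_ns = tau_free_ns, tau_bound_ns = tau_bound_ns,
                 rep_rate_hz = rep_rate_hz),
            class = "trajectory_config")
}

#' Intensity-weighted object phasors
#'
#' For every labeled object, the intensity-weighted mean of its valid
#' pixels' (g, s) coordinates. Objects with no valid pixel are dropped with
#' a warning.
#'
#' @param mask a `fibis_mask` (see [fibis_pipeline()]).
#' @param bundle a calibrated [phasor_bundle()] of the same dimensions.
#' @return data.frame with id, g_mean, s_mean, n_px, photons.
#' @export
object_phasor <- function(mask, bundle) {
  stopifnot(inherits(mask, "fibis_mask"), inherits(bundle, "phasor_bundle"))
  if (!all(dim(mask$labels) == dim(bundle$g)))
    stop("shape mismatch between mask and phasor bundle")
  if (!bundle$meta$calibrated)
    warning("phasor bundle is not calibrated; object phasors will be instrument-biased")
  ids <- mask$objects$id
  rows <- lapply(ids, function(id) {
    sel <- mask$labels == id & is.finite(bundle$g) & bundle$intensity > 0
    if (!any(sel)) return(NULL)
    w <- bundle$intensity[sel]
    data.frame(id = id,
               g_mean = sum(bundle$g[sel] * w) / sum(w),
               s_mean = sum(bundle$s[sel] * w) / sum(w),
               n_px = sum(sel), photons = sum(w))
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("dropped object(s) with no valid phasor pixels: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(0), g_mean = numeric(0), s_mean = numeric(0),
                      n_px = integer(0), photons = numeric(0))
  out
}

#' Bound-NADH fraction along the metabolic trajectory
#'
#' Projects a phasor orthogonally onto the chord between the pure free and
#' pure bound NADH phasors and returns the normalized position, clamped to
#' `[0, 1]`: 0 at the free endpoint, 1 at the bound endpoint. The free
#' fraction is `1 -` the returned value.
#'
#' @param g,s phasor coordinates (vectorized).
#' @param traj a [trajectory_config()].
#' @return bound fraction(s) in `[0, 1]`.
#' @export
fb_fraction <- function(g, s, traj = trajectory_config()) {
  stopifnot(inherits(traj, "trajectory_config"))
  pf <- single_exp_phasor(traj$tau_free_ns, traj$rep_rate_hz)
  pb <- single_exp_phasor(traj$tau_bound_ns, traj$rep_rate_hz)
  dg <- pb$g - pf$g; ds <- pb$s - pf$s
  len2 <- dg^2 + ds^2
  if (len2 <= 0) stop("degenerate trajectory: endpoints coincide")
  clamp(((g - pf$g) * dg + (s - pf$s) * ds) / len2, 0, 1)
}

#' Mahalanobis-ellipse outlier filter for phasor clouds
#'
#' Fits the mean and covariance of the (g, s) cloud and excludes points whose
#' squared Mahalanobis distance exceeds the chi-square quantile (2 degrees of
#' freedom) at the stated confidence — the "outside the ellipse" rule. For a
#' Gaussian cloud the expected exclusion rate is `1 - confidence`.
#'
#' @param g,s phasor coordinates of the cloud (>= 8 points), or `g` may be a
#'   two-column matrix.
#' @param confidence ellipse coverage, default 0.95.
#' @return list with `kept` and `excluded` index vectors, `outlier` logical
#'   vector, `d2` squared Mahalanobis distances, and `cutoff`.
#' @export
ellipse_outlier_filter <- function(g, s = NULL, confidence = 0.95) {
  if (is.matrix(g) && is.null(s)) { s <- g[, 2]; g <- g[, 1] }
  stopifnot(length(g) == length(s), confidence > 0, confidence < 1)
  if (length(g) < 8) stop("need at least 8 points to fit the outlier ellipse")
  pts <- cbind(g, s)
  mu <- colMeans(pts)
  Sigma <- stats::cov(pts)
  cutoff <- stats::qchisq(confidence, df = 2)
  if (!all(is.finite(Sigma)) || det(Sigma) <= .Machine$double.eps) {
    warning("singular phasor covariance; keeping all points")
    d2 <- rep(0, length(g))
    outlier <- rep(FALSE, length(g))
  } else {
    d2 <- stats::mahalanobis(pts, mu, Sigma)
    outlier <- d2 > cutoff
  }
  list(kept = which(!outlier), excluded = which(outlier),
       outlier = outlier, d2 = d2, cutoff = cutoff,
       center = mu, cov = Sigma)
}

#' Assemble per-mitochondrion records
#'
#' Combines segmentation geometry, object phasors, the bound-NADH fraction
#' and the ellipse outlier flag into one table (one row per mitochondrion),
#' ready for [write_object_table()]. Outlier gating is skipped (all kept)
#' when fewer than 8 objects are present.
#'
#' @param mask a `fibis_mask`.
#' @param bundle a calibrated [phasor_bundle()].
#' @param traj a [trajectory_config()].
#' @param group condition label stored with every record.
#' @param confidence ellipse confidence for outlier gating, default 0.95.
#' @return data.frame with columns id, group, area_px, size_um, centroid_y,
#'   centroid_x, g_mean, s_mean, fb_fraction, free_fraction, outlier_flag.
#' @export
mitochondrion_records <- function(mask, bundle, traj = trajectory_config(),
                                  group = "", confidence = 0.95) {
  op <- object_phasor(mask, bundle)
  geom <- mask$objects[match(op$id, mask$objects$id), ]
  fb <- fb_fraction(op$g_mean, op$s_mean, traj)
  outlier <- if (nrow(op) >= 8)
    ellipse_outlier_filter(op$g_mean, op$s_mean, confidence)$outlier
  else rep(FALSE, nrow(op))
  data.frame(id = op$id, group = group,
             area_px = geom$area_px,
             size_um = geom$equiv_diameter_um,
             centroid_y = geom$centroid_y, centroid_x = geom$centroid_x,
             g_mean = op$g_mean, s_mean = op$s_mean,
             fb_fraction = fb, free_fraction = 1 - fb,
             outlier_flag = outlier)
}

#' Pseudocolor map of per-mitochondrion bound fractions
#'
#' Paints each segmented object with the color its bound-NADH fraction maps
#' to in a monotone colormap over `[0, 1]`; background is black. Objects
#' without a record are painted grey with a warning.
#'
#' @param mask a `fibis_mask`.
#' @param records a [mitochondrion_records()] table (columns id, fb_fraction).
#' @param colormap character vector of colors spanning fractions 0 to 1;
#'   default 256 viridis colors.
#' @return an `H x W x 3` RGB array in `[0, 1]` with the palette attached as
#'   attribute `"colorbar"`.
#' @export
pseudocolor_map <- function(mask, records,
                            colormap = grDevices::hcl.colors(256, "viridis")) {
  stopifnot(inherits(mask, "fibis_mask"), is.data.frame(records))
  n <- length(colormap)
  rgb_pal <- t(grDevices::col2rgb(colormap)) / 255
  H <- nrow(mask$labels); W <- ncol(mask$labels)
  out <- array(0, dim = c(H, W, 3))
  ids <- mask$objects$id
  missing_ids <- setdiff(ids, records$id)
  if (length(missing_ids))
    warning("no record for object(s) ", paste(missing_ids, collapse = ", "),
            "; painted grey")
  for (id in ids) {
    sel <- mask$labels == id
    if (id %in% records$id) {
      f <- records$fb_fraction[match(id, records$id)]
      col <- rgb_pal[1 + round(clamp(f, 0, 1) * (n - 1)), ]
    } else col <- c(0.5, 0.5, 0.5)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- col[ch]
      out[, , ch] <- plane
    }
  }
  attr(out, "colorbar") <- colormap
  out
}

#' Compare bound-fraction distributions between two groups
#'
#' Two-sample Kolmogorov-Smirnov test (exact supremum ECDF difference,
#' asymptotic p-value) plus the quartile summaries used for boxplots.
#'
#' @param a,b numeric vectors of per-mitochondrion fractions (n >= 5 each).
#' @return object of class `fibis_group_compare` with `ks_statistic`,
#'   `p_value`, `n_a`, `n_b`, `medians` and `quartiles`.
#' @export
group_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5 || length(b) < 5)
    stop("need at least 5 observations per group")
  kt <- suppressWarnings(stats::ks.test(a, b))
  structure(list(
    ks_statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n_a = length(a), n_b = length(b),
    medians = c(a = stats::median(a), b = stats::median(b)),
    quartiles = rbind(a = stats::quantile(a, c(0.25, 0.5, 0.75)),
                      b = stats::quantile(b, c(0.25, 0.5, 0.75)))
  ), class = "fibis_group_compare")
}

#' @export
print.fibis_group_compare <- function(x, ...) {
  cat(sprintf("<group_compare> two-sample KS: D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$ks_statistic, x$p_value, x$n_a, x$n_b))
  cat(sprintf("  medians: %.4f vs %.4f\n", x$medians["a"], x$medians["b"]))
  invisible(x)
}
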