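# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components of a binary image
#'
#' Labels foreground pixels (value > 0) of a binary matrix into 8-connected
#' components. Labels are assigned in raster order of each component's first
#' pixel, starting at 1; background is 0.
#'
#' Uses a run-based two-pass union-find: foreground runs are extracted per
#' row and merged with overlapping (or diagonally touching) runs of the
#' previous row.
#'
#' @param binary logical or numeric matrix; pixels > 0 are foreground.
#' @return integer matrix of the same dimensions with component labels.
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  fg <- binary > 0
  H <- nrow(fg); W <- ncol(fg)
  labels <- matrix(0L, H, W)
  if (!any(fg)) return(labels)

  parent <- integer(0)
  ufind <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  uunion <- function(a, b) {
    ra <- ufind(a); rb <- ufind(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }

  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  prev <- integer(0)  # indices of previous row's runs
  for (y in seq_len(H)) {
    v <- fg[y, ]
    if (!any(v)) { prev <- integer(0); next }
    d <- diff(c(0L, as.integer(v), 0L))
    s <- which(d == 1L)
    e <- which(d == -1L) - 1L
    idx <- length(parent) + seq_along(s)
    parent <- c(parent, idx)
    run_row <- c(run_row, rep.int(y, length(s)))
    run_s <- c(run_s, s)
    run_e <- c(run_e, e)
    # 8-connectivity: runs touch if column spans overlap after 1-px widening
    for (k in seq_along(s)) {
      for (j in prev) {
        if (run_s[j] <= e[k] + 1L && run_e[j] >= s[k] - 1L) uunion(idx[k], j)
      }
    }
    prev <- idx
  }

  roots <- vapply(seq_along(parent), ufind, integer(1))
  # compact labels in raster order of first appearance
  first <- !duplicated(roots)
  remap <- integer(length(parent))
  remap[roots[first]] <- seq_len(sum(first))
  lab_of_run <- remap[roots]
  for (r in seq_along(run_s)) {
    labels[run_row[r], run_s[r]:run_e[r]] <- lab_of_run[r]
  }
  labels
}

# Geometry of labeled objects. Returns a data.frame with one row per label:
# id, area_px, equiv_diameter_um, major_axis_um, centroid_y, centroid_x
# (0-based pixel coordinates, origin top-left, y increasing downward).
measure_objects <- function(labels, pixel_size_um) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    return(data.frame(id = integer(0), area_px = integer(0),
                      equiv_diameter_um = numeric(0), major_axis_um = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0)))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  y <- ((idx - 1L) %% nrow(labels))      # 0-based row
  x <- ((idx - 1L) %/% nrow(labels))     # 0-based col
  f <- factor(lab, levels = ids)
  area <- as.integer(tabulate(f, nbins = length(ids)))
  cy <- as.numeric(tapply(y, f, mean))
  cx <- as.numeric(tapply(x, f, mean))
  # major axis from second central moments (regionprops convention)
  syy <- as.numeric(tapply(y, f, stats::var)) * (area - 1) / area
  sxx <- as.numeric(tapply(x, f, stats::var)) * (area - 1) / area
  sxy <- mapply(function(i) {
    sel <- lab == ids[i]
    if (sum(sel) < 2) return(0)
    mean((y[sel] - cy[i]) * (x[sel] - cx[i]))
  }, seq_along(ids))
  syy[is.na(syy)] <- 0; sxx[is.na(sxx)] <- 0
  # +1/12 accounts for unit-square pixel extent; keeps 1-px objects finite
  syy <- syy + 1 / 12; sxx <- sxx + 1 / 12
  tr <- syy + sxx
  det_ <- syy * sxx - sxy^2
  lam1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det_, 0))
  data.frame(
    id = as.integer(ids),
    area_px = area,
    equiv_diameter_um = 2 * sqrt(area / pi) * pixel_size_um,
    major_axis_um = 4 * sqrt(lam1) * pixel_size_um,
    centroid_y = cy,
    centroid_x = cx
  )
}

# Boundary pixels of a binary mask: foreground pixels with at least one
# 8-neighbour outside the mask (image border counts as outside).
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(FALSE, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- padded[2:(H + 1L), 2:(W + 1L)]
  all_nb <- inner
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    all_nb <- all_nb & padded[(2 + dy):(H + 1L + dy), (2 + dx):(W + 1L + dx)]
  }
  mask & !all_nb
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fftshift / ifftshift for matrices (move DC to the centre and back)
fftshift <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c((floor(H / 2) + 1):H, 1:floor(H / 2)),
    c((floor(W / 2) + 1):W, 1:floor(W / 2)), drop = FALSE]
}

ifftshift <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c((ceiling(H / 2) + 1):H, 1:ceiling(H / 2)),
    c((ceiling(W / 2) + 1):W, 1:ceiling(W / 2)), drop = FALSE]
}

# Separable Gaussian blur with renormalised edge handling (kernel radius 3*sigma)
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1L & j <= n
      m[cbind(i[ok], j[ok])] <- k[d + r + 1L]
    }
    m / rowSums(m)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
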