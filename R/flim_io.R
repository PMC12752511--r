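# On-disk representations: TCSPC stacks (multipage TIFF + JSON sidecar),
# phasor bundles (self-describing named-array container), object tables
# (CSV) and label masks (16-bit TIFF).
#
# Pixel convention everywhere: 0-based coordinates, row-major, origin
# top-left, y increases downward.

#' Create a TCSPC acquisition stack
#'
#' Holds the per-frame intensity images and the accumulated per-pixel photon
#' arrival-time histogram of one FLIM acquisition, plus acquisition metadata.
#' Counts must be non-negative integers; when both `frames` and `decay` are
#' populated, each pixel's decay total must equal its total across frames
#' (photon conservation).
#'
#' @param frames integer array `[F x H x W]` of per-frame photon counts.
#' @param decay integer array `[H x W x T]` of accumulated arrival-time
#'   counts.
#' @param rep_rate_hz pulse repetition rate in Hz (period_ns = 1e9 / rate).
#' @param pixel_size_um physical pixel size in um/px.
#' @param check_conservation verify photon conservation (default `TRUE`).
#' @return an object of class `tcspc_stack`.
#' @export
tcspc_stack <- function(frames, decay, rep_rate_hz, pixel_size_um,
                        check_conservation = TRUE) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            is.array(decay), length(dim(decay)) == 3,
            rep_rate_hz > 0, pixel_size_um > 0)
  if (!all(dim(frames)[2:3] == dim(decay)[1:2]))
    stop("shape error: frames are ", paste(dim(frames)[2:3], collapse = "x"),
         " but decay is ", paste(dim(decay)[1:2], collapse = "x"))
  if (any(frames < 0) || any(decay < 0)) stop("data error: negative counts")
  if (any(frames != round(frames)) || any(decay != round(decay)))
    stop("data error: counts must be integral")
  if (check_conservation) {
    frame_tot <- apply(frames, c(2, 3), sum)
    decay_tot <- apply(decay, c(1, 2), sum)
    if (!all(frame_tot == decay_tot))
      stop("photon conservation violated: per-pixel frame totals differ from decay totals")
  }
  structure(list(frames = frames, decay = decay,
                 period_ns = 1e9 / rep_rate_hz,
                 rep_rate_hz = rep_rate_hz,
                 pixel_size_um = pixel_size_um,
                 t_bins = dim(decay)[3]),
            class = "tcspc_stack")
}

#' @export
print.tcspc_stack <- function(x, ...) {
  cat(sprintf("<tcspc_stack> %d frames of %d x %d px, %d time bins\n",
              dim(x$frames)[1], dim(x$decay)[1], dim(x$decay)[2], x$t_bins))
  cat(sprintf("  rep rate %.4g MHz (period %.4g ns), pixel %.3g um, total photons %.4g\n",
              x$rep_rate_hz / 1e6, x$period_ns, x$pixel_size_um, sum(x$decay)))
  invisible(x)
}

#' Write a TCSPC stack as multipage TIFF + JSON sidecar
#'
#' Pages are the F intensity frames followed by the T decay planes, stored
#' as 16-bit unsigned TIFF; the sidecar (same basename, `.json`) carries
#' `rep_rate_hz`, `pixel_size_um`, `F`, `T`, `H`, `W`. Counts are preserved
#' bit-exactly (values above 65535 are refused).
#'
#' @param stack a [tcspc_stack()].
#' @param path output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_tcspc_stack <- function(stack, path) {
  stopifnot(inherits(stack, "tcspc_stack"))
  F_ <- dim(stack$frames)[1]; T_ <- stack$t_bins
  if (max(stack$frames) > 65535 || max(stack$decay) > 65535)
    stop("counts exceed the 16-bit TIFF range")
  pages <- c(lapply(seq_len(F_), function(f) stack$frames[f, , ] / 65535),
             lapply(seq_len(T_), function(k) stack$decay[, , k] / 65535))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(rep_rate_hz = stack$rep_rate_hz,
                            pixel_size_um = stack$pixel_size_um,
                            F = F_, T = T_,
                            H = dim(stack$decay)[1], W = dim(stack$decay)[2]),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TCSPC stack written by [write_tcspc_stack()]
#'
#' @param path `.tif`/`.tiff` path; the JSON sidecar must sit next to it.
#' @return a validated [tcspc_stack()].
#' @export
read_tcspc_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: missing JSON sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (fld in c("rep_rate_hz", "pixel_size_um", "F", "T"))
    if (is.null(meta[[fld]])) stop("format error: sidecar lacks '", fld, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  F_ <- meta$F; T_ <- meta$T
  if (length(pages) != F_ + T_)
    stop("shape error: TIFF has ", length(pages), " pages, sidecar declares F+T = ",
         F_ + T_)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  frames <- array(0L, dim = c(F_, H, W))
  for (f in seq_len(F_)) frames[f, , ] <- as.integer(round(pages[[f]] * 65535))
  decay <- array(0L, dim = c(H, W, T_))
  for (k in seq_len(T_)) decay[, , k] <- as.integer(round(pages[[F_ + k]] * 65535))
  if (any(frames < 0) || any(decay < 0)) stop("data error: negative counts")
  subsampled <- isTRUE(meta$decay_subsampled)
  out <- tryCatch(
    tcspc_stack(frames, decay, meta$rep_rate_hz, meta$pixel_size_um,
                check_conservation = !subsampled),
    error = function(e) stop(conditionMessage(e), call. = FALSE))
  if (subsampled) {
    frame_tot <- apply(frames, c(2, 3), sum)
    decay_tot <- apply(decay, c(1, 2), sum)
    if (!all(frame_tot == decay_tot))
      warning("photon totals differ between frames and (subsampled) decay")
  }
  out
}

# --- phasor bundle container -------------------------------------------------
# Self-describing single-file named-array container: ASCII magic, a 4-byte
# little-endian header length, a JSON header listing datasets {name, dims}
# and the bundle metadata, then the float64 little-endian payloads in order.
PB_MAGIC <- charToRaw("FIBISPB1")

#' Write a phasor bundle to the named-array container format
#'
#' Stores the `g`, `s` and `intensity` arrays as float64 with a JSON header
#' carrying their dimensions and the bundle metadata. Round-trips are
#' lossless at double precision.
#'
#' @param bundle a [phasor_bundle()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phasor_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "phasor_bundle"))
  datasets <- list(
    list(name = "g", dims = dim(bundle$g)),
    list(name = "s", dims = dim(bundle$s)),
    list(name = "intensity", dims = dim(bundle$intensity))
  )
  header <- jsonlite::toJSON(list(datasets = datasets, meta = bundle$meta),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             na = "null")
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(PB_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (nm in c("g", "s", "intensity"))
    writeBin(as.numeric(bundle[[nm]]), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a phasor bundle from the named-array container format
#'
#' @param path file written by [write_phasor_bundle()].
#' @return a [phasor_bundle()].
#' @export
read_phasor_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(PB_MAGIC))
  if (!identical(magic, PB_MAGIC))
    stop("format error: not a phasor bundle container")
  hlen <- readBin(con, "integer", 1, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  ds <- header$datasets
  need <- c("g", "s", "intensity")
  if (is.null(ds) || !all(need %in% ds$name))
    stop("format error: container lacks dataset(s) ",
         paste(setdiff(need, ds$name), collapse = ", "))
  arrays <- list()
  for (i in seq_len(nrow(ds))) {
    dims <- unlist(ds$dims[[i]])
    arrays[[ds$name[i]]] <- matrix(readBin(con, "numeric", prod(dims), size = 8L,
                                           endian = "little"),
                                   dims[1], dims[2])
  }
  meta <- header$meta
  phasor_bundle(arrays$g, arrays$s, arrays$intensity,
                rep_rate_hz = meta$rep_rate_hz,
                harmonic = meta$harmonic %||% 1,
                calibrated = isTRUE(meta$calibrated),
                reference_lifetime_ns = meta$reference_lifetime_ns %||% NA_real_)
}

# --- object tables -----------------------------------------------------------

OBJECT_TABLE_COLUMNS <- c("id", "group", "area_px", "size_um", "centroid_y",
                          "centroid_x", "g_mean", "s_mean", "fb_fraction",
                          "outlier_flag")

#' Write per-mitochondrion records to CSV
#'
#' Fixed column order (id, group, area_px, size_um, centroid_y, centroid_x,
#' g_mean, s_mean, fb_fraction, outlier_flag), header row, UTF-8, "."
#' decimal separator. An empty record set writes a header-only file.
#'
#' @param records data.frame from [mitochondrion_records()] (extra columns
#'   are dropped).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(OBJECT_TABLE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[, OBJECT_TABLE_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an object table written by [write_object_table()]
#'
#' @param path CSV path.
#' @return data.frame in the fixed column order.
#' @export
read_object_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(out), OBJECT_TABLE_COLUMNS))
    stop("format error: unexpected object-table columns")
  out
}

# --- label masks -------------------------------------------------------------

#' Write a label mask as 16-bit TIFF
#'
#' @param labels integer label matrix (0 = background) or a `fibis_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(labels, path) {
  if (inherits(labels, "fibis_mask")) labels <- labels$labels
  stopifnot(is.matrix(labels), all(labels >= 0), max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
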