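#' Normalize a spectrometer frame against its white-reference pixels
#'
#' Per-pixel reflectance is the pixel's digital number divided by the mean
#' digital number of the frame's reference-panel pixels in the same channel.
#' The division cancels any multiplicative factor shared by targets and
#' references (frame-level illumination). Reference pixels are excluded
#' from the output rows.
#'
#' @param frame a `spectral_frame`.
#' @return list with `pixels` (target pixel indices), `angles` (their
#'   center angles, degrees) and `reflectance` (matrix, one row per target
#'   pixel, one column per channel).
#' @export
normalize_frame <- function(frame) {
  stopifnot(inherits(frame, "spectral_frame"))
  ref <- frame$dn[frame$reference_pixels, , drop = FALSE]
  ref_mean <- colMeans(ref)
  bad <- which(ref_mean <= 0)
  if (length(bad) > 0)
    stop("non-positive reference mean in channel ", bad[1],
         " (", colnames(frame$dn)[bad[1]], ")")
  target <- setdiff(seq_len(nrow(frame$dn)), frame$reference_pixels)
  refl <- sweep(frame$dn[target, , drop = FALSE], 2, ref_mean, "/")
  list(pixels = target, angles = frame$pixel_angles[target],
       reflectance = refl)
}

#' Associate laser points with spectrometer pixels
#'
#' The overlap test mirrors the acquisition geometry: first along track
#' (horizontal) as a time window around each frame, then vertically by
#' elevation angle. A pixel is associated with a point iff
#' `|t_point - t_frame| <= horizontal_window` and the point's elevation
#' angle from the frame pose lies within the pixel's angular interval
#' widened by `footprint_deg / 2`. A point inside the overlap of two
#' widened intervals is associated with both pixels. Reference pixels never
#' match.
#'
#' @param points data.frame with columns `x`, `y`, `z`, `t`.
#' @param frames list of `spectral_frame` objects.
#' @param horizontal_window seconds; default half the frame interval.
#' @param footprint_deg angular widening; default 0.25 degrees, the laser
#'   scanner's angular resolution.
#' @return data.frame with columns `point` (row index into `points`),
#'   `frame` (frame index) and `pixel` (pixel index); zero rows when
#'   nothing matches.
#' @export
match_points_to_frames <- function(points, frames,
                                   horizontal_window = NULL,
                                   footprint_deg = 0.25) {
  empty <- data.frame(point = integer(), frame = integer(),
                      pixel = integer())
  if (length(frames) == 0L || nrow(points) == 0L) return(empty)
  frame_t <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (is.null(horizontal_window)) {
    horizontal_window <- if (length(frame_t) > 1)
      min(diff(sort(frame_t))) / 2 else 0.25
  }
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    sel <- which(abs(points$t - fr$timestamp) <= horizontal_window)
    if (length(sel) == 0L) next
    centers <- fr$pixel_angles
    spacing <- centers[2] - centers[1]
    w <- spacing / 2 + footprint_deg / 2
    dy <- points$y[sel] - fr$pose[2]
    ang <- atan2(points$z[sel] - fr$sensor_height, dy) * 180 / pi
    lo <- ceiling((ang - w - centers[1]) / spacing - 1e-9) + 1L
    hi <- floor((ang + w - centers[1]) / spacing + 1e-9) + 1L
    max_target <- min(fr$reference_pixels) - 1L
    lo <- pmax(lo, 1L)
    hi <- pmin(hi, max_target)
    n_px <- hi - lo + 1L
    keep <- n_px > 0L
    if (!any(keep)) next
    out[[f]] <- data.frame(
      point = rep(sel[keep], n_px[keep]),
      frame = f,
      pixel = sequence(n_px[keep], from = lo[keep]))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

#' Fuse laser points with normalized hyperspectral pixels
#'
#' Builds, per specimen, the fused data structure: the original point cloud
#' with a normalized reflectance spectrum attached to every point that
#' overlapped at least one spectrometer pixel. When several pixels (from
#' one or several frames) fall within a single laser point, their
#' reflectance rows are averaged unweighted.
#'
#' @param points labelled point table
#'   (`specimen_id,species,habit,x,y,z,t`), e.g. from [points_table()].
#' @param frames list of `spectral_frame` objects.
#' @param bs a [band_set()].
#' @param horizontal_window,footprint_deg see [match_points_to_frames()].
#' @return list of `fused_cloud` objects, one per specimen: `specimen_id`,
#'   `species`, `habit`, `points` (with an `n_pixels` column) and
#'   `reflectance` (matrix with one row per point, `NA` rows for points
#'   without spectra).
#' @export
fuse <- function(points, frames, bs, horizontal_window = NULL,
                 footprint_deg = 0.25) {
  stopifnot(nrow(points) > 0)
  n_ch <- length(bs)
  normed <- lapply(frames, normalize_frame)
  assoc <- match_points_to_frames(points, frames, horizontal_window,
                                  footprint_deg)

  sums <- matrix(0, nrow(points), n_ch)
  n_pix <- integer(nrow(points))
  if (nrow(assoc) > 0) {
    for (f in unique(assoc$frame)) {
      a <- assoc[assoc$frame == f, , drop = FALSE]
      rows <- match(a$pixel, normed[[f]]$pixels)
      part <- rowsum(normed[[f]]$reflectance[rows, , drop = FALSE], a$point)
      idx <- as.integer(rownames(part))
      sums[idx, ] <- sums[idx, ] + part
      cnt <- table(a$point)
      n_pix[as.integer(names(cnt))] <- n_pix[as.integer(names(cnt))] +
        as.integer(cnt)
    }
  }
  refl <- matrix(NA_real_, nrow(points), n_ch,
                 dimnames = list(NULL, names(bs)))
  has <- n_pix > 0L
  refl[has, ] <- sums[has, , drop = FALSE] / n_pix[has]

  ids <- unique(points$specimen_id)
  lapply(ids, function(id) {
    sel <- which(points$specimen_id == id)
    pts <- points[sel, c("x", "y", "z", "t"), drop = FALSE]
    pts$n_pixels <- n_pix[sel]
    rownames(pts) <- NULL
    structure(list(specimen_id = id,
                   species = points$species[sel[1]],
                   habit = points$habit[sel[1]],
                   points = pts,
                   reflectance = refl[sel, , drop = FALSE]),
              class = "fused_cloud")
  })
}

#' @export
print.fused_cloud <- function(x, ...) {
  n_spec <- sum(x$points$n_pixels > 0)
  cat(sprintf("<fused_cloud #%s> %s (%s): %d points, %d with spectra (%.0f%%)\n",
              x$specimen_id, x$species, x$habit, nrow(x$points), n_spec,
              100 * n_spec / nrow(x$points)))
  invisible(x)
}

#' Split fused specimens into the two classification datasets
#'
#' The separation dataset (conifer vs broadleaf) keeps every specimen with
#' a habit label, including unidentified species. The species dataset keeps
#' only identified species represented by at least `min_count` specimens
#' (default five, the inventory threshold that yields 133 specimens of 10
#' species from the full 168-specimen garden).
#'
#' @param specimens list of `fused_cloud` (or any objects with `species`
#'   and `habit` fields).
#' @param min_count minimum specimens per species for the species task.
#' @return list with `separation` and `species` specimen lists.
#' @export
build_datasets <- function(specimens, min_count = 5L) {
  habit <- vapply(specimens, function(s) s$habit, character(1))
  species <- vapply(specimens, function(s) s$species, character(1))
  separation <- specimens[habit %in% c("coniferous", "deciduous")]
  identified <- species != "unidentified" & !is.na(species)
  counts <- table(species[identified])
  keep_species <- names(counts)[counts >= min_count]
  list(separation = separation,
       species = specimens[identified & species %in% keep_species])
}

#' Write a fused specimen list as CSV
#'
#' Layout `specimen_id,x,y,z,t,n_pixels,ch001..ch123`; channel cells are
#' empty for points without spectra.
#'
#' @param clouds list of `fused_cloud` objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_fused_csv <- function(clouds, path) {
  rows <- lapply(clouds, function(cl)
    cbind(data.frame(specimen_id = cl$specimen_id,
                     cl$points[, c("x", "y", "z", "t", "n_pixels")]),
          as.data.frame(cl$reflectance)))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}
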