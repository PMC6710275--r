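#' Nuclear segmentation parameters
#'
#' The six tunable features used to segment and filter nuclei from the
#' counterstain: size bounds, roundness, mean intensity, the contrast
#' threshold of the foreground split, and a segmentation aggressiveness
#' controlling how readily touching nuclei are divided.
#'
#' The foreground threshold is Otsu-initialized and scaled by
#' `contrast_threshold`: threshold = 2 * contrast_threshold * Otsu, so 0.5
#' reproduces the plain Otsu split, lower values admit dimmer pixels.
#' `aggressiveness` maps linearly to the h-minima suppression depth of the
#' distance-transform watershed: depth = (1 - aggressiveness) * max distance,
#' so 0 never splits a connected blob and values near 1 split at the
#' shallowest saddle.
#'
#' The numeric filter defaults (area 15-250 um^2, roundness >= 0.3, mean
#' intensity >= 0.05) are configuration, not constants of the method.
#'
#' @param min_nuclear_area_um2,max_nuclear_area_um2 Area bounds, um^2.
#' @param min_roundness Minimum isoperimetric roundness `4*pi*A/P^2`,
#'   in `[0, 1]`.
#' @param min_mean_intensity Minimum mean counterstain intensity, `[0, 1]`.
#' @param contrast_threshold Foreground contrast scale, `[0, 1]`.
#' @param aggressiveness Watershed splitting aggressiveness, `[0, 1]`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(min_nuclear_area_um2 = 15,
                                max_nuclear_area_um2 = 250,
                                min_roundness = 0.3,
                                min_mean_intensity = 0.05,
                                contrast_threshold = 0.5,
                                aggressiveness = 0.5) {
  if (min_nuclear_area_um2 <= 0 || max_nuclear_area_um2 <= min_nuclear_area_um2) {
    stop("need 0 < min_nuclear_area_um2 < max_nuclear_area_um2")
  }
  for (nm in c("min_roundness", "min_mean_intensity", "contrast_threshold",
               "aggressiveness")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) stop(sprintf("`%s` must lie in [0, 1]", nm))
  }
  structure(list(min_nuclear_area_um2 = min_nuclear_area_um2,
                 max_nuclear_area_um2 = max_nuclear_area_um2,
                 min_roundness = min_roundness,
                 min_mean_intensity = min_mean_intensity,
                 contrast_threshold = contrast_threshold,
                 aggressiveness = aggressiveness),
            class = "segmentation_params")
}

# perimeter of a binary mask from its marching-squares contour, lightly
# smoothed (circular moving average, window 3) to undo the staircase bias
# that would otherwise depress the roundness of circular nuclei
mask_perimeter_px <- function(mask) {
  p <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  cl <- grDevices::contourLines(x = seq_len(nrow(p)), y = seq_len(ncol(p)),
                                z = p, levels = 0.5)
  if (length(cl) == 0) return(0)
  w <- 3L
  lens <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    n <- length(x)
    closed <- n > 3 && abs(x[1] - x[n]) < 1e-9 && abs(y[1] - y[n]) < 1e-9
    if (closed && n - 1 > 2 * w) {
      x <- x[-n]; y <- y[-n]; n <- n - 1L
      sm <- function(v) {
        f <- stats::filter(c(v, v, v), rep(1 / w, w))
        as.numeric(f[(n + 1):(2 * n)])
      }
      x <- sm(x); y <- sm(y)
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1))
  max(lens)
}

#' Morphometric features of one nucleus mask
#'
#' @param mask Logical (or 0/1) matrix marking the nucleus pixels, same
#'   shape as `counterstain`.
#' @param counterstain Normalized counterstain image.
#' @param pixel_size_um Micrometres per pixel.
#' @return List with `area_um2` (pixel count x pixel_size^2), `roundness`
#'   (isoperimetric quotient `4*pi*A/P^2`, capped at 1), `mean_intensity`
#'   (mean counterstain over the mask) and `centroid_um` (unweighted
#'   geometric centre, pixel-centre convention).
#' @export
compute_morphometrics <- function(mask, counterstain, pixel_size_um) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- mask > 0
  npx <- sum(mask)
  if (npx == 0) stop("empty mask")
  if (!identical(dim(mask), dim(counterstain))) {
    stop("`mask` and `counterstain` must have the same shape")
  }
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  idx <- which(mask, arr.ind = TRUE)
  # crop to the bounding box before tracing the contour
  ri <- range(idx[, 1]); rj <- range(idx[, 2])
  sub <- mask[ri[1]:ri[2], rj[1]:rj[2], drop = FALSE]
  per_px <- mask_perimeter_px(sub * 1)
  area_px <- npx
  roundness <- if (per_px > 0) min(1, 4 * pi * area_px / per_px^2) else 1
  list(area_um2 = area_px * pixel_size_um^2,
       roundness = roundness,
       mean_intensity = mean(counterstain[mask]),
       centroid_um = c(px_to_um(mean(idx[, 1]), pixel_size_um),
                       px_to_um(mean(idx[, 2]), pixel_size_um)))
}

#' Segment nuclei from the counterstain channel
#'
#' Candidate regions come from global thresholding of the counterstain
#' (Otsu scaled by `contrast_threshold`); touching candidates are divided by
#' a marker-controlled watershed on the Euclidean distance transform whose
#' h-minima suppression depth shrinks as `aggressiveness` grows. Candidates
#' failing the area, roundness or mean-intensity filters are discarded.
#' Surviving nuclei are relabelled 1..n in row-major centroid order so ids
#' are stable for a given image and parameter set.
#'
#' @param counterstain 2-D numeric matrix, intensities in `[0, 1]`.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param params A [segmentation_params()].
#' @return List with `nuclei`, a data frame (id, x_um, y_um, area_um2,
#'   roundness, mean_intensity), and `labels`, an integer label matrix in
#'   which pixel value k belongs to nucleus id k (0 = background).
#' @export
segment_nuclei <- function(counterstain, pixel_size_um,
                           params = segmentation_params()) {
  if (!is.matrix(counterstain) || !is.numeric(counterstain)) {
    stop("`counterstain` must be a 2-D numeric matrix")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive")
  }
  if (!inherits(params, "segmentation_params")) {
    stop("`params` must be created by segmentation_params()")
  }
  empty <- list(
    nuclei = data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                        area_um2 = numeric(0), roundness = numeric(0),
                        mean_intensity = numeric(0)),
    labels = matrix(0L, nrow(counterstain), ncol(counterstain)))
  if (max(counterstain) <= 0) return(empty)

  thr <- 2 * params$contrast_threshold * EBImage::otsu(counterstain, range = c(0, 1))
  fg <- counterstain > thr
  if (!any(fg)) return(empty)

  dm <- EBImage::distmap(fg)
  tol <- max((1 - params$aggressiveness) * max(dm), 1e-6)
  labels <- EBImage::watershed(dm, tolerance = tol, ext = 1)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))

  keep <- list()
  out_labels <- matrix(0L, nrow(labels), ncol(labels))
  for (lab in setdiff(sort(unique(as.vector(labels))), 0L)) {
    mask <- labels == lab
    m <- compute_morphometrics(mask, counterstain, pixel_size_um)
    if (m$area_um2 < params$min_nuclear_area_um2 ||
        m$area_um2 > params$max_nuclear_area_um2 ||
        m$roundness < params$min_roundness ||
        m$mean_intensity < params$min_mean_intensity) next
    keep[[length(keep) + 1L]] <- list(lab = lab, m = m)
  }
  if (length(keep) == 0) return(empty)

  cx <- vapply(keep, function(k) k$m$centroid_um[1], numeric(1))
  cy <- vapply(keep, function(k) k$m$centroid_um[2], numeric(1))
  ord <- order(cy, cx)  # row-major: scan down the field, then across
  nuclei <- data.frame(
    id = seq_along(ord),
    x_um = cx[ord], y_um = cy[ord],
    area_um2 = vapply(keep, function(k) k$m$area_um2, numeric(1))[ord],
    roundness = vapply(keep, function(k) k$m$roundness, numeric(1))[ord],
    mean_intensity = vapply(keep, function(k) k$m$mean_intensity, numeric(1))[ord])
  for (i in seq_along(ord)) {
    out_labels[labels == keep[[ord[i]]]$lab] <- i
  }
  list(nuclei = nuclei, labels = out_labels)
}

#' Write a nucleus table and label image
#'
#' @param seg Result of [segment_nuclei()].
#' @param csv_path Path for the per-nucleus CSV.
#' @param tiff_path Optional path for the 16-bit label TIFF.
#' @return Invisibly, `csv_path`.
#' @export
write_nuclei <- function(seg, csv_path, tiff_path = NULL) {
  utils::write.csv(seg$nuclei, csv_path, row.names = FALSE)
  if (!is.null(tiff_path)) {
    tiff::writeTIFF(seg$labels / 65535, tiff_path, bits.per.sample = 16L)
  }
  invisible(csv_path)
}
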