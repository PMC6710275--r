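#' Probe punctum detection parameters
#'
#' Defaults reproduce the assay's published settings: minimum signal size
#' 0.45 um^2, probe copy intensity threshold 0.15 and spot segmentation
#' aggressiveness 0.5. The copy intensity threshold is applied to a spot's
#' peak pixel intensity: a spot whose peak exceeds it is treated as a
#' multi-copy cluster, everything else counts as one copy regardless of
#' brightness.
#'
#' @param min_signal_area_um2 Minimum retained spot area, um^2.
#' @param pixel_intensity_threshold Pixel threshold defining spot
#'   foreground, normalized units in `[0, 1]`.
#' @param copy_intensity_threshold Peak intensity above which a spot is a
#'   cluster, `[0, 1]`.
#' @param spot_aggressiveness Local-maxima watershed splitting
#'   aggressiveness, `[0, 1]`; 0 never splits a connected component.
#' @return A `spot_params` list.
#' @export
spot_params <- function(min_signal_area_um2 = 0.45,
                        pixel_intensity_threshold = 0.03,
                        copy_intensity_threshold = 0.15,
                        spot_aggressiveness = 0.5) {
  if (min_signal_area_um2 <= 0) stop("`min_signal_area_um2` must be positive")
  for (nm in c("pixel_intensity_threshold", "copy_intensity_threshold",
               "spot_aggressiveness")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) stop(sprintf("`%s` must lie in [0, 1]", nm))
  }
  structure(list(min_signal_area_um2 = min_signal_area_um2,
                 pixel_intensity_threshold = pixel_intensity_threshold,
                 copy_intensity_threshold = copy_intensity_threshold,
                 spot_aggressiveness = spot_aggressiveness),
            class = "spot_params")
}

empty_spots <- function() {
  data.frame(probe = character(0), x_um = numeric(0), y_um = numeric(0),
             area_um2 = numeric(0), integrated_intensity = numeric(0),
             peak_intensity = numeric(0), copies = integer(0),
             cell_id = integer(0))
}

#' Detect probe puncta in one channel
#'
#' Connected components of pixels above `pixel_intensity_threshold`,
#' optionally split by a local-maxima watershed whose merge tolerance is
#' `(1 - spot_aggressiveness)` of the channel's dynamic range above the
#' threshold; components smaller than `min_signal_area_um2` are discarded.
#' Integrated intensity is background-subtracted, with the background
#' estimated as the median intensity of pixels outside all spot masks
#' (robust and parameter-free); peak intensity is the raw maximum.
#'
#' @param channel 2-D numeric matrix, normalized to `[0, 1]`.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param probe Probe name recorded on each spot.
#' @param params A [spot_params()].
#' @return Data frame of spots (probe, x_um, y_um, area_um2,
#'   integrated_intensity, peak_intensity, copies = `NA`, cell_id = `NA`),
#'   ordered row-major by centroid.
#' @export
detect_spots <- function(channel, pixel_size_um, probe = "probe",
                         params = spot_params()) {
  if (!is.matrix(channel) || !is.numeric(channel)) {
    stop("`channel` must be a 2-D numeric matrix")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive")
  }
  fg <- channel > params$pixel_intensity_threshold
  if (!any(fg)) return(empty_spots())

  relief <- channel * fg
  tol <- max((1 - params$spot_aggressiveness) *
               (max(channel) - params$pixel_intensity_threshold), 1e-6)
  labels <- EBImage::watershed(relief, tolerance = tol, ext = 1)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))

  min_px <- params$min_signal_area_um2 / pixel_size_um^2
  tab <- tabulate(labels[labels > 0])
  keep_ids <- which(tab >= min_px)
  if (length(keep_ids) == 0) return(empty_spots())

  bg <- stats::median(channel[labels == 0L])
  rows <- lapply(keep_ids, function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    vals <- channel[idx]
    data.frame(probe = probe,
               x_um = px_to_um(mean(idx[, 1]), pixel_size_um),
               y_um = px_to_um(mean(idx[, 2]), pixel_size_um),
               area_um2 = nrow(idx) * pixel_size_um^2,
               integrated_intensity = max(sum(vals - bg), 0),
               peak_intensity = max(vals),
               copies = NA_integer_, cell_id = NA_integer_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the per-copy intensity from isolated single puncta
#'
#' Isolated single puncta act as internal positive controls: their median
#' integrated intensity is the per-copy reference against which cluster
#' intensities are decomposed. A spot is "isolated" when its peak intensity
#' does not exceed the cluster criterion.
#'
#' @param spots Data frame from [detect_spots()].
#' @param copy_intensity_threshold Peak threshold separating isolated
#'   singles from clusters.
#' @param isolated_only If `TRUE` (default) calibrate on isolated spots
#'   only; otherwise use all spots.
#' @param min_spots Minimum calibration set size (default 5).
#' @return Positive scalar: the unit (per-copy) integrated intensity.
#' @export
calibrate_unit_intensity <- function(spots, copy_intensity_threshold = 0.15,
                                     isolated_only = TRUE, min_spots = 5L) {
  set <- if (isolated_only) {
    spots[spots$peak_intensity <= copy_intensity_threshold, , drop = FALSE]
  } else {
    spots
  }
  if (nrow(set) < min_spots) {
    stop(sprintf(paste0("only %d isolated puncta available (need >= %d); ",
                        "supply `unit_intensity` manually"),
                 nrow(set), min_spots))
  }
  stats::median(set$integrated_intensity)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Decompose spot intensities into probe copy counts
#'
#' Physically separated puncta always count as one probe copy. A spot whose
#' peak intensity surpasses the copy intensity threshold is a cluster and
#' contributes `round(integrated_intensity / unit_intensity)` copies
#' (half away from zero, floored at 1).
#'
#' @param spots Data frame from [detect_spots()].
#' @param unit_intensity Per-copy integrated intensity (> 0), typically
#'   from [calibrate_unit_intensity()].
#' @param params A [spot_params()] (supplies the cluster criterion).
#' @return `spots` with the `copies` column filled (integer >= 1).
#' @export
count_copies <- function(spots, unit_intensity, params = spot_params()) {
  if (!is.numeric(unit_intensity) || unit_intensity <= 0) {
    stop("`unit_intensity` must be positive")
  }
  if (nrow(spots) == 0) return(spots)
  is_cluster <- spots$peak_intensity > params$copy_intensity_threshold
  copies <- rep(1L, nrow(spots))
  copies[is_cluster] <- pmax(
    1L, as.integer(round_half_up(spots$integrated_intensity[is_cluster] /
                                   unit_intensity)))
  spots$copies <- copies
  spots
}
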