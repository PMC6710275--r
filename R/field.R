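#' Multi-channel field of view
#'
#' Container for one 2-D field after z-projection: a named list of channel
#' images on a common pixel grid, the physical pixel size, a channel-to-probe
#' map, and an optional exclusion mask marking regions to be ignored by all
#' downstream stages.
#'
#' Physical coordinates use the pixel-centre convention: a pixel at 1-based
#' matrix index `(i, j)` has centre `((i - 0.5) * pixel_size_um,
#' (j - 0.5) * pixel_size_um)` in micrometres, with the first matrix index
#' mapped to x and the second to y.
#'
#' @param channels Named list of numeric matrices with values in `[0, 1]`,
#'   all of identical dimension. One entry must be the nuclear counterstain.
#' @param pixel_size_um Positive scalar, micrometres per pixel.
#' @param channel_probe_map Named character vector mapping channel name to
#'   probe name; the counterstain channel maps to `NA`. Defaults to the
#'   identity map with `"DAPI"` treated as the counterstain.
#' @param exclusion_mask Optional logical matrix of the same dimension;
#'   `TRUE` marks excluded pixels.
#' @return An object of class `smfish_field`.
#' @export
new_field <- function(channels, pixel_size_um, channel_probe_map = NULL,
                      exclusion_mask = NULL) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1)))) {
    stop("every channel must be a 2-D numeric matrix")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must share one shape")
  }
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("channel intensities must lie in [0, 1]")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a positive scalar")
  }
  if (is.null(channel_probe_map)) {
    channel_probe_map <- stats::setNames(names(channels), names(channels))
    channel_probe_map[names(channels) == "DAPI"] <- NA_character_
  }
  if (!all(names(channel_probe_map) %in% names(channels))) {
    stop("channel_probe_map names must be channel names")
  }
  if (!is.null(exclusion_mask)) {
    if (!is.logical(exclusion_mask) || !identical(dim(exclusion_mask), dim(channels[[1]]))) {
      stop("exclusion_mask must be a logical matrix with the channels' shape")
    }
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         channel_probe_map = channel_probe_map, exclusion_mask = exclusion_mask),
    class = "smfish_field"
  )
}

#' @export
print.smfish_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<smfish_field> %d x %d px (%.1f x %.1f um), %d channel(s): %s\n",
              d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$exclusion_mask)) {
    cat(sprintf("  exclusion mask: %.1f%% of field\n", 100 * mean(x$exclusion_mask)))
  }
  invisible(x)
}

#' Probe channels of a field
#'
#' @param field An `smfish_field`.
#' @return Named character vector: probe name -> channel name, counterstain
#'   channels omitted.
#' @export
probe_channels <- function(field) {
  m <- field$channel_probe_map
  m <- m[!is.na(m)]
  stats::setNames(names(m), unname(m))
}

#' Pixel-centre coordinate conversions
#'
#' 1-based matrix index `i` maps to physical coordinate
#' `(i - 0.5) * pixel_size_um`: pixel centres, unambiguous round-tripping.
#'
#' @param idx 1-based (possibly fractional) pixel index.
#' @param um Physical coordinate in micrometres.
#' @param pixel_size_um Micrometres per pixel.
#' @return The converted coordinate(s).
#' @export
px_to_um <- function(idx, pixel_size_um) (idx - 0.5) * pixel_size_um

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_size_um) um / pixel_size_um + 0.5

clip01 <- function(x) pmin(pmax(x, 0), 1)
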