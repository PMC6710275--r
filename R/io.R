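#' Load a multi-channel TIFF and maximum-project it
#'
#' Reads a multi-page (OME-)TIFF in which pages are channels, z-planes or
#' both. `channel_map` names the channel of every page in order; pages
#' sharing a name are treated as that channel's z-stack and reduced by
#' per-pixel maximum projection. Each projected channel is then min-max
#' normalized to `[0, 1]`.
#'
#' @param path TIFF file path.
#' @param channel_map Character vector, one channel name per page. `NULL`
#'   names pages `"ch1"`, `"ch2"`, ... (one channel per page).
#' @param pixel_size_um Micrometres per pixel of the image grid.
#' @param channel_probe_map Optional named character vector channel ->
#'   probe passed through to [new_field()].
#' @param normalize Min-max normalize each channel (default `TRUE`).
#' @return An [new_field()] object.
#' @export
load_and_project <- function(path, channel_map = NULL, pixel_size_um = 0.2,
                             channel_probe_map = NULL, normalize = TRUE) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1] else
        stop(sprintf("page %d of '%s' is not single-channel grayscale", i, path))
    }
    p
  })
  if (is.null(channel_map)) {
    channel_map <- paste0("ch", seq_along(pages))
  }
  if (length(channel_map) != length(pages)) {
    stop(sprintf("'%s' has %d page(s) but `channel_map` names %d",
                 path, length(pages), length(channel_map)))
  }
  channels <- lapply(unique(channel_map), function(ch) {
    Reduce(pmax, pages[channel_map == ch])
  })
  names(channels) <- unique(channel_map)
  if (normalize) {
    channels <- lapply(channels, function(m) {
      rng <- range(m)
      if (diff(rng) == 0) matrix(0, nrow(m), ncol(m)) else
        (m - rng[1]) / diff(rng)
    })
  }
  new_field(channels, pixel_size_um, channel_probe_map = channel_probe_map)
}

#' Read a simulated field directory back into a field object
#'
#' Counterpart of [write_field()]: reads `field.tif` with the channel names
#' recorded in `channels.csv`.
#'
#' @param dir Directory written by [write_field()].
#' @param pixel_size_um Pixel size; default taken from `config.yaml` when
#'   present.
#' @param normalize Min-max normalize channels on load (default `FALSE`:
#'   simulated intensities are already in `[0, 1]`).
#' @return An [new_field()] object.
#' @export
read_field_dir <- function(dir, pixel_size_um = NULL, normalize = FALSE) {
  chan <- utils::read.csv(file.path(dir, "channels.csv"),
                          stringsAsFactors = FALSE)
  if (is.null(pixel_size_um)) {
    cfg_path <- file.path(dir, "config.yaml")
    if (!file.exists(cfg_path)) stop("no config.yaml: supply `pixel_size_um`")
    pixel_size_um <- yaml::read_yaml(cfg_path)$pixel_size_um
  }
  map <- stats::setNames(ifelse(chan$probe == "" | is.na(chan$probe),
                                NA_character_, chan$probe),
                         chan$channel)
  load_and_project(file.path(dir, "field.tif"),
                   channel_map = chan$channel[order(chan$page)],
                   pixel_size_um = pixel_size_um,
                   channel_probe_map = map, normalize = normalize)
}

validate_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || any(!is.finite(poly))) {
    stop("polygons must be finite n x 2 matrices with n >= 3")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(abs(poly[1, ] - poly[n, ]) < 1e-12)) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) stop("polygons must have at least 3 distinct vertices")
  area2 <- sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                 c(poly[-1, 1], poly[1, 1]) * poly[, 2])
  if (abs(area2) < 1e-12) stop("degenerate (zero-area) polygon")
  poly
}

#' Apply exclusion regions to a field
#'
#' Marks the interiors of the given polygons (micrometre coordinates) in
#' the field's exclusion mask. Downstream stages drop nuclei and puncta
#' whose centroids fall inside the mask.
#'
#' @param field An [new_field()] object.
#' @param polygons A single n x 2 matrix or a list of them, vertices in um.
#' @return The field with `exclusion_mask` set (previous exclusions are
#'   kept).
#' @export
apply_exclusion <- function(field, polygons) {
  if (is.matrix(polygons) || is.data.frame(polygons)) polygons <- list(polygons)
  if (length(polygons) == 0) return(field)
  polygons <- lapply(polygons, validate_polygon)
  d <- dim(field$channels[[1]])
  s <- field$pixel_size_um
  ctr <- cbind(rep(px_to_um(seq_len(d[1]), s), times = d[2]),
               rep(px_to_um(seq_len(d[2]), s), each = d[1]))
  inside <- rep(FALSE, nrow(ctr))
  for (poly in polygons) {
    bnd <- rbind(poly, poly[1, ])
    inside <- inside | mgcv::in.out(bnd, ctr)
  }
  mask <- matrix(inside, d[1], d[2])
  if (!is.null(field$exclusion_mask)) mask <- mask | field$exclusion_mask
  field$exclusion_mask <- mask
  field
}

#' Which points fall in the exclusion mask?
#'
#' @param field An [new_field()] object.
#' @param x_um,y_um Point coordinates in um.
#' @return Logical vector; all `FALSE` when the field has no mask.
#' @export
points_excluded <- function(field, x_um, y_um) {
  if (is.null(field$exclusion_mask)) return(rep(FALSE, length(x_um)))
  d <- dim(field$exclusion_mask)
  i <- pmin(pmax(round(um_to_px(x_um, field$pixel_size_um)), 1L), d[1])
  j <- pmin(pmax(round(um_to_px(y_um, field$pixel_size_um)), 1L), d[2])
  field$exclusion_mask[cbind(i, j)]
}

#' Read exclusion polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection, Feature or bare (Multi)Polygon geometry;
#' coordinates are taken as micrometres. Only outer rings are used.
#'
#' @param path GeoJSON file path.
#' @return List of n x 2 coordinate matrices for [apply_exclusion()].
#' @export
read_exclusion_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  geoms <- switch(
    g$type %||% stop("not a GeoJSON object"),
    FeatureCollection = lapply(g$features, `[[`, "geometry"),
    Feature = list(g$geometry),
    Polygon = ,
    MultiPolygon = list(g),
    stop(sprintf("unsupported GeoJSON type '%s'", g$type)))
  polys <- list()
  for (geom in geoms) {
    rings <- if (geom$type == "Polygon") list(geom$coordinates[[1]]) else
      if (geom$type == "MultiPolygon") lapply(geom$coordinates, `[[`, 1) else
        stop(sprintf("unsupported geometry type '%s'", geom$type))
    for (ring in rings) {
      polys[[length(polys) + 1L]] <-
        do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
  }
  polys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-step black-to-blue markup ramp
#'
#' @return 5 x 3 matrix of RGB rows for classes 0-4: class 0 black, classes
#'   1-4 increasingly brighter blue.
#' @export
markup_palette <- function() {
  k <- 0:4
  cbind(r = 0.1 * k, g = 0.2 * k, b = k / 4)
}

#' Render a per-cell expression markup image
#'
#' Overlays the segmented nuclei on the counterstain, filling each nucleus
#' with a five-step black-to-blue ramp by its expression class for the
#' given probe (0+ black, 1+ to 4+ increasingly brighter blue).
#'
#' @param field An [new_field()] object.
#' @param cells Cell table from [tabulate_cells()] with a `<probe>_bin`
#'   column.
#' @param probe Probe whose bins are rendered.
#' @param labels Integer nucleus label matrix from [segment_nuclei()]
#'   (pixel value = cell id).
#' @param path Optional PNG output path.
#' @return Invisibly, the rendered height x width x 3 RGB array.
#' @export
render_markup <- function(field, cells, probe, labels, path = NULL) {
  bcol <- paste0(probe, "_bin")
  if (!bcol %in% names(cells)) {
    stop(sprintf("unknown probe '%s': no bin column in `cells`", probe))
  }
  cs_name <- names(field$channel_probe_map)[is.na(field$channel_probe_map)][1]
  if (is.na(cs_name)) cs_name <- names(field$channels)[1]
  gray <- field$channels[[cs_name]]
  pal <- markup_palette()
  rgb <- array(rep(gray, 3), dim = c(nrow(gray), ncol(gray), 3))
  for (i in seq_len(nrow(cells))) {
    m <- labels == cells$cell_id[i]
    if (!any(m)) next
    col <- pal[cells[[bcol]][i] + 1L, ]
    for (c3 in 1:3) {
      plane <- rgb[, , c3]
      plane[m] <- col[c3]
      rgb[, , c3] <- plane
    }
  }
  if (!is.null(path)) {
    # matrices are x-by-y; PNG rows are y
    png::writePNG(aperm(rgb, c(2, 1, 3)), path)
  }
  invisible(rgb)
}
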