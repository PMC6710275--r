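#' Probe specification for the synthetic generator
#'
#' @param name Probe name (channel of the same name is rendered).
#' @param mean_copies Mean transcript copies per positive cell (negative
#'   binomial mean).
#' @param fraction_positive Fraction of cells expressing the probe, in
#'   `[0, 1]`.
#' @param cluster_fraction Fraction of a cell's copies that aggregate into
#'   bright multi-copy clusters rather than isolated single puncta, in
#'   `[0, 1]`.
#' @return A `probe_spec` list.
#' @export
probe_spec <- function(name, mean_copies = 5, fraction_positive = 1,
                       cluster_fraction = 0.3) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.finite(mean_copies) || mean_copies < 0) {
    stop("`mean_copies` must be non-negative")
  }
  if (fraction_positive < 0 || fraction_positive > 1) {
    stop("`fraction_positive` must lie in [0, 1]")
  }
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    stop("`cluster_fraction` must lie in [0, 1]")
  }
  structure(list(name = name, mean_copies = mean_copies,
                 fraction_positive = fraction_positive,
                 cluster_fraction = cluster_fraction),
            class = "probe_spec")
}

#' Configuration of the synthetic smFISH field generator
#'
#' Defines one confocal-like field of DAPI-stained nuclei with per-probe
#' punctum channels. Defaults emulate a 40x confocal field: 1024 x 1024
#' pixels at 0.2 um/px (a ~205 um square), 20 nuclei of 3-6 um radius, and
#' puncta rendered as 2-D Gaussians whose integrated intensity per transcript
#' copy is `unit_copy_intensity` (normalized intensity units).
#'
#' Copies per positive cell are drawn from a negative binomial with mean
#' `mean_copies` (per probe) and dispersion `copy_dispersion`; the true
#' per-cell copy distribution in tissue is unknown, so this is an explicit
#' modelling choice carried in the configuration.
#'
#' Owned puncta are placed uniformly in a disk of radius
#' `spot_placement_radius_um` (at most 25 um) around the owner nucleus
#' centroid; together with the `min_nucleus_separation_um` rejection-sampling
#' constraint (separation > 2 x placement radius) this makes the true owner
#' the nearest nucleus for every owned punctum, so proximity assignment is
#' recoverable exactly by construction.
#'
#' @param field_size_px Integer pair, field size in pixels.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param nucleus_radius_um Length-2 range of nucleus radii in um (> 0).
#' @param probe_specs List of [probe_spec()] objects.
#' @param psf_sigma_um Gaussian sigma of the rendered punctum profile, um.
#' @param unit_copy_intensity Integrated (summed normalized pixel) intensity
#'   rendered per transcript copy.
#' @param background_level Constant background added to every channel.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param autofluorescent_blob_rate Expected number of large dim
#'   autofluorescent aggregates per field (Poisson), rendered into
#'   `autofluorescence_channel`; emulates the high green-channel background of
#'   aggregate-laden tissue.
#' @param autofluorescence_channel Probe channel receiving the blobs, or
#'   `NULL` for none.
#' @param background_spot_rate Expected number of unowned single puncta per
#'   probe per field (Poisson).
#' @param spot_placement_radius_um Placement radius for owned puncta, um
#'   (<= 25).
#' @param min_nucleus_separation_um Minimum centroid-to-centroid distance
#'   enforced between nuclei, um.
#' @param copy_dispersion Negative binomial size parameter for copies per
#'   positive cell.
#' @param seed Integer seed; generation is bit-reproducible given the
#'   configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(field_size_px = c(1024L, 1024L),
                         pixel_size_um = 0.2,
                         n_nuclei = 20L,
                         nucleus_radius_um = c(3, 6),
                         probe_specs = list(probe_spec("PPIB")),
                         psf_sigma_um = 0.3,
                         unit_copy_intensity = 1.7,
                         background_level = 0.02,
                         noise_sd = 0.003,
                         autofluorescent_blob_rate = 0,
                         autofluorescence_channel = NULL,
                         background_spot_rate = 0,
                         spot_placement_radius_um = 8,
                         min_nucleus_separation_um = 18,
                         copy_dispersion = 4,
                         seed = 1L) {
  field_size_px <- as.integer(field_size_px)
  if (length(field_size_px) != 2 || any(field_size_px < 8)) {
    stop("`field_size_px` must be two integers >= 8")
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive")
  }
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 0) stop("`n_nuclei` must be non-negative")
  if (length(nucleus_radius_um) != 2 || any(nucleus_radius_um <= 0) ||
      diff(nucleus_radius_um) < 0) {
    stop("`nucleus_radius_um` must be a positive, non-decreasing range")
  }
  if (inherits(probe_specs, "probe_spec")) probe_specs <- list(probe_specs)
  if (!all(vapply(probe_specs, inherits, logical(1), "probe_spec"))) {
    stop("`probe_specs` must be a list of probe_spec objects")
  }
  pn <- vapply(probe_specs, `[[`, character(1), "name")
  if (anyDuplicated(pn)) stop("probe names must be unique")
  if ("DAPI" %in% pn) stop("'DAPI' is reserved for the counterstain channel")
  if (psf_sigma_um <= 0) stop("`psf_sigma_um` must be positive")
  if (unit_copy_intensity <= 0) stop("`unit_copy_intensity` must be positive")
  if (background_level < 0 || noise_sd < 0 || autofluorescent_blob_rate < 0 ||
      background_spot_rate < 0) {
    stop("rates, background and noise must be non-negative")
  }
  if (!is.null(autofluorescence_channel) &&
      !autofluorescence_channel %in% pn) {
    stop("`autofluorescence_channel` must name one of the probes")
  }
  if (spot_placement_radius_um <= 0 || spot_placement_radius_um > 25) {
    stop("`spot_placement_radius_um` must be in (0, 25]")
  }
  if (min_nucleus_separation_um <= 0) {
    stop("`min_nucleus_separation_um` must be positive")
  }
  if (copy_dispersion <= 0) stop("`copy_dispersion` must be positive")
  structure(
    list(field_size_px = field_size_px, pixel_size_um = pixel_size_um,
         n_nuclei = n_nuclei, nucleus_radius_um = nucleus_radius_um,
         probe_specs = probe_specs, psf_sigma_um = psf_sigma_um,
         unit_copy_intensity = unit_copy_intensity,
         background_level = background_level, noise_sd = noise_sd,
         autofluorescent_blob_rate = autofluorescent_blob_rate,
         autofluorescence_channel = autofluorescence_channel,
         background_spot_rate = background_spot_rate,
         spot_placement_radius_um = spot_placement_radius_um,
         min_nucleus_separation_um = min_nucleus_separation_um,
         copy_dispersion = copy_dispersion, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# add a 2-D Gaussian of integrated intensity `mass` centred at (cx, cy)
# (pixel units, 1-based, possibly fractional) into matrix `img` in place
add_gaussian <- function(img, cx, cy, sigma_px, mass) {
  half <- ceiling(5 * sigma_px)
  i <- max(1L, floor(cx - half)):min(nrow(img), ceiling(cx + half))
  j <- max(1L, floor(cy - half)):min(ncol(img), ceiling(cy + half))
  if (length(i) == 0 || length(j) == 0) return(img)
  gx <- exp(-(i - cx)^2 / (2 * sigma_px^2))
  gy <- exp(-(j - cy)^2 / (2 * sigma_px^2))
  img[i, j] <- img[i, j] + (mass / (2 * pi * sigma_px^2)) * outer(gx, gy)
  img
}

# uniform point in a disk of radius r around (x0, y0), rejected into the
# rectangle [lo, hi] x [lo2, hi2]
runif_disk <- function(x0, y0, r, xlim, ylim, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    rr <- r * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    x <- x0 + rr * cos(th)
    y <- y0 + rr * sin(th)
    if (x >= xlim[1] && x <= xlim[2] && y >= ylim[1] && y <= ylim[2]) {
      return(c(x, y))
    }
  }
  # fall back to clamping; only reachable for nuclei hugging the border
  c(min(max(x0, xlim[1]), xlim[2]), min(max(y0, ylim[1]), ylim[2]))
}

place_nuclei <- function(config) {
  n <- config$n_nuclei
  if (n == 0) {
    return(data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0)))
  }
  s <- config$pixel_size_um
  W <- config$field_size_px[1] * s
  H <- config$field_size_px[2] * s
  radii <- stats::runif(n, config$nucleus_radius_um[1], config$nucleus_radius_um[2])
  margin <- max(radii) + 2
  if (2 * margin >= W || 2 * margin >= H) {
    stop("field too small for the requested nucleus radii")
  }
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      x <- stats::runif(1, margin, W - margin)
      y <- stats::runif(1, margin, H - margin)
      if (i == 1 || all(sqrt((xs[seq_len(i - 1)] - x)^2 +
                             (ys[seq_len(i - 1)] - y)^2) >=
                        config$min_nucleus_separation_um)) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place %d nuclei with separation ",
                          ">= %.1f um in this field; reduce `n_nuclei` or ",
                          "`min_nucleus_separation_um`"),
                   n, config$min_nucleus_separation_um))
    }
  }
  data.frame(id = seq_len(n), x_um = xs, y_um = ys, radius_um = radii)
}

render_nuclei <- function(config, nuclei) {
  d <- config$field_size_px
  s <- config$pixel_size_um
  img <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(nuclei))) {
    r_px <- nuclei$radius_um[i] / s
    q <- stats::runif(1, 0.75, 1)          # axis ratio; mildly elliptic
    a <- r_px / sqrt(q); b <- r_px * sqrt(q)
    th <- stats::runif(1, 0, pi)
    base <- stats::runif(1, 0.55, 0.8)
    cx <- um_to_px(nuclei$x_um[i], s)
    cy <- um_to_px(nuclei$y_um[i], s)
    half <- ceiling(a) + 1L
    ii <- max(1L, floor(cx - half)):min(d[1], ceiling(cx + half))
    jj <- max(1L, floor(cy - half)):min(d[2], ceiling(cy + half))
    dx <- outer(ii - cx, rep(1, length(jj)))
    dy <- outer(rep(1, length(ii)), jj - cy)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    rho2 <- u^2 + v^2
    inside <- rho2 <= 1
    patch <- img[ii, jj]
    # flat core with a mild radial falloff keeps the blob convincingly nuclear
    patch[inside] <- pmax(patch[inside], base * (1 - 0.25 * rho2[inside]))
    img[ii, jj] <- patch
  }
  EBImage::gblur(img, sigma = max(config$psf_sigma_um / s, 0.5))
}

# split `n_clustered` copies into cluster sites of size 2-4 (a trailing
# single copy stays a singleton site)
cluster_sites <- function(n_clustered) {
  sizes <- integer(0)
  left <- n_clustered
  while (left >= 2) {
    k <- min(left, sample(2:4, 1))
    sizes <- c(sizes, k)
    left <- left - k
  }
  if (left == 1) sizes <- c(sizes, 1L)
  sizes
}

#' Generate a synthetic multiplexed smFISH field with ground truth
#'
#' Renders a DAPI channel of non-overlapping elliptical nuclei plus one
#' channel per probe in which every transcript copy contributes a 2-D
#' Gaussian of integrated intensity `unit_copy_intensity`; a k-copy cluster
#' is k superposed copies at one site. Constant background, optional
#' autofluorescent aggregates and Gaussian pixel noise are added and the
#' result clipped to `[0, 1]`. The returned ground truth records every
#' nucleus, every punctum site with its copy load and owner, and the
#' per-cell per-probe copy totals.
#'
#' @param config A [synth_config()].
#' @return A list with elements `field` (an [new_field()] object) and
#'   `truth`, itself a list of three data frames: `nuclei`
#'   (id, x_um, y_um, radius_um), `spots`
#'   (probe, x_um, y_um, copies, cell_id; `NA` cell for unowned background
#'   spots) and `cell_probe_copies` (cell_id, probe, copies, one row per
#'   cell x probe including zeros).
#' @export
generate_field <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be created by synth_config()")
  }
  withr::with_seed(config$seed, generate_field_impl(config))
}

generate_field_impl <- function(config) {
  d <- config$field_size_px
  s <- config$pixel_size_um
  W <- d[1] * s; H <- d[2] * s
  sigma_px <- config$psf_sigma_um / s

  nuclei <- place_nuclei(config)
  dapi <- if (nrow(nuclei) > 0) render_nuclei(config, nuclei) else matrix(0, d[1], d[2])

  probe_names <- vapply(config$probe_specs, `[[`, character(1), "name")
  channels <- c(list(DAPI = dapi),
                stats::setNames(replicate(length(probe_names),
                                          matrix(0, d[1], d[2]),
                                          simplify = FALSE),
                                probe_names))

  spot_rows <- list()
  copy_rows <- list()
  pad <- 1  # keep punctum centres >= 1 um off the border
  for (sp in config$probe_specs) {
    img <- channels[[sp$name]]
    n <- nrow(nuclei)
    copies_per_cell <- integer(n)
    if (n > 0 && sp$mean_copies > 0 && sp$fraction_positive > 0) {
      positive <- stats::runif(n) < sp$fraction_positive
      copies_per_cell[positive] <- stats::rnbinom(sum(positive),
                                                  size = config$copy_dispersion,
                                                  mu = sp$mean_copies)
    }
    for (i in seq_len(n)) {
      nc <- copies_per_cell[i]
      if (nc == 0) next
      n_clustered <- stats::rbinom(1, nc, sp$cluster_fraction)
      sizes <- c(cluster_sites(n_clustered), rep(1L, nc - n_clustered))
      for (k in sizes) {
        pos <- runif_disk(nuclei$x_um[i], nuclei$y_um[i],
                          config$spot_placement_radius_um,
                          c(pad, W - pad), c(pad, H - pad))
        img <- add_gaussian(img, um_to_px(pos[1], s), um_to_px(pos[2], s),
                            sigma_px, k * config$unit_copy_intensity)
        spot_rows[[length(spot_rows) + 1L]] <-
          data.frame(probe = sp$name, x_um = pos[1], y_um = pos[2],
                     copies = k, cell_id = nuclei$id[i])
      }
    }
    n_bg <- stats::rpois(1, config$background_spot_rate)
    for (b in seq_len(n_bg)) {
      pos <- c(stats::runif(1, pad, W - pad), stats::runif(1, pad, H - pad))
      img <- add_gaussian(img, um_to_px(pos[1], s), um_to_px(pos[2], s),
                          sigma_px, config$unit_copy_intensity)
      spot_rows[[length(spot_rows) + 1L]] <-
        data.frame(probe = sp$name, x_um = pos[1], y_um = pos[2],
                   copies = 1L, cell_id = NA_integer_)
    }
    if (n > 0) {
      copy_rows[[length(copy_rows) + 1L]] <-
        data.frame(cell_id = nuclei$id, probe = sp$name,
                   copies = copies_per_cell)
    }
    channels[[sp$name]] <- img
  }

  if (!is.null(config$autofluorescence_channel) &&
      config$autofluorescent_blob_rate > 0) {
    ch <- config$autofluorescence_channel
    n_blob <- stats::rpois(1, config$autofluorescent_blob_rate)
    for (b in seq_len(n_blob)) {
      sig_um <- stats::runif(1, 1, 2.5)
      peak <- stats::runif(1, 0.03, 0.08)
      sig_px <- sig_um / s
      channels[[ch]] <- add_gaussian(channels[[ch]],
                                     stats::runif(1, 1, d[1]),
                                     stats::runif(1, 1, d[2]),
                                     sig_px, peak * 2 * pi * sig_px^2)
    }
  }

  for (nm in names(channels)) {
    ch <- channels[[nm]] + config$background_level
    if (config$noise_sd > 0) {
      ch <- ch + stats::rnorm(length(ch), 0, config$noise_sd)
    }
    channels[[nm]] <- clip01(ch)
  }

  spots <- if (length(spot_rows)) do.call(rbind, spot_rows) else
    data.frame(probe = character(0), x_um = numeric(0), y_um = numeric(0),
               copies = integer(0), cell_id = integer(0))
  cpc <- if (length(copy_rows)) do.call(rbind, copy_rows) else
    data.frame(cell_id = integer(0), probe = character(0), copies = integer(0))
  rownames(spots) <- NULL; rownames(cpc) <- NULL

  map <- stats::setNames(c(NA_character_, probe_names),
                         c("DAPI", probe_names))
  list(field = new_field(channels, s, channel_probe_map = map),
       truth = list(nuclei = nuclei, spots = spots, cell_probe_copies = cpc))
}

#' Write a synthetic field and its ground truth to disk
#'
#' Writes the channels as one multi-page 16-bit TIFF (one page per channel,
#' page order = channel order), the spot and cell truth tables as CSV, and
#' the generating configuration as YAML.
#'
#' @param sim Result of [generate_field()].
#' @param config The [synth_config()] used.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_field <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tiff = file.path(dir, "field.tif"),
    channels = file.path(dir, "channels.csv"),
    spots = file.path(dir, "truth_spots.csv"),
    cells = file.path(dir, "truth_cells.csv"),
    nuclei = file.path(dir, "truth_nuclei.csv"),
    config = file.path(dir, "config.yaml")
  )
  tiff::writeTIFF(sim$field$channels, paths[["tiff"]], bits.per.sample = 16L)
  utils::write.csv(data.frame(page = seq_along(sim$field$channels),
                              channel = names(sim$field$channels),
                              probe = unname(sim$field$channel_probe_map[names(sim$field$channels)])),
                   paths[["channels"]], row.names = FALSE)
  utils::write.csv(sim$truth$spots, paths[["spots"]], row.names = FALSE)
  utils::write.csv(sim$truth$cell_probe_copies, paths[["cells"]], row.names = FALSE)
  utils::write.csv(sim$truth$nuclei, paths[["nuclei"]], row.names = FALSE)
  cfg <- unclass(config)
  cfg$probe_specs <- lapply(cfg$probe_specs, unclass)
  yaml::write_yaml(cfg, paths[["config"]], precision = 12L)
  invisible(paths)
}
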