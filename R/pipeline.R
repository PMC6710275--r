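#' Full pipeline configuration
#'
#' Bundles every stage's parameters with the probe layout. Spot parameters
#' may be shared across probes (a single [spot_params()]) or given per
#' probe (a named list), mirroring per-probe tuning of the assay.
#'
#' @param pixel_size_um Micrometres per pixel of the input images.
#' @param segmentation A [segmentation_params()].
#' @param spots A [spot_params()] or named list of them keyed by probe.
#' @param assignment An [assignment_params()].
#' @param binning A [binning_scheme()].
#' @param lineage_probes Named character vector marker probe -> lineage
#'   label.
#' @param test_probes Probes to bin and score; `NULL` = every non-marker
#'   probe present.
#' @param denominator H-score denominator rule (see [h_score()]).
#' @param unit_intensity Per-copy integrated intensity; `NULL` (default)
#'   calibrates per field and probe from isolated puncta.
#' @param min_lineage_count Lineage positivity threshold.
#' @param seed Integer seed recorded with outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size_um = 0.2,
                            segmentation = segmentation_params(),
                            spots = spot_params(),
                            assignment = assignment_params(),
                            binning = binning_scheme(),
                            lineage_probes = character(0),
                            test_probes = NULL,
                            denominator = "probe_positive",
                            unit_intensity = NULL,
                            min_lineage_count = 2L,
                            seed = 1L) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(assignment, "assignment_params"),
            inherits(binning, "binning_scheme"))
  if (inherits(spots, "spot_params")) {
    # shared across probes
  } else if (is.list(spots) &&
             all(vapply(spots, inherits, logical(1), "spot_params")) &&
             !is.null(names(spots))) {
    # per-probe
  } else {
    stop("`spots` must be a spot_params or a named list of them")
  }
  structure(list(pixel_size_um = pixel_size_um, segmentation = segmentation,
                 spots = spots, assignment = assignment, binning = binning,
                 lineage_probes = lineage_probes, test_probes = test_probes,
                 denominator = denominator, unit_intensity = unit_intensity,
                 min_lineage_count = as.integer(min_lineage_count),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

spot_params_for <- function(config, probe) {
  if (inherits(config$spots, "spot_params")) return(config$spots)
  config$spots[[probe]] %||% spot_params()
}

#' Write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  raw <- list(
    pixel_size_um = config$pixel_size_um,
    segmentation = unclass(config$segmentation),
    spots = if (inherits(config$spots, "spot_params"))
      unclass(config$spots) else lapply(config$spots, unclass),
    assignment = unclass(config$assignment),
    binning = as.list(stats::setNames(as.numeric(config$binning),
                                      names(config$binning))),
    lineage_probes = as.list(config$lineage_probes),
    test_probes = config$test_probes,
    denominator = config$denominator,
    unit_intensity = config$unit_intensity,
    min_lineage_count = config$min_lineage_count,
    seed = config$seed)
  yaml::write_yaml(raw, path, precision = 12L)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Round-trips losslessly with [write_config()].
#'
#' @param path YAML path written by [write_config()].
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spots <- if (!is.null(raw$spots$min_signal_area_um2)) {
    do.call(spot_params, raw$spots)
  } else {
    lapply(raw$spots, function(s) do.call(spot_params, s))
  }
  pipeline_config(
    pixel_size_um = raw$pixel_size_um,
    segmentation = do.call(segmentation_params, raw$segmentation),
    spots = spots,
    assignment = do.call(assignment_params, raw$assignment),
    binning = binning_scheme(stats::setNames(as.numeric(raw$binning),
                                             names(raw$binning))),
    lineage_probes = stats::setNames(as.character(unlist(raw$lineage_probes)),
                                     names(raw$lineage_probes)),
    test_probes = if (is.null(raw$test_probes)) NULL else
      as.character(unlist(raw$test_probes)),
    denominator = raw$denominator,
    unit_intensity = raw$unit_intensity,
    min_lineage_count = raw$min_lineage_count,
    seed = raw$seed)
}

#' Quantify one field end-to-end
#'
#' Runs segment -> detect -> calibrate -> count -> assign -> classify ->
#' bin -> score on a single projected field. Ground-truth nuclei may be
#' injected (a data frame with id, x_um, y_um) to bypass segmentation, e.g.
#' to isolate detection errors from segmentation errors on simulated data.
#'
#' @param field An [new_field()] object.
#' @param config A [pipeline_config()].
#' @param nuclei Optional nucleus table overriding segmentation.
#' @return List: `nuclei`, `labels` (`NULL` when nuclei were injected),
#'   `spots`, `cells`, `scores` (named list of [h_score()] results per test
#'   probe; `NULL` where the denominator was empty), `units` (per-probe
#'   unit intensities used).
#' @export
quantify_field <- function(field, config = pipeline_config(), nuclei = NULL) {
  s <- field$pixel_size_um
  labels <- NULL
  if (is.null(nuclei)) {
    cs_name <- names(field$channel_probe_map)[is.na(field$channel_probe_map)][1]
    if (is.na(cs_name)) stop("field has no counterstain channel in its map")
    seg <- segment_nuclei(field$channels[[cs_name]], s, config$segmentation)
    nuclei <- seg$nuclei
    labels <- seg$labels
  }
  keep_n <- !points_excluded(field, nuclei$x_um, nuclei$y_um)
  nuclei <- nuclei[keep_n, , drop = FALSE]

  pc <- probe_channels(field)
  spots_list <- list()
  units <- stats::setNames(numeric(0), character(0))
  for (probe in names(pc)) {
    sp_par <- spot_params_for(config, probe)
    sp <- detect_spots(field$channels[[pc[[probe]]]], s, probe = probe,
                       params = sp_par)
    sp <- sp[!points_excluded(field, sp$x_um, sp$y_um), , drop = FALSE]
    unit <- config$unit_intensity %||%
      calibrate_unit_intensity(sp, sp_par$copy_intensity_threshold)
    units[probe] <- unit
    spots_list[[probe]] <- count_copies(sp, unit, sp_par)
  }
  spots <- if (length(spots_list)) do.call(rbind, spots_list) else empty_spots()
  rownames(spots) <- NULL
  spots <- assign_spots(nuclei, spots, config$assignment)

  cells <- tabulate_cells(nuclei, spots,
                          lineage_probes = config$lineage_probes,
                          test_probes = config$test_probes,
                          scheme = config$binning,
                          min_count = config$min_lineage_count)
  test_probes <- config$test_probes %||%
    setdiff(names(pc), names(config$lineage_probes))
  scores <- lapply(stats::setNames(test_probes, test_probes), function(p) {
    tryCatch(h_score(cells, p, config$denominator), error = function(e) NULL)
  })
  list(nuclei = nuclei, labels = labels, spots = spots, cells = cells,
       scores = scores, units = units)
}

hscore_summary <- function(scores) {
  lapply(scores, function(sc) {
    if (is.null(sc)) return(NULL)
    list(h_score = sc$h_score, n_cells = sc$n_cells,
         denominator = sc$denominator,
         percent_per_class = as.list(sc$percent_per_class))
  })
}

#' Run the pipeline over a set of fields and aggregate per sample
#'
#' Processes each field (TIFF path or [write_field()] directory), writes
#' per-field CSVs (nuclei, spots, cells) and a JSON summary, then pools
#' each sample's cells across its fields and scores the pooled table —
#' pooling, not averaging of field H-scores, since the H-score is defined
#' over the entire area analysed. A failing field is reported and skipped;
#' the remaining fields are still processed.
#'
#' @param config A [pipeline_config()].
#' @param inputs Data frame with columns `sample` and `path` (TIFF file or
#'   simulated-field directory) and optionally `exclusion` (GeoJSON path,
#'   `NA` for none).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `fields` (per-field results), `samples`
#'   (per-sample pooled scores) and `errors` (named character vector of
#'   failures).
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(is.data.frame(inputs), all(c("sample", "path") %in% names(inputs)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  field_results <- list()
  errors <- character(0)
  for (i in seq_len(nrow(inputs))) {
    path <- inputs$path[i]
    name <- sub("\\.tiff?$", "", basename(path))
    res <- tryCatch({
      field <- if (dir.exists(path)) read_field_dir(path) else
        load_and_project(path, pixel_size_um = config$pixel_size_um)
      if ("exclusion" %in% names(inputs) && !is.na(inputs$exclusion[i]) &&
          nzchar(inputs$exclusion[i])) {
        field <- apply_exclusion(field,
                                 read_exclusion_geojson(inputs$exclusion[i]))
      }
      quantify_field(field, config)
    }, error = function(e) {
      errors[[paste0(name, ":quantify")]] <<- conditionMessage(e)
      message(sprintf("field '%s' failed during quantification: %s",
                      path, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    fdir <- file.path(out_dir, "fields", name)
    dir.create(fdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$nuclei, file.path(fdir, "nuclei.csv"), row.names = FALSE)
    utils::write.csv(res$spots, file.path(fdir, "spots.csv"), row.names = FALSE)
    utils::write.csv(res$cells, file.path(fdir, "cells.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(field = name, sample = inputs$sample[i],
           n_cells = nrow(res$cells), seed = config$seed,
           units = as.list(res$units), scores = hscore_summary(res$scores)),
      file.path(fdir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    res$sample <- inputs$sample[i]
    field_results[[name]] <- res
  }

  samples <- list()
  sdir <- file.path(out_dir, "samples")
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  for (smp in unique(inputs$sample)) {
    in_sample <- Filter(function(r) identical(r$sample, smp), field_results)
    if (length(in_sample) == 0) next
    pooled <- do.call(rbind, lapply(in_sample, `[[`, "cells"))
    probes <- unique(unlist(lapply(in_sample, function(r) names(r$scores))))
    scores <- lapply(stats::setNames(probes, probes), function(p) {
      tryCatch(h_score(pooled, p, config$denominator),
               error = function(e) NULL)
    })
    samples[[smp]] <- list(sample = smp, n_fields = length(in_sample),
                           n_cells = nrow(pooled), scores = scores)
    jsonlite::write_json(
      list(sample = smp, n_fields = length(in_sample),
           n_cells = nrow(pooled), scores = hscore_summary(scores)),
      file.path(sdir, paste0(smp, ".json")), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(fields = field_results, samples = samples, errors = errors))
}
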