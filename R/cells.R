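#' Spot-to-cell assignment parameters
#'
#' Puncta are ascribed to the nucleus whose geometric centre is nearest
#' (a Voronoi rule on nucleus centroids), but only within a maximum cell
#' radius of 25 um by default — approximately the maximal soma diameter of
#' the largest cortical neurons. Exact distance ties go to the lowest
#' nucleus id.
#'
#' @param max_cell_radius_um Maximum centroid distance for assignment, um.
#' @param tie_break Tie-break rule; only `"lowest-id"` is defined.
#' @return An `assignment_params` list.
#' @export
assignment_params <- function(max_cell_radius_um = 25,
                              tie_break = "lowest-id") {
  if (!is.numeric(max_cell_radius_um) || max_cell_radius_um <= 0) {
    stop("`max_cell_radius_um` must be positive")
  }
  tie_break <- match.arg(tie_break, "lowest-id")
  structure(list(max_cell_radius_um = max_cell_radius_um,
                 tie_break = tie_break),
            class = "assignment_params")
}

#' Expression binning scheme
#'
#' Cells are classed by probe copies as negative (0 copies) or 1+ to 4+
#' with minimum copies per cell of 1, 4, 10 and 16: class k is the largest
#' class whose minimum does not exceed the count (half-open intervals).
#'
#' @param minima Named numeric vector of class minima; names `"1"`..`"4"`,
#'   strictly increasing, first minimum 1.
#' @return A `binning_scheme` object.
#' @export
binning_scheme <- function(minima = c(`1` = 1, `2` = 4, `3` = 10, `4` = 16)) {
  if (length(minima) < 1 || any(diff(minima) <= 0) || minima[1] < 1) {
    stop("`minima` must be strictly increasing with first minimum >= 1")
  }
  if (is.null(names(minima))) names(minima) <- seq_along(minima)
  structure(minima, class = "binning_scheme")
}

#' Assign puncta to nuclei by centroid proximity
#'
#' @param nuclei Data frame with columns id, x_um, y_um (unique ids).
#' @param spots Data frame from [detect_spots()].
#' @param params An [assignment_params()].
#' @return `spots` with `cell_id` set to the owning nucleus id, or `NA`
#'   when no nucleus centroid lies within the maximum cell radius.
#' @export
assign_spots <- function(nuclei, spots, params = assignment_params()) {
  if (anyDuplicated(nuclei$id)) stop("nucleus ids must be unique")
  if (nrow(spots) == 0) return(spots)
  if (nrow(nuclei) == 0) {
    spots$cell_id <- NA_integer_
    return(spots)
  }
  ord <- order(nuclei$id)  # column order = ascending id, so ties.method
  nx <- nuclei$x_um[ord]   # "first" lands on the lowest id
  ny <- nuclei$y_um[ord]
  ids <- nuclei$id[ord]
  d2 <- outer(spots$x_um, nx, "-")^2 + outer(spots$y_um, ny, "-")^2
  j <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(spots)), j)])
  spots$cell_id <- ifelse(dmin <= params$max_cell_radius_um, ids[j], NA_integer_)
  spots
}

#' Classify a cell's lineage from marker-probe counts
#'
#' A cell is positive for a lineage when it carries `min_count` (default 2)
#' or more copies of that lineage's marker probe. Exactly one positive
#' marker gives that lineage; more than one gives `"multiple"`; none gives
#' `"unclassified"`.
#'
#' @param counts Named numeric vector of per-probe copy counts for one cell.
#' @param lineage_probes Named character vector mapping marker probe name to
#'   lineage label, e.g. `c(P2RY12 = "microglia", SLC1A2 = "astrocyte",
#'   MAP2 = "neuron")`.
#' @param min_count Positivity threshold (default 2).
#' @return Character scalar: a lineage label, `"multiple"` or
#'   `"unclassified"`.
#' @export
classify_lineage <- function(counts, lineage_probes, min_count = 2L) {
  if (length(lineage_probes) == 0) return("unclassified")
  cnt <- counts[names(lineage_probes)]
  cnt[is.na(cnt)] <- 0
  pos <- cnt >= min_count
  if (sum(pos) == 1) unname(lineage_probes[pos]) else
    if (sum(pos) > 1) "multiple" else "unclassified"
}

#' Bin a copy count into expression class 0-4
#'
#' @param copies Non-negative integer vector of per-cell copy counts.
#' @param scheme A [binning_scheme()].
#' @return Integer vector of classes in `{0, .., 4}`; 0 iff 0 copies.
#' @export
classify_bin <- function(copies, scheme = binning_scheme()) {
  if (any(!is.finite(copies)) || any(copies < 0)) {
    stop("`copies` must be non-negative")
  }
  findInterval(copies, as.numeric(scheme))
}

#' Tabulate per-cell results from assigned spots
#'
#' Aggregates assigned spots into one row per nucleus: per-probe copy
#' totals and signal areas, lineage label, and an expression bin for each
#' test probe. Unassigned spots are dropped.
#'
#' @param nuclei Data frame with columns id, x_um, y_um.
#' @param spots Assigned spots with `copies` filled ([count_copies()],
#'   [assign_spots()]).
#' @param lineage_probes Named character vector probe -> lineage label
#'   (may be empty).
#' @param test_probes Character vector of probes to bin; defaults to all
#'   probes present that are not lineage markers.
#' @param scheme A [binning_scheme()].
#' @param min_count Lineage positivity threshold.
#' @return Data frame with columns cell_id, x_um, y_um, lineage, then
#'   `<probe>_copies`, `<probe>_area_um2` for every probe and
#'   `<probe>_bin` for every test probe.
#' @export
tabulate_cells <- function(nuclei, spots, lineage_probes = character(0),
                           test_probes = NULL, scheme = binning_scheme(),
                           min_count = 2L) {
  probes <- sort(unique(c(as.character(spots$probe), names(lineage_probes),
                          test_probes)))
  if (is.null(test_probes)) test_probes <- setdiff(probes, names(lineage_probes))
  cells <- data.frame(cell_id = nuclei$id, x_um = nuclei$x_um,
                      y_um = nuclei$y_um)
  asg <- spots[!is.na(spots$cell_id), , drop = FALSE]
  for (p in probes) {
    sp <- asg[asg$probe == p, , drop = FALSE]
    cp <- vapply(nuclei$id, function(id) sum(sp$copies[sp$cell_id == id]),
                 numeric(1))
    ar <- vapply(nuclei$id, function(id) sum(sp$area_um2[sp$cell_id == id]),
                 numeric(1))
    cells[[paste0(p, "_copies")]] <- as.integer(cp)
    cells[[paste0(p, "_area_um2")]] <- ar
  }
  cells$lineage <- vapply(seq_len(nrow(cells)), function(i) {
    cnt <- stats::setNames(
      as.numeric(cells[i, paste0(probes, "_copies")]), probes)
    classify_lineage(cnt, lineage_probes, min_count)
  }, character(1))
  if (nrow(cells) == 0) cells$lineage <- character(0)
  for (p in test_probes) {
    cells[[paste0(p, "_bin")]] <- classify_bin(cells[[paste0(p, "_copies")]],
                                               scheme)
  }
  cells
}

#' H-score of a probe over a cell population
#'
#' H-score = 1 x (% 1+ cells) + 2 x (% 2+ cells) + 3 x (% 3+ cells) +
#' 4 x (% 4+ cells), the percentages taken over a configurable denominator
#' population; the score ranges from 0 to 400. The default denominator
#' `"probe_positive"` scores among cells with at least one copy of the
#' probe; `"all"` uses every cell; `"lineage:<label>"` restricts to one
#' lineage (cells positive for several lineage markers are labelled
#' `"multiple"` and therefore excluded from any single-lineage denominator).
#'
#' @param cells Data frame from [tabulate_cells()] carrying a
#'   `<probe>_bin` column.
#' @param probe Probe to score.
#' @param denominator `"probe_positive"`, `"all"` or `"lineage:<label>"`.
#' @return An `hscore_result` list: probe, denominator, n_cells,
#'   percent_per_class (named, classes 0-4, summing to 100) and h_score.
#' @export
h_score <- function(cells, probe, denominator = "probe_positive") {
  bcol <- paste0(probe, "_bin")
  if (!bcol %in% names(cells)) {
    stop(sprintf("no bin column for probe '%s'", probe))
  }
  keep <- if (denominator == "all") {
    rep(TRUE, nrow(cells))
  } else if (denominator == "probe_positive") {
    cells[[bcol]] >= 1
  } else if (startsWith(denominator, "lineage:")) {
    cells$lineage == sub("^lineage:", "", denominator)
  } else {
    stop("`denominator` must be 'all', 'probe_positive' or 'lineage:<label>'")
  }
  sub <- cells[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("denominator '%s' selects no cells", denominator))
  }
  pct <- 100 * vapply(0:4, function(k) mean(sub[[bcol]] == k), numeric(1))
  names(pct) <- as.character(0:4)
  structure(list(probe = probe, denominator = denominator,
                 n_cells = nrow(sub), percent_per_class = pct,
                 h_score = sum((1:4) * pct[as.character(1:4)])),
            class = "hscore_result")
}

#' @export
print.hscore_result <- function(x, ...) {
  cat(sprintf("H-score[%s | %s] = %.1f over %d cells\n",
              x$probe, x$denominator, x$h_score, x$n_cells))
  cat("  % per class:",
      paste(sprintf("%s+: %.1f", names(x$percent_per_class),
                    x$percent_per_class), collapse = "  "), "\n")
  invisible(x)
}

#' Total-intensity expression score for high-expressing genes
#'
#' For transcripts so abundant that single puncta merge (e.g. SNAP25 in
#' neurons), punctum counting fails; instead the channel's total
#' above-background intensity over the field is normalised to the number of
#' cells of the relevant lineage in the field.
#'
#' @param channel 2-D probe channel, normalized.
#' @param cells Data frame from [tabulate_cells()] with a `lineage` column.
#' @param lineage Lineage whose cell count is the denominator.
#' @param background Background level; default is the channel median.
#' @return Scalar: summed above-background intensity per lineage cell.
#' @export
intensity_score <- function(channel, cells, lineage = "neuron",
                            background = NULL) {
  n <- sum(cells$lineage == lineage)
  if (n == 0) {
    stop(sprintf("no '%s' cells in field: intensity score undefined", lineage))
  }
  if (is.null(background)) background <- stats::median(channel)
  sum(pmax(channel - background, 0)) / n
}

#' Score per-cell copy tables taken directly from ground truth
#'
#' Builds a cell table from known per-cell per-probe copy counts (for
#' example a simulation's truth tables), bypassing segmentation and
#' detection, so scores computed from imaging can be compared against
#' scores from the generating truth.
#'
#' @param cell_probe_copies Data frame (cell_id, probe, copies).
#' @param lineage_probes Named character vector probe -> lineage label.
#' @param scheme A [binning_scheme()].
#' @param min_count Lineage positivity threshold.
#' @return A cell table as from [tabulate_cells()] (without coordinates or
#'   areas).
#' @export
cells_from_truth <- function(cell_probe_copies,
                             lineage_probes = character(0),
                             scheme = binning_scheme(), min_count = 2L) {
  ids <- sort(unique(cell_probe_copies$cell_id))
  probes <- sort(unique(c(as.character(cell_probe_copies$probe),
                          names(lineage_probes))))
  cells <- data.frame(cell_id = ids)
  for (p in probes) {
    sub <- cell_probe_copies[cell_probe_copies$probe == p, , drop = FALSE]
    cp <- stats::setNames(rep(0L, length(ids)), ids)
    cp[as.character(sub$cell_id)] <- sub$copies
    cells[[paste0(p, "_copies")]] <- as.integer(unname(cp))
  }
  cells$lineage <- vapply(seq_len(nrow(cells)), function(i) {
    cnt <- stats::setNames(as.numeric(cells[i, paste0(probes, "_copies")]),
                           probes)
    classify_lineage(cnt, lineage_probes, min_count)
  }, character(1))
  if (nrow(cells) == 0) cells$lineage <- character(0)
  for (p in setdiff(probes, names(lineage_probes))) {
    cells[[paste0(p, "_bin")]] <- classify_bin(cells[[paste0(p, "_copies")]],
                                               scheme)
  }
  cells
}
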