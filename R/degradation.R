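#' Probe detectability under RNA fragmentation
#'
#' RNAscope-style assays tile a transcript with up to 20 adjacent double-Z
#' probe pairs and amplify a detectable punctum whenever at least 3
#' consecutive pairs anneal. Fragmented RNA therefore remains detectable as
#' long as some fragment still spans a run of intact pair sites, which is
#' why punctum counts are robust to RNA quality that ruins qPCR. This model
#' makes that argument quantitative at probe-pair granularity: breaks fall
#' at the junctions between adjacent pair sites, never inside one.
#'
#' @param n_pairs Number of double-Z pair sites tiling the transcript
#'   (default 20).
#' @param min_intact_run Consecutive intact pair sites needed for a
#'   detectable signal (default 3).
#' @param expected_breaks Expected number of strand breaks per molecule;
#'   each molecule receives Poisson(`expected_breaks`) breaks placed
#'   uniformly (with replacement) on the `n_pairs - 1` junctions.
#' @param n_molecules Number of molecules to simulate (> 0).
#' @param seed Integer seed.
#' @return A `degradation_model` list.
#' @export
degradation_model <- function(n_pairs = 20L, min_intact_run = 3L,
                              expected_breaks = 0, n_molecules = 1e5,
                              seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  min_intact_run <- as.integer(min_intact_run)
  if (n_pairs < 1) stop("`n_pairs` must be >= 1")
  if (min_intact_run < 1) stop("`min_intact_run` must be >= 1")
  if (!is.finite(expected_breaks) || expected_breaks < 0) {
    stop("`expected_breaks` must be non-negative")
  }
  n_molecules <- as.integer(n_molecules)
  if (is.na(n_molecules) || n_molecules <= 0) {
    stop("`n_molecules` must be positive")
  }
  structure(list(n_pairs = n_pairs, min_intact_run = min_intact_run,
                 expected_breaks = expected_breaks,
                 n_molecules = n_molecules, seed = as.integer(seed)),
            class = "degradation_model")
}

#' Fraction of molecules still detectable after fragmentation
#'
#' Monte-Carlo estimate: each molecule draws a Poisson number of breaks,
#' scatters them uniformly over the junctions between adjacent probe-pair
#' sites, and is detectable iff some resulting fragment carries at least
#' `min_intact_run` consecutive intact sites. With zero expected breaks the
#' fraction is exactly 1 (for any admissible run length); a run length
#' exceeding `n_pairs` forces 0.
#'
#' @param model A [degradation_model()].
#' @return Scalar in `[0, 1]`: the detectable fraction.
#' @export
simulate_detection_after_degradation <- function(model) {
  if (!inherits(model, "degradation_model")) {
    stop("`model` must be created by degradation_model()")
  }
  if (model$min_intact_run > model$n_pairs) return(0)
  if (model$expected_breaks == 0) return(1)
  n_junctions <- model$n_pairs - 1L
  if (n_junctions == 0L) return(1)  # a single pair site cannot be fragmented
  withr::with_seed(model$seed, {
    breaks <- stats::rpois(model$n_molecules, model$expected_breaks)
    cut <- matrix(FALSE, model$n_molecules, n_junctions)
    for (k in sort(unique(breaks[breaks > 0]))) {
      rows <- which(breaks == k)
      # k uniform junction draws per molecule; repeats collapse in `cut`
      cut[cbind(rep(rows, k),
                sample.int(n_junctions, length(rows) * k, replace = TRUE))] <- TRUE
    }
    mean(detectable_from_cuts(cut, model$n_pairs, model$min_intact_run))
  })
}

# given a molecules x junctions cut-indicator matrix, is any window of
# `min_run` consecutive pair sites free of internal cuts?
detectable_from_cuts <- function(cut, n_pairs, min_run) {
  if (min_run <= 1) return(rep(TRUE, nrow(cut)))
  w <- min_run - 1L  # junctions spanned by a window of min_run sites
  n_junctions <- ncol(cut)
  cs <- cbind(0L, matrix(cut, nrow(cut)) %*% upper.tri(diag(n_junctions), diag = TRUE))
  windows <- lapply(seq_len(n_pairs - min_run + 1L), function(i) {
    cs[, i + w] - cs[, i]
  })
  Reduce(pmin, windows) == 0
}

#' Detectability curve over a grid of break rates
#'
#' Convenience wrapper evaluating [simulate_detection_after_degradation()]
#' over a vector of expected break counts (one independent simulation per
#' rate, seeds derived from `seed`).
#'
#' @param expected_breaks Numeric vector of break rates.
#' @param n_pairs,min_intact_run,n_molecules,seed See [degradation_model()].
#' @return Data frame with columns `expected_breaks` and
#'   `fraction_detectable`.
#' @export
detectability_curve <- function(expected_breaks, n_pairs = 20L,
                                min_intact_run = 3L, n_molecules = 1e5,
                                seed = 1L) {
  frac <- vapply(seq_along(expected_breaks), function(i) {
    m <- degradation_model(n_pairs = n_pairs, min_intact_run = min_intact_run,
                           expected_breaks = expected_breaks[i],
                           n_molecules = n_molecules,
                           seed = seed + i - 1L)
    simulate_detection_after_degradation(m)
  }, numeric(1))
  data.frame(expected_breaks = expected_breaks, fraction_detectable = frac)
}
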