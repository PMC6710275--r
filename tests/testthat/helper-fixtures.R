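# Shared fixtures and independent oracles, all built in code.

.fixtures <- new.env(parent = emptyenv())

# the canonical simulated field: defaults, fixed seed; built once per run
default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- generate_field(synth_config(seed = 42))
  }
  .fixtures$sim
}

# binary disk mask (matrix of 0/1), centred
make_disk <- function(r_px, n = 2 * r_px + 9, value = 1) {
  m <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  d2 <- (row(m) - c0)^2 + (col(m) - c0)^2
  m[d2 <= r_px^2] <- value
  m
}

# two disks of radius r whose borders overlap by `frac` of the radius
make_disk_pair <- function(r_px = 15, frac = 0.2, n = 80, value = 0.8) {
  m <- matrix(0, n, n)
  off <- r_px * (2 - frac) / 2
  for (cx in c(n / 2 - off, n / 2 + off)) {
    d2 <- (row(m) - cx)^2 + (col(m) - n / 2)^2
    m[d2 <= r_px^2] <- value
  }
  m
}

# channel with 2-D Gaussian puncta at given pixel centres
gaussian_channel <- function(dim_px, centres_px, masses, sigma_px,
                             background = 0) {
  m <- matrix(background, dim_px[1], dim_px[2])
  for (k in seq_len(nrow(centres_px))) {
    i <- seq_len(dim_px[1]); j <- seq_len(dim_px[2])
    gx <- exp(-(i - centres_px[k, 1])^2 / (2 * sigma_px^2))
    gy <- exp(-(j - centres_px[k, 2])^2 / (2 * sigma_px^2))
    m <- m + masses[k] / (2 * pi * sigma_px^2) * outer(gx, gy)
  }
  m
}

# exhaustive oracle: P(some fragment has >= min_run consecutive intact
# sites) given exactly n_breaks uniform junction draws (with replacement)
enum_detect_prob <- function(n_pairs, min_run, n_breaks) {
  if (n_breaks == 0) return(as.numeric(n_pairs >= min_run))
  J <- n_pairs - 1
  grid <- as.matrix(expand.grid(rep(list(seq_len(J)), n_breaks)))
  mean(apply(grid, 1, function(cuts) {
    cuts <- sort(unique(cuts))
    max(diff(c(0, cuts, n_pairs))) >= min_run
  }))
}

# Poisson-mixture detectability, exact up to `max_breaks` (tail bounded by 0)
mixture_detect_prob <- function(n_pairs, min_run, lambda, max_breaks) {
  probs <- vapply(0:max_breaks, function(b) {
    dpois(b, lambda) * enum_detect_prob(n_pairs, min_run, b)
  }, numeric(1))
  c(lower = sum(probs), upper = sum(probs) + ppois(max_breaks, lambda,
                                                   lower.tail = FALSE))
}

# brute-force nearest-centroid-within-radius assignment oracle
brute_assign <- function(nuclei, spots, max_radius) {
  out <- rep(NA_integer_, nrow(spots))
  for (s in seq_len(nrow(spots))) {
    best <- NA_integer_; best_d <- Inf
    for (k in order(nuclei$id)) {
      d <- sqrt((spots$x_um[s] - nuclei$x_um[k])^2 +
                  (spots$y_um[s] - nuclei$y_um[k])^2)
      if (d < best_d) { best_d <- d; best <- nuclei$id[k] }
    }
    if (best_d <= max_radius) out[s] <- best
  }
  out
}

# exact Mann-Whitney oracle: U by pairwise comparison (ties count 1/2),
# p by enumerating every assignment of the pooled values to group A
brute_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  mu <- na * nb / 2
  sets <- utils::combn(na + nb, na)
  u_all <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  one_tail <- if (u_obs >= mu) mean(u_all >= u_obs - eps) else
    mean(u_all <= u_obs + eps)
  min(1, 2 * one_tail)
}

# small truth table used by several cell-level tests
toy_truth <- function() {
  data.frame(
    cell_id = rep(1:6, times = 4),
    probe = rep(c("P2RY12", "SLC1A2", "MAP2", "TREM2"), each = 6),
    copies = c(2, 0, 0, 5, 0, 1,    # P2RY12
               0, 3, 0, 2, 0, 0,    # SLC1A2
               0, 2, 4, 0, 0, 0,    # MAP2
               3, 0, 16, 10, 4, 1)) # TREM2
}

lineage_map <- c(P2RY12 = "microglia", SLC1A2 = "astrocyte", MAP2 = "neuron")
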