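test_that("assignment honours the maximum cell radius", {
  nuc <- data.frame(id = 1L, x_um = 0, y_um = 0)
  sp <- data.frame(probe = "P", x_um = c(30, 24), y_um = 0, area_um2 = 1,
                   integrated_intensity = 1, peak_intensity = 0.1,
                   copies = 1L, cell_id = NA)
  out <- assign_spots(nuc, sp)
  expect_true(is.na(out$cell_id[1]))   # 30 um > 25 um
  expect_equal(out$cell_id[2], 1L)
})

test_that("exact distance ties break to the lowest nucleus id", {
  nuc <- data.frame(id = c(7L, 3L), x_um = c(20, 0), y_um = 0)
  sp <- data.frame(probe = "P", x_um = 10, y_um = 0, area_um2 = 1,
                   integrated_intensity = 1, peak_intensity = 0.1,
                   copies = 1L, cell_id = NA)
  expect_equal(assign_spots(nuc, sp)$cell_id, 3L)
})

test_that("assignment equals the brute-force all-pairs oracle", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      nuc <- data.frame(id = sample(1:99, 50), x_um = runif(50, 0, 150),
                        y_um = runif(50, 0, 150))
      sp <- data.frame(probe = "P", x_um = runif(500, 0, 150),
                       y_um = runif(500, 0, 150), area_um2 = 1,
                       integrated_intensity = 1, peak_intensity = 0.1,
                       copies = 1L, cell_id = NA)
      got <- assign_spots(nuc, sp)$cell_id
      expect_identical(got, brute_assign(nuc, sp, 25))
    }
  })
})

test_that("every assigned spot is nearest to its own nucleus within 25 um", {
  sim <- default_sim()
  seg <- segment_nuclei(sim$field$channels$DAPI, sim$field$pixel_size_um)
  sp <- detect_spots(sim$field$channels$PPIB, sim$field$pixel_size_um,
                     probe = "PPIB")
  sp <- assign_spots(seg$nuclei, sp)
  asg <- sp[!is.na(sp$cell_id), ]
  for (i in seq_len(nrow(asg))) {
    d <- sqrt((asg$x_um[i] - seg$nuclei$x_um)^2 +
                (asg$y_um[i] - seg$nuclei$y_um)^2)
    own <- d[seg$nuclei$id == asg$cell_id[i]]
    expect_lte(own, 25)
    expect_lte(own, min(d) + 1e-9)
  }
})

test_that("lineage calls follow the two-or-more-counts rule", {
  expect_equal(classify_lineage(c(P2RY12 = 2, SLC1A2 = 0, MAP2 = 0),
                                lineage_map), "microglia")
  expect_equal(classify_lineage(c(P2RY12 = 1, SLC1A2 = 0, MAP2 = 0),
                                lineage_map), "unclassified")
  expect_equal(classify_lineage(c(P2RY12 = 0, SLC1A2 = 3, MAP2 = 2),
                                lineage_map), "multiple")
  expect_equal(classify_lineage(c(SLC1A2 = 9), lineage_map["SLC1A2"],
                                min_count = 10), "unclassified")
})

test_that("bin classes sit exactly on the printed minima", {
  expect_equal(classify_bin(c(0, 1, 3, 4, 9, 10, 15, 16, 100)),
               c(0, 1, 1, 2, 2, 3, 3, 4, 4))
  expect_true(all(diff(classify_bin(0:60)) >= 0))
  expect_error(classify_bin(-1), "non-negative")
})

test_that("H-score spans 0 to 400 and is linear in class percentages", {
  mk <- function(copies) {
    cells_from_truth(data.frame(cell_id = seq_along(copies), probe = "T",
                                copies = copies))
  }
  expect_equal(h_score(mk(rep(16, 10)), "T", "all")$h_score, 400)
  expect_equal(h_score(mk(rep(0, 10)), "T", "all")$h_score, 0)
  expect_equal(h_score(mk(c(rep(1, 5), rep(4, 5))), "T", "all")$h_score, 150)
  hs <- h_score(mk(c(0, 1, 4, 10, 16)), "T", "all")
  expect_equal(sum(hs$percent_per_class), 100)
  expect_equal(hs$h_score, 20 * (1 + 2 + 3 + 4))
  expect_error(h_score(mk(rep(0, 4)), "T", "probe_positive"), "no cells")
})

test_that("raising one cell's class never lowers the H-score", {
  base <- c(0, 1, 1, 4, 4, 10, 16, 2, 5, 11)
  mins <- c(0, 1, 4, 10, 16)
  for (i in seq_along(base)) {
    cls <- classify_bin(base[i])
    if (cls == 4) next
    bumped <- base
    bumped[i] <- mins[cls + 2]  # smallest count of the next class
    h0 <- h_score(cells_from_truth(
      data.frame(cell_id = seq_along(base), probe = "T", copies = base)),
      "T", "all")$h_score
    h1 <- h_score(cells_from_truth(
      data.frame(cell_id = seq_along(base), probe = "T", copies = bumped)),
      "T", "all")$h_score
    expect_gte(h1, h0)
  }
})

test_that("cell tables from truth match a hand-computed oracle", {
  cells <- cells_from_truth(toy_truth(), lineage_map)
  expect_equal(cells$lineage,
               c("microglia", "multiple", "neuron", "multiple",
                 "unclassified", "unclassified"))
  expect_equal(cells$TREM2_bin, c(1, 0, 4, 3, 2, 1))
  # independent H-score arithmetic on the same table
  hs <- h_score(cells, "TREM2", "all")
  pct <- 100 * as.numeric(table(factor(c(1, 0, 4, 3, 2, 1), 0:4))) / 6
  expect_equal(hs$h_score, sum(1:4 * pct[2:5]))
  # lineage-restricted denominator excludes "multiple" cells
  hm <- h_score(cells, "TREM2", "lineage:microglia")
  expect_equal(hm$n_cells, 1)
  expect_equal(hm$h_score, 100)
})

test_that("tabulate_cells aggregates assigned spot copies per probe", {
  nuc <- data.frame(id = 1:2, x_um = c(0, 50), y_um = 0)
  sp <- data.frame(probe = c("TREM2", "TREM2", "P2RY12", "TREM2"),
                   x_um = c(1, 2, 1, 51), y_um = 0, area_um2 = 0.5,
                   integrated_intensity = 1, peak_intensity = 0.1,
                   copies = c(2L, 1L, 3L, 4L), cell_id = NA)
  sp <- assign_spots(nuc, sp)
  cells <- tabulate_cells(nuc, sp, lineage_probes = lineage_map["P2RY12"])
  expect_equal(cells$TREM2_copies, c(3L, 4L))
  expect_equal(cells$P2RY12_copies, c(3L, 0L))
  expect_equal(cells$TREM2_area_um2, c(1.0, 0.5))
  expect_equal(cells$lineage, c("microglia", "unclassified"))
  expect_equal(cells$TREM2_bin, c(1L, 2L))
})

test_that("intensity score is a guarded, linear per-cell normalisation", {
  cells <- data.frame(cell_id = 1:4,
                      lineage = c("neuron", "neuron", "microglia",
                                  "unclassified"))
  ch <- matrix(0.1, 32, 32)
  ch[10:12, 10:12] <- 0.6
  expect_error(intensity_score(ch, cells[cells$lineage == "microglia", ],
                               "neuron"), "undefined")
  s1 <- intensity_score(ch, cells, "neuron")
  expect_equal(s1, 9 * 0.5 / 2)  # 9 px, 0.5 above the 0.1 background median
  doubled <- matrix(0.1, 32, 32); doubled[10:12, 10:12] <- 1.1
  expect_equal(intensity_score(doubled, cells, "neuron"), 2 * s1)
})
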