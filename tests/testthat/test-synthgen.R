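test_that("empty scene yields background-only channels and empty truth", {
  cfg <- synth_config(field_size_px = c(256, 256), n_nuclei = 0,
                      probe_specs = list(probe_spec("PPIB", mean_copies = 0)),
                      seed = 3)
  sim <- generate_field(cfg)
  expect_equal(nrow(sim$truth$nuclei), 0)
  expect_equal(nrow(sim$truth$spots), 0)
  for (ch in sim$field$channels) {
    # nothing but constant background plus clipped Gaussian noise
    expect_lt(max(abs(ch - cfg$background_level)), 6 * cfg$noise_sd)
  }
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(field_size_px = c(256, 256), n_nuclei = 4,
                      min_nucleus_separation_um = 12,
                      spot_placement_radius_um = 5, seed = 11)
  s1 <- generate_field(cfg)
  s2 <- generate_field(cfg)
  expect_identical(s1$field$channels, s2$field$channels)
  expect_identical(s1$truth, s2$truth)
})

test_that("spot truth copies are conserved against the per-cell table", {
  sim <- default_sim()
  owned <- sim$truth$spots[!is.na(sim$truth$spots$cell_id), , drop = FALSE]
  agg <- stats::aggregate(copies ~ cell_id + probe, owned, sum)
  m <- merge(sim$truth$cell_probe_copies, agg, by = c("cell_id", "probe"),
             all.x = TRUE, suffixes = c("_table", "_spots"))
  m$copies_spots[is.na(m$copies_spots)] <- 0
  expect_equal(m$copies_spots, m$copies_table)
  # total rendered copies equal the sum of drawn per-cell counts
  expect_equal(sum(owned$copies), sum(sim$truth$cell_probe_copies$copies))
})

test_that("rendered intensities stay in [0, 1]", {
  sim <- default_sim()
  for (ch in sim$field$channels) {
    expect_gte(min(ch), 0)
    expect_lte(max(ch), 1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(synth_config(noise_sd = -0.1), "non-negative")
  expect_error(synth_config(nucleus_radius_um = c(0, 5)), "positive")
  expect_error(synth_config(spot_placement_radius_um = 30), "25")
  expect_error(probe_spec("P", fraction_positive = 1.2), "0, 1")
  expect_error(synth_config(probe_specs = list(probe_spec("DAPI"))),
               "reserved")
})

test_that("a written field round-trips through TIFF and CSV", {
  cfg <- synth_config(field_size_px = c(256, 256), n_nuclei = 4,
                      min_nucleus_separation_um = 12,
                      spot_placement_radius_um = 5, seed = 5)
  sim <- generate_field(cfg)
  dir <- withr::local_tempdir()
  write_field(sim, cfg, dir)
  back <- read_field_dir(dir)
  expect_identical(names(back$channels), names(sim$field$channels))
  for (nm in names(back$channels)) {
    # 16-bit quantization bounds the round-trip error
    expect_lt(max(abs(back$channels[[nm]] - sim$field$channels[[nm]])),
              1 / 65535)
  }
  spots <- read.csv(file.path(dir, "truth_spots.csv"))
  expect_equal(spots$copies, sim$truth$spots$copies)
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$unit_copy_intensity, cfg$unit_copy_intensity)
})

test_that("autofluorescent blobs land in the configured channel only", {
  base <- list(field_size_px = c(256, 256), n_nuclei = 0,
               probe_specs = list(probe_spec("TREM2", mean_copies = 0),
                                  probe_spec("GFAP", mean_copies = 0)),
               noise_sd = 0, seed = 9)
  clean <- generate_field(do.call(synth_config, base))
  blobby <- generate_field(do.call(synth_config, c(base, list(
    autofluorescent_blob_rate = 5, autofluorescence_channel = "GFAP"))))
  expect_equal(blobby$field$channels$TREM2, clean$field$channels$TREM2)
  expect_gt(sum(blobby$field$channels$GFAP - clean$field$channels$GFAP), 0)
})
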