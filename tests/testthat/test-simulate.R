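test_that("ground truth is deterministic per seed and honours its contracts", {
  cfg <- flim_sim_config(image_size = 64, meta = fast_meta(),
                         n_dsb_foci = 6, dsb_radius_px = 4, seed = 7)
  gt1 <- make_ground_truth(cfg)
  gt2 <- make_ground_truth(cfg)
  expect_identical(gt1$compact_map$values, gt2$compact_map$values)
  expect_identical(gt1$dsb_map$values, gt2$dsb_map$values)

  nuc <- gt1$nucleus$values
  expect_true(all(nuc[gt1$compact_map$values]))   # compact inside nucleus
  expect_true(all(nuc[gt1$dsb_map$values]))       # DSB inside nucleus
  expect_false(any(gt1$compact_map$values & gt1$dsb_map$values)) # DSBs open
  # nucleus covers roughly 70% of the frame
  expect_equal(mean(nuc), 0.7, tolerance = 0.05)
  # E / tau fields match the maps
  expect_true(all(gt1$per_pixel_E[gt1$compact_map$values] == cfg$fret_e_compact))
  expect_true(all(gt1$per_pixel_E[nuc & !gt1$compact_map$values] == 0))
  expect_true(all(is.na(gt1$per_pixel_tau_ns[!nuc])))
})

test_that("realized compact area fraction hits its target", {
  for (target in c(0, 0.15, 0.3)) {
    cfg <- flim_sim_config(image_size = 96, meta = fast_meta(),
                           n_dsb_foci = 8, compact_area_fraction = target,
                           seed = 13)
    gt <- make_ground_truth(cfg)
    realized <- sum(gt$compact_map$values) / sum(gt$nucleus$values)
    expect_lt(abs(realized - target), 0.02)
  }
  # unreachable targets are a configuration error
  expect_error(
    make_ground_truth(flim_sim_config(image_size = 96, meta = fast_meta(),
                                      n_dsb_foci = 0L,
                                      compact_area_fraction = 0.5,
                                      n_compact_foci = 2L, seed = 13)),
    class = "chromphasor_config_error")
})

test_that("simulated decays are bit-reproducible and Poisson-distributed", {
  cfg <- flim_sim_config(image_size = 32, meta = fast_meta(),
                         n_dsb_foci = 2, dsb_radius_px = 3, seed = 19)
  c1 <- simulate_cell(cfg)
  c2 <- simulate_cell(cfg)
  expect_identical(c1$donor$counts, c2$donor$counts)
  expect_identical(c1$if_channel$values, c2$if_channel$values)

  # per-pixel photon totals over open pixels are iid Poisson(photons_per_pixel)
  open_px <- c1$ground_truth$nucleus$values & !c1$ground_truth$compact_map$values
  tot <- apply(c1$donor$counts, c(1, 2), sum)[open_px]
  cfg2 <- flim_sim_config(image_size = 32, meta = fast_meta(),
                          n_dsb_foci = 2, dsb_radius_px = 3, seed = 20)
  tot <- c(tot, apply(simulate_cell(cfg2)$donor$counts, c(1, 2), sum)[
    make_ground_truth(cfg2)$nucleus$values &
      !make_ground_truth(cfg2)$compact_map$values])
  expect_equal(mean(tot), cfg$photons_per_pixel, tolerance = 0.02)
  expect_equal(var(tot) / mean(tot), 1, tolerance = 0.15)
})

test_that("pure open and pure compact nuclei converge on the published phasors", {
  base <- list(image_size = 64, photons_per_pixel = 5000, n_dsb_foci = 0L,
               compact_focus_radius_px = 10)
  cfg_open <- do.call(flim_sim_config,
                      c(base, list(compact_area_fraction = 0, seed = 29)))
  cell <- simulate_cell(cfg_open)
  mp <- mean_phasor(phasor_transform(cell$donor), cell$ground_truth$nucleus)
  expect_equal(mp$g, 0.3877, tolerance = 0.01)
  expect_equal(mp$s, 0.4872, tolerance = 0.01)

  cfg_comp <- do.call(flim_sim_config,
                      c(base, list(compact_area_fraction = 1, seed = 29)))
  cellc <- simulate_cell(cfg_comp)
  mpc <- mean_phasor(phasor_transform(cellc$donor), cellc$ground_truth$nucleus)
  expect_equal(mpc$g, 0.4730, tolerance = 0.01)
  expect_equal(mpc$s, 0.4993, tolerance = 0.01)
})

test_that("raising the compact FRET efficiency rotates its phasor clockwise", {
  g_prev <- -Inf
  for (E in c(0.1, 0.16, 0.3, 0.5)) {
    cfg <- flim_sim_config(image_size = 48, fret_e_compact = E,
                           compact_area_fraction = 1,
                           compact_focus_radius_px = 10, n_dsb_foci = 0L,
                           poisson_noise = FALSE, seed = 3)
    cell <- simulate_cell(cfg)
    mp <- mean_phasor(phasor_transform(cell$donor), cell$ground_truth$nucleus)
    expect_gt(mp$g, g_prev) # g grows toward (1, 0) as lifetimes shorten
    g_prev <- mp$g
  }
})

test_that("the simulated reference dye sits at its closed-form phasor", {
  ref <- simulate_reference(4.04, size = 4)
  mp <- mean_phasor(phasor_transform(ref))
  th <- oracle_exp_phasor(4.04)
  expect_equal(mp$g, unname(th["g"]), tolerance = 2e-3)
  expect_equal(mp$s, unname(th["s"]), tolerance = 2e-3)

  # whole-bin phase corruption is an exact rotation; uniform admixture an
  # exact scaling
  bad <- simulate_reference(4.04, size = 4, phase_shift_bins = 9L,
                            mod_scale = 0.75)
  mb <- mean_phasor(phasor_transform(bad))
  clean <- mean_phasor(phasor_transform(simulate_reference(4.04, size = 4)))
  theta <- 2 * pi * 9 / 256
  expect_equal(mb$g, 0.75 * (cos(theta) * clean$g - sin(theta) * clean$s),
               tolerance = 1e-9)
  expect_equal(mb$s, 0.75 * (sin(theta) * clean$g + cos(theta) * clean$s),
               tolerance = 1e-9)

  # Poisson reference reproduces per seed
  n1 <- simulate_reference(4.04, size = 4, photons_per_pixel = 1e4,
                           poisson_noise = TRUE, seed = 5)
  n2 <- simulate_reference(4.04, size = 4, photons_per_pixel = 1e4,
                           poisson_noise = TRUE, seed = 5)
  expect_identical(n1$counts, n2$counts)
})

test_that("configuration validation rejects unphysical settings", {
  expect_error(flim_sim_config(fret_e_compact = 1), class = "chromphasor_error")
  expect_error(flim_sim_config(compact_area_fraction = 1.2),
               class = "chromphasor_error")
  expect_error(flim_sim_config(photons_per_pixel = 0),
               class = "chromphasor_error")
  expect_error(flim_sim_config(image_size = 16, dsb_radius_px = 10),
               class = "chromphasor_error")
})
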