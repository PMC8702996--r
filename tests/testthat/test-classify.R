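pal <- default_palette()
open_c <- pal[pal$label == "open", ]
comp_c <- pal[pal$label == "compact", ]

test_that("cursor assignment: centres, tie-break, and photon threshold", {
  meta <- flim_meta()
  mid_g <- (open_c$g + comp_c$g) / 2
  mid_s <- (open_c$s + comp_c$s) / 2
  g <- matrix(c(open_c$g, comp_c$g, mid_g, 0.9), 2, 2)
  s <- matrix(c(open_c$s, comp_c$s, mid_s, 0.1), 2, 2)
  photons <- matrix(100, 2, 2)
  cm <- classify_pixels(make_phasor_image(g, s, photons, meta), pal)
  expect_equal(cm$labels[1, 1], 1L) # at open centre
  expect_equal(cm$labels[2, 1], 2L) # at compact centre
  expect_equal(cm$labels[1, 2], 2L) # equidistant inside both -> compact
  expect_equal(cm$labels[2, 2], 0L) # far from both

  # photon threshold gates classification
  photons[1, 1] <- 10
  cm2 <- classify_pixels(make_phasor_image(g, s, photons, meta), pal,
                         photon_threshold = 30)
  expect_equal(cm2$labels[1, 1], 0L)
})

test_that("every pixel gets exactly one label and counts partition", {
  cfg <- flim_sim_config(image_size = 48, meta = fast_meta(),
                         n_dsb_foci = 4, dsb_radius_px = 3,
                         compact_focus_radius_px = 2, seed = 3)
  cell <- simulate_cell(cfg)
  cm <- classify_pixels(phasor_transform(cell$donor))
  tab <- tabulate(cm$labels + 1L, 3L)
  expect_equal(sum(tab), prod(dim(cm$labels)))
  df <- tibble::as_tibble(cm)
  expect_equal(nrow(df), prod(dim(cm$labels)))
  expect_false(anyNA(df$label))
})

test_that("noiseless simulation is classified exactly as the ground truth", {
  cfg <- flim_sim_config(image_size = 64, n_dsb_foci = 5, dsb_radius_px = 4,
                         poisson_noise = FALSE, seed = 5)
  cell <- simulate_cell(cfg)
  gt <- cell$ground_truth
  cm <- classify_pixels(phasor_transform(cell$donor))
  nuc <- gt$nucleus$values
  expect_identical(cm$labels == 2L, gt$compact_map$values)
  expect_identical(cm$labels == 1L, nuc & !gt$compact_map$values)
  expect_true(all(cm$labels[!nuc] == 0L)) # dark pixels below photon threshold
})

test_that("enlarging the compact cursor never loses compact pixels", {
  cfg <- flim_sim_config(image_size = 48, meta = fast_meta(),
                         n_dsb_foci = 4, dsb_radius_px = 3,
                         photons_per_pixel = 150, seed = 9)
  ph <- phasor_transform(simulate_cell(cfg)$donor)
  n_prev <- -1L
  for (r in c(0.03, 0.05, 0.08, 0.12)) {
    pal_r <- default_palette(radius = r)
    n <- compact_fraction(classify_pixels(ph, pal_r))$n_compact
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("compact fraction counts only classified pixels", {
  meta <- flim_meta()
  # 70 open pixels, 30 compact, 50 sub-threshold
  g <- matrix(c(rep(open_c$g, 70), rep(comp_c$g, 30), rep(open_c$g, 50)),
              15, 10)
  s <- matrix(c(rep(open_c$s, 70), rep(comp_c$s, 30), rep(open_c$s, 50)),
              15, 10)
  photons <- matrix(c(rep(100, 100), rep(5, 50)), 15, 10)
  cm <- classify_pixels(make_phasor_image(g, s, photons, meta), pal)
  fr <- compact_fraction(cm)
  expect_equal(fr$n_open, 70L)
  expect_equal(fr$n_compact, 30L)
  expect_equal(fr$fraction_compact, 0.30)

  # all-unclassified region is flagged undefined
  empty <- compact_fraction(cm, matrix(c(rep(FALSE, 100), rep(TRUE, 50)), 15, 10))
  expect_true(is.na(empty$fraction_compact))
})

test_that("fractions are recovered under Poisson noise at realistic budgets", {
  for (seed in 1:3) {
    cfg <- flim_sim_config(image_size = 64, compact_area_fraction = 0.5,
                           compact_focus_radius_px = 4, n_dsb_foci = 0,
                           photons_per_pixel = 500, seed = seed)
    cell <- simulate_cell(cfg)
    gt_frac <- sum(cell$ground_truth$compact_map$values) /
      sum(cell$ground_truth$nucleus$values)
    cm <- classify_pixels(phasor_transform(cell$donor))
    est <- compact_fraction(cm, cell$ground_truth$nucleus)$fraction_compact
    expect_lt(abs(est - gt_frac), 0.05)
  }
  # the balanced case holds down to 100 photons/pixel
  cfg <- flim_sim_config(image_size = 64, compact_area_fraction = 0.5,
                         compact_focus_radius_px = 4, n_dsb_foci = 0,
                         photons_per_pixel = 100, seed = 11)
  cell <- simulate_cell(cfg)
  gt_frac <- sum(cell$ground_truth$compact_map$values) /
    sum(cell$ground_truth$nucleus$values)
  est <- compact_fraction(classify_pixels(phasor_transform(cell$donor)),
                          cell$ground_truth$nucleus)$fraction_compact
  expect_lt(abs(est - gt_frac), 0.05)
})

test_that("acceptor-excess check uses nucleus means and strict inequality", {
  don <- intensity_image(matrix(10, 4, 4))
  nuc <- binary_mask(matrix(TRUE, 4, 4))
  expect_equal(
    acceptor_excess_check(don, intensity_image(matrix(20, 4, 4)), nuc),
    tibble::tibble(ratio = 2, pass = TRUE))
  eq <- acceptor_excess_check(don, don, nuc)
  expect_equal(eq$ratio, 1)
  expect_false(eq$pass)
  zero <- acceptor_excess_check(don, intensity_image(matrix(0, 4, 4)), nuc)
  expect_equal(zero$ratio, 0)
  expect_false(zero$pass)
  expect_error(
    acceptor_excess_check(intensity_image(matrix(0, 4, 4)), don, nuc),
    class = "chromphasor_error")
})
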