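test_that("phasor transform limits: delta decay and uniform decay", {
  meta <- flim_meta(n_bins = 1024L)
  delta <- rep(0, 1024); delta[1] <- 1000
  ph <- phasor_transform(profile_stack(delta, meta))
  expect_equal(ph$g[1, 1], 1, tolerance = 1e-4)
  expect_equal(ph$s[1, 1], 0, tolerance = 5e-3)

  unif <- profile_stack(rep(10, 1024), meta)
  phu <- phasor_transform(unif)
  expect_equal(phu$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(phu$s[1, 1], 0, tolerance = 1e-12)
})

test_that("discretized exponential lands on the closed-form phasor", {
  meta <- flim_meta() # 256 bins, 80 MHz
  counts <- oracle_exp_counts(2.5, meta$n_bins, period_ns(meta))
  ph <- phasor_transform(profile_stack(counts, meta))
  th <- oracle_exp_phasor(2.5)
  expect_equal(ph$g[1, 1], unname(th["g"]), tolerance = 2e-3)
  expect_equal(ph$s[1, 1], unname(th["s"]), tolerance = 2e-3)
})

test_that("single-exponential phasors match the published cursor coordinates", {
  p <- single_exponential_phasor(c(2.5, 2.1), flim_meta())
  expect_equal(round(p$g, 2), c(0.39, 0.47))
  expect_equal(round(p$s, 2), c(0.49, 0.50))
  # limits
  expect_equal(single_exponential_phasor(1e-6)$g, 1, tolerance = 1e-6)
  lim <- single_exponential_phasor(1e6)
  expect_lt(lim$g, 1e-6)
  expect_error(single_exponential_phasor(0), class = "chromphasor_domain_error")
  # universal circle, analytically
  tau <- runif(20, 0.1, 10)
  p <- single_exponential_phasor(tau)
  expect_equal((p$g - 0.5)^2 + p$s^2, rep(0.25, 20), tolerance = 1e-12)
})

test_that("zero-photon pixels are flagged undefined, photons conserved", {
  meta <- flim_meta(n_bins = 8L)
  counts <- array(0, c(2, 2, 8))
  counts[1, 1, ] <- 1:8
  img <- decay_image(counts, meta)
  ph <- phasor_transform(img)
  expect_true(is.na(ph$g[2, 2]))
  expect_true(is.na(ph$s[1, 2]))
  expect_false(is.na(ph$g[1, 1]))
  expect_identical(ph$photons, apply(counts, c(1, 2), sum))
})

test_that("lifetime inversion round-trips single exponentials", {
  meta <- flim_meta()
  p <- single_exponential_phasor(4.04, meta)
  lt <- lifetime_from_phasor(p, meta)
  expect_equal(lt$tau_phase_ns, 4.04, tolerance = 1e-9)
  expect_equal(lt$tau_mod_ns, 4.04, tolerance = 1e-9)

  # (0.5, 0.5): tau_phase = 1/omega
  lt2 <- lifetime_from_phasor(tibble::tibble(g = 0.5, s = 0.5), meta)
  expect_equal(lt2$tau_phase_ns, 1.989, tolerance = 1e-3)

  # phase == modulation lifetime anywhere on the universal circle
  for (tau in c(0.5, 2.1, 6)) {
    lt3 <- lifetime_from_phasor(single_exponential_phasor(tau, meta), meta)
    expect_equal(lt3$tau_phase_ns, lt3$tau_mod_ns, tolerance = 1e-9)
  }
  expect_error(lifetime_from_phasor(tibble::tibble(g = -0.1, s = 0.4), meta),
               class = "chromphasor_domain_error")
})

test_that("mixture algebra: midpoint, identity, and validation", {
  comp <- tibble::tibble(g = c(1, 0), s = c(0, 0))
  expect_equal(mixture_phasor(comp, c(0.5, 0.5)),
               tibble::tibble(g = 0.5, s = 0))
  one <- single_exponential_phasor(2.5)
  expect_equal(mixture_phasor(one, 1), one)
  expect_error(mixture_phasor(comp, c(0.6, 0.6)),
               class = "chromphasor_validation_error")
})

test_that("transform of a stack sum equals the photon-weighted phasor mixture", {
  meta <- flim_meta(n_bins = 128L)
  set.seed(11)
  for (rep in 1:4) {
    taus <- runif(2, 0.5, 6)
    tot <- runif(2, 1e3, 1e6)
    c1 <- oracle_exp_counts(taus[1], 128, period_ns(meta), tot[1])
    c2 <- oracle_exp_counts(taus[2], 128, period_ns(meta), tot[2])
    p1 <- phasor_transform(profile_stack(c1, meta))
    p2 <- phasor_transform(profile_stack(c2, meta))
    psum <- phasor_transform(profile_stack(c1 + c2, meta))
    f <- tot / sum(tot)
    mix <- mixture_phasor(
      tibble::tibble(g = c(p1$g[1, 1], p2$g[1, 1]),
                     s = c(p1$s[1, 1], p2$s[1, 1])), f)
    expect_equal(psum$g[1, 1], mix$g, tolerance = 1e-9)
    expect_equal(psum$s[1, 1], mix$s, tolerance = 1e-9)
  }
})

test_that("calibration corrects a known phase/modulation corruption exactly", {
  meta <- flim_meta()
  # identity: measured reference equal to theory leaves pixels untouched
  ref_id <- calibration_reference(single_exponential_phasor(4.04, meta), 4.04, meta)
  stack <- profile_stack(oracle_exp_counts(2.5, 256, period_ns(meta)), meta)
  ph <- phasor_transform(stack)
  cal <- calibrate(ph, ref_id)
  expect_equal(cal$g, ph$g, tolerance = 1e-12)

  # corrupt pixels and reference by the same rotation + scale; calibrate inverts
  theta <- 10 * pi / 180
  m <- 0.85
  rot <- function(g, s) list(g = m * (cos(theta) * g - sin(theta) * s),
                             s = m * (sin(theta) * g + cos(theta) * s))
  ph_bad <- ph
  r <- rot(ph$g, ph$s)
  ph_bad$g <- r$g; ph_bad$s <- r$s
  th <- single_exponential_phasor(4.04, meta)
  rr <- rot(th$g, th$s)
  ref_bad <- calibration_reference(tibble::tibble(g = rr$g, s = rr$s), 4.04, meta)
  rec <- calibrate(ph_bad, ref_bad)
  expect_equal(rec$g, ph$g, tolerance = 1e-9)
  expect_equal(rec$s, ph$s, tolerance = 1e-9)

  expect_error(
    calibration_reference(tibble::tibble(g = 0, s = 0), 4.04, meta),
    class = "chromphasor_calibration_error")
})

test_that("a noiseless fluorescein stack calibrates onto its own theory point", {
  meta <- flim_meta()
  stack <- simulate_reference(4.04, meta, size = 4)
  ref <- phasor_reference(stack, 4.04)
  cal <- mean_phasor(calibrate(phasor_transform(stack), ref))
  th <- single_exponential_phasor(4.04, meta)
  expect_equal(cal$g, th$g, tolerance = 1e-6)
  expect_equal(cal$s, th$s, tolerance = 1e-6)
})

test_that("stack-level corruption is removed by calibration", {
  meta <- flim_meta()
  ref_clean <- simulate_reference(4.04, meta, size = 4)
  smp_clean <- simulate_reference(2.5, meta, size = 4)
  truth <- mean_phasor(calibrate(phasor_transform(smp_clean),
                                 phasor_reference(ref_clean, 4.04)))
  ref_bad <- simulate_reference(4.04, meta, size = 4,
                                phase_shift_bins = 7L, mod_scale = 0.8)
  smp_bad <- simulate_reference(2.5, meta, size = 4,
                                phase_shift_bins = 7L, mod_scale = 0.8)
  rec <- mean_phasor(calibrate(phasor_transform(smp_bad),
                               phasor_reference(ref_bad, 4.04)))
  expect_equal(rec$g, truth$g, tolerance = 1e-6)
  expect_equal(rec$s, truth$s, tolerance = 1e-6)
})

test_that("phasor tibble export and density histogram are consistent", {
  meta <- flim_meta(n_bins = 16L)
  counts <- array(rpois(4 * 4 * 16, 50), c(4, 4, 16))
  ph <- phasor_transform(decay_image(counts, meta))
  df <- tibble::as_tibble(ph)
  expect_named(df, c("row", "col", "g", "s", "photons"))
  expect_equal(nrow(df), 16L)
  h <- phasor_density(ph, n_bins = 64)
  expect_equal(sum(h), sum(!is.na(ph$g) & ph$s >= 0 & ph$s <= 0.6 &
                             ph$g >= 0 & ph$g <= 1))
})
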