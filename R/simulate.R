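#' Synthetic FLIM-nucleus simulation configuration
#'
#' Parameters of the built-in simulator, which emulates the study conditions
#' of a DSB-inducible (DIvA-like) nucleus imaged by histone FLIM-FRET:
#' a 256 x 256 frame at 90 nm/pixel and 80 MHz with 256 time bins; open
#' chromatin as an unquenched 2.5 ns donor; compact chromatin as a
#' FRET-quenched donor at 16% efficiency (2.1 ns); ~100 disk-shaped DSB foci
#' co-localized with a simulated IF channel; and an acceptor channel in
#' excess of the donor.
#'
#' The default photon budget (800 photons/pixel) corresponds to the
#' acquisition geometry of 20 µs/pixel with 20-frame integration (400 µs
#' cumulative dwell) at a ~2 MHz detection rate, realistic for fixed nuclei
#' over-expressing a tagged histone.
#'
#' @param image_size Frame edge length in pixels.
#' @param meta A [flim_meta()].
#' @param tau_open_ns Unquenched donor lifetime in open chromatin (ns).
#' @param fret_e_compact FRET efficiency of compact chromatin, in `[0, 1)`.
#' @param compact_area_fraction Target fraction of nucleus area that is
#'   compact, in `[0, 1]`.
#' @param n_compact_foci Maximum number of compact disks placed while filling
#'   the target area fraction.
#' @param compact_focus_radius_px Radius of compact-chromatin disks (px).
#' @param n_dsb_foci Number of DSB foci (the DIvA system cuts ~100
#'   site-specific DSBs).
#' @param dsb_radius_px DSB focus radius (px); 5 px is ~0.9 µm diameter at
#'   90 nm/pixel.
#' @param dsb_opens_chromatin If `TRUE`, chromatin inside DSB foci is forced
#'   open (the phenomenology at DSB sites).
#' @param photons_per_pixel Mean photon budget per nucleus pixel.
#' @param background_fraction Autofluorescence intensity fraction `f_b`.
#' @param autofluorescence_tau_ns Autofluorescence lifetime (ns).
#' @param dark_photons Mean (time-uniform) counts per pixel outside the
#'   nucleus.
#' @param if_background Mean IF-channel background level (counts).
#' @param if_snr IF spot contrast: spot amplitude as a multiple of the
#'   background level (a spot plateau sits at `(1 + if_snr) * if_background`).
#' @param acceptor_donor_ratio Acceptor:donor intensity ratio (> 1 passes the
#'   acceptor-excess check).
#' @param poisson_noise If `FALSE`, expected-value (noiseless) images are
#'   produced.
#' @param seed Integer seed; one global seed feeds a derived seed per stage
#'   (ground truth, decay noise, acceptor, IF), so truth and noise are
#'   independently reproducible.
#' @return An object of class `flim_sim_config`.
#' @export
flim_sim_config <- function(image_size = 256L,
                            meta = flim_meta(),
                            tau_open_ns = 2.5,
                            fret_e_compact = 0.16,
                            compact_area_fraction = 0.30,
                            n_compact_foci = 5000L,
                            compact_focus_radius_px = 3,
                            n_dsb_foci = 100L,
                            dsb_radius_px = 5,
                            dsb_opens_chromatin = TRUE,
                            photons_per_pixel = 800,
                            background_fraction = 0,
                            autofluorescence_tau_ns = 1.5,
                            dark_photons = 2,
                            if_background = 10,
                            if_snr = 5,
                            acceptor_donor_ratio = 2,
                            poisson_noise = TRUE,
                            seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), meta = meta,
              tau_open_ns = tau_open_ns, fret_e_compact = fret_e_compact,
              compact_area_fraction = compact_area_fraction,
              n_compact_foci = as.integer(n_compact_foci),
              compact_focus_radius_px = compact_focus_radius_px,
              n_dsb_foci = as.integer(n_dsb_foci),
              dsb_radius_px = dsb_radius_px,
              dsb_opens_chromatin = isTRUE(dsb_opens_chromatin),
              photons_per_pixel = photons_per_pixel,
              background_fraction = background_fraction,
              autofluorescence_tau_ns = autofluorescence_tau_ns,
              dark_photons = dark_photons,
              if_background = if_background, if_snr = if_snr,
              acceptor_donor_ratio = acceptor_donor_ratio,
              poisson_noise = isTRUE(poisson_noise),
              seed = as.integer(seed))
  stopifnot(inherits(meta, "flim_meta"))
  if (cfg$image_size < 8L) abort("image_size too small.", class = "chromphasor_error")
  if (cfg$fret_e_compact < 0 || cfg$fret_e_compact >= 1) {
    abort("fret_e_compact must lie in [0, 1).", class = "chromphasor_error")
  }
  if (cfg$compact_area_fraction < 0 || cfg$compact_area_fraction > 1) {
    abort("compact_area_fraction must lie in [0, 1].", class = "chromphasor_error")
  }
  if (max(cfg$compact_focus_radius_px, cfg$dsb_radius_px) >= cfg$image_size / 2) {
    abort("focus radii must be smaller than image_size / 2.",
          class = "chromphasor_error")
  }
  if (cfg$photons_per_pixel <= 0) {
    abort("photons_per_pixel must be positive.", class = "chromphasor_error")
  }
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1) {
    abort("background_fraction must lie in [0, 1).", class = "chromphasor_error")
  }
  structure(cfg, class = "flim_sim_config")
}

# Derived per-stage seed (kept well below 2^31).
stage_seed <- function(seed, stage) {
  offs <- c(truth = 101L, decay = 211L, acceptor = 307L, ifchan = 401L,
            reference = 503L)
  (abs(as.integer(seed)) %% 1000000L) * 1009L + offs[[stage]]
}

#' Bin masses of a period-wrapped exponential decay
#'
#' Probability mass per time bin of a mono-exponential decay wrapped over the
#' laser period (at 80 MHz a 2.5 ns decay does not complete within the
#' 12.5 ns period; wrapping keeps the closed-form phasor exact). Optionally
#' circularly shifted by a whole number of bins — a pure phasor rotation by
#' `2*pi*harmonic*shift_bins/n_bins`, used to emulate an instrumental phase
#' delay.
#'
#' @param tau_ns Lifetime (ns), positive.
#' @param meta A [flim_meta()].
#' @param shift_bins Integer circular shift.
#' @return Numeric vector of length `meta$n_bins` summing to 1.
#' @export
wrapped_exp_bin_mass <- function(tau_ns, meta = flim_meta(), shift_bins = 0L) {
  stopifnot(tau_ns > 0)
  T_ns <- period_ns(meta)
  nb <- meta$n_bins
  e <- seq(0, T_ns, length.out = nb + 1L)
  cdf <- (1 - exp(-e / tau_ns)) / (1 - exp(-T_ns / tau_ns))
  p <- diff(cdf)
  k <- as.integer(shift_bins) %% nb
  if (k) p <- p[((seq_len(nb) - 1L - k) %% nb) + 1L]
  p
}

#' Ground-truth chromatin and DSB geometry
#'
#' Draws the deterministic (per seed) geometry a simulated nucleus is built
#' from: an elliptical nucleus covering ~70% of the frame, DSB foci as random
#' disks, and compact-chromatin disks placed until the target compact area
#' fraction of the nucleus is reached. When `dsb_opens_chromatin`, compact
#' disks avoid DSB foci, so `compact AND dsb` is empty while the realized
#' compact fraction still meets its target (within 0.02).
#'
#' @param cfg A [flim_sim_config()].
#' @return An object of class `ground_truth`: masks `nucleus`, `compact_map`,
#'   `dsb_map`; `per_pixel_E` and `per_pixel_tau_ns` (NA outside the
#'   nucleus); and `dsb_centers` (matrix of row/col).
#' @export
make_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "flim_sim_config"))
  set.seed(stage_seed(cfg$seed, "truth"))
  N <- cfg$image_size
  rr <- row(matrix(0, N, N))
  cc <- col(matrix(0, N, N))
  cy <- (N + 1) / 2
  cx <- (N + 1) / 2
  nucleus <- ((rr - cy) / (0.45 * N))^2 + ((cc - cx) / (0.49 * N))^2 <= 1
  nuc_idx <- which(nucleus)
  nuc_area <- length(nuc_idx)

  paint_disk <- function(mask, center, radius, allowed) {
    r0 <- (center - 1L) %% N + 1L
    c0 <- (center - 1L) %/% N + 1L
    rad <- ceiling(radius)
    rs <- max(1L, r0 - rad):min(N, r0 + rad)
    cs <- max(1L, c0 - rad):min(N, c0 + rad)
    sub <- outer((rs - r0)^2, (cs - c0)^2, "+") <= radius^2
    mask[rs, cs] <- mask[rs, cs] | (sub & allowed[rs, cs])
    mask
  }

  dsb <- matrix(FALSE, N, N)
  dsb_centers <- integer(0)
  if (cfg$n_dsb_foci > 0L) {
    dsb_centers <- sample(nuc_idx, cfg$n_dsb_foci, replace = FALSE)
    for (ct in dsb_centers) dsb <- paint_disk(dsb, ct, cfg$dsb_radius_px, nucleus)
  }

  compact <- matrix(FALSE, N, N)
  allowed <- if (cfg$dsb_opens_chromatin) nucleus & !dsb else nucleus
  target <- round(cfg$compact_area_fraction * nuc_area)
  if (target > 0L) {
    allowed_idx <- which(allowed)
    if (!length(allowed_idx)) {
      abort("no nucleus pixels available for compact chromatin (DSB foci cover the nucleus).",
            class = "chromphasor_config_error")
    }
    placed <- 0L
    while (sum(compact) < target && placed < cfg$n_compact_foci) {
      ct <- allowed_idx[sample.int(length(allowed_idx), 1L)]
      compact <- paint_disk(compact, ct, cfg$compact_focus_radius_px, allowed)
      placed <- placed + 1L
    }
    if (sum(compact) < target - 0.02 * nuc_area) {
      abort("requested compact_area_fraction unreachable within n_compact_foci disks.",
            class = "chromphasor_config_error")
    }
  }

  E <- matrix(0, N, N)
  E[compact] <- cfg$fret_e_compact
  tau <- cfg$tau_open_ns * (1 - E)
  E[!nucleus] <- NA_real_
  tau[!nucleus] <- NA_real_

  structure(
    list(nucleus = binary_mask(nucleus, list(source = "simulation")),
         compact_map = binary_mask(compact, list(source = "simulation")),
         dsb_map = binary_mask(dsb, list(source = "simulation")),
         per_pixel_E = E, per_pixel_tau_ns = tau,
         dsb_centers = cbind(row = (dsb_centers - 1L) %% N + 1L,
                             col = (dsb_centers - 1L) %/% N + 1L)),
    class = "ground_truth"
  )
}

#' Simulate the donor decay stack and companion channels
#'
#' Per nucleus pixel, photon counts per time bin are independent Poisson
#' draws whose means follow the pixel's decay profile: a mixture of the
#' donor's wrapped exponential (lifetime `tau_open * (1 - E_pixel)`) with an
#' autofluorescence component at intensity fraction `f_b`. Pixels outside the
#' nucleus receive time-uniform dark counts. The acceptor channel is
#' `acceptor_donor_ratio` times the donor intensity (with shot noise), and
#' the IF channel shows the DSB disks (softened by a 1 px Gaussian blur) at
#' contrast `if_snr` over a noisy background.
#'
#' @param gt A [make_ground_truth()] result.
#' @param cfg The matching [flim_sim_config()].
#' @return A list with elements `donor` ([decay_image()]), `acceptor` and
#'   `if_channel` ([intensity_image()]s).
#' @export
simulate_decay_image <- function(gt, cfg) {
  stopifnot(inherits(gt, "ground_truth"), inherits(cfg, "flim_sim_config"))
  N <- cfg$image_size
  nb <- cfg$meta$n_bins
  fb <- cfg$background_fraction
  p_af <- wrapped_exp_bin_mass(cfg$autofluorescence_tau_ns, cfg$meta)
  profile_for <- function(tau) (1 - fb) * wrapped_exp_bin_mass(tau, cfg$meta) + fb * p_af

  nucleus <- gt$nucleus$values
  compact <- gt$compact_map$values
  idx <- list(
    open = which(nucleus & !compact),
    compact = which(compact),
    dark = which(!nucleus)
  )
  lam <- list(
    open = cfg$photons_per_pixel * profile_for(cfg$tau_open_ns),
    compact = cfg$photons_per_pixel *
      profile_for(cfg$tau_open_ns * (1 - cfg$fret_e_compact)),
    dark = rep(cfg$dark_photons / nb, nb)
  )

  set.seed(stage_seed(cfg$seed, "decay"))
  cnt <- matrix(0, N * N, nb)
  for (cls in names(idx)) {
    n <- length(idx[[cls]])
    if (!n) next
    cnt[idx[[cls]], ] <- if (cfg$poisson_noise) {
      matrix(rpois(n * nb, rep(lam[[cls]], each = n)), n, nb)
    } else {
      matrix(rep(lam[[cls]], each = n), n, nb)
    }
  }
  donor <- decay_image(array(cnt, c(N, N, nb)), cfg$meta)

  set.seed(stage_seed(cfg$seed, "acceptor"))
  acc_mean <- matrix(cfg$dark_photons, N, N)
  acc_mean[nucleus] <- cfg$acceptor_donor_ratio * cfg$photons_per_pixel
  acc <- if (cfg$poisson_noise) {
    matrix(rpois(N * N, acc_mean), N, N)
  } else acc_mean
  acceptor <- intensity_image(acc, "acceptor", cfg$meta$pixel_size_um)

  set.seed(stage_seed(cfg$seed, "ifchan"))
  spots <- gauss_blur(gt$dsb_map$values * 1, sigma = 1)
  if_mean <- cfg$if_background * (1 + cfg$if_snr * spots)
  ifv <- if (cfg$poisson_noise) {
    matrix(rpois(N * N, if_mean), N, N)
  } else if_mean
  if_channel <- intensity_image(ifv, "IF", cfg$meta$pixel_size_um)

  list(donor = donor, acceptor = acceptor, if_channel = if_channel)
}

#' @rdname simulate_decay_image
#' @details `simulate_cell()` draws ground truth and images in one call.
#' @export
simulate_cell <- function(cfg) {
  gt <- make_ground_truth(cfg)
  c(list(ground_truth = gt), simulate_decay_image(gt, cfg))
}

# Separable Gaussian blur with a 7-tap kernel (zero padding).
gauss_blur <- function(m, sigma = 1) {
  k <- dnorm(-3:3, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    out <- matrix(0, nrow(x), ncol(x))
    for (i in -3:3) {
      rs <- seq_len(nrow(x)) + i
      ok <- rs >= 1 & rs <= nrow(x)
      out[ok, ] <- out[ok, ] + k[i + 4] * x[rs[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Simulate a uniform reference-dye decay stack
#'
#' A spatially uniform stack of wrapped-exponential decays at a known
#' lifetime (fluorescein at pH 9, 4.04 ns, by default) for exercising
#' calibration. Instrumental corruption can be emulated: a phase delay as a
#' whole-bin circular shift of the histogram (an exact rotation of the
#' discrete phasor by `2*pi*shift_bins/n_bins` per harmonic) and a modulation
#' loss as admixture of a time-uniform component (an exact radial scaling,
#' since the uniform profile has phasor zero).
#'
#' @param tau_ns Reference lifetime (ns).
#' @param meta A [flim_meta()].
#' @param size Frame edge length (pixels).
#' @param photons_per_pixel Photon budget per pixel.
#' @param phase_shift_bins Whole-bin circular shift (phase corruption).
#' @param mod_scale Modulation scale in `(0, 1]` (1 = no corruption).
#' @param poisson_noise Draw Poisson counts (`TRUE`) or expected values.
#' @param seed Seed used when `poisson_noise`.
#' @return A [decay_image()].
#' @export
simulate_reference <- function(tau_ns = 4.04, meta = flim_meta(), size = 16L,
                               photons_per_pixel = 1e6, phase_shift_bins = 0L,
                               mod_scale = 1, poisson_noise = FALSE, seed = 1L) {
  if (mod_scale <= 0 || mod_scale > 1) {
    abort("mod_scale must lie in (0, 1].", class = "chromphasor_domain_error")
  }
  nb <- meta$n_bins
  p <- wrapped_exp_bin_mass(tau_ns, meta, shift_bins = phase_shift_bins)
  p <- mod_scale * p + (1 - mod_scale) / nb
  lam <- photons_per_pixel * p
  npix <- as.integer(size)^2
  cnt <- if (poisson_noise) {
    set.seed(stage_seed(seed, "reference"))
    matrix(rpois(npix * nb, rep(lam, each = npix)), npix, nb)
  } else {
    matrix(rep(lam, each = npix), npix, nb)
  }
  decay_image(array(cnt, c(size, size, nb)), meta)
}
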