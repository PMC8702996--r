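#' FRET efficiency from donor lifetimes
#'
#' The classical definition: `E = 1 - tau_DA / tau_D`, where `tau_D` is the
#' unquenched donor lifetime and `tau_DA` the donor lifetime in the presence
#' of acceptor. The compact-chromatin state characterized by histone FRET —
#' a donor shift from 2.5 ns to 2.1 ns — corresponds to `E = 0.16`.
#'
#' @param tau_d_ns Unquenched donor lifetime (ns), positive.
#' @param tau_da_ns Quenched donor lifetime (ns), in `(0, tau_d_ns]`.
#' @return FRET efficiency in `[0, 1)`. Vectorized.
#' @export
fret_efficiency <- function(tau_d_ns, tau_da_ns) {
  if (any(tau_d_ns <= 0) || any(tau_da_ns <= 0)) {
    abort("lifetimes must be positive.", class = "chromphasor_domain_error")
  }
  if (any(tau_da_ns > tau_d_ns)) {
    abort("tau_da_ns > tau_d_ns: negative FRET efficiency is not modeled.",
          class = "chromphasor_domain_error")
  }
  1 - tau_da_ns / tau_d_ns
}

#' Point on the background-corrected FRET trajectory
#'
#' The FRET trajectory is the curve traced in phasor space by a donor
#' quenched at increasing FRET efficiency `E`, mixed with an unquenched
#' autofluorescence background. The quenched donor is modeled as a single
#' exponential with lifetime `tau_D * (1 - E)` (so its phasor slides along
#' the universal semicircle), and because FRET dims the donor, its intensity
#' fraction shrinks with `E`:
#' \deqn{f_D(E) = \frac{(1-f_b)(1-E)}{(1-f_b)(1-E) + f_b},}
#' where `f_b` is the background intensity fraction at `E = 0`. The returned
#' point is the mixture `f_D * P_quenched + (1 - f_D) * P_background`.
#' With `f_b = 0` the trajectory is the semicircle itself and `E = 1` maps to
#' the limit point (1, 0).
#'
#' @param E FRET efficiency(ies) in `[0, 1]`. Vectorized.
#' @param meta A [flim_meta()].
#' @param donor_lifetime_ns Unquenched donor lifetime (ns). Default 2.5, the
#'   H2B-eGFP donor.
#' @param background_fraction Background intensity fraction `f_b` at `E = 0`,
#'   in `[0, 1)`. Default 0.
#' @param background One-row data frame with columns `g`, `s`: the background
#'   (autofluorescence) phasor. Required when `background_fraction > 0`.
#' @return A tibble with columns `E`, `g`, `s`.
#' @export
fret_trajectory_point <- function(E, meta = flim_meta(), donor_lifetime_ns = 2.5,
                                  background_fraction = 0, background = NULL) {
  if (any(E < 0) || any(E > 1)) {
    abort("E must lie in [0, 1].", class = "chromphasor_domain_error")
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("`background_fraction` must lie in [0, 1).", class = "chromphasor_domain_error")
  }
  if (background_fraction > 0 && is.null(background)) {
    abort("`background` phasor required when background_fraction > 0.",
          class = "chromphasor_error")
  }
  bg_g <- if (is.null(background)) 0 else background$g[1]
  bg_s <- if (is.null(background)) 0 else background$s[1]
  tau_q <- donor_lifetime_ns * (1 - E)
  gq <- numeric(length(E))
  sq <- numeric(length(E))
  pos <- tau_q > 0
  if (any(pos)) {
    p <- single_exponential_phasor(tau_q[pos], meta)
    gq[pos] <- p$g
    sq[pos] <- p$s
  }
  gq[!pos] <- 1  # tau -> 0 limit of the semicircle
  sq[!pos] <- 0
  fb <- background_fraction
  num <- (1 - fb) * (1 - E)
  f_d <- ifelse(num + fb > 0, num / (num + fb), 1)  # fb = 0, E = 1: limit point
  tibble(E = E, g = f_d * gq + (1 - f_d) * bg_g, s = f_d * sq + (1 - f_d) * bg_s)
}

#' Build a sampled FRET trajectory
#'
#' Evaluates [fret_trajectory_point()] on a uniform grid of efficiencies
#' `E = 0 ... 1`. The default 101 samples give 1% resolution in `E`, well
#' below the cursor radius used for classification.
#'
#' @inheritParams fret_trajectory_point
#' @param n_samples Number of grid points (at least 2).
#' @return A tibble of class `fret_trajectory` with columns `E`, `g`, `s`
#'   (E strictly increasing) and the trajectory parameters as attributes.
#' @export
build_fret_trajectory <- function(meta = flim_meta(), donor_lifetime_ns = 2.5,
                                  background_fraction = 0, background = NULL,
                                  n_samples = 101L) {
  if (n_samples < 2L) {
    abort("`n_samples` must be at least 2.", class = "chromphasor_validation_error")
  }
  E <- seq(0, 1, length.out = n_samples)
  out <- fret_trajectory_point(E, meta, donor_lifetime_ns,
                               background_fraction, background)
  structure(out,
            donor_lifetime_ns = donor_lifetime_ns,
            background_fraction = background_fraction,
            background = background,
            meta = meta,
            class = c("fret_trajectory", class(out)))
}

#' Nearest-trajectory FRET efficiency for phasor points
#'
#' Inverse lookup: for each phasor, the grid `E` of the nearest trajectory
#' sample. Accurate to the trajectory's grid spacing.
#'
#' @param p Data frame with columns `g`, `s`.
#' @param trajectory A [build_fret_trajectory()] result.
#' @return Numeric vector of efficiencies.
#' @export
nearest_trajectory_E <- function(p, trajectory) {
  stopifnot(inherits(trajectory, "fret_trajectory"))
  vapply(seq_len(nrow(p)), function(i) {
    d2 <- (trajectory$g - p$g[i])^2 + (trajectory$s - p$s[i])^2
    trajectory$E[which.min(d2)]
  }, numeric(1))
}

#' Phasor cursor
#'
#' A circular disc in (g, s) space used in reciprocal mode: pixels whose
#' phasor falls inside the disc are painted with the cursor's label. The
#' published palette uses radius 0.05, the `± 0.05` scale printed on all four
#' cursor coordinates.
#'
#' @param g,s Cursor centre.
#' @param radius Disc radius (> 0).
#' @param label Cursor label, `"open"` or `"compact"`.
#' @return A one-row tibble with columns `label`, `g`, `s`, `radius`.
#' @export
phasor_cursor <- function(g, s, radius = 0.05, label) {
  if (radius <= 0) abort("cursor radius must be positive.",
                         class = "chromphasor_validation_error")
  tibble(label = label, g = g, s = s, radius = radius)
}

#' Default open/compact cursor palette
#'
#' The two-cursor palette for chromatin-compaction mapping: the open-chromatin
#' (teal) cursor sits at the unquenched donor phasor (2.5 ns), and the
#' compact-chromatin (red) cursor at the trajectory point for the
#' compact-state FRET efficiency (default 16%, i.e. a 2.1 ns quenched donor).
#' At 80 MHz these centres round to (0.39, 0.49) and (0.47, 0.50).
#'
#' @param meta A [flim_meta()].
#' @param donor_lifetime_ns Unquenched donor lifetime (ns).
#' @param fret_e_compact FRET efficiency of the compact state.
#' @param radius Cursor radius.
#' @return A tibble of class `cursor_palette` with one `open` and one
#'   `compact` row and provenance columns `tau_ns`, `fret_e`.
#' @export
default_palette <- function(meta = flim_meta(), donor_lifetime_ns = 2.5,
                            fret_e_compact = 0.16, radius = 0.05) {
  open_p <- single_exponential_phasor(donor_lifetime_ns, meta)
  comp_p <- fret_trajectory_point(fret_e_compact, meta, donor_lifetime_ns)
  pal <- dplyr::bind_rows(
    phasor_cursor(open_p$g, open_p$s, radius, "open"),
    phasor_cursor(comp_p$g, comp_p$s, radius, "compact")
  )
  pal$tau_ns <- c(donor_lifetime_ns, donor_lifetime_ns * (1 - fret_e_compact))
  pal$fret_e <- c(0, fret_e_compact)
  validate_palette(pal)
}

validate_palette <- function(pal) {
  if (!all(c("label", "g", "s", "radius") %in% names(pal))) {
    abort("palette needs columns label, g, s, radius.",
          class = "chromphasor_validation_error")
  }
  if (anyDuplicated(pal$label)) {
    abort("cursor labels must be unique within a palette.",
          class = "chromphasor_validation_error")
  }
  if (!setequal(pal$label, c("open", "compact"))) {
    abort("palette must contain exactly one 'open' and one 'compact' cursor.",
          class = "chromphasor_validation_error")
  }
  if (any(pal$radius <= 0)) {
    abort("cursor radii must be positive.", class = "chromphasor_validation_error")
  }
  class(pal) <- unique(c("cursor_palette", class(pal)))
  pal
}

#' Serialize / deserialize a cursor palette as JSON
#'
#' Writes cursor centres, radii, labels and the lifetime/efficiency
#' provenance of each centre.
#'
#' @param palette A `cursor_palette`.
#' @param path JSON file path.
#' @return `read_palette_json()` returns a `cursor_palette`.
#' @export
write_palette_json <- function(palette, path) {
  palette <- validate_palette(palette)
  jsonlite::write_json(as.data.frame(palette), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_palette_json
#' @export
read_palette_json <- function(path) {
  validate_palette(tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)))
}
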