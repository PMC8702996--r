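# Label codes in classification maps.
LABEL_UNCLASSIFIED <- 0L
LABEL_OPEN <- 1L
LABEL_COMPACT <- 2L

label_levels <- c("unclassified", "open", "compact")

#' Map phasor cursors back onto image pixels
#'
#' Reciprocal-mode classification: each pixel is labelled by the cursor whose
#' disc contains its (g, s) phasor. A pixel inside both discs takes the
#' nearer centre (exact ties go to `compact`, deterministically). Pixels
#' inside neither disc, with undefined phasors, or with fewer photons than
#' `photon_threshold` are `unclassified` — below roughly 30 photons the
#' phasor standard error exceeds the cursor radius, so such pixels carry no
#' usable state information.
#'
#' @param ph A `phasor_image`.
#' @param palette A `cursor_palette` with exactly one `open` and one
#'   `compact` cursor (default [default_palette()] for the image's
#'   acquisition).
#' @param photon_threshold Minimum per-pixel photon count (default 30).
#' @return An object of class `chromatin_map`: integer `labels` matrix
#'   (0 unclassified / 1 open / 2 compact), plus `photon_threshold`,
#'   `palette`, and `meta`.
#' @export
classify_pixels <- function(ph, palette = NULL, photon_threshold = 30) {
  stopifnot(inherits(ph, "phasor_image"))
  palette <- validate_palette(palette %||% default_palette(ph$meta))
  open_c <- palette[palette$label == "open", ]
  comp_c <- palette[palette$label == "compact", ]
  d1 <- (ph$g - open_c$g)^2 + (ph$s - open_c$s)^2
  d2 <- (ph$g - comp_c$g)^2 + (ph$s - comp_c$s)^2
  in1 <- !is.na(d1) & d1 <= open_c$radius^2
  in2 <- !is.na(d2) & d2 <= comp_c$radius^2
  labels <- matrix(LABEL_UNCLASSIFIED, nrow(ph$g), ncol(ph$g))
  labels[in1 & !in2] <- LABEL_OPEN
  labels[in2 & !in1] <- LABEL_COMPACT
  both <- in1 & in2
  if (any(both)) {
    labels[both] <- ifelse(d1[both] < d2[both], LABEL_OPEN, LABEL_COMPACT)
  }
  labels[ph$photons < photon_threshold] <- LABEL_UNCLASSIFIED
  structure(
    list(labels = labels, photon_threshold = photon_threshold,
         palette = palette, meta = ph$meta),
    class = "chromatin_map"
  )
}

#' @export
dim.chromatin_map <- function(x) dim(x$labels)

#' @export
print.chromatin_map <- function(x, ...) {
  n <- tabulate(x$labels + 1L, 3L)
  cat(sprintf(
    "<chromatin_map> %d x %d: %d open, %d compact, %d unclassified (photon threshold %g)\n",
    nrow(x$labels), ncol(x$labels), n[2], n[3], n[1], x$photon_threshold))
  invisible(x)
}

#' @export
#' @rdname classify_pixels
#' @param x A `chromatin_map`.
#' @param ... Unused.
as_tibble.chromatin_map <- function(x, ...) {
  tibble(
    row = as.vector(row(x$labels)),
    col = as.vector(col(x$labels)),
    label = factor(label_levels[as.vector(x$labels) + 1L], levels = label_levels)
  )
}

#' Fraction of pixels in the compact-chromatin state
#'
#' The headline metric of the assay: among classified pixels (those inside
#' either cursor), the fraction falling in the compact (FRET) cursor.
#' Unclassified pixels are excluded from both numerator and denominator.
#'
#' @param cm A [classify_pixels()] result.
#' @param mask Optional [binary_mask()] (or logical matrix) restricting the
#'   counted region, e.g. a nucleus mask.
#' @return A one-row tibble with `n_open`, `n_compact`, `fraction_compact`.
#'   `fraction_compact` is `NA` when no pixel in the region is classified.
#' @export
compact_fraction <- function(cm, mask = NULL) {
  stopifnot(inherits(cm, "chromatin_map"))
  lab <- cm$labels
  if (!is.null(mask)) lab <- lab[as_mask_matrix(mask, dim(cm$labels))]
  n_open <- sum(lab == LABEL_OPEN)
  n_compact <- sum(lab == LABEL_COMPACT)
  tibble(
    n_open = n_open, n_compact = n_compact,
    fraction_compact = if (n_open + n_compact > 0) {
      n_compact / (n_open + n_compact)
    } else NA_real_
  )
}

#' Acceptor-excess quality check
#'
#' FRET quantification through donor quenching requires the acceptor to be
#' in excess of the donor; the check computes the mean acceptor / mean donor
#' intensity ratio over the nucleus and passes iff the ratio is strictly
#' greater than 1.
#'
#' @param donor,acceptor [intensity_image()]s (matching shape).
#' @param nucleus [binary_mask()] of the nucleus (non-empty).
#' @return A one-row tibble with `ratio` and `pass`.
#' @export
acceptor_excess_check <- function(donor, acceptor, nucleus) {
  dv <- as_value_matrix(donor, "donor")
  av <- as_value_matrix(acceptor, "acceptor")
  if (!identical(dim(dv), dim(av))) {
    abort("donor and acceptor shapes differ.", class = "chromphasor_validation_error")
  }
  m <- as_mask_matrix(nucleus, dim(dv), "nucleus")
  if (!any(m)) {
    abort("nucleus mask is empty.", class = "chromphasor_validation_error")
  }
  dmean <- mean(dv[m])
  if (dmean == 0) {
    abort("mean donor intensity over the nucleus is zero.",
          class = "chromphasor_error")
  }
  ratio <- mean(av[m]) / dmean
  tibble(ratio = ratio, pass = ratio > 1)
}
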