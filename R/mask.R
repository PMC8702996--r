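#' 3x3 spatial median filter
#'
#' Replaces every pixel by the median of its 3x3 neighbourhood — the standard
#' smoothing step before thresholding an immunofluorescence image of DSB
#' foci, removing single-pixel staining noise while preserving focus edges.
#' Borders are handled by edge replication, which keeps the output shape.
#'
#' @param img An [intensity_image()] or numeric matrix.
#' @return Same type as the input, filtered.
#' @export
median_filter_3x3 <- function(img) {
  v <- as_value_matrix(img)
  nr <- nrow(v)
  nc <- ncol(v)
  pad <- v[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc), drop = FALSE]
  nbhd <- matrix(0, nr * nc, 9L)
  k <- 1L
  for (dc in 0:2) {
    for (dr in 0:2) {
      nbhd[, k] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
      k <- k + 1L
    }
  }
  out <- matrix(matrixStats::rowMedians(nbhd), nr, nc)
  if (inherits(img, "intensity_image")) {
    res <- intensity_image(out, img$channel_label, img$pixel_size_um)
    res$filter <- "median3x3"
    res
  } else {
    out
  }
}

#' Threshold an intensity image into a binary mask
#'
#' Pixels with `value >= threshold` become foreground (the comparison is
#' inclusive, deterministically). `threshold = "otsu"` computes the
#' between-class-variance-maximizing threshold of the image histogram —
#' the default for segmenting DSB foci from a median-filtered IF image,
#' where the operator-chosen absolute threshold of the original protocol is
#' replaced by a reproducible criterion. The realized threshold is recorded
#' in the mask provenance.
#'
#' @param img An [intensity_image()] or numeric matrix.
#' @param threshold A numeric threshold, or `"otsu"`.
#' @param min_size Minimum foreground-component size in pixels (8-connected);
#'   smaller components are dropped. Default 0 (no size filter).
#' @return A [binary_mask()] whose provenance records channel, filter,
#'   method and realized threshold.
#' @export
threshold_mask <- function(img, threshold = "otsu", min_size = 0L) {
  v <- as_value_matrix(img)
  channel <- if (inherits(img, "intensity_image")) img$channel_label else ""
  filt <- if (inherits(img, "intensity_image")) img$filter %||% "none" else "none"
  method <- if (is.character(threshold)) threshold else "absolute"
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu")) {
      abort("unknown threshold method; use a number or \"otsu\".",
            class = "chromphasor_validation_error")
    }
    rng <- range(v)
    if (diff(rng) == 0) {
      warn("constant image: empty mask returned.")
      th <- Inf
    } else {
      th <- EBImage::otsu(v, range = rng, levels = 256L)
    }
  } else {
    th <- threshold
    if (th > max(v)) warn("threshold above image maximum: empty mask returned.")
  }
  m <- v >= th
  if (min_size > 0L && any(m)) {
    lab <- label_particles(m, fill_holes = FALSE)
    keep <- which(tabulate(lab[lab > 0]) >= min_size)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  binary_mask(m, provenance = list(channel = channel, filter = filt,
                                   method = method, threshold = th,
                                   min_size = min_size))
}

#' Nucleus mask from the donor channel
#'
#' Restricts all per-cell fractions to the nucleus. Thresholds the donor
#' (histone-tagged fluorophore) intensity image, which is bright across the
#' whole nucleus and dark outside.
#'
#' @inheritParams threshold_mask
#' @param donor Donor-channel [intensity_image()] or matrix.
#' @return A [binary_mask()].
#' @export
nucleus_mask <- function(donor, threshold = "otsu") {
  threshold_mask(donor, threshold)
}

#' Compact-chromatin fractions inside versus outside DSB foci
#'
#' Splits the nucleus into the IF-defined foci region (`nucleus AND foci`)
#' and the surrounding nucleoplasm (`nucleus AND NOT foci`) — an exact
#' partition — and computes [compact_fraction()] on each.
#'
#' @param cm A [classify_pixels()] result.
#' @param foci [binary_mask()] of DSB foci (from [threshold_mask()]).
#' @param nucleus [binary_mask()] of the nucleus.
#' @return A one-row tibble: `fraction_inside`, `fraction_outside`,
#'   `n_pixels_inside`, `n_pixels_outside`. An empty region yields an `NA`
#'   fraction.
#' @export
inside_outside <- function(cm, foci, nucleus) {
  stopifnot(inherits(cm, "chromatin_map"))
  shape <- dim(cm$labels)
  fm <- as_mask_matrix(foci, shape, "foci")
  nm <- as_mask_matrix(nucleus, shape, "nucleus")
  inside <- nm & fm
  outside <- nm & !fm
  fi <- if (any(inside)) compact_fraction(cm, inside)$fraction_compact else NA_real_
  fo <- if (any(outside)) compact_fraction(cm, outside)$fraction_compact else NA_real_
  tibble(
    fraction_inside = fi, fraction_outside = fo,
    n_pixels_inside = sum(inside), n_pixels_outside = sum(outside)
  )
}

#' Foci fraction normalized to the surrounding nucleoplasm
#'
#' Divides the compact fraction inside DSB foci by the fraction outside,
#' removing each nucleus' baseline compaction so foci of different repair
#' pathways can be compared across cells. Values below 1 mean foci are more
#' open than their surroundings.
#'
#' @param res An [inside_outside()] result (one or more rows).
#' @return Numeric vector; `NA` where the outside fraction is zero or
#'   undefined.
#' @export
normalized_inside_fraction <- function(res) {
  out <- res$fraction_inside / res$fraction_outside
  bad <- is.na(res$fraction_outside) | res$fraction_outside == 0
  if (any(bad)) {
    warn("outside fraction zero or undefined; normalized value set to NA.")
    out[bad] <- NA_real_
  }
  out
}
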