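#' Photon-count decay image
#'
#' A time-resolved FLIM frame: for every pixel, a histogram of photon arrival
#' times over one laser period. Stored as a 3-D array indexed
#' `(row, col, bin)`; bins are 0-based in time, with bin `b` covering
#' `[b, b+1) * period / n_bins`.
#'
#' Counts are non-negative. Integer counts are what an instrument delivers;
#' real-valued counts are accepted so that noiseless expected-value stacks
#' (ideal decays) can flow through the same pipeline.
#'
#' @param counts 3-D numeric array of non-negative photon counts,
#'   dimensions `(rows, cols, n_bins)`.
#' @param meta A [flim_meta()] object; `meta$n_bins` must equal `dim(counts)[3]`.
#' @return An object of class `decay_image` with elements `counts` and `meta`.
#' @seealso [phasor_transform()], [read_decay_stack()], [write_decay_stack()]
#' @export
decay_image <- function(counts, meta) {
  stopifnot(inherits(meta, "flim_meta"))
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    abort("`counts` must be a 3-D array (row, col, bin).", class = "chromphasor_error")
  }
  d <- dim(counts)
  if (d[1] < 1L || d[2] < 1L) {
    abort("`counts` must have at least one row and one column.",
          class = "chromphasor_error")
  }
  if (d[3] != meta$n_bins) {
    abort(sprintf("bin axis length (%d) does not match meta$n_bins (%d).",
                  d[3], meta$n_bins),
          class = "chromphasor_format_error")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort("photon counts must be non-negative and non-missing.",
          class = "chromphasor_validation_error")
  }
  structure(list(counts = counts, meta = meta), class = "decay_image")
}

#' @export
dim.decay_image <- function(x) dim(x$counts)

#' @export
print.decay_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_image> %d x %d pixels, %d bins, %.4g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  print(x$meta)
  invisible(x)
}

#' 2-D intensity image
#'
#' A single-channel intensity frame (donor, acceptor, or immunofluorescence
#' channel) carried alongside decay stacks.
#'
#' @param values 2-D numeric matrix of non-negative intensities.
#' @param channel_label Free-text channel description.
#' @param pixel_size_um Pixel edge length in micrometres (may be `NA`).
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, channel_label = "", pixel_size_um = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "chromphasor_error")
  }
  if (anyNA(values) || any(values < 0)) {
    abort("intensity values must be non-negative and non-missing.",
          class = "chromphasor_validation_error")
  }
  structure(list(values = values, channel_label = channel_label,
                 pixel_size_um = pixel_size_um),
            class = "intensity_image")
}

#' @export
dim.intensity_image <- function(x) dim(x$values)

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d [%s], range %.4g..%.4g\n",
              nrow(x$values), ncol(x$values),
              if (nzchar(x$channel_label)) x$channel_label else "unlabelled",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary image mask
#'
#' A logical 2-D mask (nucleus, DSB foci, compact chromatin, ...) with a
#' provenance record of how it was made (channel, filter, realized threshold).
#'
#' @param values Logical matrix.
#' @param provenance Named list or character scalar describing origin.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, provenance = list()) {
  if (is.numeric(values) && is.matrix(values)) values <- values > 0
  if (!is.matrix(values) || !is.logical(values)) {
    abort("`values` must be a logical matrix.", class = "chromphasor_error")
  }
  if (anyNA(values)) {
    abort("mask values must not be missing.", class = "chromphasor_validation_error")
  }
  structure(list(values = values, provenance = provenance), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground pixels (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

# Coerce mask-like input (binary_mask, logical/numeric matrix) to logical matrix.
as_mask_matrix <- function(mask, shape = NULL, arg = "mask") {
  m <- if (inherits(mask, "binary_mask")) mask$values else mask
  if (is.numeric(m) && is.matrix(m)) m <- m > 0
  if (!is.matrix(m) || !is.logical(m)) {
    abort(sprintf("`%s` must be a binary_mask or a logical matrix.", arg),
          class = "chromphasor_error")
  }
  if (!is.null(shape) && !identical(dim(m), as.integer(shape))) {
    abort(sprintf("`%s` shape (%d x %d) does not match image shape (%d x %d).",
                  arg, nrow(m), ncol(m), shape[1], shape[2]),
          class = "chromphasor_validation_error")
  }
  m
}

# Extract the value matrix from intensity_image or plain matrix input.
as_value_matrix <- function(img, arg = "img") {
  v <- if (inherits(img, "intensity_image")) img$values else img
  if (!is.matrix(v) || !is.numeric(v)) {
    abort(sprintf("`%s` must be an intensity_image or numeric matrix.", arg),
          class = "chromphasor_error")
  }
  v
}
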