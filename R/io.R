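#' Read a multi-page TIFF decay stack
#'
#' Reads a time-resolved photon-count stack stored as a plain multi-page
#' grayscale TIFF (one page per time bin) with a JSON metadata sidecar.
#' Vendor FLIM formats are out of scope; TIFF + JSON is lossless and
#' tool-agnostic.
#'
#' @param path Path to the multi-page TIFF.
#' @param meta A [flim_meta()]; if `NULL`, the sidecar JSON written by
#'   [write_decay_stack()] (same path with extension `.json`) is read.
#' @return A [decay_image()].
#' @details Float-valued input pages are cast to integers by rounding; a
#'   warning reports the largest rounding error. A page count different from
#'   `meta$n_bins` is a format error; the reader never silently truncates.
#' @export
read_decay_stack <- function(path, meta = NULL) {
  if (is.null(meta)) meta <- read_meta_json(sidecar_path(path))
  stopifnot(inherits(meta, "flim_meta"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins) {
    abort(sprintf("decay stack has %d pages but meta$n_bins is %d.",
                  length(pages), meta$n_bins),
          class = "chromphasor_format_error")
  }
  shp <- dim(pages[[1]])
  if (length(shp) != 2L) {
    abort("decay stack pages must be single-channel (grayscale).",
          class = "chromphasor_format_error")
  }
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    abort("decay stack pages differ in shape.", class = "chromphasor_format_error")
  }
  counts <- array(unlist(pages, use.names = FALSE), dim = c(shp, length(pages)))
  if (any(counts < 0)) {
    abort("decay stack contains negative values.",
          class = "chromphasor_validation_error")
  }
  rounded <- round(counts)
  err <- max(abs(counts - rounded))
  if (err > 0) {
    warn(sprintf("float counts cast to integer; max rounding error %.4g.", err))
  }
  decay_image(rounded, meta)
}

#' Write a decay stack as multi-page TIFF plus JSON sidecar
#'
#' Page `b` of the TIFF holds `counts[, , b]`, stored as 16-bit grayscale.
#' The round trip through [read_decay_stack()] is lossless for integer counts
#' up to 65535 per bin; larger counts are rejected.
#'
#' @param img A [decay_image()].
#' @param path Output TIFF path; the metadata sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_decay_stack <- function(img, path) {
  stopifnot(inherits(img, "decay_image"))
  counts <- round(img$counts)
  if (max(abs(counts - img$counts)) > 0) {
    warn("non-integer counts rounded before writing.")
  }
  if (max(counts) > 65535) {
    abort("counts exceed 65535; 16-bit TIFF storage would be lossy.",
          class = "chromphasor_validation_error")
  }
  pages <- lapply(seq_len(dim(counts)[3]), function(b) counts[, , b] / 65535)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("cannot write decay stack to '%s'.", path),
          class = "chromphasor_io_error")
  }
  write_meta_json(img$meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' @rdname read_decay_stack
#' @export
read_meta_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("metadata sidecar '%s' not found.", path),
          class = "chromphasor_io_error")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  flim_meta(rep_rate_hz = j$rep_rate_hz, n_bins = j$n_bins,
            pixel_size_um = j$pixel_size_um, harmonic = j$harmonic %||% 1L)
}

#' @rdname write_decay_stack
#' @param meta A [flim_meta()] to serialize.
#' @export
write_meta_json <- function(meta, path) {
  stopifnot(inherits(meta, "flim_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write single-page grayscale intensity TIFFs
#'
#' @param path TIFF path.
#' @param channel_label Channel description attached to the result.
#' @param pixel_size_um Pixel size attached to the result (µm).
#' @return `read_intensity()` returns an [intensity_image()];
#'   `write_intensity()` returns `path` invisibly.
#' @details Multi-page or multi-channel (RGB) input is a format error:
#'   intensity channels are single-page grayscale by contract. Values are
#'   stored as 16-bit integers (exact round trip up to 65535).
#' @export
read_intensity <- function(path, channel_label = "", pixel_size_um = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 1L) {
    abort("intensity images must be single-page TIFFs.",
          class = "chromphasor_format_error")
  }
  v <- pages[[1]]
  if (length(dim(v)) != 2L) {
    abort("intensity images must be grayscale (one sample per pixel).",
          class = "chromphasor_format_error")
  }
  intensity_image(v, channel_label = channel_label, pixel_size_um = pixel_size_um)
}

#' @rdname read_intensity
#' @param img An [intensity_image()] (or numeric matrix).
#' @export
write_intensity <- function(img, path) {
  v <- round(as_value_matrix(img))
  if (max(v) > 65535) {
    abort("intensity values exceed 65535; 16-bit TIFF storage would be lossy.",
          class = "chromphasor_validation_error")
  }
  ok <- try(tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("cannot write intensity image to '%s'.", path),
          class = "chromphasor_io_error")
  }
  invisible(path)
}

#' Read / write binary masks as 8-bit TIFF (0/255)
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param path TIFF path.
#' @return `read_mask()` returns a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  ok <- try(tiff::writeTIFF(m * 1, path, bits.per.sample = 8L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("cannot write mask to '%s'.", path), class = "chromphasor_io_error")
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) != 2L) {
    abort("masks must be single-channel TIFFs.", class = "chromphasor_format_error")
  }
  binary_mask(v > 0, provenance = list(source = path))
}

#' Write a tabular result as CSV
#'
#' Comma-separated text with a header line; the standard output format for
#' per-cell fractions, foci tables, and cohort summaries.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  readr::write_csv(rows, path)
  invisible(path)
}
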