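#' Binary image of compact-chromatin pixels
#'
#' Extracts the compact-labelled pixels of a classification map as a binary
#' mask — the input to particle analysis of compact-chromatin foci.
#'
#' @param cm A [classify_pixels()] result.
#' @return A [binary_mask()].
#' @export
compact_binary <- function(cm) {
  stopifnot(inherits(cm, "chromatin_map"))
  binary_mask(cm$labels == LABEL_COMPACT,
              provenance = list(source = "chromatin_map", label = "compact"))
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions (4-connected) that do not reach the image border are
#' assigned to the enclosing particle, per the particle-analysis rule that
#' holes inside connected pixels belong to the particle.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @return A logical matrix.
#' @export
fill_mask_holes <- function(mask) {
  m <- as_mask_matrix(mask)
  EBImage::fillHull(m * 1L) > 0
}

#' Label connected particles in a binary mask
#'
#' Connected-component labeling under 8-connectivity of the foreground (all
#' adjacent non-zero pixels, including diagonals, are one particle) with
#' 4-connected background holes filled first — the Jordan-consistent pairing
#' used by standard particle-analysis routines. Particle size is
#' unrestricted and particles touching the border are kept.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param fill_holes Fill enclosed holes before labeling (default `TRUE`).
#' @return An integer matrix of labels (0 = background; particle ids are
#'   contiguous from 1 in scan order), with attribute `n` (particle count).
#' @seealso [particle_areas()]
#' @export
label_particles <- function(mask, fill_holes = TRUE) {
  m <- as_mask_matrix(mask)
  if (fill_holes) m <- fill_mask_holes(m)
  label_connected_8(m)
}

# 8-connected labeling via the pixel adjacency graph.
label_connected_8 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  fg <- which(m)
  out <- matrix(0L, nr, nc)
  attr(out, "n") <- 0L
  if (!length(fg)) return(out)
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  edges <- lapply(list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L)),
                  function(o) offset_pairs(m, o[1], o[2]))
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(cbind(vid[edges[, 1]], vid[edges[, 2]])))
  }
  comp <- igraph::components(g)$membership
  # renumber in first-appearance (column-major scan) order for determinism
  relab <- match(comp, unique(comp))
  out[fg] <- relab
  attr(out, "n") <- max(relab)
  out
}

# Foreground pixel pairs related by offset (dr, dc), as linear index columns.
offset_pairs <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(r1) || !length(c1)) return(NULL)
  a <- m[r1, c1, drop = FALSE]
  b <- m[r1 + dr, c1 + dc, drop = FALSE]
  hit <- which(a & b)
  if (!length(hit)) return(NULL)
  rr <- r1[(hit - 1L) %% length(r1) + 1L]
  cc <- c1[(hit - 1L) %/% length(r1) + 1L]
  cbind((cc - 1L) * nr + rr, (cc + dc - 1L) * nr + rr + dr)
}

#' Particle pixel counts, areas and centroids
#'
#' Quantifies labelled particles: pixel count (holes included, since labeling
#' fills them), physical area as `pixel_count * pixel_size_um^2`, and the
#' centroid of the pixel support.
#'
#' @param labeled Labeled integer matrix from [label_particles()].
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return A tibble of class `foci_table` with columns `id`, `pixel_count`,
#'   `area_um2`, `centroid_row`, `centroid_col`, and attribute
#'   `pixel_size_um`. Empty masks yield an empty table.
#' @export
particle_areas <- function(labeled, pixel_size_um) {
  stopifnot(is.matrix(labeled), is.numeric(pixel_size_um), pixel_size_um > 0)
  ids <- labeled[labeled > 0]
  if (!length(ids)) {
    out <- tibble(id = integer(), pixel_count = integer(), area_um2 = numeric(),
                  centroid_row = numeric(), centroid_col = numeric())
  } else {
    n <- max(ids)
    cnt <- tabulate(ids, n)
    rsum <- unname(rowsum(as.numeric(row(labeled)[labeled > 0]), ids)[, 1])
    csum <- unname(rowsum(as.numeric(col(labeled)[labeled > 0]), ids)[, 1])
    out <- tibble(
      id = seq_len(n), pixel_count = cnt,
      area_um2 = cnt * pixel_size_um^2,
      centroid_row = rsum / cnt, centroid_col = csum / cnt
    )
  }
  structure(out, pixel_size_um = pixel_size_um,
            class = c("foci_table", class(out)))
}

#' Pooled particle-area histogram
#'
#' Histograms particle areas (µm²), pooled across cells, into user-specified
#' or automatic bins. Default bins: 20 uniform bins from 0 to the 99th
#' percentile of the pooled areas.
#'
#' @param tables A `foci_table` or list of `foci_table`s (consistent pixel
#'   sizes).
#' @param bin_edges Strictly increasing numeric bin edges; bin `i` covers
#'   `[edge_i, edge_{i+1})`.
#' @param normalize Also report relative frequency.
#' @return A tibble with columns `bin_lo`, `bin_hi`, `count` (and
#'   `frequency` if `normalize`).
#' @export
area_histogram <- function(tables, bin_edges = NULL, normalize = FALSE) {
  if (inherits(tables, "foci_table")) tables <- list(tables)
  px <- unique(round(vapply(tables, attr, numeric(1), "pixel_size_um"), 12))
  if (length(px) > 1L) {
    abort("pooled foci tables have inconsistent pixel sizes.",
          class = "chromphasor_validation_error")
  }
  areas <- unlist(lapply(tables, function(t) t$area_um2), use.names = FALSE)
  if (is.null(bin_edges)) {
    hi <- if (length(areas)) quantile(areas, 0.99, names = FALSE) else 1
    if (hi <= 0) hi <- 1
    bin_edges <- seq(0, hi, length.out = 21L)
  }
  if (any(diff(bin_edges) <= 0)) {
    abort("bin edges must be strictly increasing.",
          class = "chromphasor_validation_error")
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(areas, bin_edges)
  idx <- idx[idx >= 1L & idx <= nb & areas < bin_edges[nb + 1L]]
  count <- tabulate(idx, nb)
  out <- tibble(bin_lo = bin_edges[-(nb + 1L)], bin_hi = bin_edges[-1L],
                count = count)
  if (normalize) out$frequency <- if (sum(count)) count / sum(count) else 0 * count
  out
}
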