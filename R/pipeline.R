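#' Analyze one nucleus end to end
#'
#' Runs the full per-cell pipeline: phasor transform of the donor decay
#' stack, optional reference calibration, nucleus segmentation from the
#' donor intensity, cursor classification, compact fraction, acceptor-excess
#' check, IF-guided inside/outside quantification (3x3 median filter +
#' threshold mask), and compact-foci particle analysis.
#'
#' @param donor A [decay_image()] of the donor channel.
#' @param acceptor Optional acceptor [intensity_image()].
#' @param if_channel Optional immunofluorescence [intensity_image()] of DSB
#'   foci.
#' @param reference Optional [calibration_reference()].
#' @param palette A `cursor_palette` (default [default_palette()]).
#' @param photon_threshold Minimum photons for classification.
#' @param nucleus_threshold,foci_threshold Threshold value or `"otsu"`.
#' @param min_focus_px Minimum IF focus size in pixels (default 0: no size
#'   filter).
#' @param cell_id,condition,channel Identifiers carried into the record.
#' @return An object of class `cell_analysis`: `summary` (one-row tibble),
#'   `classification` ([classify_pixels()] map), `foci_table`
#'   ([particle_areas()]), `nucleus`, `foci_mask`, `phasor`.
#' @export
analyze_cell <- function(donor, acceptor = NULL, if_channel = NULL,
                         reference = NULL, palette = NULL,
                         photon_threshold = 30,
                         nucleus_threshold = "otsu", foci_threshold = "otsu",
                         min_focus_px = 0L,
                         cell_id = "cell", condition = NA_character_,
                         channel = NA_character_) {
  stopifnot(inherits(donor, "decay_image"))
  ph <- phasor_transform(donor)
  if (!is.null(reference)) ph <- calibrate(ph, reference)
  palette <- palette %||% default_palette(donor$meta)

  donor_int <- intensity_image(ph$photons, "donor", donor$meta$pixel_size_um)
  nuc <- nucleus_mask(donor_int, nucleus_threshold)
  cm <- classify_pixels(ph, palette, photon_threshold)
  frac <- compact_fraction(cm, nuc)

  acc <- if (!is.null(acceptor)) {
    acceptor_excess_check(donor_int, acceptor, nuc)
  } else {
    tibble(ratio = NA_real_, pass = NA)
  }

  io <- tibble(fraction_inside = NA_real_, fraction_outside = NA_real_,
               n_pixels_inside = NA_integer_, n_pixels_outside = NA_integer_)
  norm_in <- NA_real_
  foci <- NULL
  realized_threshold <- NA_real_
  if (!is.null(if_channel)) {
    smoothed <- median_filter_3x3(if_channel)
    foci <- threshold_mask(smoothed, foci_threshold, min_size = min_focus_px)
    realized_threshold <- foci$provenance$threshold
    io <- inside_outside(cm, foci, nuc)
    norm_in <- suppressWarnings(normalized_inside_fraction(io))
  }

  labeled <- label_particles(compact_binary(cm))
  ft <- particle_areas(labeled, donor$meta$pixel_size_um)

  summary <- tibble(
    cell_id = cell_id, condition = condition, channel = channel,
    n_pixels_nucleus = sum(nuc$values),
    acceptor_donor_ratio = acc$ratio, acceptor_excess = acc$pass,
    n_open = frac$n_open, n_compact = frac$n_compact,
    fraction_compact = frac$fraction_compact,
    fraction_inside = io$fraction_inside,
    fraction_outside = io$fraction_outside,
    normalized_inside = norm_in,
    foci_threshold = realized_threshold,
    n_particles = nrow(ft),
    median_particle_area_um2 = if (nrow(ft)) median(ft$area_um2) else NA_real_
  )
  structure(list(summary = summary, classification = cm, foci_table = ft,
                 nucleus = nuc, foci_mask = foci, phasor = ph),
            class = "cell_analysis")
}

#' @export
print.cell_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cell_analysis> %s: fraction_compact = %.3f", s$cell_id,
              s$fraction_compact))
  if (!is.na(s$fraction_inside)) {
    cat(sprintf(", inside/outside = %.3f/%.3f", s$fraction_inside,
                s$fraction_outside))
  }
  cat(sprintf(", %d compact particles\n", s$n_particles))
  invisible(x)
}

#' @export
tidy.cell_analysis <- function(x, ...) x$summary

#' Run the cohort pipeline across cells
#'
#' Analyzes every cell of a cohort, aggregates per-condition summaries
#' (minimum, maximum, and sample median, as reported in box-and-whisker
#' figures, with quartiles as extensions), and runs the cohort statistics:
#' an unpaired t-test on `fraction_compact` between conditions and a paired
#' t-test on `fraction_inside` versus `fraction_outside` within each
#' condition/channel. No multiple-testing correction is applied (single
#' pairwise tests per comparison); this is noted in the report.
#'
#' Per-cell failures are quarantined and reported, not fatal: every input
#' cell appears exactly once, as a result row or a quarantined failure.
#'
#' @param cohort A data frame with columns `cell_id`, `condition`, optional
#'   `channel`, and either a list-column `config` of [flim_sim_config()]s
#'   (simulation mode) or path columns `donor` (TIFF stack with JSON
#'   sidecar), optional `acceptor`, `if_channel`, `reference` (file mode;
#'   `ref_lifetime_ns` defaults to 4.04).
#' @param palette,photon_threshold,foci_threshold,min_focus_px Passed to
#'   [analyze_cell()].
#' @return An object of class `cohort_report`: tibbles `cells`, `summary`,
#'   `tests`, `quarantined`, and `params` (thresholds and palette, for
#'   provenance).
#' @export
run_pipeline <- function(cohort, palette = NULL, photon_threshold = 30,
                         foci_threshold = "otsu", min_focus_px = 0L) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort("`cohort` must be a non-empty data frame of cells.",
          class = "chromphasor_validation_error")
  }
  if (!all(c("cell_id", "condition") %in% names(cohort))) {
    abort("`cohort` needs columns cell_id and condition.",
          class = "chromphasor_validation_error")
  }
  sim_mode <- "config" %in% names(cohort)
  if (!sim_mode && !("donor" %in% names(cohort))) {
    abort("`cohort` needs a `config` list-column or a `donor` path column.",
          class = "chromphasor_validation_error")
  }

  rows <- vector("list", nrow(cohort))
  foci_tables <- list()
  quarantined <- list()
  for (i in seq_len(nrow(cohort))) {
    ci <- cohort[i, ]
    res <- tryCatch({
      inp <- if (sim_mode) {
        cfg <- ci$config[[1]]
        if (!inherits(cfg, "flim_sim_config")) {
          abort("config column must hold flim_sim_config objects.",
                class = "chromphasor_validation_error")
        }
        sim <- simulate_cell(cfg)
        list(donor = sim$donor, acceptor = sim$acceptor,
             if_channel = sim$if_channel, reference = NULL)
      } else {
        load_cell_inputs(ci)
      }
      analyze_cell(inp$donor, inp$acceptor, inp$if_channel, inp$reference,
                   palette = palette, photon_threshold = photon_threshold,
                   foci_threshold = foci_threshold,
                   min_focus_px = min_focus_px,
                   cell_id = ci$cell_id, condition = ci$condition,
                   channel = if ("channel" %in% names(ci)) ci$channel else NA_character_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      quarantined[[length(quarantined) + 1L]] <-
        tibble(cell_id = ci$cell_id, condition = ci$condition,
               error = conditionMessage(res))
    } else {
      rows[[i]] <- res$summary
      foci_tables[[ci$cell_id]] <- res$foci_table
    }
  }
  cells <- dplyr::bind_rows(rows)
  quarantined <- if (length(quarantined)) {
    dplyr::bind_rows(quarantined)
  } else {
    tibble(cell_id = character(), condition = character(), error = character())
  }

  structure(
    list(cells = cells,
         summary = cohort_summary(cells),
         tests = cohort_tests(cells),
         quarantined = quarantined,
         foci_tables = foci_tables,
         params = list(photon_threshold = photon_threshold,
                       foci_threshold = foci_threshold,
                       min_focus_px = min_focus_px,
                       palette = palette %||% "default",
                       multiple_testing_correction = "none")),
    class = "cohort_report"
  )
}

load_cell_inputs <- function(ci) {
  donor <- read_decay_stack(ci$donor)
  grab <- function(col) {
    if (col %in% names(ci) && !is.na(ci[[col]]) && nzchar(ci[[col]])) ci[[col]] else NULL
  }
  acc <- grab("acceptor")
  ifc <- grab("if_channel")
  refp <- grab("reference")
  ref <- if (!is.null(refp)) {
    tau <- if ("ref_lifetime_ns" %in% names(ci)) ci$ref_lifetime_ns else 4.04
    phasor_reference(read_decay_stack(refp), tau)
  }
  list(donor = donor,
       acceptor = if (!is.null(acc)) read_intensity(acc, "acceptor"),
       if_channel = if (!is.null(ifc)) read_intensity(ifc, "IF"),
       reference = ref)
}

# Per-condition five-number summaries of the cohort metrics.
cohort_summary <- function(cells) {
  if (!nrow(cells)) return(tibble())
  long <- tidyr_pivot(cells)
  dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$metric),
    n = sum(!is.na(.data$value)),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    median = median(.data$value, na.rm = TRUE),
    q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    .groups = "drop"
  )
}

tidyr_pivot <- function(cells) {
  metrics <- c("fraction_compact", "fraction_inside", "fraction_outside",
               "normalized_inside", "median_particle_area_um2")
  out <- lapply(metrics, function(m) {
    tibble(condition = cells$condition, metric = m, value = cells[[m]])
  })
  dplyr::bind_rows(out)
}

cohort_tests <- function(cells) {
  tests <- list()
  conds <- unique(cells$condition)
  if (length(conds) >= 2L) {
    a <- cells$fraction_compact[cells$condition == conds[1]]
    b <- cells$fraction_compact[cells$condition == conds[2]]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) >= 2L && length(b) >= 2L) {
      t <- tryCatch(unpaired_t(a, b), error = function(e) NULL)
      if (!is.null(t)) {
        t$comparison <- sprintf("fraction_compact: %s vs %s", conds[1], conds[2])
        tests[[length(tests) + 1L]] <- t
      }
    }
  }
  groups <- split(cells, paste(cells$condition, cells$channel, sep = "/"))
  for (gname in names(groups)) {
    g <- groups[[gname]]
    ok <- !is.na(g$fraction_inside) & !is.na(g$fraction_outside)
    if (sum(ok) >= 2L) {
      t <- tryCatch(paired_t(g$fraction_inside[ok], g$fraction_outside[ok]),
                    error = function(e) NULL)
      if (!is.null(t)) {
        t$comparison <- sprintf("inside vs outside DSB foci [%s]", gname)
        tests[[length(tests) + 1L]] <- t
      }
    }
  }
  if (!length(tests)) return(tibble())
  dplyr::relocate(dplyr::bind_rows(tests), "comparison")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d cells (%d quarantined), conditions: %s\n",
              nrow(x$cells), nrow(x$quarantined),
              paste(unique(x$cells$condition), collapse = ", ")))
  if (nrow(x$tests)) {
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("  %s: t = %.3f, df = %.3g, p = %.3g (%s)\n",
                  x$tests$comparison[i], x$tests$statistic[i], x$tests$df[i],
                  x$tests$p_value[i], x$tests$kind[i]))
    }
  }
  invisible(x)
}

#' Tidy a cohort report into per-cell records
#'
#' @param x A [run_pipeline()] report.
#' @param ... Unused.
#' @return The per-cell record tibble.
#' @export
tidy.cohort_report <- function(x, ...) x$cells

#' One-row overview of a cohort report
#'
#' @param x A [run_pipeline()] report.
#' @param ... Unused.
#' @return A one-row tibble with cohort size, quarantine count, and the
#'   headline p-values.
#' @export
glance.cohort_report <- function(x, ...) {
  p_cond <- if (nrow(x$tests)) {
    p <- x$tests$p_value[x$tests$kind == "unpaired"]
    if (length(p)) p[1] else NA_real_
  } else NA_real_
  p_io <- if (nrow(x$tests)) {
    p <- x$tests$p_value[x$tests$kind == "paired"]
    if (length(p)) p[1] else NA_real_
  } else NA_real_
  tibble(n_cells = nrow(x$cells),
         n_conditions = length(unique(x$cells$condition)),
         n_quarantined = nrow(x$quarantined),
         p_condition = p_cond,
         p_inside_outside = p_io)
}

#' Simulated two-condition cohort
#'
#' Builds a cohort of simulation configurations emulating the study design:
#' untreated nuclei (no DSB induction, baseline compaction) versus nuclei
#' 2 h after DSB induction (~100 gamma-H2AX-marked foci that open locally
#' while global compaction rises). Defaults encode that design: compact area
#' fraction 0.25 untreated vs 0.35 treated, DSB foci only in the treated arm.
#'
#' @param n_per_condition Cells per condition.
#' @param image_size Frame edge length passed to each [flim_sim_config()].
#' @param compact_fraction_untreated,compact_fraction_treated Target compact
#'   area fractions of the two arms.
#' @param n_dsb_foci DSB focus count in the treated arm.
#' @param seed Base seed; each cell derives its own.
#' @param ... Further arguments passed to [flim_sim_config()].
#' @return A cohort tibble (`cell_id`, `condition`, `channel`, `config`)
#'   ready for [run_pipeline()].
#' @export
simulate_cohort <- function(n_per_condition = 5L, image_size = 256L,
                            compact_fraction_untreated = 0.25,
                            compact_fraction_treated = 0.35,
                            n_dsb_foci = 100L, seed = 1L, ...) {
  mk <- function(i, condition, frac, ndsb) {
    tibble(
      cell_id = sprintf("%s_%02d", condition, i),
      condition = condition,
      channel = "gH2AX",
      config = list(flim_sim_config(
        image_size = image_size, compact_area_fraction = frac,
        n_dsb_foci = ndsb,
        seed = (abs(as.integer(seed)) %% 100000L) * 10000L +
          ifelse(condition == "untreated", 0L, 5000L) + i, ...))
    )
  }
  dplyr::bind_rows(
    lapply(seq_len(n_per_condition), mk, condition = "untreated",
           frac = compact_fraction_untreated, ndsb = 0L),
    lapply(seq_len(n_per_condition), mk, condition = "4OHT_2h",
           frac = compact_fraction_treated, ndsb = n_dsb_foci)
  )
}
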