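#' Two-sample t-test between cell groups
#'
#' Student's two-sample t-test with pooled variance (equal variances assumed,
#' mirroring the default of common prism-style analysis software), two-sided,
#' with `df = nA + nB - 2`. Welch's correction is available by flag. Used to
#' compare per-cell compact-chromatin fractions between conditions.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param var_equal Pool variances (default `TRUE`); `FALSE` gives Welch.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `kind`,
#'   `two_sided`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
unpaired_t <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("both groups need at least 2 observations.",
          class = "chromphasor_validation_error")
  }
  na <- length(group_a)
  nb <- length(group_b)
  pooled <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (pooled == 0) {
    abort("zero pooled variance: t statistic undefined.",
          class = "chromphasor_zero_variance_error")
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, kind = "unpaired", two_sided = TRUE,
         mean_a = mean(group_a), mean_b = mean(group_b), n_a = na, n_b = nb)
}

#' Paired t-test on per-cell measurements
#'
#' One-sample t-test on paired differences (`df = n - 1`), two-sided. Used
#' for within-cell comparisons, e.g. compact fraction inside versus outside
#' DSB foci of the same nucleus.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`, paired by cell.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `kind`,
#'   `two_sided`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("paired samples must have equal length.",
          class = "chromphasor_validation_error")
  }
  if (length(x) < 2L) {
    abort("paired test needs at least 2 pairs.",
          class = "chromphasor_validation_error")
  }
  d <- x - y
  if (sd(d) == 0) {
    abort("constant differences: zero variance, t statistic undefined.",
          class = "chromphasor_zero_variance_error")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, kind = "paired", two_sided = TRUE,
         mean_diff = mean(d), n = length(x))
}
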