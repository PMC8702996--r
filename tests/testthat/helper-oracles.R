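# Independent oracles and fixture builders used across the suite.

# Closed-form phasor of a period-wrapped mono-exponential decay.
oracle_exp_phasor <- function(tau_ns, rep_rate_hz = 80e6, harmonic = 1) {
  w <- 2 * pi * harmonic * rep_rate_hz * 1e-9
  c(g = 1 / (1 + (w * tau_ns)^2), s = (w * tau_ns) / (1 + (w * tau_ns)^2))
}

# Expected bin counts of a wrapped exponential, computed independently of the
# package (direct CDF differences).
oracle_exp_counts <- function(tau_ns, n_bins, period_ns, total = 1e6) {
  e <- seq(0, period_ns, length.out = n_bins + 1)
  cdf <- (1 - exp(-e / tau_ns)) / (1 - exp(-period_ns / tau_ns))
  total * diff(cdf)
}

# Uniform-valued decay stack with the given per-bin profile at every pixel.
profile_stack <- function(profile, meta, nrow = 2, ncol = 2) {
  decay_image(
    array(rep(profile, each = nrow * ncol), c(nrow, ncol, meta$n_bins)),
    meta
  )
}

# Hand-built phasor image (for classification tests that need exact
# coordinates).
make_phasor_image <- function(g, s, photons, meta = flim_meta()) {
  structure(list(g = g, s = s, photons = photons, meta = meta),
            class = "phasor_image")
}

# Brute-force 3x3 median filter with edge replication (explicit loops).
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- numeric(9); k <- 1
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- min(max(r + dr, 1), nr)
          cc <- min(max(c + dc, 1), nc)
          vals[k] <- m[rr, cc]; k <- k + 1
        }
      }
      out[r, c] <- median(vals)
    }
  }
  out
}

# Brute-force particle labeling: border-reachability hole fill (4-connected
# background) followed by stack-based flood fill (8-connected foreground),
# renumbered in column-major first-appearance order.
oracle_label <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # hole fill
  reach <- matrix(FALSE, nr, nc)
  stack <- which(!m & (row(m) == 1 | row(m) == nr | col(m) == 1 | col(m) == nc))
  reach[stack] <- TRUE
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !m[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        stack <- c(stack, (cc - 1) * nr + rr)
      }
    }
  }
  filled <- m | (!m & !reach)
  # flood fill, 8-connected
  lab <- matrix(0L, nr, nc)
  next_id <- 0L
  for (start in which(filled)) {
    if (lab[start] > 0L) next
    next_id <- next_id + 1L
    stack <- start
    lab[start] <- next_id
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              filled[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- next_id
            stack <- c(stack, (cc - 1) * nr + rr)
          }
        }
      }
    }
  }
  lab
}

# Small acquisition for fast simulator tests.
fast_meta <- function(n_bins = 64L) flim_meta(n_bins = n_bins)
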