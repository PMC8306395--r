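#' Gaussian matched-filter kernel for photon-burst detection
#'
#' Builds the weighted-sliding-sum (WSS) template: Gaussian weights
#' \eqn{w(t) = A \exp(-(t - t_0)^2 / (2\sigma_t^2))} sampled every `dtw`
#' around the mode.  The width is ideally \eqn{\sigma_t = \omega_0 / (2 v)}
#' for a transit at constant speed `v` through a focus of waist `w0`, which
#' matches the expected temporal profile of the fluorescence burst (a matched
#' filter).  The kernel spans `span` sigma on each side of the mode and holds
#' an odd number of taps so the mode lies exactly on a sample.
#'
#' @param sigma_t temporal width of the template (s); must be at least `dtw`.
#' @param dtw sampling interval (s), default 1e-5 (10 us).
#' @param A weight amplitude at the mode, default 128.
#' @param span half-extent of the kernel in units of `sigma_t`, default 3.
#' @param threshold WSS detection threshold (weighted counts), or `NULL` to
#'   fill it in later (see [default_threshold()]).
#' @return An object of class `smr_wss_kernel` with elements `weights`
#'   (numeric taps), `offsets` (tap offsets in bins, symmetric about 0),
#'   and the configuration fields.
#' @export
wss_kernel <- function(sigma_t, dtw = 1e-5, A = 128, span = 3,
                       threshold = NULL) {
  stopifnot(sigma_t > 0, dtw > 0, A > 0, span > 0)
  if (sigma_t < dtw)
    stop("sigma_t < dtw: kernel unresolvable at this sampling interval")
  if (!is.null(threshold)) stopifnot(threshold > 0)
  n <- as.integer(floor(2 * span * sigma_t / dtw)) + 1L
  if (n %% 2L == 0L) n <- n + 1L   # keep the mode on a sample
  half <- (n - 1L) %/% 2L
  offsets <- seq.int(-half, half)
  weights <- A * exp(-(offsets * dtw)^2 / (2 * sigma_t^2))
  structure(list(weights = weights, offsets = offsets, half = half,
                 sigma_t = sigma_t, dtw = dtw, A = A, span = span,
                 threshold = threshold),
            class = "smr_wss_kernel")
}

#' @export
print.smr_wss_kernel <- function(x, ...) {
  cat(sprintf(
    "<smr_wss_kernel> %d taps, sigma_t = %g s, dtw = %g s, A = %g, threshold = %s\n",
    length(x$weights), x$sigma_t, x$dtw, x$A,
    if (is.null(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

#' Default WSS threshold from the background rate
#'
#' Eight times the expected background WSS level `B * dtw * sum(weights)`.
#' The threshold is operator-adjustable in practice; this default sits far
#' above background shot noise yet well below the peak of a bright burst.
#'
#' @param kernel a [wss_kernel()].
#' @param B background count rate (counts/s).
#' @param factor multiple of the expected background level, default 8.
#' @return threshold value (weighted counts).
#' @export
default_threshold <- function(kernel, B, factor = 8) {
  stopifnot(inherits(kernel, "smr_wss_kernel"), B >= 0, factor > 0)
  factor * B * kernel$dtw * sum(kernel$weights)
}

# Core WSS accumulation: centred, zero-padded discrete correlation of
# `x` with the kernel taps.  Accumulates tap by tap in ascending offset
# order, so a brute-force double loop in the same order reproduces the
# result bitwise (tested).
wss_core <- function(x, weights, half) {
  n <- length(x)
  xp <- c(numeric(half), as.numeric(x), numeric(half))
  acc <- numeric(n)
  for (j in seq_along(weights)) {
    acc <- acc + weights[j] * xp[j:(j + n - 1L)]
  }
  acc
}

#' Weighted sliding sum of a binned count stream
#'
#' Correlates the count stream with the matched-filter weights.  The output
#' shares the input grid; the value at bin `i` sums `weights * counts` over a
#' window centred on bin `i`, with zero padding at the edges.  For the
#' symmetric Gaussian kernel this centred convention makes the WSS maximum an
#' unbiased estimate of the transit midpoint.
#'
#' @param counts photon counts per bin (numeric vector), or an
#'   [smr_photons()] object.
#' @param kernel a [wss_kernel()] whose `dtw` matches the count binning.
#' @return numeric vector of WSS values, same length as the counts.
#' @export
wss <- function(counts, kernel) {
  stopifnot(inherits(kernel, "smr_wss_kernel"))
  if (inherits(counts, "smr_photons")) {
    if (abs(counts$bin_width - kernel$dtw) > 1e-12)
      stop("photon bin width does not match kernel dtw")
    counts <- counts$bin_counts
  }
  if (length(counts) < length(kernel$weights))
    stop("count stream shorter than the kernel")
  wss_core(counts, kernel$weights, kernel$half)
}

# Segment a logical above-threshold vector into maximal runs.
# Returns a matrix with columns start, end (1-based indices), or NULL.
threshold_runs <- function(above) {
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect photon bursts in a WSS series
#'
#' Scans for maximal runs of WSS values strictly above the threshold; each
#' run yields exactly one burst event at the run's maximum (earliest bin on
#' ties).  Runs truncated by either end of the data are still emitted and
#' flagged with `edge = TRUE`.
#'
#' @param wss_series numeric WSS values on a regular grid.
#' @param threshold detection threshold, positive.
#' @param dtw grid spacing (s), default 1e-5.
#' @param t0 time of the first WSS sample (s), default 0.
#' @return data frame of class `smr_bursts` with columns `t_peak`,
#'   `wss_peak`, `run_start`, `run_end` (seconds) and `edge` (logical).
#' @export
detect_bursts <- function(wss_series, threshold, dtw = 1e-5, t0 = 0) {
  stopifnot(is.numeric(wss_series), threshold > 0, dtw > 0)
  runs <- threshold_runs(wss_series > threshold)
  if (is.null(runs)) {
    out <- data.frame(t_peak = numeric(0), wss_peak = numeric(0),
                      run_start = numeric(0), run_end = numeric(0),
                      edge = logical(0))
    class(out) <- c("smr_bursts", "data.frame")
    return(out)
  }
  n <- length(wss_series)
  peak_idx <- integer(nrow(runs))
  peak_val <- numeric(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    sl <- wss_series[runs[k, 1]:runs[k, 2]]
    j <- which.max(sl)           # earliest maximum on ties
    peak_idx[k] <- runs[k, 1] + j - 1L
    peak_val[k] <- sl[j]
  }
  out <- data.frame(
    t_peak = t0 + (peak_idx - 1L) * dtw,
    wss_peak = peak_val,
    run_start = t0 + (runs[, 1] - 1L) * dtw,
    run_end = t0 + (runs[, 2] - 1L) * dtw,
    edge = runs[, 1] == 1L | runs[, 2] == n)
  class(out) <- c("smr_bursts", "data.frame")
  out
}

# --- streaming detector -----------------------------------------------------
# The closed-loop simulator consumes WSS values in chunks; this small state
# machine produces exactly the events detect_bursts() finds on the full
# series (equality is a test).  A run still open at a chunk boundary is
# carried; flush with wss_stream_end().

wss_stream_new <- function(threshold, dtw = 1e-5, t0 = 0) {
  list(threshold = threshold, dtw = dtw, t0 = t0,
       next_idx = 1L,              # global index of the next value to see
       open = NULL,                # list(start, peak_idx, peak_val) or NULL
       events = list())
}

wss_stream_feed <- function(st, values) {
  if (!length(values)) return(st)
  above <- values > st$threshold
  base <- st$next_idx - 1L
  runs <- threshold_runs(above)
  k0 <- 1L
  if (!is.null(st$open)) {
    if (above[1]) {
      # continuation of the carried run: fold the first run into it
      stopifnot(!is.null(runs) && runs[1, 1] == 1L)
      sl <- values[runs[1, 1]:runs[1, 2]]
      j <- which.max(sl)
      if (sl[j] > st$open$peak_val) {
        st$open$peak_val <- sl[j]
        st$open$peak_idx <- base + runs[1, 1] + j - 1L
      }
      if (runs[1, 2] < length(values)) {   # run closed inside this chunk
        st$events[[length(st$events) + 1L]] <-
          c(st$open$start, base + runs[1, 2], st$open$peak_idx,
            st$open$peak_val)
        st$open <- NULL
      }
      k0 <- 2L
    } else {
      # carried run ended exactly at the chunk boundary
      st$events[[length(st$events) + 1L]] <-
        c(st$open$start, base, st$open$peak_idx, st$open$peak_val)
      st$open <- NULL
    }
  }
  if (!is.null(runs) && k0 <= nrow(runs)) {
    for (k in k0:nrow(runs)) {
      sl <- values[runs[k, 1]:runs[k, 2]]
      j <- which.max(sl)
      if (runs[k, 2] == length(values)) {
        st$open <- list(start = base + runs[k, 1],
                        peak_idx = base + runs[k, 1] + j - 1L,
                        peak_val = sl[j])
      } else {
        st$events[[length(st$events) + 1L]] <-
          c(base + runs[k, 1], base + runs[k, 2],
            base + runs[k, 1] + j - 1L, sl[j])
      }
    }
  }
  st$next_idx <- st$next_idx + length(values)
  st
}

wss_stream_end <- function(st) {
  if (!is.null(st$open)) {
    st$events[[length(st$events) + 1L]] <-
      c(st$open$start, st$next_idx - 1L, st$open$peak_idx, st$open$peak_val)
    st$open <- NULL
  }
  st
}

# Events accumulated so far as an smr_bursts data frame.
wss_stream_events <- function(st, n_total = st$next_idx - 1L) {
  if (!length(st$events)) {
    out <- data.frame(t_peak = numeric(0), wss_peak = numeric(0),
                      run_start = numeric(0), run_end = numeric(0),
                      edge = logical(0))
    class(out) <- c("smr_bursts", "data.frame")
    return(out)
  }
  m <- do.call(rbind, st$events)
  out <- data.frame(
    t_peak = st$t0 + (m[, 3] - 1L) * st$dtw,
    wss_peak = m[, 4],
    run_start = st$t0 + (m[, 1] - 1L) * st$dtw,
    run_end = st$t0 + (m[, 2] - 1L) * st$dtw,
    edge = m[, 1] == 1L | m[, 2] == n_total)
  class(out) <- c("smr_bursts", "data.frame")
  out
}
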