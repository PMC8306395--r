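#' Photon data container
#'
#' Holds a photon stream in the two representations produced by the
#' acquisition hardware: individual arrival times as integer counts of a
#' 10 ns clock ("ticks"), and photon counts binned at the control-loop
#' sampling interval `bin_width` (default 10 us).  Tick values are stored as
#' doubles holding exact integers (exact up to 2^53, i.e. runs of many years).
#'
#' @param ticks numeric vector of photon arrival times in 10 ns clock units,
#'   non-decreasing.
#' @param bin_counts non-negative integer photon counts per bin.
#' @param bin_width bin width (s).  Default 1e-5 (10 us).
#' @param t0 time of the left edge of the first bin (s).  Default 0.
#' @param tick_unit duration of one clock tick (s).  Default 1e-8 (10 ns).
#' @return An object of class `smr_photons`.
#' @export
smr_photons <- function(ticks, bin_counts, bin_width = 1e-5, t0 = 0,
                        tick_unit = 1e-8) {
  ticks <- as.numeric(ticks)
  bin_counts <- as.numeric(bin_counts)
  stopifnot(bin_width > 0, tick_unit > 0,
            all(bin_counts >= 0), all(bin_counts == floor(bin_counts)))
  if (length(ticks) && is.unsorted(ticks)) stop("ticks must be non-decreasing")
  if (length(ticks) && any(ticks != floor(ticks)))
    stop("ticks must be integers (10 ns clock counts)")
  structure(list(ticks = ticks, bin_counts = bin_counts,
                 bin_width = bin_width, t0 = t0, tick_unit = tick_unit),
            class = "smr_photons")
}

#' @export
print.smr_photons <- function(x, ...) {
  cat(sprintf(
    "<smr_photons> %d photons, %d bins of %g s (span %.4g s)\n",
    length(x$ticks), length(x$bin_counts), x$bin_width,
    length(x$bin_counts) * x$bin_width))
  invisible(x)
}

#' Draw Poisson photons from a molecule-focus offset series
#'
#' For each time step the photon count is Poisson with mean
#' `(F * exp(-2 x^2 / w0^2) * [t < bleach_time] + B) * dt`.  Photons are
#' assigned integer 10 ns ticks placed uniformly at random within their step.
#' Uses R's global random number generator.
#'
#' @param offsets molecule position minus focus position at each step (m).
#' @param beam a [beam_model()].
#' @param dt step duration (s); must divide into, and not exceed, the photon
#'   bin width (here steps and bins coincide, `dt = bin_width`).
#' @param t0 time of the start of the first step (s).
#' @param bleach_time photobleaching instant (s); the molecular term is zero
#'   for steps starting at or after this time.  Default `Inf` (no bleaching).
#' @return an [smr_photons()] object with one bin per step.
#' @export
emit_photons <- function(offsets, beam, dt = 1e-5, t0 = 0, bleach_time = Inf) {
  stopifnot(inherits(beam, "smr_beam"), dt > 0)
  n <- length(offsets)
  t_start <- t0 + (seq_len(n) - 1) * dt
  alive <- t_start < bleach_time
  lambda <- (detection_rate(offsets, beam, include_background = FALSE) * alive +
               beam$B) * dt
  counts <- stats::rpois(n, lambda)
  ticks <- photon_ticks(counts, dt, t0)
  smr_photons(ticks, counts, bin_width = dt, t0 = t0)
}

# Uniform placement of `counts[i]` photons within bin i; returns sorted
# integer 10 ns tick values.  The within-bin offset is capped so float
# round-off can never push a photon across its bin boundary.
photon_ticks <- function(counts, dt, t0 = 0, tick_unit = 1e-8) {
  tot <- sum(counts)
  if (tot == 0) return(numeric(0))
  bin_idx <- rep.int(seq_along(counts), counts)
  tpb <- round(dt / tick_unit)          # ticks per bin (10 us / 10 ns = 1000)
  base <- round(t0 / tick_unit) + (bin_idx - 1) * tpb
  within <- pmin(floor(stats::runif(tot) * tpb), tpb - 1)
  sort(base + within)
}
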