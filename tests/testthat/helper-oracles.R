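# Independent oracles used across the suite.  These deliberately use the
# most naive formulation available (double loops, direct formulas) and stay
# independent of the package's code paths.

# Brute-force weighted sliding sum: double loop, tap-ascending accumulation,
# zero padding at the edges.
brute_wss <- function(counts, weights, half) {
  n <- length(counts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_along(weights)) {
      src <- i + j - half - 1L
      x <- if (src >= 1L && src <= n) counts[src] else 0
      s <- s + weights[j] * x
    }
    out[i] <- s
  }
  out
}

# Direct normalized autocorrelation at integer lag k on a coarsened series.
# Coarsening by `width` sums adjacent bins (matrix reshape, an independent
# path from the package's recursive coarsening).
brute_acf_point <- function(counts, lag_bins, width) {
  n2 <- length(counts) %/% width
  y <- colSums(matrix(counts[seq_len(n2 * width)], nrow = width))
  k <- lag_bins %/% width
  n <- length(y)
  a <- y[seq_len(n - k)]
  b <- y[seq.int(k + 1L, n)]
  (sum(a * b) / (n - k)) / ((sum(a) / (n - k)) * (sum(b) / (n - k)))
}

default_models <- function() {
  list(diff = diffusion_model(D = 5e-11, v = 0),
       beam = beam_model(),
       stage = stage_model(),
       control = recycling_config())
}
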