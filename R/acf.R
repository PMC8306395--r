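#' Normalized photon autocorrelation (multi-tau correlator)
#'
#' Computes \eqn{g(\tau) = \langle n(t) n(t+\tau)\rangle / \langle n\rangle^2}
#' of a binned photon count stream on a pseudo-logarithmic (multi-tau) lag
#' grid: `lags_per_octave` linearly spaced lags per octave, with the count
#' stream coarsened by a factor of two at each successive octave.  Symmetric
#' normalization is used (the two means are taken over the exact overlap of
#' the shifted series), so an uncorrelated stream gives `g ~ 1` at all lags.
#'
#' @param x an [smr_photons()] object, or a numeric vector of counts per bin
#'   (then `bin_width` must be given).
#' @param max_lag largest lag to compute (s).  Must be below half the record
#'   length.
#' @param lags_per_octave number of lags per octave, default 16.
#' @param bin_width bin width (s) when `x` is a plain vector.
#' @return data frame of class `smr_acf` with columns `lag` (s), `g`,
#'   `level` (octave index), `lag_bins` and `width_bins` (in units of the
#'   original binning).  Lag zero is excluded (shot noise).
#' @export
compute_acf <- function(x, max_lag = 0.1, lags_per_octave = 16,
                        bin_width = NULL) {
  if (inherits(x, "smr_photons")) {
    bin_width <- x$bin_width
    x <- x$bin_counts
  }
  stopifnot(is.numeric(x), !is.null(bin_width), bin_width > 0,
            lags_per_octave >= 1, max_lag > 0)
  if (sum(x) < 2) stop("need at least 2 photons to correlate")
  n0 <- length(x)
  if (max_lag >= n0 * bin_width / 2)
    stop("max_lag must be below half the record length")
  m <- as.integer(lags_per_octave)
  y <- as.numeric(x)
  level <- 0L
  rows <- list()
  repeat {
    width <- 2^level                           # coarse bin, original units
    local_lags <- if (level == 0L) seq_len(2L * m) else (m + 1L):(2L * m)
    lag_orig <- local_lags * width
    keep <- lag_orig * bin_width <= max_lag
    if (!any(keep)) break
    n <- length(y)
    for (k in local_lags[keep]) {
      if (k >= n) next
      a <- y[1:(n - k)]
      b <- y[(1 + k):n]
      gk <- (sum(a * b) / (n - k)) /
        ((sum(a) / (n - k)) * (sum(b) / (n - k)))
      rows[[length(rows) + 1L]] <-
        c(lag = k * width * bin_width, g = gk, level = level,
          lag_bins = k * width, width_bins = width)
    }
    # next octave: coarsen by 2; stop once its smallest lag exceeds max_lag
    if ((m + 1L) * 2^(level + 1) * bin_width > max_lag) break
    n2 <- length(y) %/% 2L
    if (n2 < 2L * m + 2L) break
    y <- y[seq.int(1L, 2L * n2 - 1L, by = 2L)] +
      y[seq.int(2L, 2L * n2, by = 2L)]
    level <- level + 1L
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- out[order(out$lag), ]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  class(out) <- c("smr_acf", "data.frame")
  out
}

#' Fit the 1D flow-plus-diffusion autocorrelation model
#'
#' Nonlinear least squares of
#' \deqn{g(\tau) = a_0 + \frac{a_1}{1 + a_3\tau}
#'   \exp\!\left(-\frac{a_2 \tau^2}{1 + a_3\tau}\right)}
#' to a computed autocorrelation curve.  Here `a0` is the baseline, `a1` the
#' amplitude (\eqn{F^2/(F+B)^2}), `a2 = (v/w0)^2` the squared reciprocal
#' flow time constant, and `a3 = 4D/w0^2` the reciprocal diffusion time
#' constant.  Parameters may be fixed, e.g. `fix = list(a3 = 0)` for an
#' immobilized bead.  Lags beyond `max_fit_lag` are excluded so the periodic
#' recycle peaks do not enter the fit of the first decay.
#'
#' @param curve an `smr_acf` data frame (or any data frame with `lag`, `g`).
#' @param fix named list of parameters to hold fixed.
#' @param start optional named list of starting values for free parameters.
#' @param max_fit_lag largest lag included in the fit (s); default keeps the
#'   whole curve.
#' @return list with `coefficients` (named a0..a3, fixed ones included),
#'   `se` (asymptotic standard errors, `NA` for fixed parameters),
#'   `converged`, `message` and the underlying `nls` object (or `NULL`).
#' @export
fit_acf <- function(curve, fix = list(), start = NULL, max_fit_lag = NULL) {
  stopifnot(is.data.frame(curve), all(c("lag", "g") %in% names(curve)))
  d <- curve[is.finite(curve$g), c("lag", "g")]
  if (!is.null(max_fit_lag)) d <- d[d$lag <= max_fit_lag, ]
  if (nrow(d) < 8) stop("need at least 8 lag points spanning the decay")
  pnames <- c("a0", "a1", "a2", "a3")
  if (length(fix) && !all(names(fix) %in% pnames))
    stop("fix must name parameters among a0..a3")
  free <- setdiff(pnames, names(fix))

  # starting values from curve geometry
  a0_s <- mean(utils::tail(d$g, max(3L, nrow(d) %/% 5L)))
  a1_s <- max(d$g) - a0_s
  if (a1_s <= 0) a1_s <- 1e-3
  gh <- a0_s + a1_s / 2
  above <- d$g >= gh
  tau_h <- if (any(!above)) d$lag[which(!above)[1]] else
    d$lag[nrow(d) %/% 2L]
  s0 <- list(a0 = a0_s, a1 = a1_s, a2 = log(2) / tau_h^2, a3 = 1 / tau_h / 10)
  if (!is.null(start)) s0[names(start)] <- start
  start_free <- s0[free]
  lower <- c(a0 = -Inf, a1 = 0, a2 = 0, a3 = 0)[free]

  dat <- c(as.list(d), fix)
  fit <- tryCatch(
    stats::nls(g ~ a0 + a1 / (1 + a3 * lag) *
                 exp(-a2 * lag^2 / (1 + a3 * lag)),
               data = dat, start = start_free, lower = lower,
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(coefficients = stats::setNames(rep(NA_real_, 4), pnames),
                se = stats::setNames(rep(NA_real_, 4), pnames),
                converged = FALSE, message = conditionMessage(fit),
                fit = NULL))
  }
  co <- stats::coef(fit)
  se_tab <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) stats::setNames(rep(NA_real_,
                                                             length(co)),
                                                         names(co)))
  coefs <- stats::setNames(numeric(4), pnames)
  ses <- stats::setNames(rep(NA_real_, 4), pnames)
  for (p in pnames) {
    coefs[p] <- if (p %in% names(fix)) fix[[p]] else co[[p]]
    if (p %in% names(se_tab)) ses[p] <- se_tab[[p]]
  }
  list(coefficients = coefs, se = ses, converged = TRUE, message = "ok",
       fit = fit)
}

#' Translation speed from the fitted transit time constant
#'
#' The constant-velocity transit through a Gaussian focus of waist `w0` has
#' temporal width \eqn{\sigma_t = \omega_0/(2v)}, so
#' \eqn{v = \omega_0/(2\sigma_t)}; equivalently, from the fitted flow
#' parameter \eqn{a_2 = (v/\omega_0)^2}, \eqn{v = \omega_0\sqrt{a_2}}.
#' Supply exactly one of `sigma_t` or `a2`.
#'
#' @param sigma_t transit time constant (s).
#' @param a2 fitted flow parameter (1/s^2).
#' @param w0 beam waist (m), default 1 um.
#' @return translation speed (m/s).
#' @examples
#' speed_from_transit(sigma_t = 0.47e-3)   # ~1.06e-3 m/s
#' @export
speed_from_transit <- function(sigma_t = NULL, a2 = NULL, w0 = 1e-6) {
  stopifnot(w0 > 0, xor(is.null(sigma_t), is.null(a2)))
  if (!is.null(sigma_t)) {
    if (any(sigma_t <= 0)) stop("sigma_t must be positive")
    w0 / (2 * sigma_t)
  } else {
    if (any(a2 < 0)) stop("a2 must be non-negative")
    w0 * sqrt(a2)
  }
}
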