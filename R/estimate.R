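#' Maximum-likelihood diffusivity from a single displacement
#'
#' For one displacement `dx` observed after a diffusion time `T`, the
#' likelihood of `D` is the Gaussian free-diffusion density
#' \deqn{L(D;\Delta x) = \frac{1}{\sqrt{4\pi D T}}
#'   \exp\!\left(-\frac{\Delta x^2}{4 D T}\right),}
#' maximized at \eqn{\hat D = \Delta x^2 / (2T)}.
#'
#' @param dx displacement(s) (m); vectorised.
#' @param T diffusion time (s), positive.
#' @return ML estimate(s) of `D` (m^2/s).
#' @export
ml_single <- function(dx, T) {
  if (any(T <= 0)) stop("ml_single() requires T > 0")
  dx^2 / (2 * T)
}

# direction parity must alternate strictly between consecutive cycles
check_parity <- function(cycles) {
  d <- cycles$direction
  if (!all(d %in% c(-1, 1)))
    stop("cycle directions must be +1/-1")
  if (nrow(cycles) > 1) {
    idx <- cycles$i
    adj <- which(diff(idx) == 1L)
    if (any(d[adj + 1L] != -d[adj]))
      stop("inconsistent direction parity sequence in cycle records")
  }
  invisible(TRUE)
}

#' Reconstruct molecule positions from cycle records
#'
#' During cycle `i` the stage scans from `X(i) - dir*Xt` through the centre
#' at speed `v`; the burst at `tw(i)` marks the moment the scan crosses the
#' molecule, so the molecule's capillary-frame position is
#' \deqn{X_m(i) = X(i) + \mathrm{dir}(i)\,\big[v\,(t_w(i)-t_p(i)) - X_t\big].}
#' Missed cycles are excluded; the retained records keep their original
#' cycle index so interval bookkeeping can recognise gaps.
#'
#' @param cycles an `smr_cycles` data frame (columns `i`, `tp`, `tw`, `X`,
#'   `direction`, `missed`).
#' @param v translation speed used for reconstruction (m/s).
#' @param Xt launch offset (m).  Default 4.58 um.
#' @param unit_scale metres per piezo unit.  Default 0.458 nm.
#' @param censor censor the transit displacement `v*(tw-tp)` to the physical
#'   scan window `[0, 2*Xt]`.  The focus never points outside
#'   `[X - Xt, X + Xt]`, so a burst fired outside the translation (the
#'   molecule sitting near a parked endpoint) measures the molecule at the
#'   window edge; censoring records exactly that.  With `censor = FALSE`
#'   (the default) the raw transit time is used and `tw < tp` is an error.
#' @return data frame of class `smr_positions` with columns `i`, `Xm`
#'   (molecule position, m), `dX` (transit displacement `v*(tw-tp)`, m),
#'   `X_m` (centre in metres) and `direction`; attributes `v_used`, `Xt_m`,
#'   `unit_scale`.
#' @export
reconstruct_positions <- function(cycles, v, Xt = 4.58e-6,
                                  unit_scale = 4.58e-6 / 1e4,
                                  censor = FALSE) {
  stopifnot(is.data.frame(cycles), v > 0, Xt > 0, unit_scale > 0)
  check_parity(cycles)
  keep <- !cycles$missed & !is.na(cycles$tw)
  cc <- cycles[keep, , drop = FALSE]
  dX <- v * (cc$tw - cc$tp)
  if (censor) {
    dX <- pmin(pmax(dX, 0), 2 * Xt)
  } else if (any(dX < 0)) {
    stop("found tw < tp in a non-missed cycle (use censor = TRUE for fallback-bound records)")
  }
  X_m <- cc$X * unit_scale
  out <- data.frame(i = cc$i, Xm = X_m + cc$direction * (dX - Xt),
                    dX = dX, X_m = X_m, direction = cc$direction)
  attr(out, "v_used") <- v
  attr(out, "Xt_m") <- Xt
  attr(out, "unit_scale") <- unit_scale
  class(out) <- c("smr_positions", "data.frame")
  out
}

#' Per-interval molecule displacements
#'
#' Successive differences of the reconstructed positions, restricted to
#' pairs of consecutive cycle indices (intervals that straddle a missed or
#' rejected cycle are dropped).  Algebraically each difference equals
#' \deqn{X(i+1)-X(i) - \mathrm{dir}(i)\,[\Delta X(i+1) + \Delta X(i) - 2X_t]}
#' evaluated from the raw records, an identity the tests verify.
#'
#' @param series an `smr_positions` data frame from
#'   [reconstruct_positions()].
#' @return data frame with columns `i` (index of the interval's first
#'   cycle) and `delta` (displacement, m).
#' @export
displacements <- function(series) {
  stopifnot(inherits(series, "smr_positions"))
  if (nrow(series) < 2) stop("need at least 2 reconstructed positions")
  adj <- which(diff(series$i) == 1L)
  data.frame(i = series$i[adj],
             delta = series$Xm[adj + 1L] - series$Xm[adj])
}

#' Select cycles by the 3-sigma transit-time criterion
#'
#' The histogram of observed transit times `tw - tp` is dominated by a
#' Gaussian peak (near 2.5 ms at the default operating point); cycles in
#' which the stage hit a travel limit, or the molecule drifted to the focus
#' without a translation, fall far outside it.  A Gaussian is fitted to the
#' histogram by least squares and only cycles within 3 sigma of its centre
#' are retained.  If the fit fails, the fallback is median +/- 3 MAD with a
#' warning.
#'
#' @param cycles an `smr_cycles` data frame with at least 20 non-missed
#'   cycles.
#' @param bin_width histogram bin width (s), default 0.1 ms.
#' @param censor_at optional upper censoring bound (s): transit times are
#'   censored to `[0, censor_at]` (the physical translation window) before
#'   the histogram fit and the selection, so censored edge detections are
#'   retained rather than rejected as outliers.
#' @return list with `cycles` (the retained subset), `center` and `sigma`
#'   of the fitted Gaussian (s), `n_rejected`, and `method`
#'   (`"gaussian"` or `"mad"`).
#' @export
filter_cycles <- function(cycles, bin_width = 1e-4, censor_at = NULL) {
  stopifnot(is.data.frame(cycles), bin_width > 0)
  ok <- !cycles$missed & !is.na(cycles$tw)
  tt_all <- cycles$tw - cycles$tp
  if (!is.null(censor_at)) {
    stopifnot(censor_at > 0)
    tt_all <- pmin(pmax(tt_all, 0), censor_at)
  }
  dt <- tt_all[ok]
  if (length(dt) < 20)
    stop("filter_cycles() needs at least 20 non-missed cycles")
  brk <- seq(floor(min(dt) / bin_width) * bin_width,
             max(dt) + bin_width, by = bin_width)
  h <- graphics::hist(dt, breaks = brk, plot = FALSE)
  hd <- data.frame(x = h$mids, count = h$counts)
  fit <- tryCatch(
    stats::nls(count ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = hd,
               start = list(a = max(hd$count),
                            mu = hd$x[which.max(hd$count)],
                            s = max(stats::sd(dt) / 2, bin_width)),
               lower = c(a = 0, mu = min(dt), s = bin_width / 10),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    center <- co[["mu"]]; sigma <- abs(co[["s"]]); method <- "gaussian"
  } else {
    warning("Gaussian fit of the transit-time histogram failed; ",
            "falling back to median +/- 3 MAD")
    center <- stats::median(dt)
    sigma <- stats::mad(dt)
    method <- "mad"
  }
  sel <- ok & !is.na(cycles$tw) & abs(tt_all - center) <= 3 * sigma
  list(cycles = cycles[sel, , drop = FALSE],
       center = center, sigma = sigma,
       n_rejected = sum(ok) - sum(sel), method = method)
}

#' Pooled maximum-likelihood diffusivity
#'
#' Averages the per-interval estimates \eqn{\hat D_i = \Delta_i^2/(2T)}:
#' \deqn{\hat D = \frac{1}{2NT}\sum_i \Delta_i^2,}
#' with predicted relative standard deviation \eqn{\sqrt{2/N}} (each
#' \eqn{\hat D_i} is proportional to a chi-squared variate with one degree
#' of freedom).
#'
#' @param displacements numeric vector of per-interval displacements (m),
#'   or the data frame returned by [displacements()].
#' @param T diffusion time per interval (s): the reversal delay.
#' @param N number of intervals; defaults to the number supplied.
#' @return An object of class `smr_estimate`: list with `D_i`, `D_hat`,
#'   `N`, `T` and `rel_precision`.
#' @export
ml_pooled <- function(displacements, T, N = NULL) {
  if (is.data.frame(displacements)) displacements <- displacements$delta
  stopifnot(is.numeric(displacements), length(displacements) >= 1, T > 0)
  if (is.null(N)) N <- length(displacements)
  D_i <- ml_single(displacements, T)
  structure(list(D_i = D_i, D_hat = mean(D_i), N = N, T = T,
                 rel_precision = sqrt(2 / N),
                 filter_fit = NULL, n_rejected = NA_integer_),
            class = "smr_estimate")
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("<smr_estimate> D_hat = %.4g m^2/s from N = %d intervals (T = %g s)\n",
              x$D_hat, x$N, x$T))
  cat(sprintf("  predicted relative precision sqrt(2/N) = %.3g\n",
              x$rel_precision))
  if (!is.null(x$filter_fit))
    cat(sprintf("  transit-time filter: center %.4g ms, sigma %.4g ms (%s), %d rejected\n",
                x$filter_fit$center * 1e3, x$filter_fit$sigma * 1e3,
                x$filter_fit$method, x$n_rejected))
  invisible(x)
}

#' Full diffusivity estimation pipeline from cycle records
#'
#' Applies the 3-sigma transit-time cycle filter (optional), reconstructs
#' molecule positions, forms displacements over consecutive retained cycles,
#' and pools the per-interval ML estimates.
#'
#' @param cycles an `smr_cycles` data frame.
#' @param v translation speed used for reconstruction (m/s).
#' @param Xt launch offset (m).
#' @param unit_scale metres per piezo unit.
#' @param T diffusion time per interval (s); the reversal delay.  With
#'   `use_measured_intervals = TRUE` each interval instead uses its measured
#'   `tw(i+1) - tw(i)`.
#' @param filter apply [filter_cycles()] first (default `TRUE`).
#' @param use_measured_intervals use measured burst-to-burst intervals as
#'   the per-interval diffusion times.
#' @param hist_bin histogram bin width for the cycle filter (s).
#' @param censor censor transit times to the physical scan window
#'   `[0, 2*Xt/v]` throughout (default `TRUE`); see
#'   [reconstruct_positions()].  Cycles whose stage command was clamped at
#'   a travel limit are always excluded (their launch geometry is unknown).
#' @return An object of class `smr_estimate` (see [ml_pooled()]), with the
#'   cycle-filter diagnostics attached.
#' @export
estimate_diffusivity <- function(cycles, v, Xt = 4.58e-6,
                                 unit_scale = 4.58e-6 / 1e4, T,
                                 filter = TRUE,
                                 use_measured_intervals = FALSE,
                                 hist_bin = 1e-4, censor = TRUE) {
  stopifnot(is.data.frame(cycles), T > 0)
  if (!is.null(cycles$clamped))
    cycles <- cycles[!cycles$clamped, , drop = FALSE]
  ff <- NULL
  cc <- cycles
  if (filter) {
    ff <- filter_cycles(cycles, bin_width = hist_bin,
                        censor_at = if (censor) 2 * Xt / v else NULL)
    cc <- ff$cycles
  }
  series <- reconstruct_positions(cc, v = v, Xt = Xt,
                                  unit_scale = unit_scale, censor = censor)
  dd <- displacements(series)
  if (use_measured_intervals) {
    tw_by_i <- stats::setNames(cc$tw, cc$i)
    Ti <- as.numeric(tw_by_i[as.character(dd$i + 1L)]) -
      as.numeric(tw_by_i[as.character(dd$i)])
    D_i <- dd$delta^2 / (2 * Ti)
    res <- structure(list(D_i = D_i, D_hat = mean(D_i),
                          N = length(D_i), T = T,
                          rel_precision = sqrt(2 / length(D_i)),
                          filter_fit = NULL, n_rejected = NA_integer_),
                     class = "smr_estimate")
  } else {
    res <- ml_pooled(dd, T = T)
  }
  if (!is.null(ff)) {
    res$filter_fit <- list(center = ff$center, sigma = ff$sigma,
                           method = ff$method)
    res$n_rejected <- ff$n_rejected
  }
  res
}
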