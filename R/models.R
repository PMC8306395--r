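#' Physical model of 1D drift-diffusion in the capillary
#'
#' Describes Brownian motion of a molecule confined to the axis of a
#' microchannel, governed by the 1D Fokker-Planck (drift-diffusion) equation
#' \deqn{\partial_t p = D \partial_x^2 p - v \partial_x p.}
#' Its Green's function for a point release at the origin is a Gaussian with
#' mean \eqn{\mu(t) = v t} and standard deviation \eqn{\sigma(t) = \sqrt{2Dt}}.
#'
#' @param D diffusion coefficient (m^2/s), non-negative.
#' @param v drift (flow) velocity along the channel (m/s).
#' @return An object of class `smr_diffusion`.
#' @examples
#' m <- diffusion_model(D = 5e-11)
#' propagator_pdf(0, t = 0.03, m)
#' @export
diffusion_model <- function(D, v = 0) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D), D >= 0,
            is.numeric(v), length(v) == 1L, is.finite(v))
  structure(list(D = D, v = v), class = "smr_diffusion")
}

#' @export
print.smr_diffusion <- function(x, ...) {
  cat(sprintf("<smr_diffusion> D = %g m^2/s, v = %g m/s\n", x$D, x$v))
  invisible(x)
}

#' Gaussian propagator density of the drift-diffusion model
#'
#' Probability density (1/m) of finding the molecule at displacement `x` a
#' time `t` after a point release at the origin: a Gaussian with mean
#' \eqn{vt} and standard deviation \eqn{\sqrt{2Dt}}.
#'
#' @param x displacement (m); vectorised.
#' @param t elapsed time (s), strictly positive (the `t = 0` case is the
#'   Dirac initial condition, not a density).
#' @param model a [diffusion_model()].
#' @return density values (1/m).
#' @export
propagator_pdf <- function(x, t, model) {
  stopifnot(inherits(model, "smr_diffusion"))
  if (any(t <= 0)) stop("propagator_pdf() requires t > 0")
  stats::dnorm(x, mean = model$v * t, sd = sqrt(2 * model$D * t))
}

#' One Euler-Maruyama step of the drift-diffusion process
#'
#' Advances position(s) `x` by `v*dt + sqrt(2*D*dt) * z` with `z` standard
#' normal.  For `D = 0` the step is purely deterministic advection.  Uses
#' R's global random number generator.
#'
#' @param x current position(s) (m).
#' @param dt time step (s), positive.
#' @param model a [diffusion_model()].
#' @return new position(s) (m), same length as `x`.
#' @export
step_brownian <- function(x, dt, model) {
  stopifnot(inherits(model, "smr_diffusion"), dt > 0)
  if (model$D == 0) return(x + model$v * dt)
  x + model$v * dt + sqrt(2 * model$D * dt) * stats::rnorm(length(x))
}

#' Gaussian laser focus model
#'
#' The focused beam has a Gaussian transverse intensity profile
#' \eqn{I(x) \propto \exp(-2x^2/\omega_0^2)} with \eqn{1/e^2} radius (beam
#' waist) `w0`.  A molecule at transverse offset `x` from the focus centre is
#' detected at rate \eqn{F \exp(-2x^2/\omega_0^2) + B} counts/s, where `F` is
#' the peak molecular count rate at the focus centre and `B` the background
#' rate.  This profile makes a constant-velocity transit a temporal Gaussian
#' of width \eqn{\sigma_t = \omega_0/(2v)}, consistent with the matched
#' filter used for burst detection.
#'
#' @param w0 beam waist (m), positive. Default 1 um.
#' @param F peak molecular count rate at the focus centre (counts/s).
#' @param B background count rate (counts/s), non-negative.
#' @return An object of class `smr_beam`.
#' @export
beam_model <- function(w0 = 1e-6, F = 1e5, B = 1e3) {
  stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0,
            is.numeric(F), length(F) == 1L, F > 0,
            is.numeric(B), length(B) == 1L, B >= 0)
  structure(list(w0 = w0, F = F, B = B), class = "smr_beam")
}

#' @export
print.smr_beam <- function(x, ...) {
  cat(sprintf("<smr_beam> w0 = %g m, F = %g /s, B = %g /s\n", x$w0, x$F, x$B))
  invisible(x)
}

#' Photon detection rate at a transverse offset from the focus
#'
#' @param x offset(s) from the focus centre (m).
#' @param beam a [beam_model()].
#' @param include_background add the background rate `B` (default `TRUE`).
#' @return detection rate(s) (counts/s).
#' @export
detection_rate <- function(x, beam, include_background = TRUE) {
  r <- beam$F * exp(-2 * x^2 / beam$w0^2)
  if (include_background) r + beam$B else r
}

#' Piezo translation-stage model
#'
#' The stage carries the capillary; its position is commanded in integer
#' "piezo units" converted to metres by `unit_scale`.  Motion is modelled as
#' piecewise-linear in time: constant-velocity translations at `v_trans`
#' separated by dwells.  `actuation_delay` is the latency between a motion
#' command and the start of motion.
#'
#' @param unit_scale stage displacement per piezo unit (m/unit).  Default
#'   4.58 um / 10,000 units = 0.458 nm/unit.
#' @param v_trans translation speed (m/s). Default 2 mm/s.
#' @param travel_limits length-2 numeric, allowed position range in piezo
#'   units.  Default about +/- 100 um.
#' @param actuation_delay command-to-motion latency (s).  Default 1 ms
#'   (the hardware bound is "under 2 ms").
#' @return An object of class `smr_stage`.
#' @export
stage_model <- function(unit_scale = 4.58e-6 / 1e4, v_trans = 2e-3,
                        travel_limits = c(-218340, 218340),
                        actuation_delay = 1e-3) {
  stopifnot(unit_scale > 0, v_trans > 0,
            length(travel_limits) == 2L,
            travel_limits[1] < travel_limits[2],
            actuation_delay >= 0)
  structure(list(unit_scale = unit_scale, v_trans = v_trans,
                 travel_limits = as.numeric(travel_limits),
                 actuation_delay = actuation_delay),
            class = "smr_stage")
}

#' @export
print.smr_stage <- function(x, ...) {
  cat(sprintf(
    "<smr_stage> %.4g nm/unit, v = %g m/s, limits [%g, %g] units, delay %g s\n",
    x$unit_scale * 1e9, x$v_trans, x$travel_limits[1], x$travel_limits[2],
    x$actuation_delay))
  invisible(x)
}
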