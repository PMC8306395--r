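#' Simulate a free drift-diffusion path
#'
#' Euler-Maruyama path of the 1D drift-diffusion process on a regular grid,
#' with no stage or controller.  Mostly useful for validation: over time
#' `T = n_steps * dt` the displacement has mean `v*T` and variance `2*D*T`.
#'
#' @param model a [diffusion_model()].
#' @param n_steps number of steps.
#' @param dt step size (s).
#' @param x0 starting position (m).
#' @return numeric vector of `n_steps + 1` positions including `x0`.
#' @export
simulate_free_path <- function(model, n_steps, dt, x0 = 0) {
  stopifnot(inherits(model, "smr_diffusion"), n_steps >= 1, dt > 0)
  inc <- model$v * dt + sqrt(2 * model$D * dt) * stats::rnorm(n_steps)
  c(x0, x0 + cumsum(inc))
}

#' Closed-loop single-molecule recycling experiment
#'
#' End-to-end simulation of the SMR experiment: a molecule diffuses along
#' the capillary (capillary frame) while the piezo stage translates the
#' capillary through the fixed laser focus.  Photons are emitted from the
#' molecule's instantaneous offset to the focus; the streaming
#' weighted-sliding-sum burst detector and the recycling feedback controller
#' run on the simulated 10 us count stream exactly as they would on recorded
#' data, and the full ground truth is returned for validation.
#'
#' Frames: `x_mol` is the molecule position in the capillary frame; the
#' stage scan coordinate `s(t)` is the capillary-frame position currently at
#' the focus, so the molecule's offset from the focus is `x_mol - s(t)` and a
#' burst occurs when the scan crosses the molecule.
#'
#' Each cycle lasts exactly `delta_t`.  At `tp(i)` the stage translates from
#' `X(i) - dir*Xt` through the centre `X(i)` to `X(i) + dir*Xt` at `v_trans`;
#' after the outbound translation plus the actuation delay the centre update
#' is applied (frozen if no burst was detected in time) and the stage
#' repositions to the next launch point during the dwell, reversing direction
#' at `tp(i)+delta_t`.  Destinations beyond the travel limits are clamped and
#' flagged.
#'
#' @param diffusion a [diffusion_model()].
#' @param beam a [beam_model()].
#' @param stage a [stage_model()].
#' @param control a [recycling_config()].
#' @param kernel a [wss_kernel()], or `NULL` for the matched default
#'   (`sigma_t = w0 / (2 v_trans)`, threshold 8x the background WSS level).
#' @param duration run length (s); the number of cycles is
#'   `floor(duration / delta_t)`.
#' @param x0 initial molecule position (m, capillary frame).
#' @param X0 initial controller centre (piezo units); the default (molecule
#'   at the focus with a matching centre) corresponds to starting the loop
#'   right after a first detected burst.
#' @param bleach_photons mean number of emitted molecular photons before
#'   photobleaching (exponential photon budget, i.e. a constant bleaching
#'   hazard per excitation).  Default `Inf` (no bleaching).
#' @param intruder_rate Poisson rate (1/s) at which additional independent
#'   molecules wander into the recycling region.  Default 0 (off).
#' @param store_truth keep the per-bin ground truth (adds memory; does not
#'   change the random number stream).
#' @return An object of class `smr_run`: list with `cycles` (an
#'   `smr_cycles` data frame: `i`, `tp`, `tw`, `X`, `direction`, `missed`,
#'   `clamped`, `n_extra` extra in-window events such as intruders,
#'   `rebound` fallback-bound records, `wss_peak`), `photons` ([smr_photons()]),
#'   `events` (all detected bursts), `truth` (data frame `time`, `x_mol`,
#'   `x_stage` or `NULL`), `kernel`, `bleach_time`, and the configuration.
#' @export
run_experiment <- function(diffusion, beam, stage, control = recycling_config(),
                           kernel = NULL, duration = 6, x0 = 0, X0 = NULL,
                           bleach_photons = Inf, intruder_rate = 0,
                           store_truth = TRUE) {
  stopifnot(inherits(diffusion, "smr_diffusion"), inherits(beam, "smr_beam"),
            inherits(stage, "smr_stage"), inherits(control, "smr_recycling"),
            duration > 0)
  if (is.null(kernel))
    kernel <- wss_kernel(sigma_t = beam$w0 / (2 * stage$v_trans))
  if (is.null(kernel$threshold))
    kernel$threshold <- default_threshold(kernel, beam$B)
  dtw <- kernel$dtw
  dt <- dtw                      # integration step = sampling interval
  us <- stage$unit_scale
  bins_cyc <- round(control$delta_t / dtw)
  if (abs(bins_cyc * dtw - control$delta_t) > 1e-9)
    stop("delta_t must be an integer multiple of the sampling interval dtw")
  n_cyc <- floor(duration / control$delta_t + 1e-9)
  if (n_cyc < 1) stop("duration shorter than one reversal delay")
  total <- n_cyc * bins_cyc

  st <- ctrl_init(control, stage, if (is.null(X0)) x0 / us else X0)
  nA <- min(bins_cyc, as.integer(ceiling(st$dec_off / dtw)))
  nB <- bins_cyc - nA
  delay_bins <- as.integer(round(stage$actuation_delay / dtw))
  half <- kernel$half
  wts <- kernel$weights

  counts_all <- numeric(total)
  x_all <- if (store_truth) numeric(total) else NULL
  s_all <- if (store_truth) numeric(total) else NULL
  ticks_list <- vector("list", 2L * n_cyc)
  tick_n <- 0L
  stream <- wss_stream_new(kernel$threshold, dtw, t0 = 0)
  final_ptr <- 0L

  x_cur <- x0
  bleached <- FALSE
  bleach_time <- NA_real_
  bleach_acc <- 0
  E_th <- if (is.finite(bleach_photons)) stats::rexp(1) * bleach_photons else Inf
  intruders <- numeric(0)
  spawn_bins <- integer(0)
  if (intruder_rate > 0) {
    n_sp <- stats::rpois(1, intruder_rate * total * dt)
    if (n_sp > 0)
      spawn_bins <- sort(sample.int(total, min(n_sp, total)))
  }

  # advance one phase: stage scan coordinates s_m (metres) for nb bins
  # starting at global 0-based bin `bin0`; returns nothing, mutates state.
  sim_phase <- function(s_m, bin0) {
    nb <- length(s_m)
    if (diffusion$D > 0) {
      inc <- diffusion$v * dt + sqrt(2 * diffusion$D * dt) * stats::rnorm(nb)
    } else {
      inc <- rep(diffusion$v * dt, nb)
    }
    x_start <- x_cur + c(0, cumsum(inc[-nb]))
    x_cur <<- x_cur + sum(inc)
    mol_rate <- beam$F * exp(-2 * (x_start - s_m)^2 / beam$w0^2)
    if (bleached) {
      mol_rate[] <- 0
    } else if (is.finite(E_th)) {
      cum <- bleach_acc + cumsum(mol_rate * dt)
      bi <- match(TRUE, cum >= E_th)
      if (!is.na(bi)) {
        mol_rate[bi:nb] <- 0
        bleached <<- TRUE
        bleach_time <<- (bin0 + bi - 1) * dtw
      }
      bleach_acc <<- cum[nb]
    }
    rate <- mol_rate + beam$B
    if (length(intruders)) {
      for (k in seq_along(intruders)) {
        inck <- sqrt(2 * diffusion$D * dt) * stats::rnorm(nb)
        xs <- intruders[k] + c(0, cumsum(inck[-nb]))
        intruders[k] <<- intruders[k] + sum(inck)
        rate <- rate + beam$F * exp(-2 * (xs - s_m)^2 / beam$w0^2)
      }
    }
    sp <- spawn_bins[spawn_bins > bin0 & spawn_bins <= bin0 + nb]
    if (length(sp)) {
      for (b in sp)
        intruders <<- c(intruders,
                        s_m[b - bin0] + stats::runif(1, -5e-6, 5e-6))
    }
    counts <- stats::rpois(nb, rate * dt)
    counts_all[(bin0 + 1L):(bin0 + nb)] <<- counts
    tick_n <<- tick_n + 1L
    ticks_list[[tick_n]] <<- photon_ticks(counts, dt, t0 = bin0 * dtw)
    if (store_truth) {
      x_all[(bin0 + 1L):(bin0 + nb)] <<- x_start
      s_all[(bin0 + 1L):(bin0 + nb)] <<- s_m
    }
    # finalise WSS values whose full kernel support is now available
    M <- bin0 + nb
    f2 <- M - half
    if (f2 > final_ptr) {
      f1 <- final_ptr + 1L
      lo <- f1 - half
      seg <- if (lo >= 1L) counts_all[lo:M] else
        c(numeric(1L - lo), counts_all[1:M])
      vals <- wss_core(seg, wts, half)
      stream <<- wss_stream_feed(stream, vals[(f1 - lo + 1L):(f2 - lo + 1L)])
      final_ptr <<- f2
    }
    invisible(NULL)
  }

  v <- stage$v_trans
  rec_X <- numeric(n_cyc); rec_dir <- numeric(n_cyc)
  rec_clamped <- logical(n_cyc)
  for (i in seq_len(n_cyc)) {
    tp_bin <- (i - 1L) * bins_cyc
    tp <- tp_bin * dtw
    geo <- ctrl_geometry(st)
    rec_X[i] <- st$X; rec_dir[i] <- st$dir; rec_clamped[i] <- geo$clamped
    launch_m <- geo$launch * us
    end_m <- geo$endpt * us
    sgn <- if (end_m == launch_m) st$dir else sign(end_m - launch_m)
    tA <- (0:(nA - 1L)) * dtw
    sA <- launch_m + sgn * pmin(v * tA, abs(end_m - launch_m))
    sim_phase(sA, tp_bin)
    # control decision late in the cycle, before the reposition move
    dt_transit <- NA_real_
    for (ev in stream$events) {
      tpk <- (ev[3] - 1L) * dtw
      if (tpk >= tp) {
        if (tpk <= tp + st$dec_off) dt_transit <- tpk - tp
        break
      }
    }
    st <- ctrl_decide(st, dt_transit)
    if (nB > 0L) {
      nxt <- ctrl_geometry(st)
      next_launch_m <- nxt$launch * us
      sgn2 <- if (next_launch_m == end_m) 1 else sign(next_launch_m - end_m)
      tB <- pmax((0:(nB - 1L)) - delay_bins, 0L) * dtw
      sB <- end_m + sgn2 * pmin(v * tB, abs(next_launch_m - end_m))
      sim_phase(sB, tp_bin + nA)
    }
  }
  stream <- wss_stream_end(stream)
  events <- wss_stream_events(stream, n_total = total)

  # post-hoc binding of burst events to cycles (shared with run_controller)
  tps <- (seq_len(n_cyc) - 1L) * control$delta_t
  bb <- bind_bursts(as.data.frame(events), tps, control$delta_t)
  cycles <- data.frame(i = seq_len(n_cyc), tp = tps, tw = bb$tw, X = rec_X,
                       direction = rec_dir, missed = is.na(bb$tw),
                       clamped = rec_clamped, n_extra = bb$n_extra,
                       rebound = bb$rebound, wss_peak = bb$wss_peak)
  class(cycles) <- c("smr_cycles", "data.frame")

  photons <- smr_photons(unlist(ticks_list[seq_len(tick_n)]),
                         counts_all, bin_width = dtw, t0 = 0)
  truth <- if (store_truth) {
    data.frame(time = (0:(total - 1L)) * dtw, x_mol = x_all, x_stage = s_all)
  } else NULL

  structure(list(cycles = cycles, photons = photons, events = events,
                 truth = truth, kernel = kernel,
                 bleach_time = bleach_time,
                 config = list(diffusion = diffusion, beam = beam,
                               stage = stage, control = control,
                               duration = duration, x0 = x0, X0 = X0,
                               bleach_photons = bleach_photons,
                               intruder_rate = intruder_rate)),
            class = "smr_run")
}

#' @export
print.smr_run <- function(x, ...) {
  n <- nrow(x$cycles)
  cat(sprintf(
    "<smr_run> %d cycles (%d detected, %d missed), %d photons%s\n",
    n, sum(!x$cycles$missed), sum(x$cycles$missed), length(x$photons$ticks),
    if (is.na(x$bleach_time)) "" else
      sprintf(", bleached at %.3f s", x$bleach_time)))
  invisible(x)
}

#' Simulate recycling of an immobilized bead
#'
#' A fluorescent bead fixed in the stage frame is translated back and forth
#' through the focus at `v_trans`, one pass per reversal delay, as in the
#' speed-calibration experiment.  Each constant-velocity pass produces a
#' temporally Gaussian count-rate profile of width
#' `sigma_t = w0 / (2 v_trans)`; the autocorrelation of the resulting photon
#' stream shows recycle peaks at multiples of `delta_t`.
#'
#' @param beam a [beam_model()].
#' @param stage a [stage_model()].
#' @param passes number of passes through the focus (>= 1).
#' @param delta_t reversal delay between passes (s), default 30 ms.
#' @param Xt launch offset from the bead (m), default 4.58 um.
#' @param dtw photon bin width (s), default 10 us.
#' @return an [smr_photons()] object.
#' @export
simulate_immobilized_bead <- function(beam, stage, passes, delta_t = 0.03,
                                      Xt = 4.58e-6, dtw = 1e-5) {
  stopifnot(passes >= 1, delta_t > 0, Xt > 0)
  nb <- round(delta_t / dtw)
  if (2 * Xt / stage$v_trans >= delta_t)
    stop("delta_t too short for the translation over 2*Xt")
  trel <- (0:(nb - 1L)) * dtw
  s <- vector("list", passes)
  for (p in seq_len(passes)) {
    d <- if (p %% 2L == 1L) 1 else -1
    s[[p]] <- -d * Xt + d * pmin(stage$v_trans * trel, 2 * Xt)
  }
  offsets <- 0 - unlist(s)   # bead at stage-frame origin
  emit_photons(offsets, beam, dt = dtw, t0 = 0)
}
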