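#' Recycling feedback configuration
#'
#' Parameters of the feedback loop that recycles the molecule: after each
#' detected burst the estimated molecule position (the "centre" of
#' recycling, in piezo units) is updated from the transit-time innovation,
#' and the stage is scheduled so that one translation through the centre
#' happens every reversal delay `delta_t`, in alternating directions, even
#' when the expected burst is missed.
#'
#' @param delta_t reversal delay (s): fixed cycle period.  Default 30 ms,
#'   the value that maximises the number of recycles.
#' @param Xt prescheduled launch offset from the centre (piezo units).
#'   Default 10,000 units = 4.58 um.
#' @param C feedback scale factor (piezo units per millisecond of
#'   transit-time innovation).  `NULL` (default) resolves, at run time, to
#'   the translation speed expressed in units/ms
#'   (`v_trans * 1e-3 / unit_scale`), which converts a transit-time
#'   innovation exactly into the molecule's displacement along the scan.
#'   The controller applies `C` with the sign of the current scan
#'   direction (a late transit means the molecule lies further along the
#'   direction of motion).
#' @param m_window number of most recent detected cycles over which the
#'   running mean transit time `m` is maintained.  Default 20.
#' @param miss_timeout extra wait beyond `delta_t` before a cycle is
#'   declared missed; the reversal itself is never delayed.  Default equal
#'   to `delta_t`.
#' @return An object of class `smr_recycling`.
#' @export
recycling_config <- function(delta_t = 0.03, Xt = 10000, C = NULL,
                             m_window = 20, miss_timeout = NULL) {
  stopifnot(delta_t > 0, Xt > 0, m_window >= 1)
  if (!is.null(C)) stopifnot(is.numeric(C), length(C) == 1L, is.finite(C))
  if (is.null(miss_timeout)) miss_timeout <- delta_t
  stopifnot(miss_timeout >= 0)
  structure(list(delta_t = delta_t, Xt = Xt, C = C,
                 m_window = as.integer(m_window), miss_timeout = miss_timeout),
            class = "smr_recycling")
}

#' @export
print.smr_recycling <- function(x, ...) {
  cat(sprintf(
    "<smr_recycling> delta_t = %g s, Xt = %g units, C = %s units/ms, m_window = %d\n",
    x$delta_t, x$Xt, if (is.null(x$C)) "auto" else format(x$C), x$m_window))
  invisible(x)
}

#' Update the recycling centre from a transit-time innovation
#'
#' Implements the proportional feedback update
#' \deqn{X(i+1) = ((t_w(i) - t_p(i)) - m) \times C + X(i),}
#' where `m` is the running-mean transit time and `C` converts milliseconds
#' of innovation into piezo units.  When the observed transit time equals
#' `m` the centre is unchanged.  A missing burst (`tw = NA`) leaves the
#' centre frozen.
#'
#' @param X current centre (piezo units).
#' @param tw burst peak time (s), or `NA` for a missed cycle.
#' @param tp translation start time (s); requires `tw >= tp`.
#' @param m running-mean transit time (s).
#' @param C scale factor (piezo units per millisecond), signed by the
#'   caller with the scan direction when used inside the control loop.
#' @return updated centre (piezo units).
#' @export
update_center <- function(X, tw, tp, m, C) {
  if (is.na(tw)) return(X)
  if (tw < tp) stop("update_center(): tw must be >= tp")
  X + ((tw - tp) - m) * 1e3 * C
}

# Resolve the automatic scale factor (units/ms).
resolve_C <- function(control, stage) {
  if (!is.null(control$C)) control$C
  else stage$v_trans * 1e-3 / stage$unit_scale
}

clamp_units <- function(x, limits) pmin(pmax(x, limits[1]), limits[2])

# Shared controller state machine.  Both the closed-loop simulator and the
# offline replay (run_controller) drive cycles through these helpers so
# that, given the same burst stream, they produce identical records.

ctrl_init <- function(control, stage, X0 = 0) {
  Xt_m <- control$Xt * stage$unit_scale
  trans_time <- 2 * Xt_m / stage$v_trans
  if (control$delta_t <= trans_time + stage$actuation_delay)
    stop(sprintf(
      "delta_t = %g s too short: translation over 2*Xt takes %g s (+ %g s actuation delay)",
      control$delta_t, trans_time, stage$actuation_delay))
  # The centre update must be decided before the stage repositions to the
  # next launch point; repositioning takes at most Xt/v_trans (the
  # correction is capped accordingly), so the decision can wait until late
  # in the cycle.  This lets detections during the dwell -- the molecule
  # drifting into the parked focus -- recentre the loop instead of being
  # discarded.
  dec_off <- max(trans_time,
                 control$delta_t - stage$actuation_delay - trans_time / 2)
  max_corr <- stage$v_trans *
    max(0, control$delta_t - dec_off - stage$actuation_delay) /
    stage$unit_scale                  # piezo units
  list(control = control, stage = stage,
       C = resolve_C(control, stage),
       X = X0,                        # current centre, piezo units
       dir = 1,                       # scan direction of the next cycle
       m = Xt_m / stage$v_trans,      # running-mean transit time (s)
       m_hist = numeric(0),
       trans_time = trans_time, dec_off = dec_off, max_corr = max_corr)
}

# One control decision: given the bound transit time (tw - tp in seconds,
# or NA when missed), update centre and running mean.  Returns the state.
# Transit times beyond the translation window are clamped to it: the scan
# stopped at the far endpoint, so a later burst locates the molecule there.
ctrl_decide <- function(st, dt_transit) {
  if (!is.na(dt_transit)) {
    dt_eff <- min(dt_transit, st$trans_time)
    Xnew <- update_center(st$X, dt_eff, 0, st$m, st$dir * st$C)
    corr <- max(-st$max_corr, min(st$max_corr, Xnew - st$X))
    st$X <- st$X + corr
    if (dt_transit <= st$trans_time) {   # genuine translation transit
      st$m_hist <- c(st$m_hist, dt_transit)
      nh <- length(st$m_hist)
      if (nh > st$control$m_window)
        st$m_hist <- st$m_hist[(nh - st$control$m_window + 1L):nh]
      st$m <- mean(st$m_hist)
    }
  }
  st$dir <- -st$dir
  st
}

# Bind detected burst events to cycles.  Primary rule: the first event with
# t_peak in [tp(i), tp(i) + delta_t) belongs to cycle i; later events in the
# window are counted as extras (e.g. intruders).  Fallback: a cycle with no
# event of its own claims the last *extra* event of the previous window --
# a molecule parked near the launch point fires during the preceding dwell,
# so its peak lands just before tp(i); the reconstruction censors such
# transit times to the scan window.  Fallback-bound cycles are flagged
# `rebound` and never used for control decisions.
bind_bursts <- function(events, tps, delta_t) {
  n <- length(tps)
  tw <- rep(NA_real_, n)
  wpk <- rep(NA_real_, n)
  n_extra <- integer(n)
  rebound <- logical(n)
  if (nrow(events)) {
    if (is.null(events$wss_peak)) events$wss_peak <- NA_real_
    ord <- order(events$t_peak)
    events <- events[ord, , drop = FALSE]
    cyc <- findInterval(events$t_peak, tps)
    for (i in seq_len(n)) {
      w <- which(cyc == i & events$t_peak < tps[i] + delta_t)
      if (length(w)) {
        tw[i] <- events$t_peak[w[1]]
        wpk[i] <- events$wss_peak[w[1]]
        n_extra[i] <- length(w) - 1L
      }
    }
    if (n > 1) for (i in 2:n) {
      if (!is.na(tw[i])) next
      w <- which(cyc == i - 1L)
      if (length(w) >= 2L) {
        k <- w[length(w)]
        tw[i] <- events$t_peak[k]
        wpk[i] <- events$wss_peak[k]
        rebound[i] <- TRUE
        n_extra[i - 1L] <- n_extra[i - 1L] - 1L
      }
    }
  }
  list(tw = tw, wss_peak = wpk, n_extra = n_extra, rebound = rebound)
}

# Geometry of cycle i before its decision: launch and far endpoint in piezo
# units, clamped to the travel limits.
ctrl_geometry <- function(st) {
  lim <- st$stage$travel_limits
  launch <- clamp_units(st$X - st$dir * st$control$Xt, lim)
  endpt <- clamp_units(st$X + st$dir * st$control$Xt, lim)
  clamped <- (st$X - st$dir * st$control$Xt != launch) ||
    (st$X + st$dir * st$control$Xt != endpt)
  list(launch = launch, endpt = endpt, clamped = clamped)
}

#' Replay the recycling feedback loop over a recorded burst stream
#'
#' Runs the same controller logic the closed-loop simulator uses, but driven
#' by an already-detected list of burst events (e.g. from [detect_bursts()]
#' applied to recorded counts).  Each cycle lasts exactly `delta_t`: the
#' stage translates from `X(i) - dir*Xt` through the centre to
#' `X(i) + dir*Xt` at `v_trans`, dwells, repositions to the next launch
#' point once the centre update is known, and reverses.  The first burst
#' with `t_peak` in `[tp(i), tp(i)+delta_t)` is bound to cycle `i`; a cycle
#' with no burst is marked missed and its centre frozen.  Bursts must be
#' available by the end of the outbound translation (plus the actuation
#' delay) to influence the centre; later bursts are still recorded.
#'
#' @param bursts an `smr_bursts` data frame (or any data frame with a
#'   `t_peak` column), in time order.
#' @param control a [recycling_config()].
#' @param stage a [stage_model()].
#' @param t_end end of the run (s); the number of cycles is
#'   `floor(t_end / delta_t)`.
#' @param X0 initial centre (piezo units), default 0.
#' @param kernel optional [wss_kernel()]: when given, the replay restricts
#'   each control decision to events whose WSS run had *completed and been
#'   finalised* by the decision point, exactly as the streaming detector
#'   inside [run_experiment()] does (the filter introduces a fixed latency
#'   of half a kernel plus one bin).  With the default `NULL`, any event
#'   peaking before the decision point is usable.
#' @return list with `cycles` (an `smr_cycles` data frame: `i`, `tp`, `tw`,
#'   `X`, `direction`, `missed`, `clamped`, `n_extra`) and `trajectory`
#'   (data frame of constant-velocity/dwell segments: `t0`, `t1`, `from`,
#'   `to` in piezo units).
#' @export
run_controller <- function(bursts, control, stage, t_end, X0 = 0,
                           kernel = NULL) {
  stopifnot(inherits(control, "smr_recycling"), inherits(stage, "smr_stage"))
  ord <- order(bursts$t_peak)
  tpk <- as.numeric(bursts$t_peak)[ord]
  run_end <- if (!is.null(bursts$run_end)) as.numeric(bursts$run_end)[ord]
  else tpk
  n_cyc <- floor(t_end / control$delta_t + 1e-9)
  if (n_cyc < 1) stop("t_end shorter than one reversal delay")
  st <- ctrl_init(control, stage, X0)
  us <- stage$unit_scale
  dec_off <- st$dec_off
  segs <- vector("list", n_cyc)
  pos <- NULL  # current stage position (units); set at first cycle launch
  rec_X <- numeric(n_cyc); rec_dir <- numeric(n_cyc)
  rec_clamped <- logical(n_cyc)
  for (i in seq_len(n_cyc)) {
    tp <- (i - 1) * control$delta_t
    geo <- ctrl_geometry(st)
    if (is.null(pos)) pos <- geo$launch
    in_window <- which(tpk >= tp & tpk < tp + control$delta_t)
    tw <- if (length(in_window)) tpk[in_window[1]] else NA_real_
    usable <- !is.na(tw) && tw <= tp + dec_off
    if (usable && !is.null(kernel)) {
      # streaming information set: the run must have closed early enough
      # for the finalised WSS to include the bin after its end
      dec_bin_t <- ceiling(dec_off / kernel$dtw) * kernel$dtw
      known_by <- tp + dec_bin_t - (kernel$half + 2L) * kernel$dtw
      usable <- run_end[in_window[1]] <= known_by + 1e-12
    }
    rec_X[i] <- st$X; rec_dir[i] <- st$dir; rec_clamped[i] <- geo$clamped
    st <- ctrl_decide(st, if (usable) tw - tp else NA_real_)
    # trajectory: translation, dwell, reposition (if needed), dwell
    tr_dist <- abs(geo$endpt - pos) * us
    t_tr <- tr_dist / stage$v_trans
    nxt <- ctrl_geometry(st)   # launch of cycle i+1 under updated centre
    t_rep0 <- tp + dec_off + stage$actuation_delay
    rep_dist <- abs(nxt$launch - geo$endpt) * us
    t_rep <- rep_dist / stage$v_trans
    segs[[i]] <- data.frame(
      t0 = c(tp, tp + t_tr, t_rep0, t_rep0 + t_rep),
      t1 = c(tp + t_tr, t_rep0, t_rep0 + t_rep, tp + control$delta_t),
      from = c(pos, geo$endpt, geo$endpt, nxt$launch),
      to = c(geo$endpt, geo$endpt, nxt$launch, nxt$launch))
    pos <- nxt$launch
  }
  tps <- (seq_len(n_cyc) - 1) * control$delta_t
  bb <- bind_bursts(as.data.frame(bursts), tps, control$delta_t)
  cycles <- data.frame(i = seq_len(n_cyc), tp = tps, tw = bb$tw,
                       X = rec_X, direction = rec_dir,
                       missed = is.na(bb$tw), clamped = rec_clamped,
                       n_extra = bb$n_extra, rebound = bb$rebound,
                       wss_peak = bb$wss_peak)
  class(cycles) <- c("smr_cycles", "data.frame")
  traj <- do.call(rbind, segs)
  traj <- traj[traj$t1 > traj$t0, ]
  rownames(traj) <- NULL
  list(cycles = cycles, trajectory = traj)
}
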