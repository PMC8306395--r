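#' Default run configuration
#'
#' Nested list of all tunable parameters with the experiment's defaults:
#' reversal delay 30 ms, launch offset 10,000 piezo units (4.58 um),
#' weight amplitude 128, sampling interval 10 us, beam waist 1 um.
#'
#' @return nested named list with sections `diffusion`, `beam`, `stage`,
#'   `control`, `kernel`, `estimator`, `run`.
#' @export
smr_config <- function() {
  list(
    diffusion = list(D = 5e-11, v = 0),
    beam = list(w0 = 1e-6, F = 1e5, B = 1e3),
    stage = list(unit_scale = 4.58e-6 / 1e4, v_trans = 2e-3,
                 travel_limits = c(-218340, 218340),
                 actuation_delay = 1e-3),
    control = list(delta_t = 0.03, Xt = 10000, C = NULL,
                   m_window = 20, miss_timeout = NULL),
    kernel = list(sigma_t = NULL, dtw = 1e-5, A = 128, span = 3,
                  threshold = NULL),
    estimator = list(v_used = 2e-3, T = NULL, filter = TRUE,
                     use_measured_intervals = FALSE, hist_bin = 1e-4),
    run = list(duration = 6, x0 = 0, bleach_photons = Inf,
               intruder_rate = 0, store_truth = FALSE)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop(sprintf("unknown configuration key: '%s'", full))
    if (is.null(user[[nm]])) next   # explicit null keeps the default
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file whose sections mirror [smr_config()]; missing fields
#' are filled with the defaults, unknown keys are rejected, and every
#' section is validated by constructing its model object (errors name the
#' offending section).  An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML file.
#' @return validated configuration list (classed `smr_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config file must contain a YAML mapping")
  cfg <- merge_config(smr_config(), user)
  validate_config(cfg)
  structure(cfg, class = c("smr_config", class(cfg)))
}

#' Save a configuration as YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  config_models(cfg)
  invisible(TRUE)
}

#' Build model objects from a configuration list
#'
#' @param cfg configuration list as from [smr_config()] or [load_config()].
#' @return list with `diffusion`, `beam`, `stage`, `control`, `kernel`
#'   model objects plus the `estimator` and `run` sections.
#' @export
config_models <- function(cfg) {
  section <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("invalid '%s' configuration: %s", what,
                   conditionMessage(e)), call. = FALSE))
  }
  diffusion <- section("diffusion",
                       diffusion_model(cfg$diffusion$D, cfg$diffusion$v))
  beam <- section("beam",
                  beam_model(cfg$beam$w0, cfg$beam$F, cfg$beam$B))
  stage <- section("stage",
                   stage_model(cfg$stage$unit_scale, cfg$stage$v_trans,
                               cfg$stage$travel_limits,
                               cfg$stage$actuation_delay))
  control <- section("control",
                     recycling_config(cfg$control$delta_t, cfg$control$Xt,
                                      cfg$control$C, cfg$control$m_window,
                                      cfg$control$miss_timeout))
  sigma_t <- if (is.null(cfg$kernel$sigma_t))
    beam$w0 / (2 * stage$v_trans) else cfg$kernel$sigma_t
  kernel <- section("kernel",
                    wss_kernel(sigma_t, cfg$kernel$dtw, cfg$kernel$A,
                               cfg$kernel$span, cfg$kernel$threshold))
  run <- cfg$run
  if (is.null(run$bleach_photons)) run$bleach_photons <- Inf
  estimator <- cfg$estimator
  if (is.null(estimator$T)) estimator$T <- control$delta_t
  list(diffusion = diffusion, beam = beam, stage = stage,
       control = control, kernel = kernel, estimator = estimator,
       run = run)
}

# ---- photon and table files ------------------------------------------------

#' Write/read photon data (JSON container)
#'
#' A single plain-text JSON file holding the 10 ns tick values, the binned
#' counts, and the binning metadata; round-trips losslessly (ticks are
#' integers well below 2^53).
#'
#' @param photons an [smr_photons()] object.
#' @param path output path.
#' @return `path` (write) or an [smr_photons()] object (read).
#' @export
write_photons <- function(photons, path) {
  stopifnot(inherits(photons, "smr_photons"))
  jsonlite::write_json(
    list(bin_width = photons$bin_width, t0 = photons$t0,
         tick_unit = photons$tick_unit,
         ticks = photons$ticks, bin_counts = photons$bin_counts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_photons
#' @export
read_photons <- function(path) {
  if (!file.exists(path)) stop("photon file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  smr_photons(if (is.null(x$ticks)) numeric(0) else x$ticks,
              if (is.null(x$bin_counts)) numeric(0) else x$bin_counts,
              bin_width = x$bin_width, t0 = x$t0, tick_unit = x$tick_unit)
}

#' Write/read binned counts as CSV
#'
#' Two columns: `t_s` (bin start time) and `count`.
#'
#' @param photons an [smr_photons()] object (write) or a path (read).
#' @param path output path.
#' @return `path` (write) or an [smr_photons()] object without ticks (read).
#' @export
write_counts_csv <- function(photons, path) {
  stopifnot(inherits(photons, "smr_photons"))
  n <- length(photons$bin_counts)
  df <- data.frame(
    t_s = fmt_num(photons$t0 + (seq_len(n) - 1) * photons$bin_width),
    count = photons$bin_counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @param bin_width bin width (s); inferred from the time column if `NULL`.
#' @export
read_counts_csv <- function(path, bin_width = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("t_s", "count") %in% names(df)))
    stop("counts CSV must have columns t_s, count")
  bw <- if (is.null(bin_width)) {
    if (nrow(df) < 2) stop("cannot infer bin width from a single row")
    stats::median(diff(df$t_s))
  } else bin_width
  smr_photons(numeric(0), df$count, bin_width = bw, t0 = df$t_s[1])
}

# full-precision decimal formatting so CSV round-trips are exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write/read cycle records as CSV
#'
#' Columns `i`, `tp_s`, `tw_s` (empty for missed cycles), `X_units`,
#' `direction`, `missed`, plus `clamped` and `n_extra` when present.
#' Numeric values are written with 17 significant digits, so a round-trip
#' is exact.
#'
#' @param cycles an `smr_cycles` data frame.
#' @param path output path.
#' @return `path` (write) or an `smr_cycles` data frame (read).
#' @export
write_cycles <- function(cycles, path) {
  stopifnot(is.data.frame(cycles))
  df <- data.frame(i = cycles$i,
                   tp_s = fmt_num(cycles$tp),
                   tw_s = fmt_num(cycles$tw),
                   X_units = fmt_num(cycles$X),
                   direction = cycles$direction,
                   missed = cycles$missed)
  if (!is.null(cycles$clamped)) df$clamped <- cycles$clamped
  if (!is.null(cycles$n_extra)) df$n_extra <- cycles$n_extra
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  if (!file.exists(path)) stop("cycle file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("i", "tp_s", "tw_s", "X_units", "direction", "missed")
  if (!all(need %in% names(df)))
    stop("cycle CSV must have columns: ", paste(need, collapse = ", "))
  num <- function(col, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !(allow_na & (is.na(df[[col]]) | df[[col]] == "NA"))
    if (any(bad))
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   col, which(bad)[1], path))
    v
  }
  out <- data.frame(i = as.integer(num("i")), tp = num("tp_s"),
                    tw = num("tw_s", allow_na = TRUE),
                    X = num("X_units"), direction = num("direction"),
                    missed = as.logical(df$missed))
  out$missed <- out$missed | is.na(out$tw)
  if (!is.null(df$clamped)) out$clamped <- as.logical(df$clamped)
  if (!is.null(df$n_extra)) out$n_extra <- as.integer(df$n_extra)
  class(out) <- c("smr_cycles", "data.frame")
  out
}

#' Write/read burst events as CSV
#'
#' Columns `t_peak_s`, `wss_peak`, `run_start_s`, `run_end_s`, `edge`.
#'
#' @param bursts an `smr_bursts` data frame.
#' @param path output path.
#' @return `path` (write) or an `smr_bursts` data frame (read).
#' @export
write_bursts <- function(bursts, path) {
  df <- data.frame(t_peak_s = fmt_num(bursts$t_peak),
                   wss_peak = fmt_num(bursts$wss_peak),
                   run_start_s = fmt_num(bursts$run_start),
                   run_end_s = fmt_num(bursts$run_end),
                   edge = bursts$edge)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  if (!file.exists(path)) stop("burst file not found: ", path)
  df <- utils::read.csv(path)
  out <- data.frame(t_peak = as.numeric(df$t_peak_s),
                    wss_peak = as.numeric(df$wss_peak),
                    run_start = as.numeric(df$run_start_s),
                    run_end = as.numeric(df$run_end_s),
                    edge = as.logical(df$edge))
  class(out) <- c("smr_bursts", "data.frame")
  out
}
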