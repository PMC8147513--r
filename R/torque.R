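#' Construct a torque trace from one manipulandum trial
#'
#' A torque trace is the digitized resistive torque recorded while the
#' manipulandum imposes passive sinusoidal pronation/supination on the
#' forearm. Time must lie on a uniform grid; the sampling rate is taken from
#' the grid when not supplied.
#'
#' @param torque numeric vector, torque in N·m.
#' @param fs sampling rate in Hz (nominal 1000). Ignored when `t` is given.
#' @param t optional time vector in seconds; must be strictly increasing and
#'   uniformly spaced to within 1e-9 s.
#' @param meta optional named list of trial annotations (stimulation
#'   frequency, participant id, visit, ...).
#' @return an object of class `torque_trace` with fields `t`, `torque`,
#'   `fs` and `meta`.
#' @export
torque_trace <- function(torque, fs = 1000, t = NULL, meta = list()) {
  torque <- as.numeric(torque)
  if (length(torque) < 2L)
    invalid_parameter("a torque trace needs at least 2 samples")
  if (is.null(t)) {
    if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
      invalid_parameter("`fs` must be a positive sampling rate in Hz")
    t <- (seq_along(torque) - 1) / fs
  } else {
    t <- as.numeric(t)
    if (length(t) != length(torque))
      invalid_parameter("`t` and `torque` must have the same length")
    dt <- diff(t)
    if (any(dt <= 0))
      invalid_parameter("`t` must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9)
      invalid_parameter("`t` must be uniformly spaced (within 1e-9 s)")
    fs <- 1 / mean(dt)
  }
  structure(list(t = t, torque = torque, fs = fs, meta = meta),
            class = "torque_trace")
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("<torque_trace> %d samples, fs = %g Hz, duration = %.3f s\n",
              length(x$torque), x$fs, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Low-pass filter a torque trace
#'
#' Applies a digital Butterworth low-pass filter to the torque channel,
#' mirroring the front end of the rigidity pipeline (2 poles, 20 Hz cutoff
#' at 1 kHz sampling). Filtering is causal (forward-only) by default, as in
#' real-time use; set `zero_phase = TRUE` for forward-backward filtering
#' when phase distortion matters more than causality.
#'
#' @param trace a [torque_trace()].
#' @param cutoff cutoff frequency in Hz. Must be below the Nyquist rate.
#' @param order filter order (number of poles).
#' @param zero_phase logical; use forward-backward (zero-phase) filtering.
#' @return a `torque_trace` of identical length and time base with the
#'   filtered torque.
#' @export
lowpass_filter <- function(trace, cutoff = 20, order = 2, zero_phase = FALSE) {
  stopifnot(inherits(trace, "torque_trace"))
  nyq <- trace$fs / 2
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    invalid_parameter("`cutoff` must be a positive frequency in Hz")
  if (cutoff >= nyq)
    invalid_parameter(sprintf(
      "cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)", cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  y <- if (zero_phase) {
    as.numeric(signal::filtfilt(bf, trace$torque))
  } else {
    as.numeric(signal::filter(bf, trace$torque))
  }
  out <- trace
  out$torque <- y
  out$meta$filtered <- list(cutoff_hz = cutoff, order = order,
                            zero_phase = zero_phase)
  out
}

#' Compute the RoMaR rigidity value of a torque trace
#'
#' The Robotic Manipulandum Rigidity (RoMaR) value summarizes one trial: the
#' filtered torque is rectified and integrated over time (trapezoidal rule)
#' to obtain the angular impulse, and RoMaR is the ordinary-least-squares
#' slope of that impulse versus time over the analysis window. For a
#' stationary signal this equals the mean rectified torque, so RoMaR carries
#' the units of torque (N·m·s per s).
#'
#' The first `warmup` seconds are discarded; the following `window` seconds
#' are analysed. Traces longer than `warmup + window` are truncated.
#'
#' @param trace a [torque_trace()], normally already low-pass filtered. Set
#'   `filter = TRUE` to apply [lowpass_filter()] with its defaults first.
#' @param warmup seconds discarded at the start of the trial.
#' @param window analysis window length in seconds.
#' @param filter logical; low-pass filter the trace before rectification.
#' @return an object of class `romar_value`: list with `value` (the slope),
#'   `window` (`c(t_start, t_end)`) and `fit_residual` (RMS of the linear
#'   fit to the impulse).
#' @export
compute_romar <- function(trace, warmup = 5, window = 20, filter = FALSE) {
  stopifnot(inherits(trace, "torque_trace"))
  if (warmup < 0 || window <= 0)
    invalid_parameter("`warmup` must be >= 0 and `window` > 0 seconds")
  if (filter) trace <- lowpass_filter(trace)
  t0 <- trace$t[1]
  keep <- trace$t - t0 >= warmup & trace$t - t0 <= warmup + window
  n <- sum(keep)
  if (n < 2L)
    insufficient_data(sprintf(
      "trace has %d samples in [%g, %g] s; need the full analysis window",
      n, warmup, warmup + window))
  # a nominal T-second trial sampled at fs covers [0, T - 1/fs]
  dur <- trace$t[length(trace$t)] - t0 + 1 / trace$fs
  if (dur + 1e-9 < warmup + window)
    insufficient_data(sprintf(
      "trace duration %.3f s is shorter than warmup + window = %g s",
      dur, warmup + window))
  tt <- trace$t[keep]
  x <- abs(trace$torque[keep])
  if (all(x == 0)) {
    warning("all-zero torque in analysis window; RoMaR = 0")
    return(structure(list(value = 0, window = c(warmup, warmup + window),
                          fit_residual = 0), class = "romar_value"))
  }
  # cumulative angular impulse by the trapezoidal rule
  dt <- diff(tt)
  impulse <- c(0, cumsum(dt * (x[-1] + x[-length(x)]) / 2))
  fit <- stats::lm.fit(cbind(1, tt - tt[1]), impulse)
  structure(list(
    value = unname(fit$coefficients[2]),
    window = c(warmup, warmup + window),
    fit_residual = sqrt(mean(fit$residuals^2))
  ), class = "romar_value")
}

#' @export
print.romar_value <- function(x, ...) {
  cat(sprintf("RoMaR = %.5g N·m (window %g–%g s, fit RMS %.3g)\n",
              x$value, x$window[1], x$window[2], x$fit_residual))
  invisible(x)
}

#' Read a torque trace from CSV
#'
#' Expects a header with columns `time_s` and `torque_nm`; any additional
#' columns are ignored.
#'
#' @param path path to the CSV file.
#' @param meta optional trial annotations attached to the trace.
#' @return a [torque_trace()].
#' @export
read_torque_csv <- function(path, meta = list()) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("time_s", "torque_nm")
  if (!all(need %in% names(df)))
    validation_error(sprintf("torque CSV must have columns %s",
                             paste(need, collapse = ", ")),
                     fields = setdiff(need, names(df)))
  torque_trace(df$torque_nm, t = df$time_s, meta = meta)
}

#' Write RoMaR results to CSV
#'
#' @param results data.frame with columns `frequency_hz`, `romar`,
#'   `fit_residual` (e.g. accumulated over trials).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_romar_csv <- function(results, path) {
  need <- c("frequency_hz", "romar", "fit_residual")
  if (!all(need %in% names(results)))
    validation_error(sprintf("results must have columns %s",
                             paste(need, collapse = ", ")))
  utils::write.csv(results[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
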