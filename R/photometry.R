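#' Fibre-photometry trace
#'
#' Two-channel fluorescence time series: the calcium-dependent 465 nm
#' channel and the calcium-independent 405 nm isosbestic control, with the
#' intervention time and a pre-event baseline window.
#'
#' @param time_s Sample times (seconds), strictly increasing.
#' @param F465,F405 Channel fluorescence; `F405` must be strictly positive.
#' @param event_time_s Intervention timestamp (seconds).
#' @param baseline_window Two-element window (seconds) preceding the event;
#'   default the full pre-event span.
#' @return A `photometry_trace`.
#' @export
photometry_trace <- function(time_s, F465, F405, event_time_s,
                             baseline_window = NULL) {
  stopifnot(length(time_s) == length(F465), length(time_s) == length(F405),
            length(time_s) >= 2L)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("sample times must be strictly increasing")
  baseline_window <- baseline_window %||% c(min(time_s), event_time_s)
  if (baseline_window[2] > event_time_s + 1e-9)
    stop("baseline window must precede the event")
  structure(list(time_s = as.numeric(time_s), F465 = as.numeric(F465),
                 F405 = as.numeric(F405),
                 event_time_s = as.numeric(event_time_s),
                 baseline_window = as.numeric(baseline_window)),
            class = "photometry_trace")
}

#' Isosbestic ratio signal
#'
#' The fluorescence signal is the ratio of the 465 nm channel to the 405 nm
#' isosbestic channel, `F(t) = F465(t) / F405(t)`; any artefact that
#' multiplies both channels cancels exactly.
#'
#' @param trace A [photometry_trace()].
#' @return Numeric signal vector.
#' @export
ratio_signal <- function(trace) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (any(trace$F405 <= 0))
    stop("isosbestic channel must be strictly positive")
  trace$F465 / trace$F405
}

#' Baseline F0
#'
#' `F0` is the median of the ratio signal within the pre-event baseline
#' window (R's `median`: the mean of the two middle values for an even
#' count). The median makes the baseline robust to transient spikes.
#'
#' @param signal Ratio signal (from [ratio_signal()]).
#' @param time_s Matching sample times.
#' @param window Two-element window (seconds).
#' @return Scalar `F0`.
#' @export
baseline_f0 <- function(signal, time_s, window) {
  stopifnot(length(signal) == length(time_s), length(window) == 2L)
  sel <- time_s >= window[1] & time_s <= window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  stats::median(signal[sel])
}

#' dF/F in percent
#'
#' `dff_percent(t) = 100 * (F(t) - F0) / F0`.
#'
#' @param signal Ratio signal.
#' @param f0 Baseline scalar (> 0).
#' @param time_s Sample times.
#' @return A `dff_trace`: data frame with `time_s`, `dff_percent`, and
#'   attribute `F0`.
#' @export
dff <- function(signal, f0, time_s) {
  stopifnot(length(signal) == length(time_s))
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be positive")
  out <- data.frame(time_s = time_s, dff_percent = 100 * (signal - f0) / f0)
  attr(out, "F0") <- f0
  class(out) <- c("dff_trace", "data.frame")
  out
}

#' Post-intervention response AUC
#'
#' Trapezoidal integral of the percent dF/F over a time window, in
#' percent-minutes. The default window in the pipeline is the full 20-min
#' post-event recording.
#'
#' @param dff_trace A [dff()] result.
#' @param window Two-element window (seconds) within the trace span.
#' @return Scalar AUC (% min).
#' @export
response_auc <- function(dff_trace, window) {
  stopifnot(inherits(dff_trace, "dff_trace"), length(window) == 2L,
            window[2] > window[1])
  t <- dff_trace$time_s
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9)
    stop("AUC window outside the trace span")
  y <- dff_trace$dff_percent
  sel <- t > window[1] & t < window[2]
  tt <- c(window[1], t[sel], window[2])
  yy <- c(stats::approx(t, y, window[1], rule = 2)$y, y[sel],
          stats::approx(t, y, window[2], rule = 2)$y)
  trapz_(s_to_min(tt), yy)
}

#' Simulate a two-channel photometry trace
#'
#' Both channels share a multiplicative slow artefact (sinusoid) and an
#' exponential bleach trend; the calcium response - an exponential rise to
#' a plateau of fractional `amplitude` after the event - is applied to the
#' 465 nm channel only. Multiplicative Gaussian noise is independent per
#' channel. Deterministic given `seed`.
#'
#' @param duration_s Total recording length (default 1800 s: 10-min
#'   baseline + 20-min post).
#' @param fs Sampling rate (Hz), default 20.
#' @param event_time_s Intervention time (default 600 s).
#' @param amplitude Fractional plateau response on the ratio signal
#'   (0.2 = +20%); may be negative for suppression.
#' @param tau_s Response onset time constant (seconds).
#' @param artefact_amp,artefact_period_s Shared sinusoidal artefact.
#' @param bleach_tau_s Shared bleaching time constant (`Inf` = none).
#' @param noise_sd Per-channel multiplicative noise SD (0 = noiseless).
#' @param b465,b405 Channel baselines.
#' @param seed Integer seed.
#' @return List with `trace` ([photometry_trace()]) and `truth_dff`
#'   (ground-truth percent dF/F).
#' @export
simulate_trace <- function(duration_s = 1800, fs = 20, event_time_s = 600,
                           amplitude = 0.2, tau_s = 30,
                           artefact_amp = 0.05, artefact_period_s = 300,
                           bleach_tau_s = 3600, noise_sd = 0,
                           b465 = 2, b405 = 1, seed = 1L) {
  stopifnot(duration_s > event_time_s, fs > 0, tau_s > 0,
            b465 > 0, b405 > 0)
  t <- seq(0, duration_s, by = 1 / fs)
  resp <- ifelse(t >= event_time_s,
                 amplitude * (1 - exp(-(t - event_time_s) / tau_s)), 0)
  art <- (1 + artefact_amp * sin(2 * pi * t / artefact_period_s)) *
    exp(-t / bleach_tau_s)
  noise <- with_seed_(seed, list(n465 = stats::rnorm(length(t), 0, noise_sd),
                                 n405 = stats::rnorm(length(t), 0, noise_sd)))
  F465 <- b465 * art * (1 + resp) * (1 + noise$n465)
  F405 <- b405 * art * (1 + noise$n405)
  trace <- photometry_trace(t, F465, F405, event_time_s,
                            baseline_window = c(0, event_time_s))
  list(trace = trace, truth_dff = 100 * resp)
}

#' One-call photometry pipeline
#'
#' Ratio signal, median baseline `F0`, percent dF/F and post-event AUC.
#'
#' @param trace A [photometry_trace()].
#' @param auc_window Window for [response_auc()]; default event time to end
#'   of trace.
#' @return List with `f0`, `dff` (a `dff_trace`), `auc_pct_min`,
#'   `mean_dff_post`.
#' @export
analyze_photometry <- function(trace, auc_window = NULL) {
  f <- ratio_signal(trace)
  f0 <- baseline_f0(f, trace$time_s, trace$baseline_window)
  dd <- dff(f, f0, trace$time_s)
  auc_window <- auc_window %||% c(trace$event_time_s, max(trace$time_s))
  post <- dd$time_s >= auc_window[1] & dd$time_s <= auc_window[2]
  list(f0 = f0, dff = dd,
       auc_pct_min = response_auc(dd, auc_window),
       mean_dff_post = mean(dd$dff_percent[post]))
}

#' Read / write photometry traces as CSV
#'
#' Columns `time_s`, `F465`, `F405`; events as a separate CSV with
#' `event_time_s` (first row used).
#' @param trace A [photometry_trace()].
#' @param path,events_path File paths.
#' @export
write_trace_csv <- function(trace, path, events_path = NULL) {
  utils::write.csv(data.frame(time_s = trace$time_s, F465 = trace$F465,
                              F405 = trace$F405), path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(data.frame(event_time_s = trace$event_time_s,
                                label = "event"),
                     events_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param event_time_s Event time if no events file is given.
#' @export
read_trace_csv <- function(path, events_path = NULL, event_time_s = NULL) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "F465", "F405") %in% names(tab)))
    stop("trace CSV must have columns time_s, F465, F405")
  if (!is.null(events_path))
    event_time_s <- utils::read.csv(events_path)$event_time_s[1]
  if (is.null(event_time_s)) stop("an event time is required")
  photometry_trace(tab$time_s, tab$F465, tab$F405, event_time_s)
}
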