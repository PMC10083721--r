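#' Pre-stimulus baseline of a trace
#'
#' The mean of all samples strictly before the stimulus event. Used as the
#' basal Ca2+ level (b\[Ca2+\]_cyt or b\[Ca2+\]_ER) for baseline
#' subtraction.
#'
#' @param tr a [ca_trace()] carrying the stimulus event.
#' @param stim_label stimulus event label (default `"TG"`).
#' @return Baseline concentration (uM).
#' @export
estimate_baseline <- function(tr, stim_label = "TG") {
  stopifnot(inherits(tr, "ca_trace"))
  t_stim <- event_time(tr, stim_label)
  pre <- tr$value[tr$t < t_stim]
  if (length(pre) < 3L) {
    stop("need at least 3 pre-stimulus samples to estimate a baseline")
  }
  mean(pre)
}

moving_average <- function(x, window) {
  if (window %% 2L != 1L || window < 1L) {
    stop("smoothing window must be an odd positive number of samples")
  }
  n <- length(x)
  if (window >= n) stop("smoothing window must be shorter than the trace")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)  # shrinking window at the edges
}

#' Smoothed first derivative of a trace
#'
#' Centred moving-average smoothing followed by central differences;
#' the two end points use one-sided differences. Output has the same length
#' and time base as the input, in uM/s.
#'
#' @param tr a [ca_trace()].
#' @param window odd moving-average window in samples (default 5).
#' @return A [ca_trace()] whose `value` is d\[Ca2+\]/dt (uM/s); events are
#'   carried over.
#' @export
smooth_derivative <- function(tr, window = 5L) {
  stopifnot(inherits(tr, "ca_trace"))
  s <- moving_average(tr$value, window)
  d <- central_difference(s, tr$dt)
  out <- tr
  out$value <- d
  out
}

central_difference <- function(s, dt) {
  n <- length(s)
  d <- numeric(n)
  d[1] <- (s[2] - s[1]) / dt
  d[n] <- (s[n] - s[n - 1]) / dt
  if (n > 2L) d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  d
}

#' Inflection point of the ER depletion
#'
#' The time at which -d\[Ca2+\]_ER/dt reaches its maximum after the
#' stimulus. It divides the mobilisation into an early phase (cumulative
#' SERCA inhibition building up) and a late phase in which the unmasked ER
#' leak drives a first-order depletion; rate fits start here. Ties are
#' broken toward the earliest time.
#'
#' @param er_tr an ER-channel [ca_trace()] spanning the stimulus event.
#' @param window smoothing window (samples) passed to [smooth_derivative()].
#' @param stim_label stimulus event label (default `"TG"`).
#' @return A list with `t_inflect` (s), `ca_er_at` (uM, ER level there) and
#'   `index` (sample index into the trace).
#' @export
find_inflection <- function(er_tr, window = 5L, stim_label = "TG") {
  stopifnot(inherits(er_tr, "ca_trace"))
  t_stim <- event_time(er_tr, stim_label)
  d <- smooth_derivative(er_tr, window)
  post <- which(er_tr$t >= t_stim)
  # end samples carry one-sided differences; exclude them from the argmax
  post <- setdiff(post, c(1L, length(er_tr$t)))
  if (!length(post)) stop("no post-stimulus samples on the ER trace")
  negd <- -d$value[post]
  if (max(negd) <= 1e-15) {
    stop("ER trace shows no post-stimulus decay; inflection point undefined")
  }
  i <- post[which.max(negd)]  # which.max takes the earliest tie
  list(t_inflect = er_tr$t[i], ca_er_at = er_tr$value[i], index = i)
}

#' Model-free metrics of a stimulus-evoked Ca2+ transient
#'
#' Baseline, peak amplitude (p-Delta\[Ca2+\]_cyt), time-to-peak, area under
#' the baseline-subtracted curve, and duration. The integration window runs
#' from the stimulus until the trace first returns to within
#' `duration_frac` (default 5%) of the peak amplitude above baseline after
#' the peak, or to the trace end; `duration` is the length of that window.
#' The AUC is the trapezoid integral of `value - baseline` clipped at zero
#' (so noise excursions below baseline do not subtract area).
#'
#' @param tr a [ca_trace()] carrying the stimulus event.
#' @param stim_label stimulus event label (default `"TG"`).
#' @param duration_frac return-to-baseline criterion as a fraction of the
#'   peak amplitude (default 0.05).
#' @param full_support if `TRUE`, integrate to the trace end regardless of
#'   the duration criterion (duration still reported by the criterion).
#' @param baseline optional externally supplied baseline (uM); default is
#'   [estimate_baseline()].
#' @return A list of class `transient_metrics`: `baseline` (uM),
#'   `peak_amplitude` (uM), `t_peak` (s, from the stimulus), `auc` (uM s),
#'   `duration` (s), and `flat` (`TRUE` when no transient was detected, in
#'   which case the metrics are zero and a warning is raised).
#' @export
transient_metrics <- function(tr, stim_label = "TG", duration_frac = 0.05,
                              full_support = FALSE, baseline = NULL) {
  stopifnot(inherits(tr, "ca_trace"))
  t_stim <- event_time(tr, stim_label)
  if (is.null(baseline)) baseline <- estimate_baseline(tr, stim_label)
  post <- which(tr$t >= t_stim)
  if (!length(post)) stop("no post-stimulus samples")
  y <- tr$value[post] - baseline
  tt <- tr$t[post] - t_stim
  ip <- which.max(y)
  peak_amplitude <- y[ip]
  if (peak_amplitude <= 0 || all(abs(y) < 1e-15)) {
    warning("no transient above baseline detected; returning zero metrics")
    out <- list(baseline = baseline, peak_amplitude = 0, t_peak = 0,
                auc = 0, duration = 0, flat = TRUE)
    class(out) <- "transient_metrics"
    return(out)
  }
  back <- which(y[seq(ip, length(y))] <= duration_frac * peak_amplitude)
  iend <- if (length(back)) ip + back[1] - 1L else length(y)
  duration <- tt[iend]
  iint <- if (full_support) length(y) else iend
  yc <- pmax(y[seq_len(iint)], 0)
  auc <- trapz(tt[seq_len(iint)], yc)
  out <- list(baseline = baseline, peak_amplitude = peak_amplitude,
              t_peak = tt[ip], auc = auc, duration = duration, flat = FALSE)
  class(out) <- "transient_metrics"
  out
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<transient_metrics> baseline %.4g uM | peak amplitude %.4g uM | ",
    "t_peak %.4g s | AUC %.4g uM*s | duration %.4g s%s\n"),
    x$baseline, x$peak_amplitude, x$t_peak, x$auc, x$duration,
    if (x$flat) " [flat]" else ""))
  invisible(x)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Percent depletion of the ER Ca2+ store
#'
#' `100 * (b_er - ca_er) / b_er`: how far the ER Ca2+ level has fallen from
#' its basal value.
#'
#' @param b_er basal ER Ca2+ (uM), > 0.
#' @param ca_er current ER Ca2+ (uM), `0 <= ca_er <= b_er` (vectorised).
#' @return Percent depletion.
#' @examples
#' percent_depletion(370, 348)  # ~6% at the cytosolic peak
#' @export
percent_depletion <- function(b_er, ca_er) {
  if (!is.finite(b_er) || b_er <= 0) stop("b_er must be > 0")
  ca_er <- as.numeric(ca_er)
  if (any(ca_er < 0) || any(ca_er > b_er)) {
    stop("require 0 <= ca_er <= b_er")
  }
  100 * (b_er - ca_er) / b_er
}

#' Store-operated Ca2+ entry rate after Ca2+ re-addition
#'
#' Least-squares slope of the cytosolic trace over a window starting at the
#' Ca2+ re-addition event: the empirical SOCE influx rate J_entry, in
#' nM/s.
#'
#' @param tr cytosolic [ca_trace()] carrying the re-addition event.
#' @param readd_label event label of the Ca2+ re-addition (default
#'   `"ca_readd"`).
#' @param fit_window window length (s) after the event used for the fit.
#' @return A list with `slope` (nM/s), `se` (nM/s, OLS standard error) and
#'   `n` (samples used).
#' @export
soce_slope <- function(tr, readd_label = "ca_readd", fit_window = 60) {
  stopifnot(inherits(tr, "ca_trace"))
  t0 <- event_time(tr, readd_label)
  if (t0 + fit_window > tr$t[length(tr$t)] + 1e-9) {
    stop("fit window extends beyond the end of the trace")
  }
  sel <- tr$t >= t0 & tr$t <= t0 + fit_window + 1e-9
  if (sum(sel) < 3L) stop("need at least 3 samples in the fit window")
  x <- tr$t[sel]
  y <- tr$value[sel]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  # se computed directly so an exactly linear segment yields se = 0
  # (summary.lm warns on perfect fits)
  s2 <- sum(stats::residuals(fit)^2) / (length(x) - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  list(slope = slope * 1000, se = se * 1000, n = sum(sel))
}
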