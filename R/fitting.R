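#' Fit an exponential decay to a trace segment
#'
#' Nonlinear least squares of `C0 * exp(-k * t)` (time measured from the
#' start of the segment), initialised from a log-linear regression. Serves
#' both the cytosolic clearance assay (k = k_clear, after chelating
#' external Ca2+) and the ER depletion time course (k = k_depl, after the
#' inflection point).
#'
#' @param tr_segment a [ca_trace()] restricted to the decaying segment
#'   (see [trace_window()]); at least 5 samples, all values > 0.
#' @param control a [minpack.lm::nls.lm.control()] list for the optimiser.
#' @return An object of class `exp_decay_fit` with elements `k` (s^-1),
#'   `tau` (s, exactly `1/k`), `c0` (uM), `rmse` (uM), `window`
#'   (`c(t_start, t_end)`, s), `n`, `data` and `fitted`.
#' @examples
#' tr <- ca_trace(seq(0, 180, 3), 0.5 * exp(-28.34e-3 * seq(0, 180, 3)))
#' fit_exponential_decay(tr)
#' @export
fit_exponential_decay <- function(tr_segment,
                                  control = minpack.lm::nls.lm.control(
                                    ftol = 1e-13, ptol = 1e-13,
                                    maxiter = 500)) {
  stopifnot(inherits(tr_segment, "ca_trace"))
  if (length(tr_segment$t) < 5L) stop("need at least 5 samples")
  if (any(tr_segment$value <= 0)) {
    stop("all segment values must be > 0 for an exponential-decay fit")
  }
  tt <- tr_segment$t - tr_segment$t[1]
  y <- tr_segment$value
  ll <- stats::lm(log(y) ~ tt)
  k0 <- -unname(stats::coef(ll)[2])
  c00 <- exp(unname(stats::coef(ll)[1]))
  if (!is.finite(k0) || k0 <= 0) {
    stop("segment is not decaying (log-linear slope >= 0); fit failed. ",
         sprintf("log-slope = %g per s", -k0))
  }
  fit <- minpack.lm::nlsLM(y ~ c0 * exp(-k * tt),
                           start = list(c0 = c00, k = k0),
                           lower = c(1e-12, 1e-12), control = control)
  k <- unname(stats::coef(fit)["k"])
  c0 <- unname(stats::coef(fit)["c0"])
  if (k <= 0) stop(sprintf("fitted rate is non-positive (k = %g)", k))
  res <- stats::residuals(fit)
  structure(list(k = k, tau = 1 / k, c0 = c0,
                 rmse = sqrt(mean(res^2)),
                 window = range(tr_segment$t), n = length(y),
                 data = data.frame(t = tr_segment$t, value = y),
                 fitted = c0 * exp(-k * tt)),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_decay_fit> k = %.6g s^-1 (tau = %.6g s), C0 = %.4g uM, rmse = %.3g uM, n = %d\n",
    x$k, x$tau, x$c0, x$rmse, x$n))
  invisible(x)
}

#' @export
coef.exp_decay_fit <- function(object, ...) {
  c(c0 = object$c0, k = object$k)
}

#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  object$c0 * exp(-object$k * (t - object$window[1]))
}

#' @export
residuals.exp_decay_fit <- function(object, ...) {
  object$data$value - object$fitted
}

#' Estimate the ER Ca2+ depletion rate from the rate-vs-level relation
#'
#' For a first-order depletion, -d\[Ca2+\]_ER/dt plotted against
#' \[Ca2+\]_ER is a straight line with slope k_depl. The derivative is the
#' smoothed central difference of [smooth_derivative()]; the regressor is
#' the *smoothed* ER level (so the moving-average attenuation cancels
#' between derivative and level), and the one-sided end-point derivative
#' samples are excluded. The decaying phase is selected automatically from
#' the inflection point (maximum of -d\[Ca2+\]_ER/dt) to the trace end, or
#' from an explicit time window.
#'
#' @param er_tr ER-channel [ca_trace()] spanning the stimulus event.
#' @param window `"auto"` (default) or a numeric `c(t_start, t_end)` window
#'   in seconds.
#' @param deriv_window smoothing window (samples) for the derivative.
#' @param stim_label stimulus event label (default `"TG"`).
#' @return An object of class `depletion_fit` with `k_depl` (s^-1),
#'   `tau_depl` (s, exactly `1/k_depl`), `intercept` (uM/s), `r_squared`,
#'   `window` (s), `n` and `data` (the phase points used:
#'   `ca_er`, `neg_dca_dt`).
#' @examples
#' t <- seq(0, 600, 10)
#' tr <- ca_trace(t, 370 * exp(-6.28e-3 * t), "er", c(TG = 0))
#' fit_depletion_rate(tr)
#' @export
fit_depletion_rate <- function(er_tr, window = "auto", deriv_window = 5L,
                               stim_label = "TG") {
  stopifnot(inherits(er_tr, "ca_trace"))
  s <- moving_average(er_tr$value, deriv_window)
  d <- central_difference(s, er_tr$dt)
  n <- length(er_tr$t)
  interior <- seq(2L, n - 1L)  # drop one-sided end-point derivatives
  if (identical(window, "auto")) {
    infl <- find_inflection(er_tr, deriv_window, stim_label)
    idx <- interior[er_tr$t[interior] >= infl$t_inflect]
    win <- c(infl$t_inflect, er_tr$t[n])
  } else {
    win <- as.numeric(window)
    if (length(win) != 2L || win[1] >= win[2]) {
      stop("explicit window must be c(t_start, t_end) with t_start < t_end")
    }
    idx <- interior[er_tr$t[interior] >= win[1] & er_tr$t[interior] <= win[2]]
  }
  if (length(idx) < 5L) stop("fewer than 5 phase points in the fit window")
  x <- s[idx]
  y <- -d[idx]
  fit <- stats::lm(y ~ x)
  k_depl <- unname(stats::coef(fit)[2])
  if (!is.finite(k_depl) || k_depl <= 0) {
    stop(sprintf("no first-order decay: fitted slope %g <= 0", k_depl))
  }
  structure(list(k_depl = k_depl, tau_depl = 1 / k_depl,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 window = win, n = length(idx),
                 data = data.frame(ca_er = x, neg_dca_dt = y)),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf(
    "<depletion_fit> k_depl = %.6g s^-1 (tau_depl = %.6g s), r^2 = %.4f, n = %d, window [%g, %g] s\n",
    x$k_depl, x$tau_depl, x$r_squared, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
coef.depletion_fit <- function(object, ...) {
  c(k_depl = object$k_depl, intercept = object$intercept)
}

#' Fit the Bateman model to a cytosolic Ca2+ transient
#'
#' Least-squares fit of the one-compartment transient
#' `b_lER * k_leak/(k_clear - k_leak) * (exp(-k_leak t) - exp(-k_clear t))`
#' to a baseline-subtracted post-stimulus cytosolic trace. By default the
#' clearance rate is fixed to a value measured separately with the
#' clearance assay and only `(b_lER, k_leak)` are estimated; with
#' `k_clear_fixed = FALSE` all three parameters are free.
#'
#' Because the model is symmetric under exchanging the two rates
#' (flip-flop), a free three-parameter fit cannot label them from the curve
#' alone. The free fit therefore constrains `k_leak <= k_clear` unless
#' `flip_flop = TRUE`, and the summary flags the identifiability hazard.
#'
#' Initialisation is deterministic: `k_leak` from the log-slope of the
#' decay tail, `b_lER` from `AUC * k_clear`.
#'
#' @param cyt_tr cytosolic [ca_trace()]. If `stim_label` names an event on
#'   the trace, the baseline is estimated and subtracted and the
#'   post-stimulus segment is used; otherwise the trace is taken to be an
#'   already baseline-subtracted transient with t = 0 at the stimulus.
#' @param k_clear clearance rate (s^-1): the fixed value when
#'   `k_clear_fixed = TRUE`, the starting value otherwise.
#' @param k_clear_fixed keep `k_clear` at the supplied value (default
#'   `TRUE`).
#' @param stim_label stimulus event label, or `NULL` for a pre-subtracted
#'   transient. Default `"TG"` when present on the trace.
#' @param flip_flop allow `k_leak > k_clear` in the free fit (default
#'   `FALSE`).
#' @param control optimiser control, see [minpack.lm::nls.lm.control()].
#' @return An object of class `bateman_fit` with elements `params`
#'   (a [bateman_params()]), `k_clear_fixed`, `flip_flop`, `rmse` (uM),
#'   `vcov` (covariance of the free parameters), `baseline` (uM or `NA`),
#'   `data` (`t` since stimulus, `delta` uM), `fitted`, `n` and `call`.
#' @examples
#' p <- bateman_params(2.40, 14.55e-3, 28.34e-3)
#' t <- seq(0, 600, 3)
#' tr <- ca_trace(t, bateman_transient(t, p), "cyt")
#' fit_bateman(tr, k_clear = 28.34e-3)
#' @export
fit_bateman <- function(cyt_tr, k_clear, k_clear_fixed = TRUE,
                        stim_label = if ("TG" %in% names(cyt_tr$events))
                          "TG" else NULL,
                        flip_flop = FALSE,
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-15, ptol = 1e-15, maxiter = 1000)) {
  stopifnot(inherits(cyt_tr, "ca_trace"))
  if (!is.finite(k_clear) || k_clear <= 0) {
    stop("k_clear must be a strictly positive rate (s^-1)")
  }
  baseline <- NA_real_
  if (!is.null(stim_label)) {
    t_stim <- event_time(cyt_tr, stim_label)
    baseline <- estimate_baseline(cyt_tr, stim_label)
    post <- cyt_tr$t >= t_stim
    tt <- cyt_tr$t[post] - t_stim
    y <- cyt_tr$value[post] - baseline
  } else {
    tt <- cyt_tr$t - cyt_tr$t[1]
    y <- cyt_tr$value
  }
  if (length(tt) < 10L) stop("need at least 10 post-stimulus samples")
  if (max(abs(y)) < 1e-12) stop("all-zero transient; nothing to fit")

  # deterministic initialisation
  b0 <- max(trapz(tt, pmax(y, 0)) * k_clear, 1e-6)
  ip <- which.max(y)
  tail_idx <- which(seq_along(y) > ip & y > 0.05 * y[ip])
  k0 <- if (length(tail_idx) >= 3L) {
    sl <- stats::coef(stats::lm(log(y[tail_idx]) ~ tt[tail_idx]))[2]
    ifelse(is.finite(sl) && sl < 0, -unname(sl), k_clear / 2)
  } else k_clear / 2
  k0 <- min(max(k0, 1e-6), if (flip_flop) 10 * k_clear else
    k_clear * (1 - 1e-9))

  if (k_clear_fixed) {
    kc <- k_clear
    fit <- minpack.lm::nlsLM(
      y ~ bateman_eval(tt, b, kl, kc),
      start = list(b = b0, kl = k0),
      lower = c(1e-12, 1e-12), control = control)
    co <- stats::coef(fit)
    pars <- bateman_params(unname(co["b"]), unname(co["kl"]), kc)
  } else if (!flip_flop) {
    # parameterise k_clear = k_leak + dk, dk >= 0 enforces k_leak <= k_clear
    fit <- minpack.lm::nlsLM(
      y ~ bateman_eval(tt, b, kl, kl + dk),
      start = list(b = b0, kl = k0, dk = max(k_clear - k0, 1e-6)),
      lower = c(1e-12, 1e-12, 0), control = control)
    co <- stats::coef(fit)
    pars <- bateman_params(unname(co["b"]), unname(co["kl"]),
                           unname(co["kl"] + co["dk"]))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ bateman_eval(tt, b, kl, kc),
      start = list(b = b0, kl = k0, kc = k_clear),
      lower = c(1e-12, 1e-12, 1e-12), control = control)
    co <- stats::coef(fit)
    pars <- bateman_params(unname(co["b"]), unname(co["kl"]),
                           unname(co["kc"]))
  }
  res <- stats::residuals(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(params = pars, k_clear_fixed = k_clear_fixed,
                 flip_flop = flip_flop,
                 rmse = sqrt(mean(res^2)), vcov = vc,
                 baseline = baseline,
                 data = data.frame(t = tt, delta = y),
                 fitted = stats::fitted(fit), n = length(y),
                 call = match.call()),
            class = "bateman_fit")
}

#' @export
print.bateman_fit <- function(x, ...) {
  p <- x$params
  cat("One-compartment (Bateman) Ca2+ transient fit\n")
  cat(sprintf("  b_lER  = %.6g uM\n  k_leak = %.6g s^-1 (tau = %.4g s)\n",
              p$b_lER, p$k_leak, 1 / p$k_leak))
  cat(sprintf("  k_clear = %.6g s^-1 (tau = %.4g s)%s\n",
              p$k_clear, 1 / p$k_clear,
              if (x$k_clear_fixed) " [fixed]" else " [fitted]"))
  cat(sprintf("  rmse = %.3g uM on %d samples\n", x$rmse, x$n))
  invisible(x)
}

#' @export
summary.bateman_fit <- function(object, ...) {
  an <- bateman_analytics(object$params)
  out <- list(params = object$params, analytics = an,
              rmse = object$rmse, n = object$n,
              k_clear_fixed = object$k_clear_fixed,
              vcov = object$vcov,
              flip_flop_hazard = !object$k_clear_fixed)
  class(out) <- "summary.bateman_fit"
  out
}

#' @export
print.summary.bateman_fit <- function(x, ...) {
  p <- x$params
  cat("One-compartment (Bateman) Ca2+ transient fit\n")
  cat(sprintf("  b_lER = %.6g uM, k_leak = %.6g s^-1, k_clear = %.6g s^-1%s\n",
              p$b_lER, p$k_leak, p$k_clear,
              if (x$k_clear_fixed) " (fixed)" else ""))
  cat(sprintf("  t_peak = %.4g s, peak = %.4g uM, AUC = %.4g uM*s, gain = %.4g\n",
              x$analytics$t_peak, x$analytics$peak, x$analytics$auc,
              x$analytics$gain))
  cat(sprintf("  rmse = %.3g uM, n = %d\n", x$rmse, x$n))
  if (x$flip_flop_hazard) {
    cat("  note: with both rates free the model is symmetric under",
        "exchanging k_leak and k_clear\n  (flip-flop); labels rely on the",
        "constraint k_leak <= k_clear.\n")
  }
  invisible(x)
}

#' @export
coef.bateman_fit <- function(object, ...) {
  p <- object$params
  c(b_lER = p$b_lER, k_leak = p$k_leak, k_clear = p$k_clear)
}

#' @export
fitted.bateman_fit <- function(object, ...) object$fitted

#' @export
residuals.bateman_fit <- function(object, ...) {
  object$data$delta - object$fitted
}

#' @export
predict.bateman_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  bateman_transient(t, object$params)
}

#' @export
plot.bateman_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$delta, pch = 16, cex = 0.4,
                 col = "grey50", xlab = "time since stimulus (s)",
                 ylab = "Delta[Ca2+]_cyt (uM)", ...)
  tgrid <- seq(min(x$data$t), max(x$data$t), length.out = 400)
  graphics::lines(tgrid, bateman_transient(tgrid, x$params), col = "red3",
                  lwd = 2)
  invisible(x)
}

#' @export
simulate.bateman_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- object$fitted
  out <- as.data.frame(
    replicate(nsim, mu + stats::rnorm(length(mu), sd = object$rmse)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(t = object$data$t, out)
}
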