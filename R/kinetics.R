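#' Bateman model parameters
#'
#' Parameters of the one-compartment model of a TG-induced cytosolic Ca2+
#' transient: a first-order ER Ca2+ leak (rate `k_leak`, driven by the
#' luminal pool `b_lER`) feeding the cytosol, and a first-order clearance
#' (rate `k_clear`) draining it. The baseline-subtracted transient is the
#' difference-of-exponentials Bateman solution (see [bateman_transient()]).
#'
#' `b_lER` is the leak-driving luminal concentration, a free model parameter
#' on the uM scale; it is deliberately not tied to the measured bulk ER
#' Ca2+ level (hundreds of uM), which is heavily buffered.
#'
#' @param b_lER leak-driving luminal Ca2+ pool (uM), > 0.
#' @param k_leak ER Ca2+ leak rate (s^-1), > 0.
#' @param k_clear cytosolic Ca2+ clearance rate (s^-1), > 0.
#' @return An object of class `bateman_params`.
#' @examples
#' bateman_params(2.40, 14.55e-3, 28.34e-3)
#' @export
bateman_params <- function(b_lER, k_leak, k_clear) {
  vals <- c(b_lER = b_lER, k_leak = k_leak, k_clear = k_clear)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("b_lER, k_leak and k_clear must all be strictly positive and finite")
  }
  structure(as.list(vals), class = "bateman_params")
}

#' @export
print.bateman_params <- function(x, ...) {
  cat(sprintf(
    "<bateman_params> b_lER = %g uM, k_leak = %g s^-1, k_clear = %g s^-1\n",
    x$b_lER, x$k_leak, x$k_clear))
  invisible(x)
}

# Relative rate separation below which the equal-rate limit form is used:
# under ~1e-6 the cancellation error in (e^{-k1 t} - e^{-k2 t}) exceeds the
# error of the b*k*t*exp(-k*t) limit.
.bateman_eps_rel <- 1e-6

bateman_eval <- function(t, b_lER, k_leak, k_clear,
                         eps_rel = .bateman_eps_rel) {
  if (abs(k_clear - k_leak) < eps_rel * k_clear) {
    k <- (k_leak + k_clear) / 2
    b_lER * k * t * exp(-k * t)
  } else {
    b_lER * (k_leak / (k_clear - k_leak)) *
      (exp(-k_leak * t) - exp(-k_clear * t))
  }
}

#' Bateman transient: baseline-subtracted cytosolic Ca2+ time course
#'
#' Evaluates
#' \deqn{\Delta[Ca^{2+}]_{cyt}(t) = b_{lER} \frac{k_{leak}}{k_{clear}-k_{leak}}
#'   \left(e^{-k_{leak} t} - e^{-k_{clear} t}\right)}
#' the closed-form solution of sequential first-order leak and clearance.
#' When the two rates are (numerically) equal the analytic limit
#' `b_lER * k * t * exp(-k t)` with `k = (k_leak + k_clear)/2` is used. The
#' result is >= 0 for all t >= 0 and tends to 0 as t grows.
#'
#' Note the curve determines the two rates only as an unordered pair:
#' exchanging `k_leak` and `k_clear` while rescaling the pool so that
#' `b_lER * k_leak` stays fixed reproduces the identical time course. This
#' "flip-flop" ambiguity matters when both rates are fitted freely; see
#' [fit_bateman()].
#'
#' @param t time since the stimulus (s), numeric vector, >= 0.
#' @param p a [bateman_params()].
#' @return Delta\[Ca2+\]_cyt (uM), same length as `t`.
#' @examples
#' p <- bateman_params(2.40, 14.55e-3, 28.34e-3)
#' bateman_transient(c(0, 48.4, 600), p)
#' @export
bateman_transient <- function(t, p) {
  stopifnot(inherits(p, "bateman_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0 (time since stimulus)")
  bateman_eval(t, p$b_lER, p$k_leak, p$k_clear)
}

#' Term-by-term breakdown of the Bateman transient
#'
#' Decomposes the transient into the factors used to reason about its shape:
#' `Fa = exp(-k_leak t)`, `Fb = exp(-k_clear t)`, `Fc = Fa - Fb` and
#' `Fd = gain * Fc` with `gain = k_leak / (k_clear - k_leak)`, so that
#' `b_lER * Fd` equals [bateman_transient()]. The gain diverges as
#' `k_leak -> k_clear`; equal rates are a degenerate case and are signalled
#' as an error.
#'
#' @param t time since the stimulus (s), numeric vector, >= 0.
#' @param p a [bateman_params()].
#' @return A list with `t`, `Fa`, `Fb`, `Fc`, `Fd` (dimensionless) and
#'   `gain`.
#' @export
bateman_components <- function(t, p) {
  stopifnot(inherits(p, "bateman_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0 (time since stimulus)")
  if (abs(p$k_clear - p$k_leak) < .bateman_eps_rel * p$k_clear) {
    stop("gain k_leak/(k_clear - k_leak) is undefined at k_leak = k_clear ",
         "(degenerate case; the transient itself remains defined)")
  }
  Fa <- exp(-p$k_leak * t)
  Fb <- exp(-p$k_clear * t)
  gain <- p$k_leak / (p$k_clear - p$k_leak)
  list(t = t, Fa = Fa, Fb = Fb, Fc = Fa - Fb, Fd = gain * (Fa - Fb),
       gain = gain)
}

#' Closed-form analytics of a Bateman transient
#'
#' Peak time, peak amplitude, area under the curve and gain:
#' `t_peak = log(k_clear/k_leak) / (k_clear - k_leak)` (limit `1/k` at equal
#' rates, where the peak is `b_lER/e`), `auc = b_lER / k_clear`
#' (the integral of the transient over all time), and
#' `gain = k_leak / (k_clear - k_leak)` (`Inf` flag at equal rates).
#'
#' @param p a [bateman_params()].
#' @return A list with `t_peak` (s), `peak` (uM), `auc` (uM s), `gain`.
#' @examples
#' bateman_analytics(bateman_params(2.40, 14.55e-3, 28.34e-3))
#' @export
bateman_analytics <- function(p) {
  stopifnot(inherits(p, "bateman_params"))
  equal <- abs(p$k_clear - p$k_leak) < .bateman_eps_rel * p$k_clear
  if (equal) {
    k <- (p$k_leak + p$k_clear) / 2
    t_peak <- 1 / k
    gain <- Inf
  } else {
    t_peak <- log(p$k_clear / p$k_leak) / (p$k_clear - p$k_leak)
    gain <- p$k_leak / (p$k_clear - p$k_leak)
  }
  list(t_peak = t_peak,
       peak = bateman_transient(t_peak, p),
       auc = p$b_lER / p$k_clear,
       gain = gain)
}

#' Exponential decay with time constant
#'
#' Evaluates `C0 * exp(-k * t)` and reports the time constant `tau = 1/k`
#' alongside; the form shared by cytosolic clearance after interrupting
#' Ca2+ entry and by ER depletion after full SERCA blockade.
#'
#' @param t time (s), >= 0.
#' @param C0 initial concentration (uM), >= 0.
#' @param k decay rate (s^-1), > 0.
#' @return A list with `value` (uM, same length as `t`), `k` and `tau` (s).
#' @examples
#' exponential_decay(165, C0 = 1, k = 6.06e-3)  # C0/e at t = tau
#' @export
exponential_decay <- function(t, C0, k) {
  if (!is.finite(k) || k <= 0) stop("k must be strictly positive")
  if (!is.finite(C0) || C0 < 0) stop("C0 must be >= 0")
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0")
  list(value = C0 * exp(-k * t), k = k, tau = 1 / k)
}

#' First-order Ca2+ flux
#'
#' `J = k * C`: the instantaneous flux of a first-order process. With
#' `k = k_leak` and the luminal ER Ca2+ level it gives the ER Ca2+ leak
#' `J_leak`; with `k = k_clear` and the cytosolic level it gives the
#' clearance flux `J_clear`.
#'
#' @param k rate constant (s^-1), >= 0.
#' @param C concentration (uM), >= 0 (vectorised).
#' @return Flux (uM s^-1).
#' @examples
#' first_order_flux(15e-3, 370)  # ~5.6 uM/s ER leak at basal ER Ca2+
#' @export
first_order_flux <- function(k, C) {
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be >= 0")
  C <- as.numeric(C)
  if (any(!is.finite(C)) || any(C < 0)) stop("C must be >= 0")
  k * C
}

#' Amplification/attenuation phase diagram of Bateman transients
#'
#' Simulates one transient per `k_leak` grid point at a fixed clearance
#' rate, with the leak-driving pool either held constant or declining along
#' the grid (emulating progressive ER Ca2+ loss as the leak grows). With a
#' constant pool, peak amplitude rises monotonically with `k_leak` while
#' time-to-peak and duration shrink; with a declining pool the peak first
#' rises (amplification) then falls (attenuation).
#'
#' @param k_leak_grid vector of leak rates (s^-1), strictly positive.
#' @param b_lER either a single reference pool size (uM), used for every
#'   grid point, or a vector of pool sizes matching `k_leak_grid`.
#' @param k_clear clearance rate (s^-1).
#' @param t time grid (s) for the simulated transients (default 0--600 s,
#'   1 s steps).
#' @param b_schedule if `b_lER` is scalar: `"constant"` keeps the pool
#'   fixed; `"declining"` scales it linearly from 100% down to
#'   `decline_to` (default 15%) across the grid.
#' @param decline_to final fraction of the reference pool for the declining
#'   schedule.
#' @return A list of class `phase_diagram` with `transients` (long-format
#'   data.frame: `k_leak`, `b_lER`, `t`, `delta_ca_cyt`) and `metrics`
#'   (one row per transient: `k_leak`, `b_lER`, `t_peak`, `peak`, `auc`,
#'   `gain`, `duration`). Duration is the time for the transient to fall
#'   back below 5% of its peak after the peak, measured on `t`.
#' @examples
#' pd <- phase_diagram(seq(8e-3, 35e-3, by = 3e-3), b_lER = 2.4,
#'                     k_clear = 28e-3)
#' pd$metrics
#' @export
phase_diagram <- function(k_leak_grid, b_lER, k_clear,
                          t = seq(0, 600, by = 1),
                          b_schedule = c("constant", "declining"),
                          decline_to = 0.15) {
  b_schedule <- match.arg(b_schedule)
  k_leak_grid <- as.numeric(k_leak_grid)
  if (!length(k_leak_grid) || any(k_leak_grid <= 0)) {
    stop("k_leak_grid must be non-empty and strictly positive")
  }
  n <- length(k_leak_grid)
  if (length(b_lER) == 1L) {
    b_grid <- if (b_schedule == "constant") rep(b_lER, n) else {
      b_lER * seq(1, decline_to, length.out = n)
    }
  } else if (length(b_lER) == n) {
    b_grid <- as.numeric(b_lER)
  } else {
    stop("b_lER must be scalar or match the length of k_leak_grid")
  }
  if (any(b_grid <= 0)) stop("b_lER values must be strictly positive")

  trans <- vector("list", n)
  metr <- vector("list", n)
  for (i in seq_len(n)) {
    p <- bateman_params(b_grid[i], k_leak_grid[i], k_clear)
    y <- bateman_transient(t, p)
    an <- bateman_analytics(p)
    ip <- which.max(y)
    after <- which(y[seq(ip, length(y))] < 0.05 * an$peak)
    duration <- if (length(after)) t[ip + after[1] - 1L] - t[1] else
      t[length(t)] - t[1]
    trans[[i]] <- data.frame(k_leak = k_leak_grid[i], b_lER = b_grid[i],
                             t = t, delta_ca_cyt = y)
    metr[[i]] <- data.frame(k_leak = k_leak_grid[i], b_lER = b_grid[i],
                            t_peak = an$t_peak, peak = an$peak,
                            auc = an$auc, gain = an$gain,
                            duration = duration)
  }
  structure(list(transients = do.call(rbind, trans),
                 metrics = do.call(rbind, metr),
                 k_clear = k_clear, b_schedule = b_schedule),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d transients, k_clear = %g s^-1, %s b_lER\n",
              nrow(x$metrics), x$k_clear, x$b_schedule))
  print(x$metrics, ...)
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  tr <- x$transients
  ks <- unique(tr$k_leak)
  cols <- grDevices::hcl.colors(length(ks), "Zissou 1")
  graphics::plot(NA, xlim = range(tr$t), ylim = c(0, max(tr$delta_ca_cyt)),
                 xlab = "time since TG (s)",
                 ylab = "Delta[Ca2+]_cyt (uM)", ...)
  for (i in seq_along(ks)) {
    sub <- tr[tr$k_leak == ks[i], ]
    graphics::lines(sub$t, sub$delta_ca_cyt, col = cols[i])
  }
  invisible(x)
}
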