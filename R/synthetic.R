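#' Imaging protocol specification for the synthetic generator
#'
#' Describes one simulated imaging run: which protocol is emulated, when
#' the solution-change / drug events occur, the sampling interval, the
#' duration, per-channel Gaussian noise levels and the RNG seed. Dual-sensor
#' protocols (simultaneous FURA-2 + D1ER) sample every 10 s; FURA-2-alone
#' protocols every 3 s, matching typical acquisition rates.
#'
#' @param protocol_id one of `"tg_zero_ca"`, `"tg_with_ca"`, `"iono"`,
#'   `"tg_then_iono"`, `"ca_readdition"`, `"clearance_assay"`,
#'   `"puro_pretreat"`.
#' @param events named numeric vector of event times (s); defaults depend
#'   on the protocol (TG/IONO at 60 s; the clearance assay re-adds Ca2+ at
#'   30 s and chelates with EGTA at 90 s).
#' @param sampling_dt sampling interval (s); default 10 for dual-sensor
#'   protocols, 3 otherwise.
#' @param duration recording length (s), at least the last event time.
#' @param noise_sd_cyt,noise_sd_er additive Gaussian noise SD per sample
#'   (uM); defaults 0.02 (cytosol) and 5 (ER).
#' @param seed integer RNG seed (mandatory: fixtures carry their seed, no
#'   global random state is consumed).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol_id = c("tg_zero_ca", "tg_with_ca",
                                          "iono", "tg_then_iono",
                                          "ca_readdition", "clearance_assay",
                                          "puro_pretreat"),
                          events = NULL, sampling_dt = NULL, duration = 600,
                          noise_sd_cyt = 0.02, noise_sd_er = 5,
                          seed = 1L) {
  protocol_id <- match.arg(protocol_id)
  dual <- protocol_id %in% c("tg_zero_ca", "tg_then_iono", "puro_pretreat")
  if (is.null(sampling_dt)) sampling_dt <- if (dual) 10 else 3
  if (sampling_dt <= 0) stop("sampling_dt must be > 0")
  if (is.null(events)) {
    events <- switch(protocol_id,
      tg_zero_ca = , tg_with_ca = , puro_pretreat = c(TG = 60),
      iono = c(IONO = 60),
      tg_then_iono = c(TG = 60, IONO = 400),
      ca_readdition = c(TG = 60, ca_readd = 360),
      clearance_assay = c(ca_readd = 30, EGTA = 90))
  }
  events <- normalise_events(events)
  if (duration < max(events)) stop("duration must cover all event times")
  if (noise_sd_cyt < 0 || noise_sd_er < 0) stop("noise SDs must be >= 0")
  structure(list(protocol_id = protocol_id, events = events,
                 sampling_dt = sampling_dt, duration = duration,
                 noise_sd_cyt = noise_sd_cyt, noise_sd_er = noise_sd_er,
                 seed = as.integer(seed), dual_sensor = dual),
            class = "protocol_spec")
}

#' Ground-truth parameters for a synthetic experiment
#'
#' The kinetic truth from which the generator builds its traces, and
#' against which recovery is judged: Bateman parameters of the cytosolic
#' transient, the ER depletion rate, basal levels, the sigmoidal onset of
#' the ER depletion (emulating the cumulative SERCA inhibition after
#' thapsigargin reaches the cytosol), and the SOCE rise rate for
#' re-addition / clearance protocols.
#'
#' @param bateman a [bateman_params()].
#' @param k_depl ER Ca2+ depletion rate (s^-1).
#' @param baseline_cyt basal cytosolic Ca2+ (uM), default 0.063.
#' @param b_er basal ER Ca2+ (uM), default 370.
#' @param onset_midpoint,onset_width logistic-onset parameters (s) of the
#'   ER depletion after the TG event; defaults 60 and 15.
#' @param soce_slope SOCE rise rate (nM/s); required by the
#'   `ca_readdition` and `clearance_assay` protocols, otherwise `NULL`.
#' @param b_iono luminal pool (uM) driving an IONO-evoked transient; when
#'   `NULL` the Bateman `b_lER` is reused.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(bateman, k_depl = 6.28e-3, baseline_cyt = 0.063,
                         b_er = 370, onset_midpoint = 60, onset_width = 15,
                         soce_slope = NULL, b_iono = NULL) {
  stopifnot(inherits(bateman, "bateman_params"))
  vals <- c(k_depl = k_depl, baseline_cyt = baseline_cyt, b_er = b_er,
            onset_midpoint = onset_midpoint, onset_width = onset_width)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ground-truth rates, levels and onset parameters must be > 0")
  }
  if (!is.null(soce_slope) && (!is.finite(soce_slope) || soce_slope <= 0)) {
    stop("soce_slope must be > 0 (nM/s) when given")
  }
  structure(list(bateman = bateman, k_depl = k_depl,
                 baseline_cyt = baseline_cyt, b_er = b_er,
                 onset_midpoint = onset_midpoint, onset_width = onset_width,
                 soce_slope = soce_slope, b_iono = b_iono),
            class = "ground_truth")
}

# integral of the logistic activation a(u) = plogis((u - m)/w) from 0 to tau,
# in closed form; log1p(exp(x)) evaluated overflow-safely.
logistic_onset_integral <- function(tau, midpoint, width) {
  l1pe <- function(x) ifelse(x > 30, x + log1p(exp(-x)), log1p(exp(x)))
  width * (l1pe((tau - midpoint) / width) - l1pe(-midpoint / width))
}

#' Noiseless ER depletion curve with sigmoidal onset
#'
#' `b_er * exp(-k_depl * s(tau))` where `s(tau)` is the closed-form
#' integral of a logistic activation: flat before the onset, sigmoidal
#' through it, and asymptotically a pure exponential decay at rate
#' `k_depl`. The analytic derivative `-k_depl * a(tau) * value` is returned
#' alongside (its maximum magnitude marks the depletion inflection point).
#'
#' @param tau time since the TG event (s), >= 0.
#' @param b_er basal ER Ca2+ (uM).
#' @param k_depl depletion rate (s^-1).
#' @param onset_midpoint,onset_width logistic onset parameters (s).
#' @return A list with `value` (uM) and `deriv` (uM/s, d\[Ca2+\]_ER/dt).
#' @export
er_depletion_curve <- function(tau, b_er, k_depl, onset_midpoint = 60,
                               onset_width = 15) {
  tau <- as.numeric(tau)
  s <- logistic_onset_integral(tau, onset_midpoint, onset_width)
  a <- stats::plogis((tau - onset_midpoint) / onset_width)
  value <- b_er * exp(-k_depl * s)
  list(value = value, deriv = -k_depl * a * value)
}

logistic_ramp <- function(tau, midpoint, width) {
  stats::plogis((tau - midpoint) / width)
}

#' Generate a synthetic paired cytosolic/ER imaging experiment
#'
#' Builds noiseless model traces from the ground truth and adds independent
#' Gaussian noise per channel and sample. The cytosolic channel is baseline
#' plus a Bateman transient starting at each stimulus event (optionally
#' shaped by a logistic onset; off by default so transients match the
#' closed-form model exactly). The ER channel (dual-sensor protocols only)
#' is flat at `b_er` before TG, then follows [er_depletion_curve()]. The
#' `clearance_assay` protocol instead produces a linear SOCE rise at
#' `soce_slope` from the re-addition event, then an exponential decay at
#' `k_clear` after the EGTA event; `ca_readdition` appends a linear SOCE
#' rise to the TG transient. Identical seeds give bit-identical output.
#'
#' @param proto a [protocol_spec()].
#' @param truth a [ground_truth()].
#' @param output `"concentration"` (default) or `"ratio"`; ratio mode also
#'   returns the traces passed through [concentration_to_ratio()].
#' @param cal_cyt,cal_er [calibration_params()] used in ratio mode
#'   (defaults: the placeholder fura2 and d1er calibrations).
#' @param cyt_onset apply the logistic onset to the cytosolic transient as
#'   well (default `FALSE`).
#' @return A list of class `synthetic_experiment`: `cyt` ([ca_trace()]),
#'   `er` ([ca_trace()] or `NULL`), `truth`, `proto`, and in ratio mode
#'   `cyt_ratio` / `er_ratio` (data.frames `time_s`, `ratio`).
#' @examples
#' tru <- ground_truth(bateman_params(2.40, 14.55e-3, 28.34e-3))
#' ex <- generate_experiment(protocol_spec("tg_zero_ca", seed = 42), tru)
#' ex$cyt
#' @export
generate_experiment <- function(proto, truth,
                                output = c("concentration", "ratio"),
                                cal_cyt = calibration_params("fura2"),
                                cal_er = calibration_params("d1er"),
                                cyt_onset = FALSE) {
  stopifnot(inherits(proto, "protocol_spec"), inherits(truth, "ground_truth"))
  output <- match.arg(output)
  if (proto$protocol_id %in% c("ca_readdition", "clearance_assay") &&
      is.null(truth$soce_slope)) {
    stop(sprintf("protocol '%s' requires a soce_slope in the ground truth",
                 proto$protocol_id))
  }
  t <- seq(0, proto$duration, by = proto$sampling_dt)
  ev <- proto$events

  cyt <- rep(truth$baseline_cyt, length(t))
  if (proto$protocol_id == "clearance_assay") {
    cyt <- cyt + clearance_assay_signal(t, ev, truth)
  } else {
    for (lab in names(ev)) {
      if (!lab %in% c("TG", "IONO")) next
      tau <- pmax(t - ev[[lab]], 0)
      on <- t >= ev[[lab]]
      p <- truth$bateman
      if (lab == "IONO" && !is.null(truth$b_iono)) {
        p <- bateman_params(truth$b_iono, p$k_leak, p$k_clear)
      }
      y <- bateman_transient(tau, p)
      if (cyt_onset) {
        y <- y * logistic_ramp(tau, truth$onset_midpoint, truth$onset_width)
      }
      cyt <- cyt + ifelse(on, y, 0)
    }
    if (proto$protocol_id == "ca_readdition") {
      tau <- pmax(t - ev[["ca_readd"]], 0)
      cyt <- cyt + truth$soce_slope / 1000 * tau
    }
  }

  er <- NULL
  if (proto$dual_sensor) {
    if (!"TG" %in% names(ev)) stop("dual-sensor protocols need a TG event")
    tau <- pmax(t - ev[["TG"]], 0)
    er <- er_depletion_curve(tau, truth$b_er, truth$k_depl,
                             truth$onset_midpoint, truth$onset_width)$value
    er[t < ev[["TG"]]] <- truth$b_er
  }

  # seeded, state-restoring noise draw: identical seed => identical bytes
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  set.seed(proto$seed)
  if (proto$noise_sd_cyt > 0) {
    cyt <- cyt + stats::rnorm(length(t), sd = proto$noise_sd_cyt)
  }
  if (!is.null(er) && proto$noise_sd_er > 0) {
    er <- er + stats::rnorm(length(t), sd = proto$noise_sd_er)
  }
  cyt <- pmax(cyt, 0)
  if (!is.null(er)) er <- pmax(er, 0)

  out <- list(cyt = ca_trace(t, cyt, "cyt", ev),
              er = if (!is.null(er)) ca_trace(t, er, "er", ev),
              truth = truth, proto = proto)
  if (output == "ratio") {
    out$cyt_ratio <- data.frame(time_s = t,
                                ratio = concentration_to_ratio(cyt, cal_cyt))
    if (!is.null(er)) {
      out$er_ratio <- data.frame(time_s = t,
                                 ratio = concentration_to_ratio(er, cal_er))
    }
  }
  class(out) <- "synthetic_experiment"
  out
}

clearance_assay_signal <- function(t, ev, truth) {
  t_r <- ev[["ca_readd"]]
  t_e <- ev[["EGTA"]]
  if (t_e <= t_r) stop("EGTA event must follow the Ca2+ re-addition")
  slope <- truth$soce_slope / 1000  # nM/s -> uM/s
  rise <- slope * (pmin(t, t_e) - t_r)
  rise[t < t_r] <- 0
  peak <- slope * (t_e - t_r)
  decay_phase <- t >= t_e
  rise[decay_phase] <- peak *
    exp(-truth$bateman$k_clear * (t[decay_phase] - t_e))
  rise
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> protocol %s, seed %d\n",
              x$proto$protocol_id, x$proto$seed))
  print(x$cyt)
  if (!is.null(x$er)) print(x$er)
  invisible(x)
}

#' Canonical fixture suite: control / 500-PURO / 1000-PURO + clearance assay
#'
#' Writes the trace files used as the package's canonical test inputs: three
#' paired cytosolic/ER dual-sensor experiments whose Bateman parameters and
#' ER depletion rates mimic the control and puromycin-treated conditions
#' (k_leak 14.55e-3 / 21.03e-3 / 30.07e-3 s^-1, b_lER 2.40 / 2.38 /
#' 0.62 uM, k_depl 6.28e-3 / 10.14e-3 / 22.51e-3 s^-1, k_clear
#' 28.34e-3 s^-1 throughout), plus one clearance-assay recording (SOCE rise
#' 29.25 nM/s). Each fixture is written in a noisy and a noiseless variant,
#' and a YAML manifest records the full ground truth and seeds.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed base seed; per-fixture seeds are derived from it.
#' @param noise_sd_cyt,noise_sd_er noise levels (uM) for the noisy
#'   variants.
#' @return The manifest (a list), invisibly; side effect: CSV trace files
#'   and `manifest.yaml` under `out_dir`.
#' @export
fixture_suite <- function(out_dir, seed = 20230327L,
                          noise_sd_cyt = 0.02, noise_sd_er = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create fixture directory")
  conds <- data.frame(
    id = c("control", "puro500", "puro1000"),
    k_leak = c(14.55e-3, 21.03e-3, 30.07e-3),
    b_lER = c(2.40, 2.38, 0.62),
    k_depl = c(6.28e-3, 10.14e-3, 22.51e-3),
    b_er = c(370, 370 * 0.85, 370 * 0.41),
    stringsAsFactors = FALSE)
  k_clear <- 28.34e-3
  manifest <- list(seed = seed, fixtures = list())
  for (i in seq_len(nrow(conds))) {
    tru <- ground_truth(
      bateman_params(conds$b_lER[i], conds$k_leak[i], k_clear),
      k_depl = conds$k_depl[i], b_er = conds$b_er[i])
    fseed <- seed + i
    files <- list()
    for (variant in c("noisy", "noiseless")) {
      proto <- protocol_spec("tg_zero_ca", seed = fseed,
        noise_sd_cyt = if (variant == "noisy") noise_sd_cyt else 0,
        noise_sd_er = if (variant == "noisy") noise_sd_er else 0)
      ex <- generate_experiment(proto, tru)
      fc <- file.path(out_dir,
                      sprintf("%s_%s_cyt.csv", conds$id[i], variant))
      fe <- file.path(out_dir,
                      sprintf("%s_%s_er.csv", conds$id[i], variant))
      write_ca_trace(ex$cyt, fc)
      write_ca_trace(ex$er, fe)
      files[[variant]] <- list(cyt = basename(fc), er = basename(fe))
    }
    manifest$fixtures[[conds$id[i]]] <- list(
      protocol = "tg_zero_ca", seed = fseed, files = files,
      events = as.list(protocol_spec("tg_zero_ca")$events),
      truth = list(b_lER = conds$b_lER[i], k_leak = conds$k_leak[i],
                   k_clear = k_clear, k_depl = conds$k_depl[i],
                   b_er = conds$b_er[i], baseline_cyt = 0.063,
                   onset_midpoint = 60, onset_width = 15),
      noise = list(sd_cyt = noise_sd_cyt, sd_er = noise_sd_er,
                   note = paste("ER noise SD is an assumed value;",
                                "not derivable from population summaries")))
  }
  tru_cl <- ground_truth(bateman_params(2.40, 14.55e-3, k_clear),
                         soce_slope = 29.25)
  for (variant in c("noisy", "noiseless")) {
    proto <- protocol_spec("clearance_assay", duration = 300,
                           seed = seed + 10L,
                           noise_sd_cyt = if (variant == "noisy")
                             noise_sd_cyt else 0)
    ex <- generate_experiment(proto, tru_cl)
    f <- file.path(out_dir, sprintf("clearance_%s_cyt.csv", variant))
    write_ca_trace(ex$cyt, f)
    manifest$fixtures[[paste0("clearance_", variant)]] <- list(
      protocol = "clearance_assay", seed = seed + 10L,
      files = list(cyt = basename(f)),
      events = as.list(protocol_spec("clearance_assay")$events),
      truth = list(soce_slope = 29.25, k_clear = k_clear,
                   baseline_cyt = 0.063),
      noise = list(sd_cyt = if (variant == "noisy") noise_sd_cyt else 0))
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
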