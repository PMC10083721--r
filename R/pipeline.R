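#' Run the full trace-analysis pipeline from a run-config file
#'
#' Executes the standard analysis chain on one experiment:
#' calibrate (optional, for raw-ratio inputs) -> baseline and transient
#' metrics -> smoothed derivatives and ER inflection point -> depletion /
#' clearance / Bateman fits -> flux estimates. Emits a human-readable
#' report (`report.txt`, every numeric field carries its unit) and a
#' machine-readable table (`report.csv`) in the configured output
#' directory.
#'
#' The run-config is a YAML file (or an equivalent named list):
#' \preformatted{
#' traces:
#'   cyt: control_cyt.csv        # delimited trace, header time_s,value,unit,channel
#'   er: control_er.csv          # optional
#'   clearance: clearance.csv    # optional clearance-assay recording
#' events: [{label: TG, time_s: 60}]
#' clearance_events: [{label: ca_readd, time_s: 30}, {label: EGTA, time_s: 90}]
#' calibration:                  # optional: only when traces hold raw ratios
#'   cyt: {sensor_id: fura2, K: 0.22, R_min: 0.5, R_max: 5}
#'   er:  {sensor_id: d1er,  K: 60,   R_min: 0.5, R_max: 5}
#' fit:
#'   k_clear: 0.02834            # s^-1, fixed in the Bateman fit
#'   derivative_window: 5        # samples
#'   window_mode: auto           # or [t_start, t_end]
#'   soce_window: 50             # s, slope window after Ca2+ re-addition
#' output_dir: out
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param config path to a YAML run-config, or a named list of the same
#'   shape.
#' @return A list of class `erleak_report` with the computed quantities
#'   (baseline, peak amplitude, AUC, t_peak, duration, k_depl/tau_depl,
#'   k_clear/tau_clear when a clearance trace is given, k_leak/b_lER,
#'   J_leak at the basal ER level, percent ER depletion at the cytosolic
#'   peak), invisibly; report files as a side effect when `output_dir` is
#'   set.
#' @export
run_analysis <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config stage: file not found: %s", config))
    }
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$traces$cyt)) {
    stop("config stage: need at least a cytosolic trace under traces$cyt")
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  events <- config_events(config$events)
  fitopt <- config$fit
  k_clear <- fitopt$k_clear %||% 28.34e-3
  dwin <- as.integer(fitopt$derivative_window %||% 5L)
  stim <- fitopt$stim_label %||% "TG"

  cal <- config$calibration
  load_trace <- function(path, ev, which) {
    tr <- tryCatch(read_ca_trace(resolve(path), events = ev),
                   error = function(e) {
                     stop(sprintf("input stage: %s", conditionMessage(e)),
                          call. = FALSE)
                   })
    if (!is.null(cal[[which]])) {
      cc <- do.call(calibration_params, cal[[which]])
      tr <- ca_trace(tr$t, ratio_to_concentration(tr$value, cc),
                     tr$channel, tr$events)
    }
    tr
  }

  cyt <- load_trace(config$traces$cyt, events, "cyt")
  er <- if (!is.null(config$traces$er)) {
    load_trace(config$traces$er, events, "er")
  }

  rep <- list()
  rep$baseline_cyt_uM <- with_stage("baseline",
                                    estimate_baseline(cyt, stim))
  tm <- with_stage("metrics", transient_metrics(cyt, stim))
  rep$peak_amplitude_uM <- tm$peak_amplitude
  rep$t_peak_s <- tm$t_peak
  rep$auc_uMs <- tm$auc
  rep$duration_s <- tm$duration

  if (!is.null(er)) {
    rep$baseline_er_uM <- with_stage("baseline",
                                     estimate_baseline(er, stim))
    infl <- with_stage("inflection", find_inflection(er, dwin, stim))
    rep$t_inflect_s <- infl$t_inflect - event_time(er, stim)
    rep$ca_er_at_inflection_uM <- infl$ca_er_at
    wmode <- fitopt$window_mode %||% "auto"
    if (!identical(wmode, "auto")) wmode <- as.numeric(unlist(wmode))
    dep <- with_stage("depletion_fit",
                      fit_depletion_rate(er, wmode, dwin, stim))
    rep$k_depl_per_s <- dep$k_depl
    rep$tau_depl_s <- dep$tau_depl
    # ER level at the cytosolic peak -> percent store depletion there
    t_at_peak <- event_time(cyt, stim) + tm$t_peak
    i_er <- which.min(abs(er$t - t_at_peak))
    rep$percent_depletion_at_cyt_peak <- with_stage(
      "depletion_percent",
      percent_depletion(rep$baseline_er_uM,
                        min(er$value[i_er], rep$baseline_er_uM)))
  }

  if (!is.null(config$traces$clearance)) {
    cev <- config_events(config$clearance_events)
    cl <- load_trace(config$traces$clearance, cev, "cyt")
    rep$soce_slope_nM_per_s <- with_stage(
      "soce",
      soce_slope(cl, fit_window = fitopt$soce_window %||% 50)$slope)
    t_e <- event_time(cl, "EGTA")
    base_cl <- mean(cl$value[cl$t < event_time(cl, "ca_readd")])
    seg <- trace_window(cl, from = t_e)
    seg <- ca_trace(seg$t, pmax(seg$value - base_cl, 1e-6), "cyt")
    clf <- with_stage("clearance_fit", fit_exponential_decay(seg))
    rep$k_clear_per_s <- clf$k
    rep$tau_clear_s <- clf$tau
  }

  bf <- with_stage("bateman_fit",
                   fit_bateman(cyt, k_clear = k_clear,
                               stim_label = stim))
  rep$k_leak_per_s <- bf$params$k_leak
  rep$tau_leak_s <- 1 / bf$params$k_leak
  rep$b_lER_uM <- bf$params$b_lER
  rep$k_clear_fixed_per_s <- bf$params$k_clear
  rep$bateman_rmse_uM <- bf$rmse
  if (!is.null(er)) {
    rep$j_leak_uM_per_s <- first_order_flux(bf$params$k_leak,
                                            rep$baseline_er_uM)
  }

  class(rep) <- "erleak_report"
  if (!is.null(config$output_dir)) {
    outd <- config$output_dir
    if (!dir.exists(outd)) outd <- file.path(base_dir, outd)
    dir.create(outd, recursive = TRUE, showWarnings = FALSE)
    write_report(rep, outd)
  }
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s stage: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

config_events <- function(ev) {
  if (is.null(ev)) return(NULL)
  if (!is.null(names(ev)) && all(vapply(ev, is.numeric, TRUE))) {
    return(unlist(ev))
  }
  stats::setNames(vapply(ev, function(e) as.numeric(e$time_s), 0),
                  vapply(ev, function(e) as.character(e$label), ""))
}

report_units <- c(
  baseline_cyt_uM = "uM", peak_amplitude_uM = "uM", t_peak_s = "s",
  auc_uMs = "uM*s", duration_s = "s", baseline_er_uM = "uM",
  t_inflect_s = "s", ca_er_at_inflection_uM = "uM",
  k_depl_per_s = "s^-1", tau_depl_s = "s",
  percent_depletion_at_cyt_peak = "%", soce_slope_nM_per_s = "nM/s",
  k_clear_per_s = "s^-1", tau_clear_s = "s", k_leak_per_s = "s^-1",
  tau_leak_s = "s", b_lER_uM = "uM", k_clear_fixed_per_s = "s^-1",
  bateman_rmse_uM = "uM", j_leak_uM_per_s = "uM/s")

write_report <- function(rep, out_dir) {
  keys <- names(rep)
  df <- data.frame(quantity = keys,
                   value = vapply(keys, function(k) rep[[k]], 0),
                   unit = unname(report_units[keys]),
                   row.names = NULL, stringsAsFactors = FALSE)
  utils::write.csv(df, file.path(out_dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  txt <- c("Thapsigargin-induced Ca2+ mobilisation: analysis report",
           strrep("-", 56),
           sprintf("%-32s %14.6g %s", df$quantity, df$value, df$unit))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(df)
}

#' @export
print.erleak_report <- function(x, ...) {
  cat("Thapsigargin-induced Ca2+ mobilisation: analysis report\n")
  for (k in names(x)) {
    cat(sprintf("  %-32s %14.6g %s\n", k, x[[k]],
                report_units[[k]] %||% ""))
  }
  invisible(x)
}
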