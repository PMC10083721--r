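#' Uniformly sampled Ca2+ concentration trace
#'
#' Container for a single-channel time series of Ca2+ concentrations, the
#' basic currency of the package. Time is in seconds, concentrations in
#' micromolar; cytosolic channels are typically in the 0.05--2 uM range and
#' ER-luminal channels in the hundreds of uM. Protocol events (stimulus
#' applications, solution changes) are carried as labelled time marks so
#' downstream analyses can anchor baselines and fit windows.
#'
#' @param t numeric vector of sample times (s), strictly increasing and
#'   uniformly spaced (relative tolerance 1e-9).
#' @param value numeric vector of concentrations (uM), same length as `t`,
#'   all finite.
#' @param channel `"cyt"` or `"er"`.
#' @param events named numeric vector (or list coercible to one) of protocol
#'   event times (s), e.g. `c(TG = 60)`. Event times must fall inside
#'   `range(t)`.
#'
#' @return An object of class `ca_trace`: a list with elements `t`, `value`,
#'   `channel`, `events` and `dt` (the sampling interval, s).
#' @examples
#' tr <- ca_trace(seq(0, 300, 3), rep(0.063, 101), "cyt", c(TG = 60))
#' tr
#' @export
ca_trace <- function(t, value, channel = c("cyt", "er"), events = NULL) {
  channel <- match.arg(channel)
  t <- as.numeric(t)
  value <- as.numeric(value)
  if (length(t) < 2L) stop("a trace needs at least two samples")
  if (length(t) != length(value)) stop("`t` and `value` lengths differ")
  if (anyNA(t) || anyNA(value) || any(!is.finite(value))) {
    stop("trace times and values must be finite")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("`t` must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1)) {
    stop("`t` must be uniformly sampled (relative tolerance 1e-9)")
  }
  events <- normalise_events(events)
  if (length(events) &&
      (any(events < t[1]) || any(events > t[length(t)]))) {
    stop("event times must lie within the trace time range")
  }
  structure(
    list(t = t, value = value, channel = channel, events = events,
         dt = dt[1]),
    class = "ca_trace"
  )
}

normalise_events <- function(events) {
  if (is.null(events) || length(events) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.list(events)) events <- unlist(events)
  ev <- as.numeric(events)
  names(ev) <- names(events)
  if (is.null(names(ev)) || any(!nzchar(names(ev)))) {
    stop("events must be a named vector of times, e.g. c(TG = 60)")
  }
  ev
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s channel: %d samples, dt = %g s, t in [%g, %g] s\n",
              x$channel, length(x$t), x$dt, x$t[1], x$t[length(x$t)]))
  cat(sprintf("  value range: [%.4g, %.4g] uM\n",
              min(x$value), max(x$value)))
  if (length(x$events)) {
    cat("  events:", paste(sprintf("%s@%gs", names(x$events), x$events),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ca_trace <- function(x, ...) {
  data.frame(time_s = x$t, value = x$value, unit = "uM",
             channel = x$channel, stringsAsFactors = FALSE)
}

#' @export
plot.ca_trace <- function(x, ...,
                          xlab = "time (s)",
                          ylab = sprintf("[Ca2+]_%s (uM)", x$channel)) {
  graphics::plot(x$t, x$value, type = "l", xlab = xlab, ylab = ylab, ...)
  if (length(x$events)) {
    graphics::abline(v = x$events, lty = 3, col = "grey40")
    graphics::mtext(names(x$events), side = 3, at = x$events, cex = 0.7)
  }
  invisible(x)
}

#' Look up an event time on a trace
#'
#' @param tr a [ca_trace()].
#' @param label event label, e.g. `"TG"`.
#' @return The event time (s).
#' @export
event_time <- function(tr, label) {
  stopifnot(inherits(tr, "ca_trace"))
  if (!label %in% names(tr$events)) {
    stop(sprintf("event '%s' not found on trace (have: %s)", label,
                 if (length(tr$events)) {
                   paste(names(tr$events), collapse = ", ")
                 } else "none"))
  }
  unname(tr$events[[label]])
}

#' Extract a time window of a trace as a new trace
#'
#' @param tr a [ca_trace()].
#' @param from,to window bounds in seconds (inclusive); `NULL` means the
#'   trace end on that side. Events outside the window are dropped.
#' @return A [ca_trace()] restricted to the window.
#' @export
trace_window <- function(tr, from = NULL, to = NULL) {
  stopifnot(inherits(tr, "ca_trace"))
  if (is.null(from)) from <- tr$t[1]
  if (is.null(to)) to <- tr$t[length(tr$t)]
  keep <- tr$t >= from - 1e-12 & tr$t <= to + 1e-12
  if (sum(keep) < 2L) stop("window contains fewer than two samples")
  ev <- tr$events[tr$events >= min(tr$t[keep]) & tr$events <= max(tr$t[keep])]
  ca_trace(tr$t[keep], tr$value[keep], tr$channel, ev)
}

#' Read a trace from a delimited text file
#'
#' Expects a header `time_s,value,unit,channel`. Values with unit `nM` are
#' converted to uM on input; all in-memory traces are in uM.
#'
#' @param path file path.
#' @param events optional named event times (s), attached to the trace
#'   (run-config files carry events separately from the trace table).
#' @param sep field separator (default comma).
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(path, events = NULL, sep = ",") {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_s", "value", "unit", "channel")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed trace file %s: needs columns %s", path,
                 paste(need, collapse = ", ")))
  }
  tvec <- suppressWarnings(as.numeric(df$time_s))
  vvec <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(tvec) | !is.finite(vvec))
  if (length(bad)) {
    stop(sprintf("malformed trace file %s: non-numeric data at line %d",
                 path, bad[1] + 1L))
  }
  df$time_s <- tvec
  df$value <- vvec
  unit <- unique(df$unit)
  if (length(unit) != 1L || !unit %in% c("uM", "nM")) {
    stop(sprintf("trace file %s: unit column must be uniformly 'uM' or 'nM'",
                 path))
  }
  val <- if (unit == "nM") df$value / 1000 else df$value
  chan <- unique(df$channel)
  if (length(chan) != 1L) stop(sprintf("trace file %s mixes channels", path))
  ca_trace(df$time_s, val, chan, events)
}

#' Write a trace to a delimited text file
#'
#' @param tr a [ca_trace()].
#' @param path output path.
#' @param unit `"uM"` (default) or `"nM"` for the on-disk values.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(tr, path, unit = c("uM", "nM")) {
  stopifnot(inherits(tr, "ca_trace"))
  unit <- match.arg(unit)
  df <- as.data.frame(tr)
  if (unit == "nM") {
    df$value <- df$value * 1000
    df$unit <- "nM"
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
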