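# shared fixtures: the control-condition kinetic parameters and small
# trace builders used across the suite
control_params <- function() bateman_params(2.40, 14.55e-3, 28.34e-3)

# values frozen from an independent dense-grid / fine-trapezoid oracle
# (dt = 0.01 s) evaluated on the difference-of-exponentials directly
CONTROL_PEAK <- 0.609790
CONTROL_T_PEAK <- 48.35
CONTROL_AUC <- 84.685956
CONTROL_GAIN <- 1.055112

bateman_trace <- function(p = control_params(), dt = 3, duration = 600,
                          baseline = 0, t_stim = NULL) {
  if (is.null(t_stim)) {
    t <- seq(0, duration, dt)
    ca_trace(t, baseline + bateman_transient(t, p), "cyt")
  } else {
    t <- seq(0, duration, dt)
    y <- baseline + ifelse(t >= t_stim,
                           bateman_transient(pmax(t - t_stim, 0), p), 0)
    ca_trace(t, y, "cyt", c(TG = t_stim))
  }
}

exp_trace <- function(k, C0 = 370, dt = 10, duration = 600,
                      channel = "er", events = c(TG = 0)) {
  t <- seq(0, duration, dt)
  ca_trace(t, C0 * exp(-k * t), channel, events)
}
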