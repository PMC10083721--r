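test_that("trace container enforces uniform sampling and event bounds", {
  expect_error(ca_trace(c(0, 1, 3), c(1, 1, 1)), "uniform")
  expect_error(ca_trace(c(0, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(ca_trace(0:10, c(rep(1, 10), NA)), "finite")
  expect_error(ca_trace(0:10, rep(1, 11), events = c(TG = 99)), "within")
  tr <- ca_trace(seq(0, 30, 3), rep(0.1, 11), "cyt", c(TG = 9))
  expect_s3_class(tr, "ca_trace")
  expect_equal(tr$dt, 3)
  expect_equal(event_time(tr, "TG"), 9)
  expect_error(event_time(tr, "IONO"), "not found")
})

test_that("trace files round-trip through the delimited format", {
  tr <- ca_trace(seq(0, 30, 3), seq(0.1, 0.2, length.out = 11), "cyt")
  f <- tempfile(fileext = ".csv")
  write_ca_trace(tr, f)
  back <- read_ca_trace(f, events = c(TG = 9))
  expect_equal(back$value, tr$value, tolerance = 1e-12)
  expect_equal(event_time(back, "TG"), 9)
  # nM on disk converts to uM in memory
  write_ca_trace(tr, f, unit = "nM")
  expect_equal(read_ca_trace(f)$value, tr$value, tolerance = 1e-12)
})

test_that("baseline is the mean of pre-stimulus samples", {
  tr <- ca_trace(seq(0, 300, 3), rep(0.063, 101), "cyt", c(TG = 60))
  expect_equal(estimate_baseline(tr), 0.063)
  # linear drift: mean of a line is its value at the window centre
  t <- seq(0, 300, 3)
  m <- 2e-4
  drift <- ca_trace(t, 0.05 + m * t, "cyt", c(TG = 60))
  pre_t <- t[t < 60]
  expect_equal(estimate_baseline(drift), 0.05 + m * mean(pre_t))
  short <- ca_trace(seq(0, 300, 3), rep(0.063, 101), "cyt", c(TG = 3))
  expect_error(estimate_baseline(short), "3 pre-stimulus")
})

test_that("baseline estimate is within sampling error for noisy traces", {
  set.seed(5)
  n_pre <- 20
  t <- seq(0, 600, 3)
  y <- 0.063 + stats::rnorm(length(t), sd = 0.005)
  tr <- ca_trace(t, y, "cyt", c(TG = t[n_pre + 1]))
  expect_lt(abs(estimate_baseline(tr) - 0.063), 3 * 0.005 / sqrt(n_pre))
})

test_that("smoothed derivative is exact on constants and ramps", {
  t <- seq(0, 300, 3)
  expect_equal(smooth_derivative(ca_trace(t, rep(1, 101)))$value,
               rep(0, 101))
  ramp <- smooth_derivative(ca_trace(t, 0.01 * t))
  expect_equal(ramp$value[4:98], rep(0.01, 95), tolerance = 1e-12)
})

test_that("smoothed derivative tracks the analytic exponential derivative", {
  k <- 6.28e-3
  t <- seq(0, 600, 10)
  C <- 370 * exp(-k * t)
  d <- smooth_derivative(ca_trace(t, C, "er"))$value
  interior <- 4:(length(t) - 3)
  expect_lt(max(abs(d[interior] + k * C[interior]) / (k * C[interior])),
            0.005)
})

test_that("inflection point detection follows the depletion derivative", {
  # pure exponential from the stimulus: -dC/dt is monotone decreasing, so
  # (without a smoothing halo) the maximum sits at the first post-stimulus
  # interior sample
  tr <- exp_trace(6.28e-3, dt = 10)
  infl <- find_inflection(tr, window = 1L)
  expect_equal(infl$index, 2L)

  # sigmoidal onset into exponential decay: compare with the analytic
  # derivative argmax of the generating curve
  t <- seq(0, 600, 10)
  tg <- 60
  tau <- pmax(t - tg, 0)
  curve <- er_depletion_curve(tau, 370, 6.28e-3, 60, 15)
  y <- ifelse(t < tg, 370, curve$value)
  tr2 <- ca_trace(t, y, "er", c(TG = tg))
  t_true <- t[which.max(ifelse(t < tg, 0, -curve$deriv))]
  infl2 <- find_inflection(tr2)
  expect_lte(abs(infl2$t_inflect - t_true), 10)

  flat <- ca_trace(t, rep(370, length(t)), "er", c(TG = tg))
  expect_error(find_inflection(flat), "no post-stimulus decay")
})

test_that("transient metrics recover the model peak and AUC", {
  tr <- bateman_trace(dt = 3, duration = 600, baseline = 0.063, t_stim = 60)
  tm <- transient_metrics(tr)
  expect_equal(tm$baseline, 0.063)
  expect_equal(tm$peak_amplitude, CONTROL_PEAK,
               tolerance = 0.01)
  expect_equal(tm$t_peak, CONTROL_T_PEAK, tolerance = 3 / CONTROL_T_PEAK)
  tm_full <- transient_metrics(tr, full_support = TRUE)
  expect_equal(tm_full$auc, CONTROL_AUC, tolerance = 0.02)
  expect_lte(tm$duration, tm_full$duration)
})

test_that("flat traces give zero metrics with a warning", {
  tr <- ca_trace(seq(0, 300, 3), rep(0.063, 101), "cyt", c(TG = 60))
  expect_warning(tm <- transient_metrics(tr), "no transient")
  expect_equal(tm$peak_amplitude, 0)
  expect_equal(tm$auc, 0)
  expect_true(tm$flat)
})

test_that("metrics are invariant under a constant offset", {
  tr <- bateman_trace(dt = 3, duration = 600, baseline = 0.063, t_stim = 60)
  shifted <- ca_trace(tr$t, tr$value + 0.5, "cyt", tr$events)
  a <- transient_metrics(tr)
  b <- transient_metrics(shifted)
  expect_equal(b$peak_amplitude, a$peak_amplitude, tolerance = 1e-12)
  expect_equal(b$auc, a$auc, tolerance = 1e-12)
  expect_equal(b$baseline, a$baseline + 0.5)
})

test_that("percent depletion arithmetic", {
  expect_equal(round(percent_depletion(370, 348)), 6)
  expect_equal(percent_depletion(370, 348), 100 * 22 / 370)
  expect_equal(percent_depletion(100, 100), 0)
  expect_equal(percent_depletion(100, 50), 50)
  expect_error(percent_depletion(100, 120), "<=")
  expect_error(percent_depletion(0, 0), "> 0")
})

test_that("SOCE slope recovers linear rises", {
  t <- seq(0, 300, 3)
  readd <- 60
  rise <- ifelse(t >= readd, 29.25e-3 * (t - readd), 0)
  tr <- ca_trace(t, 0.063 + rise, "cyt", c(ca_readd = readd))
  expect_equal(soce_slope(tr, fit_window = 60)$slope, 29.25,
               tolerance = 1e-9)
  flat <- ca_trace(t, rep(0.063, length(t)), "cyt", c(ca_readd = readd))
  expect_equal(soce_slope(flat, fit_window = 60)$slope, 0)
  expect_error(soce_slope(tr, fit_window = 500), "beyond")

  set.seed(9)
  t20 <- seq(0, 57, 3)  # 20 samples
  y <- 0.1 + 51.42e-3 * t20 + stats::rnorm(20, sd = 5e-3)
  tr_noisy <- ca_trace(t20, y, "cyt", c(ca_readd = 0))
  fit <- soce_slope(tr_noisy, fit_window = 57)
  expect_lt(abs(fit$slope - 51.42), 3 * fit$se)
})
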