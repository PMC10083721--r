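test_that("noiseless generator output equals the closed-form model", {
  tru <- ground_truth(control_params())
  proto <- protocol_spec("tg_zero_ca", noise_sd_cyt = 0, noise_sd_er = 0,
                         seed = 1)
  ex <- generate_experiment(proto, tru)
  t <- ex$cyt$t
  tg <- event_time(ex$cyt, "TG")
  expected <- 0.063 + ifelse(t >= tg,
                             bateman_transient(pmax(t - tg, 0),
                                               control_params()), 0)
  expect_equal(ex$cyt$value, expected, tolerance = 1e-15)
  expect_equal(ex$er$value[t < tg], rep(370, sum(t < tg)))
  # far past the onset the ER channel decays at k_depl
  late <- t > tg + 300
  lograt <- diff(log(ex$er$value[late]))
  expect_equal(lograt / -ex$er$dt, rep(tru$k_depl, sum(late) - 1),
               tolerance = 1e-3)
})

test_that("seeds make the generator reproducible", {
  tru <- ground_truth(control_params())
  a <- generate_experiment(protocol_spec("tg_zero_ca", seed = 99), tru)
  b <- generate_experiment(protocol_spec("tg_zero_ca", seed = 99), tru)
  c <- generate_experiment(protocol_spec("tg_zero_ca", seed = 100), tru)
  expect_identical(a$cyt$value, b$cyt$value)
  expect_identical(a$er$value, b$er$value)
  expect_false(identical(a$cyt$value, c$cyt$value))
  # the generator does not disturb the session RNG stream
  set.seed(123); before <- stats::rnorm(1)
  set.seed(123)
  invisible(generate_experiment(protocol_spec("tg_zero_ca", seed = 5), tru))
  expect_identical(stats::rnorm(1), before)
})

test_that("sampling defaults follow the sensor configuration", {
  expect_equal(protocol_spec("tg_zero_ca")$sampling_dt, 10)  # dual sensor
  expect_equal(protocol_spec("tg_with_ca")$sampling_dt, 3)   # FURA-2 alone
  expect_equal(protocol_spec("clearance_assay")$sampling_dt, 3)
})

test_that("noise realisations match the configured sigma", {
  tru <- ground_truth(control_params())
  proto <- protocol_spec("tg_with_ca", sampling_dt = 3, duration = 600,
                         noise_sd_cyt = 0.02, seed = 7)
  noiseless <- generate_experiment(
    protocol_spec("tg_with_ca", sampling_dt = 3, duration = 600,
                  noise_sd_cyt = 0, seed = 7), tru)
  noisy <- generate_experiment(proto, tru)
  res <- noisy$cyt$value - noiseless$cyt$value
  expect_gte(length(res), 200)
  expect_lt(abs(stats::sd(res) - 0.02) / 0.02, 0.10)
})

test_that("ratio output mode round-trips through the calibration", {
  tru <- ground_truth(control_params())
  cal <- calibration_params("fura2", K = 0.22, R_min = 0.5, R_max = 5)
  ex <- generate_experiment(protocol_spec("tg_zero_ca", seed = 3,
                                          noise_sd_cyt = 0,
                                          noise_sd_er = 0),
                            tru, output = "ratio", cal_cyt = cal)
  expect_true(all(ex$cyt_ratio$ratio > cal$R_min - 1e-12))
  expect_true(all(ex$cyt_ratio$ratio < cal$R_max))
  back <- ratio_to_concentration(ex$cyt_ratio$ratio, cal)
  expect_equal(back, ex$cyt$value, tolerance = 1e-10)
})

test_that("protocol/truth combinations are validated", {
  tru <- ground_truth(control_params())  # no soce_slope
  expect_error(generate_experiment(protocol_spec("clearance_assay"), tru),
               "soce_slope")
  expect_error(generate_experiment(protocol_spec("ca_readdition"), tru),
               "soce_slope")
})

test_that("clearance-assay protocol rises at the SOCE slope then decays", {
  tru <- ground_truth(control_params(), soce_slope = 29.25)
  proto <- protocol_spec("clearance_assay", duration = 300,
                         noise_sd_cyt = 0, seed = 2)
  ex <- generate_experiment(proto, tru)
  sl <- soce_slope(ex$cyt, fit_window = 50)
  expect_equal(sl$slope, 29.25, tolerance = 1e-9)
  t_e <- event_time(ex$cyt, "EGTA")
  seg <- trace_window(ex$cyt, from = t_e)
  seg <- ca_trace(seg$t, seg$value - 0.063, "cyt")
  fit <- fit_exponential_decay(seg)
  expect_equal(fit$k, control_params()$k_clear, tolerance = 1e-8)
})

test_that("fixture suite writes the canonical set and honest manifest", {
  dir <- withr::local_tempdir()
  man <- fixture_suite(dir)
  expect_setequal(names(man$fixtures),
                  c("control", "puro500", "puro1000",
                    "clearance_noisy", "clearance_noiseless"))
  paired <- man$fixtures[c("control", "puro500", "puro1000")]
  expect_true(all(vapply(paired, function(f)
    file.exists(file.path(dir, f$files$noisy$er)), TRUE)))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))

  # noiseless self-consistency: fitting returns the manifest truth
  for (id in names(paired)) {
    f <- paired[[id]]
    tr <- read_ca_trace(file.path(dir, f$files$noiseless$cyt),
                        events = unlist(f$events))
    fit <- fit_bateman(tr, k_clear = f$truth$k_clear)
    expect_equal(fit$params$k_leak, f$truth$k_leak, tolerance = 1e-6)
    expect_equal(fit$params$b_lER, f$truth$b_lER, tolerance = 1e-6)
  }
})

test_that("noisy fixtures are recovered within their precision", {
  dir <- withr::local_tempdir()
  man <- fixture_suite(dir)
  for (id in c("control", "puro500", "puro1000")) {
    f <- man$fixtures[[id]]
    tr <- read_ca_trace(file.path(dir, f$files$noisy$cyt),
                        events = unlist(f$events))
    fit <- fit_bateman(tr, k_clear = f$truth$k_clear)
    err <- abs(fit$params$k_leak - f$truth$k_leak)
    # single-draw precision is set by the parameter's standard error
    # (dual-sensor sampling leaves ~55 informative points per transient)
    se <- sqrt(fit$vcov["kl", "kl"])
    expect_lt(err, 3 * se)
    expect_lt(se / f$truth$k_leak, 0.06)
  }
  # ER depletion rates from the noisy ER channels, against manifest truth
  for (id in c("control", "puro500", "puro1000")) {
    f <- man$fixtures[[id]]
    er <- read_ca_trace(file.path(dir, f$files$noisy$er),
                        events = unlist(f$events))
    dep <- fit_depletion_rate(er)
    expect_lt(abs(dep$k_depl - f$truth$k_depl) / f$truth$k_depl, 0.25)
  }
})
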