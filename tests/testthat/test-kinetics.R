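test_that("exponential decay reports value and time constant", {
  d <- exponential_decay(0, C0 = 0.5, k = 28.34e-3)
  expect_equal(d$value, 0.5)
  expect_equal(exponential_decay(1 / 0.01, C0 = 2, k = 0.01)$value,
               2 / exp(1))
  # k = 6.06e-3 s^-1 corresponds to tau = 165 s
  d <- exponential_decay(165, C0 = 1, k = 6.06e-3)
  expect_equal(round(d$tau), 165)
  expect_equal(d$value, exp(-6.06e-3 * 165))
  expect_error(exponential_decay(1, 1, k = 0), "positive")
  expect_error(exponential_decay(1, 1, k = -0.1), "positive")
})

test_that("first-order flux reproduces leak and clearance magnitudes", {
  expect_equal(first_order_flux(21e-3, 370), 7.77)
  j_clear <- first_order_flux(28.34e-3, 0.45) * 1000  # uM/s -> nM/s
  expect_equal(j_clear, 12.753)
  expect_gte(j_clear, 10)
  expect_lte(j_clear, 13)
  expect_equal(first_order_flux(0, 5), 0)
  expect_error(first_order_flux(-1e-3, 1), ">= 0")
  expect_error(first_order_flux(1e-3, -1), ">= 0")
})

test_that("Bateman transient matches the dense-grid oracle at the peak", {
  p <- control_params()
  expect_equal(bateman_transient(0, p), 0)
  an <- bateman_analytics(p)
  expect_equal(an$t_peak, CONTROL_T_PEAK, tolerance = 0.01 / CONTROL_T_PEAK)
  expect_equal(an$peak, CONTROL_PEAK, tolerance = 1e-5)
  t <- seq(0, 2000, 0.5)
  y <- bateman_transient(t, p)
  expect_true(all(y >= 0))
  expect_lt(y[length(y)], 1e-6)
})

test_that("equal-rate limit peaks at b_lER/e at t = 1/k", {
  k <- 0.02
  p <- bateman_params(1.5, k, k)
  expect_equal(bateman_transient(1 / k, p), 1.5 / exp(1))
  an <- bateman_analytics(p)
  expect_equal(an$t_peak, 1 / k)
  expect_equal(an$peak, 1.5 / exp(1))
  expect_identical(an$gain, Inf)
})

test_that("degenerate-limit branch is continuous", {
  k <- 0.02
  b <- 2
  t <- seq(0, 400, 1)
  lim <- bateman_transient(t, bateman_params(b, k, k))
  peak <- b / exp(1)
  for (eps in c(1e-9, -1e-9)) {
    near <- bateman_transient(t, bateman_params(b, k, k * (1 + eps)))
    expect_lt(max(abs(near - lim)), 1e-7 * peak)
  }
})

test_that("rate exchange with a rescaled pool reproduces the same curve", {
  # the curve pins down the rates only as an unordered pair: swapping them
  # while holding b_lER * k_leak fixed is indistinguishable (flip-flop
  # identifiability hazard)
  t <- seq(0, 500, 2)
  a <- bateman_transient(t, bateman_params(1.8, 0.012, 0.03))
  b <- bateman_transient(t, bateman_params(1.8 * 0.012 / 0.03, 0.03, 0.012))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("component breakdown reconstructs the transient", {
  p <- control_params()
  t <- seq(0, 600, 3)
  cp <- bateman_components(t, p)
  expect_equal(cp$Fa[1], 1)
  expect_equal(cp$Fb[1], 1)
  expect_equal(cp$Fc[1], 0)
  expect_equal(cp$Fd[1], 0)
  expect_equal(cp$gain, CONTROL_GAIN, tolerance = 1e-5)
  expect_equal(p$b_lER * cp$Fd, bateman_transient(t, p), tolerance = 1e-12)
  nz <- cp$Fc != 0
  expect_equal(cp$Fd[nz] / cp$Fc[nz], rep(cp$gain, sum(nz)))
  expect_error(bateman_components(t, bateman_params(1, 0.02, 0.02)),
               "degenerate")
})

test_that("closed-form AUC and peak agree with numerical integration", {
  set.seed(42)
  for (i in 1:50) {
    kl <- stats::runif(1, 2e-3, 50e-3)
    kc <- stats::runif(1, 2e-3, 50e-3)
    if (abs(kc - kl) < 1e-4) kc <- kc + 1e-3
    b <- stats::runif(1, 0.1, 5)
    p <- bateman_params(b, kl, kc)
    tmax <- 20 / min(kl, kc)
    t <- seq(0, tmax, length.out = 20000)
    y <- bateman_transient(t, p)
    num <- sum((y[-1] + y[-length(y)]) / 2 * diff(t))
    expect_equal(bateman_analytics(p)$auc, num,
                 tolerance = 1e-5)
  }
})

test_that("analytic peak location matches grid argmax within one step", {
  set.seed(43)
  for (i in 1:20) {
    p <- bateman_params(stats::runif(1, 0.5, 3),
                        stats::runif(1, 5e-3, 30e-3),
                        stats::runif(1, 5e-3, 40e-3))
    t <- seq(0, 1500, 0.01)
    i_max <- which.max(bateman_transient(t, p))
    expect_lt(abs(bateman_analytics(p)$t_peak - t[i_max]), 0.01 + 1e-9)
  }
})

test_that("phase diagram reproduces amplification and attenuation", {
  grid <- seq(8e-3, 35e-3, by = 3e-3)
  pd_const <- phase_diagram(grid, b_lER = 2.40, k_clear = 28e-3)
  expect_equal(nrow(pd_const$metrics), 10)
  expect_equal(length(unique(pd_const$transients$k_leak)), 10)
  expect_true(all(diff(pd_const$metrics$peak) > 0))
  expect_true(all(diff(pd_const$metrics$t_peak) < 0))
  expect_true(all(diff(pd_const$metrics$duration) <= 0))

  pd_decl <- phase_diagram(grid, b_lER = 2.40, k_clear = 28e-3,
                           b_schedule = "declining")
  pk <- pd_decl$metrics$peak
  i_max <- which.max(pk)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(pk))
  expect_true(all(diff(pk[1:i_max]) > 0))
  expect_true(all(diff(pk[i_max:length(pk)]) < 0))
  # shape (normalised time course) is set by k_leak only, not by b_lER
  expect_equal(pd_decl$metrics$t_peak, pd_const$metrics$t_peak)
})
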