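interior <- function(x, frac = 0.1) {
  n <- length(x)
  seq(floor(frac * n) + 1L, ceiling((1 - frac) * n))
}
rms <- function(x) sqrt(mean(x^2))

test_that("baseline-wander spline tracks smooth trends", {
  fs <- 200
  # all-zero signal -> all-zero estimate
  expect_equal(estimate_bw(numeric(10 * fs), fs)$values, numeric(10 * fs))
  # linear ramp: collinear nodes give back the ramp on interior samples
  t <- (0:(10 * fs - 1)) / fs
  ramp <- 0.1 * t
  est <- estimate_bw(ramp, fs)$values
  i <- interior(ramp)
  expect_lt(max(abs(est[i] - ramp[i])), 1e-6)
  # 0.2 Hz drift: RMSE <= 0.05 mV on the interior 80%
  t30 <- (0:(30 * fs - 1)) / fs
  drift <- 0.5 * sin(2 * pi * 0.2 * t30)
  est30 <- estimate_bw(drift, fs)$values
  i30 <- interior(drift)
  expect_lt(rms(est30[i30] - drift[i30]), 0.05)
  # too-short input
  expect_error(estimate_bw(numeric(100), fs), "too short")
})

test_that("notch residual isolates the mains component", {
  fs <- 200
  # DC passes the notch: residual ~ 0 after edge trim
  dc <- estimate_pli(rep(1, 60 * fs), fs)$values
  expect_lt(max(abs(dc[interior(dc)])), 1e-6)
  # pure 50 Hz tone: residual RMS within 10% of 1/sqrt(2)
  t <- (0:(20 * fs - 1)) / fs
  tone <- sin(2 * pi * 50 * t)
  p <- estimate_pli(tone, fs)$values
  expect_equal(rms(p[interior(p)]), sqrt(0.5), tolerance = 0.1)
  # 1 Hz + 50 Hz mixture: residual correlates with the 50 Hz part
  mix <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 50 * t)
  pm <- estimate_pli(mix, fs)$values
  i <- interior(pm)
  expect_gt(cor(pm[i], (0.2 * sin(2 * pi * 50 * t))[i]), 0.95)
  # out-of-band 5 Hz tone is barely touched
  five <- sin(2 * pi * 5 * t)
  p5 <- estimate_pli(five, fs)$values
  expect_lt(rms(p5[i]) / rms(five[i]), 0.05)
  # undersampled configuration
  expect_error(estimate_pli(numeric(1000), fs = 90, f0 = 50), "notch")
})

test_that("SDN block statistic matches hand computation and known noise", {
  # constant signal -> identically zero
  expect_equal(estimate_sdn(rep(3.3, 400), 200)$values, numeric(400))
  # fs = 4, blocks of 2 samples all {0, 2}: sd = sqrt(2), group spread 0
  x <- rep(c(0, 2), 20)
  expect_equal(estimate_sdn(x, 4)$values, rep(sqrt(2), 40), tolerance = 1e-12)
  # iid Gaussian sigma = 1: mean SDN in [1.0, 1.2] (Monte-Carlo-frozen band)
  set.seed(101)
  g <- estimate_sdn(rnorm(60 * 200), 200)$values
  expect_gt(mean(g), 1.0)
  expect_lt(mean(g), 1.2)
  # configuration errors
  expect_error(estimate_sdn(numeric(100), fs = 2, block_s = 0.5), "at least 2")
})

test_that("naive amplitude is the elementwise absolute value", {
  expect_equal(naive_amplitude(c(-0.2, 0.1, 0)), c(0.2, 0.1, 0))
  expect_equal(naive_amplitude(numeric(5)), numeric(5))
  sdn <- estimate_sdn(rnorm(2000), 200)
  expect_equal(naive_amplitude(sdn), sdn$values)  # idempotent on >= 0
})

test_that("decomposition residual excludes most modelled noise", {
  fs <- 200
  rec0 <- ecg_record(numeric(10 * fs), fs)
  d0 <- decompose(rec0)
  expect_equal(d0$bw$values, numeric(10 * fs))
  expect_equal(d0$pli$values, numeric(10 * fs))
  expect_equal(d0$sdn$values, numeric(10 * fs))
  expect_equal(d0$residual, numeric(10 * fs))

  t <- (0:(30 * fs - 1)) / fs
  i <- interior(t)
  tone <- sin(2 * pi * 50 * t)
  dt <- decompose(ecg_record(tone, fs))
  expect_lt(rms(dt$residual[i]) / rms(tone[i]), 0.15)

  both <- 0.05 * t + tone
  db <- decompose(ecg_record(both, fs))
  expect_lt(rms(db$residual[i]) / rms(both[i]), 0.20)
})

test_that("estimators are positively homogeneous, length-preserving, and SDN shift-invariant", {
  set.seed(5)
  fs <- 200
  x <- rnorm(20 * fs) + 0.5 * sin(2 * pi * 0.3 * (0:(20 * fs - 1)) / fs)
  for (c_scale in c(0.5, 3)) {
    expect_equal(estimate_bw(c_scale * x, fs)$values,
                 c_scale * estimate_bw(x, fs)$values, tolerance = 1e-9)
    expect_equal(estimate_pli(c_scale * x, fs)$values,
                 c_scale * estimate_pli(x, fs)$values, tolerance = 1e-9)
    expect_equal(estimate_sdn(c_scale * x, fs)$values,
                 c_scale * estimate_sdn(x, fs)$values, tolerance = 1e-9)
  }
  expect_equal(estimate_sdn(x + 7.5, fs)$values, estimate_sdn(x, fs)$values,
               tolerance = 1e-9)
  expect_true(all(estimate_sdn(x, fs)$values >= 0))
  for (f in list(estimate_bw, estimate_pli, estimate_sdn))
    expect_length(f(x, fs)$values, length(x))
})
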