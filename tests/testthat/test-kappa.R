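test_that("a unit-slope ramp gives kappa = 1 exactly at every time scale", {
  ramp <- generate_segment(synth_spec("ramp", slope = 1))
  for (dt in default_delta_ts()) {
    ks <- kappa_series(ramp, dt)
    expect_equal(ks$n_excluded, 0)
    expect_true(all(abs(ks$values - 1) < 1e-12))
    s <- kappa_summary(ks)
    expect_equal(s$kappa_avg, 1, tolerance = 1e-12)
    expect_equal(s$low_it_fraction, 0)
  }
})

test_that("an alternating 0/2 signal gives kappa = ln2/ln dt with nothing excluded", {
  alt <- generate_segment(synth_spec("alternating", amplitude = 2))
  ks <- kappa_series(alt, 0.004)
  expected <- log(2) / log(0.004)  # 0.693147 / -5.521461
  expect_equal(expected, -0.1255369, tolerance = 1e-6)
  expect_true(all(abs(ks$values - expected) < 1e-12))
  expect_equal(ks$n_excluded, 0)
  s <- kappa_summary(ks, low_threshold = 0.2)
  expect_equal(s$kappa_avg, expected)
  expect_equal(s$low_it_fraction, 1)
})

test_that("a constant signal excludes every instant and summarizing it is an error", {
  const <- voltage_segment(rep(3.3, 15000), fs = 250)
  ks <- kappa_series(const, 0.004)
  expect_length(ks$values, 0)
  expect_equal(ks$n_excluded, ks$n_total)
  expect_error(kappa_summary(ks), "degenerate segment",
               class = "iekappa_degenerate_error")
})

test_that("interval validation: dt = 1 s, sub-sample lags, and lags beyond the segment", {
  seg <- voltage_segment(rnorm(15000), fs = 250)
  expect_error(kappa_series(seg, 1), "log\\(delta_t\\) = 0",
               class = "iekappa_param_error")
  expect_error(kappa_series(seg, 0.0001), "zero-sample lag",
               class = "iekappa_param_error")
  expect_error(kappa_series(seg, 100), "shorter than",
               class = "iekappa_param_error")
  # a dt that is not a whole number of samples needs the explicit override
  expect_error(kappa_series(seg, 0.0045), "whole number of samples",
               class = "iekappa_param_error")
  ks <- kappa_series(seg, 0.0045, allow_lag_rounding = TRUE)
  expect_equal(ks$lag_samples, 1L)
})

test_that("candidate-instant bookkeeping: values + excluded = n - lag", {
  seg <- voltage_segment(round(rnorm(15000), 1), fs = 250)  # quantized: ties
  for (dt in c(0.004, 0.4, 4)) {
    ks <- kappa_series(seg, dt)
    expect_identical(length(ks$values) + ks$n_excluded, ks$n_total)
    expect_true(all(is.finite(ks$values)))
  }
  ks4 <- kappa_series(seg, 4)
  expect_equal(ks4$n_total, 15000 - 1000)
  expect_gt(kappa_series(seg, 0.004)$n_excluded, 0)
})

test_that("white Gaussian noise matches the closed-form mean kappa", {
  wn <- generate_segment(synth_spec("white_noise", sigma = 1, seed = 2024))
  s <- kappa_summary(kappa_series(wn, 0.004))
  expect_equal(expected_kappa_white_noise(1, 0.004), 0.052270,
               tolerance = 1e-5)
  expect_equal(s$kappa_avg, expected_kappa_white_noise(1, 0.004),
               tolerance = 0.01 / abs(expected_kappa_white_noise(1, 0.004)))
})

test_that("rescaling the voltage shifts every kappa by ln(a)/ln(dt) exactly", {
  wn <- generate_segment(synth_spec("white_noise", sigma = 1, seed = 11))
  for (a in c(0.01, 3.7)) {
    scaled <- voltage_segment(a * wn$samples, fs = wn$fs)
    for (dt in c(0.004, 4)) {
      k0 <- kappa_series(wn, dt)$values
      k1 <- kappa_series(scaled, dt)$values
      expect_equal(k1, k0 + log(a) / log(dt), tolerance = 1e-12)
    }
  }
})

test_that("the mean is a pure reduction: invariant to sample-order permutation of values", {
  wn <- generate_segment(synth_spec("white_noise", seed = 5))
  ks <- kappa_series(wn, 0.04)
  set.seed(1)
  ks_perm <- ks
  ks_perm$values <- sample(ks$values)
  expect_equal(kappa_summary(ks)$kappa_avg, kappa_summary(ks_perm)$kappa_avg)
  expect_equal(kappa_summary(ks)$low_it_fraction,
               kappa_summary(ks_perm)$low_it_fraction)
})

test_that("multiscale_summaries emits one labeled row per scale and tags failing scales", {
  ramp <- generate_segment(synth_spec("ramp"))
  s <- multiscale_summaries(ramp)
  expect_equal(nrow(s), 4)
  expect_equal(s$delta_t_s, default_delta_ts())
  expect_true(all(abs(s$kappa_avg - 1) < 1e-12))
  err <- tryCatch(multiscale_summaries(ramp, delta_ts = c(0.004, 1)),
                  error = identity)
  expect_s3_class(err, "iekappa_param_error")
  expect_match(conditionMessage(err), "delta_t_s = 1")
})

test_that("power-law increment signals return kappa0 + ln(c)/ln(dt) at the declared lag", {
  for (seed in 1:3) {
    k0 <- 0.37; cc <- 2.5; dt <- 0.004
    seg <- generate_segment(synth_spec("powerlaw_increment", kappa0 = k0,
                                       c = cc, lag_delta_t_s = dt,
                                       seed = seed))
    ks <- kappa_series(seg, dt)
    expect_equal(max(abs(ks$values - (k0 + log(cc) / log(dt)))), 0,
                 tolerance = 1e-12)
  }
  # with c = 1 the recovery is exact
  seg1 <- generate_segment(synth_spec("powerlaw_increment", kappa0 = 0.8,
                                      c = 1, lag_delta_t_s = 0.04, seed = 4))
  expect_true(all(abs(kappa_series(seg1, 0.04)$values - 0.8) < 1e-12))
})

test_that("fBm mean kappa follows H + (ln sigma + E ln|Z|)/ln dt within Monte-Carlo error", {
  h <- 0.5; sigma <- 1
  dts <- c(0.004, 0.04)
  for (dt in dts) {
    means <- vapply(1:10, function(seed) {
      kappa_summary(kappa_series(quick_fbm(h, sigma, seed), dt))$kappa_avg
    }, 1)
    se <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - expected_kappa_fbm(h, sigma, dt)), 3 * se)
  }
})

test_that("Hurst regression of mean log increments on log dt recovers H", {
  for (h in c(0.3, 0.7)) {
    est <- mean(vapply(1:10, function(seed)
      estimate_hurst(quick_fbm(h, sigma = 0.1, seed = 100 + seed)), 1))
    expect_lt(abs(est - h), 0.05)
  }
})

test_that("summary TSVs append and read back", {
  wn <- generate_segment(synth_spec("white_noise", seed = 8))
  s <- multiscale_summaries(wn)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s[1:2, ], f)
  write_summary_tsv(s[3:4, ], f)
  back <- read_summary_tsv(f)
  expect_equal(nrow(back), 4)
  expect_equal(back$kappa_avg, signif(s$kappa_avg, 6))
})
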