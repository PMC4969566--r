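test_that("KDE of a standard normal sample matches the analytic density at 0", {
  set.seed(42)
  p <- estimate_pdf(rnorm(1e5))
  at0 <- approx(p$grid, p$density, xout = 0)$y
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.01 / 0.39894)
})

test_that("KDE densities are nonnegative, on an even grid, and integrate to ~1", {
  set.seed(7)
  samples <- list(rnorm(500), rexp(3000), runif(50, -2, 2),
                  c(rnorm(1000, -3, 0.1), rnorm(1000, 3, 0.1)))
  for (v in samples) {
    p <- estimate_pdf(v)
    expect_true(all(p$density >= 0))
    steps <- diff(p$grid)
    expect_lt(diff(range(steps)), 1e-8 * mean(steps))
    integral <- sum(diff(p$grid) *
                      (head(p$density, -1) + tail(p$density, -1)) / 2)
    expect_gte(integral, 0.98)
    expect_lte(integral, 1.02)
  }
})

test_that("KDE equivariance: rescaling the sample by a rescales the density curve", {
  set.seed(3)
  v <- rnorm(20000)
  a <- 2.5
  p1 <- estimate_pdf(v)
  p2 <- estimate_pdf(a * v)
  # p2(x) should equal p1(x/a)/a
  ref <- approx(p1$grid, p1$density, xout = p2$grid / a)$y / a
  keep <- !is.na(ref)
  expect_equal(p2$density[keep], ref[keep], tolerance = 0.02)
})

test_that("degenerate kappa samples are rejected by the KDE", {
  expect_error(estimate_pdf(rep(1, 100)), "zero spread",
               class = "iekappa_degenerate_error")
  expect_error(estimate_pdf(rnorm(5)), "at least 10",
               class = "iekappa_degenerate_error")
})

test_that("the periodogram peaks at the frequency of a planted cosine, matching a DFT oracle", {
  grid <- seq(0, 1, length.out = 512)
  pdf <- structure(list(grid = grid, density = 1 + 0.3 * cos(2 * pi * 5 * grid),
                        bandwidth = 0.01, n_sample = 512L),
                   class = "pdf_estimate")
  pg <- lomb_scargle(pdf)
  f_hat <- pg$frequencies[which.max(pg$power)]
  step <- pg$frequencies[2] - pg$frequencies[1]
  expect_lte(abs(f_hat - 5), step + 1e-12)
  # independent check: plain DFT on the same even grid finds the same peak
  f_dft <- dft_peak_frequency(grid, pdf$density)
  expect_lte(abs(f_hat - f_dft), 1 / diff(range(grid)))
})

test_that("the periodogram frequency grid follows the oversampled recipe", {
  set.seed(1)
  p <- estimate_pdf(rnorm(1000), n_grid = 256)
  pg <- lomb_scargle(p, oversample = 4, hifac = 1)
  span <- diff(range(p$grid))
  expect_equal(pg$frequencies[1], 1 / (span * 4))
  expect_equal(length(pg$frequencies), 4 * 256 / 2)
  expect_true(all(pg$power >= 0))
})

test_that("a constant density has no periodogram", {
  pdf <- structure(list(grid = seq(0, 1, length.out = 128),
                        density = rep(1, 128), bandwidth = 0.1,
                        n_sample = 100L),
                   class = "pdf_estimate")
  expect_error(lomb_scargle(pdf), "constant density",
               class = "iekappa_degenerate_error")
})

test_that("white-noise input yields mean normalized power near 1", {
  set.seed(99)
  grid <- seq(0, 1, length.out = 256)
  means <- replicate(40, {
    pdf <- structure(list(grid = grid, density = rnorm(256),
                          bandwidth = 0.01, n_sample = 256L),
                     class = "pdf_estimate")
    mean(lomb_scargle(pdf)$power)
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1), 3 * se)
})

test_that("the peak-significance threshold matches its closed form", {
  z <- ls_threshold(2 * 512, p_cut = 0.01)
  expect_equal(z, -log(1 - 0.99^(1 / 1024)))
  expect_equal(z, 11.532, tolerance = 1e-4)
  # inverting back recovers the false-alarm probability
  expect_lt(abs(1 - (1 - exp(-z))^1024 - 0.01), 1e-10)
})

test_that("significant power sums powers at or above the cutoff, boundary inclusive", {
  # place one power exactly on the p = 0.01 cutoff: it must be included
  z <- ls_threshold(2 * 512, 0.01)
  pg <- structure(list(frequencies = 1:5, power = c(0.5, z, 1, z + 2, 0.1),
                       n_grid = 512L, span = 1, oversample = 4, hifac = 1,
                       m_independent = NA, z_threshold = NA,
                       significant_power = NA, p_cut = NA),
                  class = "periodogram_result")
  out <- significant_power(pg, pdf_points = 512, p_cut = 0.01)
  expect_equal(out$z_threshold, z)
  expect_equal(out$m_independent, 1024L)
  expect_equal(out$significant_power, z + (z + 2))  # boundary value counts

  low <- structure(pg, class = "periodogram_result")
  low$power <- rep(0.5, 5)
  none <- significant_power(low, pdf_points = 512, p_cut = 0.01)
  expect_equal(none$significant_power, 0)

  tz <- significant_power(pg, pdf_points = 512, p_cut = 0.01,
                          area = "trapezoid")
  expect_equal(tz$significant_power, (z + z + 2) * 1)
})

test_that("significant power never increases when p_cut decreases", {
  set.seed(12)
  pg <- kappa_periodicity(comb_sample(), p_cut = 0.05)
  prev <- Inf
  for (p_cut in c(0.05, 0.01, 0.001, 1e-6)) {
    s <- significant_power(pg, p_cut = p_cut)$significant_power
    expect_lte(s, prev + 1e-12)
    expect_lte(s, sum(pg$power))
    prev <- s
  }
})

test_that("a comb-structured kappa distribution produces a significant peak at 1/spacing", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    pg <- kappa_periodicity(comb_sample(spacing = 0.1))
    step <- pg$frequencies[2] - pg$frequencies[1]
    sig <- pg$power >= pg$z_threshold
    any(sig & abs(pg$frequencies - 10) <= step + 1e-9)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
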