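test_that("penalised B-spline smoothing reproduces constants and interpolates when saturated", {
  g <- default_psd_grid()
  basis <- bspline_basis(g)
  for (pen in c(0, 1e-2, 10)) {
    sm <- bspline_smooth(rep(3.2, length(g)), basis, pen)
    expect_equal(as.numeric(sm$smoothed), rep(3.2, length(g)), tolerance = 1e-10)
  }
  sat <- bspline_basis(g, n_basis = length(g))
  y <- sin(g / 2) + cos(g / 7)
  sm <- bspline_smooth(y, sat, penalty = 0)
  expect_equal(as.numeric(sm$smoothed), y, tolerance = 1e-8)
})

test_that("residual sum of squares is nondecreasing in the penalty", {
  g <- default_psd_grid()
  basis <- bspline_basis(g)
  set.seed(11)
  y <- sin(g / 3) + rnorm(length(g), 0, 0.2)
  rss <- vapply(10^seq(-4, 2), function(pen) {
    sm <- bspline_smooth(y, basis, pen)
    sum((y - sm$smoothed)^2)
  }, 0)
  expect_true(all(diff(rss) >= -1e-10))
})

test_that("spectral fit recovers a pure aperiodic spectrum exactly", {
  g <- default_psd_grid()
  y <- simulate_raw_psd(g, offset = 1, exponent = 1, peaks = NULL, noise_sd = 0)
  fit <- fit_spectral_model(y, g)
  expect_equal(nrow(fit$peaks), 0L)
  expect_equal(fit$offset, 1, tolerance = 1e-6)
  expect_equal(fit$exponent, 1, tolerance = 1e-6)
  expect_gte(fit$r_squared, 0.999)
})

test_that("spectral fit recovers a single oscillatory peak from noisy input", {
  g <- default_psd_grid()
  y <- simulate_raw_psd(g, 1, 1, rbind(c(10, 0.5, 1.5)), noise_sd = 0.01,
                        seed = 5)
  fit <- fit_spectral_model(y, g)
  expect_equal(nrow(fit$peaks), 1L)
  expect_lt(abs(fit$peaks$center - 10), 0.25)
  expect_lt(abs(fit$peaks$amplitude - 0.5), 0.05)
  expect_lt(abs(fit$peaks$sd - 1.5), 0.3)
})

test_that("peaks below the absolute height threshold are not extracted", {
  g <- default_psd_grid()
  y <- simulate_raw_psd(g, 1, 1, rbind(c(10, 0.03, 1.5)), noise_sd = 0)
  fit <- fit_spectral_model(y, g)
  expect_equal(nrow(fit$peaks), 0L)
})

test_that("returned peaks always satisfy the declared height and width bounds", {
  g <- default_psd_grid()
  s <- spectral_settings()
  set.seed(17)
  for (i in 1:10) {
    pk <- rbind(c(runif(1, 3, 25), runif(1, 0.05, 1), runif(1, 0.4, 4)),
                c(runif(1, 3, 25), runif(1, 0.05, 1), runif(1, 0.4, 4)))
    y <- simulate_raw_psd(g, runif(1, 0, 2), runif(1, 0.5, 1.5), pk,
                          noise_sd = 0.02, seed = i)
    fit <- fit_spectral_model(y, g, s)
    if (nrow(fit$peaks) > 0) {
      expect_true(all(fit$peaks$amplitude >= s$min_peak_height))
      expect_true(all(fit$peaks$sd >= s$sd_limits[1] - 1e-9))
      expect_true(all(fit$peaks$sd <= s$sd_limits[2] + 1e-9))
      expect_true(all(fit$peaks$center >= s$fit_range[1] &
                      fit$peaks$center <= s$fit_range[2]))
    }
  }
})

test_that("peak extraction is idempotent on the cleaned residual", {
  g <- default_psd_grid()
  y <- simulate_raw_psd(g, 1.2, 0.9, rbind(c(6, 0.4, 1), c(10, 0.6, 1.5)),
                        noise_sd = 0)
  fit <- fit_spectral_model(y, g)
  cleaned <- y - fit$peak_curve
  fit2 <- fit_spectral_model(cleaned, g)
  expect_equal(nrow(fit2$peaks), 0L)
})

test_that("peak-only curves superpose linearly and vanish without peaks", {
  g <- default_psd_grid()
  expect_equal(peak_curve(data.frame(center = numeric(0),
                                     amplitude = numeric(0),
                                     sd = numeric(0)), g),
               rep(0, length(g)))
  p1 <- data.frame(center = 10, amplitude = 0.5, sd = 1.5)
  p2 <- data.frame(center = 20, amplitude = 0.3, sd = 2)
  expect_equal(peak_curve(p1, g)[g == 10], 0.5)
  expect_equal(peak_curve(rbind(p1, p2), g),
               peak_curve(p1, g) + peak_curve(p2, g), tolerance = 1e-12)
})

test_that("batch parameterisation achieves high mean goodness of fit at low noise", {
  g <- default_psd_grid()
  set.seed(23)
  curves <- t(sapply(1:20, function(i)
    simulate_raw_psd(g, runif(1, 0.5, 1.5), runif(1, 0.8, 1.2),
                     rbind(c(runif(1, 8, 12), runif(1, 0.3, 0.8), runif(1, 1, 2))),
                     noise_sd = 0.02, seed = 100 + i)))
  batch <- fit_spectral_batch(curves, g)
  expect_gt(mean(batch$report$r_squared), 0.95)
})
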