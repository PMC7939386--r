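test_that("exponential fitter is exact on noiseless transients", {
  tr <- gen_stopped_flow_trace(k_obs = 100, amplitudes = 1, offset = 0.2,
                               duration = 0.1, dt = 1e-4, noise_sd = 0)
  fit <- fit_exponential(tr)
  expect_equal(fit$rates, 100, tolerance = 1e-6)
  expect_equal(fit$amplitudes, 1, tolerance = 1e-6)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)

  tr2 <- gen_stopped_flow_trace(k_obs = c(300, 30),
                                amplitudes = c(0.5, 0.5), offset = 0,
                                duration = 0.3, dt = 1e-4, noise_sd = 0)
  fit2 <- fit_exponential(tr2, n_phases = 2)
  expect_equal(fit2$rates, c(300, 30), tolerance = 0.01)  # fast first
  expect_equal(fit2$amplitudes, c(0.5, 0.5), tolerance = 0.01)
})

test_that("dead-time truncation leaves a noiseless rate unbiased", {
  tr <- gen_stopped_flow_trace(k_obs = 354, amplitudes = -1, offset = 1,
                               duration = 0.03, dt = 2e-5, noise_sd = 0)
  fit <- fit_exponential(tr, t_start = 0.002)
  expect_equal(fit$rates, 354, tolerance = 1e-6)
  expect_equal(fit$t_start, 0.002)
})

test_that("two-phase fit of single-phase data leaves one phase negligible", {
  tr <- gen_stopped_flow_trace(k_obs = 150, amplitudes = 1, offset = 0,
                               duration = 0.1, dt = 1e-4, noise_sd = 0)
  fit <- fit_exponential(tr, n_phases = 2)
  amps <- abs(fit$amplitudes)
  dominant <- which.max(amps)
  expect_lt(min(amps) / sum(amps), 0.01)
  expect_equal(fit$rates[dominant], 150, tolerance = 0.01)
})

test_that("a flat trace is flagged degenerate rather than erroring", {
  tr <- sf_trace(seq(0, 0.1, 1e-3), rep(1, 101))
  fit <- fit_exponential(tr)
  expect_true(fit$degenerate)
})

test_that("linear k_obs fit reproduces generating lines exactly", {
  cc <- c(2.5, 5, 7.5, 10)
  # lm flags exact collinear data; only the coefficients matter here
  f <- suppressWarnings(fit_linear_kobs(cc, 29 * cc + 354))
  expect_equal(f$slope, 29, tolerance = 1e-10)
  expect_equal(f$intercept, 354, tolerance = 1e-10)

  cc2 <- c(0.25, 0.5, 1, 2)
  f2 <- suppressWarnings(fit_linear_kobs(cc2, 17 * cc2))
  expect_equal(f2$slope, 17, tolerance = 1e-10)
  expect_equal(f2$intercept, 0, tolerance = 1e-8)

  # two points: the interpolating line
  f3 <- fit_linear_kobs(c(1, 3), c(10, 20))
  expect_equal(f3$slope, 5)
  expect_equal(f3$intercept, 5)
  expect_error(fit_linear_kobs(c(1, 1), c(2, 3)), "distinct")
})

test_that("saturation fit recovers generating parameters and conventions", {
  cc <- c(10, 25, 50, 100, 250, 500, 1000)
  fit <- fit_saturation(cc, 172 * cc / (119 + cc))
  expect_equal(fit$kmax, 172, tolerance = 1e-6)
  expect_equal(fit$k_half, 119, tolerance = 1e-6)

  # rate at c = k_half is halfway between baseline and kmax
  p_half <- 172 * 119 / (119 + 119)
  expect_equal(p_half, 172 / 2)

  # equal weights reproduce the unweighted fit exactly
  set.seed(5)
  noisy <- 172 * cc / (119 + cc) + rnorm(7, 0, 3)
  f_un <- fit_saturation(cc, noisy)
  f_eq <- fit_saturation(cc, noisy, weights = rep(2, 7))
  expect_equal(f_eq$kmax, f_un$kmax, tolerance = 1e-8)
  expect_equal(f_eq$k_half, f_un$k_half, tolerance = 1e-8)
})

test_that("saturation fit is scale-equivariant in the rates", {
  cc <- c(5, 10, 20, 80, 320)
  set.seed(9)
  r <- 90 * cc / (35 + cc) + rnorm(5, 0, 1)
  f1 <- fit_saturation(cc, r)
  f2 <- fit_saturation(cc, 10 * r)
  expect_equal(f2$kmax, 10 * f1$kmax, tolerance = 1e-6)
  expect_equal(f2$k_half, f1$k_half, tolerance = 1e-6)
})

test_that("saturation fit warns when k_half is an extrapolation", {
  cc <- c(100, 200, 400, 800)
  expect_warning(fit_saturation(cc, 50 * cc / (2 + cc)), "outside")
})

test_that("dwell-time CDF inversion recovers off-rates", {
  set.seed(13)
  d <- rexp(500, 1 / 5)
  fit <- fit_dwell_times(d)
  expect_equal(fit$mean_dwell_s, 5, tolerance = 0.1)
  expect_equal(fit$koff_per_s, 1 / fit$mean_dwell_s, tolerance = 1e-12)
  # the assay arithmetic: a 3.7 s mean dwell is a 0.27 s^-1 off-rate
  set.seed(14)
  fit37 <- fit_dwell_times(rexp(4000, 1 / 3.7))
  expect_equal(round(fit37$koff_per_s, 2), 0.27)
  expect_error(fit_dwell_times(rexp(5, 1)), "at least 10")
})

test_that("dwell-based off-rate is unbiased across replicates", {
  koffs <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    fit_dwell_times(rexp(200, 0.27))$koff_per_s
  }, double(1))
  se <- sd(koffs) / sqrt(200)
  expect_lt(abs(mean(koffs) - 0.27), 3 * se + 0.27 / 200)
})

test_that("off-rate hyperbola fit recovers exact curves and pins the apo point", {
  p <- off_rate_curve_params(0.09, 0.27, 93)
  cc <- c(0, 10, 100, 300, 1000, 3000)
  fit <- fit_off_rate_vs_adp(cc, off_rate_at_adp(p, cc))
  expect_equal(fit$koff_apo, 0.09, tolerance = 1e-6)
  expect_equal(fit$koff_max, 0.27, tolerance = 1e-6)
  expect_equal(fit$k_d, 93, tolerance = 1e-4)
})

test_that("sparse off-rate points converge with a wide K_D interval", {
  # the four-point assay table: convergence expected, precision not
  fit <- fit_off_rate_vs_adp(c(0, 10, 300, 1000),
                             c(0.09, 0.14, 0.21, 0.27))
  expect_s3_class(fit, "off_rate_curve_params")
  expect_true(fit$monotone_increasing)
  expect_gt(diff(fit$ci$k_d), 100)  # poorly conditioned by design
})

test_that("half-site amplitude ratios compare fitted amplitudes", {
  both <- fit_exponential(gen_stopped_flow_trace(100, amplitudes = 1,
                                                 duration = 0.1,
                                                 dt = 1e-4, noise_sd = 0))
  one <- fit_exponential(gen_stopped_flow_trace(100, amplitudes = 0.5,
                                                duration = 0.1,
                                                dt = 1e-4, noise_sd = 0))
  expect_equal(half_site_amplitude_ratio(one, both), 0.5,
               tolerance = 1e-6)
  expect_equal(half_site_amplitude_ratio(both, both), 1)
  # observed relative amplitudes without vs with ATP
  expect_equal(0.2 / 0.36, 0.56, tolerance = 0.01)
})
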