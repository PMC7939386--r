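test_that("run tables enforce the censoring bookkeeping", {
  expect_error(run_table(y = c(1, 2), w = c(1, 0), t = c(0.5, 2)),
               "exceeds")
  expect_error(run_table(y = 1, w = 0, t = 2), "y = t")
  expect_error(run_table(y = -1, w = 1), ">= 0")
  expect_error(run_table(y = 1, w = 2), "0 or 1")
  rt <- run_table(y = c(1, 2), w = c(1, 0), t = c(3, 2))
  expect_s3_class(rt, "run_table")
})

test_that("log-likelihood has its maximum at the closed-form estimate", {
  one <- run_table(y = 1, w = 1)
  opt <- optimize(function(l) run_length_loglik(l, one), c(1e-4, 100),
                  maximum = TRUE)
  expect_equal(opt$maximum, 1, tolerance = 1e-5)

  # dL/dlambda = 0 at lambda = 1/3 for y = {1,2,3}, w = {1,1,0}
  expect_equal(1 / brute_force_theta(toy_runs()), 1 / 3, tolerance = 1e-6)

  # appending a censored record can only lower the fitted detachment rate
  lam0 <- 1 / brute_force_theta(toy_runs())
  more <- run_table(y = c(1, 2, 3, 2.5), w = c(1, 1, 0, 0))
  expect_lte(1 / brute_force_theta(more), lam0)
  expect_error(run_length_loglik(-1, toy_runs()), "> 0")
})

test_that("censored MLE matches hand evaluation on the toy table", {
  est <- censored_mle(toy_runs())
  expect_equal(est$theta_hat, 3.0)
  expect_equal(est$se, 2.53, tolerance = 1e-2)
  # frozen from the closed-form SE: theta^2 / sum(1 - exp(-y/theta))
  expect_equal(est$se, sqrt(9 / sum(1 - exp(-c(1, 2, 3) / 3))),
               tolerance = 1e-12)
  expect_equal(est$naive_mean, 2.0)
  expect_identical(est$n_censored, 1L)
})

test_that("MLE reduces to the naive mean without censoring and doubles at half", {
  set.seed(7)
  y <- rexp(40, 1 / 4)
  expect_equal(censored_mle(run_table(y, rep(1L, 40)))$theta_hat,
               mean(y), tolerance = 1e-14)
  w_half <- rep(c(1L, 0L), 20)
  est <- censored_mle(run_table(y, w_half))
  expect_equal(est$theta_hat / est$naive_mean, 2, tolerance = 1e-14)
  expect_error(censored_mle(run_table(y, rep(0L, 40))), "censored")
})

test_that("closed form equals brute-force likelihood maximisation", {
  for (seed in 1:20) {
    rt <- random_run_table(seed)
    if (sum(rt$w) == 0) next
    expect_equal(censored_mle(rt)$theta_hat, brute_force_theta(rt),
                 tolerance = 1e-8)
  }
})

test_that("estimate is invariant under record permutation", {
  rt <- random_run_table(99)
  perm <- rt[sample(nrow(rt)), ]
  class(perm) <- class(rt)
  expect_equal(censored_mle(perm)$theta_hat, censored_mle(rt)$theta_hat)
})

test_that("Kaplan-Meier restricted mean agrees with hand computation", {
  # no censoring: restricted mean is the sample mean
  set.seed(3)
  y <- rexp(30, 1 / 2)
  expect_equal(kaplan_meier_mean(run_table(y, rep(1L, 30))), mean(y),
               tolerance = 1e-9)
  # product-limit by hand: S = 1 on [0,1), 2/3 on [1,2), 1/3 on [2,3)
  expect_equal(kaplan_meier_mean(toy_runs()), 2.0, tolerance = 1e-9)
})

test_that("Kaplan-Meier and MLE agree within 10% at moderate censoring", {
  runs <- gen_run_table(theta = 5.6, n = 2000, mt_length = c(10, 24),
                        seed = 5)
  expect_lt(censored_mle(runs)$fraction_censored, 0.40)
  km <- kaplan_meier_mean(runs)
  mle <- censored_mle(runs)$theta_hat
  expect_lt(abs(km - mle) / mle, 0.10)
})

test_that("bootstrap interval behaves on degenerate and synthetic tables", {
  # zero-variance data: interval collapses onto the common value
  rt <- run_table(rep(2, 20), rep(1L, 20))
  bs <- bootstrap_ci(rt, n_boot = 200, seed = 1)
  expect_equal(unname(bs$ci), c(2, 2))
  expect_equal(bs$se_boot, 0)

  # width shrinks roughly as 1/sqrt(n)
  w_small <- diff(bootstrap_ci(gen_run_table(5.6, 150, seed = 2),
                               n_boot = 400, seed = 3)$ci)
  w_large <- diff(bootstrap_ci(gen_run_table(5.6, 2400, seed = 2),
                               n_boot = 400, seed = 3)$ci)
  expect_equal(w_small / w_large, 4, tolerance = 0.35)
})

test_that("bootstrap SE agrees with the asymptotic SE at the assay scale", {
  runs <- gen_run_table(theta = 5.6, n = 534, seed = 11)
  est <- censored_mle(runs)
  bs <- bootstrap_ci(runs, n_boot = 1000, seed = 12)
  expect_lt(abs(bs$se_boot - est$se) / est$se, 0.25)
})

test_that("truncated-CDF fit recovers the exponential mean above a cutoff", {
  set.seed(21)
  x <- rexp(534, 1 / 3.6)
  fit <- truncated_cdf_mean(x, cutoff = 0.4)
  expect_equal(fit$mean_run_length, 3.6, tolerance = 0.15)
  # cutoff 0 reproduces (approximately) the sample mean
  fit0 <- truncated_cdf_mean(x, cutoff = 0)
  expect_equal(fit0$mean_run_length, mean(x), tolerance = 0.1)
  # memorylessness: shifting data and cutoff together leaves theta fixed
  fit_shift <- truncated_cdf_mean(x + 1, cutoff = 1.4)
  expect_equal(fit_shift$theta, fit$theta, tolerance = 1e-6)
  expect_error(truncated_cdf_mean(x[1:5], cutoff = 0.4), "at least 10")
})

test_that("run tables round-trip through the CSV schema", {
  runs <- gen_run_table(theta = 4, n = 60, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_run_table(runs, f)
  hdr <- names(read.csv(f, nrows = 1))
  expect_true(all(c("run_length_um", "censored", "dist_to_end_um",
                    "mt_length_um") %in% hdr))
  back <- read_run_table(f)
  expect_equal(back$y, runs$y)
  expect_equal(back$w, runs$w)
  expect_equal(back$t, runs$t)
  # censored column on disk is 1 = ran off the end = complement of w
  disk <- read.csv(f)
  expect_identical(disk$censored, 1L - runs$w)
})
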