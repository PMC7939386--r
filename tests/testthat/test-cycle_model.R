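test_that("weak-state kinetic race probability matches direct evaluation", {
  expect_equal(p_detach_per_step(0.27, 189), 0.27 / (189 + 0.27),
               tolerance = 1e-12)
  expect_equal(p_detach_per_step(0.27, 189), 1.4266e-3, tolerance = 1e-4)
  expect_identical(p_detach_per_step(0, 5), 0)
  expect_identical(p_detach_per_step(1, 1), 0.5)
  expect_identical(p_detach_per_step(0.5, fast()), 0)
  expect_equal(p_detach_per_step(0.27, 189, approximate = TRUE), 0.27 / 189)
  expect_error(p_detach_per_step(0, 0), "undefined")
  expect_error(p_detach_per_step(-1, 5), "non-negative")
})

test_that("approximate race agrees with exact to <1% for processive motors", {
  set.seed(42)
  for (i in 1:50) {
    kd <- runif(1, 0.01, 2)
    kon <- kd * runif(1, 100, 5000)
    exact <- p_detach_per_step(kd, kon)
    approx <- p_detach_per_step(kd, kon, approximate = TRUE)
    expect_lt(abs(approx - exact) / exact, 0.01)
  }
})

test_that("processivity rearrangement recovers the tethered-head rate", {
  expect_equal(kon_th_from_processivity(0.27, 700), 189)
  expect_equal(kon_th_from_processivity(3, 1), 3)
  expect_equal(kon_th_from_processivity(0.27, 700, exact = TRUE),
               0.27 * 699)
  # composing the two operations round-trips the mean number of steps
  kon <- kon_th_from_processivity(0.27, 700)
  expect_equal(1 / p_detach_per_step(0.27, kon), 701, tolerance = 1e-3)
  # the exact rearrangement round-trips exactly
  kon_ex <- kon_th_from_processivity(0.27, 700, exact = TRUE)
  expect_equal(1 / p_detach_per_step(0.27, kon_ex), 700, tolerance = 1e-12)
  expect_error(kon_th_from_processivity(0.27, 0.5), ">= 1")
  expect_error(kon_th_from_processivity(0, 700), "> 0")
})

test_that("cycle time budget sums reciprocal rates with FAST terms at zero", {
  b <- cycle_time_budget(kif1a_rates(), atp_conc = 2000)
  hand <- 1000 * (1 / (1.4 * 2000) + 1 / 189 + 1 / 354)
  expect_equal(b$total_ms, hand, tolerance = 1e-12)
  expect_equal(b$total_ms, 8.47, tolerance = 1e-3)
  expect_equal(b$cycle_rate_per_s, 118, tolerance = 1e-2)
  expect_equal(sum(b$occupancy_pct), 100, tolerance = 1e-9)
  expect_identical(unname(b$durations_ms[b$is_fast]), c(0, 0))

  # single-term budget: everything fast except tethered-head attachment
  rs <- rate_set(kon_atp = 1e9, k_hyd = fast(), kon_th = 189,
                 koff_adp_fh = fast(), koff_rh = fast())
  b1 <- cycle_time_budget(rs, atp_conc = 1)
  expect_equal(b1$total_ms, 5.29, tolerance = 1e-3)
})

test_that("cycle time budget is strictly decreasing in each finite rate", {
  base <- rate_set(kon_atp = 1.4, k_hyd = 300, kon_th = 189,
                   koff_adp_fh = 354, koff_rh = 200)
  t0 <- cycle_time_budget(base, 2000)$total_ms
  for (nm in c("kon_atp", "k_hyd", "kon_th", "koff_adp_fh", "koff_rh")) {
    up <- unclass(base)
    up[[nm]] <- up[[nm]] * 1.5
    t1 <- cycle_time_budget(do.call(rate_set, up), 2000)$total_ms
    expect_lt(t1, t0)
  }
})

test_that("cycle time budget rejects zero rates and missing ATP", {
  rs <- rate_set(kon_atp = 1.4, k_hyd = 0, kon_th = 189,
                 koff_adp_fh = 354, koff_rh = fast())
  expect_error(cycle_time_budget(rs, 2000), "infinite transition duration")
  expect_error(cycle_time_budget(kif1a_rates(), 0), "atp_conc")
})

test_that("rear-head rate from the half-site comparison", {
  expect_equal(rear_head_rate_from_half_site(65, 112), 155,
               tolerance = 1e-2)
  expect_true(is_fast(rear_head_rate_from_half_site(220, 172)))
  expect_equal(rear_head_rate_from_half_site(50, 100), 100)  # (k, 2k) -> 2k
  # recomposition recovers the stepping rate to machine precision
  k_rh <- rear_head_rate_from_half_site(65, 112)
  expect_equal(1 / (1 / 112 + 1 / k_rh), 65, tolerance = 1e-12)
  expect_error(rear_head_rate_from_half_site(0, 10), "> 0")
})

test_that("nucleotide-dependent off-rate hyperbola", {
  p <- off_rate_curve_params(0.09, 0.27, 93)
  expect_equal(off_rate_at_adp(p, 0), 0.09)
  expect_equal(off_rate_at_adp(p, Inf), 0.27)
  expect_equal(off_rate_at_adp(p, 93), 0.18)  # midpoint = mean of extremes
  expect_error(off_rate_at_adp(p, -5), ">= 0")
  # monotone nondecreasing iff koff_max >= koff_apo
  adp <- seq(0, 5000, length.out = 200)
  expect_true(all(diff(off_rate_at_adp(p, adp)) >= 0))
  p_dec <- off_rate_curve_params(0.3, 0.1, 93)
  expect_false(p_dec$monotone_increasing)
  expect_true(all(diff(off_rate_at_adp(p_dec, adp)) <= 0))
})

test_that("derived motility quantities and the 2 s.f. reporting layer", {
  d <- derived_motility_quantities(velocity = 1.77, run_length = 5.6)
  expect_equal(d$stepping_rate_per_s, 221.25)
  expect_equal(signif2(d$stepping_rate_per_s), 220)
  expect_equal(d$n_steps, 700)
  d2 <- derived_motility_quantities(velocity = 1.56, run_length = 5.6)
  expect_equal(signif2(d2$koff_mt_per_s), 0.28)
  expect_equal(d2$run_time_s, 5.6 / 1.56)
  expect_error(derived_motility_quantities(1.5, 0), "> 0")
})

test_that("rate sets validate and round-trip through YAML and JSON", {
  expect_error(rate_set(kon_th = -1), "negative")
  expect_error(rate_set(step_size = 0), "step_size")
  rs <- kif1a_rates()
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_rate_set(rs, f)
    back <- read_rate_set(f)
    expect_s3_class(back, "rate_set")
    expect_identical(unclass(back), unclass(rs))
  }
  # FAST sentinel is serialized as the string "fast"
  f <- tempfile(fileext = ".yaml")
  write_rate_set(rs, f)
  expect_true(any(grepl("fast", readLines(f))))
  expect_error(read_rate_set(tempfile(fileext = ".txt")), "format")
})
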