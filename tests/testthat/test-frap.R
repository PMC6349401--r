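test_that("normalized pre-bleach mean is 1", {
  clean <- generate_frap_trace(noise_sd = 0, seed = 2)
  expect_equal(mean(correct_and_normalize(clean$trace)$values[1:10]), 1)
  noisy <- generate_frap_trace(noise_sd = 0.02, seed = 2)
  expect_equal(mean(correct_and_normalize(noisy$trace)$values[1:10]), 1,
               tolerance = 0.02)
})

test_that("constant reference and zero background reduce to simple normalization", {
  times <- seq(0, 10, by = 0.2)
  n <- length(times)
  bleach <- c(rep(100, 5), 30 + 50 * (1 - exp(-(seq_len(n - 5) - 1) * 0.2)))
  trace <- frap_trace(times, bleach, rep(400, n), rep(0, n), 5L)
  curve <- correct_and_normalize(trace)
  expect_equal(curve$values, bleach / mean(bleach[1:5]))
})

test_that("nonpositive corrected reference is an error", {
  times <- 0:19
  expect_error(correct_and_normalize(
    frap_trace(times, rep(10, 20), rep(5, 20), rep(5, 20), 3L)),
    "invalid reference")
})

test_that("acquisition bleaching is corrected to within 1% of ground truth", {
  sim <- generate_frap_trace(mobile_fraction = 60, tau = 3,
                             acq_bleach_rate = 0.02, noise_sd = 0,
                             background_level = 40, seed = 6)
  curve <- correct_and_normalize(sim$trace)
  post <- 11:300
  t_b <- curve$times[11]
  f0 <- 0.3
  f_inf <- f0 + 0.6 * (1 - f0)
  truth <- f0 + (f_inf - f0) * (1 - exp(-(curve$times[post] - t_b) / 3))
  expect_lt(max(abs(curve$values[post] - truth)), 0.01)
})

test_that("normalization is invariant to common rescaling of the raw ROIs", {
  sim <- generate_frap_trace(seed = 12)
  tr <- sim$trace
  scaled <- frap_trace(tr$times, 7 * tr$bleach_roi, 7 * tr$reference_roi,
                       7 * tr$background_roi, tr$n_prebleach)
  expect_equal(correct_and_normalize(tr)$values,
               correct_and_normalize(scaled)$values)
})

test_that("full and null recovery give mobile fractions 100 and ~0", {
  full <- generate_frap_trace(mobile_fraction = 100, noise_sd = 0,
                              acq_bleach_rate = 0, seed = 1)
  fit_full <- fit_recovery(correct_and_normalize(full$trace))
  expect_equal(fit_full$mobile_fraction, 100, tolerance = 0.01)
  flat <- generate_frap_trace(mobile_fraction = 0, noise_sd = 0.002,
                              acq_bleach_rate = 0, seed = 1)
  fit_flat <- fit_recovery(correct_and_normalize(flat$trace))
  expect_lt(fit_flat$mobile_fraction, 2)
  expect_equal(fit_full$half_time, fit_full$tau * log(2))
})

test_that("simulated 60% mobile fraction is recovered within 3 points", {
  sim <- generate_frap_trace(mobile_fraction = 60, tau = 3,
                             bleach_depth = 0.2, n_frames = 150L,
                             noise_sd = 0.01, seed = 15)
  fit <- fit_recovery(correct_and_normalize(sim$trace))
  expect_lte(abs(fit$mobile_fraction - 60), 3)
  expect_lt(abs(fit$tau - 3) / 3, 0.3)
})

test_that("estimated mobile fraction rises strictly with the simulated plateau", {
  mfs <- vapply(c(20, 40, 60, 80), function(mf) {
    sim <- generate_frap_trace(mobile_fraction = mf, tau = 3,
                               noise_sd = 0.01, seed = 77)
    fit_recovery(correct_and_normalize(sim$trace))$mobile_fraction
  }, numeric(1))
  expect_true(all(diff(mfs) > 0))
})

test_that("fit_recovery rejects curves without a bleach drop", {
  times <- seq(0, 20, by = 0.2)
  vals <- rep(1, length(times))
  expect_error(fit_recovery(list(times = times, values = vals),
                            n_prebleach = 10L), "not below")
})

test_that("batch_frap reports per-trace rows, group stats and failures", {
  sims <- lapply(1:10, function(i)
    generate_frap_trace(mobile_fraction = 60, tau = 3, noise_sd = 0.02,
                        seed = 100 + i))
  out <- batch_frap(lapply(sims, `[[`, "trace"))
  expect_equal(nrow(out$results), 10L)
  expect_equal(out$summary$n, 10L)
  expect_lte(abs(out$summary$mobile_fraction_mean - 60),
             2 * max(out$summary$mobile_fraction_sd, 1))
  # single trace: N = 1, undefined sd
  one <- batch_frap(list(sims[[1]]$trace))
  expect_equal(one$summary$n, 1L)
  expect_true(is.na(one$summary$mobile_fraction_sd))
  # a broken trace is recorded, not fatal
  broken <- frap_trace(seq(0, 19) * 0.2, rep(100, 20), rep(100, 20),
                       rep(0, 20), 5L)
  mixed <- batch_frap(list(good = sims[[1]]$trace, bad = broken))
  expect_equal(mixed$summary$n, 1L)
  expect_match(mixed$results$error[mixed$results$trace == "bad"], ".+")
})
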