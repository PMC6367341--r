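table2_free <- tibble::tibble(tau_ns = c(3.09, 4.72, 6.83),
                              alpha = c(0.31, 0.04, 0.65))

test_that("amplitude-weighted lifetime is the weighted mean and permutation-invariant", {
  expect_equal(average_lifetime(table2_free$tau_ns, table2_free$alpha), 5.5862)
  expect_equal(average_lifetime(c(3.23, 5.32, 6.96), c(0.33, 0.03, 0.64)), 5.6799)
  expect_equal(average_lifetime(5, 1), 5)
  p <- sample(3)
  expect_equal(average_lifetime(table2_free$tau_ns[p], table2_free$alpha[p]),
               average_lifetime(table2_free$tau_ns, table2_free$alpha))
  expect_warning(out <- average_lifetime(c(2, 4), c(2, 2)), "normalising")
  expect_equal(out, 3)
})

test_that("noiseless single-exponential decay is recovered essentially exactly", {
  t <- (0:4095) * 0.0125
  d <- tibble::tibble(time_ns = t, counts = 1e4 * exp(-t / 5))
  fit <- fit_decay(d, 1, baseline = FALSE)
  expect_equal(fit$components$tau_ns, 5, tolerance = 1e-6)
  expect_equal(fit$tau_avg, 5, tolerance = 1e-6)
  expect_lt(fit$chisq_red, 0.1)
})

test_that("noiseless tri-exponential components are recovered to convergence precision", {
  d <- gen_decay(peak_counts = 1e4, seed = 1)
  d$counts <- round(d$mu, 9)  # strip Poisson noise, keep the exact model
  fit <- fit_decay(tibble::tibble(time_ns = d$time_ns, counts = d$mu), 3,
                   baseline = FALSE)
  expect_equal(fit$components$tau_ns, table2_free$tau_ns, tolerance = 1e-6)
  expect_equal(fit$components$alpha, table2_free$alpha, tolerance = 1e-6)
  expect_equal(fit$tau_avg, 5.5862, tolerance = 1e-6)
})

test_that("Poisson-noised decay from the free-protein truth recovers tau_avg within 3%", {
  d <- gen_decay(peak_counts = 1e4, seed = 11)
  fit <- fit_decay(d, 3)
  expect_equal(fit$tau_avg, 5.5862, tolerance = 0.03)
  expect_gt(fit$chisq_red, 0.8)
  expect_lt(fit$chisq_red, 1.3)
  # amplitudes normalised regardless of intensity scale
  expect_equal(sum(fit$components$alpha), 1, tolerance = 1e-9)
  d2 <- gen_decay(peak_counts = 5e4, seed = 11)
  expect_equal(sum(fit_decay(d2, 3)$components$alpha), 1, tolerance = 1e-9)
  # components sorted ascending
  expect_true(!is.unsorted(fit$components$tau_ns))
})

test_that("two-component fit agrees with a brute-force (tau1, tau2) grid oracle", {
  t <- (0:2047) * 0.025
  y <- 6000 * exp(-t / 1.5) + 4000 * exp(-t / 6)
  d <- tibble::tibble(time_ns = t, counts = y)
  fit <- fit_decay(d, 2, baseline = FALSE)
  coarse <- decay_grid_fit(t, y, seq(1.0, 2.0, 0.01), seq(5.5, 6.5, 0.01))
  expect_equal(fit$components$tau_ns[1], coarse[1], tolerance = 0.005)
  expect_equal(fit$components$tau_ns[2], coarse[2], tolerance = 0.005)
})

test_that("model selection finds one component for mono- and three for separated tri-exponentials", {
  t <- (0:1023) * 0.05
  d1 <- withr::with_seed(5, tibble::tibble(
    time_ns = t, counts = rpois(length(t), 1e4 * exp(-t / 4))))
  sel1 <- select_model(d1, max_components = 3)
  expect_identical(sel1$n_components, 1L)

  sep <- tibble::tibble(tau_ns = c(0.8, 3.0, 8.0), alpha = c(0.4, 0.35, 0.25))
  hits <- vapply(1:20, function(s) {
    d <- gen_decay(components = sep, peak_counts = 1e4, seed = 100 + s)
    sel <- tryCatch(select_model(d, max_components = 4), error = function(e) NULL)
    !is.null(sel) && sel$n_components == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("lifetime comparison reproduces the free-vs-bound corroboration", {
  cmp <- compare_lifetimes(5.586, 5.680)
  expect_equal(cmp$relative_change, (5.680 - 5.586) / 5.586, tolerance = 1e-12)
  expect_true(cmp$static_supported)
  expect_true(compare_lifetimes(5.586, 5.586)$static_supported)
  big <- compare_lifetimes(5.586, 2.8)
  expect_false(big$static_supported)
  expect_lt(big$relative_change, -0.45)
})

test_that("decay histogram validation rejects bad grids", {
  expect_error(fit_decay(tibble::tibble(time_ns = c(0, 1, 1.5), counts = c(5, 4, 3)), 1),
               "uniform")
  expect_error(fit_decay(tibble::tibble(time_ns = 0:20, counts = c(rep(2, 20), -1)), 1),
               "non-negative")
})
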