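test_that("inner-filter correction matches direct evaluation and its invariants", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.10, 0.06), 100 * exp(0.08))
  # doubling A_ex strictly increases the corrected intensity
  expect_gt(correct_inner_filter(100, 0.20, 0.06), correct_inner_filter(100, 0.10, 0.06))
  # commutes with intensity scaling
  expect_equal(correct_inner_filter(5 * 123, 0.1, 0.2),
               5 * correct_inner_filter(123, 0.1, 0.2))
  expect_error(correct_inner_filter(100, -0.1, 0), "non-negative")
})

test_that("Beer-Lambert concentration is linear and reproduces the stock prep", {
  expect_equal(concentration_from_absorbance(0.7370, 36850, 1), 2e-5)
  expect_equal(concentration_from_absorbance(0, 36850, 1), 0)
  expect_equal(concentration_from_absorbance(2 * 0.31, 36850, 1),
               2 * concentration_from_absorbance(0.31, 36850, 1))
})

test_that("Stern-Volmer fit inverts the noiseless static-quenching model", {
  d <- gen_titration(K_SV = 1.26e5, temperatures_K = 298, noise_cv = 0, seed = 1)
  fit <- suppressWarnings(fit_stern_volmer(d))
  expect_equal(fit$K_SV, 1.26e5, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  # constant F means no quenching
  flat <- tibble::tibble(Q_molar = seq(0, 6e-6, 1e-6), F = 500)
  f0 <- suppressWarnings(fit_stern_volmer(flat))
  expect_lt(abs(f0$K_SV), 1e-6)
  expect_equal(f0$intercept, 1, tolerance = 1e-12)
  # unit invariance: only the ratio enters
  d2 <- dplyr::mutate(d, F_obs = F_obs * 1e3)
  expect_equal(suppressWarnings(fit_stern_volmer(d2))$K_SV, fit$K_SV)
})

test_that("Stern-Volmer mean recovery stays within 2% at 1% noise", {
  ksv <- vapply(1:200, function(s) {
    d <- gen_titration(K_SV = 1.26e5, temperatures_K = 298, seed = s)
    fit_stern_volmer(d)$K_SV
  }, numeric(1))
  expect_lt(abs(mean(ksv) / 1.26e5 - 1), 0.02)
})

test_that("double-log fit recovers K_a, n and agrees with K_SV for single-site data", {
  d <- gen_titration(K_SV = 1.14e5, temperatures_K = 298, noise_cv = 0, seed = 1)
  dl <- suppressWarnings(fit_double_log(d))
  expect_equal(dl$n, 1, tolerance = 1e-9)
  expect_equal(dl$K_a, 1.14e5, tolerance = 1e-9)
  expect_equal(dl$log10_K_a, log10(1.14e5), tolerance = 1e-9)
  sv <- suppressWarnings(fit_stern_volmer(d))
  # both estimate the association constant on noiseless single-site data
  expect_equal(dl$K_a / sv$K_SV, 1, tolerance = 0.01)
})

test_that("non-quenched points are dropped with a warning, too few error", {
  d <- gen_titration(K_SV = 1.2e5, temperatures_K = 298, noise_cv = 0, seed = 1)
  d$F_obs[2] <- d$F_obs[1] * 1.01  # above the reference
  expect_warning(fit_double_log(d), "dropping 1 point")
  short <- tibble::tibble(Q_molar = c(0, 1e-6, 2e-6), F = c(100, 99, 101))
  expect_error(suppressWarnings(fit_double_log(short)), "fewer than 3")
  expect_error(fit_stern_volmer(tibble::tibble(Q_molar = c(0, 1e-6), F = c(100, 90))),
               "at least 3")
})

test_that("titration validation catches missing reference and duplicates", {
  no_ref <- tibble::tibble(Q_molar = c(1e-6, 2e-6, 3e-6, 4e-6), F = c(90, 80, 70, 60))
  expect_error(fit_stern_volmer(no_ref), "no reference intensity")
  dup <- tibble::tibble(Q_molar = c(0, 1e-6, 1e-6, 2e-6), F = c(100, 90, 91, 80))
  expect_error(fit_stern_volmer(dup), "duplicate")
})

test_that("mechanism classification follows the temperature trend and lifetime evidence", {
  ksv <- tibble::tibble(temperature_K = c(298, 304, 310),
                        K_SV = c(1.26e5, 1.11e5, 1.00e5))
  expect_identical(classify_mechanism(ksv, lifetime_change = 0.017), "static")
  expect_identical(classify_mechanism(ksv), "static")  # no lifetime evidence
  rising <- tibble::tibble(temperature_K = c(298, 304, 310),
                           K_SV = c(1.0e5, 1.1e5, 1.3e5))
  expect_identical(classify_mechanism(rising, lifetime_change = -0.30), "dynamic")
  expect_identical(classify_mechanism(rising, lifetime_change = 0.01), "inconclusive")
  one <- tibble::tibble(temperature_K = 298, K_SV = 1.2e5)
  expect_identical(classify_mechanism(one), "inconclusive")
})

test_that("affinity classes split at 1e3 and 1e6 L/mol", {
  expect_identical(classify_affinity(c(1e2, 1.14e5, 1e7)),
                   c("weak", "moderate", "strong"))
  expect_identical(classify_affinity(1e3), "moderate")
  expect_error(classify_affinity(-1), "positive")
})

test_that("tidy and glance expose the fitted quantities", {
  d <- gen_titration(K_SV = 1.2e5, temperatures_K = 298, noise_cv = 0.005, seed = 3)
  sv <- fit_stern_volmer(d)
  td <- tidy(sv)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate[td$term == "K_SV"], sv$K_SV)
  gl <- glance(fit_double_log(d))
  expect_true(gl$r.squared > 0.9 && gl$r.squared <= 1)
})
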