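#' Inner-filter correction of observed fluorescence intensities
#'
#' Re-absorption of excitation and emission light by the sample attenuates the
#' measured fluorescence. The standard multiplicative correction restores the
#' true intensity from the absorbances at the excitation and emission
#' wavelengths:
#' \deqn{F_{corr} = F_{obs} \, e^{(A_{ex}+A_{em})/2}}
#'
#' @param F_obs Observed fluorescence intensity (arbitrary units). Vectorised.
#' @param A_ex Absorbance at the excitation wavelength (unitless, >= 0).
#' @param A_em Absorbance at the emission wavelength (unitless, >= 0).
#' @return Corrected intensity, same length/units as `F_obs`; always
#'   `>= F_obs`.
#' @examples
#' correct_inner_filter(100, 0.10, 0.06)
#' @export
correct_inner_filter <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0, na.rm = TRUE) || any(A_em < 0, na.rm = TRUE)) {
    abort("absorbances must be non-negative")
  }
  F_obs * exp((A_ex + A_em) / 2)
}

#' Concentration from absorbance (Beer-Lambert law)
#'
#' @param A Absorbance (unitless).
#' @param epsilon Molar extinction coefficient, L mol^-1 cm^-1. The serum
#'   albumin value at 280 nm is 36,850.
#' @param l Path length in cm (default 1).
#' @return Molar concentration `A / (epsilon * l)`.
#' @examples
#' concentration_from_absorbance(0.7370, 36850) # 2e-5 M
#' @export
concentration_from_absorbance <- function(A, epsilon, l = 1) {
  stopifnot_scalar_pos(epsilon, "epsilon")
  stopifnot_scalar_pos(l, "l")
  A / (epsilon * l)
}

check_titration_series <- function(data) {
  if (!"F" %in% names(data) && "F_obs" %in% names(data)) {
    A_ex <- data$A_ex %||% 0
    A_em <- data$A_em %||% 0
    data$F <- correct_inner_filter(data$F_obs, A_ex, A_em)
  }
  if (!all(c("Q_molar", "F") %in% names(data))) {
    abort("titration data needs columns `Q_molar` and `F` (or `F_obs`)")
  }
  data <- dplyr::arrange(data, .data$Q_molar)
  if (any(data$Q_molar < 0)) abort("quencher concentrations must be non-negative")
  if (anyDuplicated(data$Q_molar)) abort("duplicate quencher concentrations")
  if (sum(data$Q_molar == 0) != 1L) abort("no reference intensity: exactly one Q = 0 row required")
  if (any(data$F <= 0)) abort("intensities must be positive")
  data
}

#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation \eqn{F_0/F = 1 + K_{SV}[Q]} by ordinary least
#' squares of the intensity ratio on quencher concentration. The reference
#' intensity \eqn{F_0} is the row at `Q_molar == 0`, which is excluded from the
#' regression (its ratio is 1 by construction). Intensities are assumed already
#' inner-filter corrected (see [correct_inner_filter()]).
#'
#' @param data A data frame with columns `Q_molar` (mol/L) and `F` (corrected
#'   intensity), containing exactly one `Q_molar == 0` row.
#' @param temperature Temperature in kelvin carried into the result (taken
#'   from a `temperature_K` column if present).
#' @return An object of class `sv_fit` with elements `K_SV`, `K_SV_se`,
#'   `intercept`, `intercept_se`, `r_squared`, `temperature_K` and the
#'   underlying `lm` fit. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- gen_titration(noise_cv = 0, seed = 1)
#' fit_stern_volmer(dplyr::filter(d, temperature_K == 298))
#' @export
fit_stern_volmer <- function(data, temperature = NULL) {
  temperature <- temperature %||%
    (if ("temperature_K" %in% names(data)) unique(data$temperature_K)[1] else NA_real_)
  data <- check_titration_series(data)
  F0 <- data$F[data$Q_molar == 0]
  pts <- dplyr::filter(data, .data$Q_molar > 0)
  if (nrow(pts) < 3L) abort("at least 3 nonzero-quencher points required")
  ratio <- F0 / pts$F
  if (any(!is.finite(ratio))) abort("non-finite intensity ratio")
  fit <- lm(ratio ~ Q, data = data.frame(ratio = ratio, Q = pts$Q_molar))
  s <- summary(fit)
  structure(
    list(
      K_SV = unname(coef(fit)[2]),
      K_SV_se = s$coefficients[2, 2],
      intercept = unname(coef(fit)[1]),
      intercept_se = s$coefficients[1, 2],
      r_squared = s$r.squared,
      temperature_K = temperature,
      n_points = nrow(pts),
      fit = fit
    ),
    class = "sv_fit"
  )
}

#' Double-logarithm binding fit (association constant and Hill coefficient)
#'
#' For static quenching the association constant \eqn{K_a} and Hill coefficient
#' \eqn{n} follow from the modified Stern-Volmer relation
#' \deqn{\log_{10}\frac{F_0-F}{F} = \log_{10} K_a + n \log_{10}[Q]}
#' fitted by ordinary least squares on the base-10 log-transformed variables.
#' Points with \eqn{F \ge F_0} at nonzero quencher (no net quenching, typically
#' noise at low quencher) are dropped with a warning.
#'
#' @inheritParams fit_stern_volmer
#' @return An object of class `dlog_fit` with elements `K_a`, `K_a_se`
#'   (delta-method from the intercept), `n`, `n_se`, `r_squared`,
#'   `temperature_K`. Has [tidy()] and [glance()] methods.
#' @export
fit_double_log <- function(data, temperature = NULL) {
  temperature <- temperature %||%
    (if ("temperature_K" %in% names(data)) unique(data$temperature_K)[1] else NA_real_)
  data <- check_titration_series(data)
  F0 <- data$F[data$Q_molar == 0]
  pts <- dplyr::filter(data, .data$Q_molar > 0)
  bad <- pts$F >= F0
  if (any(bad)) {
    warn(sprintf("dropping %d point(s) with F >= F0 (no net quenching)", sum(bad)))
    pts <- pts[!bad, , drop = FALSE]
  }
  if (nrow(pts) < 3L) abort("fewer than 3 usable points for the double-log fit")
  y <- log10((F0 - pts$F) / pts$F)
  x <- log10(pts$Q_molar)
  fit <- lm(y ~ x)
  s <- summary(fit)
  logKa <- unname(coef(fit)[1])
  logKa_se <- s$coefficients[1, 2]
  Ka <- 10^logKa
  structure(
    list(
      K_a = Ka,
      K_a_se = Ka * log(10) * logKa_se,
      log10_K_a = logKa,
      n = unname(coef(fit)[2]),
      n_se = s$coefficients[2, 2],
      r_squared = s$r.squared,
      temperature_K = temperature,
      n_points = nrow(pts),
      fit = fit
    ),
    class = "dlog_fit"
  )
}

#' Fit quenching and binding constants for every temperature of a titration
#'
#' Convenience wrapper mapping [fit_stern_volmer()] and [fit_double_log()]
#' over the temperature blocks of a long titration table.
#'
#' @param data A titration tibble as returned by [read_titration()] or
#'   [gen_titration()]: columns `temperature_K`, `Q_molar`, `F` (corrected
#'   intensity; if only `F_obs`, `A_ex`, `A_em` are present the inner-filter
#'   correction is applied first).
#' @return A tibble with one row per temperature: `temperature_K`, `K_SV`,
#'   `K_SV_se`, `sv_intercept`, `sv_r_squared`, `K_a`, `K_a_se`, `n`, `n_se`,
#'   `dlog_r_squared`, `affinity_class`.
#' @export
quench_table <- function(data) {
  if (!"F" %in% names(data)) {
    data <- dplyr::mutate(data, F = correct_inner_filter(.data$F_obs, .data$A_ex, .data$A_em))
  }
  data |>
    dplyr::group_by(.data$temperature_K) |>
    dplyr::group_map(function(d, key) {
      sv <- fit_stern_volmer(d, temperature = key$temperature_K)
      dl <- fit_double_log(d, temperature = key$temperature_K)
      tibble::tibble(
        temperature_K = key$temperature_K,
        K_SV = sv$K_SV, K_SV_se = sv$K_SV_se,
        sv_intercept = sv$intercept, sv_r_squared = sv$r_squared,
        K_a = dl$K_a, K_a_se = dl$K_a_se,
        n = dl$n, n_se = dl$n_se,
        dlog_r_squared = dl$r_squared,
        affinity_class = classify_affinity(dl$K_a)
      )
    }) |>
    purrr::list_rbind()
}

#' Classify the fluorescence-quenching mechanism
#'
#' Ground-state (static) quenching is indicated by Stern-Volmer constants that
#' fall with temperature while the fluorescence lifetime is essentially
#' unchanged; collisional (dynamic) quenching by constants that rise with
#' temperature while the lifetime shortens.
#'
#' @param ksv_by_T A data frame with columns `temperature_K` and `K_SV`, or a
#'   list of `sv_fit` objects.
#' @param lifetime_change Optional relative change of the amplitude-weighted
#'   lifetime between free and ligand-bound protein (fraction, e.g. `0.017`),
#'   as returned by [compare_lifetimes()].
#' @param tolerance Maximum absolute relative lifetime change still consistent
#'   with a static mechanism (default 0.05).
#' @return One of `"static"`, `"dynamic"`, `"inconclusive"`.
#' @examples
#' ksv <- tibble::tibble(temperature_K = c(298, 304, 310),
#'                       K_SV = c(1.26e5, 1.11e5, 1.00e5))
#' classify_mechanism(ksv, lifetime_change = 0.017)
#' @export
classify_mechanism <- function(ksv_by_T, lifetime_change = NULL, tolerance = 0.05) {
  if (tolerance <= 0 || tolerance >= 1) abort("tolerance must be in (0, 1)")
  if (is.list(ksv_by_T) && !is.data.frame(ksv_by_T) &&
      all(vapply(ksv_by_T, inherits, logical(1), "sv_fit"))) {
    ksv_by_T <- tibble::tibble(
      temperature_K = vapply(ksv_by_T, `[[`, numeric(1), "temperature_K"),
      K_SV = vapply(ksv_by_T, `[[`, numeric(1), "K_SV")
    )
  }
  ksv_by_T <- dplyr::arrange(ksv_by_T, .data$temperature_K)
  if (nrow(ksv_by_T) < 2L && is.null(lifetime_change)) return("inconclusive")
  dec <- nrow(ksv_by_T) >= 2L && all(diff(ksv_by_T$K_SV) < 0)
  inc <- nrow(ksv_by_T) >= 2L && all(diff(ksv_by_T$K_SV) > 0)
  lt_static <- is.null(lifetime_change) || abs(lifetime_change) < tolerance
  lt_dynamic <- !is.null(lifetime_change) && lifetime_change < -tolerance
  if (dec && lt_static) return("static")
  if (inc && lt_dynamic) return("dynamic")
  "inconclusive"
}

#' Classify binding-affinity strength from the association constant
#'
#' Association constants between 10^3 and 10^6 L/mol are conventionally called
#' moderate binding; below and above are weak and strong.
#'
#' @param K_a Association constant(s), L/mol. Vectorised.
#' @return Character vector: `"weak"`, `"moderate"` or `"strong"`.
#' @examples
#' classify_affinity(1.14e5)
#' @export
classify_affinity <- function(K_a) {
  if (any(K_a <= 0)) abort("K_a must be positive")
  dplyr::case_when(
    K_a < 1e3 ~ "weak",
    K_a <= 1e6 ~ "moderate",
    TRUE ~ "strong"
  )
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer fit (T = %s K): K_SV = %.4g +/- %.2g L/mol, intercept = %.4f, R^2 = %.4f\n",
    format(x$temperature_K), x$K_SV, x$K_SV_se, x$intercept, x$r_squared
  ))
  invisible(x)
}

#' @export
print.dlog_fit <- function(x, ...) {
  cat(sprintf(
    "Double-log binding fit (T = %s K): K_a = %.4g +/- %.2g L/mol, n = %.3f +/- %.3f, R^2 = %.4f\n",
    format(x$temperature_K), x$K_a, x$K_a_se, x$n, x$n_se, x$r_squared
  ))
  invisible(x)
}
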