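#' Gibbs free energy of binding
#'
#' \deqn{\Delta G = -RT \ln K_a} with R = 8.314 J mol^-1 K^-1; the result is
#' reported in kJ/mol.
#'
#' @param K_a Association constant, L/mol (> 0). Vectorised.
#' @param T_K Absolute temperature, kelvin (> 0). Vectorised.
#' @return Gibbs free energy in kJ/mol (negative for spontaneous binding).
#' @examples
#' delta_g(1.14e5, 298)
#' @export
delta_g <- function(K_a, T_K) {
  if (any(K_a <= 0) || any(T_K <= 0)) abort("K_a and T_K must be positive")
  -GAS_CONSTANT * T_K * log(K_a) / 1000
}

#' van't Hoff analysis of the temperature dependence of an association constant
#'
#' Regresses \eqn{\ln K_a} on \eqn{1/T} by ordinary least squares:
#' slope \eqn{= -\Delta H / R}, intercept \eqn{= \Delta S / R}. The regression
#' uses the natural logarithm (the base cancels in \eqn{\Delta H}; the
#' intercept conversion is exact). Per-temperature \eqn{\Delta G} values come
#' from [delta_g()]; standard errors are those of the regression coefficients.
#' Duplicate temperatures are collapsed to their mean \eqn{\ln K_a} with a
#' warning. The fit is unweighted; set `weights` to `1/se^2`-style weights to
#' propagate per-point uncertainty instead.
#'
#' @param data Data frame with columns `temperature_K` and `K_a` (L/mol).
#' @param weights Optional regression weights (same length as rows of `data`).
#' @return Object of class `vant_hoff_fit`: `dH_kJ_mol`, `dH_se`,
#'   `dS_J_mol_K`, `dS_se`, `r_squared`, `force_label`, `spontaneous`, and a
#'   per-temperature tibble `by_temperature` with `dG_kJ_mol` and the fitted
#'   `ln K_a`. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- tibble::tibble(temperature_K = c(298, 304, 310),
#'                     K_a = c(1.14e5, 1.03e5, 0.85e5))
#' vant_hoff(d)
#' @export
vant_hoff <- function(data, weights = NULL) {
  if (!all(c("temperature_K", "K_a") %in% names(data))) {
    abort("need columns `temperature_K` and `K_a`")
  }
  if (any(data$K_a <= 0) || any(data$temperature_K <= 0)) {
    abort("temperatures and K_a must be positive")
  }
  if (anyDuplicated(data$temperature_K)) {
    warn("duplicate temperatures collapsed to mean ln K_a")
    data <- data |>
      dplyr::group_by(.data$temperature_K) |>
      dplyr::summarise(K_a = exp(mean(log(.data$K_a))), .groups = "drop")
    weights <- NULL
  }
  if (nrow(data) < 2L) abort("at least 2 distinct temperatures required")
  data <- dplyr::arrange(data, .data$temperature_K)
  df <- data.frame(lnK = log(data$K_a), invT = 1 / data$temperature_K)
  fit <- lm(lnK ~ invT, data = df, weights = weights)
  s <- summary(fit)
  dH <- -GAS_CONSTANT * unname(coef(fit)[2]) / 1000
  dS <- GAS_CONSTANT * unname(coef(fit)[1])
  se <- if (nrow(data) > 2L) s$coefficients[, 2] else c(NA_real_, NA_real_)
  by_T <- tibble::tibble(
    temperature_K = data$temperature_K,
    K_a = data$K_a,
    dG_kJ_mol = delta_g(data$K_a, data$temperature_K),
    ln_K_a_fitted = unname(predict(fit))
  )
  structure(
    list(
      dH_kJ_mol = dH, dH_se = GAS_CONSTANT * se[2] / 1000,
      dS_J_mol_K = dS, dS_se = GAS_CONSTANT * se[1],
      r_squared = s$r.squared,
      force_label = classify_forces(dH, dS),
      spontaneous = all(by_T$dG_kJ_mol < 0),
      by_temperature = by_T,
      fit = fit
    ),
    class = "vant_hoff_fit"
  )
}

#' Classify the dominant intermolecular force from thermodynamic signs
#'
#' Sign rules relating the enthalpy and entropy of binding to the dominant
#' interaction: exothermic with entropy gain points to electrostatic forces;
#' exothermic with entropy loss to hydrogen bonding / van der Waals; endothermic
#' with entropy gain to hydrophobic forces.
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dS Entropy change, J/mol/K.
#' @return One of `"electrostatic"`, `"hydrogen_bond_vdw"`, `"hydrophobic"`,
#'   `"mixed"`.
#' @examples
#' classify_forces(-18.78, 33.92)
#' @export
classify_forces <- function(dH, dS) {
  if (!is.finite(dH) || !is.finite(dS)) abort("dH and dS must be finite")
  if (dH < 0 && dS > 0) return("electrostatic")
  if (dH < 0 && dS < 0) return("hydrogen_bond_vdw")
  if (dH > 0 && dS > 0) return("hydrophobic")
  "mixed"
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "van't Hoff fit over %d temperatures:\n  dH = %.3f +/- %.3g kJ/mol, dS = %.3f +/- %.3g J/mol/K, R^2 = %.5f\n  dominant force: %s; spontaneous: %s\n",
    nrow(x$by_temperature), x$dH_kJ_mol, x$dH_se, x$dS_J_mol_K, x$dS_se,
    x$r_squared, x$force_label, x$spontaneous
  ))
  print(x$by_temperature)
  invisible(x)
}
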