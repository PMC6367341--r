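#' Tidy a Stern-Volmer fit
#' @param x An `sv_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.sv_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "K_SV"),
    estimate = c(x$intercept, x$K_SV),
    std.error = c(x$intercept_se, x$K_SV_se)
  )
}

#' @rdname tidy.sv_fit
#' @export
glance.sv_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_points,
                 temperature_K = x$temperature_K)
}

#' Tidy a double-logarithm binding fit
#' @param x A `dlog_fit`.
#' @param ... Unused.
#' @return Tibble with rows for `K_a` and the Hill coefficient `n`.
#' @export
tidy.dlog_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K_a", "n"),
    estimate = c(x$K_a, x$n),
    std.error = c(x$K_a_se, x$n_se)
  )
}

#' @rdname tidy.dlog_fit
#' @export
glance.dlog_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_points,
                 temperature_K = x$temperature_K)
}

#' Tidy a van't Hoff fit
#' @param x A `vant_hoff_fit`.
#' @param ... Unused.
#' @return Tibble with rows for the enthalpy (kJ/mol) and entropy (J/mol/K).
#' @export
tidy.vant_hoff_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dH_kJ_mol", "dS_J_mol_K"),
    estimate = c(x$dH_kJ_mol, x$dS_J_mol_K),
    std.error = c(x$dH_se, x$dS_se)
  )
}

#' @rdname tidy.vant_hoff_fit
#' @export
glance.vant_hoff_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    nobs = nrow(x$by_temperature),
    force_label = x$force_label,
    spontaneous = x$spontaneous
  )
}

#' Tidy a multi-exponential decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble of components (`tau_ns`, `alpha`).
#' @export
tidy.decay_fit <- function(x, ...) {
  x$components
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    tau_avg_ns = x$tau_avg,
    tau_avg_se = x$tau_avg_se,
    chisq_red = x$chisq_red,
    nobs = x$n_channels
  )
}
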