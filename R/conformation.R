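#' Mean residue ellipticity from raw circular-dichroism signal
#'
#' \deqn{MRE = \frac{\theta\,(\mathrm{mdeg})}{10\, C_p\, n\, l}} with the
#' protein concentration \eqn{C_p} in mol/L, \eqn{n} the residue count and
#' \eqn{l} the path length in cm; the result is in deg cm^2 dmol^-1.
#'
#' @param theta Ellipticity in millidegrees (any sign). Vectorised.
#' @param C_p Molar protein concentration (> 0).
#' @param n_res Number of protein residues (585 for human serum albumin).
#' @param l Path length, cm (default 1).
#' @return Mean residue ellipticity, deg cm^2 dmol^-1.
#' @examples
#' mre(-223.5, 2e-6, 585, 1) # about -19103
#' @export
mre <- function(theta, C_p, n_res, l = 1) {
  stopifnot_scalar_pos(C_p, "C_p")
  stopifnot_scalar_pos(n_res, "n_res")
  stopifnot_scalar_pos(l, "l")
  theta / (C_p * n_res * l * 10)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' Linear interpolation between the 208 nm mean-residue-ellipticity reference
#' values of random coil (-4,000) and pure alpha-helix (-33,000):
#' \deqn{\alpha\text{-helix}\,(\%) = \frac{-MRE_{208} - 4000}{33000 - 4000}
#'   \times 100}
#' Values outside \[0, 100\] are returned unclipped with a warning - they are
#' diagnostic of a bad input, not silently truncated.
#'
#' @param MRE_208 Mean residue ellipticity at 208 nm, deg cm^2 dmol^-1.
#'   Vectorised.
#' @return Helix content in percent.
#' @examples
#' helix_fraction(-19103.2) # 52.08
#' @export
helix_fraction <- function(MRE_208) {
  if (any(!is.finite(MRE_208))) abort("MRE_208 must be finite")
  h <- (-MRE_208 - 4000) / 29000 * 100
  if (any(h < 0 | h > 100)) warn("helix fraction outside [0, 100]: check the input")
  h
}

mre_at_208 <- function(wavelength_nm, theta_mdeg) {
  if (min(wavelength_nm) > 208 || max(wavelength_nm) < 208) {
    abort("208 nm lies outside the wavelength grid")
  }
  i <- which.min(abs(wavelength_nm - 208))
  theta_mdeg[i]
}

#' Helix-content changes across a series of CD spectra
#'
#' Computes the alpha-helix percentage of each spectrum from its ellipticity
#' at the grid point nearest 208 nm (via [mre()] and [helix_fraction()]) and
#' the change relative to the first (reference) spectrum.
#'
#' @param spectra Long data frame with columns `label`, `wavelength_nm`,
#'   `theta_mdeg`, `C_p_molar`, `n_res`, `path_cm` (metadata constant within
#'   each label). Labels are processed in order of first appearance; the first
#'   is the reference.
#' @return A tibble with one row per label: `label`, `mre_208`, `helix_pct`,
#'   `delta_helix_pct` (vs the reference).
#' @export
helix_change <- function(spectra) {
  req <- c("label", "wavelength_nm", "theta_mdeg", "C_p_molar", "n_res", "path_cm")
  if (!all(req %in% names(spectra))) {
    abort(paste("need columns", paste(req, collapse = ", ")))
  }
  labels <- unique(spectra$label)
  if (length(labels) < 2L) abort("at least 2 spectra required")
  out <- purrr::map(labels, function(lb) {
    d <- dplyr::filter(spectra, .data$label == lb) |>
      dplyr::arrange(.data$wavelength_nm)
    theta208 <- mre_at_208(d$wavelength_nm, d$theta_mdeg)
    m <- mre(theta208, d$C_p_molar[1], d$n_res[1], d$path_cm[1])
    tibble::tibble(label = lb, mre_208 = m, helix_pct = helix_fraction(m))
  }) |>
    purrr::list_rbind()
  out$delta_helix_pct <- out$helix_pct - out$helix_pct[1]
  out
}

#' Peak shift between two synchronous-fluorescence spectra
#'
#' Locates each spectrum's emission maximum by 3-point quadratic interpolation
#' around the maximal grid point (sub-grid shifts are invisible to a bare
#' argmax on coarse grids) and reports the shift of the perturbed spectrum
#' relative to the reference. Shifts within 0.5 nm are called `"none"`.
#'
#' @param reference,perturbed Data frames with columns `wavelength_nm` and
#'   `intensity` on identical grids.
#' @return A list with `delta_lambda_nm` and `direction` (`"blue"`, `"red"`,
#'   `"none"`).
#' @export
peak_shift <- function(reference, perturbed) {
  for (d in list(reference, perturbed)) {
    if (!all(c("wavelength_nm", "intensity") %in% names(d))) {
      abort("spectra need columns `wavelength_nm` and `intensity`")
    }
  }
  if (nrow(reference) != nrow(perturbed) ||
      max(abs(reference$wavelength_nm - perturbed$wavelength_nm)) > 1e-9) {
    abort("wavelength grids must match")
  }
  locate <- function(w, y) {
    i <- which.max(y)
    if (i == 1L || i == length(y)) return(w[i])
    # quadratic through the three points around the maximum
    dw <- w[i + 1] - w[i]
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom == 0) return(w[i])
    w[i] + 0.5 * dw * (y[i - 1] - y[i + 1]) / denom
  }
  l_ref <- locate(reference$wavelength_nm, reference$intensity)
  l_per <- locate(perturbed$wavelength_nm, perturbed$intensity)
  d <- l_per - l_ref
  list(
    delta_lambda_nm = d,
    direction = if (d < -0.5) "blue" else if (d > 0.5) "red" else "none"
  )
}
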