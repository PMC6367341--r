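#' Default ground truth for the synthetic generators
#'
#' Study conditions of the serum-albumin / azo-colorant system: three
#' temperatures with Stern-Volmer constants around 1e5 L/mol that fall with
#' temperature, a tri-exponential tryptophan decay near 5.6 ns, helix content
#' near 52%, and a site-I binding ligand.
#'
#' @return A named list of generator defaults (`K_SV`, `K_a`, `n`,
#'   `lifetime_components`, `helix_pct`, `planted_site`, trajectory plateau
#'   values).
#' @export
default_truth <- function() {
  list(
    temperatures_K = c(298, 304, 310),
    K_SV = c(1.26e5, 1.11e5, 1.00e5),
    K_a = c(1.14e5, 1.03e5, 0.85e5),
    n = 1,
    lifetime_components = tibble::tibble(
      tau_ns = c(3.09, 4.72, 6.83),
      alpha = c(0.31, 0.04, 0.65)
    ),
    helix_pct = c(52.08, 49.25, 47.69),
    planted_site = "site_I",
    plateau_rmsd_A = 3.4,
    plateau_rg_A = 27.6
  )
}

#' Simulate a fluorescence quenching titration
#'
#' Static-quenching model: the true intensity follows
#' \eqn{F = F_0 / (1 + K_{SV} [Q])}; with Hill coefficient `n != 1` the
#' bound fraction generalises to \eqn{F = F_0/(1 + K_a [Q]^n)}. Optional
#' inner-filter attenuation multiplies by \eqn{e^{-(A_{ex}+A_{em})/2}} with
#' absorbances linear in quencher concentration. Noise is multiplicative
#' Gaussian with coefficient of variation `noise_cv`.
#'
#' @param K_SV Quenching constants, L/mol, one per temperature.
#' @param temperatures_K Temperatures (K), same length as `K_SV`.
#' @param n Hill coefficient (default 1, single-site).
#' @param F0 Reference intensity at zero quencher.
#' @param Q_grid Quencher concentrations in mol/L (must include 0). The study
#'   design is 0-6 uM in 1 uM steps.
#' @param noise_cv Coefficient of variation of multiplicative noise
#'   (default 0.01, a typical spectrofluorometer repeatability).
#' @param ife Absorbance-per-molar slopes `c(ex = ..., em = ...)` for a
#'   simulated inner-filter effect, or `NULL` (default) for none.
#' @param seed Integer seed; the output is reproducible per seed.
#' @return A tibble with columns `temperature_K`, `Q_molar`, `F_obs`, `A_ex`,
#'   `A_em` (and the noise-free `F_true`), one block per temperature.
#' @export
gen_titration <- function(K_SV = default_truth()$K_SV,
                          temperatures_K = default_truth()$temperatures_K,
                          n = 1, F0 = 1000,
                          Q_grid = seq(0, 6e-6, by = 1e-6),
                          noise_cv = 0.01, ife = NULL, seed = 1L) {
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (length(K_SV) != length(temperatures_K)) {
    abort("K_SV and temperatures_K must have equal length")
  }
  withr::with_seed(seed, {
    purrr::map2(K_SV, temperatures_K, function(k, temp) {
      F_true <- F0 / (1 + k * Q_grid^n)
      A_ex <- if (is.null(ife)) rep(0, length(Q_grid)) else ife[["ex"]] * Q_grid
      A_em <- if (is.null(ife)) rep(0, length(Q_grid)) else ife[["em"]] * Q_grid
      F_obs <- F_true * exp(-(A_ex + A_em) / 2)
      if (noise_cv > 0) F_obs <- F_obs * (1 + rnorm(length(F_obs), 0, noise_cv))
      tibble::tibble(
        temperature_K = temp, Q_molar = Q_grid,
        F_obs = F_obs, A_ex = A_ex, A_em = A_em, F_true = F_true
      )
    }) |>
      purrr::list_rbind()
  })
}

#' Simulate a photon-counting decay histogram
#'
#' Expected counts \eqn{\mu(t) = b + \sum_i A_i e^{-t/\tau_i}} scaled so the
#' maximum equals `peak_counts`; observed counts are Poisson draws.
#'
#' @param components Tibble with columns `tau_ns` and `alpha` (pre-exponential
#'   fractions). Defaults to the free-protein tri-exponential truth.
#' @param peak_counts Expected counts in the peak channel (>= 100).
#' @param n_channels Number of time channels.
#' @param channel_width_ns Channel width, ns. The defaults span ~51 ns,
#'   about nine mean lifetimes.
#' @param baseline Constant dark-count level per channel.
#' @param seed Integer seed.
#' @return A tibble with `time_ns`, `counts` and the noise-free `mu`.
#' @export
gen_decay <- function(components = default_truth()$lifetime_components,
                      peak_counts = 1e4, n_channels = 1024,
                      channel_width_ns = 0.05, baseline = 0, seed = 1L) {
  if (peak_counts < 100) abort("peak_counts must be >= 100")
  t <- (seq_len(n_channels) - 1) * channel_width_ns
  shape <- rowSums(vapply(seq_len(nrow(components)), function(i) {
    components$alpha[i] * exp(-t / components$tau_ns[i])
  }, numeric(length(t))))
  mu <- baseline + (peak_counts - baseline) * shape / max(shape)
  withr::with_seed(seed, {
    tibble::tibble(time_ns = t, counts = rpois(length(mu), mu), mu = mu)
  })
}

#' Simulate a far-UV circular-dichroism spectrum series
#'
#' A smooth double-minimum alpha-helical template (bands at 208 and 220 nm)
#' is scaled so the 208 nm mean residue ellipticity equals
#' \eqn{-(4000 + 290\,h)} for helix content `h` percent, then converted to raw
#' millidegrees through the mean-residue-ellipticity relation.
#'
#' @param helix_pct Helix percentages, one spectrum each (default: the free,
#'   1:1 and 1:3 study series).
#' @param labels Spectrum labels (default `"ratio_1"`, ... or names of
#'   `helix_pct`).
#' @param C_p Molar protein concentration (default 2e-6).
#' @param n_res Residue count (default 585).
#' @param l Path length, cm.
#' @param wavelength_nm Wavelength grid (default 190-260 nm by 0.5).
#' @param noise_mdeg Additive Gaussian noise SD in mdeg (default 0).
#' @param seed Integer seed.
#' @return Long tibble: `label`, `wavelength_nm`, `theta_mdeg`, `C_p_molar`,
#'   `n_res`, `path_cm` - the shape [helix_change()] consumes.
#' @export
gen_cd <- function(helix_pct = default_truth()$helix_pct, labels = NULL,
                   C_p = 2e-6, n_res = 585, l = 1,
                   wavelength_nm = seq(190, 260, by = 0.5),
                   noise_mdeg = 0, seed = 1L) {
  if (any(helix_pct < 0 | helix_pct > 100)) abort("helix_pct must be in [0, 100]")
  labels <- labels %||% names(helix_pct) %||% paste0("spectrum_", seq_along(helix_pct))
  template <- exp(-(wavelength_nm - 208)^2 / (2 * 6.5^2)) +
    0.93 * exp(-(wavelength_nm - 220)^2 / (2 * 7.5^2))
  t208 <- template[which.min(abs(wavelength_nm - 208))]
  withr::with_seed(seed, {
    purrr::map2(helix_pct, labels, function(h, lb) {
      mre208 <- -(4000 + 290 * h)
      mre_curve <- mre208 * template / t208
      theta <- mre_curve * (C_p * n_res * l * 10)
      if (noise_mdeg > 0) theta <- theta + rnorm(length(theta), 0, noise_mdeg)
      tibble::tibble(
        label = lb, wavelength_nm = wavelength_nm, theta_mdeg = theta,
        C_p_molar = C_p, n_res = n_res, path_cm = l
      )
    }) |>
      purrr::list_rbind()
  })
}

#' Simulate site-marker competitive-displacement curves
#'
#' Probes marking the planted site displace the ligand: their intensity
#' ratio declines linearly to `1 - drop` at the final molar ratio. Probes of
#' other sites stay flat, and probes flagged `"step"` show the
#' cooperative-binding signature (an initial drop, then flat).
#'
#' @param drops Named numeric vector of total drops per probe (names are probe
#'   names known to [probe_sites()] unless `sites` is given).
#' @param patterns Named character vector `"linear"`/`"step"` per probe;
#'   unnamed probes default to `"linear"`.
#' @param sites Optional named character vector overriding the bundled
#'   probe-site map.
#' @param ratios Probe:ligand molar ratios (default 0 to 3 by 0.5).
#' @param noise_sd Additive Gaussian noise on the intensity ratio
#'   (default 0.01).
#' @param F0 Probe-free intensity scale.
#' @param seed Integer seed.
#' @return Long tibble: `probe`, `probe_site`, `ratio`, `I`, `F`.
#' @export
gen_competition <- function(drops = c("warfarin" = 0.35,
                                      "dansyl-L-arginine" = 0.20,
                                      "ibuprofen" = 0.03,
                                      "dansyl-L-sarcosine" = 0.10),
                            patterns = c("dansyl-L-sarcosine" = "step"),
                            sites = NULL, ratios = seq(0, 3, by = 0.5),
                            noise_sd = 0.01, F0 = 1000, seed = 1L) {
  if (any(drops < 0 | drops > 1)) abort("drops must be in [0, 1]")
  site_map <- sites %||% setNames(probe_sites()$probe_site, probe_sites()$probe)
  withr::with_seed(seed, {
    purrr::imap(drops, function(drop, probe) {
      pattern <- patterns[probe] %||% "linear"
      if (is.na(pattern)) pattern <- "linear"
      I <- if (pattern == "step") {
        ifelse(ratios == 0, 1, 1 - drop)
      } else {
        1 - drop * ratios / max(ratios)
      }
      if (noise_sd > 0) {
        jitter <- rnorm(length(I), 0, noise_sd)
        jitter[ratios == 0] <- 0  # the reference point defines I = 1
        I <- I + jitter
      }
      tibble::tibble(
        probe = probe,
        probe_site = unname(site_map[probe]),
        ratio = ratios, I = I, F = I * F0
      )
    }) |>
      purrr::list_rbind()
  })
}

#' Simulate a molecular-dynamics-like trajectory with a planted plateau
#'
#' Builds a compact random-coil reference scaled to the requested radius of
#' gyration, then perturbs it frame by frame with an isotropic displacement
#' whose root-mean-square amplitude ramps linearly to `plateau_rmsd` over the
#' first `ramp_frac` of the run and holds there, composed with a random rigid
#' motion per frame (which superposition must undo).
#'
#' @param n_atoms Number of (carbon-mass) atoms.
#' @param n_frames Number of frames.
#' @param plateau_rmsd Planted plateau RMSD, \eqn{\text{\AA}}.
#' @param plateau_rg Radius of gyration of the reference, \eqn{\text{\AA}}.
#' @param dt_ps Frame spacing, ps (default 10, the usual trajectory stride).
#' @param ramp_frac Fraction of the run spent ramping (default 0.4).
#' @param seed Integer seed.
#' @return A list: `model` (reference atom tibble), `frames` (list of
#'   coordinate matrices), `time_ps`, and `truth` (the planted values).
#' @export
gen_trajectory <- function(n_atoms = 200, n_frames = 300, plateau_rmsd = 3.4,
                           plateau_rg = 27.6, dt_ps = 10, ramp_frac = 0.4,
                           seed = 1L) {
  if (plateau_rmsd <= 0 || plateau_rg <= 0) abort("plateau values must be positive")
  withr::with_seed(seed, {
    ref <- matrix(rnorm(n_atoms * 3), ncol = 3)
    ref <- sweep(ref, 2, colMeans(ref))
    ref <- ref * plateau_rg / radius_of_gyration(ref)
    ramp_end <- max(1L, floor(ramp_frac * n_frames))
    target <- pmin(seq_len(n_frames) / ramp_end, 1) * plateau_rmsd
    frames <- lapply(seq_len(n_frames), function(i) {
      D <- matrix(rnorm(n_atoms * 3), ncol = 3)
      D <- sweep(D, 2, colMeans(D))
      D <- D * target[i] / sqrt(mean(rowSums(D^2)))
      X <- ref + D
      # random rigid motion; a correct analysis removes it exactly
      ang <- stats::runif(1, 0, 2 * pi)
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      sweep(X %*% Rm, 2, stats::runif(3, -10, 10), `+`)
    })
    model <- tibble::tibble(
      serial = seq_len(n_atoms), name = "CA", element = "C",
      resid = "ALA", resno = seq_len(n_atoms), chain = "A",
      x = ref[, 1], y = ref[, 2], z = ref[, 3],
      mass = 12.011, type = "ATOM"
    )
    list(
      model = model, frames = frames,
      time_ps = (seq_len(n_frames) - 1) * dt_ps,
      truth = list(plateau_rmsd_A = plateau_rmsd, plateau_rg_A = plateau_rg,
                   ramp_end_ps = (ramp_end - 1) * dt_ps, seed = seed)
    )
  })
}
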