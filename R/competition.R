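#' Site-marker probes and the albumin sites they mark
#'
#' Warfarin marks Sudlow's site I (subdomain IIA) and ibuprofen site II
#' (subdomain IIIA); dansyl-L-arginine occupies the FA7 pocket overlapping
#' site I, and dansyl-L-sarcosine the FA1 heme cleft (site III, subdomain IB).
#'
#' @return A tibble with columns `probe` and `probe_site`.
#' @export
probe_sites <- function() {
  tibble::tibble(
    probe = c("warfarin", "ibuprofen", "dansyl-L-arginine", "dansyl-L-sarcosine"),
    probe_site = c("site_I", "site_II", "site_I", "site_III")
  )
}

#' Displacement ratio of a ligand-protein complex under a competing probe
#'
#' \eqn{I = F/F_0}: the fluorescence of the complex at a given probe:ligand
#' molar ratio relative to the probe-free intensity. Scale-invariant in the
#' intensity units.
#'
#' @param F Intensity in the presence of probe (>= 0). Vectorised.
#' @param F0 Probe-free intensity (> 0).
#' @return Fraction `F / F0`.
#' @export
displacement_ratio <- function(F, F0) {
  if (any(F0 <= 0)) abort("F0 must be positive")
  if (any(F < 0)) abort("F must be non-negative")
  F / F0
}

#' Trend of a competitive-displacement curve
#'
#' Summarises one probe's displacement curve: the OLS slope of \eqn{I} against
#' molar ratio, the total intensity drop at the final ratio, whether the curve
#' is monotonically decreasing (pairwise, with 1% tolerance), and whether it
#' shows the step-then-flat signature of cooperative binding at a distinct
#' site (an initial drop followed by a flat tail).
#'
#' @param data Data frame with columns `ratio` (probe:ligand molar ratio,
#'   ascending, including 0) and either `I` (displacement ratio) or `F`
#'   (intensity; the `ratio == 0` row then defines F0).
#' @param flat_tol Relative tolerance used in the monotonicity / flatness
#'   checks (default 0.01).
#' @return A one-row tibble: `slope`, `total_drop`, `monotone_decreasing`,
#'   `step_then_flat`.
#' @export
displacement_trend <- function(data, flat_tol = 0.01) {
  if (!"ratio" %in% names(data)) abort("need a `ratio` column")
  data <- dplyr::arrange(data, .data$ratio)
  if (any(data$ratio < 0)) abort("ratios must be non-negative")
  if (!"I" %in% names(data)) {
    if (!"F" %in% names(data)) abort("need an `I` or `F` column")
    F0 <- data$F[data$ratio == 0]
    if (length(F0) != 1L) abort("need exactly one ratio = 0 row to define F0")
    data$I <- displacement_ratio(data$F, F0)
  }
  if (nrow(data) < 3L) abort("at least 3 ratios required")
  fit <- lm(I ~ ratio, data = data)
  d <- diff(data$I)
  monotone <- all(d <= flat_tol)
  total_drop <- 1 - data$I[nrow(data)]
  # step-then-flat: a real initial drop, then a tail whose fitted trend adds
  # little further change (noise-robust via the tail OLS slope)
  first_drop <- data$I[1] - data$I[2]
  tail_pts <- data[-1, , drop = FALSE]
  tail_fit <- lm(I ~ ratio, data = tail_pts)
  tail_change <- abs(coef(tail_fit)[2]) * diff(range(tail_pts$ratio))
  step_flat <- first_drop >= 5 * flat_tol &&
    tail_change <= max(2 * flat_tol, first_drop / 3)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    total_drop = total_drop,
    monotone_decreasing = monotone,
    step_then_flat = step_flat
  )
}

#' Assign the ligand's binding site from a panel of site-marker curves
#'
#' Probes are ranked by their total intensity drop among curves that decline
#' monotonically; step-then-flat curves (the cooperative-binding signature)
#' are excluded from the ranking but reported. The ligand is assigned the site
#' of the top-ranked probe when its drop reaches `min_drop` and exceeds the
#' best drop at any other site by at least `margin`; otherwise the assignment
#' is flagged ambiguous.
#'
#' @param data Long data frame with columns `probe`, `ratio` and `I` (or `F`
#'   with a `ratio == 0` reference row per probe). A `probe_site` column is
#'   joined from [probe_sites()] when absent.
#' @param min_drop Minimum total drop for an assignment (default 0.10).
#' @param margin Minimum lead over the best other-site drop (default 0.05).
#' @return A list with `site` (character or `NA`), `ambiguous` (logical) and
#'   `ranking`, a tibble of per-probe trends ordered by drop.
#' @export
assign_site <- function(data, min_drop = 0.10, margin = 0.05) {
  if (!"probe" %in% names(data)) abort("need a `probe` column")
  if (!"probe_site" %in% names(data)) {
    data <- dplyr::left_join(data, probe_sites(), by = "probe")
    if (any(is.na(data$probe_site))) abort("unknown probe; supply a `probe_site` column")
  }
  ranking <- data |>
    dplyr::group_by(.data$probe, .data$probe_site) |>
    dplyr::group_map(function(d, key) {
      dplyr::bind_cols(key, displacement_trend(d))
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$total_drop))
  if (dplyr::n_distinct(ranking$probe_site) < 2L) {
    abort("probes must cover at least 2 sites")
  }
  eligible <- dplyr::filter(ranking, .data$monotone_decreasing, !.data$step_then_flat)
  res <- list(site = NA_character_, ambiguous = TRUE, ranking = ranking)
  if (nrow(eligible) == 0L) return(res)
  top <- eligible[1, ]
  others <- dplyr::filter(eligible, .data$probe_site != top$probe_site)
  runner_up <- if (nrow(others)) max(others$total_drop) else 0
  if (top$total_drop >= min_drop && top$total_drop - runner_up >= margin) {
    res$site <- top$probe_site
    res$ambiguous <- FALSE
  }
  res
}
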