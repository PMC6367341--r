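read_checked_csv <- function(path, required) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(d) == 0L) abort(sprintf("empty file: %s", path))
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  d
}

#' Read a fluorescence titration CSV
#'
#' Expects comma-separated, dot-decimal data with a header row and columns
#' `temperature_K`, `Q_molar`, `F_obs`, `A_ex`, `A_em` - one block per
#' temperature, each containing exactly one `Q_molar == 0` row that defines
#' the reference intensity. Units are fixed (mol/L, K); temperatures are
#' kelvin everywhere in this package, never Celsius.
#'
#' @param path CSV path.
#' @return A tibble sorted by temperature then ascending quencher
#'   concentration.
#' @export
read_titration <- function(path) {
  d <- read_checked_csv(path, c("temperature_K", "Q_molar", "F_obs", "A_ex", "A_em"))
  d <- dplyr::arrange(d, .data$temperature_K, .data$Q_molar)
  for (temp in unique(d$temperature_K)) {
    blk <- d[d$temperature_K == temp, ]
    if (sum(blk$Q_molar == 0) != 1L) {
      abort(sprintf("no reference intensity: temperature %s needs exactly one Q = 0 row", temp))
    }
    if (anyDuplicated(blk$Q_molar)) {
      abort(sprintf("duplicate quencher concentrations at %s K", temp))
    }
  }
  d
}

#' Write a titration table to CSV (full numeric precision)
#' @param data Titration tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a photon-counting decay histogram CSV (`time_ns`, `counts`)
#' @param path CSV path.
#' @return Tibble validated for a uniform, strictly increasing time grid.
#' @export
read_decay <- function(path) {
  check_decay_histogram(read_checked_csv(path, c("time_ns", "counts")))
}

#' Read a circular-dichroism spectrum CSV
#'
#' Expects `wavelength_nm` and `theta_mdeg` plus either metadata columns
#' (`label`, `C_p_molar`, `n_res`, `path_cm`) or the corresponding arguments.
#'
#' @param path CSV path.
#' @param C_p,n_res,l Metadata used when the file carries none.
#' @param label Spectrum label when the file carries none.
#' @return Long tibble in the shape [helix_change()] consumes.
#' @export
read_cd <- function(path, C_p = NULL, n_res = NULL, l = NULL, label = NULL) {
  d <- read_checked_csv(path, c("wavelength_nm", "theta_mdeg"))
  if (!"label" %in% names(d)) d$label <- label %||% "spectrum_1"
  if (!"C_p_molar" %in% names(d)) d$C_p_molar <- C_p %||% abort("supply C_p")
  if (!"n_res" %in% names(d)) d$n_res <- n_res %||% abort("supply n_res")
  if (!"path_cm" %in% names(d)) d$path_cm <- l %||% abort("supply l")
  dplyr::arrange(d, .data$label, .data$wavelength_nm)
}

#' Read a site-marker competition CSV (`probe`, `ratio`, `F` or `I`)
#' @param path CSV path.
#' @return Long tibble sorted by probe and ratio.
#' @export
read_competition <- function(path) {
  d <- read_checked_csv(path, c("probe", "ratio"))
  if (!any(c("F", "I") %in% names(d))) abort("need an `F` or `I` column")
  dplyr::arrange(d, .data$probe, .data$ratio)
}

default_config <- function() {
  list(
    mechanism_lifetime_tolerance = 0.05,
    n_decay_components = 3,
    contact_cutoff_A = 3.5,
    min_drop = 0.10,
    site_margin = 0.05,
    seed = 1L
  )
}

input_digest <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    rlang::hash(x)
  }
}

as_stage_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

run_stage <- function(expr) {
  tryCatch(
    c(list(ok = TRUE), expr),
    error = function(e) list(ok = FALSE, error = conditionMessage(e))
  )
}

#' Run the full binding-analysis pipeline
#'
#' Chains the stages over whatever inputs are supplied; each stage that fails
#' records its error in the report without aborting the others. Given fixed
#' inputs and configuration the report is deterministic.
#'
#' @param inputs Named list; any subset of
#'   \describe{
#'     \item{`titration`}{tibble or CSV path ([read_titration()] shape)}
#'     \item{`decay_free`, `decay_bound`}{decay tibbles or CSV paths}
#'     \item{`competition`}{competition tibble or CSV path}
#'     \item{`cd`}{CD long tibble or CSV path (then needs metadata columns)}
#'     \item{`ligand`, `protein`}{atom tibbles or PDB paths for contact
#'       analysis}
#'     \item{`trajectory`}{list with `model`, `frames`, `time_ps` (e.g. from
#'       [gen_trajectory()] or [parse_trajectory()])}
#'   }
#' @param config Named list overriding [pipeline defaults][run_pipeline]:
#'   `mechanism_lifetime_tolerance` (0.05), `n_decay_components` (3),
#'   `contact_cutoff_A` (3.5), `min_drop` (0.10), `site_margin` (0.05),
#'   `seed`.
#' @return A list of class `binding_report`: `stages` (one entry per stage
#'   run) and `provenance` (input digests, config echo, package version).
#' @export
run_pipeline <- function(inputs, config = list()) {
  if (length(inputs) == 0L) abort("at least one stage input required")
  cfg <- utils::modifyList(default_config(), config)
  stages <- list()

  lifetime_change <- NULL
  if (!is.null(inputs$decay_free)) {
    stages$lifetime <- run_stage({
      free <- fit_decay(as_stage_input(inputs$decay_free, read_decay),
                        cfg$n_decay_components)
      out <- list(free = decay_fit_summary(free))
      if (!is.null(inputs$decay_bound)) {
        bound <- fit_decay(as_stage_input(inputs$decay_bound, read_decay),
                           cfg$n_decay_components)
        cmp <- compare_lifetimes(free, bound, cfg$mechanism_lifetime_tolerance)
        out$bound <- decay_fit_summary(bound)
        out$comparison <- as.list(cmp)
      }
      out
    })
    if (isTRUE(stages$lifetime$ok) && !is.null(stages$lifetime$comparison)) {
      lifetime_change <- stages$lifetime$comparison$relative_change
    }
  }

  if (!is.null(inputs$titration)) {
    stages$quenching <- run_stage({
      titr <- as_stage_input(inputs$titration, read_titration)
      qt <- quench_table(titr)
      list(
        table = qt,
        mechanism = classify_mechanism(
          dplyr::select(qt, "temperature_K", "K_SV"),
          lifetime_change = lifetime_change,
          tolerance = cfg$mechanism_lifetime_tolerance
        )
      )
    })
    stages$thermo <- run_stage({
      qt <- stages$quenching$table
      if (is.null(qt)) abort("quenching stage failed; no K_a series")
      vh <- vant_hoff(dplyr::select(qt, "temperature_K", "K_a"))
      list(
        dH_kJ_mol = vh$dH_kJ_mol, dH_se = vh$dH_se,
        dS_J_mol_K = vh$dS_J_mol_K, dS_se = vh$dS_se,
        r_squared = vh$r_squared, force_label = vh$force_label,
        spontaneous = vh$spontaneous,
        by_temperature = vh$by_temperature
      )
    })
  }

  if (!is.null(inputs$competition)) {
    stages$competition <- run_stage({
      comp <- as_stage_input(inputs$competition, read_competition)
      res <- assign_site(comp, min_drop = cfg$min_drop, margin = cfg$site_margin)
      list(site = res$site, ambiguous = res$ambiguous, ranking = res$ranking)
    })
  }

  if (!is.null(inputs$cd)) {
    stages$cd <- run_stage({
      list(helix = helix_change(as_stage_input(inputs$cd, read_cd)))
    })
  }

  if (!is.null(inputs$ligand) && !is.null(inputs$protein)) {
    stages$structure_contacts <- run_stage({
      lig <- as_stage_input(inputs$ligand, parse_structure)
      pro <- as_stage_input(inputs$protein, parse_structure)
      list(contacts = find_polar_contacts(lig, pro, cfg$contact_cutoff_A))
    })
  }

  if (!is.null(inputs$trajectory)) {
    stages$trajectory <- run_stage({
      tr <- inputs$trajectory
      st <- trajectory_stats(tr$frames, tr$model, time_ps = tr$time_ps)
      list(
        plateau_start_ps = st$plateau_start_ps,
        plateau_mean_rmsd_A = st$plateau_mean_rmsd,
        plateau_mean_rg_A = st$plateau_mean_rg,
        n_frames = nrow(st$series)
      )
    })
  }

  structure(
    list(
      stages = stages,
      provenance = list(
        package_version = as.character(packageVersion("quenchbind")),
        config = cfg,
        input_digests = lapply(inputs, input_digest)
      )
    ),
    class = "binding_report"
  )
}

decay_fit_summary <- function(fit) {
  list(
    components = fit$components,
    tau_avg_ns = fit$tau_avg,
    tau_avg_se = fit$tau_avg_se,
    chisq_red = fit$chisq_red
  )
}

#' Write a pipeline report to JSON
#'
#' Numbers are written at full precision so that write-read round trips are
#' lossless and identical inputs reproduce byte-identical report bodies (no
#' timestamps are stored).
#'
#' @param report A `binding_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a pipeline report back from JSON
#' @param path JSON path written by [write_report()].
#' @return A `binding_report` (tabular stage members come back as lists of
#'   columns; numeric values round-trip at full double precision).
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat("binding-analysis report:", paste(names(x$stages), collapse = ", "), "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    status <- if (isTRUE(st$ok)) "ok" else paste("FAILED:", st$error)
    cat(sprintf("  %-18s %s\n", nm, status))
  }
  invisible(x)
}
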