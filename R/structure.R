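ELEMENT_MASSES <- stats::setNames(
  c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 55.845, 65.38, 22.990, 35.45),
  c("H", "C", "N", "O", "S", "P", "FE", "ZN", "NA", "CL")
)

element_mass <- function(element) {
  m <- ELEMENT_MASSES[toupper(element)]
  missing <- is.na(m)
  if (any(missing)) {
    m[missing] <- vapply(element[missing], function(e) {
      tryCatch(bio3d::atom2mass(e), error = function(err) NA_real_)
    }, numeric(1))
  }
  unname(m)
}

#' Parse a PDB file into an atom table
#'
#' Reads ATOM/HETATM records (via \pkg{bio3d}); of alternate locations only
#' blank or 'A' are kept, and waters can be stripped. Elements come from PDB
#' columns 77-78 when present, falling back to atom-name heuristics.
#'
#' @param path Path to a PDB file.
#' @param strip_water Drop water residues (HOH/WAT) if `TRUE`.
#' @param hetatm Keep HETATM records (default `TRUE`).
#' @return A tibble with columns `serial`, `name`, `element`, `resid`,
#'   `resno`, `chain`, `x`, `y`, `z` (\eqn{\text{\AA}}), `mass` (amu), `type`.
#' @export
parse_structure <- function(path, strip_water = FALSE, hetatm = TRUE) {
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) abort("no atoms in PDB input")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (strip_water) at <- at[!at$resid %in% c("HOH", "WAT", "H2O"), , drop = FALSE]
  if (nrow(at) == 0L) abort("no atoms left after filtering")
  element <- at$elesy
  blank <- is.na(element) | element == ""
  if (any(blank)) {
    element[blank] <- vapply(at$elety[blank], function(n) {
      tryCatch(bio3d::atom2ele(n), error = function(e) {
        sub("^[0-9]*([A-Za-z]).*$", "\\1", n)
      })
    }, character(1))
  }
  tibble::tibble(
    serial = at$eleno,
    name = at$elety,
    element = toupper(element),
    resid = at$resid,
    resno = at$resno,
    chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    mass = element_mass(toupper(element)),
    type = at$type
  )
}

#' Parse a multi-model PDB file as a trajectory
#'
#' @param path Path to a multi-model PDB file (one MODEL per frame, constant
#'   atom ordering).
#' @param dt_ps Time between frames, ps (default 10). PDB files carry no
#'   times, so they are reconstructed as `0, dt, 2 dt, ...`.
#' @inheritParams parse_structure
#' @return A list with `model` (atom tibble of the first frame), `frames`
#'   (list of n-by-3 coordinate matrices) and `time_ps`.
#' @export
parse_trajectory <- function(path, dt_ps = 10, strip_water = FALSE) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) abort("no atoms in PDB input")
  model <- parse_structure(path, strip_water = strip_water)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  keep <- pdb$atom$eleno %in% model$serial
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    m[keep, , drop = FALSE]
  })
  list(model = model, frames = frames,
       time_ps = (seq_along(frames) - 1) * dt_ps)
}

#' Select atoms from an atom table
#'
#' @param model Atom tibble from [parse_structure()].
#' @param selection `"heavy"` (non-hydrogen, the default for RMSD),
#'   `"backbone"` (N, CA, C, O of ATOM records) or `"all"`.
#' @param chain Optional chain filter.
#' @return Logical index vector over the rows of `model`.
#' @export
select_atoms <- function(model, selection = c("heavy", "backbone", "all"),
                         chain = NULL) {
  selection <- match.arg(selection)
  idx <- switch(selection,
    heavy = model$element != "H",
    backbone = model$type == "ATOM" & model$name %in% c("N", "CA", "C", "O"),
    all = rep(TRUE, nrow(model))
  )
  if (!is.null(chain)) idx <- idx & model$chain %in% chain
  idx
}

coords_of <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(x[, c("x", "y", "z")])
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of a mobile coordinate set onto a reference by
#' singular value decomposition of the covariance matrix; a proper rotation
#' (determinant +1) is enforced, so reflections never occur.
#'
#' @param mobile,reference n-by-3 coordinate matrices (or atom tibbles) with
#'   matching atom order, n >= 3, not collinear.
#' @return A list with `rotation` (3x3), `translation` (length 3; the aligned
#'   coordinates are `mobile %*% rotation + translation`), `rmsd`
#'   (\eqn{\text{\AA}} after superposition) and `aligned` (the transformed
#'   mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- coords_of(mobile); Q <- coords_of(reference)
  if (nrow(P) != nrow(Q)) abort("coordinate sets must have equal atom counts")
  if (nrow(P) < 3L) abort("at least 3 atoms required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_rank <- svd(Pc)$d
  if (sv_rank[2] < 1e-8 * max(sv_rank[1], 1)) abort("collinear coordinate set")
  C <- crossprod(Pc, Qc)
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  list(
    rotation = R,
    translation = cq - drop(cp %*% R),
    rmsd = rmsd,
    aligned = sweep(aligned, 2, cq, `+`)
  )
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of atoms from their centre of
#' mass: \eqn{R_g = \sqrt{\sum m_i |r_i - r_{com}|^2 / \sum m_i}}. With
#' `masses = NULL` all atoms weigh equally (geometric Rg).
#'
#' @param coords n-by-3 coordinate matrix or atom tibble (masses then taken
#'   from its `mass` column unless overridden).
#' @param masses Optional atomic masses, amu.
#' @return Radius of gyration in \eqn{\text{\AA}}.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  if (is.data.frame(coords) && is.null(masses) && "mass" %in% names(coords)) {
    masses <- coords$mass
  }
  X <- coords_of(coords)
  if (nrow(X) < 1L) abort("at least one atom required")
  if (is.null(masses)) masses <- rep(1, nrow(X))
  if (any(masses <= 0) || length(masses) != nrow(X)) abort("masses must be positive, one per atom")
  com <- colSums(X * masses) / sum(masses)
  sq <- rowSums(sweep(X, 2, com)^2)
  sqrt(sum(masses * sq) / sum(masses))
}

#' Per-frame RMSD / radius-of-gyration series with plateau statistics
#'
#' Each frame is rigidly superposed onto the reference over the selected
#' atoms (Kabsch); the per-frame RMSD and mass-weighted Rg are reported along
#' with the detected plateau. The plateau start is the first time after which
#' the sliding-window mean RMSD (window = 10% of the trajectory) changes by
#' less than 2% per window; plateau means are computed over frames at or
#' after that time.
#'
#' @param frames List of n-by-3 coordinate matrices (same atom order as the
#'   reference), e.g. from [parse_trajectory()] or [gen_trajectory()].
#' @param reference Reference atom tibble or coordinate matrix.
#' @param masses Atomic masses for Rg (taken from the reference tibble's
#'   `mass` column when available; equal weights otherwise).
#' @param time_ps Frame times, ps (default `0, 10, 20, ...`).
#' @param selection Logical/integer index of atoms to use (default all rows).
#' @param window Optional fixed `c(t_start, t_end)` in ps overriding plateau
#'   detection for the plateau means.
#' @param fit Superpose each frame before the RMSD (default `TRUE`); with
#'   `FALSE` the RMSD is computed in the fixed laboratory frame.
#' @return A list with `series` (tibble `time_ps`, `rmsd_A`, `rg_A`),
#'   `plateau_start_ps`, `plateau_mean_rmsd`, `plateau_mean_rg`.
#' @export
trajectory_stats <- function(frames, reference, masses = NULL, time_ps = NULL,
                             selection = NULL, window = NULL, fit = TRUE) {
  ref_is_df <- is.data.frame(reference)
  if (is.null(masses) && ref_is_df && "mass" %in% names(reference)) {
    masses <- reference$mass
  }
  R <- coords_of(reference)
  if (is.null(selection)) selection <- rep(TRUE, nrow(R))
  if (!any(selection)) abort("empty atom selection")
  Rs <- R[selection, , drop = FALSE]
  ms <- if (is.null(masses)) rep(1, sum(selection)) else masses[selection]
  if (is.null(time_ps)) time_ps <- (seq_along(frames) - 1) * 10
  series <- purrr::map2(frames, time_ps, function(fr, tp) {
    Fs <- coords_of(fr)[selection, , drop = FALSE]
    r <- if (fit) {
      kabsch_superpose(Fs, Rs)$rmsd
    } else {
      sqrt(mean(rowSums((Fs - Rs)^2)))
    }
    tibble::tibble(time_ps = tp, rmsd_A = r,
                   rg_A = radius_of_gyration(Fs, ms))
  }) |>
    purrr::list_rbind()

  if (is.null(window)) {
    plateau_start <- detect_plateau(series$time_ps, series$rmsd_A)
    in_plateau <- series$time_ps >= plateau_start
  } else {
    plateau_start <- window[1]
    in_plateau <- series$time_ps >= window[1] & series$time_ps <= window[2]
  }
  list(
    series = series,
    plateau_start_ps = plateau_start,
    plateau_mean_rmsd = mean(series$rmsd_A[in_plateau]),
    plateau_mean_rg = mean(series$rg_A[in_plateau])
  )
}

# first time after which the sliding-window mean changes < rel_tol per window
detect_plateau <- function(time_ps, values, frac = 0.10, rel_tol = 0.02) {
  n <- length(values)
  w <- max(2L, floor(frac * n))
  if (n <= 2L * w) return(time_ps[1])
  rm <- vapply(seq_len(n - w + 1L), function(i) mean(values[i:(i + w - 1L)]),
               numeric(1))
  lag <- w
  chg <- abs(rm[seq_len(length(rm) - lag) + lag] - rm[seq_len(length(rm) - lag)])
  rel <- chg / pmax(abs(rm[seq_len(length(rm) - lag)]), 1e-12)
  rel[chg == 0] <- 0
  ok <- rel < rel_tol
  idx <- which(rev(cumprod(rev(ok))) == 1)
  if (length(idx) == 0L) return(time_ps[n])  # never settles
  time_ps[idx[1]]
}

#' Polar contacts between a bound ligand and its protein
#'
#' Distance-based screen for hydrogen-bond candidates: every ligand N/O/S to
#' protein N/O/S pair within the cutoff is reported. Carbon-only pairs are
#' classified non-polar and excluded from the candidate list. No
#' donor/acceptor angle term is applied - distances are what docking reports
#' print.
#'
#' @param ligand,protein Atom tibbles from [parse_structure()].
#' @param cutoff Maximum donor-acceptor distance, \eqn{\text{\AA}}
#'   (default 3.5).
#' @return A tibble with `ligand_atom`, `protein_atom`, `protein_residue`,
#'   `distance_A`, `classification`, sorted by distance.
#' @export
find_polar_contacts <- function(ligand, protein, cutoff = 3.5) {
  if (cutoff <= 0) abort("cutoff must be positive")
  polar <- c("N", "O", "S")
  lig <- dplyr::filter(ligand, .data$element %in% polar)
  pro <- dplyr::filter(protein, .data$element %in% polar)
  if (nrow(lig) == 0L || nrow(pro) == 0L) {
    return(tibble::tibble(ligand_atom = character(), protein_atom = character(),
                          protein_residue = character(), distance_A = numeric(),
                          classification = character()))
  }
  D <- sqrt(outer(lig$x, pro$x, `-`)^2 +
            outer(lig$y, pro$y, `-`)^2 +
            outer(lig$z, pro$z, `-`)^2)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  tibble::tibble(
    ligand_atom = lig$name[hit[, 1]],
    protein_atom = pro$name[hit[, 2]],
    protein_residue = paste0(pro$resid[hit[, 2]], pro$resno[hit[, 2]]),
    distance_A = D[hit],
    classification = "hbond_candidate"
  ) |>
    dplyr::arrange(.data$distance_A)
}
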