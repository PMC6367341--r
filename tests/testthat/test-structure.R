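test_that("PDB parsing keeps one altloc, resolves elements and masses", {
  f <- write_pdb_fixture(demo_pdb_lines())
  at <- parse_structure(f)
  # altloc B dropped, water kept by default
  expect_equal(nrow(at), 5)
  expect_false(any(grepl("B$", at$name) & at$resid == "ARG" & at$serial == 4))
  expect_setequal(at$element, c("N", "C", "O"))
  expect_equal(at$mass[at$element == "N"][1], 14.007)
  expect_equal(at$x[at$serial == 5], 6.09)

  dry <- parse_structure(f, strip_water = TRUE)
  expect_false(any(dry$resid == "HOH"))
  atom_only <- parse_structure(f, hetatm = FALSE)
  expect_true(all(atom_only$type == "ATOM"))
})

test_that("atom selections behave", {
  f <- write_pdb_fixture(demo_pdb_lines())
  at <- parse_structure(f)
  expect_true(all(select_atoms(at, "heavy")))
  bb <- select_atoms(at, "backbone")
  expect_setequal(at$name[bb], c("N", "CA"))
  expect_equal(sum(select_atoms(at, "all")), nrow(at))
})

test_that("Kabsch superposition undoes an arbitrary rigid motion exactly", {
  X <- withr::with_seed(10, matrix(rnorm(150), ncol = 3))
  ang <- c(0.4, 1.1, -0.7)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0, -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  Y <- sweep(X %*% (Rx %*% Ry %*% Rz), 2, c(5, -3, 12), `+`)
  fit <- kabsch_superpose(Y, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$aligned, X, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # transform contract: mobile %*% rotation + translation = aligned
  expect_equal(sweep(Y %*% fit$rotation, 2, fit$translation, `+`), fit$aligned,
               tolerance = 1e-9)
})

test_that("Kabsch never returns a reflection and rejects degenerate input", {
  # a mirrored cloud must be fit by a proper rotation (rmsd > 0), not det = -1
  X <- withr::with_seed(11, matrix(rnorm(60), ncol = 3))
  Xm <- X %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(Xm, X)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_gt(fit$rmsd, 0.1)
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(X[1:10, ], X), "equal atom counts")
})

test_that("Kabsch RMSD matches the brute-force rotation-grid oracle", {
  for (s in 1:3) {
    withr::with_seed(100 + s, {
      X <- matrix(rnorm(150), ncol = 3)
      Y <- X + matrix(rnorm(150, sd = 0.8), ncol = 3)
    })
    k <- kabsch_superpose(Y, X)$rmsd
    g <- rotation_grid_rmsd(Y, X)
    expect_equal(k, g, tolerance = 1e-3)
    expect_lte(k, g + 1e-9)  # Kabsch is the optimum; the grid can only tie or lose
  }
})

test_that("radius of gyration matches closed forms and the direct sum", {
  # two unit masses 2 apart: Rg = 1
  expect_equal(radius_of_gyration(rbind(c(-1, 0, 0), c(1, 0, 0))), 1)
  # 4 corners of a square with side 2: every atom sqrt(2) from the centre
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2))
  # mass weighting moves the com: masses 3 and 1 at x = 0, 4 -> com at 1
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two, c(3, 1)), sqrt((3 * 1 + 1 * 9) / 4))
  X <- withr::with_seed(12, matrix(rnorm(90), ncol = 3))
  m <- withr::with_seed(13, runif(30, 1, 16))
  expect_equal(radius_of_gyration(X, m), rg_direct(X, m), tolerance = 1e-12)
  expect_error(radius_of_gyration(X, m[-1]), "one per atom")
})

test_that("trajectory statistics recover the planted plateau within 2%", {
  tr <- gen_trajectory(seed = 4)
  st <- trajectory_stats(tr$frames, tr$model, time_ps = tr$time_ps)
  expect_equal(st$plateau_mean_rmsd, 3.4, tolerance = 0.02)
  expect_equal(st$plateau_mean_rg, 27.6, tolerance = 0.02)
  expect_gte(st$plateau_start_ps, tr$truth$ramp_end_ps * 0.5)
  expect_lte(st$plateau_start_ps, tr$truth$ramp_end_ps * 1.8)
  expect_equal(nrow(st$series), length(tr$frames))
  # a fixed window overrides detection
  stw <- trajectory_stats(tr$frames, tr$model, time_ps = tr$time_ps,
                          window = c(2000, 2990))
  expect_equal(stw$plateau_start_ps, 2000)
  idx <- tr$time_ps >= 2000
  expect_equal(stw$plateau_mean_rmsd, mean(st$series$rmsd_A[idx]), tolerance = 1e-12)
})

test_that("without superposition the rigid motion dominates the RMSD", {
  tr <- gen_trajectory(n_frames = 40, seed = 5)
  fit_on <- trajectory_stats(tr$frames, tr$model, time_ps = tr$time_ps[1:40])
  fit_off <- trajectory_stats(tr$frames, tr$model, time_ps = tr$time_ps[1:40],
                              fit = FALSE)
  expect_gt(mean(fit_off$series$rmsd_A), mean(fit_on$series$rmsd_A))
})

test_that("polar contacts report N/O/S pairs within the cutoff, sorted", {
  pro <- parse_structure(write_pdb_fixture(demo_pdb_lines()), strip_water = TRUE)
  lig <- parse_structure(write_pdb_fixture(ligand_pdb_lines()))
  ct <- find_polar_contacts(lig, pro, cutoff = 3.5)
  expect_equal(nrow(ct), 2)
  expect_true(!is.unsorted(ct$distance_A))
  expect_equal(ct$distance_A[1], 3.09, tolerance = 1e-9)
  expect_identical(ct$protein_residue[1], "ARG197")
  expect_identical(ct$ligand_atom, c("O1", "O1"))
  # carbon never appears on either side
  expect_false(any(ct$protein_atom == "CA"))
  # tighter cutoff drops the longer contact
  expect_equal(nrow(find_polar_contacts(lig, pro, cutoff = 3.1)), 1)
  # no polar ligand atoms -> empty, typed
  lig_c <- dplyr::filter(lig, element == "C")
  empty <- find_polar_contacts(lig_c, pro)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("ligand_atom", "protein_atom", "protein_residue",
                        "distance_A", "classification"))
})
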