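# Independent oracles used to cross-check the package's numerics.

# Brute-force rotation search: minimises RMSD over rotations by a coarse
# Euler-angle grid followed by successive local refinement. Never touches the
# SVD path under test.
rotation_grid_rmsd <- function(mobile, reference, levels = 6) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, g) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  score <- function(a, b, g) sqrt(mean(rowSums((P %*% rot(a, b, g) - Q)^2)))
  centre <- c(0, pi / 2, 0)
  step <- pi / 12
  best <- c(centre, score(centre[1], centre[2], centre[3]))
  # level 1: full sweep at 15 degrees
  grid <- seq(0, 2 * pi - step, by = step)
  for (a in grid) for (b in seq(0, pi, by = step)) for (g in grid) {
    s <- score(a, b, g)
    if (s < best[4]) best <- c(a, b, g, s)
  }
  for (lv in seq_len(levels)) {
    step <- step / 3
    offs <- seq(-4, 4) * step
    for (a in best[1] + offs) for (b in best[2] + offs) for (g in best[3] + offs) {
      s <- score(a, b, g)
      if (s < best[4]) best <- c(a, b, g, s)
    }
  }
  best[4]
}

# direct-summation radius of gyration
rg_direct <- function(X, m = rep(1, nrow(X))) {
  com <- colSums(X * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m))
}

# brute-force grid search for a 2-component decay on noiseless data: profile
# the amplitudes (linear given taus) over a (tau1, tau2) grid
decay_grid_fit <- function(t, y, tau1_grid, tau2_grid) {
  best <- c(NA, NA, Inf)
  for (t1 in tau1_grid) for (t2 in tau2_grid) {
    if (t2 <= t1) next
    X <- cbind(exp(-t / t1), exp(-t / t2))
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best[3]) best <- c(t1, t2, rss)
  }
  best
}

# a minimal hand-written PDB: three protein atoms (one with altloc A/B),
# a water, and a ligand oxygen placed 3.09 A from a guanidinium nitrogen
demo_pdb_lines <- function() {
  c(
    "ATOM      1  N   ARG A 197       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ARG A 197       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  NH1AARG A 197       3.000   1.000   0.500  0.70  0.00           N",
    "ATOM      4  NH1BARG A 197       3.100   1.100   0.600  0.30  0.00           N",
    "ATOM      5  NE  ARG A 197       6.090   4.230   0.500  1.00  0.00           N",
    "HETATM    6  O   HOH A 300      18.000  18.000  18.000  1.00  0.00           O",
    "END"
  )
}

ligand_pdb_lines <- function() {
  # O1 sits 3.09 A from NH1A (3.0, 1.0, 0.5) along x
  c(
    "HETATM    1  O1  LIG B   1       6.090   1.000   0.500  1.00  0.00           O",
    "HETATM    2  C1  LIG B   1       7.200   1.000   0.500  1.00  0.00           C",
    "END"
  )
}

write_pdb_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
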