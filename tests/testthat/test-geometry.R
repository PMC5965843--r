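test_that("superposing identical coordinate sets gives zero RMSD and identity", {
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  sup <- kabsch_superpose(A, A)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-8)
})

test_that("a constructed rigid motion is inverted exactly", {
  set.seed(42)
  A <- matrix(rnorm(24), 8, 3)
  R <- rotation_matrix(c(0, 0, 1), 90)
  B <- sweep(A %*% t(R), 2, c(5, 0, 0), "+")
  sup <- kabsch_superpose(A, B)
  expect_lt(sup$rmsd, 1e-10)
  ## recovered transform composed with the generating motion is identity
  expect_equal(sup$rotation %*% R, diag(3), tolerance = 1e-6)
  expect_equal(apply_transform(B, sup), A, tolerance = 1e-8)
})

test_that("Kabsch beats random alternative rotations (optimality property)", {
  set.seed(7)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.3), 12, 3)   # noisy partner
  best <- kabsch_superpose(A, B)$rmsd
  cb <- colMeans(B); ca <- colMeans(A)
  for (k in 1:200) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    alt <- sweep(sweep(B, 2, cb) %*% t(R), 2, ca, "+")
    expect_gte(sqrt(mean(rowSums((A - alt)^2))) + 1e-12, best)
  }
})

test_that("fixed-frame RMSD never beats the refitted optimum", {
  set.seed(3)
  for (k in 1:25) {
    A <- matrix(rnorm(30), 10, 3)
    B <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
    tr <- list(rotation = rotation_matrix(rnorm(3), runif(1, 0, 360)),
               translation = rnorm(3))
    expect_gte(rmsd_in_frame(A, B, tr) + 1e-12, kabsch_superpose(A, B)$rmsd)
  }
  expect_equal(rmsd_in_frame(A, A), 0)
})

test_that("superposition rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "3 paired points")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3, 3), matrix(rnorm(12), 4, 3)),
               "paired")
  collinear <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_warning(kabsch_superpose(collinear, collinear), "collinear")
})

test_that("torsion angles follow the IUPAC convention", {
  ## planar cis arrangement -> 0; trans -> 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, -1, 0))), 180)
  ## right-handed quarter turn is +90
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, 0, 1)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "coincident")
})

test_that("torsions and RMSDs are invariant under a common rigid motion", {
  set.seed(5)
  p <- lapply(1:4, function(i) rnorm(3))
  A <- matrix(rnorm(30), 10, 3); B <- A + matrix(rnorm(30, sd = 0.2), 10, 3)
  d0 <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  r0 <- kabsch_superpose(A, B)$rmsd
  for (k in 1:10) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360)); t <- rnorm(3, sd = 10)
    mv <- function(x) as.numeric(R %*% x + t)
    expect_equal(dihedral_angle(mv(p[[1]]), mv(p[[2]]), mv(p[[3]]), mv(p[[4]])),
                 d0, tolerance = 1e-8)
    Am <- sweep(A %*% t(R), 2, t, "+"); Bm <- sweep(B %*% t(R), 2, t, "+")
    expect_equal(kabsch_superpose(Am, Bm)$rmsd, r0, tolerance = 1e-8)
  }
})

test_that("structure self-alignment pairs every residue at zero RMSD", {
  s <- build_peptide("ACDEFGHIKLMN", phi = -70, psi = 150)
  al <- align_structures(s, s, mode = "identical-numbering")
  expect_equal(al$n_aligned, 12L)
  expect_lt(al$rmsd, 1e-10)
  al2 <- align_structures(s, s, mode = "sequence-guided")
  expect_equal(al2$n_aligned, 12L)
  expect_lt(al2$rmsd, 1e-10)
})

test_that("sequence-guided alignment with trimming localises a moved region", {
  ## same sequence, one conformer with a kinked tail: trimming should keep
  ## the rigid body and drop the divergent residues
  n <- 20
  phi <- rep(-57, n); psi <- rep(-47, n)
  a <- build_peptide(strrep("A", n), phi = phi, psi = psi)
  psi2 <- psi; psi2[15] <- 100   # kink after residue 15
  b <- build_peptide(strrep("A", n), phi = phi, psi = psi2)
  al <- align_structures(a, b, mode = "sequence-guided")
  expect_lt(al$rmsd, 2.0)
  expect_lt(al$n_aligned, n)        # tail trimmed
  expect_gte(al$n_aligned, 13L)     # rigid head kept
  ## no crossings: paired indices strictly increasing
  expect_true(all(diff(al$correspondence$resno_a) > 0))
  expect_true(all(diff(al$correspondence$resno_b) > 0))
})

test_that("region RMSD in the global frame matches a hand-built computation", {
  n <- 12
  a <- build_peptide(strrep("A", n))
  b <- perturb_rigid(a, axis = c(1, 1, 0), angle_deg = 30, translation = c(3, 2, 1))
  rr <- region_rmsd(a, b, resno = 4:9, elety = "CA")
  ## rigid motion of the whole chain: global superposition is exact, so the
  ## region deviates by nothing
  expect_lt(rr$region_rmsd, 1e-8)
  expect_equal(rr$n_atoms, 6L)
})
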