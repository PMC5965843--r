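test_that("built peptides return exactly the specified backbone torsions", {
  s <- build_peptide(strrep("A", 10), phi = -57, psi = -47)
  bd <- backbone_dihedrals(s)
  interior <- 2:9
  expect_equal(bd$phi[interior], rep(-57, 8), tolerance = 1e-6)
  expect_equal(bd$psi[interior], rep(-47, 8), tolerance = 1e-6)
  expect_true(all(abs(abs(bd$omega[interior]) - 180) < 1e-6))
  ## termini flagged absent
  expect_true(is.na(bd$phi[1]) && is.na(bd$omega[1]))
  expect_true(is.na(bd$psi[10]))
  ## a different conformation round-trips too
  s2 <- build_peptide("AAAAAA", phi = c(0, -130, 75, -60, 120, -80),
                      psi = c(150, 140, -30, 135, 10, 160))
  bd2 <- backbone_dihedrals(s2)
  expect_equal(bd2$phi[2:6], c(-130, 75, -60, 120, -80), tolerance = 1e-6)
  expect_equal(bd2$psi[2:5], c(140, -30, 135, 10), tolerance = 1e-6)
})

test_that("dihedrals agree with the bio3d torsion oracle on a real structure", {
  pdb_path <- system.file("examples", "1hel.pdb", package = "bio3d")
  skip_if(pdb_path == "", "bio3d example structure unavailable")
  s <- read_structure(pdb_path)
  bd <- backbone_dihedrals(s)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(pdb_path))$tbl
  ## compare phi/psi for a spread of interior residues
  for (i in c(5, 20, 40, 60, 80, 100, 120)) {
    expect_equal(bd$phi[i], unname(tor[i, "phi"]), tolerance = 1e-2)
    expect_equal(bd$psi[i], unname(tor[i, "psi"]), tolerance = 1e-2)
  }
})

test_that("chain breaks suppress torsions across the gap", {
  a <- build_peptide("AAAA")
  b <- build_peptide("AAAA")
  b$atoms$resno <- b$atoms$resno + 10L
  b$atoms$x <- b$atoms$x + 50           # far away: CA-CA > 4.5 A
  b$atoms$eleno <- b$atoms$eleno + max(a$atoms$eleno)
  s <- new_structure(rbind(a$atoms, b$atoms), id = "broken")
  bd <- backbone_dihedrals(s)
  expect_true(is.na(bd$psi[bd$resno == 4]))   # last residue before the gap
  expect_true(is.na(bd$phi[bd$resno == 11]))  # first residue after the gap
  expect_false(is.na(bd$phi[bd$resno == 3]))
})

test_that("Ramachandran classification is glycine-aware", {
  ## canonical alpha-helix point is favored for every residue type
  for (res in c("ALA", "GLY", "TRP", "SER"))
    expect_equal(classify_rama(-57, -47, res)$label, "favored-general")
  ## positive-phi extended region: fine for glycine, outlier otherwise
  expect_equal(classify_rama(120, -150, "GLY")$label, "glycine-only")
  expect_equal(classify_rama(120, -150, "ALA")$label, "outlier")
  ## left-handed helix is allowed-general (not glycine-only)
  expect_equal(classify_rama(60, 40, "ASN")$label, "allowed-general")
  expect_error(classify_rama(NA, 30, "ALA"), "present")
})

test_that("classification is total and deterministic over the torus grid", {
  labels <- c("favored-general", "allowed-general", "glycine-only", "outlier")
  grid <- seq(-170, 180, by = 35)
  for (res in c("ALA", "GLY")) {
    for (phi in grid) for (psi in grid) {
      r1 <- classify_rama(phi, psi, res)
      expect_true(r1$label %in% labels)
      expect_identical(r1, classify_rama(phi, psi, res))
      if (res == "ALA") expect_false(r1$label == "glycine-only")
    }
  }
})

test_that("peptide flips are detected only at the constructed bond", {
  fp <- make_flip_pair("AAAAAAAA", flip_at = 4)
  hit <- detect_peptide_flip(fp$original, fp$flipped, 4)
  expect_true(hit$flipped)
  expect_gt(hit$angle, 120)
  for (i in c(2, 3, 5, 6)) {
    miss <- detect_peptide_flip(fp$original, fp$flipped, i)
    expect_false(miss$flipped)
    expect_lt(miss$angle, 45)
  }
  ## identical conformers: no flip anywhere
  same <- detect_peptide_flip(fp$original, fp$original, 4)
  expect_equal(same$angle, 0, tolerance = 1e-8)
  expect_false(same$flipped)
  ## symmetric in argument order
  expect_equal(detect_peptide_flip(fp$flipped, fp$original, 4)$angle,
               hit$angle, tolerance = 1e-8)
})

test_that("flipping twice restores the original carbonyl", {
  fp <- make_flip_pair("AAAAAAAA", flip_at = 4)
  twice <- ploopflex:::flip_carbonyl(fp$flipped, 4L)
  back <- detect_peptide_flip(fp$original, twice, 4)
  expect_false(back$flipped)
  expect_lt(back$angle, 1e-6)
})

test_that("flip detection is invariant under rigid motion of either input", {
  fp <- make_flip_pair("AAAAAAAA", flip_at = 4)
  moved <- perturb_rigid(fp$flipped, axis = c(2, -1, 1), angle_deg = 123,
                         translation = c(-4, 9, 2))
  expect_equal(detect_peptide_flip(fp$original, moved, 4)$angle,
               detect_peptide_flip(fp$original, fp$flipped, 4)$angle,
               tolerance = 1e-8)
})

test_that("P-loop state calls match the constructed amide orientations", {
  sa <- make_ploop_fixture(active = TRUE)
  si <- make_ploop_fixture(active = FALSE)
  ra <- ploop_state(sa, 1)
  ri <- ploop_state(si, 1)
  expect_equal(ra$state, "active")
  expect_equal(ri$state, "inactive")
  expect_gt(ra$mean_cosine, 0.2)
  expect_lt(ri$mean_cosine, -0.2)
  expect_equal(ra$pocket_tag, "ligand-centroid")
  ## cosines bounded
  expect_true(all(abs(ra$per_residue$cosine) <= 1))
  ## state is invariant under rigid motion
  moved <- perturb_rigid(sa, axis = c(1, 0, 2), angle_deg = 200,
                         translation = c(10, -3, 7))
  rm_ <- ploop_state(moved, 1)
  expect_equal(rm_$state, "active")
  expect_equal(rm_$mean_cosine, ra$mean_cosine, tolerance = 1e-8)
})

test_that("P-loop state falls back to the catalytic SG and errors sensibly", {
  sa <- make_ploop_fixture(active = TRUE)
  ## strip the ligand: no SG present either (fixture cysteine has no side
  ## chain beyond CB), so the pocket is unresolvable
  sa$atoms <- sa$atoms[sa$atoms$type == "ATOM", , drop = FALSE]
  expect_error(ploop_state(sa, 1), "unresolvable")
  ## ligand-centroid demanded but absent -> indeterminate with warning
  expect_warning(r <- ploop_state(sa, 1, pocket = "ligand-centroid"),
                 "indeterminate|ligand")
  expect_equal(r$state, "indeterminate")
  ## motif partially missing -> precondition error
  s <- build_peptide("AAAA")
  expect_error(ploop_state(s, 1), "not all present")
})

test_that("ensemble histograms are normalised with fixed 10-degree bins", {
  one <- make_dihedral_ensemble(resno = 3, angle = "psi", values = -47)
  h1 <- ensemble_dihedral_histogram(one, 3, "psi")
  expect_equal(sum(h1$freq), 1, tolerance = 1e-9)
  expect_equal(sum(h1$freq == 1), 1L)      # single model: one bin holds all
  expect_length(h1$freq, 36L)
  ## evenly spaced torsions, one per bin
  ens <- make_dihedral_ensemble(resno = 3, angle = "psi", values = seq(-175, 175, 10))
  h <- ensemble_dihedral_histogram(ens, 3, "psi")
  expect_equal(h$freq, rep(1 / 36, 36), tolerance = 1e-9)
  expect_equal(h$n_models, 36L)
  ## the torsions laid down are the requested ones
  expect_equal(sort(h$values), seq(-175, 175, 10), tolerance = 1e-6)
})

test_that("phi-ensembles and edge values bin correctly", {
  ens <- make_dihedral_ensemble(resno = 3, angle = "phi", values = c(-179.5, 175.5, -170.5, 170.5))
  h <- ensemble_dihedral_histogram(ens, 3, "phi")
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  expect_equal(h$freq[1], 0.5, tolerance = 1e-9)   # (-180, -170]
  expect_equal(h$freq[36], 0.5, tolerance = 1e-9)  # (170, 180]
})
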