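test_that("an ideal backbone hydrogen bond is found and a stretched one is not", {
  hb <- find_hbonds(make_hbond_fixture(2.9))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$don_resno, 5L)
  expect_equal(hb$don_atom, "N")
  expect_equal(hb$acc_resno, 1L)
  expect_equal(hb$acc_atom, "O")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(nrow(find_hbonds(make_hbond_fixture(5.0))), 0L)
  ## tightening the distance cutoff never adds bonds
  expect_equal(nrow(find_hbonds(make_hbond_fixture(2.9), dist_max = 2.5)), 0L)
})

test_that("hydrogen-bond sets survive rigid motion and obey cutoff monotonicity", {
  s <- build_peptide(strrep("A", 12), phi = -57, psi = -47)  # helix: i+4 -> i bonds
  hb0 <- find_hbonds(s)
  expect_gt(nrow(hb0), 0L)
  moved <- perturb_rigid(s, axis = c(3, 1, -2), angle_deg = 141,
                         translation = c(8, -5, 11))
  hb1 <- find_hbonds(moved)
  expect_equal(hb1[, c("don_resno", "don_atom", "acc_resno", "acc_atom")],
               hb0[, c("don_resno", "don_atom", "acc_resno", "acc_atom")])
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-8)
  ## looser distance criterion is a superset
  loose <- find_hbonds(s, dist_max = 4.0)
  expect_true(all(ploopflex:::hbond_key(hb0) %in% ploopflex:::hbond_key(loose)))
})

test_that("network differencing isolates exactly the broken bond", {
  a <- make_hbond_fixture(2.9)
  d0 <- compare_hbond_networks(a, a)
  expect_equal(nrow(d0$only_in_a), 0L)
  expect_equal(nrow(d0$only_in_b), 0L)
  expect_equal(nrow(d0$shared), 1L)
  ## break the bond in b by construction
  b <- make_hbond_fixture(5.0)
  d1 <- compare_hbond_networks(a, b)
  expect_equal(nrow(d1$only_in_a), 1L)
  expect_equal(d1$only_in_a$acc_resno, 1L)
  expect_equal(nrow(d1$only_in_b), 0L)
  expect_equal(nrow(d1$shared), 0L)
  ## the three sets partition the union
  expect_equal(nrow(d1$only_in_a) + nrow(d1$shared), nrow(d1$bonds_a))
  expect_equal(nrow(d1$only_in_b) + nrow(d1$shared), nrow(d1$bonds_b))
})

test_that("contact counting matches the brute-force oracle by construction", {
  ## glycine has no side-chain carbon
  s <- build_peptide("AGA")
  expect_equal(count_cc_contacts(s, 2)$count, 0L)
  ## compact helix: CB atoms pack against neighbouring carbons
  h <- build_peptide(strrep("A", 8), phi = -57, psi = -47)
  for (rn in c(2, 4, 6)) {
    got <- count_cc_contacts(h, rn)
    expect_equal(got$count, brute_force_cc(h, rn))
  }
  ## unknown residue errors
  expect_error(count_cc_contacts(h, 99), "not found")
})

test_that("contact counts equal brute force on a deposited-format structure", {
  pdb_path <- system.file("examples", "1hel.pdb", package = "bio3d")
  skip_if(pdb_path == "", "bio3d example structure unavailable")
  s <- read_structure(pdb_path)
  for (rn in c(3, 28, 63, 108)) {
    expect_equal(count_cc_contacts(s, rn)$count, brute_force_cc(s, rn))
  }
})

test_that("contact counts are monotone in cutoff, atom removal, and rigid-motion invariant", {
  h <- build_peptide(strrep("A", 8), phi = -57, psi = -47)
  c35 <- count_cc_contacts(h, 4, cutoff = 3.5)$count
  c45 <- count_cc_contacts(h, 4, cutoff = 4.5)$count
  c60 <- count_cc_contacts(h, 4, cutoff = 6.0)$count
  expect_true(c35 <= c45 && c45 <= c60)
  ## removing atoms never increases the count
  h2 <- h
  h2$atoms <- h2$atoms[!(h2$atoms$resno == 5), , drop = FALSE]
  expect_lte(count_cc_contacts(h2, 4, cutoff = 6.0)$count, c60)
  ## rigid motion: exact equality
  moved <- perturb_rigid(h, axis = c(1, 5, 2), angle_deg = 77, translation = c(2, 2, 2))
  expect_identical(count_cc_contacts(moved, 4)$count, c45)
  ## alternate conventions are consistent
  expect_lte(count_cc_contacts(h, 4, convention = "partners")$count, c45)
  expect_lte(count_cc_contacts(h, 4, convention = "pairs-nonadjacent")$count, c45)
})

test_that("the contact profile aggregates per-residue counts coherently", {
  h <- build_peptide("AGAFAGAW", phi = -57, psi = -47)
  pr <- contact_profile(h)
  expect_equal(nrow(pr$profile), 8L)
  expect_true(all(pr$profile$count[pr$profile$resid == "GLY"] == 0))
  expect_equal(pr$mean_count, mean(pr$profile$count))
  ## per-residue counts equal brute force across the whole chain
  for (i in seq_len(8))
    expect_equal(pr$profile$count[i], brute_force_cc(h, pr$profile$resno[i]))
  ## excluding hydrophilic-group carbons can only reduce counts
  f <- build_peptide("ARAEANAH", phi = -57, psi = -47)
  full <- contact_profile(f)$profile$count
  excl <- contact_profile(f, exclude_hydrophilic = TRUE)$profile$count
  expect_true(all(excl <= full))
})

test_that("a single-residue structure has no contacts", {
  s <- build_peptide("AA")
  s$atoms <- s$atoms[s$atoms$resno == 1, , drop = FALSE]
  expect_equal(count_cc_contacts(s, 1)$count, 0L)
})
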