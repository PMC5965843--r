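## shared fixture builders -- everything is generated in code, no data files

xyz_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

## P-loop motif peptide (HCxxGxxR) with a one-atom pocket "ligand" placed
## along (active) or against (inactive) the mean backbone-amide direction
## of the four central residues, so the state call is known by construction
make_ploop_fixture <- function(active = TRUE) {
  s <- build_peptide("HCMGGLGR", phi = -57, psi = -47, id = "ploop-fixture")
  at <- s$atoms
  coord <- function(rn, nm) as.numeric(at[at$resno == rn & at$elety == nm,
                                          c("x", "y", "z")][1L, ])
  hdir <- function(rn) {
    N <- coord(rn, "N"); CA <- coord(rn, "CA"); Cp <- coord(rn - 1L, "C")
    h <- -(((CA - N) / sqrt(sum((CA - N)^2))) + ((Cp - N) / sqrt(sum((Cp - N)^2))))
    h / sqrt(sum(h^2))
  }
  central <- 4:7
  hmean <- colMeans(t(vapply(central, hdir, numeric(3))))
  hmean <- hmean / sqrt(sum(hmean^2))
  ncent <- colMeans(t(vapply(central, function(rn) coord(rn, "N"), numeric(3))))
  pocket <- ncent + (if (active) 4 else -4) * hmean
  lig <- data.frame(model = 1L, type = "HETATM", eleno = max(at$eleno) + 1L,
                    elety = "V", alt = "", resid = "VO4", chain = "A",
                    resno = 201L, insert = "", x = pocket[1L], y = pocket[2L],
                    z = pocket[3L], o = 1, b = 0, elesy = "V",
                    stringsAsFactors = FALSE)
  s$atoms <- rbind(at, lig)
  s
}

## a minimal two-residue fixture with an ideal backbone N-H...O=C hydrogen
## bond whose donor-acceptor distance is controlled
make_hbond_fixture <- function(d = 2.9) {
  rows <- list()
  add <- function(eleno, elety, resid, resno, x, y, z, elesy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = 1L, type = "ATOM", eleno = eleno, elety = elety, alt = "",
      resid = resid, chain = "A", resno = resno, insert = "",
      x = x, y = y, z = z, o = 1, b = 0, elesy = elesy,
      stringsAsFactors = FALSE)
  }
  ## residue 1: carbonyl acceptor, O at origin, C=O along -x
  add(1, "N",  "ALA", 1, -2.9, 1.0, 0, "N")
  add(2, "CA", "ALA", 1, -2.4, 0.0, 1.2, "C")
  add(3, "C",  "ALA", 1, -1.23, 0.0, 0, "C")
  add(4, "O",  "ALA", 1, 0.0, 0.0, 0, "O")
  ## residue 5 (sequence-distant): amide N donor straight down +x from O
  add(5, "N",  "GLY", 5, d, 0.0, 0, "N")
  add(6, "CA", "GLY", 5, d + 0.9, 1.2, 0, "C")
  add(7, "C",  "GLY", 5, d + 2.3, 1.0, 0, "C")
  add(8, "O",  "GLY", 5, d + 2.9, 2.05, 0, "O")
  new_structure(do.call(rbind, rows), id = sprintf("hbond-fixture-%.1f", d))
}

## brute-force O(N^2) oracle for side-chain carbon-carbon contact counting
brute_force_cc <- function(s, resno, chain = NULL, cutoff = 4.5) {
  at <- select_atoms(s, chain = chain, type = "polymer")
  sc <- at[at$resno == resno & at$elesy == "C" & !(at$elety %in% c("C", "CA")), ]
  other <- at[at$resno != resno & at$elesy == "C", ]
  n <- 0L
  for (i in seq_len(nrow(sc))) for (j in seq_len(nrow(other))) {
    d <- sqrt(sum((as.numeric(sc[i, c("x", "y", "z")]) -
                     as.numeric(other[j, c("x", "y", "z")]))^2))
    if (d <= cutoff) n <- n + 1L
  }
  n
}

## minimal single-ATOM-record PDB text
one_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00 10.00           C",
    "END"), path)
  path
}
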