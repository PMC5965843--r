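## ---- ideal geometry ---------------------------------------------------------

.geom_env <- new.env(parent = emptyenv())

ideal_geometry <- function() {
  if (is.null(.geom_env$tab)) {
    path <- system.file("extdata", "ideal_geometry_v1.csv", package = "ploopflex")
    if (path == "") path <- file.path("inst", "extdata", "ideal_geometry_v1.csv")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .geom_env$tab <- stats::setNames(tab$value, tab$parameter)
  }
  .geom_env$tab
}

## natural extension of reference frame: place p4 given p1,p2,p3, the p3-p4
## bond length, the p2-p3-p4 angle and the p1-p2-p3-p4 torsion (degrees)
nerf_place <- function(p1, p2, p3, bond, angle, torsion) {
  a <- deg2rad(angle); t <- deg2rad(torsion)
  bc <- unitv(p3 - p2)
  n <- unitv(vcross(p2 - p1, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(a), bond * sin(a) * cos(t), bond * sin(a) * sin(t))
  p3 + bc * d[1L] + m * d[2L] + n * d[3L]
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation about `axis` (through the origin) by `angle_deg`.
#'
#' @param axis length-3 direction vector (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Build an ideal-geometry polypeptide with prescribed dihedrals
#'
#' Constructs backbone atoms (N, CA, C, O) plus CB for non-glycine
#' residues by sequential natural-extension placement from an ideal
#' bond-length/angle table (shipped, versioned). The torsions actually
#' laid down are exactly the requested phi/psi/omega, so measuring them
#' back with [backbone_dihedrals()] recovers the specification at interior
#' residues. CB is placed by the standard tetrahedral construction
#' (improper torsion C-N-CA-CB of -123 degrees, L-chirality).
#'
#' @param sequence one-letter amino-acid string, length >= 2.
#' @param phi,psi per-residue torsions in degrees (scalars recycled).
#'   `phi[1]` is unused; `psi[n]` only orients the terminal carbonyl.
#' @param omega peptide-bond torsions (scalar recycled; default 180,
#'   trans).
#' @param chain chain id for the built structure.
#' @param id structure label.
#' @return a `struct3d`.
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                          chain = "A", id = "synthetic-peptide") {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(letters1)
  if (n < 2L) stop("sequence must contain at least 2 residues")
  if (!all(letters1 %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]))
    stop("invalid residue letter in sequence")
  aa3 <- bio3d::aa123(letters1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  g <- ideal_geometry()
  coords <- list()   # per residue: named list of atom coordinates
  ## residue 1 in a canonical local frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g[["b_n_ca"]], 0, 0)
  a <- deg2rad(g[["a_n_ca_c"]])
  C1 <- CA1 + g[["b_ca_c"]] * c(-cos(a), sin(a), 0)
  coords[[1L]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    prev <- coords[[i - 1L]]
    N <- nerf_place(prev$N, prev$CA, prev$C, g[["b_c_n"]], g[["a_ca_c_n"]], psi[i - 1L])
    CA <- nerf_place(prev$CA, prev$C, N, g[["b_n_ca"]], g[["a_c_n_ca"]], omega[i])
    C <- nerf_place(prev$C, N, CA, g[["b_ca_c"]], g[["a_n_ca_c"]], phi[i])
    coords[[i]] <- list(N = N, CA = CA, C = C)
  }
  ## carbonyl O anti to the next amide N (torsion psi + 180), CB by the
  ## chirality improper
  for (i in seq_len(n)) {
    cc <- coords[[i]]
    coords[[i]]$O <- nerf_place(cc$N, cc$CA, cc$C, g[["b_c_o"]], g[["a_ca_c_o"]],
                                wrap180(psi[i] + 180))
    if (letters1[i] != "G")
      coords[[i]]$CB <- nerf_place(cc$C, cc$N, cc$CA, g[["b_ca_cb"]],
                                   g[["a_n_ca_cb"]], g[["t_c_n_ca_cb"]])
  }
  rows <- list(); eleno <- 0L
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O", "CB")) {
      p <- coords[[i]][[nm]]
      if (is.null(p)) next
      eleno <- eleno + 1L
      rows[[eleno]] <- data.frame(
        model = 1L, type = "ATOM", eleno = eleno, elety = nm, alt = "",
        resid = aa3[i], chain = chain, resno = i, insert = "",
        x = p[1L], y = p[2L], z = p[3L], o = 1, b = 0,
        elesy = substr(nm, 1L, 1L), stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), id = id)
}

#' Apply a recorded rigid motion to a structure
#'
#' Rotates all atoms about `axis` (through the origin) by `angle_deg`,
#' then translates. The generating motion is recorded in the result's
#' `motion` attribute, so superposition code can be checked for exact
#' recovery.
#'
#' @param s a `struct3d`.
#' @param axis rotation axis (length-3).
#' @param angle_deg rotation angle, degrees.
#' @param translation length-3 translation vector (Angstrom).
#' @return transformed `struct3d` with attribute `motion` (list `rotation`,
#'   `translation`).
#' @export
perturb_rigid <- function(s, axis = c(0, 0, 1), angle_deg = 0,
                          translation = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  xyz <- atom_xyz(s$atoms)
  new_xyz <- sweep(xyz %*% t(R), 2L, translation, "+")
  s$atoms$x <- new_xyz[, 1L]; s$atoms$y <- new_xyz[, 2L]; s$atoms$z <- new_xyz[, 3L]
  attr(s, "motion") <- list(rotation = R, translation = translation)
  s
}

#' Construct a peptide-flip conformer pair
#'
#' Builds a peptide from the given dihedral specification and a second
#' conformer in which the carbonyl unit of residue `flip_at` (atoms C and
#' O, together with the following amide N) is rotated 180 degrees about
#' the CA(i)-CA(i+1) axis — the local geometry stays closed because both
#' CA anchors lie on the rotation axis. The pair emulates the
#' peptide-plane flips seen between active and inactive conformers.
#'
#' @inheritParams build_peptide
#' @param flip_at interior residue index i of the flipped i/i+1 bond.
#' @return list of two `struct3d`: `original`, `flipped`.
#' @export
make_flip_pair <- function(sequence, flip_at, phi = -57, psi = -47, omega = 180) {
  s <- build_peptide(sequence, phi = phi, psi = psi, omega = omega)
  n <- max(s$atoms$resno)
  if (flip_at < 2L || flip_at >= n - 1L)
    stop("flip_at must be an interior residue (2..", n - 2L, ")")
  flipped <- flip_carbonyl(s, flip_at)
  list(original = s, flipped = flipped)
}

## rotate the i/i+1 peptide unit (C_i, O_i, N_{i+1}) 180 deg about CA-CA
flip_carbonyl <- function(s, i) {
  at <- s$atoms
  ca_i <- as.numeric(at[at$resno == i & at$elety == "CA", c("x", "y", "z")][1L, ])
  ca_j <- as.numeric(at[at$resno == i + 1L & at$elety == "CA", c("x", "y", "z")][1L, ])
  R <- rotation_matrix(ca_j - ca_i, 180)
  move <- (at$resno == i & at$elety %in% c("C", "O")) |
          (at$resno == i + 1L & at$elety == "N")
  xyz <- atom_xyz(at[move, , drop = FALSE])
  new_xyz <- sweep(sweep(xyz, 2L, ca_i) %*% t(R), 2L, ca_i, "+")
  at$x[move] <- new_xyz[, 1L]; at$y[move] <- new_xyz[, 2L]; at$z[move] <- new_xyz[, 3L]
  s$atoms <- at
  s$id <- paste0(s$id, "-flip", i)
  s
}

#' Multi-model dihedral ensemble
#'
#' Builds a poly-alanine peptide and generates `length(values)` models in
#' which the chosen backbone torsion of residue `resno` takes each value in
#' turn (all downstream atoms rotated about the torsion bond). Used to
#' exercise ensemble dihedral-frequency histograms without running any
#' dynamics.
#'
#' @param n_res number of residues (default 5).
#' @param resno residue whose torsion is varied (interior).
#' @param angle `"phi"` or `"psi"`.
#' @param values torsion values, degrees, one per model.
#' @return a multi-model `struct3d`.
#' @export
make_dihedral_ensemble <- function(n_res = 5L, resno = 3L,
                                   angle = c("phi", "psi"), values) {
  angle <- match.arg(angle)
  if (resno <= 1L || resno >= n_res)
    stop("resno must be interior so the torsion is defined")
  base <- build_peptide(strrep("A", n_res), phi = -57, psi = -47)
  bd <- backbone_dihedrals(base)
  base_val <- bd[[angle]][bd$resno == resno]
  at0 <- base$atoms
  if (angle == "psi") {
    p2 <- as.numeric(at0[at0$resno == resno & at0$elety == "CA", c("x", "y", "z")][1L, ])
    p3 <- as.numeric(at0[at0$resno == resno & at0$elety == "C", c("x", "y", "z")][1L, ])
    move <- (at0$resno == resno & at0$elety == "O") | at0$resno > resno
  } else {
    p2 <- as.numeric(at0[at0$resno == resno & at0$elety == "N", c("x", "y", "z")][1L, ])
    p3 <- as.numeric(at0[at0$resno == resno & at0$elety == "CA", c("x", "y", "z")][1L, ])
    move <- (at0$resno == resno & at0$elety %in% c("C", "O")) | at0$resno > resno
  }
  M <- length(values)
  xyz0 <- atom_xyz(at0)
  coords <- vector("list", M)
  for (m in seq_len(M)) {
    delta <- values[m] - base_val
    R <- rotation_matrix(p3 - p2, delta)
    xm <- xyz0
    xm[move, ] <- sweep(sweep(xyz0[move, , drop = FALSE], 2L, p3) %*% t(R), 2L, p3, "+")
    coords[[m]] <- xm
  }
  big <- at0[rep(seq_len(nrow(at0)), times = M), , drop = FALSE]
  big$model <- rep(seq_len(M), each = nrow(at0))
  all_xyz <- do.call(rbind, coords)
  big$x <- all_xyz[, 1L]; big$y <- all_xyz[, 2L]; big$z <- all_xyz[, 3L]
  new_structure(big, id = "synthetic-ensemble")
}

#' Simulate fluorogenic phosphatase assay progress curves
#'
#' Generates product-accumulation curves in the initial-rate regime:
#' product(t) = v(S0) * t with v from the Michaelis-Menten rate at each
#' starting substrate concentration, plus per-point noise (multiplicative
#' Gaussian by default, plate-reader-like). Defaults mirror a DiFMUP assay
#' read at 2-minute intervals for 10 minutes over six substrate
#' concentrations from 50 to 1500 uM with 10 nM enzyme. Replicate k draws
#' from its own seed stream (`seed + k - 1`), so any single replicate is
#' reproducible in isolation. A warning is raised if product exceeds 10%
#' of S0 within the simulated window, where the initial-rate assumption
#' frays.
#'
#' @param kcat_s turnover number, 1/s.
#' @param km_mM Michaelis constant, mM.
#' @param enzyme_nM enzyme concentration, nM (default 10).
#' @param substrate_uM substrate concentrations, uM.
#' @param times_min sampling times, minutes.
#' @param noise_sd noise standard deviation as a fraction of signal
#'   (multiplicative) or in uM (additive).
#' @param noise `"multiplicative"` or `"additive"`.
#' @param seed integer master seed.
#' @param replicates number of replicate datasets.
#' @return tidy data frame: `time_min`, `signal` (product, uM),
#'   `substrate_uM`, `enzyme_nM`, `replicate`.
#' @export
simulate_progress_curves <- function(kcat_s, km_mM, enzyme_nM = 10,
                                     substrate_uM = c(50, 100, 250, 500, 1000, 1500),
                                     times_min = seq(0, 10, by = 2),
                                     noise_sd = 0.02,
                                     noise = c("multiplicative", "additive"),
                                     seed = 1L, replicates = 1L) {
  noise <- match.arg(noise)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (kcat_s <= 0 || km_mM <= 0) stop("kcat and KM must be positive")
  enzyme_uM <- enzyme_nM / 1000
  km_uM <- km_mM * 1000
  out <- list()
  for (k in seq_len(replicates)) {
    set.seed(seed + k - 1L)
    for (S0 in substrate_uM) {
      v <- kcat_s * 60 * enzyme_uM * S0 / (km_uM + S0)   # uM/min
      prod <- v * times_min
      sig <- switch(noise,
        multiplicative = prod * (1 + stats::rnorm(length(prod), 0, noise_sd)),
        additive = prod + stats::rnorm(length(prod), 0, noise_sd))
      if (max(prod) > 0.1 * S0)
        warning("product exceeds 10% of S0 = ", S0,
                " uM within the window; initial-rate assumption is strained")
      out[[length(out) + 1L]] <- data.frame(
        time_min = times_min, signal = sig, substrate_uM = S0,
        enzyme_nM = enzyme_nM, replicate = k)
    }
  }
  do.call(rbind, out)
}
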