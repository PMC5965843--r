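#' Optimal rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation `R` and translation `t` minimising the RMSD
#' of `t(R %*% t(coords_b)) + t` onto `coords_a` over the paired rows, by
#' SVD of the cross-covariance matrix with the usual reflection correction.
#'
#' @param coords_a,coords_b N x 3 matrices of paired coordinates (Angstrom),
#'   N >= 3.
#' @return list of class `superposition` with elements `rotation` (3 x 3,
#'   det +1), `translation` (length-3), `rmsd` (Angstrom), `n_atoms`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must be paired (equal row count)")
  n <- nrow(coords_a)
  if (n < 3L) stop("at least 3 paired points are required")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2L, ca); B <- sweep(coords_b, 2L, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    warning("near-degenerate (collinear) point set; rotation poorly determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ca - R %*% cb)
  fit <- sweep(B %*% t(R), 2L, ca, "+")
  rmsd <- sqrt(mean(rowSums((coords_a - fit)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param transform a `superposition` (or any list with `rotation` and
#'   `translation`).
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Identity rigid transform
#' @return a `superposition`-shaped transform with R = I, t = 0.
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 rmsd = 0, n_atoms = 0L), class = "superposition")
}

#' RMSD in a fixed frame (no re-fitting)
#'
#' Region RMSDs quoted "when superimposed" are evaluated in the frame of a
#' global superposition; this applies a given transform to `coords_b` and
#' measures the deviation without re-fitting.
#'
#' @param coords_a,coords_b paired N x 3 matrices.
#' @param transform rigid transform applied to `coords_b` (default identity).
#' @return RMSD in Angstrom.
#' @export
rmsd_in_frame <- function(coords_a, coords_b, transform = identity_transform()) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must be paired (equal row count)")
  fit <- apply_transform(coords_b, transform)
  sqrt(mean(rowSums((coords_a - fit)^2)))
}

#' Torsion angle of four points
#'
#' Signed dihedral in degrees, IUPAC convention, range (-180, 180], via the
#' atan2 construction. Invariant under a common rigid motion of all four
#' points.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b1) < 1e-6 || vnorm(b2) < 1e-6 || vnorm(b3) < 1e-6)
    stop("coincident consecutive points: torsion undefined")
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m <- unitv(b2)
  ang <- atan2(sum(vcross(n1, n2) * m), sum(n1 * n2)) * 180 / pi
  wrap180(ang)
}

## CA-trace table for one chain: resno/insert/resid plus CA coordinates
ca_table <- function(s, chain = NULL, model = 1L) {
  chain <- default_chain(s, chain)
  at <- select_atoms(s, chain = chain, elety = "CA", type = "polymer", model = model)
  at <- at[!duplicated(paste(at$resno, at$insert)), , drop = FALSE]
  if (nrow(at) == 0L) stop("no CA atoms in chain '", chain, "'")
  at
}

#' Structure-to-structure alignment and superposition
#'
#' Establishes a residue correspondence between the default (or given)
#' chains of two structures, then superposes the paired CA atoms. In
#' `"sequence-guided"` mode, a global pairwise sequence alignment (BLOSUM62,
#' affine gaps, open 10 / extend 0.5) proposes candidate pairs which are
#' then refined by iterative Kabsch superposition with outlier trimming:
#' pairs deviating by more than `2 * RMSD` (floor 2.0 Angstrom) are dropped
#' and the fit repeated to convergence (max 10 cycles). This mirrors the
#' "N structurally aligned residues" convention of structure-comparison
#' reports. In `"identical-numbering"` mode residues are paired by author
#' number (appropriate for conformers of the same protein) and no trimming
#' is applied unless `trim = TRUE`.
#'
#' @param a,b `struct3d` objects.
#' @param mode `"sequence-guided"` or `"identical-numbering"`.
#' @param chain_a,chain_b chain ids; default first polymer chain of each.
#' @param trim apply iterative trimming (default TRUE for sequence-guided).
#' @param max_cycles trimming cycle cap.
#' @return list with `correspondence` (data frame: `resno_a`, `resno_b`,
#'   `dist` after superposition, `kept`), `superposition` (over kept pairs),
#'   `n_aligned`, `rmsd`.
#' @export
align_structures <- function(a, b, mode = c("sequence-guided", "identical-numbering"),
                             chain_a = NULL, chain_b = NULL, trim = NULL,
                             max_cycles = 10L) {
  mode <- match.arg(mode)
  if (is.null(trim)) trim <- (mode == "sequence-guided")
  ca_a <- ca_table(a, chain_a); ca_b <- ca_table(b, chain_b)
  if (mode == "identical-numbering") {
    common <- intersect(ca_a$resno, ca_b$resno)
    if (!length(common)) stop("no residues with shared numbering to align")
    ia <- match(common, ca_a$resno); ib <- match(common, ca_b$resno)
  } else {
    seq_a <- strsplit(extract_sequence(a, chain = default_chain(a, chain_a)), "")[[1L]]
    seq_b <- strsplit(extract_sequence(b, chain = default_chain(b, chain_b)), "")[[1L]]
    pal <- Biostrings::pairwiseAlignment(
      paste(seq_a, collapse = ""), paste(seq_b, collapse = ""),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    al_a <- strsplit(as.character(Biostrings::alignedPattern(pal)), "")[[1L]]
    al_b <- strsplit(as.character(Biostrings::alignedSubject(pal)), "")[[1L]]
    ia <- integer(0); ib <- integer(0); i <- 0L; j <- 0L
    for (k in seq_along(al_a)) {
      if (al_a[k] != "-") i <- i + 1L
      if (al_b[k] != "-") j <- j + 1L
      if (al_a[k] != "-" && al_b[k] != "-") { ia <- c(ia, i); ib <- c(ib, j) }
    }
    if (!length(ia)) stop("sequence alignment produced no residue pairs")
  }
  A <- atom_xyz(ca_a[ia, ]); B <- atom_xyz(ca_b[ib, ])
  keep <- rep(TRUE, nrow(A))
  sup <- kabsch_superpose(A, B)
  if (trim) {
    for (cyc in seq_len(max_cycles)) {
      sup <- kabsch_superpose(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
      dev <- sqrt(rowSums((A - apply_transform(B, sup))^2))
      cut <- max(2 * sup$rmsd, 2.0)
      new_keep <- dev <= cut
      if (sum(new_keep) < 3L || identical(new_keep, keep)) break
      keep <- new_keep
    }
    sup <- kabsch_superpose(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
  }
  dev <- sqrt(rowSums((A - apply_transform(B, sup))^2))
  corr <- data.frame(resno_a = ca_a$resno[ia], resno_b = ca_b$resno[ib],
                     dist = dev, kept = keep)
  list(correspondence = corr, superposition = sup,
       n_aligned = sum(keep), rmsd = sup$rmsd)
}

#' Region RMSD between two structures in a common frame
#'
#' Convenience wrapper: superposes the two structures globally (via
#' [align_structures()]), then reports the RMSD of a residue-range atom
#' selection evaluated in that global frame (default) or locally re-fitted.
#'
#' @param a,b `struct3d` objects.
#' @param resno residue numbers of the region (author numbering, inclusive).
#' @param elety atom names to use (default `"CA"`).
#' @param chain_a,chain_b chain ids.
#' @param mode alignment mode passed to [align_structures()].
#' @param refit if TRUE, re-fit the region locally instead of using the
#'   global frame.
#' @return list: `region_rmsd`, `n_atoms`, `global` (alignment result).
#' @export
region_rmsd <- function(a, b, resno, elety = "CA", chain_a = NULL, chain_b = NULL,
                        mode = "identical-numbering", refit = FALSE) {
  al <- align_structures(a, b, mode = mode, chain_a = chain_a, chain_b = chain_b)
  sel_a <- select_atoms(a, chain = default_chain(a, chain_a), resno = resno,
                        elety = elety)
  sel_b <- select_atoms(b, chain = default_chain(b, chain_b), resno = resno,
                        elety = elety)
  key_a <- paste(sel_a$resno, sel_a$insert, sel_a$elety)
  key_b <- paste(sel_b$resno, sel_b$insert, sel_b$elety)
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("region atoms not shared between the structures")
  A <- atom_xyz(sel_a[match(common, key_a), ])
  B <- atom_xyz(sel_b[match(common, key_b), ])
  r <- if (refit) kabsch_superpose(A, B)$rmsd
       else rmsd_in_frame(A, B, al$superposition)
  list(region_rmsd = r, n_atoms = length(common), global = al)
}
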