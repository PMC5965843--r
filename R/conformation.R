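#' Backbone dihedral table for a chain
#'
#' One record per residue with phi, psi and omega in degrees, range
#' (-180, 180]. phi(i) uses C(i-1), N(i), CA(i), C(i); psi(i) uses N(i),
#' CA(i), C(i), N(i+1); omega(i) describes the peptide bond into residue i,
#' CA(i-1), C(i-1), N(i), CA(i). Angles are `NA` at chain termini and
#' across chain breaks (consecutive CA-CA distance > `break_cutoff`).
#'
#' @param s a `struct3d`.
#' @param chain chain id; default first polymer chain.
#' @param model model number.
#' @param break_cutoff CA-CA distance (Angstrom) beyond which consecutive
#'   residues are treated as disconnected (default 4.5).
#' @return data frame: `resno`, `resid`, `phi`, `psi`, `omega`.
#' @export
backbone_dihedrals <- function(s, chain = NULL, model = 1L, break_cutoff = 4.5) {
  chain <- default_chain(s, chain)
  at <- select_atoms(s, chain = chain, type = "polymer", model = model)
  rt <- residue_table(s, chain = chain, model = model)
  rt <- rt[rt$backbone_complete, , drop = FALSE]
  if (nrow(rt) == 0L) stop("chain '", chain, "' has no backbone-complete residue")
  getat <- function(resno, insert, name) {
    row <- at[at$resno == resno & at$insert == insert & at$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  n <- nrow(rt)
  phi <- psi <- omega <- rep(NA_real_, n)
  connected <- function(i, j) {
    ci <- getat(rt$resno[i], rt$insert[i], "CA")
    cj <- getat(rt$resno[j], rt$insert[j], "CA")
    !is.null(ci) && !is.null(cj) && vnorm(ci - cj) <= break_cutoff
  }
  for (i in seq_len(n)) {
    N  <- getat(rt$resno[i], rt$insert[i], "N")
    CA <- getat(rt$resno[i], rt$insert[i], "CA")
    C  <- getat(rt$resno[i], rt$insert[i], "C")
    if (i > 1L && connected(i - 1L, i)) {
      Cp  <- getat(rt$resno[i - 1L], rt$insert[i - 1L], "C")
      CAp <- getat(rt$resno[i - 1L], rt$insert[i - 1L], "CA")
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, N, CA, C)
      if (!is.null(Cp) && !is.null(CAp)) omega[i] <- dihedral_angle(CAp, Cp, N, CA)
    }
    if (i < n && connected(i, i + 1L)) {
      Nn <- getat(rt$resno[i + 1L], rt$insert[i + 1L], "N")
      if (!is.null(Nn)) psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  data.frame(resno = rt$resno, resid = rt$resid, phi = phi, psi = psi,
             omega = omega, stringsAsFactors = FALSE)
}

## ---- Ramachandran classification ------------------------------------------

## cached region table (versioned polygon file under extdata)
.rama_env <- new.env(parent = emptyenv())

rama_regions <- function() {
  if (is.null(.rama_env$regions)) {
    path <- system.file("extdata", "rama_regions_v1.csv", package = "ploopflex")
    if (path == "") path <- file.path("inst", "extdata", "rama_regions_v1.csv")
    .rama_env$regions <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .rama_env$regions
}

## even-odd rule point-in-polygon; vertices in order, polygon closed implicitly
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

in_region_class <- function(phi, psi, cls) {
  reg <- rama_regions()
  reg <- reg[reg$class == cls, , drop = FALSE]
  for (id in unique(reg$region_id)) {
    poly <- reg[reg$region_id == id, , drop = FALSE]
    if (point_in_polygon(phi, psi, poly$phi, poly$psi)) return(id)
  }
  NA_character_
}

#' Glycine-aware Ramachandran classification
#'
#' Classifies a (phi, psi) pair against coarse published-style region
#' polygons shipped as a versioned data file. The contract is polygon
#' membership, not probability density. Glycine, lacking a side chain, has
#' additional allowed regions (mostly at positive phi) that are outliers
#' for every other residue type.
#'
#' @param phi,psi backbone torsions in degrees; both must be present.
#' @param res_type 3- or 1-letter residue code (only "is glycine" matters).
#' @return list: `label` in `favored-general`, `allowed-general`,
#'   `glycine-only`, `outlier`; `region_id` (polygon hit or `NA`).
#' @export
classify_rama <- function(phi, psi, res_type = "ALA") {
  if (is.na(phi) || is.na(psi))
    stop("phi and psi must both be present for classification")
  phi <- wrap180(phi); psi <- wrap180(psi)
  is_gly <- toupper(res_type) %in% c("G", "GLY")
  hit <- in_region_class(phi, psi, "favored")
  if (!is.na(hit)) return(list(label = "favored-general", region_id = hit))
  hit <- in_region_class(phi, psi, "allowed")
  if (!is.na(hit)) return(list(label = "allowed-general", region_id = hit))
  if (is_gly) {
    hit <- in_region_class(phi, psi, "glycine")
    if (!is.na(hit)) return(list(label = "glycine-only", region_id = hit))
  }
  list(label = "outlier", region_id = NA_character_)
}

## ---- peptide-flip detection -------------------------------------------------

#' Detect a peptide-bond flip between two conformers
#'
#' The carbonyl of residue `i` is compared between structures `a` and `b`
#' after superposing the flanking CA frame (CA of i-1, i, i+1, i+2). The
#' reported angle is between the two C=O unit vectors; a genuine peptide
#' flip is close to 180 degrees while ordinary loop adjustment stays well
#' under the 90-degree threshold.
#'
#' @param a,b `struct3d` objects (conformers with shared numbering).
#' @param resno residue `i` of the i/i+1 peptide bond.
#' @param chain_a,chain_b chain ids.
#' @param threshold flip threshold in degrees (default 90).
#' @return list: `resno`, `partner`, `angle` (degrees, 0-180), `flipped`,
#'   `threshold`.
#' @export
detect_peptide_flip <- function(a, b, resno, chain_a = NULL, chain_b = NULL,
                                threshold = 90) {
  cha <- default_chain(a, chain_a); chb <- default_chain(b, chain_b)
  frame_res <- (resno - 1L):(resno + 2L)
  ca_a <- select_atoms(a, chain = cha, resno = frame_res, elety = "CA")
  ca_b <- select_atoms(b, chain = chb, resno = frame_res, elety = "CA")
  if (nrow(ca_a) < 4L || nrow(ca_b) < 4L)
    stop("flanking CA frame (residues ", resno - 1L, "-", resno + 2L,
         ") incomplete in one of the structures")
  common <- intersect(ca_a$resno, ca_b$resno)
  A <- atom_xyz(ca_a[match(common, ca_a$resno), ])
  B <- atom_xyz(ca_b[match(common, ca_b$resno), ])
  sup <- kabsch_superpose(A, B)
  co_vec <- function(s, ch, rn, tr = NULL) {
    cat_ <- select_atoms(s, chain = ch, resno = rn, elety = c("C", "O"))
    C <- cat_[cat_$elety == "C", ]; O <- cat_[cat_$elety == "O", ]
    if (nrow(C) == 0L || nrow(O) == 0L)
      stop("carbonyl C/O missing for residue ", rn)
    pc <- as.numeric(C[1L, c("x", "y", "z")]); po <- as.numeric(O[1L, c("x", "y", "z")])
    if (!is.null(tr)) {
      pc <- as.numeric(apply_transform(matrix(pc, 1L), tr))
      po <- as.numeric(apply_transform(matrix(po, 1L), tr))
    }
    unitv(po - pc)
  }
  va <- co_vec(a, cha, resno)
  vb <- co_vec(b, chb, resno, tr = sup)
  ang <- acos(max(-1, min(1, sum(va * vb)))) * 180 / pi
  list(resno = resno, partner = resno + 1L, angle = ang,
       flipped = ang > threshold, threshold = threshold)
}

## ---- P-loop amide orientation ----------------------------------------------

## planar-amide pseudo-hydrogen: N-H direction opposite the bisector of
## N->CA and N->C(i-1); X-ray models carry no hydrogens
amide_h_direction <- function(N, CA, Cprev) {
  -unitv(unitv(CA - N) + unitv(Cprev - N))
}

#' P-loop state from backbone amide orientations
#'
#' For the PTP signature motif HCxxGxxR starting at `motif_start`, scores
#' the four central residues (motif positions 4-7; Gly95-Gly98 when the
#' motif starts at His92) by the cosine between each backbone N-H direction
#' (planar pseudo-hydrogen) and the direction from N to the active-site
#' pocket centre. Amides pointing into the pocket (mean cosine > `margin`,
#' with at least 3 of the 4 residues individually above it) give an
#' `active` call; the mirror condition gives `inactive`; anything else is
#' `indeterminate`.
#'
#' @param s a `struct3d`.
#' @param motif_start author residue number of the motif histidine.
#' @param chain chain id.
#' @param pocket `"auto"` (ligand centroid when a hetero ligand sits near
#'   the motif, else catalytic-cysteine SG), `"ligand-centroid"`, or
#'   `"catalytic-sg"`.
#' @param margin cosine margin separating active/inactive from
#'   indeterminate (default 0.2).
#' @return list: `state`, `mean_cosine`, `per_residue` (data frame `resno`,
#'   `cosine`), `pocket_center`, `pocket_tag`.
#' @export
ploop_state <- function(s, motif_start, chain = NULL,
                        pocket = c("auto", "ligand-centroid", "catalytic-sg"),
                        margin = 0.2) {
  pocket <- match.arg(pocket)
  chain <- default_chain(s, chain)
  motif <- motif_start + 0:7
  rt <- residue_table(s, chain = chain)
  if (!all(motif %in% rt$resno))
    stop("P-loop motif residues ", motif_start, "-", motif_start + 7L,
         " not all present in chain '", chain, "'")
  motif_ca <- select_atoms(s, chain = chain, resno = motif, elety = "CA")
  motif_centroid <- colMeans(atom_xyz(motif_ca))

  ligand_centroid <- function() {
    het <- select_atoms(s, type = "hetero")
    het <- het[!(het$resid %in% WATER_RESIDS), , drop = FALSE]
    if (nrow(het) == 0L) return(NULL)
    d <- sqrt(rowSums(sweep(atom_xyz(het), 2L, motif_centroid)^2))
    near <- het[d < 8, , drop = FALSE]
    if (nrow(near) == 0L) return(NULL)
    ## centroid of the closest hetero residue's heavy atoms
    key <- paste(near$chain, near$resno, near$resid)
    best <- names(sort(tapply(d[d < 8], key, min)))[1L]
    colMeans(atom_xyz(near[key == best, , drop = FALSE]))
  }
  sg_center <- function() {
    sg <- select_atoms(s, chain = chain, resno = motif_start + 1L, elety = "SG")
    if (nrow(sg) == 0L) return(NULL)
    as.numeric(sg[1L, c("x", "y", "z")])
  }
  center <- NULL; tag <- NA_character_
  if (pocket %in% c("auto", "ligand-centroid")) {
    center <- ligand_centroid(); tag <- "ligand-centroid"
  }
  if (is.null(center) && pocket == "ligand-centroid") {
    warning("no hetero ligand near the motif; P-loop state indeterminate")
    return(list(state = "indeterminate", mean_cosine = NA_real_,
                per_residue = NULL, pocket_center = NULL, pocket_tag = NA_character_))
  }
  if (is.null(center)) { center <- sg_center(); tag <- "catalytic-sg" }
  if (is.null(center)) stop("pocket centre unresolvable: no ligand and no catalytic SG")

  central <- motif_start + 3:6
  at <- select_atoms(s, chain = chain, type = "polymer")
  getat <- function(rn, name) {
    row <- at[at$resno == rn & at$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  cosines <- vapply(central, function(rn) {
    N <- getat(rn, "N"); CA <- getat(rn, "CA"); Cp <- getat(rn - 1L, "C")
    if (is.null(N) || is.null(CA) || is.null(Cp)) return(NA_real_)
    h <- amide_h_direction(N, CA, Cp)
    sum(h * unitv(center - N))
  }, numeric(1))
  mean_cos <- mean(cosines, na.rm = TRUE)
  n_above <- sum(cosines > margin, na.rm = TRUE)
  n_below <- sum(cosines < -margin, na.rm = TRUE)
  state <- if (mean_cos > margin && n_above >= 3L) "active"
           else if (mean_cos < -margin && n_below >= 3L) "inactive"
           else "indeterminate"
  list(state = state, mean_cosine = mean_cos,
       per_residue = data.frame(resno = central, cosine = cosines),
       pocket_center = center, pocket_tag = tag)
}

## ---- ensemble dihedral histogram -------------------------------------------

#' Dihedral-frequency histogram over a coordinate ensemble
#'
#' For a multi-model structure (e.g. frames of a simulation), measures one
#' backbone torsion of one residue in every model and bins the values into
#' 36 fixed bins of width 10 degrees spanning (-180, 180], normalised to
#' sum to 1.
#'
#' @param s a multi-model `struct3d`.
#' @param resno residue number.
#' @param angle `"phi"` or `"psi"`.
#' @param chain chain id.
#' @return list: `resno`, `angle`, `breaks` (37 edges), `mids`, `freq`
#'   (length 36, sums to 1), `n_models`, `values`.
#' @export
ensemble_dihedral_histogram <- function(s, resno, angle = c("phi", "psi"),
                                        chain = NULL) {
  angle <- match.arg(angle)
  chain <- default_chain(s, chain)
  models <- sort(unique(s$atoms$model))
  if (!length(models)) stop("structure contains no models")
  at <- s$atoms[s$atoms$type == "ATOM" & s$atoms$chain == chain, , drop = FALSE]
  pick <- function(rn, name) at[at$resno == rn & at$elety == name, , drop = FALSE]
  quad <- switch(angle,
    phi = list(pick(resno - 1L, "C"), pick(resno, "N"), pick(resno, "CA"), pick(resno, "C")),
    psi = list(pick(resno, "N"), pick(resno, "CA"), pick(resno, "C"), pick(resno + 1L, "N")))
  if (any(vapply(quad, nrow, 1L) < length(models)))
    stop("residue ", resno, " is not backbone-complete (with its ", angle,
         " partner) in every model")
  ## one coordinate matrix per torsion atom, row m = model m
  Q <- lapply(quad, function(q) {
    q <- q[!duplicated(q$model), , drop = FALSE]
    atom_xyz(q[match(models, q$model), , drop = FALSE])
  })
  vals <- vapply(seq_along(models), function(m)
    dihedral_angle(Q[[1L]][m, ], Q[[2L]][m, ], Q[[3L]][m, ], Q[[4L]][m, ]),
    numeric(1))
  breaks <- seq(-180, 180, by = 10)
  ## values are in (-180, 180]; bin (a, b] so that +180 lands in the top bin
  idx <- findInterval(vals, breaks, left.open = TRUE, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L
  freq <- tabulate(idx, nbins = 36L) / length(vals)
  list(resno = resno, angle = angle, breaks = breaks,
       mids = breaks[-37L] + 5, freq = freq, n_models = length(vals),
       values = vals)
}
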