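## donor and acceptor heavy atoms by residue type (hydrogens are absent in
## X-ray models; all criteria are heavy-atom based)

SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", TRP = "NE1",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2")
)

## covalent-bond heuristic used to find the donor's antecedent heavy atoms
BOND_CUTOFF <- 1.9

hb_candidates <- function(at, role) {
  bb <- if (role == "donor") at$elety == "N" & at$resid != "PRO" else at$elety == "O"
  tab <- if (role == "donor") SIDECHAIN_DONORS else SIDECHAIN_ACCEPTORS
  sc <- rep(FALSE, nrow(at))
  for (res in names(tab)) sc <- sc | (at$resid == res & at$elety %in% tab[[res]])
  at[bb | sc, , drop = FALSE]
}

#' Detect hydrogen bonds between (or within) atom selections
#'
#' Geometric heavy-atom criterion suited to hydrogen-free crystal
#' structures: donor-acceptor distance at most `dist_max` (default 3.5
#' Angstrom) and, for every heavy atom covalently bonded to the donor, an
#' antecedent-donor-acceptor angle of at least `angle_min` (default 90
#' degrees), which rejects geometries where the acceptor sits behind the
#' donor's bonded framework. Donors are backbone N (except proline) and
#' side-chain N/O (plus Cys SG); acceptors are backbone O and side-chain
#' O/N.
#'
#' @param s a `struct3d`.
#' @param region_a,region_b residue-number vectors delimiting the two
#'   regions; bonds pair one atom from each. With `region_b = NULL`, all
#'   bonds within `region_a` (or the whole chain when that is also NULL)
#'   are returned.
#' @param chain chain id.
#' @param dist_max,angle_min criteria (Angstrom, degrees).
#' @param model model number.
#' @return data frame, one row per bond: donor and acceptor residue
#'   number/name/atom, `distance`, `angle` (minimum antecedent angle).
#' @export
find_hbonds <- function(s, region_a = NULL, region_b = NULL, chain = NULL,
                        dist_max = 3.5, angle_min = 90, model = 1L) {
  chain <- default_chain(s, chain)
  at <- select_atoms(s, chain = chain, type = "polymer", model = model)
  sel_a <- if (is.null(region_a)) at else at[at$resno %in% region_a, , drop = FALSE]
  sel_b <- if (is.null(region_b)) sel_a else at[at$resno %in% region_b, , drop = FALSE]
  don <- rbind(hb_candidates(sel_a, "donor"), hb_candidates(sel_b, "donor"))
  acc <- rbind(hb_candidates(sel_b, "acceptor"), hb_candidates(sel_a, "acceptor"))
  don <- don[!duplicated(paste(don$resno, don$insert, don$elety)), , drop = FALSE]
  acc <- acc[!duplicated(paste(acc$resno, acc$insert, acc$elety)), , drop = FALSE]
  empty <- data.frame(don_resno = integer(0), don_resid = character(0),
                      don_atom = character(0), acc_resno = integer(0),
                      acc_resid = character(0), acc_atom = character(0),
                      distance = numeric(0), angle = numeric(0))
  if (nrow(don) == 0L || nrow(acc) == 0L) return(empty)
  in_a <- function(rn) is.null(region_a) || rn %in% region_a
  in_b <- function(rn) is.null(region_b) || rn %in% region_b
  cross_ok <- function(dr, ar) {
    if (is.null(region_b)) TRUE
    else (in_a(dr) && in_b(ar)) || (in_b(dr) && in_a(ar))
  }
  rows <- list()
  for (i in seq_len(nrow(don))) {
    D <- as.numeric(don[i, c("x", "y", "z")])
    ## antecedents: bonded heavy atoms in the donor's residue (and the
    ## preceding residue's C for a backbone N)
    res_at <- at[at$resno %in% c(don$resno[i], don$resno[i] - 1L), , drop = FALSE]
    dists <- sqrt(rowSums(sweep(atom_xyz(res_at), 2L, D)^2))
    antecedents <- res_at[dists > 1e-6 & dists < BOND_CUTOFF, , drop = FALSE]
    if (nrow(antecedents) == 0L) next
    for (j in seq_len(nrow(acc))) {
      if (don$resno[i] == acc$resno[j] && don$insert[i] == acc$insert[j]) next
      if (!cross_ok(don$resno[i], acc$resno[j])) next
      A <- as.numeric(acc[j, c("x", "y", "z")])
      d <- vnorm(A - D)
      if (d > dist_max || d < 1e-3) next
      angs <- vapply(seq_len(nrow(antecedents)), function(k)
        vangle(as.numeric(antecedents[k, c("x", "y", "z")]), D, A), numeric(1))
      if (min(angs) < angle_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        don_resno = don$resno[i], don_resid = don$resid[i], don_atom = don$elety[i],
        acc_resno = acc$resno[j], acc_resid = acc$resid[j], acc_atom = acc$elety[j],
        distance = d, angle = min(angs), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$don_resno, out$don_atom, out$acc_resno, out$acc_atom), , drop = FALSE]
}

hbond_key <- function(hb) {
  if (nrow(hb) == 0L) return(character(0))
  paste(hb$don_resno, hb$don_atom, hb$acc_resno, hb$acc_atom, sep = "|")
}

#' Difference two hydrogen-bond networks
#'
#' Detects bonds over the same region pair in two conformers and partitions
#' them into bonds only in `a`, only in `b`, and shared, matching by donor
#' and acceptor residue number plus atom name. This is the operation behind
#' "a well-ordered hydrogen-bond network present in one conformer but not
#' the other" comparisons.
#'
#' @inheritParams find_hbonds
#' @param a,b `struct3d` conformers with shared numbering.
#' @param chain_a,chain_b chain ids.
#' @return list of data frames `only_in_a`, `only_in_b`, `shared`, plus
#'   the full per-structure bond tables `bonds_a`, `bonds_b`.
#' @export
compare_hbond_networks <- function(a, b, region_a = NULL, region_b = NULL,
                                   chain_a = NULL, chain_b = NULL,
                                   dist_max = 3.5, angle_min = 90) {
  ha <- find_hbonds(a, region_a, region_b, chain = chain_a,
                    dist_max = dist_max, angle_min = angle_min)
  hb <- find_hbonds(b, region_a, region_b, chain = chain_b,
                    dist_max = dist_max, angle_min = angle_min)
  ka <- hbond_key(ha); kb <- hbond_key(hb)
  list(only_in_a = ha[!(ka %in% kb), , drop = FALSE],
       only_in_b = hb[!(kb %in% ka), , drop = FALSE],
       shared = ha[ka %in% kb, , drop = FALSE],
       bonds_a = ha, bonds_b = hb)
}

#' Side-chain carbon-carbon packing contacts of one residue
#'
#' Counts carbon-carbon atom pairs between the side-chain carbons of the
#' residue (CB and beyond) and carbon atoms of every other residue of the
#' same polymer chain within `cutoff` Angstrom. The literal convention
#' (`"pairs"`) counts unordered atom pairs with partner carbons from
#' backbone or side chain and no sequence-neighbour exclusion; because
#' published counts rarely state their convention, `"partners"` (distinct
#' partner atoms) and `"pairs-nonadjacent"` (excluding residues i-1/i+1)
#' are also available so a printed value can be located among them.
#'
#' @param s a `struct3d`.
#' @param resno residue number.
#' @param chain chain id.
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param convention `"pairs"`, `"partners"`, or `"pairs-nonadjacent"`.
#' @param model model number.
#' @return list: `resno`, `resid`, `count`, `cutoff`, `convention`,
#'   `partners` (data frame of contributing partner residues/atoms).
#' @export
count_cc_contacts <- function(s, resno, chain = NULL, cutoff = 4.5,
                              convention = c("pairs", "partners", "pairs-nonadjacent"),
                              model = 1L) {
  convention <- match.arg(convention)
  chain <- default_chain(s, chain)
  at <- select_atoms(s, chain = chain, type = "polymer", model = model)
  res_rows <- at[at$resno == resno, , drop = FALSE]
  if (nrow(res_rows) == 0L) stop("residue ", resno, " not found in chain '", chain, "'")
  sc <- res_rows[res_rows$elesy == "C" &
                   !(res_rows$elety %in% c("C", "CA")), , drop = FALSE]
  partners_all <- at[at$resno != resno & at$elesy == "C", , drop = FALSE]
  if (convention == "pairs-nonadjacent")
    partners_all <- partners_all[abs(partners_all$resno - resno) > 1L, , drop = FALSE]
  if (nrow(sc) == 0L || nrow(partners_all) == 0L)
    return(list(resno = resno, resid = res_rows$resid[1L], count = 0L,
                cutoff = cutoff, convention = convention,
                partners = data.frame()))
  P <- atom_xyz(partners_all)
  hit_pairs <- 0L
  hit_partner <- rep(FALSE, nrow(partners_all))
  for (i in seq_len(nrow(sc))) {
    d2 <- rowSums(sweep(P, 2L, as.numeric(sc[i, c("x", "y", "z")]))^2)
    within <- d2 <= cutoff^2
    hit_pairs <- hit_pairs + sum(within)
    hit_partner <- hit_partner | within
  }
  count <- if (convention == "partners") sum(hit_partner) else hit_pairs
  partners <- partners_all[hit_partner, c("resno", "resid", "elety"), drop = FALSE]
  rownames(partners) <- NULL
  list(resno = resno, resid = res_rows$resid[1L], count = as.integer(count),
       cutoff = cutoff, convention = convention, partners = partners)
}

## carbons belonging to hydrophilic functional groups (imidazole,
## guanidinium, carboxylate, amide) -- excludable from packing counts
HYDROPHILIC_GROUP_CARBONS <- list(
  HIS = c("CG", "CD2", "CE1"), ARG = "CZ",
  ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD"
)

#' Per-residue packing-contact profile
#'
#' Runs [count_cc_contacts()] over every residue of the chain and returns
#' the per-residue table plus an aggregate by residue type. With
#' `exclude_hydrophilic = TRUE`, carbons of hydrophilic functional groups
#' (histidine imidazole, arginine guanidinium, aspartate/glutamate
#' carboxylate, asparagine/glutamine amide) are removed from the side-chain
#' atom sets before counting.
#'
#' @inheritParams count_cc_contacts
#' @param exclude_hydrophilic drop hydrophilic-group carbons (default FALSE).
#' @return list: `profile` (data frame `resno`, `resid`, `count`),
#'   `by_residue_type` (mean count per residue type), `mean_count`.
#' @export
contact_profile <- function(s, chain = NULL, cutoff = 4.5,
                            convention = "pairs", exclude_hydrophilic = FALSE,
                            model = 1L) {
  chain <- default_chain(s, chain)
  s2 <- s
  if (exclude_hydrophilic) {
    at <- s2$atoms
    drop <- rep(FALSE, nrow(at))
    for (res in names(HYDROPHILIC_GROUP_CARBONS))
      drop <- drop | (at$resid == res & at$elety %in% HYDROPHILIC_GROUP_CARBONS[[res]])
    s2$atoms <- at[!drop, , drop = FALSE]
  }
  rt <- residue_table(s2, chain = chain, model = model)
  counts <- vapply(rt$resno, function(rn)
    count_cc_contacts(s2, rn, chain = chain, cutoff = cutoff,
                      convention = convention, model = model)$count,
    integer(1))
  prof <- data.frame(resno = rt$resno, resid = rt$resid, count = counts,
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ resid, data = prof, FUN = mean)
  list(profile = prof, by_residue_type = agg, mean_count = mean(counts))
}
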