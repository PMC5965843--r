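#' End-to-end conformer comparison report
#'
#' Orchestrates the full comparison between two conformers of a P-loop
#' phosphatase: global superposition, region RMSDs in the global frame,
#' backbone dihedrals of flagged residues, peptide-flip scans, P-loop
#' amide-orientation state calls, hydrogen-bond network differencing, and
#' packing-contact highlights. Every number in the report is reproducible
#' from the inputs plus the recorded parameters.
#'
#' @param a,b `struct3d` objects (conformers or homologues).
#' @param motif_start author residue number of the P-loop histidine; `NA`
#'   skips the P-loop state and flip scan.
#' @param mode alignment mode for the global superposition (see
#'   [align_structures()]).
#' @param regions named list of residue-number vectors whose CA RMSD is
#'   reported in the global frame (default: the P-loop motif when
#'   `motif_start` is given).
#' @param flip_scan residue numbers to test for peptide flips (default:
#'   the motif and nothing else; only meaningful for shared numbering).
#' @param dihedral_residues residues whose phi/psi/omega are tabulated.
#' @param hbond_regions list of two residue-number vectors for the network
#'   diff (default: the motif vs everything, skipped when `NULL`).
#' @param contact_residues residues whose packing-contact counts are
#'   highlighted.
#' @param params overrides for thresholds: `flip_threshold`,
#'   `hb_dist_max`, `hb_angle_min`, `contact_cutoff`, `amide_margin`.
#' @param json_path optional path; when given the report is also written
#'   as JSON.
#' @return list of class `comparison_report`.
#' @export
run_compare <- function(a, b, motif_start = NA, mode = "identical-numbering",
                        regions = NULL, flip_scan = NULL,
                        dihedral_residues = NULL, hbond_regions = NULL,
                        contact_residues = NULL, params = list(),
                        json_path = NULL) {
  p <- utils::modifyList(list(flip_threshold = 90, hb_dist_max = 3.5,
                              hb_angle_min = 90, contact_cutoff = 4.5,
                              amide_margin = 0.2), params)
  al <- align_structures(a, b, mode = mode)
  if (is.null(regions) && !is.na(motif_start))
    regions <- stats::setNames(list(motif_start + 0:7), "p-loop")
  region_tab <- NULL
  if (length(regions)) {
    region_tab <- do.call(rbind, lapply(names(regions), function(nm) {
      rr <- tryCatch(region_rmsd(a, b, resno = regions[[nm]], mode = mode),
                     error = function(e) NULL)
      if (is.null(rr)) return(NULL)
      data.frame(region = nm, rmsd = rr$region_rmsd, n_atoms = rr$n_atoms)
    }))
  }
  if (is.null(flip_scan) && !is.na(motif_start)) flip_scan <- motif_start + 0:6
  flips <- NULL
  if (length(flip_scan)) {
    flips <- do.call(rbind, lapply(flip_scan, function(rn) {
      fr <- tryCatch(detect_peptide_flip(a, b, rn, threshold = p$flip_threshold),
                     error = function(e) NULL)
      if (is.null(fr)) return(NULL)
      data.frame(resno = fr$resno, angle = fr$angle, flipped = fr$flipped)
    }))
  }
  dihedrals <- NULL
  if (length(dihedral_residues)) {
    da <- backbone_dihedrals(a); db <- backbone_dihedrals(b)
    da <- da[da$resno %in% dihedral_residues, , drop = FALSE]
    db <- db[db$resno %in% dihedral_residues, , drop = FALSE]
    dihedrals <- merge(da, db, by = "resno", suffixes = c("_a", "_b"))
  }
  states <- NULL
  if (!is.na(motif_start)) {
    states <- list(
      a = tryCatch(ploop_state(a, motif_start, margin = p$amide_margin),
                   error = function(e) list(state = "indeterminate", error = conditionMessage(e))),
      b = tryCatch(ploop_state(b, motif_start, margin = p$amide_margin),
                   error = function(e) list(state = "indeterminate", error = conditionMessage(e))))
  }
  netdiff <- NULL
  if (!is.null(hbond_regions)) {
    netdiff <- compare_hbond_networks(a, b, region_a = hbond_regions[[1L]],
                                      region_b = hbond_regions[[2L]],
                                      dist_max = p$hb_dist_max,
                                      angle_min = p$hb_angle_min)
  }
  contacts <- NULL
  if (length(contact_residues)) {
    contacts <- do.call(rbind, lapply(contact_residues, function(rn) {
      ca <- tryCatch(count_cc_contacts(a, rn, cutoff = p$contact_cutoff),
                     error = function(e) NULL)
      cb <- tryCatch(count_cc_contacts(b, rn, cutoff = p$contact_cutoff),
                     error = function(e) NULL)
      data.frame(resno = rn,
                 count_a = if (is.null(ca)) NA_integer_ else ca$count,
                 count_b = if (is.null(cb)) NA_integer_ else cb$count)
    }))
  }
  report <- list(
    inputs = c(a = a$id, b = b$id),
    parameters = p,
    global = list(rmsd = al$rmsd, n_aligned = al$n_aligned, mode = mode),
    region_rmsd = region_tab,
    dihedrals = dihedrals,
    peptide_flips = flips,
    ploop_state = if (is.null(states)) NULL else
      list(a = states$a$state, b = states$b$state,
           mean_cosine_a = states$a$mean_cosine, mean_cosine_b = states$b$mean_cosine),
    hbond_diff = if (is.null(netdiff)) NULL else
      list(only_in_a = netdiff$only_in_a, only_in_b = netdiff$only_in_b,
           shared = netdiff$shared),
    contacts = contacts,
    provenance = list(package = "ploopflex",
                      version = as.character(utils::packageVersion("ploopflex")),
                      date = format(Sys.Date())))
  class(report) <- "comparison_report"
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n", x$inputs[["a"]], x$inputs[["b"]]))
  cat(sprintf("  global: rmsd %.4g A over %d aligned residues (%s)\n",
              x$global$rmsd, x$global$n_aligned, x$global$mode))
  if (!is.null(x$region_rmsd))
    for (i in seq_len(nrow(x$region_rmsd)))
      cat(sprintf("  region %-10s rmsd %.4g A over %d atoms\n",
                  x$region_rmsd$region[i], x$region_rmsd$rmsd[i],
                  x$region_rmsd$n_atoms[i]))
  if (!is.null(x$peptide_flips)) {
    fl <- x$peptide_flips[x$peptide_flips$flipped, , drop = FALSE]
    cat(sprintf("  peptide flips: %s\n",
                if (nrow(fl)) paste(fl$resno, collapse = ", ") else "none"))
  }
  if (!is.null(x$ploop_state))
    cat(sprintf("  P-loop state: %s vs %s\n", x$ploop_state$a, x$ploop_state$b))
  invisible(x)
}
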