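#' Hierarchical coordinate model
#'
#' A `struct3d` object holds the atoms of a macromolecular structure as a
#' single flat table with one row per atom and an explicit `model` column,
#' the in-memory form every analysis function in this package consumes.
#' Polymer (`ATOM`) and hetero (`HETATM`) records are kept in the same table
#' and separated by the `type` column; waters are dropped on reading unless
#' requested. Columns: `model`, `type`, `eleno`, `elety` (atom name), `alt`,
#' `resid` (3-letter residue name), `chain`, `resno` (author numbering),
#' `insert`, `x`, `y`, `z`, `o` (occupancy), `b` (B-factor, A^2), `elesy`
#' (element symbol).
#'
#' @param atoms data frame with the columns listed above.
#' @param id accession code or free-text label.
#' @return an object of class `struct3d`.
#' @export
new_structure <- function(atoms, id = "structure") {
  req <- c("model", "type", "eleno", "elety", "alt", "resid", "chain",
           "resno", "insert", "x", "y", "z", "o", "b", "elesy")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "struct3d")
}

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")

## modified residues treated as part of the polymer
MODIFIED_POLYMER <- c("MSE", "CSO", "SEP", "TPO", "PTR", "MLY")

#' @export
print.struct3d <- function(x, ...) {
  at <- x$atoms
  pol <- at[at$type == "ATOM", ]
  cat(sprintf("<struct3d> %s: %d model(s), chains [%s], %d polymer atoms, %d hetero atoms\n",
              x$id, length(unique(at$model)),
              paste(unique(pol$chain), collapse = ","),
              nrow(pol), sum(at$type != "ATOM")))
  invisible(x)
}

#' Number of models in a structure
#' @param s a `struct3d`.
#' @return integer count.
#' @export
n_models <- function(s) length(unique(s$atoms$model))

#' Chain identifiers of the polymer
#' @param s a `struct3d`.
#' @return character vector in file order.
#' @export
polymer_chains <- function(s) {
  unique(s$atoms$chain[s$atoms$type == "ATOM"])
}

default_chain <- function(s, chain = NULL) {
  ch <- polymer_chains(s)
  if (!length(ch)) stop("structure has no polymer chain")
  if (is.null(chain)) return(ch[1L])
  if (!chain %in% s$atoms$chain) stop("chain '", chain, "' not present in ", s$id)
  chain
}

## resolve alternate conformers: keep the highest-occupancy altloc per atom,
## ties broken by the alphabetically first altloc id
resolve_altlocs <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  has_alt <- alt != "" & alt != " "
  if (!any(has_alt)) return(at)
  key <- paste(at$model, at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    o <- at$o[idx]; o[is.na(o)] <- 1
    best <- idx[order(-o, alt[idx])][1L]
    keep[idx] <- FALSE
    keep[best] <- TRUE
  }
  at[keep, , drop = FALSE]
}

bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  base <- data.frame(
    model = 1L, type = a$type, eleno = a$eleno, elety = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt), resid = a$resid, chain = a$chain,
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    elesy = guess_element(a$elesy, a$elety),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L) {
    out <- vector("list", nrow(xyz))
    for (m in seq_len(nrow(xyz))) {
      bm <- base
      crd <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
      bm$model <- m
      bm$x <- crd[, 1]; bm$y <- crd[, 2]; bm$z <- crd[, 3]
      out[[m]] <- bm
    }
    base <- do.call(rbind, out)
  }
  base
}

guess_element <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  bad <- e == ""
  if (any(bad)) {
    nm <- gsub("[^A-Za-z].*$", "", trimws(elety[bad]))
    first <- toupper(substr(nm, 1L, 1L))
    ## two-letter elements that appear in protein/ligand work
    two <- toupper(substr(nm, 1L, 2L))
    e[bad] <- ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "NA", "CL", "BR", "CU"),
                     two, first)
  }
  e
}

#' Read a coordinate file into a `struct3d`
#'
#' Wraps the bio3d PDB/mmCIF readers and normalises the result: alternate
#' conformers are reduced to the highest-occupancy one (ties to the
#' alphabetically first altloc), waters are discarded by default, and
#' common modified residues (e.g. selenomethionine) are kept in the polymer
#' partition.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param keep_waters keep water residues (default `FALSE`).
#' @param id label for the structure; defaults to the file stem.
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_waters = FALSE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    switch(format,
           pdb = bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
           mmcif = bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse '", path, "' as ", format, ": ",
                             conditionMessage(e)))
  at <- bio3d_to_atoms(pdb)
  ## modified residues read as HETATM belong to the polymer
  at$type[at$type == "HETATM" & at$resid %in% MODIFIED_POLYMER] <- "ATOM"
  if (!keep_waters) at <- at[!(at$resid %in% WATER_RESIDS), , drop = FALSE]
  at <- resolve_altlocs(at)
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE)
  new_structure(at, id = id)
}

#' Write a `struct3d` to a PDB file
#'
#' Emits fixed-width PDB ATOM/HETATM records (coordinates to 3 decimals)
#' through the bio3d writer; multi-model structures produce MODEL blocks.
#'
#' @param s a `struct3d`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  if (nrow(at) == 0L) stop("refusing to write a structure with no atoms")
  models <- sort(unique(at$model))
  a1 <- at[at$model == models[1L], , drop = FALSE]
  xyz <- do.call(rbind, lapply(models, function(m) {
    am <- at[at$model == m, , drop = FALSE]
    if (nrow(am) != nrow(a1))
      stop("models differ in atom count; cannot write multi-model PDB")
    as.vector(t(atom_xyz(am)))
  }))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = a1$type, resno = a1$resno, resid = a1$resid,
                     eleno = a1$eleno, elety = a1$elety, chain = a1$chain,
                     insert = ifelse(a1$insert == "", NA, a1$insert),
                     o = a1$o, b = a1$b, elesy = a1$elesy)
    TRUE
  }, error = function(e) stop("could not write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Select atoms from a structure
#'
#' Filters the atom table by chain, residue numbers, atom names, element and
#' polymer/hetero class, returning rows in stable (chain, residue, atom)
#' order. An empty result is returned as an empty table, not an error.
#'
#' @param s a `struct3d`.
#' @param chain chain id(s), or `NULL` for all.
#' @param resno integer vector of author residue numbers (e.g. `92:99`),
#'   inclusive, or `NULL` for all.
#' @param elety atom-name set (e.g. `"CA"`), or `NULL`.
#' @param element element symbol set (e.g. `"C"`), or `NULL`.
#' @param type `"polymer"`, `"hetero"` or `"all"`.
#' @param model model number (default 1).
#' @return atom-table data frame (possibly zero rows).
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, elety = NULL,
                         element = NULL, type = c("polymer", "hetero", "all"),
                         model = 1L) {
  type <- match.arg(type)
  at <- s$atoms
  keep <- at$model == model
  if (type == "polymer") keep <- keep & at$type == "ATOM"
  if (type == "hetero")  keep <- keep & at$type != "ATOM"
  if (!is.null(chain))   keep <- keep & at$chain %in% chain
  if (!is.null(resno))   keep <- keep & at$resno %in% resno
  if (!is.null(elety))   keep <- keep & at$elety %in% elety
  if (!is.null(element)) keep <- keep & at$elesy %in% toupper(element)
  out <- at[keep, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$insert, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-letter sequence of a polymer chain
#'
#' @param s a `struct3d`.
#' @param chain chain id; defaults to the first polymer chain.
#' @param model model number.
#' @return character scalar, one letter per residue in author order;
#'   residues without a standard mapping become `"X"` (selenomethionine and
#'   similar modified residues map to their parent letter).
#' @export
extract_sequence <- function(s, chain = NULL, model = 1L) {
  chain <- default_chain(s, chain)
  at <- select_atoms(s, chain = chain, type = "polymer", model = model)
  if (nrow(at) == 0L) stop("chain '", chain, "' has no polymer residues")
  key <- paste(at$resno, at$insert)
  res <- at$resid[!duplicated(key)]
  lett <- suppressWarnings(bio3d::aa321(res))
  lett[is.na(lett) | lett == ""] <- "X"
  paste(lett, collapse = "")
}

#' Residue-level view of a chain
#'
#' @param s a `struct3d`.
#' @param chain chain id; default first polymer chain.
#' @param model model number.
#' @return data frame with one row per residue: `resno`, `insert`, `resid`,
#'   and `backbone_complete` (TRUE iff N, CA, C, O all present).
#' @export
residue_table <- function(s, chain = NULL, model = 1L) {
  chain <- default_chain(s, chain)
  at <- select_atoms(s, chain = chain, type = "polymer", model = model)
  key <- paste(at$resno, at$insert, sep = "\r")
  ukey <- unique(key)
  out <- do.call(rbind, lapply(ukey, function(k) {
    rows <- at[key == k, , drop = FALSE]
    data.frame(resno = rows$resno[1L], insert = rows$insert[1L],
               resid = rows$resid[1L],
               backbone_complete = all(c("N", "CA", "C", "O") %in% rows$elety),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
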