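# Coordinate model: a Structure is a light S3 wrapper around an atom table
# (one row per heavy atom) in file order.  Columns: chain, resno, insert,
# resname, atom, element, x, y, z, occ.  Residue identity keeps the author
# numbering plus insertion code, so proposals cite author site labels.

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns chain, resno, insert, resname, atom,
#'   element, x, y, z, occ
#' @param id string label (e.g. a PDB id)
#' @return object of class `prot_structure`
#' @export
structure_from_atoms <- function(atoms, id = "struct") {
  needed <- c("chain", "resno", "insert", "resname", "atom",
              "element", "x", "y", "z", "occ")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms)[, needed]
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  structure(list(id = id, atoms = atoms), class = "prot_structure")
}

#' @export
print.prot_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf("<prot_structure '%s': %d atoms, %d residues, chains %s>\n",
              x$id, nrow(x$atoms), nrow(res),
              paste(unique(res$chain), collapse = ",")))
  invisible(x)
}

residue_key <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

#' Residue table of a Structure
#'
#' @param s a `prot_structure`
#' @return data.frame with one row per residue, in file order: key, chain,
#'   resno, insert, resname, n_atoms, has_full_backbone
#' @export
structure_residues <- function(s) {
  a <- s$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  idx <- !duplicated(key)
  res <- data.frame(key = key[idx], chain = a$chain[idx],
                    resno = a$resno[idx], insert = a$insert[idx],
                    resname = a$resname[idx], stringsAsFactors = FALSE)
  res$n_atoms <- as.integer(table(key)[res$key])
  res$has_full_backbone <- vapply(res$key, function(k) {
    all(BACKBONE_ATOMS %in% a$atom[key == k])
  }, logical(1))
  rownames(res) <- NULL
  res
}

#' Atoms of one residue
#'
#' @param s a `prot_structure`
#' @param key residue key `"chain:resno[icode]"`
#' @return data.frame of that residue's atom rows
#' @export
residue_atoms <- function(s, key) {
  a <- s$atoms
  a[residue_key(a$chain, a$resno, a$insert) == key, , drop = FALSE]
}

#' Backbone completeness of one residue
#'
#' TRUE iff the residue holds all of N, CA, C, O.
#'
#' @inheritParams residue_atoms
#' @export
has_full_backbone <- function(s, key) {
  all(BACKBONE_ATOMS %in% residue_atoms(s, key)$atom)
}

#' Coordinate matrix of a Structure
#'
#' @param s a `prot_structure`
#' @return numeric n x 3 matrix
#' @export
structure_coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

element_from_name <- function(atom) {
  stripped <- gsub("[0-9']", "", atom)
  substr(stripped, 1, 1)
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Clean a parsed structure
#'
#' Applies the standard preparation used throughout: optionally keep a
#' single chain, drop HETATM/water records, drop hydrogens and deuteriums,
#' resolve alternate locations to the highest occupancy (ties broken by
#' file order), and drop residues whose name is not one of the twenty
#' standard amino acids (logged as a warning).  Cleaning is idempotent.
#'
#' @param s a `prot_structure` (may still carry altlocs etc.)
#' @param chain optional chain identifier to retain
#' @param drop_het drop heteroatom records (default TRUE)
#' @return cleaned `prot_structure`
#' @export
clean_structure <- function(s, chain = NULL, drop_het = TRUE) {
  a <- s$atoms
  if (!is.null(chain)) {
    if (!chain %in% a$chain)
      stop("chain '", chain, "' not present in structure '", s$id, "'")
    a <- a[a$chain == chain, , drop = FALSE]
  }
  if (drop_het && "het" %in% names(a)) a <- a[!a$het, , drop = FALSE]
  a <- a[!a$resname %in% WATER_RESNAMES, , drop = FALSE]
  a <- a[!a$element %in% c("H", "D"), , drop = FALSE]
  nonstd <- setdiff(unique(a$resname), AA3)
  if (length(nonstd) > 0) {
    warning("dropping non-standard residues: ",
            paste(nonstd, collapse = ", "))
    a <- a[a$resname %in% AA3, , drop = FALSE]
  }
  if (nrow(a) > 0 && "alt" %in% names(a)) {
    akey <- paste(residue_key(a$chain, a$resno, a$insert), a$atom)
    keep <- unlist(lapply(split(seq_len(nrow(a)), akey), function(i) {
      i[which.max(a$occ[i])]      # ties: first in file order (which.max)
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
    a$alt <- NULL
  }
  a$het <- NULL
  if (nrow(a) == 0)
    stop("structure '", s$id, "' is empty after cleaning")
  rownames(a) <- NULL
  structure_from_atoms(a, id = s$id)
}

#' Read a PDB-format structure
#'
#' Parses a PDB file (first model only), then cleans it: optional chain
#' selection, HETATM/water removal, hydrogen removal, altloc resolution by
#' highest occupancy, non-standard residues dropped with a warning.
#'
#' @param path PDB file path
#' @param chain optional chain id to retain
#' @param drop_het drop HETATM records (default TRUE)
#' @param id structure label; defaults to the file base name
#' @return cleaned `prot_structure`
#' @export
read_structure <- function(path, chain = NULL, drop_het = TRUE, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  # rm.alt=FALSE: altloc resolution is occupancy-based, done in cleaning
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     element_from_name(at$elety), at$elesy),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  raw <- structure(list(id = id, atoms = atoms), class = "prot_structure")
  clean_structure(raw, chain = chain, drop_het = drop_het)
}

#' Write a Structure in PDB format
#'
#' Fixed-width ATOM records; coordinates to three decimals. Round-tripping
#' through [read_structure()] reproduces residue keys, atom names and
#' coordinates within 0.001 Angstrom.
#'
#' @param s a non-empty `prot_structure`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  if (is.null(a) || nrow(a) == 0) stop("refusing to write empty structure")
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resname,
                     eleno = seq_len(nrow(a)), elety = a$atom,
                     chain = ifelse(a$chain == "", " ", a$chain),
                     insert = ifelse(a$insert == "", NA, a$insert),
                     o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
    TRUE
  }, error = function(e) {
    stop("cannot write PDB file '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Apply a rigid transform to a Structure
#'
#' @param s a `prot_structure`
#' @param tr a `rigid_transform` (see [kabsch_superpose()])
#' @return transformed `prot_structure`
#' @export
transform_structure <- function(s, tr) {
  xyz <- apply_transform(structure_coords(s), tr)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}
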