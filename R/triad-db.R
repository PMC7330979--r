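# Triad pairs and the searchable template database: extraction around each
# detected interaction, single-linkage clustering per category, and flat-file
# persistence (PDB fragments + TSV index + signature matrix).

triad_residue_order <- function() {
  # residue slots in fixed order: (n-1, n, n+1, n'-1, n', n'+1)
  c("m1", "n", "p1", "m1p", "np", "p1p")
}

#' Build one triad pair around a residue pair
#'
#' Collects the 24 main-chain coordinates of residues n-1, n, n+1, n'-1,
#' n', n'+1 (atoms N, CA, C, O in fixed order) plus the side-chain atoms
#' (beyond CA, i.e. including CB) of n and n'.  The first residue (n) is
#' the member with the lower (chain, resno, insert) key.
#'
#' @param s cleaned `prot_structure`
#' @param key_n,key_np residue keys of the interacting (or candidate) pair
#' @param kind interaction kind seeding the triad, or NA for a search
#'   target
#' @param interaction optional one-row interaction record
#' @return object of class `triad_pair`, or NULL (with a message) when a
#'   flank is missing or a backbone is incomplete
#' @export
make_triad_pair <- function(s, key_n, key_np, kind = NA_character_,
                            interaction = NULL) {
  res <- structure_residues(s)
  pos_n <- match(key_n, res$key)
  pos_np <- match(key_np, res$key)
  if (is.na(pos_n) || is.na(pos_np))
    stop("residue not found in structure: ",
         paste(setdiff(c(key_n, key_np), res$key), collapse = ", "))
  # order so n precedes n' in the chain
  if (pos_np < pos_n) { tmp <- pos_n; pos_n <- pos_np; pos_np <- tmp }
  slots <- c(pos_n - 1, pos_n, pos_n + 1, pos_np - 1, pos_np, pos_np + 1)
  if (any(slots < 1) || any(slots > nrow(res))) {
    message("triad skipped (missing flank): ", key_n, " / ", key_np)
    return(NULL)
  }
  keys <- res$key[slots]
  if (length(unique(keys)) != 6) {
    message("triad skipped (overlapping triads): ", key_n, " / ", key_np)
    return(NULL)
  }
  # flanks must be covalent neighbours on the same chain
  if (length(unique(res$chain[slots])) != 1) {
    message("triad skipped (flank crosses chains): ", key_n, " / ", key_np)
    return(NULL)
  }
  bb <- matrix(NA_real_, nrow = 24, ncol = 3)
  rn <- character(24)
  for (i in seq_along(slots)) {
    ra <- residue_atoms(s, keys[i])
    for (j in seq_along(BACKBONE_ATOMS)) {
      row <- ra[ra$atom == BACKBONE_ATOMS[j], , drop = FALSE]
      if (nrow(row) != 1) {
        message("triad skipped (incomplete backbone at ", keys[i], "): ",
                key_n, " / ", key_np)
        return(NULL)
      }
      k <- (i - 1) * 4 + j
      bb[k, ] <- as.numeric(row[1, c("x", "y", "z")])
      rn[k] <- paste(triad_residue_order()[i], BACKBONE_ATOMS[j], sep = "|")
    }
  }
  rownames(bb) <- rn
  side <- function(key) {
    ra <- residue_atoms(s, key)
    ra <- ra[!ra$atom %in% c(BACKBONE_ATOMS, "OXT"), , drop = FALSE]
    m <- as.matrix(ra[, c("x", "y", "z")])
    rownames(m) <- ra$atom
    m
  }
  structure(list(
    source_id = s$id,
    chain = res$chain[pos_n],
    pair = c(res$key[pos_n], res$key[pos_np]),
    pair_names = c(res$resname[pos_n], res$resname[pos_np]),
    kind = kind,
    backbone = bb,
    sidechain_n = side(res$key[pos_n]),
    sidechain_np = side(res$key[pos_np]),
    interaction = interaction
  ), class = "triad_pair")
}

#' The 24-atom main-chain alignment set of a triad pair
#'
#' @param t a `triad_pair`
#' @return 24 x 3 coordinate matrix, rows ordered (n-1, n, n+1, n'-1, n',
#'   n'+1) x (N, CA, C, O)
#' @export
triad_backbone <- function(t) {
  stopifnot(inherits(t, "triad_pair"))
  t$backbone
}

#' All atoms of a triad pair (backbone plus side chains of n and n')
#' @param t a `triad_pair`
#' @return data.frame resname, atom, x, y, z
#' @keywords internal
triad_atoms <- function(t) {
  resn <- sub("\\|.*", "", rownames(t$backbone))
  bbnames <- rep(c("XXX"), 24)
  names6 <- c("GLY", t$pair_names[1], "GLY", "GLY", t$pair_names[2], "GLY")
  names(names6) <- triad_residue_order()
  bb <- data.frame(resname = unname(names6[resn]),
                   atom = sub(".*\\|", "", rownames(t$backbone)),
                   x = t$backbone[, 1], y = t$backbone[, 2],
                   z = t$backbone[, 3], stringsAsFactors = FALSE)
  sc <- function(m, nm) {
    if (nrow(m) == 0) return(NULL)
    data.frame(resname = nm, atom = rownames(m), x = m[, 1], y = m[, 2],
               z = m[, 3], stringsAsFactors = FALSE)
  }
  out <- rbind(bb, sc(t$sidechain_n, t$pair_names[1]),
               sc(t$sidechain_np, t$pair_names[2]))
  rownames(out) <- NULL
  out
}

#' Extract triad pairs around detected interactions
#'
#' One triad pair per distinct (residue pair, kind); when several atom
#' pairs report the same interaction the closest is kept.  Pairs whose six
#' residues are not all present with full backbones are skipped with a
#' logged reason.
#'
#' @param s cleaned `prot_structure`
#' @param inter interaction table from [detect_sidechain_interactions()]
#' @return list of `triad_pair`
#' @export
extract_triad_pairs <- function(s, inter) {
  if (nrow(inter) == 0) return(list())
  inter <- inter[order(inter$distance), , drop = FALSE]
  id <- paste(inter$res_a, inter$res_b, inter$kind)
  inter <- inter[!duplicated(id), , drop = FALSE]
  inter <- inter[order(inter$res_a, inter$res_b, inter$kind), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(inter))) {
    t <- make_triad_pair(s, inter$res_a[i], inter$res_b[i],
                         kind = inter$kind[i], interaction = inter[i, ])
    if (!is.null(t)) out[[length(out) + 1]] <- t
  }
  out
}

#' Pairwise main-chain RMSD matrix over triads
#' @param triads list of `triad_pair`
#' @return symmetric matrix of minimum-pairing RMSDs
#' @export
triad_rmsd_matrix <- function(triads) {
  n <- length(triads)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- triad_rmsd(triads[[i]], triads[[j]])$rmsd
  }
  d
}

triad_sort_order <- function(triads) {
  order(vapply(triads, function(t) t$source_id, ""),
        vapply(triads, function(t) t$pair[1], ""),
        vapply(triads, function(t) t$pair[2], ""),
        vapply(triads, function(t) ifelse(is.na(t$kind), "", t$kind), ""))
}

#' Single-linkage clustering of triad pairs
#'
#' Clusters under main-chain triad RMSD with merges allowed at distance
#' <= cutoff; the representative of each cluster is its first member under
#' the deterministic input ordering (sorted by source id, then residue
#' keys).
#'
#' @param triads list of `triad_pair` sharing one residue-pair category
#' @param cutoff clustering RMSD cutoff, Angstrom (> 0)
#' @return list of clusters; each a list with `representative` (a
#'   `triad_pair`), `members` (list of `triad_pair`) and `size`
#' @export
cluster_triads <- function(triads, cutoff = 0.5) {
  stopifnot(cutoff > 0)
  if (length(triads) == 0) return(list())
  triads <- triads[triad_sort_order(triads)]
  if (length(triads) == 1)
    return(list(list(representative = triads[[1]], members = triads,
                     size = 1L)))
  d <- triad_rmsd_matrix(triads)
  memb <- cluster_distance_matrix(d, cutoff)
  lapply(sort(unique(memb)), function(cl) {
    idx <- which(memb == cl)
    list(representative = triads[[idx[1]]], members = triads[idx],
         size = length(idx))
  })
}

# single-linkage threshold clustering on a precomputed distance matrix;
# clusters are numbered by first appearance so the first member of cluster
# i precedes that of cluster i+1
cluster_distance_matrix <- function(d, cutoff) {
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  memb <- stats::cutree(hc, h = cutoff)
  match(memb, unique(memb))
}

first_residue_group <- function(t) {
  if (!is.na(t$kind) && t$kind == "disulfide") "CYS" else t$pair_names[1]
}

triad_category <- function(t) {
  if (!is.na(t$kind) && t$kind == "disulfide") return("CYS-CYS")
  paste(t$pair_names[1], t$pair_names[2], sep = "-")
}

#' Enumerate the storage categories of the database
#'
#' Ordered (first residue x partner) pairs over the 11 hydrogen-bond/ionic
#' capable residue types, plus the single disulfide (CYS-CYS) class:
#' 11 x 11 + 1 = 122 categories, regrouped into 12 first-residue groups.
#'
#' @return character vector of category names, length 122
#' @export
db_categories <- function() {
  c(as.vector(outer(DB_RESIDUES_HB, DB_RESIDUES_HB, paste, sep = "-")),
    "CYS-CYS")
}

empty_db_index <- function() {
  data.frame(id = character(0), source_id = character(0),
             chain = character(0), res_n = character(0),
             res_np = character(0), name_n = character(0),
             name_np = character(0), kind = character(0),
             group = character(0), category = character(0),
             cluster_size = integer(0), stringsAsFactors = FALSE)
}

#' Build the triad-pair template database
#'
#' Runs detection, triad extraction, per-category single-linkage clustering
#' and representative selection over a set of template structure files,
#' then computes cutoff-scanning signatures of the representatives and
#' fits the SVD reduction model.
#'
#' @param paths character vector of PDB file paths (>= 1)
#' @param cutoff clustering RMSD cutoff, Angstrom (default 0.5)
#' @param chain optional chain to retain from every input
#' @param sig_params signature parameters from [signature_params()]
#' @param energy_fraction fraction of the singular-value sum retained by
#'   the SVD model (default 0.7)
#' @param structures optional list of pre-built `prot_structure`s, used
#'   instead of reading `paths`
#' @return object of class `triad_db`: list with `triads` (representatives),
#'   `index` (tabular metadata), `signatures`, `svd`, `reduced`,
#'   `sig_params`, `cutoff`
#' @export
build_database <- function(paths = NULL, cutoff = 0.5, chain = NULL,
                           sig_params = signature_params(),
                           energy_fraction = 0.7, structures = NULL) {
  if (is.null(structures)) {
    stopifnot(length(paths) >= 1)
    # deterministic over input order
    paths <- sort(paths)
    structures <- lapply(paths, read_structure, chain = chain)
  } else {
    structures <- structures[order(vapply(structures, function(s) s$id, ""))]
  }
  triads <- list()
  for (s in structures) {
    inter <- detect_sidechain_interactions(s)
    triads <- c(triads, extract_triad_pairs(s, inter))
  }
  reps <- list()
  index <- empty_db_index()
  if (length(triads) > 0) {
    cats <- vapply(triads, triad_category, "")
    for (cat in sort(unique(cats))) {
      clusters <- cluster_triads(triads[cats == cat], cutoff = cutoff)
      for (cl in clusters) {
        t <- cl$representative
        reps[[length(reps) + 1]] <- t
        index <- rbind(index, data.frame(
          id = "", source_id = t$source_id, chain = t$chain,
          res_n = t$pair[1], res_np = t$pair[2],
          name_n = t$pair_names[1], name_np = t$pair_names[2],
          kind = t$kind, group = first_residue_group(t),
          category = triad_category(t), cluster_size = cl$size,
          stringsAsFactors = FALSE))
      }
    }
    index$id <- sprintf("T%04d", seq_len(nrow(index)))
  } else {
    warning("no triad pairs extracted: database is empty")
  }
  db <- structure(list(triads = reps, index = index, signatures = NULL,
                       svd = NULL, reduced = NULL, sig_params = sig_params,
                       cutoff = cutoff), class = "triad_db")
  if (length(reps) > 0) {
    db$signatures <- t(vapply(reps, function(t)
      compute_signature(t, sig_params)$values,
      numeric(signature_length(sig_params))))
    rownames(db$signatures) <- index$id
    db$svd <- tryCatch(fit_svd(db$signatures, energy_fraction),
                       error = function(e) NULL)
    if (!is.null(db$svd)) {
      db$reduced <- db$signatures %*% db$svd$basis
      rownames(db$reduced) <- index$id
    }
  }
  db
}

#' @export
print.triad_db <- function(x, ...) {
  cat(sprintf("<triad_db: %d representatives, %d groups, cutoff %.2f A>\n",
              nrow(x$index), length(unique(x$index$group)), x$cutoff))
  if (nrow(x$index) > 0) print(table(x$index$group))
  invisible(x)
}

#' Representative counts per first-residue group
#' @param db a `triad_db`
#' @return named integer vector over the 12 groups
#' @export
db_group_counts <- function(db) {
  groups <- c(sort(DB_RESIDUES_HB), "CYS")
  n <- vapply(groups, function(g) sum(db$index$group == g), integer(1))
  n[order(names(n))]
}

triad_to_structure <- function(t, id) {
  ta <- triad_atoms(t)
  resn <- sub("\\|.*", "", rownames(t$backbone))
  # residue numbering 1..6 in slot order; side chains share n=2, n'=5
  slot_of <- c(m1 = 1L, n = 2L, p1 = 3L, m1p = 4L, np = 5L, p1p = 6L)
  bb_res <- unname(slot_of[resn])
  sc_res <- c(rep(2L, nrow(t$sidechain_n)), rep(5L, nrow(t$sidechain_np)))
  atoms <- data.frame(chain = "A", resno = c(bb_res, sc_res), insert = "",
                      resname = ta$resname, atom = ta$atom,
                      element = element_from_name(ta$atom),
                      x = ta$x, y = ta$y, z = ta$z, occ = 1,
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  structure_from_atoms(atoms, id = id)
}

structure_to_triad <- function(s, row) {
  t <- make_triad_pair(s, "A:2", "A:5", kind = row$kind)
  if (is.null(t)) stop("corrupt fragment for ", row$id)
  t$source_id <- row$source_id
  t$chain <- row$chain
  t$pair <- c(row$res_n, row$res_np)
  t$pair_names <- c(row$name_n, row$name_np)
  t
}

#' Persist a database to a directory
#'
#' Writes one PDB fragment file per representative (six residues, the two
#' triads), a TSV index, the signature matrix and the SVD model, all as
#' plain text.  [load_database()] inverts this within 0.001 A.
#'
#' @param db a `triad_db`
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
save_database <- function(db, dir) {
  dir.create(file.path(dir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.table(db$index, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(db$index))) {
    write_structure(triad_to_structure(db$triads[[i]], db$index$id[i]),
                    file.path(dir, "fragments",
                              paste0(db$index$id[i], ".pdb")))
  }
  meta <- list(cutoff = db$cutoff, sig_params = unclass(db$sig_params))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(db$signatures))
    utils::write.table(db$signatures, file.path(dir, "signatures.tsv"),
                       sep = "\t", quote = FALSE, col.names = FALSE,
                       row.names = TRUE)
  if (!is.null(db$svd)) save_svd_model(db$svd, file.path(dir, "svd"))
  invisible(dir)
}

#' Load a database saved by [save_database()]
#'
#' @param dir database directory
#' @return a `triad_db`
#' @export
load_database <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  if (!file.exists(idx_path)) stop("no database index at ", idx_path)
  index <- utils::read.table(idx_path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  if (nrow(index) > 0) index$cluster_size <- as.integer(index$cluster_size)
  else index <- empty_db_index()
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  sig_params <- do.call(signature_params, meta$sig_params)
  triads <- list()
  for (i in seq_len(nrow(index))) {
    fp <- file.path(dir, "fragments", paste0(index$id[i], ".pdb"))
    if (!file.exists(fp))
      stop("database fragment missing for index row ", index$id[i],
           ": ", fp)
    triads[[i]] <- structure_to_triad(read_structure(fp), index[i, ])
  }
  db <- structure(list(triads = triads, index = index, signatures = NULL,
                       svd = NULL, reduced = NULL, sig_params = sig_params,
                       cutoff = meta$cutoff), class = "triad_db")
  sp <- file.path(dir, "signatures.tsv")
  if (file.exists(sp) && nrow(index) > 0) {
    m <- utils::read.table(sp, sep = "\t", header = FALSE,
                           row.names = 1)
    db$signatures <- as.matrix(m)
    colnames(db$signatures) <- NULL
  }
  if (file.exists(file.path(dir, "svd", "spectrum.tsv"))) {
    db$svd <- load_svd_model(file.path(dir, "svd"))
    if (!is.null(db$signatures)) {
      db$reduced <- db$signatures %*% db$svd$basis
      rownames(db$reduced) <- db$index$id
    }
  }
  db
}
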