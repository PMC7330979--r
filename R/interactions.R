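# Side-chain interaction detection (database side) and the seven-type
# contact classification used for wild-vs-mutant evaluation.

pairwise_dists <- function(xa, xb) {
  # xa: n x 3, xb: m x 3 -> n x m Euclidean distance matrix
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

atoms_with_keys <- function(s) {
  a <- s$atoms
  a$key <- residue_key(a$chain, a$resno, a$insert)
  a
}

# TRUE for residue pairs to exclude from contact counting: same residue, or
# sequence-adjacent on the same chain (covalent geometry is not a contact).
excluded_pair <- function(chain_a, resno_a, chain_b, resno_b) {
  chain_a == chain_b & abs(resno_a - resno_b) <= 1
}

#' Detect database-side side-chain interactions
#'
#' Scans all inter-residue side-chain atom pairs and reports hydrogen bonds
#' (both atoms in the hydrogen-bond atom list, distance < 3.50 A), ionic
#' interactions (one atom from the positive group ARG CZ / HIS CD2, CE1,
#' CG, one from the negative group ASP CG, OD1, OD2 / GLU CD, distance
#' < 6.00 A) and disulfide bonds (CYS SG-SG < 2.08 A).  Intra-residue and
#' sequence-adjacent pairs are excluded; each qualifying atom pair is
#' reported once with `res_a` the lower residue key.
#'
#' @param s cleaned `prot_structure`
#' @return data.frame with columns kind, res_a, res_b, name_a, name_b,
#'   atom_a, atom_b, distance (possibly zero rows)
#' @export
detect_sidechain_interactions <- function(s) {
  a <- atoms_with_keys(s)
  a <- a[!a$atom %in% BACKBONE_ATOMS & a$atom != "OXT", , drop = FALSE]
  empty <- data.frame(kind = character(0), res_a = character(0),
                      res_b = character(0), name_a = character(0),
                      name_b = character(0), atom_a = character(0),
                      atom_b = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0) return(empty)
  out <- list()
  emit <- function(kind, ia, ib, d) {
    # order so that res_a is the earlier residue (chain, resno, insert)
    ord <- order(a$chain[c(ia, ib)], a$resno[c(ia, ib)],
                 a$insert[c(ia, ib)])
    ii <- c(ia, ib)[ord]
    data.frame(kind = kind,
               res_a = a$key[ii[1]], res_b = a$key[ii[2]],
               name_a = a$resname[ii[1]], name_b = a$resname[ii[2]],
               atom_a = a$atom[ii[1]], atom_b = a$atom[ii[2]],
               distance = d, stringsAsFactors = FALSE)
  }
  scan <- function(idx_a, idx_b, cutoff, kind, symmetric) {
    if (length(idx_a) == 0 || length(idx_b) == 0) return()
    dm <- pairwise_dists(
      as.matrix(a[idx_a, c("x", "y", "z")]),
      as.matrix(a[idx_b, c("x", "y", "z")]))
    hits <- which(dm < cutoff, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      ia <- idx_a[hits[h, 1]]; ib <- idx_b[hits[h, 2]]
      if (ia == ib) next
      if (symmetric && ia > ib) next   # count unordered pair once
      if (excluded_pair(a$chain[ia], a$resno[ia], a$chain[ib], a$resno[ib]))
        next
      out[[length(out) + 1]] <<- emit(kind, ia, ib, dm[hits[h, 1], hits[h, 2]])
    }
  }
  in_table <- function(tab)
    which(mapply(function(r, at) at %in% tab[[r]], a$resname, a$atom))
  hb_idx <- in_table(HB_ATOMS)
  scan(hb_idx, hb_idx, INTERACTION_CUTOFFS["hydrogen_bond"],
       "hydrogen_bond", symmetric = TRUE)
  scan(in_table(IONIC_POSITIVE_ATOMS), in_table(IONIC_NEGATIVE_ATOMS),
       INTERACTION_CUTOFFS["ionic"], "ionic", symmetric = FALSE)
  ss_idx <- in_table(DISULFIDE_ATOMS)
  scan(ss_idx, ss_idx, INTERACTION_CUTOFFS["disulfide"],
       "disulfide", symmetric = TRUE)
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$res_a, res$res_b, res$kind, res$atom_a, res$atom_b), ]
  rownames(res) <- NULL
  res
}

# covalent antecedent used for donor-angle tests on hydrogen-free
# structures: the nearest other heavy atom of the same residue.
donor_antecedent_coords <- function(a, idx) {
  same <- which(a$key == a$key[idx])
  same <- setdiff(same, idx)
  if (length(same) == 0) return(NULL)
  p <- as.numeric(a[idx, c("x", "y", "z")])
  dm <- sqrt(colSums((t(as.matrix(a[same, c("x", "y", "z")])) - p)^2))
  as.numeric(a[same[which.min(dm)], c("x", "y", "z")])
}

angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

empty_contact_profile <- function() {
  p <- as.list(rep(0L, length(CONTACT_TYPES)))
  names(p) <- CONTACT_TYPES
  structure(p, class = "contact_profile")
}

#' Classify inter-residue contacts into seven types
#'
#' Counts heavy-atom contacts per type: hydrogen bonds (donor-acceptor
#' distance <= 3.5 A passing a 90-degree donor-angle criterion measured at
#' the donor via its covalent antecedent, since cleaned structures carry no
#' hydrogens), weak hydrogen bonds (carbon donor, <= 3.6 A, relaxed angle
#' band 30-150 degrees), polar and weak polar (the same distance rules with
#' the angle criterion dropped), ionic (opposing formal-charge groups
#' <= 4.0 A), aromatic (ring pairs with ring atoms <= 4.5 A or centroids
#' <= 6.0 A) and hydrophobic (apolar atoms <= 4.5 A).  Intra-residue and
#' sequence-adjacent pairs are excluded.  By construction hydrogen_bond <=
#' polar and weak_hb <= weak_polar.
#'
#' @param s cleaned `prot_structure`
#' @return a `contact_profile`: named integer counts for hydrogen_bond,
#'   weak_hb, ionic, aromatic, polar, weak_polar, hydrophobic
#' @export
classify_contacts <- function(s) {
  a <- atoms_with_keys(s)
  prof <- empty_contact_profile()
  xyz <- as.matrix(a[, c("x", "y", "z")])

  flag <- function(tab) mapply(function(r, at) at %in% tab[[r]],
                               a$resname, a$atom)
  is_donor <- a$atom == "N" | flag(DONOR_ATOMS)
  is_acceptor <- a$atom %in% c("O", "OXT") | flag(ACCEPTOR_ATOMS)
  is_weak_donor <- a$element == "C"
  is_pos <- flag(CHARGE_POSITIVE_ATOMS)
  is_neg <- flag(CHARGE_NEGATIVE_ATOMS)
  is_apolar <- flag(APOLAR_ATOMS) | (a$resname == "MET" & a$atom == "SD")

  count_pairs <- function(flag_a, flag_b, cutoff, angle_fun = NULL) {
    ia <- which(flag_a); ib <- which(flag_b)
    if (length(ia) == 0 || length(ib) == 0) return(0L)
    dm <- pairwise_dists(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    hits <- which(dm <= cutoff, arr.ind = TRUE)
    n <- 0L
    seen <- character(0)
    for (h in seq_len(nrow(hits))) {
      i <- ia[hits[h, 1]]; j <- ib[hits[h, 2]]
      if (i == j) next
      if (excluded_pair(a$chain[i], a$resno[i], a$chain[j], a$resno[j]))
        next
      id <- paste(min(i, j), max(i, j))
      if (id %in% seen) next       # unordered atom pair counted once
      if (!is.null(angle_fun) && !angle_fun(i, j)) next
      seen <- c(seen, id)
      n <- n + 1L
    }
    n
  }
  donor_angle_ok <- function(min_deg, max_deg) function(i, j) {
    # i indexes the donor side; accept if the antecedent-donor-acceptor
    # angle at either qualifying orientation lies in the band
    ok_dir <- function(d, acc) {
      ante <- donor_antecedent_coords(a, d)
      if (is.null(ante)) return(TRUE)
      th <- angle_deg(ante, as.numeric(a[d, c("x", "y", "z")]),
                      as.numeric(a[acc, c("x", "y", "z")]))
      th >= min_deg && th <= max_deg
    }
    ok_dir(i, j)
  }

  # polar / hydrogen bond: donor-acceptor pairs; the pair qualifies in
  # either orientation, so count unions of the two directional scans
  da_pair <- function(cutoff, angle_fun = NULL) {
    ia <- which(is_donor); ib <- which(is_acceptor)
    if (length(ia) == 0 || length(ib) == 0) return(0L)
    dm <- pairwise_dists(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    hits <- which(dm <= cutoff, arr.ind = TRUE)
    seen <- character(0); n <- 0L
    for (h in seq_len(nrow(hits))) {
      i <- ia[hits[h, 1]]; j <- ib[hits[h, 2]]
      if (i == j) next
      if (excluded_pair(a$chain[i], a$resno[i], a$chain[j], a$resno[j]))
        next
      id <- paste(min(i, j), max(i, j))
      if (id %in% seen) next
      if (!is.null(angle_fun) && !angle_fun(i, j)) next
      seen <- c(seen, id)
      n <- n + 1L
    }
    n
  }
  prof$polar <- da_pair(3.5)
  prof$hydrogen_bond <- da_pair(3.5, donor_angle_ok(90, 180))
  prof$weak_polar <- count_pairs(is_weak_donor, is_acceptor, 3.6)
  prof$weak_hb <- count_pairs(is_weak_donor, is_acceptor, 3.6,
                              donor_angle_ok(30, 150))
  prof$ionic <- count_pairs(is_pos, is_neg, 4.0)
  prof$hydrophobic <- count_pairs(is_apolar, is_apolar, 4.5)

  # aromatic: enumerate rings per residue, compare ring pairs
  res <- structure_residues(s)
  rings <- list()
  for (r in seq_len(nrow(res))) {
    defs <- AROMATIC_RINGS[[res$resname[r]]]
    if (is.null(defs)) next
    ra <- residue_atoms(s, res$key[r])
    for (d in defs) {
      sel <- ra[ra$atom %in% d, c("x", "y", "z"), drop = FALSE]
      if (nrow(sel) == length(d))
        rings[[length(rings) + 1]] <- list(
          key = res$key[r], chain = res$chain[r], resno = res$resno[r],
          xyz = as.matrix(sel))
    }
  }
  n_arom <- 0L
  if (length(rings) >= 2) {
    for (i in seq_len(length(rings) - 1)) for (j in (i + 1):length(rings)) {
      ri <- rings[[i]]; rj <- rings[[j]]
      if (ri$key == rj$key) next
      if (excluded_pair(ri$chain, ri$resno, rj$chain, rj$resno)) next
      dm <- pairwise_dists(ri$xyz, rj$xyz)
      cen <- sqrt(sum((colMeans(ri$xyz) - colMeans(rj$xyz))^2))
      if (min(dm) <= 4.5 || cen <= 6.0) n_arom <- n_arom + 1L
    }
  }
  prof$aromatic <- n_arom
  prof[] <- lapply(prof, as.integer)
  prof
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("<contact_profile>\n")
  print(unlist(x))
  invisible(x)
}

#' Per-type contact count differences
#'
#' @param wild,mutant `contact_profile`s computed with identical rules
#' @return named integer vector, `mutant - wild` for each of the seven
#'   contact types
#' @export
contact_delta <- function(wild, mutant) {
  stopifnot(inherits(wild, "contact_profile"),
            inherits(mutant, "contact_profile"))
  unlist(mutant[CONTACT_TYPES]) - unlist(wild[CONTACT_TYPES])
}
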