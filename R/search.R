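# The search engine: enumerate candidate residue pairs in the target,
# match their triads against database representatives (signature pre-filter
# then main-chain superposition), graft template side chains, flag steric
# clashes and label proposals.

#' Search parameters
#'
#' All printed defaults in one place: target pairs need alpha carbons
#' 3.35-16.40 A apart; matches need main-chain RMSD < 0.5 A; a grafted atom
#' within 2.0 A of the neighbourhood flags a clash; region searches keep
#' pairs with a member within 10 A of the query residue.
#'
#' @param ca_min,ca_max alpha-carbon distance window, Angstrom
#' @param rmsd_threshold superposition gate, Angstrom
#' @param clash_cutoff clash distance, Angstrom
#' @param region_center optional residue key restricting the search region
#' @param region_radius region radius, Angstrom
#' @param ssv_cutoff signature-filter distance; `Inf` disables the filter
#' @param min_seq_separation minimum sequence separation so the two triads
#'   never share residues
#' @return object of class `search_params`
#' @export
search_params <- function(ca_min = 3.35, ca_max = 16.40,
                          rmsd_threshold = 0.5, clash_cutoff = 2.0,
                          region_center = NULL, region_radius = 10,
                          ssv_cutoff = Inf, min_seq_separation = 3) {
  stopifnot(ca_min > 0, ca_min < ca_max, rmsd_threshold > 0,
            clash_cutoff > 0, region_radius > 0, min_seq_separation >= 1)
  structure(list(ca_min = ca_min, ca_max = ca_max,
                 rmsd_threshold = rmsd_threshold,
                 clash_cutoff = clash_cutoff,
                 region_center = region_center,
                 region_radius = region_radius, ssv_cutoff = ssv_cutoff,
                 min_seq_separation = min_seq_separation),
            class = "search_params")
}

#' Enumerate candidate target residue pairs
#'
#' Same-chain residue pairs whose alpha carbons lie within the distance
#' window, separated by at least `min_seq_separation` positions, with all
#' six triad residues present and carrying full backbones, and not already
#' interacting through their side chains (hydrogen bond, ionic or
#' disulfide).  With a region centre set, at least one member's alpha
#' carbon must lie within `region_radius` of the centre's.
#'
#' @param s cleaned `prot_structure`
#' @param p a `search_params`
#' @return list of records: `res_a`, `res_b` (keys, a before b), `ca_dist`,
#'   `triad` (a `triad_pair`)
#' @export
enumerate_target_pairs <- function(s, p = search_params()) {
  res <- structure_residues(s)
  ca <- merge(res, s$atoms[s$atoms$atom == "CA", ], sort = FALSE,
              by = c("chain", "resno", "insert", "resname"))
  ca <- ca[match(res$key, ca$key), , drop = FALSE]
  center_xyz <- NULL
  if (!is.null(p$region_center)) {
    ci <- match(p$region_center, ca$key)
    if (is.na(ci) || is.na(ca$x[ci]))
      stop("region centre residue not found: ", p$region_center)
    center_xyz <- as.numeric(ca[ci, c("x", "y", "z")])
  }
  inter <- detect_sidechain_interactions(s)
  interacting <- unique(paste(inter$res_a, inter$res_b))
  out <- list()
  n <- nrow(res)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (i == j || j > n) next
      if (res$chain[i] != res$chain[j]) next
      if (j - i < p$min_seq_separation) next
      if (is.na(ca$x[i]) || is.na(ca$x[j])) next
      d <- sqrt(sum((as.numeric(ca[i, c("x", "y", "z")]) -
                     as.numeric(ca[j, c("x", "y", "z")]))^2))
      if (d < p$ca_min || d > p$ca_max) next
      if (paste(res$key[i], res$key[j]) %in% interacting) next
      if (!is.null(center_xyz)) {
        di <- sqrt(sum((as.numeric(ca[i, c("x", "y", "z")]) - center_xyz)^2))
        dj <- sqrt(sum((as.numeric(ca[j, c("x", "y", "z")]) - center_xyz)^2))
        if (di > p$region_radius && dj > p$region_radius) next
      }
      t <- suppressMessages(make_triad_pair(s, res$key[i], res$key[j]))
      if (is.null(t)) next
      if (any(c(res$resname[i], res$resname[j]) == "PRO"))
        message("note: proline site in target pair ", res$key[i], "/",
                res$key[j], " (backbone phi is constrained)")
      out[[length(out) + 1]] <- list(res_a = res$key[i], res_b = res$key[j],
                                     ca_dist = d, triad = t)
    }
  }
  out
}

one_letter <- function(resname) {
  x <- AA_3TO1[resname]
  ifelse(is.na(x), "X", x)
}

site_label <- function(key) sub("^[^:]*:", "", key)

#' Category labels of a proposal
#'
#' Fixed property table over the proposed identities: positive (ARG, LYS,
#' HIS), negative (ASP, GLU), aromatic (TRP, TYR, HIS), hydrophobic (ALA,
#' VAL, LEU, ILE, MET, PHE), and disulfide when both proposed residues are
#' CYS.
#'
#' @param proposed_a,proposed_b three-letter codes of the proposed pair
#' @return character vector of labels (possibly empty)
#' @export
label_proposal <- function(proposed_a, proposed_b) {
  pair <- c(proposed_a, proposed_b)
  labels <- character(0)
  if (any(pair %in% CATEGORY_POSITIVE)) labels <- c(labels, "positive")
  if (any(pair %in% CATEGORY_NEGATIVE)) labels <- c(labels, "negative")
  if (any(pair %in% CATEGORY_AROMATIC)) labels <- c(labels, "aromatic")
  if (any(pair %in% CATEGORY_HYDROPHOBIC))
    labels <- c(labels, "hydrophobic")
  if (all(pair == "CYS")) labels <- c(labels, "disulfide")
  labels
}

empty_proposals <- function() {
  data.frame(notation = character(0), site_a = character(0),
             wild_a = character(0), proposed_a = character(0),
             site_b = character(0), wild_b = character(0),
             proposed_b = character(0), template = character(0),
             template_id = character(0), template_pair = character(0),
             rmsd = numeric(0), pairing = character(0),
             clash = logical(0), clash_pairs = character(0),
             categories = character(0), ddg = numeric(0),
             target_id = character(0), stringsAsFactors = FALSE)
}

#' Propose double mutations for a target structure
#'
#' For every enumerated target pair: the signature pre-filter prunes the
#' representative set (when `ssv_cutoff` is finite and the database carries
#' an SVD model), surviving representatives are aligned by main-chain
#' superposition (both pairings), and every match with RMSD at most the
#' threshold yields one proposal carrying the template provenance, the
#' grafted-clash flag and category labels.  Output is sorted by RMSD, then
#' notation.
#'
#' @param s cleaned `prot_structure` (the target)
#' @param db a `triad_db`
#' @param p a `search_params`
#' @return data.frame of proposals (zero rows allowed); columns include
#'   notation (e.g. "S44K/K48N"), sites, wild and proposed identities,
#'   template, rmsd, pairing, clash, categories
#' @export
propose_mutations <- function(s, db, p = search_params()) {
  targets <- enumerate_target_pairs(s, p)
  props <- empty_proposals()
  if (length(targets) == 0 || nrow(db$index) == 0) {
    attr(props, "counts") <- c(pairs_enumerated = length(targets),
                               alignments = 0L, proposals = 0L)
    return(props)
  }
  use_filter <- is.finite(p$ssv_cutoff) && !is.null(db$svd)
  n_align <- 0L
  for (tg in targets) {
    cand_ids <- db$index$id
    if (use_filter) {
      red <- reduce_signature(compute_signature(tg$triad, db$sig_params),
                              db$svd)
      cand_ids <- filter_candidates(red, db, p$ssv_cutoff)
    }
    for (id in cand_ids) {
      i <- match(id, db$index$id)
      tpl <- db$triads[[i]]
      fit <- triad_rmsd(tg$triad, tpl)
      n_align <- n_align + 1L
      if (fit$rmsd > p$rmsd_threshold) next
      # map proposed identities onto target sites per winning pairing
      if (fit$pairing == "direct") {
        prop_a <- tpl$pair_names[1]; prop_b <- tpl$pair_names[2]
      } else {
        prop_a <- tpl$pair_names[2]; prop_b <- tpl$pair_names[1]
      }
      wild_a <- tg$triad$pair_names[1]; wild_b <- tg$triad$pair_names[2]
      notation <- paste0(
        one_letter(wild_a), site_label(tg$res_a), one_letter(prop_a), "/",
        one_letter(wild_b), site_label(tg$res_b), one_letter(prop_b))
      row <- data.frame(
        notation = notation, site_a = tg$res_a, wild_a = wild_a,
        proposed_a = prop_a, site_b = tg$res_b, wild_b = wild_b,
        proposed_b = prop_b, template = db$index$source_id[i],
        template_id = id,
        template_pair = paste0(one_letter(tpl$pair_names[1]),
                               site_label(tpl$pair[1]), "-",
                               one_letter(tpl$pair_names[2]),
                               site_label(tpl$pair[2])),
        rmsd = fit$rmsd, pairing = fit$pairing, clash = NA,
        clash_pairs = "",
        categories = paste(label_proposal(prop_a, prop_b),
                           collapse = ","),
        ddg = NA_real_,   # pass-through column for an external predictor
        target_id = s$id, stringsAsFactors = FALSE)
      props <- rbind(props, row)
    }
  }
  if (nrow(props) > 0) {
    props <- props[order(props$rmsd, props$notation), , drop = FALSE]
    rownames(props) <- NULL
    for (r in seq_len(nrow(props))) {
      mut <- graft_sidechains(s, props[r, ], db)
      rep <- detect_clash(mut, props[r, ], cutoff = p$clash_cutoff)
      props$clash[r] <- rep$clash
      props$clash_pairs[r] <- paste(rep$pairs, collapse = ";")
    }
  }
  attr(props, "counts") <- c(pairs_enumerated = length(targets),
                             alignments = n_align,
                             proposals = nrow(props))
  props
}

#' Graft template side chains onto the target
#'
#' Builds the mutant structure for one proposal: the target backbone (N,
#' CA, C, O) of both sites is kept, side-chain atoms (beyond CA) are
#' replaced by the template residues' side chains carried through the
#' template-to-target superposition transform, and the residue names are
#' updated.  All other residues are untouched.
#'
#' @param s the target `prot_structure` the proposal was produced from
#' @param prop one proposal row from [propose_mutations()]
#' @param db the `triad_db` holding the template fragment
#' @return mutant `prot_structure`
#' @export
graft_sidechains <- function(s, prop, db) {
  prop <- as.list(prop)
  if (!identical(prop$target_id, s$id))
    stop("proposal provenance mismatch: proposal for '", prop$target_id,
         "', structure is '", s$id, "'")
  i <- match(prop$template_id, db$index$id)
  if (is.na(i))
    stop("template fragment ", prop$template_id, " not found in database")
  tpl <- db$triads[[i]]
  target_triad <- make_triad_pair(s, prop$site_a, prop$site_b)
  if (is.null(target_triad)) stop("target triad cannot be rebuilt")
  mb <- triad_backbone(tpl)
  if (prop$pairing == "swapped") mb <- mb[c(13:24, 1:12), , drop = FALSE]
  fit <- kabsch_superpose(mb, triad_backbone(target_triad))
  # template side chains mapped onto (site_a, site_b) per pairing
  if (prop$pairing == "direct") {
    sc <- list(a = tpl$sidechain_n, b = tpl$sidechain_np)
  } else {
    sc <- list(a = tpl$sidechain_np, b = tpl$sidechain_n)
  }
  newname <- c(a = prop$proposed_a, b = prop$proposed_b)
  sites <- c(a = prop$site_a, b = prop$site_b)
  a <- s$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  for (side in c("a", "b")) {
    sel <- key == sites[[side]]
    keep <- sel & (a$atom %in% BACKBONE_ATOMS)
    drop <- sel & !keep
    anchor <- which(sel)[1]
    chain <- a$chain[anchor]; resno <- a$resno[anchor]
    insert <- a$insert[anchor]
    a <- a[!drop, , drop = FALSE]
    a$resname[residue_key(a$chain, a$resno, a$insert) == sites[[side]]] <-
      newname[[side]]
    m <- sc[[side]]
    if (nrow(m) > 0) {
      xyz <- apply_transform(m, fit$transform)
      add <- data.frame(chain = chain, resno = resno, insert = insert,
                        resname = newname[[side]], atom = rownames(m),
                        element = element_from_name(rownames(m)),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
                        stringsAsFactors = FALSE)
      # insert after the residue's backbone rows to keep residue grouping
      pos <- max(which(residue_key(a$chain, a$resno, a$insert) ==
                         sites[[side]]))
      a <- rbind(a[seq_len(pos), , drop = FALSE], add,
                 if (pos < nrow(a)) a[(pos + 1):nrow(a), , drop = FALSE])
    }
    key <- residue_key(a$chain, a$resno, a$insert)
  }
  mut <- structure_from_atoms(a, id = paste0(s$id, "|", prop$notation))
  attr(mut, "mutated_sites") <- unname(sites)
  mut
}

#' Steric-clash screen for a grafted mutant
#'
#' A clash is flagged when any newly inserted side-chain atom (beyond CA,
#' at either mutated site) lies closer than `cutoff` to any atom outside
#' the two mutated residues; the two mutated residues themselves are
#' excluded so covalent geometry never counts.
#'
#' @param mutant structure produced by [graft_sidechains()]
#' @param prop the proposal row that produced it
#' @param cutoff clash distance, Angstrom (default 2.0)
#' @return list with `clash` (logical) and `pairs` (character vector of
#'   offending "atom--atom (d A)" descriptions)
#' @export
detect_clash <- function(mutant, prop, cutoff = 2.0) {
  prop <- as.list(prop)
  a <- mutant$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  sites <- c(prop$site_a, prop$site_b)
  inserted <- key %in% sites & !a$atom %in% BACKBONE_ATOMS
  neighbourhood <- !key %in% sites
  pairs <- character(0)
  if (any(inserted) && any(neighbourhood)) {
    dm <- pairwise_dists(
      as.matrix(a[inserted, c("x", "y", "z")]),
      as.matrix(a[neighbourhood, c("x", "y", "z")]))
    hits <- which(dm < cutoff, arr.ind = TRUE)
    ii <- which(inserted); jj <- which(neighbourhood)
    for (h in seq_len(nrow(hits))) {
      i <- ii[hits[h, 1]]; j <- jj[hits[h, 2]]
      pairs <- c(pairs, sprintf("%s/%s--%s/%s (%.2f A)", key[i], a$atom[i],
                                key[j], a$atom[j],
                                dm[hits[h, 1], hits[h, 2]]))
    }
  }
  list(clash = length(pairs) > 0, pairs = pairs)
}

#' Summarize proposals by mutation site pair
#'
#' Collapses multiple templates proposing the same substitution pair at
#' the same sites, keeping the best (lowest) RMSD and the template count.
#'
#' @param props proposal table from [propose_mutations()]
#' @return data.frame with one row per (sites, proposed identities)
#' @export
summarize_proposals <- function(props) {
  if (nrow(props) == 0)
    return(data.frame(notation = character(0), n_templates = integer(0),
                      best_rmsd = numeric(0), any_clash_free = logical(0),
                      stringsAsFactors = FALSE))
  sp <- split(seq_len(nrow(props)), props$notation)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(notation = props$notation[idx[1]],
               n_templates = length(idx),
               best_rmsd = min(props$rmsd[idx]),
               any_clash_free = any(!props$clash[idx]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$best_rmsd, out$notation), , drop = FALSE]
  rownames(out) <- NULL
  out
}
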