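# Cutoff-scanning structural fingerprints of triad pairs, SVD reduction and
# the Euclidean pre-filter that prunes expensive superpositions.
#
# A signature counts atom pairs per unordered pharmacophore-class pair and
# per cumulative distance bin: entry (p,q,c) = number of atom pairs with one
# atom of class p, one of class q, at distance <= c.  Entries are therefore
# non-decreasing across bins within one class pair, and rigid motions leave
# the signature unchanged.

#' Signature parameters
#'
#' @param d_min minimum cutoff distance, Angstrom (default 0)
#' @param d_max maximum cutoff distance, Angstrom (default 10)
#' @param step cutoff distance step, Angstrom (default 0.1)
#' @return object of class `signature_params`
#' @export
signature_params <- function(d_min = 0, d_max = 10, step = 0.1) {
  if (!(d_min < d_max) || step <= 0)
    stop("invalid signature parameters: need d_min < d_max and step > 0")
  structure(list(d_min = d_min, d_max = d_max, step = step),
            class = "signature_params")
}

signature_bins <- function(params) {
  seq(params$d_min + params$step, params$d_max, by = params$step)
}

signature_class_pairs <- function() {
  k <- length(PHARMACOPHORE_CLASSES)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(a = PHARMACOPHORE_CLASSES[idx[, 1]],
             b = PHARMACOPHORE_CLASSES[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Length of a signature vector under given parameters
#' @param params a `signature_params`
#' @return integer feature count (#class pairs x #bins)
#' @export
signature_length <- function(params) {
  nrow(signature_class_pairs()) * length(signature_bins(params))
}

#' Compute the cutoff-scanning signature of a triad pair
#'
#' All atoms of the triad (the 24 main-chain atoms plus the side chains of
#' n and n') are typed by the fixed pharmacophore table (8 classes,
#' multi-class membership allowed); for every atom pair at distance d and
#' every cumulative cutoff c >= d, each unordered class pair formed by the
#' two atoms' classes is incremented once.
#'
#' @param t a `triad_pair`
#' @param params a `signature_params`
#' @return object of class `signature_vector` with fields `values`
#'   (named numeric vector) and `params`
#' @export
compute_signature <- function(t, params = signature_params()) {
  stopifnot(inherits(params, "signature_params"))
  atoms <- triad_atoms(t)
  cp <- signature_class_pairs()
  bins <- signature_bins(params)
  nb <- length(bins)
  pair_id <- function(a, b) {
    lo <- pmin(match(a, PHARMACOPHORE_CLASSES),
               match(b, PHARMACOPHORE_CLASSES))
    hi <- pmax(match(a, PHARMACOPHORE_CLASSES),
               match(b, PHARMACOPHORE_CLASSES))
    match(paste(lo, hi), paste(match(cp$a, PHARMACOPHORE_CLASSES),
                               match(cp$b, PHARMACOPHORE_CLASSES)))
  }
  counts <- matrix(0, nrow = nrow(cp), ncol = nb)
  n <- nrow(atoms)
  if (n >= 2) {
    classes <- lapply(seq_len(n), function(i)
      atom_pharmacophore(atoms$resname[i], atoms$atom[i]))
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    # bin edges get a small tolerance so a distance lying exactly on an
    # edge is binned identically after any rigid motion of the triad
    edge_tol <- 1e-9
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > params$d_max + edge_tol || d < params$d_min) next
      bin <- which(bins >= d - edge_tol)[1]
      if (is.na(bin)) next
      combos <- unique(pair_id(
        rep(classes[[i]], each = length(classes[[j]])),
        rep(classes[[j]], times = length(classes[[i]]))))
      counts[combos, bin] <- counts[combos, bin] + 1
    }
    counts <- t(apply(counts, 1, cumsum))   # cumulative over bins
  }
  values <- as.numeric(t(counts))  # feature order: class pair, then bins
  names(values) <- paste(rep(paste(cp$a, cp$b, sep = "|"), each = nb),
                         rep(format(bins, trim = TRUE), nrow(cp)),
                         sep = "@")
  structure(list(values = values, params = params),
            class = "signature_vector")
}

#' Fit an SVD reduction model over a signature matrix
#'
#' Exact factorization A = U S V^T; the retained dimensionality k is the
#' smallest number of leading singular values reaching `energy_fraction`
#' of the spectrum sum (mode "singular", the default) or of the sum of
#' squared singular values (mode "variance").
#'
#' @param m numeric matrix, one signature per row
#' @param energy_fraction target fraction in (0, 1]
#' @param mode "singular" or "variance"
#' @return object of class `svd_model` with `basis` (features x k,
#'   orthonormal columns), `singular_values`, `k`, `energy_fraction`,
#'   `mode`
#' @export
fit_svd <- function(m, energy_fraction = 0.7, mode = c("singular",
                                                       "variance")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (nrow(m) < 1) stop("need at least one signature row")
  if (!(energy_fraction > 0 && energy_fraction <= 1))
    stop("energy_fraction must be in (0, 1]")
  dec <- svd(m)
  d <- dec$d
  if (all(d < 1e-12))
    stop("degenerate spectrum: all singular values are zero")
  w <- if (mode == "singular") d else d^2
  k <- which(cumsum(w) / sum(w) >= energy_fraction - 1e-12)[1]
  k <- max(1L, k)
  structure(list(basis = dec$v[, seq_len(k), drop = FALSE],
                 singular_values = d, k = k,
                 energy_fraction = energy_fraction, mode = mode),
            class = "svd_model")
}

#' Project a signature onto the retained singular directions
#'
#' @param v a `signature_vector` or numeric vector
#' @param model an `svd_model`
#' @return numeric k-vector
#' @export
reduce_signature <- function(v, model) {
  x <- if (inherits(v, "signature_vector")) v$values else as.numeric(v)
  if (length(x) != nrow(model$basis))
    stop("signature length ", length(x), " does not match model feature ",
         "count ", nrow(model$basis))
  as.numeric(x %*% model$basis)
}

#' Signature pre-filter over database representatives
#'
#' Retains the representatives whose reduced-signature Euclidean distance
#' to the target's reduced signature is at most `cutoff`.  This is a
#' pre-filter only; matches are always confirmed by main-chain
#' superposition.
#'
#' @param target_reduced reduced k-vector of the target triad
#' @param db a `triad_db` with reduced signatures
#' @param cutoff distance cutoff; `Inf` disables the filter
#' @return character vector of retained representative ids
#' @export
filter_candidates <- function(target_reduced, db, cutoff = Inf) {
  if (is.null(db$reduced) || nrow(db$index) == 0)
    return(db$index$id)
  if (length(target_reduced) != ncol(db$reduced))
    stop("reduced-signature dimension mismatch: target ",
         length(target_reduced), ", database ", ncol(db$reduced))
  d <- sqrt(rowSums(sweep(db$reduced, 2, target_reduced)^2))
  db$index$id[d <= cutoff]
}

#' Smallest lossless signature-filter cutoff on a database
#'
#' For a set of target triads, finds the largest reduced-signature distance
#' between any target and any representative it matches under the RMSD
#' gate; filtering at (or above) this cutoff provably loses no match for
#' these targets.
#'
#' @param targets list of `triad_pair`
#' @param db a `triad_db` with fitted SVD model
#' @param rmsd_threshold superposition gate, Angstrom (default 0.5)
#' @return numeric scalar (0 when no target matches anything)
#' @export
calibrate_ssv_cutoff <- function(targets, db, rmsd_threshold = 0.5) {
  if (is.null(db$svd)) stop("database carries no SVD model")
  worst <- 0
  for (t in targets) {
    red <- reduce_signature(compute_signature(t, db$sig_params), db$svd)
    for (i in seq_along(db$triads)) {
      if (triad_rmsd(t, db$triads[[i]])$rmsd <= rmsd_threshold) {
        d <- sqrt(sum((red - db$reduced[i, ])^2))
        worst <- max(worst, d)
      }
    }
  }
  worst
}

save_svd_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(singular_value = model$singular_values),
    file.path(dir, "spectrum.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(model$basis, file.path(dir, "basis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(k = model$k,
                        energy_fraction = model$energy_fraction,
                        mode = model$mode),
                   file.path(dir, "model.yaml"))
}

load_svd_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  d <- utils::read.table(file.path(dir, "spectrum.tsv"), sep = "\t",
                         header = TRUE)$singular_value
  basis <- as.matrix(utils::read.table(file.path(dir, "basis.tsv"),
                                       sep = "\t", header = FALSE))
  colnames(basis) <- NULL
  structure(list(basis = basis, singular_values = d, k = meta$k,
                 energy_fraction = meta$energy_fraction, mode = meta$mode),
            class = "svd_model")
}
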