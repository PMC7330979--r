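# Rigid-body least-squares superposition (Kabsch) and the triad-pair RMSD
# used to gate every mutation proposal.  RMSD = sqrt(mean(delta_i^2)) over
# the corresponded atoms after the optimal rigid transform.

#' Rigid transform constructor
#'
#' @param rotation 3x3 proper rotation matrix (det +1)
#' @param translation length-3 numeric
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation, translation) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' Maps each row x to `R x + t`.
#'
#' @param x n x 3 coordinate matrix
#' @param tr a `rigid_transform`
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(x, tr) {
  sweep(x %*% t(tr$R), 2, tr$t, "+")
}

#' Compose the inverse of a rigid transform
#' @param tr a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), -as.numeric(t(tr$R) %*% tr$t))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `moving` (transformed) and `fixed`, with the atom correspondence given
#' by row order.  The reflection branch is sign-corrected so the returned
#' rotation always has determinant +1 (mirror images are chemically
#' invalid).
#'
#' @param moving n x 3 matrix (n >= 3, non-collinear)
#' @param fixed n x 3 matrix, same n
#' @return list with `transform` (a `rigid_transform`) and `rmsd` (Angstrom)
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(moving)
  if (n < 3) stop("superposition needs at least 3 corresponded atoms")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  mc <- sweep(moving, 2, cm); fc <- sweep(fixed, 2, cf)
  # collinearity check: centered points must span a plane
  if (any(!is.finite(mc)) || any(!is.finite(fc)))
    stop("non-finite coordinates")
  for (m in list(mc, fc)) {
    sv <- svd(m, nu = 0, nv = 0)$d
    if (sv[2] <= max(sv[1], 1) * 1e-12)
      stop("degenerate (collinear) point set: superposition ill-conditioned")
  }
  h <- t(mc) %*% fc
  dec <- svd(h)
  d <- sign(det(dec$v %*% t(dec$u)))
  if (d == 0) d <- 1
  rot <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tra <- cf - as.numeric(rot %*% cm)
  tr <- rigid_transform(rot, tra)
  dev <- apply_transform(moving, tr) - fixed
  list(transform = tr, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Main-chain RMSD between two triad pairs
#'
#' Superposes the 24 main-chain atoms (residues n-1, n, n+1, n'-1, n', n'+1;
#' atoms N, CA, C, O in fixed order).  Because the residue pair is
#' unordered, both pairings of the target pair onto the template pair --
#' direct and swapped -- are evaluated and the minimum-RMSD pairing is
#' returned.
#'
#' @param target a `triad_pair` (see [extract_triad_pairs()])
#' @param template a `triad_pair`
#' @return list with `rmsd`, `transform` (template -> target frame) and
#'   `pairing` ("direct" or "swapped")
#' @export
triad_rmsd <- function(target, template) {
  tb <- triad_backbone(target)
  mb <- triad_backbone(template)
  fits <- list(
    direct = kabsch_superpose(mb, tb),
    swapped = kabsch_superpose(mb[c(13:24, 1:12), , drop = FALSE], tb))
  best <- if (fits$direct$rmsd <= fits$swapped$rmsd) "direct" else "swapped"
  list(rmsd = fits[[best]]$rmsd, transform = fits[[best]]$transform,
       pairing = best)
}

#' Worked-example helper: triad RMSD between residue pairs of two files
#'
#' Reads two PDB files, builds the triad pair around each requested residue
#' pair, and reports the minimum main-chain RMSD over both pairings.  This
#' reproduces published cross-structure alignments when the corresponding
#' coordinate files are available locally.
#'
#' @param path_a,path_b PDB file paths
#' @param pair_a,pair_b length-2 integer residue numbers of the interacting
#'   pair in each structure
#' @param chain_a,chain_b chain identifiers (default "A")
#' @return list with `rmsd` and `pairing`
#' @export
triad_rmsd_between <- function(path_a, pair_a, path_b, pair_b,
                               chain_a = "A", chain_b = "A") {
  sa <- read_structure(path_a, chain = chain_a)
  sb <- read_structure(path_b, chain = chain_b)
  ta <- make_triad_pair(sa, residue_key(chain_a, pair_a[1], ""),
                        residue_key(chain_a, pair_a[2], ""))
  tb <- make_triad_pair(sb, residue_key(chain_b, pair_b[1], ""),
                        residue_key(chain_b, pair_b[2], ""))
  fit <- triad_rmsd(ta, tb)
  list(rmsd = fit$rmsd, pairing = fit$pairing)
}
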