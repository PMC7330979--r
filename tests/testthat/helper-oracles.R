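# Independent oracles and shared fixture builders.  Each oracle follows a
# different algorithmic route than the implementation it checks.

# Quaternion (Horn) superposition: optimal RMSD from the largest
# eigenvalue of the 4x4 quaternion matrix -- no rotation matrix is ever
# formed, so this is independent of the SVD-based Kabsch path.
horn_rmsd <- function(moving, fixed) {
  n <- nrow(moving)
  mc <- sweep(moving, 2, colMeans(moving))
  fc <- sweep(fixed, 2, colMeans(fixed))
  s <- t(mc) %*% fc
  q <- matrix(0, 4, 4)
  q[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  q[1, 2] <- q[2, 1] <- s[2, 3] - s[3, 2]
  q[1, 3] <- q[3, 1] <- s[3, 1] - s[1, 3]
  q[1, 4] <- q[4, 1] <- s[1, 2] - s[2, 1]
  q[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  q[2, 3] <- q[3, 2] <- s[1, 2] + s[2, 1]
  q[2, 4] <- q[4, 2] <- s[3, 1] + s[1, 3]
  q[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  q[3, 4] <- q[4, 3] <- s[2, 3] + s[3, 2]
  q[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lambda <- max(eigen(q, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(mc^2) + sum(fc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# Brute-force single-linkage threshold clustering: connected components of
# the graph with edges d <= cutoff, found by breadth-first search.
brute_single_linkage <- function(d, cutoff) {
  n <- nrow(d)
  memb <- rep(NA_integer_, n)
  cl <- 0L
  for (start in seq_len(n)) {
    if (!is.na(memb[start])) next
    cl <- cl + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(memb[v])) next
      memb[v] <- cl
      nb <- which(d[v, ] <= cutoff & is.na(memb))
      queue <- c(queue, nb)
    }
  }
  memb
}

# Brute-force all-pairs interaction scan implementing the atom lists and
# cutoffs directly with nested loops (no vectorised distance matrix).
brute_interactions <- function(s) {
  a <- s$atoms
  a$key <- paste0(a$chain, ":", a$resno, ifelse(a$insert == "", "",
                                                a$insert))
  a <- a[!a$atom %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
  hb <- list(ARG = c("NE", "NH1", "NH2"), ASN = c("ND2", "OD1"),
             ASP = c("OD1", "OD2"), GLN = c("NE2", "OE1"), LYS = "NZ",
             GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG",
             THR = "OG1", TRP = "NE1", TYR = "OH")
  pos <- list(ARG = "CZ", HIS = c("CD2", "CE1", "CG"))
  neg <- list(ASP = c("CG", "OD1", "OD2"), GLU = "CD")
  out <- list()
  n <- nrow(a)
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (a$key[i] == a$key[j]) next
    if (a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) <= 1) next
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                   c(a$x[j], a$y[j], a$z[j]))^2))
    rec <- function(kind) {
      ord <- order(a$chain[c(i, j)], a$resno[c(i, j)], a$insert[c(i, j)])
      ii <- c(i, j)[ord]
      data.frame(kind = kind, res_a = a$key[ii[1]], res_b = a$key[ii[2]],
                 atom_a = a$atom[ii[1]], atom_b = a$atom[ii[2]],
                 distance = d, stringsAsFactors = FALSE)
    }
    if (d < 3.50 && a$atom[i] %in% hb[[a$resname[i]]] &&
        a$atom[j] %in% hb[[a$resname[j]]])
      out[[length(out) + 1]] <- rec("hydrogen_bond")
    ion_ij <- a$atom[i] %in% pos[[a$resname[i]]] &&
      a$atom[j] %in% neg[[a$resname[j]]]
    ion_ji <- a$atom[j] %in% pos[[a$resname[j]]] &&
      a$atom[i] %in% neg[[a$resname[i]]]
    if (d < 6.00 && (ion_ij || ion_ji))
      out[[length(out) + 1]] <- rec("ionic")
    if (d < 2.08 && a$resname[i] == "CYS" && a$resname[j] == "CYS" &&
        a$atom[i] == "SG" && a$atom[j] == "SG")
      out[[length(out) + 1]] <- rec("disulfide")
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$res_a, res$res_b, res$kind, res$atom_a, res$atom_b), ]
}

# ---- shared fixture builders ----

# minimal residue: backbone placed locally around an anchor, plus named
# side-chain atoms at explicit coordinates
res_atoms <- function(resno, resname, anchor, side = list(),
                      chain = "A", insert = "") {
  bb <- rbind(N = anchor + c(-0.7, 0.6, 0), CA = anchor,
              C = anchor + c(0.8, 0.5, 0.3), O = anchor + c(0.9, 1.6, 0.4))
  at <- rbind(bb, do.call(rbind, side))
  data.frame(chain = chain, resno = resno, insert = insert,
             resname = resname, atom = rownames(at),
             element = substr(gsub("[0-9]", "", rownames(at)), 1, 1),
             x = at[, 1], y = at[, 2], z = at[, 3], occ = 1,
             stringsAsFactors = FALSE)
}

two_residue_structure <- function(resname_a, side_a, resname_b, side_b,
                                  resno = c(1, 5), id = "pairfix") {
  structure_from_atoms(rbind(
    res_atoms(resno[1], resname_a, c(0, 0, 0), side_a),
    res_atoms(resno[2], resname_b, c(20, 0, 0), side_b)), id = id)
}

# one feasible planted-interaction fixture per seed: tries a short list of
# geometries and returns the first that the generator accepts
planted_case <- function(seed, n_residues = 18, jitter = 4) {
  options_list <- list(
    list(i = 5, j = 9, kind = "disulfide", distance = 2.0),
    list(i = 4, j = 8, kind = "disulfide", distance = 2.0),
    list(i = 5, j = 9, kind = "hydrogen_bond", distance = 3.0),
    list(i = 6, j = 10, kind = "hydrogen_bond", distance = 3.2),
    list(i = 5, j = 10, kind = "ionic", distance = 4.5))
  for (pl in options_list) {
    s <- tryCatch(
      make_fixture(fixture_spec(n_residues = n_residues,
                                planted_interactions = list(pl),
                                seed = seed,
                                torsion_jitter_deg = jitter),
                   id = paste0("tmpl", seed)),
      error = function(e) NULL)
    if (!is.null(s)) return(list(structure = s, plant = pl))
  }
  stop("no feasible plant for seed ", seed)
}

random_points <- function(n, seed, spread = 10) {
  set.seed(seed)
  matrix(stats::runif(n * 3, -spread, spread), ncol = 3)
}
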