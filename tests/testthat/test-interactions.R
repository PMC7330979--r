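# Side-chain interaction detection (database side) and the seven-type
# contact classification.

test_that("each interaction kind is detected with its atom list and cutoff", {
  # disulfide: CYS SG-SG at 2.00 A
  s <- two_residue_structure("CYS", list(SG = c(2, 2, 0)),
                             "CYS", list(SG = c(4, 2, 0)))
  inter <- detect_sidechain_interactions(s)
  expect_equal(nrow(inter), 1)
  expect_equal(inter$kind, "disulfide")
  expect_equal(inter$distance, 2.0)

  # ARG NH1 vs ASP OD1 at 3.20 A: hydrogen bond, and ionic only through
  # the listed ionic atoms (NH1 is not in the ionic list)
  s <- two_residue_structure("ARG", list(NH1 = c(2, 2, 0)),
                             "ASP", list(OD1 = c(5.2, 2, 0)))
  inter <- detect_sidechain_interactions(s)
  expect_setequal(inter$kind, "hydrogen_bond")
  expect_equal(inter$atom_a, "NH1")

  # SER OG vs TYR OH at 4.00 A: beyond the hydrogen-bond cutoff, and
  # neither atom is in the ionic list -> nothing
  s <- two_residue_structure("SER", list(OG = c(2, 2, 0)),
                             "TYR", list(OH = c(6, 2, 0)))
  expect_equal(nrow(detect_sidechain_interactions(s)), 0)

  # ionic: ARG CZ vs GLU CD at 5.0 A
  s <- two_residue_structure("ARG", list(CZ = c(2, 2, 0)),
                             "GLU", list(CD = c(7, 2, 0)))
  inter <- detect_sidechain_interactions(s)
  expect_equal(inter$kind, "ionic")
})

test_that("interaction boundaries flip exactly at the printed cutoffs", {
  at <- function(resname_a, atom_a, resname_b, atom_b, d) {
    sa <- list(); sa[[atom_a]] <- c(2, 2, 0)
    sb <- list(); sb[[atom_b]] <- c(2 + d, 2, 0)
    detect_sidechain_interactions(
      two_residue_structure(resname_a, sa, resname_b, sb))
  }
  expect_equal(at("SER", "OG", "THR", "OG1", 3.49)$kind, "hydrogen_bond")
  expect_equal(nrow(at("SER", "OG", "THR", "OG1", 3.51)), 0)
  expect_equal(at("CYS", "SG", "CYS", "SG", 2.07)$kind, "disulfide")
  expect_equal(nrow(at("CYS", "SG", "CYS", "SG", 2.09)), 0)
  expect_equal(at("ARG", "CZ", "GLU", "CD", 5.99)$kind, "ionic")
  expect_equal(nrow(at("ARG", "CZ", "GLU", "CD", 6.01)), 0)
})

test_that("intra-residue and sequence-adjacent pairs are excluded", {
  a <- rbind(
    res_atoms(1, "CYS", c(0, 0, 0), list(SG = c(0, 2, 0))),
    res_atoms(2, "CYS", c(1, 0, 0), list(SG = c(1.5, 2, 0))))
  s <- structure_from_atoms(a, id = "adj")
  expect_equal(nrow(detect_sidechain_interactions(s)), 0)
})

test_that("vectorised detection matches the brute-force all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    resnames <- sample(c("ARG", "ASP", "GLU", "SER", "THR", "CYS", "LYS",
                         "TYR", "HIS", "ASN"), 8, replace = TRUE)
    side_tab <- list(
      ARG = c("NE", "NH1", "CZ"), ASP = c("CG", "OD1", "OD2"),
      GLU = c("CD", "OE1"), SER = "OG", THR = "OG1", CYS = "SG",
      LYS = "NZ", TYR = "OH", HIS = c("ND1", "NE2", "CG"),
      ASN = c("ND2", "OD1"))
    rows <- lapply(seq_along(resnames), function(i) {
      anchor <- runif(3, 0, 8)
      side <- lapply(side_tab[[resnames[i]]], function(nm)
        anchor + runif(3, -1.5, 1.5))
      names(side) <- side_tab[[resnames[i]]]
      res_atoms(i * 2, resnames[i], anchor, side)
    })
    s <- structure_from_atoms(do.call(rbind, rows), id = "rand")
    got <- detect_sidechain_interactions(s)
    want <- brute_interactions(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      cols <- c("kind", "res_a", "res_b", "atom_a", "atom_b")
      expect_equal(got[, cols], want[, cols], ignore_attr = TRUE)
      expect_equal(got$distance, want$distance, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("interactions are reported once per unordered pair, with res_a first", {
  s <- two_residue_structure("CYS", list(SG = c(2, 2, 0)),
                             "CYS", list(SG = c(4, 2, 0)))
  inter <- detect_sidechain_interactions(s)
  expect_equal(nrow(inter), 1)
  expect_lt(as.integer(sub("A:", "", inter$res_a)),
            as.integer(sub("A:", "", inter$res_b)))
})

test_that("shrinking a cutoff never increases detections (monotonicity proxy)", {
  # distances straddling the cutoffs: detections at the printed cutoff are
  # a superset of those the tighter geometry admits
  s_near <- two_residue_structure("SER", list(OG = c(2, 2, 0)),
                                  "THR", list(OG1 = c(4.5, 2, 0)))
  s_far <- two_residue_structure("SER", list(OG = c(2, 2, 0)),
                                 "THR", list(OG1 = c(5.4, 2, 0)))
  expect_gte(nrow(detect_sidechain_interactions(s_near)),
             nrow(detect_sidechain_interactions(s_far)))
})

test_that("contact classification follows the seven printed rules", {
  # two apolar side-chain carbons at 4.0 A -> hydrophobic
  s <- two_residue_structure("LEU", list(CG = c(2, 2, 0)),
                             "VAL", list(CG1 = c(6, 2, 0)))
  p <- classify_contacts(s)
  expect_equal(p$hydrophobic, 1L)
  expect_equal(p$ionic, 0L)

  # ARG NH1 vs GLU OE1 at 3.8 A -> ionic (and polar: donor-acceptor <= 3.5
  # fails at 3.8, so polar stays 0)
  s <- two_residue_structure("ARG", list(NH1 = c(2, 2, 0)),
                             "GLU", list(OE1 = c(5.8, 2, 0)))
  p <- classify_contacts(s)
  expect_equal(p$ionic, 1L)
  expect_equal(p$polar, 0L)

  # donor-acceptor at 3.4 A failing the 90-degree angle test: polar
  # counts, hydrogen_bond does not.  The donor antecedent (CB) is placed
  # so the antecedent-donor-acceptor angle is acute.
  a <- rbind(
    res_atoms(1, "SER", c(0, 0, 0),
              list(CB = c(1.5, 0, 0), OG = c(2.9, 0, 0))),
    res_atoms(5, "ASN", c(20, 10, 0),
              list(OD1 = c(2.9, 0, 0) + 3.4 * c(-0.5, -0.866, 0))))
  s <- structure_from_atoms(a, id = "angle")
  p <- classify_contacts(s)
  expect_equal(p$polar, 1L)
  expect_equal(p$hydrogen_bond, 0L)
})

test_that("aromatic ring contacts count by ring atoms or centroid distance", {
  ring <- function(center, r = 1.39) {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    m <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang),
               center[3])
    rownames(m) <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    lapply(seq_len(6), function(i) m[i, ]) |>
      stats::setNames(rownames(m))
  }
  a <- rbind(
    res_atoms(1, "PHE", c(0, -5, 0), ring(c(0, 0, 0))),
    res_atoms(5, "PHE", c(5, -5, 0), ring(c(5, 0, 0))))
  s <- structure_from_atoms(a, id = "rings")
  expect_equal(classify_contacts(s)$aromatic, 1L)   # centroids 5 A apart
  a2 <- rbind(
    res_atoms(1, "PHE", c(0, -5, 0), ring(c(0, 0, 0))),
    res_atoms(5, "PHE", c(12, -5, 0), ring(c(12, 0, 0))))
  expect_equal(classify_contacts(structure_from_atoms(a2, "far"))$aromatic,
               0L)
})

test_that("profile invariants hold on generated structures", {
  for (seed in 1:5) {
    cs <- planted_case(seed)
    p <- classify_contacts(cs$structure)
    expect_lte(p$hydrogen_bond, p$polar)
    expect_lte(p$weak_hb, p$weak_polar)
    expect_true(all(unlist(p) >= 0))
  }
})

test_that("contact deltas subtract per type", {
  s <- two_residue_structure("LEU", list(CG = c(2, 2, 0)),
                             "VAL", list(CG1 = c(6, 2, 0)))
  p <- classify_contacts(s)
  expect_true(all(contact_delta(p, p) == 0))
  q <- p; q$hydrogen_bond <- p$hydrogen_bond + 2L
  d <- contact_delta(p, q)
  expect_equal(unname(d["hydrogen_bond"]), 2L)
  q2 <- p; q2$hydrophobic <- p$hydrophobic - 1L
  expect_equal(unname(contact_delta(p, q2)["hydrophobic"]), -1L)
})
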