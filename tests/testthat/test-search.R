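# Search engine: target-pair enumeration, proposal generation, grafting,
# clash screening and category labels.

# hand-built chain with controllable CA-CA distance for the target pair
# (A:2, A:6): residues sit on a line, residue 6 is shifted so its CA lies
# exactly `d` from residue 2's CA
line_chain <- function(d, n = 9, id = "line") {
  rows <- lapply(seq_len(n), function(i) {
    anchor <- c(4 * i, 0.5, 0)
    if (i == 6) anchor <- c(8 + d, 0.5, 0)
    res_atoms(i, "ALA", anchor)
  })
  structure_from_atoms(do.call(rbind, rows), id = id)
}

pair_in <- function(targets, a, b) {
  any(vapply(targets, function(t) t$res_a == a && t$res_b == b,
             logical(1)))
}

test_that("pair enumeration respects the alpha-carbon distance window", {
  p <- search_params()
  expect_false(pair_in(enumerate_target_pairs(line_chain(3.34), p),
                       "A:2", "A:6"))
  expect_true(pair_in(enumerate_target_pairs(line_chain(3.36), p),
                      "A:2", "A:6"))
  expect_true(pair_in(enumerate_target_pairs(line_chain(16.39), p),
                      "A:2", "A:6"))
  expect_false(pair_in(enumerate_target_pairs(line_chain(16.41), p),
                       "A:2", "A:6"))
})

test_that("neighbouring and already-interacting pairs are excluded", {
  s <- make_fixture(fixture_spec(n_residues = 12), id = "sep")
  targets <- enumerate_target_pairs(s, search_params())
  seps <- vapply(targets, function(t) {
    abs(diff(as.integer(sub("A:", "", c(t$res_a, t$res_b)))))
  }, numeric(1))
  expect_true(all(seps >= 3))
  # plant an interaction: that pair disappears from the target list
  cs <- planted_case(1, jitter = 0)
  keyp <- paste0("A:", c(cs$plant$i, cs$plant$j))
  with_int <- enumerate_target_pairs(cs$structure, search_params())
  expect_false(pair_in(with_int, keyp[1], keyp[2]))
  stripped <- strip_to_alanine(cs$structure, keyp)
  without_int <- enumerate_target_pairs(stripped, search_params())
  expect_true(pair_in(without_int, keyp[1], keyp[2]))
})

test_that("region search keeps pairs with a member near the centre", {
  s <- make_fixture(fixture_spec(n_residues = 30), id = "reg")
  p_all <- search_params()
  p_reg <- search_params(region_center = "A:5", region_radius = 10)
  all_t <- enumerate_target_pairs(s, p_all)
  reg_t <- enumerate_target_pairs(s, p_reg)
  expect_lt(length(reg_t), length(all_t))
  ca <- s$atoms[s$atoms$atom == "CA", ]
  cen <- as.numeric(ca[ca$resno == 5, c("x", "y", "z")])
  for (t in reg_t) {
    keys <- as.integer(sub("A:", "", c(t$res_a, t$res_b)))
    dmin <- min(vapply(keys, function(k)
      sqrt(sum((as.numeric(ca[ca$resno == k, c("x", "y", "z")]) - cen)^2)),
      numeric(1)))
    expect_lte(dmin, 10)
  }
  expect_error(enumerate_target_pairs(s, search_params(
    region_center = "A:99")), "not found")
})

test_that("planted templates are recovered at numerically zero RMSD", {
  cs <- planted_case(5)
  db <- build_database(structures = list(cs$structure), cutoff = 0.5)
  keyp <- paste0("A:", c(cs$plant$i, cs$plant$j))
  tgt <- strip_to_alanine(cs$structure, keyp)
  tgt$id <- "target"
  tgt <- transform_structure(tgt, random_rigid_transform(11))
  props <- propose_mutations(tgt, db, search_params())
  expect_gt(nrow(props), 0)
  expect_true(all(props$rmsd <= 0.5))
  hit <- props[props$site_a == keyp[1] & props$site_b == keyp[2], ]
  expect_equal(nrow(hit), 1)
  expect_lte(hit$rmsd, 1e-6)
  tplnames <- db$triads[[1]]$pair_names
  expect_setequal(c(hit$proposed_a, hit$proposed_b), tplnames)
  # notation: wild+site+proposed joined by "/"
  expect_match(hit$notation, sprintf("^A%d[A-Z]/A%d[A-Z]$",
                                     cs$plant$i, cs$plant$j))
})

test_that("an empty database or an unreachable gate yields no proposals", {
  cs <- planted_case(1)
  tgt <- strip_to_alanine(cs$structure,
                          paste0("A:", c(cs$plant$i, cs$plant$j)))
  s_plain <- make_fixture(fixture_spec(n_residues = 8), id = "plain")
  db_empty <- suppressWarnings(build_database(structures = list(s_plain)))
  expect_equal(nrow(propose_mutations(tgt, db_empty, search_params())), 0)
  # helix templates cannot match a strand target under the 0.5 A gate
  db <- build_database(structures = list(cs$structure), cutoff = 0.5)
  strand <- make_fixture(fixture_spec(n_residues = 14,
                                      secondary_structure = "strand"),
                         id = "strandtgt")
  props <- propose_mutations(strand, db, search_params())
  expect_equal(nrow(props), 0)
})

test_that("grafting conserves the backbone and reproduces template side chains", {
  cs <- planted_case(6)
  db <- build_database(structures = list(cs$structure), cutoff = 0.5)
  keyp <- paste0("A:", c(cs$plant$i, cs$plant$j))
  tgt <- strip_to_alanine(cs$structure, keyp)
  tgt$id <- "target"
  tr <- random_rigid_transform(21)
  tgt <- transform_structure(tgt, tr)
  props <- propose_mutations(tgt, db, search_params())
  hit <- props[props$site_a == keyp[1] & props$site_b == keyp[2], ][1, ]
  mut <- graft_sidechains(tgt, hit, db)
  # backbone identical to the wild target everywhere
  wb <- tgt$atoms[tgt$atoms$atom %in% c("N", "CA", "C", "O"), ]
  mb <- mut$atoms[mut$atoms$atom %in% c("N", "CA", "C", "O"), ]
  expect_equal(wb[, c("resno", "atom", "x", "y", "z")],
               mb[, c("resno", "atom", "x", "y", "z")],
               ignore_attr = TRUE)
  # grafted side chains land on the (moved) template coordinates
  tpl_moved <- transform_structure(cs$structure, tr)
  for (k in keyp) {
    want <- residue_atoms(tpl_moved, k)
    got <- residue_atoms(mut, k)
    want <- want[!want$atom %in% c("N", "CA", "C", "O"), ]
    got <- got[!got$atom %in% c("N", "CA", "C", "O"), ]
    want <- want[order(want$atom), ]; got <- got[order(got$atom), ]
    expect_equal(got$atom, want$atom)
    expect_lt(max(abs(as.matrix(got[, c("x", "y", "z")]) -
                      as.matrix(want[, c("x", "y", "z")]))), 1e-6)
  }
  # non-mutated residues untouched
  other <- setdiff(structure_residues(tgt)$key, keyp)
  for (k in other[c(1, length(other))])
    expect_equal(residue_atoms(tgt, k)$x, residue_atoms(mut, k)$x)
  # provenance check: grafting onto a different structure errors
  other_s <- make_fixture(fixture_spec(n_residues = 18), id = "other")
  expect_error(graft_sidechains(other_s, hit, db), "provenance")
})

test_that("clash detection flips at the cutoff and excludes the mutated pair", {
  base <- rbind(
    res_atoms(2, "CYS", c(0, 0, 0), list(SG = c(0, 3, 0))),
    res_atoms(6, "CYS", c(6, 0, 0), list(SG = c(6, 3, 0))),
    res_atoms(10, "ALA", c(12, 0, 0)))
  prop <- list(site_a = "A:2", site_b = "A:6")
  place_neighbor <- function(d) {
    a <- base
    a$x[a$resno == 10 & a$atom == "CA"] <- 0 + d
    a$y[a$resno == 10 & a$atom == "CA"] <- 3
    a$z[a$resno == 10 & a$atom == "CA"] <- 0
    structure_from_atoms(a, id = "clashfix")
  }
  expect_true(detect_clash(place_neighbor(1.99), prop, 2.0)$clash)
  expect_false(detect_clash(place_neighbor(2.01), prop, 2.0)$clash)
  rep <- detect_clash(place_neighbor(1.5), prop, 2.0)
  expect_match(rep$pairs[1], "SG")
  # an inserted atom close to its own residue's CA is not a clash
  a_self <- base
  a_self$x[a_self$resno == 2 & a_self$atom == "SG"] <- 0
  a_self$y[a_self$resno == 2 & a_self$atom == "SG"] <- 1.0
  expect_false(detect_clash(structure_from_atoms(a_self, "selffix"),
                            prop, 2.0)$clash)
})

test_that("category labels follow the property table", {
  expect_setequal(label_proposal("ASP", "ARG"), c("negative", "positive"))
  expect_setequal(label_proposal("CYS", "CYS"), "disulfide")
  expect_equal(label_proposal("SER", "THR"), character(0))
  expect_setequal(label_proposal("HIS", "GLU"),
                  c("positive", "aromatic", "negative"))
})

test_that("proposals are deterministically sorted and summarizable", {
  cs <- planted_case(7)
  db <- build_database(structures = list(cs$structure), cutoff = 0.5)
  tgt <- strip_to_alanine(cs$structure,
                          paste0("A:", c(cs$plant$i, cs$plant$j)))
  tgt$id <- "target"
  props <- propose_mutations(tgt, db, search_params())
  expect_true(!is.unsorted(props$rmsd))
  again <- propose_mutations(tgt, db, search_params())
  expect_identical(props, again)
  sm <- summarize_proposals(props)
  expect_lte(nrow(sm), nrow(props))
  expect_true(all(sm$n_templates >= 1))
})
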