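# triadmut

Propose stabilizing **pairs of point mutations** for a protein structure,
justified by interactions observed in known structures.

Protein engineers often want to rigidify a fold by adding a new
side-chain–side-chain contact — a hydrogen bond, a salt bridge, or a
disulfide — without disturbing the backbone. `triadmut` automates the
search: if two residues in the target are close in space but not
interacting, and some known structure contains an *interacting* residue
pair whose local main-chain conformation matches the target's, then the
known pair can be transplanted onto the target sites as a double
substitution.

The unit of comparison is the **triad pair**: the two residues of interest
(*n*, *n′*) together with their sequence neighbours (*n−1*, *n+1*, *n′−1*,
*n′+1*). Two triad pairs are compared on the 24 main-chain atoms (N, Cα,
C, O of the six residues) by least-squares rigid superposition (Kabsch),
scored as

    RMSD = sqrt( (1/N) * Σᵢ δᵢ² ),   N = 24,

where δᵢ is the residual of atom *i* after the optimal rotation and
translation. A template justifies a proposal only when RMSD < 0.5 Å.

The pipeline:

1. **Database build** — side-chain interactions are detected in template
   structures by fixed atom lists and cutoffs (hydrogen bond < 3.50 Å,
   ionic < 6.00 Å, disulfide S–S < 2.08 Å); a triad pair is extracted
   around each one, clustered per residue-pair category by single linkage
   on main-chain RMSD, and each cluster's first member becomes the stored
   representative. Categories follow the 11 hydrogen-bond/ionic-capable
   residue types plus one disulfide class (11 × 11 + 1 = 122), regrouped
   into 12 first-residue databases.
2. **Search** — every same-chain residue pair with Cα–Cα distance in
   3.35–16.40 Å, not adjacent, not already interacting, is a candidate
   site pair. Its triad is compared against the representatives; an
   optional pre-filter prunes alignments by the Euclidean distance
   between SVD-reduced cutoff-scanning fingerprints of the triads.
3. **Graft & clash** — for every match, the template side chains are
   carried through the superposition transform onto the target backbone;
   any grafted atom closer than 2 Å to the neighbourhood flags a steric
   clash (flagged, not dropped).
4. **Evaluation** — wild and mutant structures are compared by seven
   inter-residue contact types (hydrogen bond, weak hydrogen bond, ionic,
   aromatic, polar, weak polar, hydrophobic), with per-type
   kept-or-increased accuracies and a paired one-tailed t-test.

A synthetic-structure generator (ideal helix/strand backbones with
planted interactions) makes the whole pipeline testable offline.

## Worked example

Build a one-template database from a synthetic helix carrying a planted
SER–THR hydrogen bond, strip that pair to alanine, move the target to an
arbitrary frame, and search:

```r
library(triadmut)

tpl <- make_fixture(fixture_spec(n_residues = 18,
         planted_interactions = list(list(i = 5, j = 9,
                                          kind = "hydrogen_bond",
                                          distance = 3.0)),
         seed = 11, torsion_jitter_deg = 4), id = "template1")
detect_sidechain_interactions(tpl)
#>            kind res_a res_b name_a name_b atom_a atom_b distance
#> 1 hydrogen_bond   A:5   A:9    SER    THR     OG    OG1        3

db <- build_database(structures = list(tpl), cutoff = 0.5)

tgt <- strip_to_alanine(tpl, c("A:5", "A:9"))
tgt$id <- "mytarget"
tgt <- transform_structure(tgt, random_rigid_transform(7))

props <- propose_mutations(tgt, db, search_params())
head(props[, c("notation", "template", "template_pair", "rmsd", "clash")])
#>   notation  template template_pair         rmsd clash
#> 1  A5S/A9T template1         S5-T9 2.639748e-15 FALSE
#> 2  A4S/A8T template1         S5-T9 2.369168e-01 FALSE
#> 3 A6S/A10T template1         S5-T9 2.411923e-01 FALSE
#> ...
```

The top proposal recovers the planted pair exactly: mutate the alanines
at sites 5 and 9 to the template's SER/THR (`A5S/A9T`), with main-chain
RMSD at machine precision and no clash. The other rows are the same
template matched to neighbouring helical windows — the backbone there is
similar but not identical, hence RMSD of 0.2–0.4 Å. Grafting the top
proposal and re-counting contacts shows the expected gain:

```r
mut <- graft_sidechains(tgt, props[1, ], db)
ev  <- evaluate_proposals(tgt, list(mut))
subset(ev$details, delta != 0)
#>             mutant          type wild_count mutant_count delta
#> 1 mytarget|A5S/A9T hydrogen_bond         39           41     2
#> 2 mytarget|A5S/A9T       weak_hb         22           25     3
#> 5 mytarget|A5S/A9T         polar         39           43     4
#> 6 mytarget|A5S/A9T    weak_polar         22           25     3
```

A command-line front end wrapping the same functions lives at
`inst/cli/triadmut.R` (`build-db`, `search`, `evaluate`, `fixtures`,
`pipeline` subcommands), and `run_pipeline()` drives the whole chain from
one YAML configuration.

For users with coordinate files at hand, `triad_rmsd_between()` reports
the cross-structure triad RMSD for any two residue pairs — e.g.
`triad_rmsd_between("protease.pdb", c(19, 35), "membrane.pdb", c(94, 190))`
measures how well one structure's site pair overlaps another's
interacting pair, the same comparison the search engine applies to every
database representative.

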