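---
title: "Methods: backbone-conserved mutation-pair proposals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backbone-conserved mutation-pair proposals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`triadmut` rests on one structural hypothesis: a pair of non-interacting
residues in a target protein may be substituted by a pair of *interacting*
residues taken from a known structure, provided the local main-chain
conformation around both sites is conserved. If the main chain is
conserved, the transplanted side chains can adopt the interacting
conformation already observed in nature, and the new contact (hydrogen
bond, salt bridge or disulfide) is expected to conserve or improve
stability.

"Local main chain" is operationalised as the **triad pair**: the two
residues of interest *n* and *n′* plus their covalent neighbours *n−1*,
*n+1*, *n′−1*, *n′+1*. Conservation is measured by the least-squares RMSD
over the 24 main-chain atoms (six residues × N, Cα, C, O) after optimal
rigid superposition. The atom correspondence is fixed — residues in the
order (*n−1*, *n*, *n+1*, *n′−1*, *n′*, *n′+1*), atoms in the order N,
CA, C, O — and, because an interaction is an unordered pair, both
pairings of the target pair onto the template pair are evaluated and the
minimum kept. Missing the swapped match would halve sensitivity for no
physical reason.

The superposition is the classic Kabsch solution via the SVD of the 3×3
cross-covariance matrix, with the reflection branch sign-corrected so the
rotation always has determinant +1 (a mirror-image match is chemically
meaningless). Degenerate inputs — fewer than three points, or collinear
point sets — raise an error rather than returning an ill-conditioned
answer.

## Database construction

Template structures are cleaned (first model only, one chain if
requested, HETATM/water records dropped, hydrogens dropped, alternate
locations resolved to the highest occupancy with ties broken by file
order, non-standard residues dropped with a warning). Side-chain
interactions are then detected by fixed atom lists and cutoffs:

| kind          | cutoff   | atoms                                         |
|---------------|----------|-----------------------------------------------|
| hydrogen bond | < 3.50 Å | ARG NE/NH1/NH2, ASN ND2/OD1, ASP OD1/OD2, GLN NE2/OE1, LYS NZ, GLU OE1/OE2, HIS ND1/NE2, SER OG, THR OG1, TRP NE1, TYR OH |
| ionic         | < 6.00 Å | positive: ARG CZ; HIS CD2/CE1/CG — negative: ASP CG/OD1/OD2; GLU CD |
| disulfide     | < 2.08 Å | CYS SG                                        |

These tables are implemented verbatim, including their surprises (LYS NZ
under hydrogen bonds but not ionic; HIS ring carbons under ionic):
"correcting" them would silently change database contents. An ionic
interaction additionally requires one atom from the positive and one from
the negative group — the only chemically coherent reading of opposing
charges. Intra-residue and sequence-adjacent pairs are excluded
everywhere, so covalent geometry never masquerades as a contact.

One triad pair is extracted per distinct (residue pair, kind); when
several atom pairs report the same interaction the closest is kept.
Extraction requires all six residues present with complete backbones;
failures are skipped with a logged reason.

Triads are stored in ordered categories (first residue × partner), where
"first" means the lower author residue number. Over the 11
hydrogen-bond/ionic-capable residue types this gives 11 × 11 = 121
categories, plus a single disulfide (CYS–CYS) class: 122 in total,
regrouped into 12 first-residue databases. Cysteine appears only through
disulfides, because its side chain is absent from the hydrogen-bond and
ionic atom lists.

Within each category, redundancy is removed by **single-linkage
clustering** under the main-chain triad RMSD (clusters are the connected
components of the graph with edges RMSD ≤ cutoff). The default cutoff is
0.5 Å — the midpoint of the empirically useful 0.3–0.9 Å range — and is
exposed in the configuration. The clustering distance deliberately uses
main-chain atoms only: representatives must generalise across side-chain
conformers. Input structures are sorted by identifier before clustering
and the representative is the first member of each cluster under that
ordering, so identical input sets yield identical databases regardless of
argument order.

## Search

Candidate site pairs in the target are same-chain residue pairs whose
Cα–Cα distance lies in **3.35–16.40 Å** (the observed range of Cα
distances across interacting pairs), separated by at least 3 sequence
positions (so the two triads never share a residue — "not neighbours" is
otherwise unquantified), with complete triads, and not already
interacting through the database-side rules. Evaluation-type contacts
(e.g. hydrophobic) do not exclude a pair. A region search keeps pairs
with at least one member's Cα within 10 Å of a query residue; the
inclusive one-member reading maximises recall. Wild-type identities are
unrestricted — even nonpolar sites are candidates, since it is the
proposed pair, not the current one, that must interact.

Each surviving template match with RMSD ≤ **0.5 Å** becomes a proposal.
The proposed identities are the template pair's residue names, mapped
through the winning pairing; the notation is `wild+site+proposed` for
both sites joined by `/` (e.g. `S44K/K48N`). Output is sorted by RMSD and
then notation, deterministically.

### The signature pre-filter

Aligning every target triad against every representative is the cost
bottleneck at scale. A pre-filter prunes alignments using
**cutoff-scanning fingerprints**: every atom of a triad is typed by a
fixed pharmacophore table (8 classes — hydrophobic, aromatic, positive,
negative, donor, acceptor, sulfur, neutral — with multi-class membership),
and the signature counts atom pairs per unordered class pair and per
cumulative distance bin (defaults 0–10 Å in 0.1 Å steps, giving
36 × 100 = 3600 features). Entries are non-decreasing across bins within
a class pair, and rigid motions leave the signature unchanged; both
properties are tested. The feature count is a derived property of the
parameters, not a constant to reproduce — the original fingerprint
implementations bin differently.

The database signature matrix is reduced by SVD (A = U S Vᵀ); the
retained dimensionality *k* is the smallest number of leading singular
values whose sum reaches 70 % of the spectrum sum. The literal
singular-value reading is the default; weighting by squared singular
values (variance) is available as a mode switch, since either convention
is defensible. Query triads are projected onto the retained
right-singular directions (x ↦ xV_k) — stated explicitly because
projection conventions differ between implementations. Candidate
representatives are those within a Euclidean distance cutoff of the
reduced query.

At full database scale a fixed filter cutoff (13, in raw-count units) was
historically calibrated; its scale depends on the fingerprint's feature
scaling, so at fixture scale the default is ∞ (filter disabled) and
`calibrate_ssv_cutoff()` reports the smallest provably lossless cutoff
for a given target set and database. Distances are computed on raw
counts, with no normalisation — none is defensible without a reference
implementation to match.

### Grafting and clash screening

For each proposal the template's side-chain atoms (beyond Cα, i.e.
including Cβ) are carried through the template-to-target superposition
transform and replace the target side chains at both sites; the target
backbone (N, Cα, C, O) is never touched. A steric clash is flagged when
any grafted atom lies closer than **2.0 Å** to any atom outside the two
mutated residues; the mutated residues themselves are excluded so
covalent geometry cannot count as a clash. Clashing proposals are
retained and flagged rather than dropped — the flag supports both a
"hide clashes" view and a sortable column, and hiding is presentation,
not science. Proline sites are noted in the search log (backbone φ is
constrained) but are not excluded. A `ddg` column is emitted empty so an
external stability predictor can be joined onto the proposal table.

## Evaluation

Wild and mutant structures are compared by seven inter-residue contact
types. Hydrogen bonds use donor–acceptor distance ≤ 3.5 Å plus a
90° angle criterion; weak hydrogen bonds use carbon donors, ≤ 3.6 Å and a
relaxed 30–150° band; polar and weak polar are the same distance rules
without the angle; ionic is opposing formal-charge groups ≤ 4.0 Å;
aromatic is ring pairs with ring atoms ≤ 4.5 Å or centroids ≤ 6.0 Å;
hydrophobic is apolar atom pairs ≤ 4.5 Å (side-chain carbons not bonded
to N/O/S, plus the MET sulfur, from a fixed shipped table).

Cleaned structures carry no hydrogens, so the donor angle is measured at
the donor heavy atom against its covalent antecedent (the nearest
same-residue heavy atom). This is a documented approximation to
hydrogen-explicit angle criteria; the exact hydrogen-placement
conventions of external contact tools cannot be reproduced without
hydrogens, which is also why the package never claims numerical equality
with them. By construction hydrogen bonds ⊆ polar and weak HB ⊆ weak
polar — both invariants are tested. Whether two acceptor-only atoms may
hydrogen-bond on the database side is deliberately left permissive (any
listed-atom pair counts): the atom table does not mark donor/acceptor
roles, and restricting it would be an invention.

Per contact type, the summary reports the fraction of mutants whose count
increased or was kept (delta ≥ 0), the strict-increase fraction, and the
reduced-or-kept fraction — the latter is the natural reading for
hydrophobic contacts, which are expected to *drop* when polar side chains
are grafted in. The paired one-tailed t-test on wild/mutant counts
routes through the standard t distribution on n−1 degrees of freedom;
the tail direction is a required argument because "one-tailed" alone is
ambiguous, and zero-variance differences raise a degenerate-test error
rather than silently reporting 0 or 1.

## The synthetic-structure generator

`make_fixture()` builds ideal-geometry backbones (standard bond lengths
and angles, ω = 180°; helix φ = −57°, ψ = −47°; strand φ = −120°,
ψ = +120°) by sequential natural-extension placement, with optional
Gaussian torsion jitter (seeded, restoring the caller's RNG state).
Planted interactions place real interacting atoms — SER OG / THR OG1 for
hydrogen bonds, ARG CZ / ASP CG-OD1-OD2 for ionic pairs, CYS SG / SG for
disulfides — at *exactly* the requested distance along the Cβ–Cβ axis;
geometrically unreachable requests raise an infeasibility error rather
than silently bending geometry.

What the generator emulates: backbone regularity, detectable planted
contacts, full-backbone completeness, determinism. What it does not:
side-chain rotamer diversity, packing density, solvent, crystal contacts,
real loop geometry, or realistic counts of spurious near-matches. Passing
the planted-recovery suite therefore demonstrates the machinery is exact
and lossless under controlled conditions — not that proposal precision on
real proteins will be high. On real structures the search will return
many low-RMSD matches whose biological value must be judged downstream
(the clash flag, contact deltas and external stability predictors).

## Numerical choices

* Signature bin edges carry a 10⁻⁹ tolerance so a distance lying exactly
  on an edge bins identically after any rigid motion.
* Altloc ties (equal occupancy) resolve to the first conformer in file
  order; PDB coordinates round-trip to the format's three decimals.
* Single-linkage clustering is computed by hierarchical clustering with a
  height cut at the cutoff; cluster labels are renumbered by first
  appearance so representatives are reproducible.
* Superposition rejects collinear point sets at a relative singular-value
  threshold of 10⁻¹²; the triad atom set in practice always spans 3-D.
* `which.max` tie-breaking and pre-sorted inputs make every pipeline
  output byte-reproducible for identical inputs.

## Problem sizes

The test suite and the acceptance script run at fixture scale: chains of
9–30 residues, databases of one to a handful of representatives, 20
planted-recovery cases, 100-instance clustering and 1000-case
superposition property checks. These sizes exercise every code path while
keeping the whole suite in minutes; the algorithms themselves are
size-independent, and the database builder is the same code that would
ingest thousands of structures.

## Known limitations

* Only the first model of multi-model (NMR) files is read; assemblies and
  mmCIF are out of scope.
* Non-standard residues (MSE and friends) are dropped, not remapped.
* Grafts are rigid transplants: no rotamer optimisation or minimisation,
  so a flagged clash may be resolvable in reality and an unflagged graft
  may still be strained.
* Inter-chain (interface) mutations are not proposed; flanks must be
  covalent neighbours within one chain.
* External stability predictors are supported only as a pass-through
  column; the package makes no free-energy claims of its own.
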