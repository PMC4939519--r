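---
title: "Template-based prediction of protein-ligand binding sites"
author: "TemplateSites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based prediction of protein-ligand binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TemplateSites)
```

## The method

Most proteins of known structure bind their ligands in pockets that are
conserved across structurally similar proteins.  TemplateSites exploits this:
it keeps a database of *bound templates* — protein chains co-crystallised with
a ligand under strict quality control — and predicts binding sites on a query
chain by superposing similar templates onto it, carrying each template's
ligand along, and looking for positions in space where many transferred
ligands agree.

Every query chain is processed by one of three routes:

1. **Stable bound chains** (Part 1).  If the query itself carries a ligand
   that passes the ligand-size and complex-stability gates (below), the site
   is read off directly: the site residues are all residues with any heavy
   atom within 8 Å of any ligand heavy atom, and the site center is the
   geometric center of those atoms.  Multiple stable ligands give multiple
   sites, ranked by ligand heavy-atom count (the ranking criterion is our
   choice; larger ligands define their pocket more robustly).
2. **Homology retrieval** (Part 2).  Otherwise, if the chain has a fold
   classification (supplied as a plain mapping file `pdb_id chain_id class`)
   and templates of the same class exist, those templates are candidates.
3. **Chain-length retrieval** (Part 3).  Otherwise every template whose
   length differs from the query's by strictly less than 30 % is a
   candidate.  If the homology route produced candidates but none survived
   the stability gate against the query, the chain falls through to this
   route rather than stopping — each stage of the workflow "or enters the
   following process".

For routes 2 and 3 the query is aligned against every candidate, candidates
are ranked by similarity, the ligands of at most the top 20 templates are
mapped into the query frame, and the mapped ligand centers are clustered
(below) into up to three ranked sites.  Site residues around a mapped ligand
use a wider 10 Å radius than the 8 Å bound-chain radius, absorbing the
alignment error inherent in transferred ligands.

## The template database

Templates come from PDB-format files pushed through a four-stage cascade
(`buildDatabase()`), with per-stage survivor counts recorded in the manifest:

1. **Entry quality** (`rulesOfFive()`): protein-only polymers (no DNA/RNA),
   X-ray experiment, resolution in (0, 3.0] Å, at least one free ligand, at
   least one chain longer than 20 residues.
2. **Chain length**: chains of 20 residues or fewer are removed.  The two
   natural readings of the length rule ("over 20" vs "fewer than 20
   removed") disagree at exactly 20; we keep chains of length ≥ 21.
3. **Ligand size**: a chain must own a true ligand.  A HETATM group is a
   true ligand iff it appears in the HET records, is absent from the MODRES
   records (a modified residue of the polymer is not a ligand), is not water
   (HOH/DOD/WAT), and has ≥ 6 heavy atoms.  Hydrogens never count: crystal
   structures rarely resolve them, so counting them would make the rule
   deposition-dependent.
4. **Complex stability** (`stabilityOfComplex()`): the binding site computed
   from the ligand must be self-consistent — some ligand atom must lie
   within 4 Å of the geometric center of the site's heavy atoms, where the
   site is the ligand's 8 Å residue shell.  A ligand grazing a flat surface
   fails: its residue shell is one-sided, so the shell's center falls inside
   the protein, far from the ligand.  An empty shell is unstable.  Unstable
   ligands are dropped; a chain survives if at least one of its ligands is
   stable.

The free-ligand predicate at stage 1 deliberately defers the atom-count rule
to stage 3, keeping the two filters distinct and the stage counts
interpretable.  The site center uses *all* heavy atoms of the site residues
(not only CA); this is configurable in spirit but fixed here for
determinism — the choice matters only for marginal ligands.

Ligand-to-chain assignment uses the chain identifier on the HETATM records;
when that chain has no polymer residues, the ligand is assigned to the
polymer chain whose atoms come closest to the ligand center.  A ligand is
assigned to exactly one chain; interface ligands shared by two chains seed a
template only for the assigned chain.

The database is persisted as an inspectable directory (JSON manifest,
per-entry PDB files, TSV indexes); identical inputs produce byte-identical
output.

## Structural alignment

The aligner is a compact combinatorial-extension-style engine over CA
coordinates:

* **Aligned fragment pairs (AFPs)**: all pairs of 8-residue windows whose
  intra-fragment CA distance matrices agree to a mean absolute difference of
  at most 3.0 Å.  Internal distances are rigid-motion invariant, so AFP
  detection is too.
* **Path extension**: a dynamic program chains AFPs into the best sequential
  path.  Two AFPs may follow each other either on the same diagonal with
  overlap (their residue pairs are consistent — this is what lets a
  self-alignment cover all *n* residues rather than the largest multiple of
  8) or disjointly with gaps of at most 30 residues per chain and a
  cross-fragment mean distance difference of at most 4.0 Å.  The objective
  maximises aligned residues; ties break on the smaller sum of fragment
  differences, then on the earlier fragment, so results are deterministic.
* **Superposition**: a single SVD-based Kabsch fit over the aligned CA pairs
  (proper rotation enforced; no iterative trimming — the acceptance
  properties only require exactness on rigid and near-rigid cases, and a
  single fit keeps the transform a pure function of the path).

The window length (8), the two distance cut-offs (3.0/4.0 Å) and the gap
bound (30) follow common combinatorial-extension practice and are exposed in
`siteConfig()`.  The candidate-window cap (`maxAfps`, 5000, smallest
differences kept) guards against pathological self-similar chains.

Templates are ranked by a similarity score of our own definition (the
workflow only requires *some* length-normalised, bounded similarity):

$$\mathrm{score} = \frac{N_\mathrm{aligned}}{\min(n_q, n_t)}
  \cdot \frac{1}{1 + \mathrm{RMSD}/r_0}, \qquad r_0 = 3\ \text{Å},$$

which is 1 exactly for a self-alignment and decays with both coverage loss
and distortion.  Ties break on lower RMSD, then lexicographic entry id.

## Consensus clustering of mapped ligands

Each selected template's ligands are transformed into the query frame; a
mapped ligand whose transferred position fails the stability gate against
the query is discarded (a ligand landing off the protein surface cannot
define a site), and templates with no surviving ligand are dropped before
ranking.  The surviving centers are clustered by iterative election:

1. For every remaining center, count the *other* remaining centers at
   distance strictly less than the cluster radius (3.0 Å by default, valid
   1–8 Å).  Counting the center itself would shift every count by one and
   could never change the winner.
2. The center with the largest count becomes the next site center; ties go
   to the ligand from the best-ranked template, then to input order.
3. The winner and every center within the radius are removed, and counting
   restarts from scratch.  Repeat up to three sites.

No cluster count has to be guessed: the radius is the only constraint, and
it has a physical meaning (two transferred ligands within 3 Å indicate the
same pocket).  A site's *support* is its cluster size, elected ligand
included, so a singleton site has support 1.  Site residues are computed
from the elected ligand only (not the whole cluster union): the elected
ligand is by construction the best-supported position, and using the union
would let outlier cluster members inflate the site.

### Boundary conventions

Distance comparisons are closed (≤) for site membership (8 Å, 10 Å), for
the stability distance (4 Å) and for the evaluation hit distance (4 Å), and
open (<) for the clustering neighbour count and the 30 % length-index
window.  These follow the natural reading of each rule ("within" vs "less
than") and are asserted at their boundaries in the test suite.

## Evaluation

Two metrics score a prediction against the experimentally observed ligands:

* **Center-hit accuracy**: a predicted site counts as correct if its center
  lies within 4 Å of any heavy atom of a true ligand; Top1/Top3 success ask
  whether the first / any of the first three sites hit.
* **Residue-level MCC**: residues are partitioned into predicted-site vs
  not (Top1 site residues) and experimental-site vs not (8 Å shell of the
  experimental ligands), giving TP/TN/FP/FN and
  $$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
    {\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}}.$$
  A zero factor in the denominator yields MCC 0 (the standard convention).

A bound query whose ligand passes the stability gate is scored a hit with
MCC 1 *by definition*, without running a prediction — its site is read
directly off its own ligand, so the prediction equals the truth.  A bound
query that fails the gate is treated as unbound with its original ligands
removed, and is scored like any unbound query.  The hit criterion compares
the *predicted center* against the *true ligand's atoms*; this is the usual
reading of the 4 Å center criterion and the only one available when scoring
unbound predictions.

## The synthetic-structure generator

Real template libraries require bulk structure downloads; the generator
(`fixtureSpec()`, `generateBound()`, `deriveUnbound()`, `generateCorpus()`)
builds everything the pipeline consumes from a seed:

* **Backbones** are parametric CA traces with 3.8 Å spacing plus a pseudo
  side-chain centroid 1.5 Å along the local convexity direction: a
  spherical-spiral cage of up to 28 residues around the pocket center
  (guaranteeing, by symmetry, that the stability gate holds for a ligand
  placed at the center) and a family-specific smoothly-kinked tail.
  Members of a fold family share shape parameters and differ by 0.15 Å
  coordinate noise and a random rigid motion; the corpus generator verifies
  at generation time that clean backbones of different families align below
  score 0.29, bumping a family's variant parameter until they do.
* **Ligands** are blobs of 8 heavy atoms (icosahedral directions, 1.4 Å
  radius) plus one hydrogen to exercise heavy-atom counting; two waters
  exercise the water exclusion.
* **Defects** produce structures that fail exactly one gate: `nmr` and
  `high_resolution` fail entry quality; `small_ligand` (5 atoms) fails the
  ligand-size stage; `unstable_ligand` (placed off the tail, pushed outward
  until the gate genuinely fails) fails stability; `modres_mask` lists the
  ligand in MODRES and therefore fails the entry-level free-ligand
  predicate — by cascade monotonicity it is also absent from every later
  stage; `short_chain` adds an extra 12-residue chain that the length
  filter removes (a *lone* short chain would already fail entry quality, so
  the defect is implemented as an extra chain to exercise stage 2
  specifically).
* **Unbound queries** are bound fixtures with all HET groups removed, a
  seeded rigid motion, and optional Gaussian coordinate noise (σ = 0.3 Å in
  the end-to-end suites, a mild model of conformational difference between
  bound and unbound forms); the ground truth is transported through the
  same motion.

What the generator does **not** emulate: real side chains and rotamers,
sequence-structure correlation, crystallographic artefacts (symmetry mates,
partial occupancy beyond simple altLoc pairs, missing density), realistic
ligand chemistry, and genuinely hard fold discrimination — synthetic
families are cleanly separable by construction.  Passing tests therefore
demonstrate the correctness of the machinery (filters, indexes, alignment,
mapping, clustering, metrics) under controlled geometry, not benchmark
accuracy on real PDB data, which additionally depends on the database
snapshot and on the similarity metric details.

## Problem sizes and determinism

The shipped test and acceptance suites run at deliberately desk-sized
scales, chosen so the full suite completes in a few minutes on one CPU:
corpora of 10–20 entries of 56–68 residues, 20 unbound end-to-end queries
per route, 200 random clustering instances of up to 50 centers, 100 random
rigid-motion recoveries, and 1,000 random confusion matrices.  All
randomness flows through explicit seeds; the pipeline itself (build,
predict, evaluate) contains no random choices, and repeated runs are
byte-identical.  The only compiled code is the AFP scan and the chaining
dynamic program (Rcpp), the two kernels whose cost grows quadratically in
chain length.

## Known limitations

* Sequential alignments only: non-sequential (permuted) structural
  similarity is invisible to the AFP chaining.
* A single final superposition: no iterative rejection of outlier pairs, so
  heavily distorted alignments report a blended transform.
* One model per file (model 1) and no assembly expansion.
* The similarity score and several tie-breaks are package-defined
  conventions; rankings on real data are not expected to match any
  particular external implementation bit-for-bit.
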