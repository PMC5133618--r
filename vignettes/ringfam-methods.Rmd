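---
title: "ringfam: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringfam: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringfam)
```

`ringfam` re-implements, as a reusable and testable pipeline, the
genome-wide characterisation of a plant ATL ubiquitin-ligase family: motif
identification, protein feature annotation, duplication-mode
classification, phylogeny-guided nomenclature and expression profiling.
This vignette records the models behind each stage, the tunable parameters
with their defaults and rationale, and the design decisions taken where
the methodology left genuine freedom.

## The RING-H2 motif grammar

ATL proteins are defined by a RING-H2 zinc finger whose eight
Zn-coordinating ligands occur in the order C-C-C-H-H-C-C-C, with a
conserved proline one residue (`PC`, the BTL configuration) or two
residues (`PxC`, the classic ATL configuration) before the third cysteine,
and in practice a tryptophan exactly three residues after the fourth
cysteine (`CxxxW`). The general family consensus is

```
Cys-X(2)-Cys-X(n)-Px-Cys-X(1)-His-X(2)-His-X(2)-Cys-X(n)-Cys-X(2)-Cys
```

and the fixed-spacing seed form used to anchor searches is
`CxxC(13x)PxCxHxxHxxCxxxW(7x)CxxCW` (`seed_grammar()`).

A `motif_grammar` object fixes, for each of the seven inter-ligand gaps, a
minimum and maximum residue count. Two of the gaps are variable in the
consensus; their default range is **4–30 residues**, bracketing the seed
motif's fixed 13 and 7 while keeping the search bounded. Ranges are
expressed as *total* gap lengths, so the C2→C3 gap includes the `Px`/`P`
prefix (default range 6–32) and the C6→C7 gap includes the `xxxW` prefix
(default range 8–34).

Decisions worth recording:

* **Proline rule default is `either`.** The family admits both subtypes;
  the scan itself is subtype-agnostic and `classify_subtype()` separates
  `ATL_PxC` from `BTL_PC` afterwards. Restricted grammars (`PxC`, `PC`)
  are available for targeted scans.
* **Adjacency takes precedence.** If prolines sit at both C3−1 and C3−2,
  the match is typed `PC`: "immediately adjacent" is the stronger, more
  specific statement.
* **All placements are reported.** The scanner enumerates every
  non-identical ligand placement, ordered by first-ligand position;
  downstream annotation uses the first (most N-terminal) match, which
  matches the one-domain-per-protein usage of the family literature and is
  deterministic.
* **`X` never matches** a ligand, the proline or a required tryptophan; a
  record containing characters outside the 20-letter alphabet plus `X` is
  rejected with a diagnostic.
* Coordinates are 1-based inclusive throughout, matching the biological
  convention of the motif notation.
* "Three residues downstream of the fourth cysteine" is interpreted as
  exactly three non-ligand residues between C6 and the tryptophan
  (`CxxxW`), consistent with the seed form. The trailing W after the last
  cysteine appears only in the seed form, so `require_trailing_w` defaults
  to `FALSE`.

The scanner is checked in two independent ways: against a brute-force
oracle that compiles one exact regular expression per spacer tuple and
enumerates overlapping placements with lookahead, and against
generator-planted motifs and single-violation decoys.

## N-terminal categories and the published discrepancy

Members are placed in exactly one of five categories from their subtype,
TM/hydrophobic code and BZF status: `TM_PxC`, `BZF_PC`, `Hyd_PC`,
`BZF_Hyd_PC`, `NoNterm`. The published prose counts for the 96-member
grapevine family (45 + 10 + 25 + 3 + 16) sum to 99 because the three
BZF-plus-hydrophobic members are also counted inside the ten BZF members.
`ringfam` keeps the categories **mutually exclusive** (they partition the
family) and reports the published aggregate counts (10 BZF in total, 58
TM-bearing, 15 hydrophobic-only, 16 with no N-terminal feature) alongside;
it does not attempt to reproduce the overlapping prose partition, and the
packaged table is never "corrected".

## Hydropathy, regions and physical parameters

Transmembrane/hydrophobic calling uses the Kyte–Doolittle sliding-window
mean with **window 19, TM threshold 1.6, hydrophobic threshold 0.8,
minimum run length 15 centres**. The window and the 1.6 cutoff are the
classic published transmembrane heuristic; the source methodology names
the method but no parameters, so these are explicit, configurable
stand-ins. The 0.8 threshold separates "hydrophobic region" calls, mapped
to the family's `0.5` code (one or more hydrophobic regions, count not
preserved — the full region list is retained internally). This is a
hydropathy heuristic, not an HMM: TMHMM-style external calls can be
supplied through `ingest_domain_table()` and take precedence in user
workflows.

The GLD (Gly-Leu-Asp) motif is graded `complete` > `GLx` = `GxD` > `Gxx`,
leftmost on ties, within a search region defaulting to the stretch between
the last N-terminal called region and the first RING ligand — the
published "appropriate position" is not defined, so the region is
configurable.

Isoelectric points use the Henderson–Hasselbalch net-charge sum over free
termini and D, E, C, Y, H, K, R, solved by bisection. The bisection
converges to 1e-6 pH internally — well below the 0.01 pH reporting
precision — because for highly charged peptides a 0.005 pH offset already
moves the net charge by more than 0.01 units. Two pKa sets are available:
EMBOSS (default) and a ProtParam-style (Bjellqvist) set; the source cites
a web calculator but not its constants. Molecular weight sums average
residue masses plus one water; `X` contributes a documented 110 Da
placeholder and no charge.

## Duplication modes

Gene models come from GFF3 (longest mRNA by summed exon width; exonless
mRNAs degrade to single-exon models with a warning) and are ranked along
each chromosome by start coordinate. Homology hits are reduced to the
**best five non-self subjects per query at E ≤ 1e-5** (ties at the k-th
place broken by lexicographically smaller subject), mirroring the
published filtering.

Collinear blocks are chained by dynamic programming per chromosome pair,
in both orientations, with **max rank gap 25** between consecutive anchors
and **minimum block size 5** — the published "standard settings" of the
MCScanX-style workflow are not printed, so these are the MCScanX defaults,
all configurable. Blocks are extracted greedily from the longest chain
down without anchor reuse; among equal-length chains the lexicographically
smallest anchor sequence wins and forward orientation is preferred, making
extraction deterministic and equal to exhaustive search at small sizes
(property-tested to 12 anchors).

Mode assignment uses the precedence **segmental/WGD > tandem > proximal >
dispersed**: block membership first, then a paralog at rank distance ≤ 1
on the same chromosome (tandem), ≤ 10 (proximal, again an explicit
stand-in for an unpublished window), any remaining paralog (dispersed),
else singleton. Genes on unplaced scaffolds (`chrUn`) have no rank
geometry and can only be dispersed or singleton. Retention enrichment is a
two-sided Fisher exact test per mode on the (family vs background) ×
(mode vs other) table, Bonferroni-corrected by the number of modes;
zero-margin tables report p = 1 and are flagged.

## Nomenclature

Names are assigned from a phylogeny whose leaves split into numbered
reference genes (e.g. `AtATL43`) and unnamed targets:

1. a target whose unique nearest reference — by **patristic distance**,
   with a relative tie tolerance of 1e-6 — reciprocally has that target as
   its unique nearest target inherits the reference number;
2. two or more targets equidistant from a single reference share its
   number with letter suffixes `a`, `b`, … in tree-traversal order;
3. a target tied between two or more references (the operationalisation
   chosen here for "matches more than one reference gene", e.g. sister to
   a reference clade) takes a new number above the reference maximum;
4. remaining targets are numbered progressively.

New numbers (rules 3 and 4) are drawn from one strictly increasing counter
along a **fixed post-order traversal rooted at the lexicographically
smallest leaf** — "numbering proceeds along the tree" needs a concrete,
rotation-invariant order, and this one is reproducible for any input
rotation of the same unrooted topology. The distance metric, tolerance and
traversal are package decisions; the source defines none of them.

Supporting machinery: a Gblocks-like curation keeping runs of columns with
gap fraction ≤ 0.5 and length ≥ 5 ("relaxed" settings, parameters
unpublished); neighbour joining (via `ape`) with negative branches clamped
to 0 as a stand-in tree builder for synthetic runs — maximum-likelihood
trees are ingested as newick, never re-inferred; and support-based edge
collapsing (default threshold 70) implemented as exact edge contraction.

## Expression profiling

Atlas profiles are median-centred per gene (idempotent, exact zero row
medians). Clustering uses Pearson distance (1 − r) with **average
linkage**; the source names only the metric, and average linkage is the
convention of the MeV-era tooling it used. The agglomerator is hand-rolled
so the tie-break (smallest index pair at equal distance) is explicit and
deterministic; it emits a standard `hclust` object so `stats::cutree()`
applies. Zero-variance genes get distance 1 to everything, with a warning.

Responsiveness follows the published thresholds: |log2FC| > 0.5 and FDR <
0.05 in **at least two conditions**, with the relaxed count (FDR < 0.05 in
≥ 1 condition, any fold change) reported alongside. Missing statistics are
treated as not significant and counted. DE statistics themselves are
inputs: the limma/DESeq2 models of the original analysis are out of scope,
and the provided two-group Welch t-test with BH adjustment is a clearly
labelled, non-equivalent stand-in for synthetic runs only.

Co-expression is the weighted Pearson coefficient; the published weighting
scheme is not specified, so weights default to unit (ordinary Pearson) and
user weights are accepted. The Mantel test correlates upper-triangle
entries and permutes rows and columns of one matrix jointly; it is
one-sided (greater), defaults to 999 permutations, and requires an
explicit seed — the source reports a "simulated p-value" without a
permutation count. Both correlation and distance orientations of the
matrices are accepted; users choose the orientation and the sign of the
expected association accordingly.

## The synthetic world

The generators produce the *stated* conditions of the study design, not
tuned ones:

* `gen_proteome()` plants grammar-compliant motifs (ATL = PxC, BTL = PC
  with a BZF placeholder annotation) inside random flanks, and decoys
  violating **exactly one** constraint (ligand substitution, out-of-range
  spacer, missing tryptophan). Background composition is uniform over the
  20 amino acids — the simplest null for false-positive behaviour;
  Swiss-Prot-like composition would only lower the already negligible
  chance background rate. Decoys are rejection-sampled until the scanner
  finds nothing anywhere, so "decoys never match" is exact by
  construction and the tests verify it with the independent regex oracle.
* `gen_genome()` (defaults: 200 genes, 4 chromosomes) plants WGD pairs as
  runs of ≥ 5 consecutive anchors between chr1 and chr2 (runs spaced by
  more than the chain gap so blocks never merge), tandem pairs at adjacent
  ranks, proximal pairs within the rank-10 window and dispersed pairs
  spread across chromosome pairs so no non-block pair accumulates enough
  anchors to chain. Noise hits are emitted with E-values **above** the
  1e-5 retention threshold: they exercise the filter while keeping planted
  truth exact. (Rejection-sampling noise below the threshold would
  silently relabel singleton genes as dispersed; weak-E-value noise avoids
  that without weakening the filter's role.)
* `gen_expression()` (defaults: 96 genes × 54 samples, 5 clusters, 10
  contrasts, 65% responsive — the family size, atlas breadth, cluster
  count and responsive fraction of the study it emulates) separates
  cluster means by the planted effect and gives responsive genes |log2FC|
  equal to the effect with tiny p-values in exactly two contrasts, the
  stated minimum. With `effect_lfc = 0` nothing is planted and every
  statistic is null.

What the synthetic world does **not** emulate: real sequence composition
and homology structure (hits are declared, not aligned), chromosome-scale
coordinates, array/RNA-seq noise models, or correlated tests. A green test
therefore establishes algorithmic correctness against known truth — it
does not establish that the pipeline would reproduce the published
genome-wide partition (31/13/1/51), stress-responsive counts (62/81/54/73/
41) or GLD grading (17/23/12), which require the real proteome, genome and
expression repositories and are out of desk scope.

## Calibration tests

Two null calibrations are part of acceptance:

* **Responsiveness.** With effect 0 the per-contrast p-values are
  independent uniforms; the event "any gene reaches FDR < 0.05" in a
  single contrast has probability exactly α by Simes' identity, so the
  empirical rate over 500 replicates must lie in [0.03, 0.07] at α =
  0.05. This single-contrast, relaxed-flag reading is the only one under
  which the stated band is attainable: the strict two-condition rule with
  a fold-change threshold has essentially zero false-positive probability
  under the generator's null, which would make the calibration vacuous.
* **Mantel.** Under independent matrices the permutation p-value is
  uniform on its grid, so the rejection rate at 0.05 over 500 replicates
  (999 permutations, n = 30) must also lie in [0.03, 0.07].

Both use fixed seeds chosen before the tests were first run; they are
statistical statements and would be reported honestly if a seed landed
outside the band.

## Numerical conventions and degenerate inputs

* All coordinates 1-based inclusive; ranks per chromosome by start.
* Bisection bracket [0, 14] pH; undefined pI returns `NA`.
* Sequences shorter than the hydropathy window give an empty profile with
  a warning, never an error.
* Empty alignment curation results are errors advising relaxed thresholds.
* Zero-margin Fisher tables: p = 1 by convention, flagged.
* Mantel on constant matrices is an error (the statistic is undefined).
* The packaged family table is checksum-guarded and immutable; the two
  known transcription notes (an extraction artifact in one UniProt
  accession, bracketed synonyms split into their own column) are recorded
  in the repository notes, not silently altered.

## Known limitations

* TM/hydrophobic calling is a hydropathy heuristic; counts of hydrophobic
  regions are collapsed to the `0.5` code for compatibility with the
  published table.
* Nomenclature rule 3's trigger is this package's operationalisation; a
  different reading of "matches more than one reference" could renumber
  tail members.
* The collinearity chainer scores chains by anchor count (unit weights),
  not alignment score — sufficient for rank-geometry classification, not
  a replacement for MCScanX on real genomes.
* `welch_de()` is not a substitute for moderated DE models on real data.
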