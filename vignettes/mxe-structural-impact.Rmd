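---
title: "Quantifying the structural impact of mutually exclusive exon switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the structural impact of mutually exclusive exon switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxestruct)
```

Homologous mutually exclusive exons (MXEs) swap a short peptide between
two otherwise identical protein isoforms. This vignette explains what
`mxestruct` computes, why the defaults are what they are, how the
randomisation nulls are constructed, and what the synthetic benchmark
does and does not demonstrate.

## The detection model

A gene model is a set of transcripts over a universe of exons. Coding
exons are joined in an undirected graph with two edge types: *overlap*
(shared genomic bases — alternative boundary forms of "the same" exon)
and *co-occurrence* (joint appearance in a transcript). A pair of
consecutive coding exons is mutually exclusive only if no transcript
contains both **and** the pair cannot be linked through the graph. A
subtlety: with co-occurrence edges, naive connectivity would link every
exon pair through shared constitutive neighbours. The criterion used here
contracts exons connected by overlap chains into groups and rejects a
pair when its two groups are bridged by any co-occurrence other than the
pair's own direct one. This is the reading under which the canonical
two-transcript example (T1 = [E1, E2, E4], T2 = [E1, E3, E4]) yields the
candidate (E2, E3) while an exon overlapping E3 that co-occurs with E2
correctly kills it.

Candidates must then share their reading frame (equal codon phase at the
exon start), be similar in length, and be demonstrably homologous.

* **Length filter**: pass iff |log10(len_a/len_b)| <= 0.25. The base-10
  log and the *similarity* direction (<=) are deliberate: the threshold
  bounds the ratio to within 10^0.25 ≈ 1.78-fold, which is what "similar
  in length" means operationally. (The source protocol's prose states
  the inequality in the opposite direction while describing similar
  lengths; similarity is the only reading consistent with the filter's
  purpose.)
* **Homology filter**: Smith–Waterman with BLOSUM62, gap open 11, extend
  1, percent identity over aligned columns, and a Karlin–Altschul
  E-value `E = K·m·n·exp(-λS)` with the gapped BLOSUM62 constants
  λ = 0.267, K = 0.041. Thresholds: identity >= 25%, E <= 0.005, both
  peptides >= 8 residues (shorter peptides cannot support a homology
  call at all). Implementing the scoring in-package rather than shelling
  out to BLAST makes the filter deterministic and self-contained; the
  E-value constants are fixed and the raw score is checked against an
  exhaustive dynamic-programming oracle in the tests.

A residue split across an exon junction belongs to the exon supplying at
least two of its three codon nucleotides; the degenerate 1+1+1 split
(microexons) assigns it to the exon holding the middle nucleotide. This
makes per-exon peptide segments partition the transcript peptide exactly,
which the tests verify.

Cassette events take the longest protein isoform and look for the next
longest whose chain differs by exactly one coding, non-terminal exon —
the minimal, least structure-disrupting exon loss. Microexons are exons
of at most 27 nt. Isoform combinatorics over disjoint MXE clusters is the
product of cluster sizes; the bundled DSCAM-like fixture (12/48/33/2)
gives 38,016.

## Physicochemical scoring

Variable residues are the columns of the global isoform-pair alignment
(Needleman–Wunsch, BLOSUM62, open 10, extend 0.5) that differ by
substitution or gap. Traceback tie-breaking is delegated to the
Biostrings implementation; it is deterministic, and alignment *scores*
(what the oracle tests pin down) are tie-independent.

Each variable column scores its McLachlan physicochemical similarity;
the event score is the mean over columns mapped to the structure, so an
event is summarised on the same 0–6 scale as a single substitution, and
a mean of 2 or less flags a radical chemical change. The embedded table
keeps the published off-diagonal McLachlan values; identity scores are
capped at 6 to keep the whole table on the documented 0–6 scale. The cap
is immaterial in practice — identical columns are by construction never
variable residues — and load-time validation asserts symmetry, the
range, and identity scores in {5, 6}. Gap columns score 0 ("no
similarity or a deletion").

When a disorder-score table is supplied, an isoform with more than 50%
of residues above score 0.5 is treated as intrinsically disordered and
excluded from structural analysis; scores are inputs rather than an
embedded predictor so the gate is testable offline.

## Structural measures

Structures are read from PDB files (heavy atoms, first model, highest-
occupancy altloc, hetero groups excluded). Isoforms map onto structures
by global alignment; a map must cover at least 80% of structure residues
to be usable, and the pipeline additionally requires the mapped identity
to exceed 40%, standing in for the homology search that precedes mapping
in a full template-based protocol (without it, any same-length sequence
would "cover" a template through substitution columns).

Solvent accessibility is Shrake–Rupley with probe 1.4 Å, Bondi van der
Waals radii and 960 sphere points per atom placed on a deterministic
golden-section spiral, making results reproducible bit-for-bit. At 960
points the isolated-atom error against 4π(r+p)² is well under 2%, and
total SASA is rotation-invariant to better than 0.5% (both tested).
Relative ASA divides by the Tien et al. theoretical maxima; exposure is
strictly rASA > 10%.

Variable residues are clustered by single linkage at 8 Å over minimum
heavy-atom inter-residue distances (the residue-centroid alternative is
a configuration away; minimum-atom distance was chosen because the
protocol's distance computation is explicitly all-atom). Clusters need
at least 3 residues. Cluster–site distance is measured from the cluster
centre of mass (over member heavy atoms) to the nearest site heavy atom
and set to 0 when a site residue is itself a member. All distance
cutoffs in the package are inclusive (<=), applied uniformly: cluster
mode 6 Å, residue mode 4 Å.

FunSites are conserved columns of a family alignment: a Valdar-style
weighted sum of pairs in its identity-indicator form (identical pair 1,
mismatch or gap 0, sequences weighted by mean distance to the rest), so
an invariant column scores 1 and a uniformly variable column scores near
0. FunSites (score >= 0.7, configurable) are only emitted when the
diversity-of-positions score — the scaled count of distinct column
scores — exceeds 70, since conservation carries no signal in a
low-diversity alignment. Allosteric candidates are residues at or above
the 95th percentile of betweenness centrality in the 5 Å minimum-atom
contact network, computed per connected component, with threshold ties
included and a degenerate flag when all centralities coincide.

## Null models

Three randomisations calibrate the observed geometry:

1. **Random regions** (exposure): contiguous sequence windows of the
   splice-region length, uniformly placed, 10,000 draws; compared with
   observed exposure by Wilcoxon signed-rank across events. Contiguous
   windows (not arbitrary residue subsets) are used because the splice
   region itself is contiguous in sequence.
2. **Grown random clusters** (proximity): from a uniform seed residue,
   residues within 2 Å of the current set are added nearest-first until
   the observed cluster size is reached. The 2 Å rule effectively walks
   covalent neighbours; on chain breaks (or sparse toy structures) the
   nearest residue overall is added instead, and that fallback is
   surfaced in the result. Growth is deterministic given the seed
   residue, so the null is computed by precomputing the outcome per
   possible seed and resampling seeds — identical distribution, far
   cheaper. The dataset-level test is a one-sided Z-score on the
   proportion of events whose cluster is close, against null proportions
   formed by drawing one random cluster per event.
3. **Pattern placement** (residue mode): the observed spacing pattern of
   variable residues slides to uniform offsets along the mapped chain.

Empirical p-values use the add-one estimator (1 + k)/(n + 1) and are
printed as "< 1/n" when no resample is as extreme. For cancer-mutation
proximity the observed cluster distance honours the in-cluster-zero
convention while null distances are raw centre-of-mass distances; the
raw null is continuous, so an observed 0 is genuinely unreachable by
chance placements and reports p < 0.0001 at 10,000 draws.

Exact tests (Wilcoxon, Mann–Whitney, Fisher) use the standard stats
implementations — exact enumeration at small n without ties, normal
approximation with tie correction otherwise — and are checked against
full enumeration oracles in the tests. The Z-test is one-sided toward
enrichment (the direction the study's hypotheses take); its type-I error
is verified at 5% ± 1.5% over 1,000 trials in which the "observed"
statistic is itself drawn from the cluster null (batch means of 10
distances, which makes the statistic near-normal without changing what
is being tested).

## The synthetic benchmark

The generator plants, at codon level (so nucleotide filters are really
exercised): MXE pairs mutated to a target peptide identity; one negative
control per filter — a transcript containing both exons, a +1 nt CDS
extension that shifts the partner's phase while preserving its peptide,
a 1.8-fold length violation, sub-8-residue twins, and an unrelated
partner; cassette and microexon genes; an NMD-tagged transcript that
must be dropped on read; and the DSCAM-like cluster gene. Defaults
follow the study-scale statistics: planted exons of 36 residues at 67%
identity (substituted positions evenly spread so the variable patch is
contiguous in 3D). Toy structures are ideal helices (rise 1.5 Å,
100°/residue, Cα radius 2.3 Å, one pseudo side-chain atom 1.5 Å further
out) whose sequence equals the event's host isoform, with an occluding
atom sheath burying part of the constitutive region, "near" functional
sites within 6 Å of the variable-patch centre of mass and "far" sites at
least 20 Å away, plus cancer-mutation tables planted inside, near and
far from the variable set.

Benchmark sizes (20 genes, 10 planted pairs, 5 structures of ~70
residues, 10,000 null draws) keep a full run around half a minute while
leaving every statistic well away from its decision boundaries.

What passing the benchmark shows: every stage computes what it claims
on inputs whose truth is known, filters reject exactly what they should,
and the nulls are calibrated. What it does not show: performance on real
annotation (fragmented CDS records, many-transcript genes, pseudo-
autosomal duplications), real structures (side-chain packing, missing
density, multi-domain contacts), or real conservation patterns —
the toy helices have no tertiary packing beyond the planted sheath, and
the planted MSAs are column-independent. Conclusions about real genomes
require the corresponding real inputs in the same formats.

## Known limitations and open choices

* "Same reading frame" is implemented as equal start phase; equal end
  phase is not required.
* Ties for the "longest transcript" hosting an exon break
  lexicographically by transcript id, for determinism.
* The conservation score is the identity-indicator instantiation of the
  weighted sum of pairs; similarity-matrix variants give a ~0.4 baseline
  for random columns and would need a rescaled FunSite threshold.
* The duplicate-sequence monotonicity one might expect of conservation
  scores does not hold under distance-based sequence weighting and is
  not claimed.
* The cluster-growth fallback on stalled growth (add the overall nearest
  residue) is a choice; it is isolated behind `growth_cutoff` and the
  `fallback_used` flag.
* Partial terminal codons translate as floor(n/3) codons with a flag;
  selenocysteine and ambiguity codons become `X`.
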