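# mxestruct

Structural and functional impact of homologous mutually exclusive exon
(MXE) switching.

## The problem

Mutually exclusive exons are pairs (or clusters) of exons of which exactly
one appears in any mature transcript. When the two exons arose by
duplication of an ancestral exon, the two protein isoforms differ only in
a short homologous peptide — the *variable residues* — while the rest of
the protein is unchanged. Whether such a switch matters functionally
depends on where those residues sit in the folded protein: buried
switches threaten stability, surface switches can rewire binding sites,
catalytic pockets, allosteric channels and PTM motifs, and the same
regions may be hit by somatic cancer mutations.

`mxestruct` implements that analysis end to end for annotation-plus-
structure inputs, together with a synthetic-data generator that plants
every kind of event (and one negative control per detection filter) with
known ground truth, so the whole pipeline is testable offline.

## What the package computes

**Event detection.** For each gene, coding exons are linked in a graph
(edges from genomic overlap or transcript co-occurrence). A candidate MXE
pair must be consecutive in the genome, never co-occur in a transcript,
be unlinkable through the graph, share its reading frame (equal start
phase), be similar in length (|log10 ratio| <= 0.25) and be homologous
when translated: Smith–Waterman (BLOSUM62, 11/1) with a Karlin–Altschul
E-value `E = K m n e^{-lambda S}` (lambda = 0.267, K = 0.041), requiring
identity >= 25%, E <= 0.005 and both peptides >= 8 residues. Cassette
exons (single coding non-terminal exon loss between the two longest
isoforms) and microexons (<= 27 nt) are classified alongside, and
combinatorial isoform counts are the product of MXE cluster sizes — the
DSCAM-like fixture with clusters of 12, 48, 33 and 2 exons gives
12 x 48 x 33 x 2 = 38,016 isoforms.

**Physicochemical change.** Variable residues are the differing columns
of the global isoform-pair alignment. Each column scores its McLachlan
similarity (0–6; gaps 0); the per-event score is the mean over mapped
variable columns, with score <= 2 flagging a radical chemical change.

**Structural quantification.** Isoforms map onto structures by global
alignment (>= 80% residue coverage required). Solvent accessibility is
computed with an in-package Shrake–Rupley routine (probe 1.4 Å, Bondi
radii, deterministic golden-spiral points); a residue is exposed iff its
relative ASA exceeds 10%. Variable residues are clustered by single
linkage at 8 Å (minimum size 3); a cluster is close to a functional site
if its centre of mass lies within 6 Å (4 Å any-atom in residue mode), and
cancer-mutation proximity uses the same two modes.

**Null models and tests.** Exposure is compared with 10,000 random
contiguous regions of the same length (Wilcoxon signed-rank across
events). Cluster–site proximity is compared with 10,000 random clusters
grown from random seed residues at <= 2 Å steps (one-sided Z-test on the
proportion of events close). Residue-level calls use a spacing-pattern
placement null, with empirical p = (1 + #as-extreme)/(n + 1). FunSites
are conserved alignment columns (weighted sum of pairs) gated by a
diversity-of-positions score (DOPS > 70); allosteric residues are the top
5 percentile of betweenness centrality in the 5 Å contact network; gene
set enrichment is Fisher's exact test with Benjamini–Hochberg correction.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
synthetic benchmark (20 genes, 10 planted MXE pairs, 5 toy structures):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_events.R
Rscript analysis/03_structure_pipeline.R
Rscript analysis/04_summary.R
```

which prints (seed 1):

```
MXE detection: 10 events; precision 1.00, recall 1.00
Mean identity of detected pairs: 69.8% (planted target 67%)
Negative controls rejected: 5 (reasons: cooccurrence, frame, length, min_len, evalue)
Surface exposure vs random regions: Wilcoxon V=15, p=0.0625 (n=5)
cluster proximity to CSA: observed 1.00 vs null 0.119 +/- 0.144, z=6.10, p=5.46e-10
cluster proximity to PPI: observed 0.00 vs null 0.477 +/- 0.223, z=-2.14, p=0.984
```

Every planted pair is recovered, each negative control is rejected by
exactly the filter it violates, the planted-near catalytic sites (CSA)
show strong enrichment while the planted-far interaction sites (PPI) do
not, and an in-cluster cancer-mutation plant is called at distance 0 with
empirical p < 0.0001. Stage tables land under `results/`.

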