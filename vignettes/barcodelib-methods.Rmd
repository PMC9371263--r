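---
title: "Building and auditing a multi-marker DNA barcode reference library"
author: "barcodelib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and auditing a multi-marker DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodelib)
```

## The problem

A DNA barcode reference library links short mitochondrial fragments —
typically the COI "Folmer" region, often complemented by 16S and ND2 —
to reliably identified species. Before such a library can be trusted for
identification it has to be *audited*: duplicates and off-target
sequences removed, nuclear pseudogene copies (NUMTs) screened out, and
the distance structure examined for the pathologies that undermine
distance-based identification — species pairs sharing haplotypes (no
barcode gap), deeply divergent intraspecific lineages (cryptic diversity
or misidentification), and query lineages matching no reference at all.
`barcodelib` implements that workflow end-to-end for a tabular library of
COI/16S/ND2 records, and ships a seeded simulator so every stage is
testable without any external data.

## Distances

All quantitative results rest on the **uncorrected p-distance** computed
under **pairwise deletion**: for a pair of aligned sequences, columns
where either member carries a gap or any symbol outside `{A, C, G, T}`
are excluded from both numerator and denominator, and the distance is
the fraction of mismatching remaining columns. Uncorrected distances
(rather than model-corrected ones) keep values directly comparable
across taxa and with the published literature for this fauna. When a
pair has *no* comparable column the distance is masked (`NA`), never
reported as 0.

Library records are unaligned fragments of very different lengths
(COI fragments of a few hundred bp against near-full-length references),
so by default every pair is aligned independently with an affine-gap
global aligner with **free end gaps** (Gotoh algorithm): a run of `L`
gap characters costs `gap_open + (L - 1) * gap_extend` (defaults −8 /
−1, match +1, mismatch −1) unless the run touches either end of the
alignment, in which case it is free. Free end gaps are what lets a
245 bp fragment nest inside a 700 bp sequence without penalty.
Tie-breaking is deterministic (match/mismatch preferred over a gap, a
gap in the first sequence over a gap in the second), so results are
reproducible to the byte. A consequence worth knowing: for two
sequences with *no* homology the optimum is the degenerate disjoint
overlap (score 0, zero comparable sites, masked distance) rather than a
forced all-mismatch alignment — we consider the masked distance the
correct answer for non-homologous input. An `msa` mode scores
pre-aligned, equal-length sequences directly, for consuming external
multiple alignments.

Strand orientation is normalized before aligning: the shorter sequence
is tested in both orientations against the longer and the one sharing
more exact 11-mers wins. Distances are reported as percentages rounded
to one decimal, matching the precision conventional in barcoding papers.

## Partitions, gaps and anomaly flags

Every unordered pair of same-marker records is classified by taxonomy:
**intraspecific** (same species name), **congeneric interspecific**
(same genus, different species) or **intergeneric** (different genus,
across families included). Open-nomenclature names ("cf.", "sp.",
"aff.") are preserved and act as distinct species-level terminals, so
*Oreochromis* sp. is its own lineage rather than being merged into the
genus. Per-class pair counts are disjoint and exhaustive over the
unmasked pairs; summaries report count, mean, min and max.

Three audits consume the matrix:

* **Barcode gap per species** — maximum intraspecific distance versus
  minimum distance to the nearest non-conspecific. The gap flag is true
  only when `min_inter > max_intra` and `min_inter > 0`; singletons get
  an indeterminate (masked) flag.
* **Deep lineages** — single-linkage clustering of each species'
  records at a threshold, default 3.0% (chosen from the divergences at
  which Malagasy fish lineages have been flagged as taxonomically
  problematic, roughly 3–5%); two or more clusters flag the species.
  Thresholds below 0.5% are suppressed: at that scale every haplotype
  becomes its own "cluster" and the flag is meaningless.
* **Zero-distance species pairs** — any cross-species pair at exactly
  0% distance (shared haplotypes). A caller-supplied exclusion list of
  record ids is honored before partitioning, mirroring the standard
  practice of removing known introgressed specimens before computing
  library-wide statistics.

## Assignment

Queries are assigned against a **reference panel** of reliably
identified sequences of one marker. Identity is `100 × (1 −
p-distance)` over the pairwise alignment; per species the best exemplar
counts (best-close-match convention, not a centroid). Calls:
`assigned` at ≥ 99.0% identity, `cf` in [97.5, 99.0), `undetermined`
below 97.5%, and `ambiguous` whenever the two top species lie within
0.5 identity points of each other. The defaults interpolate the
identities at which published assignments of Malagasy tilapia ND2
lineages were accepted (99.5%, 99.7%) and the divergence at which a
lineage was left undetermined (≥ 2.7%); both thresholds are flags. Note
the semantic difference from field usage: here `cf` is purely a
distance-band call, while in the taxonomic literature "cf." often also
reflects missing morphological evidence.

Assigned labels propagate across markers within a sample (a COI record
inherits the species of its sample's assigned ND2 record, with
provenance `transferred`); conflicts with existing labels are flagged,
never overwritten; undetermined samples receive an open-nomenclature
lineage tag ("*Genus* sp."). A syntopy report lists distinct assigned
species per locality (by name, by coordinates rounded to three decimals
when unnamed, else pooled as "unlocalized").

## Trees and monophyly

For screening, an internal neighbor-joining builder turns any distance
matrix into an unrooted tree (classic Q-criterion agglomeration,
lowest-index tie-break, negative branch lengths clamped to zero with a
warning). External trees — e.g. from likelihood tools — are consumed as
Newick, including quoted labels and internal support values. NJ here is
a screening substitute, not a replacement for likelihood inference;
topology near short internal branches should not be over-read.

Monophyly is decided on **bipartitions** of the unrooted tree: a
species with two or more leaves is monophyletic iff some edge isolates
exactly its leaf set. This makes verdicts rooting-independent and needs
no outgroup. For failures the report lists the intruding species found
in the smallest bipartition side containing the species' leaves.

## The simulator: what it emulates, and what it does not

`simulate_library()` generates a library with nested taxonomy (families
> genera > species > samples) by evolving sequences down that
hierarchy under independent-site Jukes–Cantor-style substitution. A
branch of `r` substitutions per site changes each site with probability
`0.75 (1 − exp(−4r/3))`, the JC transition probability mass to the
other three bases, so branch loads compose exactly and the *expected*
p-distance between two tips is the saturation transform of their path
load. Branch loads are calibrated by inverting that transform so that
the three pair classes hit their targets exactly in expectation:
defaults d_w = 1% within species, d_c = 6% between congeners,
d_g = 20% between genera — the three divergence strata observed in
mixed vertebrate barcode libraries. Family membership only labels
genera: all intergeneric pairs are exchangeable at d_g, which keeps the
intergeneric class mean on target instead of inflating it with an
arbitrary extra between-family stratum.

COI output is coding-frame consistent: the root sequence is drawn
stop-free in frame 1 (vertebrate mitochondrial code) and substitutions
that would create a stop codon simply pick a different target base —
the *number* of changed sites, and hence the calibration, is untouched.

The reference panel holds each species' ancestral sequence, so a clean
sample sits ~d_w/2 from its own exemplar (~99.5% identity at the
defaults) — comfortably `assigned` — while remaining ~d_c from other
exemplars. One sample per species plus the orphans form the designated
query set in the truth table, mirroring the practice of matching
selected lineages against a dedicated panel rather than re-assigning
the whole library.

Anomalies reproduce the three pathologies the audit is built to catch:

* **Shared haplotype pair**: two nominal congeneric species share their
  ancestral sequence, and one sample of the second is an exact copy of
  a sample of the first. This yields exactly one zero-distance species
  pair and reciprocal non-monophyly — *without* planting a cross-species
  copy at congeneric distance inside one species, which would have
  triggered a spurious deep-split flag in the recipient.
* **Deep intraspecific split**: half of one species' samples descend
  from an extra branch placing the two lineages 5% apart (expected),
  above the 3% flag threshold but below congeneric divergence, so the
  species stays monophyletic while being flagged.
* **Orphan lineage**: an unnamed terminal ("*Genus* sp.") at 10%
  expected distance from its nearest exemplar and absent from the
  panel, so assignment must return `undetermined`.

What the simulator does **not** emulate: indels (beyond optional
terminal truncation to fragment lengths), rate heterogeneity among
sites or lineages, base-composition bias, coalescent variance,
gene flow and introgression, sequencing error, and contamination. A
green test on simulated data therefore establishes that the *analysis
logic* recovers a known structure, not that the pipeline is robust to
every artifact of real libraries.

## Numerical choices

* Degenerate inputs: p-distance over zero comparable sites is masked;
  an all-masked query is `unalignable`; fewer than three taxa is fatal
  for NJ; masked matrix cells entering NJ are imputed with the maximum
  observed distance, with a warning.
* Duplicate definition is `(accession, marker, sequence)`. Identical
  sequences from distinct samples without shared accessions are *not*
  duplicates — shared haplotypes are biological signal the audit
  exists to find.
* The fragment filter is alignment-based (≥150 comparable sites at
  ≥60% identity against a per-marker anchor) rather than a length
  cut-off, because genuine fragments down to ~245 bp belong in the
  library while random sequence matches an anchor at only ~25%.
* The NUMT screen picks, per COI record, the forward reading frame with
  the fewest internal stops and flags records whose best frame still
  contains one; >20% ambiguity codes make a record `unscreenable`.
* All reported distances are rounded to one decimal as percentages;
  matrices keep full precision internally.

## Known limitations

Exact reproduction of distance statistics computed by other tools can
differ in the second decimal depending on whether pairs are aligned
independently (our default) or through one multiple alignment per gene
(`msa` mode, with the alignment supplied externally); both modes are
provided because published workflows rarely state which convention they
used. The GenBank flatfile reader is deliberately minimal (LOCUS /
FEATURES / ORIGIN, single-line qualifiers) — it ingests standard
nucleotide flatfiles but is not a general-purpose parser. Assignment
does not attempt hybrid or introgression detection: a query carrying an
introgressed mitochondrial genome will be confidently assigned to the
donor lineage, which is exactly why exclusion lists exist.
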