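---
title: "Building species-level genome catalogs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building species-level genome catalogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcatalog)
```

# Overview

`gutcatalog` implements the computational core of large-scale microbial
genome cataloguing: starting from thousands of assemblies — isolate
genomes and metagenome-assembled genomes (MAGs) — it filters them by
quality, groups them into species at the 95% average nucleotide identity
(ANI) boundary, selects a best representative per species, dereplicates
near-identical conspecific genomes, summarises each species' gene content
as a pan-genome, catalogs intraspecies single-nucleotide variants (SNVs)
against the representative, and reports diversity statistics. Because the
full public collections behind such catalogs are far beyond desk scale,
the package ships a synthetic-collection generator with planted ground
truth, so every stage can be validated end to end.

# Quality model

A genome's quality score is

$$\mathrm{QS} = \mathrm{completeness} - 5 \times \mathrm{contamination},$$

with both terms in percent (as estimated upstream by marker-gene tools;
those estimates are *inputs* here, not something the package computes). A
genome is admitted when completeness > 50, contamination < 5 and QS > 50,
all three comparisons strict: a genome at exactly 50.0% completeness or
exactly 5.0% contamination fails. The Genomic Standards Consortium
"high-quality" tier additionally requires completeness > 90,
contamination < 5, the 5S/16S/23S rRNA genes, and at least 18 of the 20
standard tRNAs.

Representatives are ranked by

$$\mathrm{Score} = \mathrm{completeness} - 5 \times \mathrm{contamination}
  + 0.5 \times \log_{10}(N50),$$

with isolate genomes always outranking MAGs regardless of score. The log
base is not fixed by convention in the dereplication literature; we use
base 10 (the magnitude that makes the N50 term a small tie-breaker
against the percent-scale quality terms) and expose it as a parameter.

Strain heterogeneity is estimated from a read pileup as the percentage of
qualifying positions (depth ≥ 10 after discarding bases with quality
< 30) whose minor-allele fraction reaches a threshold (default 0.2). At
least 100 qualifying positions are required; otherwise the estimate is
flagged insufficient rather than returned. This is a deliberate
simplification of codon-aware polymorphism callers, which count
nonsynonymous changes over coding positions: our estimator is
annotation-free and treats all positions alike, and the minor-allele
threshold is a package default, not an inference of any published tool's
internal setting.

# Distance kernel

Sketching follows the MinHash bottom-s construction: canonical k-mers
(the lexicographic minimum of a k-mer and its reverse complement) are
hashed with a seeded 64-bit mixing hash, and the s smallest distinct
hashes form the sketch (defaults k = 21, s = 1000). Hashes are truncated
to 53 bits so they round-trip exactly through R doubles. The Mash
distance between sketches is

$$d = -\tfrac{1}{k}\,\ln\!\frac{2j}{1+j},$$

where j is the Jaccard index estimated from the merged bottom-s sketch;
zero shared hashes give d = 1 by convention.

ANI and alignment fraction (AF) are estimated by fragment mapping: each
genome is cut into non-overlapping 1,000-bp fragments, each fragment is
anchored onto the other genome by shared 15-mers (diagonal voting over
both orientations, at least 5 anchors), and scored by column comparison
on the winning diagonal. Fragments overhanging a contig end are scored on
the mapped portion only (minimum 100 bp overlap). ANI is the mean mapped
fragment identity pooled over both directions; each direction's coverage
is mapped length over genome length, and AF follows the configured
coverage mode: `"larger"` (the default, the larger of the two directional
coverages), `"smaller"`, or `"query"`. The fragment length of 1,000 bp
suits the 50–500 kb genomes this package typically handles; tools built
for multi-megabase genomes default to ~3 kb fragments, which here would
leave too few fragments per genome.

The published procedure uses a ≥ 30% AF rule in two places (cluster
membership and cultured-status matching) without stating which genome's
length anchors the fraction; we therefore expose the convention as a
parameter. Cluster membership uses `"larger"`; cultured-status matching
anchors coverage on the species representative (`"query"`), so that a
short external reference covering little of the species genome cannot
qualify as a match.

# Species clustering

Clustering is two-stage. Stage one groups genomes by single-linkage on
Mash distance at 0.10 — a recall-oriented pre-filter whose only job is to
avoid splitting a true species across groups. Stage two is greedy
centroid clustering within each primary group: genomes are ranked by
representative score (isolates first, ties broken by genome id); the
top-ranked unassigned genome seeds a cluster and every unassigned genome
with ANI ≥ 95 and AF ≥ 0.30 to the seed joins it. The seed is the
representative, which makes representative-selection semantics exact by
construction and keeps the procedure deterministic — the reason we prefer
greedy clustering over graph linkage for this stage.

For collections larger than a chunk size, genomes are shuffled with a
seed, chunks are clustered independently, chunk representatives are
pooled and re-clustered, and each non-representative genome follows its
chunk representative into the final cluster. How pooled re-clustering
should interact with isolate priority when chunks disagree is not
specified by the published procedure; "members follow their
representative" is the consistent reading we adopt. On collections whose
species are separated by several ANI points from the 95% threshold,
chunked and unchunked runs give identical partitions (asserted by test).

Conspecific dereplication collapses genomes at 99.9% ANI (greedy, in
score order), then keeps at most one genome per sample. The per-sample
rule affects frequency counting and rarefaction input only — catalog
membership is untouched. Intraspecies structure is summarised by
complete-linkage hierarchical clustering on Mash distances, cut at 0.03
(≈ 97% ANI) and 0.01 (≈ 99% ANI); singleton species report one cluster,
flagged. Clustering agreement is quantified by the adjusted Rand index
computed from the pair-counting contingency table.

# Pan-genomes

Protein clustering is greedy and incremental: sequences sorted by
decreasing length; each sequence joins the earliest-founded cluster whose
centroid it matches at the target identity over ≥ 80% of the shorter
sequence, else founds a new cluster. Identity is matches over alignment
columns of a glocal alignment — global on the shorter sequence, local on
the longer — computed with Biostrings' pairwise aligner; this
approximates the shorter-sequence coverage mode of the clustering tools
used at catalog scale. Per-species pan-genomes cluster at 90% identity;
the presence matrix is boolean with paralogs counted once (no paralog
splitting); gene clusters with presence ≥ 90% are core, < 10% rare, the
rest intermediate. The "intraspecies" profile admits only near-complete
genomes (completeness ≥ 90) and requires ≥ 10 conspecific genomes.
Normalized pan-genome size divides the number of gene clusters by the
representative's gene count. Catalog merging co-clusters the union of two
centroid sets and reports the overlap and the percent increase over the
baseline catalog, rounded to the nearest integer. One engine performs
both the per-species and the catalog-scale clustering here, so absolute
cluster counts may differ from pipelines that used different engines at
the same identity.

# SNV catalog

Members are aligned to their species representative by
anchor-chain-and-extend: unique 19-mers of the representative anchor the
member on both strands; collinear anchors are chained; equal-length
inter-anchor gaps are compared column-by-column, unequal small gaps are
closed by Needleman–Wunsch; chains are extended into unanchored tails
with an X-drop rule (the whole tail is committed when the extension
reaches a contig boundary without the score collapsing, so substitutions
at contig edges are not lost). Blocks are filtered to a one-to-one
mapping by keeping, in decreasing score order, only blocks that overlap
no kept block on either axis — the analogue of reference- and query-side
repeat filtering — so no representative base is covered twice.

Substitutions are every aligned column with differing non-gap bases,
reported on the representative's forward strand. Single-base insertions
and deletions are never counted as SNVs, and multi-base indels only break
columns. A locus/alternate-allele pair enters the species catalog only
when ≥ 2 conspecific members carry the alternate allele; species need
≥ 3 conspecific genomes. When one member carries two different alternate
alleles at a locus across its contigs (a contamination artifact), each
allele is tallied independently. SNVs are flagged continent- or
genome-type-specific when all carriers share one continent or type;
continent-specific counts are normalized by the number of genomes from
that continent.

Pairwise SNV density gates on near-complete genomes (≥ 90% completeness),
≥ 10 conspecific genomes, and caps species at the 1,000 best genomes by
representative score. Density is substitutions per kilobase of *aligned*
representative sequence by default; whether the original analyses
normalized by aligned length or genome length is not stated, so the
denominator is a switch (`denominator = "aligned"` or `"genome"`).

# Diversity statistics

Geographic diversity is the Shannon index over the per-continent
proportions of samples containing the species; proportions are
renormalized over continents with non-zero prevalence before the entropy
(natural log). Neither the renormalization nor the log base is pinned
down by the published description, so both are options; renormalized
natural-log is the default, bounded by ln(number of continents).
Rarefaction curves average cumulative distinct species over random genome
permutations (default 100 replicates, seed mandatory); the hypergeometric
closed form $E[S_n] = \sum_s (1 - \binom{N-N_s}{n}/\binom{N}{n})$ is
provided as an independent check. Classification improvement is
$(p_{new} - p_{ref})/p_{ref} \times 100$ per sample, undefined (flagged)
when $p_{ref} = 0$. Phylogenetic diversity is the branch-length sum;
cultured PD sums the subtree spanning the cultured leaves (paths between
cultured leaves; a single cultured leaf spans nothing), uncultured-
exclusive PD is the difference, and uncultured monophyletic groups are
the maximal internal nodes whose descendant leaves are all uncultured.

# The synthetic collection

The generator emulates exactly the structure the analysis assumes. All
species ancestors derive from one root sequence by substitution at the
inter-species divergence (default 0.10 per species, so every
inter-species pair is ≥ 10% diverged — safely below 95% ANI; configs
with divergence ≤ 0.05 are rejected as violating species separability).
Conspecific genomes mutate the ancestor at the intraspecies SNV rate
(default 0.002/bp; every planted substitution is recorded with its
carrier), are fragmented into 4–8 contigs, and degraded by deleting a
contiguous block at a contig boundary (default 0–20% of the genome), so
completeness maps exactly onto the retained fraction. Contamination, when
enabled, injects whole contigs from another species' ancestor — the
binning-error mechanism quality filtering guards against. Genomes are
labeled isolate with probability 0.2, samples receive continents i.i.d.
with configurable weights, and one sample may contain genomes of several
species. Default genome length is 100 kb and collections are a handful
of species with 10–15 genomes each (the validation suite and the
acceptance script use 40-kb genomes and 3–5 species so the full pipeline
runs in seconds to a few minutes on one CPU).

The truth object records species labels, planted SNVs with their
survival through deletion, per-genome contig-to-ancestor interval maps,
gene-family presence, and true deleted/contaminated fractions.
`truthSnvCatalog()` derives the expected SNV catalog for a species purely
from this bookkeeping — no alignment — which makes exact
precision/recall checks of the SNV pipeline possible.

What the generator does **not** emulate: read-level sequencing error,
realistic gene synteny and operon structure, assembly-graph artifacts
(chimeras, collapsed repeats), ambiguous bases, and horizontal transfer.
Passing tests on synthetic collections therefore demonstrates the
correctness of the clustering/calling logic under the stated statistical
model, not robustness to every artifact of real assemblies.

# Numerical and reproducibility choices

All randomness flows through a single integer seed per run; generation is
byte-reproducible for a fixed config. The MinHash hash seed is a fixed,
recorded constant. Tie-breaks are deterministic throughout: genome-id
lexicographic order in score ties, leftmost target position in fragment
mapping, earliest-founded cluster in greedy protein clustering. Pipeline
stage outputs are pure functions of config + seed, asserted by checksum
replay in the manifest. Degenerate inputs are defined, not accidental:
empty collections cluster to an empty result; an empty pileup or one
with < 100 qualifying positions yields an insufficient-data flag, not an
error; singleton species report one dendrogram cluster, flagged; species
below the SNV or pan-genome gates are skipped with a logged reason.

# Known limitations

The fragment ANI estimator is not bit-compatible with FastANI, nor the
aligner with nucmer; they reproduce the decision rules (thresholds,
filters, exclusions) rather than the exact numerics of those tools.
Greedy secondary clustering depends on the score ranking; adversarial
collections with chained intermediates near the 95% boundary can split
differently from graph-based linkage (the primary Mash pre-grouping makes
this rare at realistic separations). Protein clustering is quadratic per
centroid and sized for desk-scale collections, not for hundreds of
millions of sequences. The SNV catalog is assembly-based; read-based
calling, phasing and dN/dS are out of scope, as is taxonomy assignment.
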