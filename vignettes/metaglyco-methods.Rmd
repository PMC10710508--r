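---
title: "MetaGlyco methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaGlyco methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaGlyco)
```

MetaGlyco quantifies microbial carbohydrate utilisation from long-read
metagenomes, metatranscriptomes and glycan microarrays. This vignette
is the package's own account of the methods: what each estimator
assumes, which parameters matter, how the synthetic-data generator is
calibrated, and where the design was genuinely open.

## Two-stage LCA classification

Long reads carry several genes, and genes differ in how well their
best protein hits resolve taxonomy. The package therefore classifies
in two stages. First, hits are filtered with *strict* thresholds —
identity > 65 %, e-value < 1e-10, query cover > 50 %; boundary values
are rejected because the thresholds are defined as strict
inequalities. Each gene gets the last common ancestor (LCA) of the
surviving hits' subject taxa; a gene with no surviving hit is
unclassified. Second, the read receives the LCA over its *classified*
genes only. Excluding unclassified genes (rather than letting them
drag the read to the root) is what makes the second stage an
information gain: a read with one well-resolved gene lends that
resolution to its neighbours. When the read is classified, its taxon
overrides the per-gene calls for downstream taxon-resolved profiles;
genes on unclassified reads keep their own calls, so propagation never
reduces the number of classified genes.

The LCA itself is the deepest node ancestral-or-equal to every input
taxon. It is idempotent, order-invariant, and monotone (adding taxa
can only move the result rootward) — properties the test suite checks
against a brute-force root-path-intersection oracle on random trees.

Hits are consumed as provided: the upstream aligner's own pre-filter
and any bitscore weighting are out of scope, and taxids must be
current in the supplied taxonomy (no merged-id remapping).

## Genome equivalents and species proxies

Sixteen ribosomal protein genes (L2, L3, L4, L5, L6, L14, L15, L16,
L18, L22, L24, S3, S8, S10, S17, S19) are near-universally single-copy
in bacteria and archaea, so the average number of times they occur in
a sample estimates the number of genomes sequenced. `genomeEquivalents()`
takes the arithmetic mean of the 16 per-marker gene counts; an
optional per-gene weight column supports depth-weighted counting for
workflows that average marker sequencing depth instead of counts (the
two readings coincide for unassembled reads counted once). The
count-based definition is primary in this package; both run through
one code path.

For species-level resolution, four of the markers (L3, L4, L6, S8)
are clustered at gene-specific nucleotide-identity thresholds.
Published per-gene thresholds exist but are not hard-coded here; the
thresholds are mandatory configuration with a documented default of
99 % for all four markers. Clustering is greedy centroid clustering:
sequences are processed longest-first (lexicographic id on ties) and
each joins the first centroid reached at or above the threshold.
Pairwise identity is computed from a global end-gap-free alignment
(match +1, mismatch −1, linear gap −2) as matches over alignment
columns, with the denominator floored at the shorter sequence's
length. The floor matters: a pure overlap alignment between two
*unrelated* sequences collapses to a short, near-perfect chance
overlap that would otherwise pass any identity threshold. For genuine
homologs the optimal alignment spans the sequences and the floor is
inactive.

The species-count proxy is the mean cluster count over the four
markers. Community composition uses the L6 clusters only (one marker,
so each genome is counted once), with cluster weight count 1 per gene
for metagenomes or TPM for metatranscriptomes, aggregated by the
cluster's majority-vote taxon (strictly most frequent member taxon;
ties fall back to the LCA of the tied taxa). Marker genes are pooled
across samples before clustering — per-sample clustering would make
cluster identities incomparable between samples, which defeats
composition comparison.

## Truncated average depth

Mean per-base depth is sensitive to repeats (depth spikes) and to
edge effects (depth holes), so genome abundance uses the central
truncated mean: conceptually sort the genome's per-base depth
multiset, discard the lowest and highest `floor(L(1-f)/2)` positions
(`f` = 0.8 by default, i.e. TAD80), and average the remainder. The
implementation works directly on run-length BEDGraph intervals —
sorting runs by depth and trimming by cumulative width — and equals
the per-base definition exactly; an epsilon inside the `floor` guards
against binary-float artefacts (`1 - 0.8` is slightly below 0.2, which
would otherwise under-trim genomes whose length is a multiple of 10).

Uncovered positions count as depth zero, which is why a genome-length
manifest is required whenever the depth track omits zero runs; tracks
produced with full-genome coverage reporting carry their length
implicitly. Relative abundance is the quotient of TAD and the
sample's genome equivalents: the estimated fraction of community
genomes belonging to that MAG. A covered-fraction report flags
genomes below a configurable floor (default 10 %) whose TAD rests on
few positions; the flag is advisory only, since no minimum covered
fraction is part of the abundance definition.

## Transcription metrics

TPM is rate-based: `tpm_g = 1e6 (c_g/l_g) / Σ_u (c_u/l_u)` where the
universe `u` defines the denominator. Gene length is the annotated
nucleotide length of the predicted gene, because transcripts are
recruited against predicted gene sequences. MAG genes are converted
with the *community* denominator (`magTpm()`), so a MAG's values are
directly comparable with community values and sum to at most one
million.

MAG relative transcription divides the MAG's mean SC-RBP TPM by the
sample's mean SC-RBP TPM. For MAGs missing markers the mean runs over
the markers present, with a floor of eight markers (half the set)
below which no value is emitted — a genome represented by fewer
markers gives an unstable mean, and eight mirrors the usual inclusion
rule for marker-based genome trees. By construction, MAGs that
partition a sample's SC-RBP expression have ratios summing to one.

Per-family transcription shares divide each MAG's family transcripts
by the family's sample-wide total; the unassigned remainder is
reported as "other community members". In the pipeline the family
total is the sum over community-predicted genes plus MAG genes of
that family, which guarantees the total bounds the per-MAG parts in
synthetic data where the two gene sets receive independent counts. A
family with zero transcripts is reported absent rather than as a 0/0
share. Families whose summed TPM strictly exceeds the MAG's mean
SC-RBP TPM are labelled up-transcribed: transcription above the
ribosomal baseline.

## PUL detection

A polysaccharide utilization locus couples a SusC/SusD transporter
pair with degradative carbohydrate-active enzymes. On an ordered gene
list (strand is ignored; the rule is symmetric under locus reversal)
two clauses trigger a call:

1. an *adjacent* susC/susD pair (consecutive ordinals, either order)
   with at least two degradative CAZymes within `maxGap` (default 6)
   intervening genes of the pair, or
2. at least three degradative CAZymes in which consecutive members
   are separated by at most `maxGap` intervening genes.

Degradative means GH, PL or CE by default. CBMs bind rather than
cleave and are excluded; both the inclusion of CE and the whole set
are configurable. A gene labelled both susC and CAZyme takes the susC
role for clause 1 and still counts as a CAZyme for clause 2.
Overlapping clause hits merge into one call spanning their union
(pair-triggered calls dominate the label), so each gene belongs to at
most one call. The proximity window of clause 1 is applied with the
same `maxGap` for determinism, since "nearby" is otherwise
underspecified. The test suite checks the implementation against an
independently coded brute-force rule checker on every role sequence
up to length eight, plus planted-locus recovery.

## Microarray signal processing

Glycan microarray spot signals are semi-quantitative: each antibody
has its own avidity, so values are comparable within an antibody
across samples but never between antibodies — no cross-antibody
statistic is ever derived. The chain is: (1) scale all signals so the
dataset maximum (by design a standard-control spot) is exactly 100;
(2) average the quadruplicate spots per (sample, extraction,
antibody); (3) retain antibodies whose best mean reaches 5 (non-strict,
as the threshold is defined with ≥) in at least one sample; (4) sum
the H2O, EDTA and NaOH extraction means per (sample, antibody), a
missing extraction contributing zero. Standard-control spots set the
scale in step 1 but never enter epitope tables. Filtering on replicate
means is the default; a `filterOn = "spot"` switch filters on single
normalised spots instead, for protocols that filter before averaging.
The retention filter is applied per-extraction mean (not to the
extraction-summed value), so a genuinely present epitope concentrated
in one solvent is retained.

## The synthetic-data generator

Every input has a seeded generator with emitted ground truth, and all
generators are pure functions of (parameters, seed). They emulate:

* **Taxonomy** — a random rooted tree, ranks domain through species,
  each node's parent drawn uniformly from the rank above.
* **Community** — Dirichlet relative abundances with symmetric
  concentration 3: moderately uneven, so that every genome retains
  enough coverage for depth-based estimation, consistent with
  recovered population genomes rather than the full rank-abundance
  tail of a natural community.
* **Hits** — per gene, 1–5 informative hits to the true species (70 %)
  or a same-genus species, at identities 80–100 %, e-values 1e-30 to
  1e-15, covers 60–100 % — all passing the retention filter by
  construction. A `noise` fraction of genes receives one spurious hit
  emulating protein-homology misassignment, which overwhelmingly goes
  to close relatives: same family with probability 0.95, anywhere
  otherwise, at identities 50–72 % straddling the 65 % threshold.
* **Depth** — per-base Poisson draws around `abundance ×
  genome equivalents`, run-length encoded with zero runs included.
* **Transcripts** — negative-binomial counts with expectation
  proportional to rate × length; rates log-normal (sdlog 1.5, a wide
  dynamic range), dispersion 0.01 modelling the mild technical
  overdispersion of counting reads from a single library (biological
  between-replicate dispersion is larger, but no replicates are
  simulated). Truth TPM follows analytically from the rates.
* **Loci** — PUL architectures planted at random positions among
  filler genes, truth spans recorded.
* **Microarray** — present epitopes draw per-extraction bases of
  15–60 raw units, absent ones 0.2–2, replicates at a configurable
  CV; control spots at 200–250 dominate the raw scale, so present
  epitopes normalise to ≥ 6 and absent ones to < 1.

`makeStudy()` composes everything into an eight-sample study (four
stations × surface/bottom mixed layer, per-sample abundances drawn
around a shared community base) with genome length 5 kb, 50 genome
equivalents and 2e5 transcripts per sample. These sizes keep a full
study generation-plus-pipeline run in the low minutes on a single
core while leaving every estimator's statistics intact; the
recovery-focused simulations use larger sizes (genome length 1e5,
library 1e6, 1000 reads/genes) where the corresponding checks demand
them.

What the generator does *not* emulate: sequence-level read errors,
chimeras, conserved-domain cross-family homology, uneven intra-genome
coverage (GC bias, origin effects), rRNA carry-over, or compositional
coupling between samples. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated noise
models, not robustness to every artefact of real data.

## Numerical and interface choices

* Coordinates are 0-based half-open (BEDGraph convention) everywhere
  internally; ordinals are 0-based gene indices along a read/contig.
* Readers validate strictly and report 1-based line numbers; malformed
  rows are never coerced. Write→read round trips are the identity for
  every owned format.
* All share tables sum to 1 within 1e-9; TPM universes sum to 1e6
  within 1e-6 relative.
* `runAll()` executes classify → markers → abundance → transcription →
  profiles → pul → microarray; missing inputs abort before any stage,
  a stage failure aborts naming the stage and suffixes its partial
  outputs with `.partial`. Outputs carry a provenance header (version,
  config hash, seed) and `manifest.json` records MD5 checksums;
  stages are deterministic given inputs, so re-runs are
  byte-identical. The package's interface is its exported functions;
  `inst/scripts/run-all.R` is a thin shell wrapper over `runAll()`.

## Known limitations

* The greedy clustering result depends on processing order (mitigated
  by the longest-first rule) and is a proxy for, not equal to,
  average-linkage ANI clustering.
* Genome equivalents inherit any bias in marker annotation; a missed
  marker deflates all PMG values proportionally.
* The PUL rule is architectural: it cannot distinguish degradative
  loci from syntenic false positives, and substrate assignment is out
  of scope.
* Microarray epitope abundances are semi-quantitative within an
  antibody only; extraction sums assume the three solvents partition
  the extractable epitope pool.
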