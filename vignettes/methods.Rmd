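---
title: "Models and methods behind scmethpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmethpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmethpipe)
library(data.table)
```

# Overview

`scmethpipe` processes single-cell combinatorially indexed bisulfite
sequencing data from raw read pairs to cell-type clusters and methylome
statistics. Cells are identified by the combination of three indexes --
a tagmentation barcode read as the first 8 bases of read 2, and a pair
of PCR-well indexes (i5/i7) -- rather than by physical isolation, so the
computational workflow has to solve problems that bulk pipelines do not:
correcting index sequencing errors without corrupting single-cell
identity, recognizing barcode collisions (two nuclei that end up with
the same index combination), removing PCR duplicates per cell, and
clustering cells from very sparse per-cell methylomes.

Because the datasets this kind of assay is applied to are typically
under controlled access, the package ships a complete synthetic-data
generator with recorded ground truth. Every guarantee the pipeline makes
is tested against that truth.

# The synthetic experiment

## Genomes and cytosine sites

`make_genomes()` draws two i.i.d. random genomes, one per species of a
two-species mixing ("barnyard") experiment. Two independent sequences at
GC fraction 0.4 share only ~26% per-base identity, so read-to-species
assignment is unambiguous -- which is the property the barnyard analysis
needs, not sequence realism (real genomes, repeats and CpG islands are
deliberately out of scope). Cytosine sites are indexed on both strands
with their reference context: CG when the next base on the site's own
strand is G, otherwise CH (CHG and CHH are merged throughout, matching
the merged non-CpG extraction convention). A cytosine at a chromosome
edge has no next base and is classed CH.

## Cell types

A `cell_type_profile` is a global CH methylation probability, a global
CG methylation probability, and optional marker-region overrides. The
presets follow mammalian brain conventions: neurons carry abundant mCH
(a few percent of CH sites), glia almost none, and mCG is globally high
in all types. This single global-mCH axis is what separates neurons
from glia in real window-level analyses, and it is the separation the
clustering tests exploit.

Flat per-site probabilities are sufficient for window-level clustering
but are degenerate for *site-level concordance*: two cells whose sites
are independent Bernoulli draws at the same p agree at rate
p^2 + (1-p)^2, which for p near 0.5 equals the between-type agreement.
Where tests need within-type concordance to exceed between-type
concordance, the simulated types carry block-structured marker regions
(each type strongly methylated in its own third of the genome) --
the synthetic analogue of cell-type differentially methylated regions,
which is exactly the signal the real concordance analysis measures.

## The indexing layout and collisions

`assign_cells()` deposits nuclei into PCR wells a fixed number of sort
events at a time (default 22, the regime the pipeline targets), assigns
each nucleus one of B tagmentation barcodes (default 96), and merges
nuclei that share (well, tag) into one observed barcode flagged as a
collision doublet. The per-nucleus collision probability is the birthday
bound `1 - (1 - 1/B)^(n-1)`; at n = 22, B = 96 this is 19.66%, which is
also what `expected_collision()` reports.

**Whitelist distances.** Index correction allows up to 2 substitutions.
For the correction to be provably collision-free the whitelist needs
minimum pairwise hamming distance 5; for a 3-error index to be provably
*rejected* it needs distance 6 (at distance 5, three errors aimed at the
support of a neighbouring codeword can land within radius 2 of it). An
8-base index can hold only a few dozen distance-5 codewords and about a
dozen at distance 6 -- far fewer than 96. The package therefore
generates distance-5/6 whitelists for small index sets (and uses them in
its exactness tests), and falls back to distance 3 (exact single-error
correction) for 96-entry tagmentation whitelists, where residual 2-error
ambiguity is a ~3e-5 per-read event at typical index error rates.

## Reads, conversion and duplicates

Each molecule is a genomic fragment assigned with equal probability to
the original-top (C->T converted, tag `CT`) or original-bottom (`GA`)
strand. Read 1 carries a 10-base random-priming segment of H bases
(A/C/T each 1/3) and reads the fragment's far end in PBAT
(complementary) orientation; read 2 carries the 8-base tagmentation
index and a fixed 21-base mosaic-end segment (the canonical 19-base Tn5
recognition sequence plus a 2-base pad, chosen once as a package
constant) and reads the near end directionally. True methylation states
are drawn once per (cell, site) so that all molecules of a cell agree;
conversion noise (failure rate: unmethylated C read as C;
over-conversion: methylated C read as T) is applied per molecule, so PCR
copies share it, while sequencing errors are fresh per copy. Copy counts
are `1 + Poisson(duplicate_rate - 1)`, i.e. `duplicate_rate` is the mean
number of copies per unique molecule and 1 means no duplication.

The truth SAM stores each read's interval, strand and conversion tag
(`XG:Z:CT`/`GA`, the bismark convention), plus the observed barcode
(`CB`) and the emitting nucleus (`XI`) -- the latter distinction matters
for collision doublets, whose reads legitimately carry two cells under
one barcode.

# Read processing

Demultiplexing corrects the three indexes independently (whether the
original tooling corrects jointly is unknown; independent correction is
the conservative, testable choice). A pair is assigned only when all
three correct uniquely; ambiguous corrections are rejected rather than
resolved, because a mis-assigned read corrupts a cell irreversibly
while a rejected one merely costs coverage. N bases count as
mismatches. Structural trims remove the 10-base random-priming prefix of
read 1 and bases 1-29 of read 2 (index + mosaic end); adapter trimming
removes a perfect 3' suffix match of at least 5 adapter bases and then
always the last 10 bases of read 2, which may reach into the mate's
random-priming segment.

Duplicate removal is barcode-aware with key (barcode, chromosome,
alignment start, strand). Start-only keys (no fragment end) are
appropriate for randomly primed bisulfite libraries where mate structure
is unreliable. Ties are broken by the lexicographically smallest read
name, making output order-independent.

Methylation calling uses the conversion tag: for `CT` alignments each
covered reference C yields methylated (read C) or unmethylated (read T);
for `GA` the mirror logic applies at reference G positions, recorded as
minus-strand cytosines. Context always comes from the reference, never
the read. A read base consistent with neither state (sequencing error)
yields no call.

Cell QC keeps cells with at least a configurable number of unique reads
-- the coverage floor is experiment-dependent and the package
deliberately ships no default for it -- and a global mCH below 10%,
since apparent mCH above that in mammalian tissue indicates failed
bisulfite conversion rather than biology. Cells with no CH calls have
undefined mCH and fail.

TSS enrichment is signal/background with the 200 bp window on the TSS as
signal and two 200 bp windows whose *centers* sit 1000 bp away as
background ("1000 bp away" is ambiguous between center and edge; the
centered reading is implemented and the offset is a parameter). The
score is used inversely here: successful nucleosome disruption brings an
ATAC-like enrichment back to ~1.

# Barnyard analysis

Barcodes are assigned to a species when the majority species holds at
least 90% of reads (the threshold is not stated anywhere authoritative;
0.9 is the package's configurable choice), otherwise they are mixed.
Since same-species collisions are invisible, the corrected total doublet
rate divides the observed mixed fraction by `2 pA pB`, the probability
that a random two-cell collision spans species, with pA and pB estimated
from assigned singlets. This is the standard barnyard correction; it is
slightly conservative-biased upward because same-species doublets
inflate the singlet pool and >2-cell collisions are more often mixed,
but its 95% binomial confidence interval covers the true simulated rate
across all tested conditions (2-20% collision rates, balanced and 90/10
mixes). No claim is made that it reproduces any particular published
observed/expected rate pair, whose derivation is not reconstructable
from printed counts.

Crosstalk is measured as the fraction of a singlet cell's reads aligning
to the other species. Note that with a crosstalk (read-reassignment)
rate c and species read share q, the expected measured contamination is
~c x q, since only reassignments *across* species are visible.

# Window matrices and clustering

CH methylation is summarized in non-overlapping genomic windows (250 kbp
conventional for CH, whose signal lives at gene-body scale; 50 kbp for
CG-only analyses, closer to CpG-island scale). Per cell and window the
matrix stores the methylated-call fraction and the distinct-site count;
uncovered entries are missing, not zero.

The coverage filter is two-pass and order-sensitive by construction:
first cells are kept if a fraction of *all* windows reaches the site
minimum (CH defaults 20 sites in 75% of windows), then windows are kept
if a fraction of the *retained* cells reaches the same minimum (75%; CG
defaults 5/25%/50%). A property test pins this ordering against an
exhaustive reimplementation.

Before reduction, missing fractions are imputed with the window mean
across covered cells (the least-informative fill: an imputed cell sits
at the window's center of mass; a per-cell global-mCH fill is available
as an alternative), and windows are mean-centered -- without centering
the first component is global methylation level and dominates the
reduction; centering can be disabled to match a strictly
"no normalization" reading. The SVD is exact (base `La.svd`) truncated
to 50 components; at these matrix sizes a Lanczos solver would change
nothing but the dependency list. Cells are then linked to their 30
nearest neighbours (Euclidean in component space; k = 30 is the common
community-detection default, no value being stated upstream) and the
graph is partitioned with Louvain modularity optimization under a fixed
seed, with index-ordered tie-breaks, so a given matrix and seed always
reproduce the same labels. The 2-D embedding is decorative and
pluggable; the default returns the first two component scores, and any
embedder with the same signature (e.g. a UMAP wrapper) can be passed in.

Cross-experiment merging concatenates matrices on an identical window
set with experiment-prefixed barcodes and applies no batch
normalization; tests verify that batch-free simulated batches mix to
near-maximal entropy within clusters, which is what "no normalization
needed" operationally means.

# Methylome statistics

**Saturation.** `coverage_saturation()` repeats (default) 100 iterations
of sampling 250 cells in random order, accumulating covered sites, and
reports the mean number of cells to reach 80% of the site universe.
Closed-form constructions validate it: ten disjoint 10% coverages need
exactly 8 cells; independent 20% coverages need the smallest n with
1 - 0.8^n >= 0.8, also 8.

**Region methylation.** Cluster-level pooling (total methylated / total
calls across member cells) rather than per-cell averaging, because
per-cell promoter coverage is a handful of calls and pooled fractions
are the only stable estimator. Promoter presets: the calling promoter
spans 1500 bp upstream to 1000 bp downstream of the TSS (the two
published statements of this interval disagree in sign convention; the
upstream-1500 reading is the preset and both distances are arguments),
the wide promoter 5000/2500, gene bodies +/-2000 bp flanks, all
strand-aware and clipped. Z-scores are computed per region across
clusters with the sample standard deviation; a zero standard deviation
gives z = 0, and clusters with no calls in a region are excluded from
that region's z-scoring.

**Concordance.** Cell-cell similarity restricted to promoter CG sites:
each (cell, site) is binarized to methylated iff its methylated-call
fraction is at least 0.5 (most sites carry one read; the tie at exactly
0.5 goes to methylated, a deterministic choice), and each pair scores
shared-state sites / shared sites. Independent half-methylated cells
calibrate to 0.5 = p^2 + (1-p)^2; identical cells to 1. Cluster-level
summaries are hierarchically ordered for display.

**Motif profiles.** Calls within 500 bp of motif centers are pooled per
cluster into 100 half-open 10 bp bins covering [-500, +500), the center
falling on a bin boundary (consistent with the half-open window
convention everywhere else; the alternative 101-bin layout centers a bin
on the motif). Offsets are negated for minus-strand motifs, and
out-of-bounds bins at chromosome edges are skipped. Motif *scanning* is
out of scope; centers arrive as intervals.

# Problem sizes and what the tests show

The packaged validations run on deliberately small instances: 20-100 kb
genomes, hundreds to a few thousand cells, thousands of calls per cell.
These sizes make every guarantee checkable exactly against ground truth
(brute-force duplicate keys, per-site state equality, exhaustive filter
evaluation) while keeping the full suite in the minutes range. What
passing them shows is that the *algorithms* are correct under the
statistical structure the generator emulates -- index errors,
collisions, duplication, conversion noise, type-specific methylation.
What they cannot show is robustness to properties of real data the
generator does not model: repetitive sequence and mapping ambiguity,
coverage biases, chimeric reads, indels, batch effects, or cell types
that differ more subtly than the presets. The clustering acceptance
threshold (ARI >= 0.9 on three types at ~6-sigma multivariate
separation) is a correctness floor for well-separated types, not a
sensitivity claim.

# Known limitations

- Quality scores are constant; no quality-based trimming or calling.
- Single-end treatment of read pairs downstream of demultiplexing; no
  overlap clipping or M-bias handling.
- The doublet correction documents its own model (see above); printed
  rates from any specific experiment are not reproduction targets.
- The simulator emits no indels or chimeras, and its genomes are
  compositionally uniform.
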