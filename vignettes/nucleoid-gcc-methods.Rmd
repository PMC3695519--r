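---
title: "Methods: GCC analysis of a circular bacterial nucleoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GCC analysis of a circular bacterial nucleoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoidgcc)
```

# The problem

Genome conformation capture (GCC) is an unbiased proximity-ligation assay:
cross-linked chromatin is digested with a restriction enzyme (a 4-cutter
such as HhaI, recognizing GCGC and cutting after the third base), diluted,
ligated, and the ligation products sequenced as read pairs. Each uniquely
mapped read pair reports one spatial contact between two restriction
fragments of the circular chromosome. Because no enrichment step is
applied, the library also preserves DNA dosage information — in
fast-growing bacteria, overlapping replication rounds create an
origin-to-terminus copy-number gradient of around 3:1 that any analysis of
contact frequency has to account for.

This package implements the full desk-side analysis for such an
experiment on a single circular replicon: network assembly with an
empirical noise threshold, copy-number estimation and correction, contact
and domain metrics, a circular permutation test for the spatial clustering
of genomic region sets, and the integration of expression changes with
spatial structure. A synthetic-data module generates every input with
known ground truth, so all stages are testable without any sequencing
data.

# Coordinate model

All coordinates are 0-based, half-open and circular; file readers convert
at the boundary (BED is native; SAM's 1-based positions are shifted on
read). `digest_genome()` scans the doubled sequence so motif occurrences
wrapping the coordinate origin are cut like any other, and overlapping
occurrences (GCGCGC) each cut. The enzyme's 2-nt overhang is ignored: a
single blunt cut coordinate defines fragment boundaries, because fragment
identity — not end chemistry — is what matters downstream. With $k \ge 1$
cuts there are exactly $k$ fragments partitioning the circle; fragment
midpoints are `start + floor(length/2)`.

`circular_distance(a, b, L) = min(|a-b|, L-|a-b|)` is the metric used
everywhere; all separations therefore live in $[0, L/2]$.

# Network assembly and the ligation-control cutoff

`assemble_network()` keeps read pairs with both ends uniquely mapped,
increments the count of each unordered fragment pair, and routes pairs
flagged as ligation controls (exogenous DNA spiked before ligation) to a
separate control network. Duplicate read pairs are counted, not removed —
no deduplication step is part of the procedure. The invariant
`retained + dropped + controls = input` is checked in the tests on every
run.

Random inter-molecular ligation produces false contacts; the spiked
control DNA measures that background directly. `derive_cutoff()` takes
the **maximum count observed among control interactions** and
`apply_cutoff()` retains genomic interactions with counts strictly above
it. The maximum is deliberately conservative: the controls empirically
bound what random ligation can produce in this library. Two alternatives
are exposed for sensitivity analysis: a quantile of the control counts,
and a per-million scaling for libraries of very different depth (the
default is the global raw-count rule).

Interactions are classified as `self` (one fragment), `adjacent`
(circularly consecutive fragments), `short` (midpoint separation below
800 bp) or `long` (800 bp up to half the genome). The 800-bp default
separates trivially ligated neighbours from genuine long-range contacts
and is the threshold used by every downstream exclusion rule.

Replicate concordance uses Cohen's kappa on binary detection vectors.
The pair universe matters: over *all* possible fragment pairs the huge
number of absent–absent cells inflates agreement, so
`network_presence()` defaults to the union of pairs detected in either
network, and the universe is always an explicit argument.

# Copy number

`depth_windows()` counts read starts in 1000-bp windows and records each
window's GC fraction. `copy_number_profile()` divides each window's count
by the median count of windows with similar GC (bins of width 0.05 over
the observed range, bins with fewer than 10 covered windows merged with
neighbours) and rescales so the genome-wide median is 1. No segmentation
is attempted: only the relative per-window values and the Ori:Ter profile
enter the downstream mathematics, so a median-per-GC-bin normalization is
sufficient and keeps the estimator transparent.

`ori_ter_ratio()` averages the profile within a flank of the origin and
of the terminus. The flank should stay small relative to the genome so
the means sample the gradient's endpoints; the default 100 kb is about 2%
of a 4.64-Mb chromosome, and analyses on scaled-down synthetic genomes
use the same 2% fraction (`L/50`).

`correct_binned_interactions()` tallies (by default long-distance)
interaction counts into 10-kb bins — an interaction with endpoints in two
bins contributes to both — and divides by the number of fragment
midpoints in the bin times its mean copy number. This is the 1-D per-bin
correction used to ask whether contact frequency merely tracks dosage;
for contact matrices a product-form correction
($M_{ij} / \mathrm{cn}_i \mathrm{cn}_j$) is available via the `cn`
argument of `contact_matrix()`.

# Contact and domain metrics

* `contact_matrix()`: symmetric binned count matrix (50-kb bins show the
  Ori and Ter domains; 20-kb bins resolve candidate boundaries); totals
  are conserved exactly.
* `crossing_profile()`: for each interaction, the fragments whose
  midpoints lie strictly inside the **shorter arc** between the endpoint
  midpoints are crossed by it. The shorter arc is the maximum-likelihood
  loop path on a circle; when the two arcs tie exactly (antipodal
  endpoints) both count at half weight. A hard macrodomain boundary would
  appear as a dip in this profile. Weighting by read counts is the
  default; a binary per-interaction mode is available.
* `loop_lengths()`, `partner_counts()`: count-weighted contact-distance
  distribution and distinct partners per fragment (a self-interaction
  makes a fragment its own single partner; read counts never change
  partner counts).
* `find_peaks()`: bins above `median + 3*MAD` of the covered bins,
  adjacent peak bins merged (including across the origin wrap). The rule
  is a robust-outlier formalization of peaks that would otherwise be
  labelled by eye; it refuses to run on fewer than 10 covered bins.

# The clustering permutation test

The central question: does a set of genomic regions (binding sites for
MatP/matS, SeqA, SlmA, a NAP, or a regulated gene set) sit in an unusual
interaction environment, and in particular do its members contact *each
other* more than expected? Two statistics are tallied from the
cutoff-applied network after excluding self and short-distance
interactions (which are trivially enriched near any region):

* **total interaction frequency** — summed read counts of interactions
  touching at least one region (each interaction counted once, however
  many regions it touches);
* **clustering frequency** — summed counts of interactions whose two
  endpoints overlap two *different* regions. An interaction whose both
  ends fall inside the same region counts toward total but not
  clustering.

"Frequency" means summed read counts; a binary distinct-interaction mode
exists for sensitivity analysis. Observed statistics are compared with
`n_random = 1000` randomized region sets under two nulls:

* **RS (random spacing)**: each region gets an independent uniform start
  and keeps its length; randomized regions may not overlap one another
  (real binding-site sets are disjoint), enforced by whole-set rejection
  sampling and switchable via `allow_overlap`.
* **CLS (conserved linear spacing)**: the whole configuration is rotated
  by one uniform offset, preserving every pairwise circular gap exactly.
  A rotation (no reflection) is the operation that realizes
  "distances maintained" on a circle.

Empirical p-values use the plain frequency convention
`p_high = #(null >= obs)/N`, `p_low = #(null <= obs)/N`. The add-one
estimator `(r+1)/(N+1)` is provided and used in calibration studies,
where `p = 0` artifacts would distort uniformity checks. Under a fixed
seed the draw stream is fully reproducible (all draws for the first
method, then the second, from one stream).

Calibration and power are verified in the test suite: across 200
no-signal networks the fraction of upper-tail clustering p-values at or
below 0.05 stays in the binomial band around 0.05 for both nulls, and 10
planted regions with 10-fold pairwise contact enrichment on a 500-kb
genome are recovered at `p_high <= 0.005` in at least 19 of 20 generator
seeds. The planted-recovery experiment switches off the Ori-domain
enrichment and the dosage gradient so that the null reflects placement
alone; with them on, random region sets landing near the origin make the
RS null heavy-tailed — a genuine property of such data worth remembering
when interpreting small p-values near Ori.

# Expression and genome order

`log2_ratios()` floors levels at 1 unit of the expression scale, combines
replicates by geometric mean (ratios are multiplicative) and computes
log2 condition ratios; `call_regulated()` calls genes up or down at
|log2| ≥ 1 with replicate sign consistency. The exact significance rule
used for the original regulated-gene lists is not reproducible here, so
the threshold is an explicit tunable and all downstream analyses are
validated against synthetic truth rather than particular gene counts.

`binned_expression_null()` averages a per-gene value in 50-kb bins and
compares with per-bin 2.5–97.5% envelopes from shuffling values over the
fixed gene positions ("randomized genomes"). `expression_acf()` computes
the standard sample autocorrelation of ratios along gene order; the
ordering is treated as linear, since for lags far below the gene count
the circular wrap contributes negligibly. `gc_expression_correlation()`
checks that expression changes are not a base-composition artifact. The
up/down gene sets feed `clustering_test()` unchanged, which is exercised
end-to-end in the tests.

# The synthetic-data generators

`synth_config()` fixes the ground truth; each generator draws from a
stream derived from the master seed (offsets: genome +1, network +2,
controls +3, depth +4, expression +5), so every stage is individually
reproducible. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `L` | 500 kb | desk-scale genome; all rates/ratios below are scale-free |
| `mean_spacing` | 256 bp | expectation for a 4-cutter site (4^4) |
| `R` | 3 | fast-growth Ori:Ter dosage ratio |
| gradient | $R^{1 - d_\mathrm{ori}/(L/2)}$ | monotone Ori→Ter decay with exact endpoint ratio R |
| `gamma` | 1 | contact decay $(d+1)^{-\gamma}$ |
| `lambda0` | 1000 | library of ~10^5 informative long-range counts |
| `alpha`, `ori_radius` | 4, 0.1 L | high-contact Ori domain |
| `m_regions`, `region_length`, `beta` | 10, 1 kb, 10 | planted clustered set |
| `control_pairs`, `control_rate` | 200, 1 | low-count uniform ligation spike |
| `depth_mean` | 50 / kb-window | coverage at which gradient recovery is tested |
| `n_genes` | 0.9 / kb | enterobacterial gene density |
| `ar_rho`, `ar_sd` | 0.85, 0.5 | gene-order autocorrelation; background within two-fold |
| blocks | 20 genes at ±3 | strongly regulated contiguous regulons |
| `rep_sd` | 0.05 | tight replicate agreement of normalized arrays |

Counts are Poisson by default; an `overdispersion` knob switches the
network counts to negative binomial (`var = mu + d*mu^2`), and the
pipeline's statistics — count sums and permutation ranks — are
insensitive to mild overdispersion. The synthetic genome plants GCGC
motifs at geometric spacing in a G-free A/C/T background whose C fraction
varies with a 25-kb period: GC then varies across windows (exercising GC
normalization) without being confounded with chromosome-scale position —
a genome-wide GC trend would alias into the dosage gradient and is a
known limitation of GC-median normalization, not something the generator
should build in silently.

What the generators do **not** emulate: read-level errors and mappability
structure (uniqueness flags are inputs), PCR duplicate structure,
replication-fork dynamics, multi-replicon genomes, and microarray
normalization artifacts. Passing tests therefore demonstrate the
statistical machinery on data matching the model's assumptions, not
robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* Canonical pair keys (`frag_a <= frag_b`) everywhere; empty networks are
  explicit empty results, not errors, except where a statistic is
  undefined (loop lengths of an empty network).
* An empty control network yields cutoff 0 with a warning.
* Kappa is `NA` with a warning when both raters are constant and equal
  (expected agreement 1).
* `find_peaks()` refuses fewer than 10 covered bins;
  `copy_number_profile()` refuses all-zero depth; GC bins with fewer
  than 10 covered windows merge forward, a trailing undersized group
  merging backward.
* RS placement aborts after 10,000 whole-set rejections — region sets
  covering a large genome fraction should set `allow_overlap = TRUE`.
* Antipodal crossing arcs get half weight each; binned quantities use
  `ceiling(L/bin)` bins with a short final bin.

# Problem sizes used in the checks

Test-suite studies run at: 100-kb genomes with 200 randomizations per
null for the calibration study (200 tests), the stated 500-kb genome
with 1000 randomizations over 20 seeds for planted-cluster recovery, a
2-Mb genome for dosage-gradient recovery (so the 2% flank averages
enough windows for a stable ratio), 4000 genes for ACF recovery, and 40
generator seeds for planted-block detection. These sizes give each
stochastic check a comfortable margin relative to its tolerance while
keeping the suite fast.
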