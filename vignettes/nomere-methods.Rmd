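---
title: "Models and methods behind nomere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nomere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nomere` analyses single-cell NOMe-seq data — joint profiles of endogenous
CpG methylation (WCG context) and GpC-methyltransferase-marked chromatin
accessibility (GCH context) — together with matched single-cell RNA-seq, in
the setting of mouse preimplantation embryos. This vignette explains the
statistical models the package implements, the choices made where the
underlying procedures are genuinely open, and what the synthetic-data
generator does and does not emulate.

## Quantification model

Every methylation or accessibility level in the package is a *read-pooled
ratio*: the sum of methylated read counts (C) over the sum of all covered
reads (C + T) across the sites of a region. This is deliberately not the
mean of per-site ratios; low-coverage sites contribute proportionally to
their read support. Regions with no covered site are missing, never zero.

Region geometry conventions:

* Cytosine positions are 1-based (the bisulfite-caller dialect); all
  intervals are 0-based half-open (BED). Conversion happens only at
  read/write boundaries.
* WCG and GCH sites are keyed by (chromosome, position, strand) and never
  strand-collapsed; the GpC mark is intrinsically strand-specific.
* TSS metrics use strand-aware windows: methylation over 1 kb upstream to
  0.5 kb downstream of the TSS, accessibility over 200 bp upstream to
  100 bp downstream.
* Genic profiles run from 2.5 kb upstream of the TSS through the gene body
  to 2.5 kb downstream of the TES: flanks in base space (150-bp windows at
  50-bp steps, 48 per flank), the body in fraction space (100 equal
  fractions, 2-fraction windows at 1-fraction steps, 99 windows). The
  allele-resolved variant uses 500/100 bp flank windows (21 per flank) and
  10/2 fraction body windows (46).

Per-window profile-versus-expression correlations across genes within one
cell are available plain and site-count-weighted; the weighted variant
(weights = covered sites per gene-window) is the default. Expression enters
these profile correlations as `log2(TPM + 1)` — a standard variance
stabilization; the transform is configurable.

## NDR detection

GCH calls of all cells in a group (typically a developmental stage) are
pooled per site. 120-bp windows at 20-bp spacing are compared against the
genomic background with a 2x2 chi-square test — window (C, T) versus the
remaining genome-wide (C, T) — with 1 degree of freedom and no continuity
correction. At the extreme significance cutoff in force (p <= 1e-15) and
the read counts involved, the Yates correction is immaterial; an exact
binomial oracle agrees with the chi-square ranking at Spearman rho > 0.99.

"Significantly elevated" is implemented as a post-hoc direction filter on
the two-sided statistic: only windows whose GCH rate exceeds the genomic
rate are eligible. Kept windows that overlap or are book-ended merge into
regions (a gap-tolerance argument exists, default 0); merged regions must
be at least 140 bp long — so a single isolated 120-bp window can never
pass — contain at least 5 distinct GCH sites, and avoid the blacklist by
at least 1 bp. Sub-threshold windows between two significant windows break
a region by default; the gap argument allows sensitivity analyses. Window
tiling is phased at chromosome offset 0 for determinism. Each NDR reports
the minimum constituent-window p, its distinct-site count, and the pooled
accessibility over the merged interval.

Classification against gene models: an NDR overlapping a TSS point is a
`TSS_NDR`; otherwise within 2 kb of the nearest TSS, `Proximal_NDR`;
otherwise `Distal_NDR`.

## CRE-gene linking

Candidate pairs are all (NDR, gene) combinations with the NDR within
100 kb of the gene (upstream of the TSS through downstream of the TES).
Filters, applied before testing: per-cell NDR observations with fewer than
3 covered sites are set missing; NDRs observed in fewer than 25% of cells
are dropped; NDRs and genes with zero variance across the remaining cells
are dropped ("nonvariable" is operationalized as exactly zero variance —
no threshold is imposed); genes expressed (TPM > 0) in fewer than 5 cells
are dropped.

The association statistic is a weighted Pearson correlation with weights
equal to the unique covered sites in the NDR per cell (WCG sites for
methylation links, GCH sites for accessibility links):

r_w = sum w (x - xbar_w)(y - ybar_w) /
      sqrt(sum w (x - xbar_w)^2 * sum w (y - ybar_w)^2)

Expression enters untransformed (TPM). Significance is a two-sided
Student's t-test with t = r sqrt((n-2)/(1-r^2)) and n = number of
contributing cells — the weights do not shrink the degrees of freedom;
this is the simplest reading of a t-test on a weighted correlation, and an
effective-sample-size alternative would be strictly more conservative.
p-values are BH-adjusted across all candidate pairs of one invocation (one
family per modality and gene set); links with FDR < 0.1 are significant,
signed by r_w.

The companion gene screen (for, e.g., ZGA genes: 2-cell versus zygote) is
a Wilcoxon rank-sum test on `log2(TPM + 1)` with BH adjustment combined
with an inclusive mean-TPM fold-change cutoff (>= 4 at FDR < 0.01 by
default); a user-supplied gene list can substitute for the screen.

Overlap enrichment of a region set against an annotation is
`log2(observed / expected)` with the expectation from length-matched
regions placed uniformly on the genome (excluding the blacklist), averaged
over draws; zero counts trigger add-one smoothing, flagged in the result.

## TF activity

Raw activity of a TF in a cell is the pooled GCH ratio over the TF's
binding sites (motif hits merged and extended ±50 bp from the center;
cells covering fewer than 10 sites are missing). The background
distribution resamples site sets of the same size, uniformly without
replacement, from a pool of candidate sites (the 101-bp site universe over
distal NDRs); each background set is evaluated in the same cell on that
cell's covered sites, so coverage is matched by construction. Activity is

z = (ACC_TF - mean(ACC_bg)) / sd(ACC_bg)

with the sample (n-1) standard deviation over 1,000 permutations; z is
missing (not infinite) when the background is degenerate. Whether the
original procedure permuted site labels within a cell or resampled site
sets is not determinable from its description; the resampling reading
preserves both the set size and the pool's accessibility distribution, and
is isolated behind `sample_background()` so alternatives are pluggable.
Background sets are drawn once per TF and reused across cells, which makes
an independent same-seed reimplementation reproduce z exactly.

## Lineage reconstruction

Methylation maintenance failure at replication partitions methylation
complementarily between daughter cells. In bin space (1-Mb bins, bins with
fewer than 3 covered sites discarded per cell) this leaves a signature in
the raw (uncentered) pairwise Pearson correlations between blastomeres of
one embryo, computed pairwise-complete with a minimum of 10 shared bins
(the floor is a stability choice; the source procedure states none).

At the 4-cell stage the two daughters of the same 2-cell blastomere are
the most *anti*-correlated pair; the package enumerates all 3 perfect
matchings of the 4 cells and minimizes the within-pair correlation sum. At
the 8-cell stage sisters (separated only by the well-maintained third
cleavage) are the most *positively* correlated, so the 105 matchings are
searched maximizing the within-pair sum; pair-level correlations (mean of
the 4 inter-cell values) are then minimized over the 3 pairings of the 4
sister pairs to recover the grandmother groups, because cells of the same
grandmother but different mothers are anti-correlated. The search is
exhaustive — exactness is free at 3 and 105 candidates — with
deterministic lexicographic tie-breaks, flagged when they fire. A
transcriptome variant (Spearman on `log2(TPM+1)`, maximization at both
levels) is provided, default off.

Heterogeneity analyses assign every unordered cell pair to
intra-embryonic / inter-embryonic / same-mother / same-grandmother classes
(same-grandmother excludes same-mother pairs) and compare class
distributions of Spearman correlations with Welch t-tests.

## CNV inference

From expression: genes are ordered along the genome, each gene's
`log2(TPM+1)` is replaced by the moving average over the 50 genes upstream
and downstream (plus itself — immaterial at this width — truncated at
chromosome boundaries), and values are centered per cell. The log
transform before averaging is a stabilization choice; the profile is a
visual/confirmatory instrument, not a discrete caller.

From bisulfite reads: raw counts in 1-Mb bins are divided by the
mappable fraction (bins under 0.75 masked), normalized by the median count
of bins in the same GC decile, then divided by the genome-wide median —
a deterministic, dependency-free correction validated by the
flat-after-correction property (a 2-fold implanted GC trend is removed).
Candidate runs are maximal consecutive stretches of bins beyond a cut
(gain > 1.36, loss < 0.67, both strict — the boundary values never
trigger); missing bins break runs; a run is called iff it spans strictly
more than 10 bins and its median passes the same cut. Requiring every bin
and the median is one concrete, conservative reading of a median-over-runs
rule; since per-bin thresholding already implies the median condition, the
gate reduces to per-bin thresholding plus the run-length rule.

## Allelic tests

Allele-tagged calls (maternal/paternal, SNP-split upstream of this
package) are summed per 0-anchored 500-bp tile, per allele, over all cells
of a stage; tiles must be covered by at least 3 cells per allele. "Sites
summed" is read as read-level C/T sums, consistent with the read-pooled
levels used everywhere else. Each tile is tested with a two-sided Fisher
exact test on [[mat_C, mat_T], [pat_C, pat_T]], BH-adjusted within one
stage-and-context family, significant at FDR < 0.01. Zero-margin tables
are defined with p = 1.

## The synthetic-data generator

The generator produces the study conditions every stage is tested under;
its defaults are fixed once and not tuned per test.

**Methylomes.** A founder zygote draws per-bin methylation (10-kb latent
bins) from Beta(30, 30). At cleavage k each bin's maintenance failure is
`delta = (1 - m_k) * |Normal(0, sigma_dev)|` with `sigma_dev = 0.15`, and
the daughters receive `m + s*delta` and `m - s*delta` (random sign s,
clipped to [0,1]) — the minimal mechanism that makes daughter deviations
complementary while conserving the mother's level in expectation.
Maintenance is *per cleavage* (`maintenance_efficiency` is a vector): with
a single efficiency applied at every cleavage, sisters would share all
variance except the final-cleavage deviation and could never be
anti-correlated — the covariance algebra forces
Cov(sisters) >= Var(founder) > 0. The observed pattern (strong sister
anti-correlation with mildly positive cross-pairs at the 4-cell stage)
requires the final cleavage's deviation to dominate; the defaults
therefore use a near-perfect first cleavage, `c(1, 0.3)` for 4-cell and
`c(1, 0.3, 0.9)` for 8-cell simulations. Under these defaults the
generator reproduces the qualitative sign pattern (sisters ~ -0.4,
cross-pairs ~ +0.25 at the 4-cell stage, sisters strongly positive at the
8-cell stage) and the rise in same-mother correlation from the 4-cell to
the 8-cell stage; the magnitude of maintenance failure in real embryos is
not quantified anywhere, so only the sign structure should be read as
biological.

**Expression.** Log-normal TPM-scale values (gene-level log-mean spread 1,
per-cell noise sd 0.6 on the log scale) with stage structure: ZGA genes'
zygote mean divided by 8, ICM/TE markers elevated 4-fold in their
blastocyst class. Columns are not renormalized to sum to 1e6 —
renormalization would couple genes and break the independent-noise
contract of the generator.

**Accessibility.** Background GCH sites methylate at `p_bg = 0.25`;
implanted 300-bp NDRs (with dedicated GpC-dense sites, ~50/kb) at
`p_open = 0.75`. Linked NDRs interpolate `p_bg -> p_open` through a
logistic of the linked gene's standardized `log2(TPM+1)` — standardizing
avoids heavy-tail leverage from raw TPM — with the logistic scale chosen
per link by a one-dimensional search so that the *predicted realized*
correlation (generating-rate correlation attenuated by binomial counting
noise) hits the target `r_true`; negative targets invert the coupling.

**Allelic and CNV.** Imbalanced tiles use rates (0.8, 0.2)
maternal/paternal; balanced tiles share a Beta(5,5) rate. Binned DNA
counts are Poisson with mean `depth * copy_ratio * gc_bias`; the default
1,000 reads per 1-Mb bin corresponds to a typical single-cell bisulfite
library (millions of reads over a ~2,600-bin genome). Expression of genes
inside CNV blocks is scaled by the copy ratio.

**What is not modeled:** read/sequence level artifacts, bisulfite
conversion errors, doublets, cell-cycle structure (and hence the
high-accessibility artifact cluster such data can contain), fragment-level
correlation between neighboring sites, and distance-decay of enhancer
effects. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under the declared generative
model, not performance on any real library.

## Problem sizes and determinism

All simulation-backed checks run on a desk-scale genome (2 chromosomes x
10 Mb; 2 x 100 Mb where a 15-bin CNV must be a small fraction of the
genome, and 2 x 250 Mb where 2,000 NDR-gene pairs must be 100-kb
separated), chosen so the full evaluation suite completes in minutes while
every scenario keeps the statistical regime of the full-scale analysis
(per-site depths, per-bin read counts, cells per stage). Every stochastic
step is seeded; a fixed seed reproduces all outputs byte-identically, and
the evaluation entry points (`ndr_operating_characteristics()`,
`lineage_recovery()`, `cre_operating_characteristics()`,
`tf_operating_characteristics()`, `cnv_operating_characteristics()`,
`allelic_operating_characteristics()`, `maintenance_sweep()`) re-derive
their streams from a single seed argument.

## Known limitations

* The mitochondrial QC fraction is computed from expression counts of a
  supplied mitochondrial gene set, approximating a read-level fraction.
* The weighted-correlation t-test uses n-2 degrees of freedom regardless
  of weight dispersion; strongly unequal weights make it slightly liberal.
* The permutation background for TF activity is drawn once per TF, not
  per cell; per-cell draws would only decorrelate scores across cells at
  1,000x the cost.
* `overlap_enrichment()`'s add-one smoothing bounds how negative a
  depletion estimate can be when the expected overlap is small.
* The run-based CNV caller cannot detect blocks shorter than 11 bins by
  construction, and a single noisy bin inside a block splits the run;
  detection rates quoted by the evaluation functions are for 15-bin blocks
  at the default depth.
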