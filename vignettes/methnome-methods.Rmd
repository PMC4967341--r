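---
title: "methnome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methnome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methnome analyses count-level bisulfite data for two-state comparisons of
the kind that arise in cellular differentiation studies — the motivating
setting is monocyte-to-macrophage differentiation, where a small set of
distal regulatory regions is rapidly demethylated, becomes nucleosome-free
and gains active-enhancer histone marks. The package covers five analytical
stages (differential methylation, NOMe-seq accessibility peaks, region
enrichment, BS/oxBS hydroxymethylation, and histone-signature clustering)
plus a synthetic-data module that plants known truth for all of them. This
vignette records the models, the defaults and why they are what they are,
and the numerical decisions a user may want to revisit.

## Conventions

All flat tables use 0-based, half-open coordinates (BED semantics); the
`GRanges` objects the package returns use the Bioconductor 1-based closed
convention, and conversion happens only in `as_genomic_regions()` /
`regions_to_frame()`. A "methylation site table" is a data frame with one
row per cytosine per sample: `chrom`, `pos`, `strand`, `context`,
`sample_id`, `meth`, `total`. Methylated fraction is `meth/total`;
sites with `total = 0` are carried but never contribute to any estimate.

Cytosine contexts follow the NOMe-seq partition (H = A/C/T): **HCG** is the
endogenous CpG readout, **GCH** the accessibility readout (the exogenous
GpC methyltransferase only reaches nucleosome-free DNA), **GCG** is
ambiguous between the two signals and therefore flagged and excluded by
every downstream consumer, and **HCH** is untouched by either enzyme and
serves as the bisulfite conversion control (`hch_rate()`). Context is
classified against the reference genome, not the read, reverse-strand
cytosines on the complement.

## Methylation calling

`call_methylation()` reduces aligned read-base records to counts. A record
contributes only if its mapping quality is at least 30 and its base quality
at least 17 — the thresholds are strict "lower than" exclusions, so the
boundary values pass — and only C (methylated) and T (converted) bases
count. CpG strand collapsing is available but off by default
(`collapse_strands`), since the original pipeline does not state whether
its caller merged strands.

## The synthetic study

The generators are pure functions of their parameters and a seed, and their
defaults are the package's model of the motivating study design:

* genome: i.i.d. bases at GC 0.4 (human-like); every cytosine catalogued
  with its context;
* methylomes: two cell states x two donors, baseline CpG methylation 0.85
  (the focal regions are highly methylated in the precursor state),
  Poisson coverage 30x, symmetric bisulfite conversion error 0.005
  (within a >= 95% conversion requirement), an optional per-donor baseline
  shift (SD 0.02) mimicking donor-dominated variance components;
* planted DMRs: blocks of 6–12 consecutive CpGs with methylation difference
  0.4 by default, 96% losing methylation in the differentiated state and
  4% gaining (mirroring a 110:4 ratio); intra-block CpG gaps are bounded at
  150 bp because focal DMRs (85–1697 bp with at least four CpGs) are
  locally CpG-dense, and a block interrupted by a long CpG-free stretch
  would not be one contiguous region;
* NOMe data: GCH sites emit at `p_open = 0.5` inside planted 500-bp NDRs
  and `p_closed = 0.05` outside, coverage 20x; GCG sites are generated but
  flagged; HCH sites emit at the conversion error rate;
* BS/oxBS pairs: `bs_meth ~ Bin(n, 5mC + 5hmC)`,
  `oxbs_meth ~ Bin(n, 5mC)`, depth 2000x (targeted amplicons);
* TFBS track: one 150-bp interval planted inside 90% of the query regions
  plus 100 background intervals per Mb;
* histone signal: three signature classes over six marks and two cell
  states (class 1 gains H3K27ac/H3K4me1/H3K4me3 and loses H3K27me3;
  class 2 shows the same gains on constitutive H3K36me3; class 3 is
  constitutively marked with H3K4me1 reduced after differentiation),
  shaped over 40 + 40 + 40 bins with Gaussian noise (SD 0.1).

What the generator does **not** emulate: read-level artefacts (alignment
error, PCR duplicates, M-bias), CpG-island structure and regional
methylation autocorrelation, copy-number and SNP effects, or read-length
coverage autocorrelation (coverage is i.i.d. Poisson per site). Passing the
recovery suites therefore demonstrates correctness of the inference given
the count model, not robustness to upstream processing artefacts.

## DMR calling

Each sample's methylome is smoothed with a tricube-kernel,
coverage-weighted running mean (`smooth_methylation()`). The window spans
at least `window_bp` (default 100 bp) and at least `min_sites` CpGs
(default 3), widening symmetrically in distance where CpGs are sparse.
The bandwidth is deliberately below the size of the smallest regions the
caller should resolve (85 bp upward): a kernel of ~70 CpGs — the scale
published for broad smoothing-based callers — averages a 6–12-CpG block
against ten times as much background, diluting a methylation difference of
0.4 to ~0.1 and making focal regions undetectable in principle. Both
scales are available through the arguments; the default serves the focal
regime.

`per_cpg_statistic()` forms the signed difference of group-mean smoothed
fractions. Its denominator is the across-sample standard error, pooled by
a running mean of the variance over +/-50 neighbouring CpGs — with two
samples per group the single-site variance estimate has ~2 degrees of
freedom, and without pooling its chi-square noise fragments candidate
regions — and floored at the 75th percentile of all site SEs so that
near-zero local variance cannot inflate the statistic. Two-sided p-values
use a standard-normal reference (conservative, since the floor biases the
denominator upward) and are Benjamini–Hochberg adjusted across all sites.
With one sample per group the statistic degrades to a z-score scaled by
`mad(diff)` and the output is flagged.

`find_dmrs()` takes maximal runs of same-sign CpGs with q-value at most
1e-4 and inter-CpG gaps of at most 300 bp. Run ends are trimmed where a
site lacks support — its smoothed difference or its own raw difference
falls below half the reporting threshold — because smoothing spills signal
onto neighbouring CpGs and those shoulder sites must not define region
boundaries (nor let a 3-CpG block masquerade as a 4-CpG region). A
candidate is reported when it retains at least 4 CpGs and the
coverage-weighted **raw** group methylation difference over its CpGs is at
least 0.3 in absolute value: the minimum-difference filter refers to the
region's actual methylation difference; the smoothed values drive
detection only. (Filtering on the smoothed mean instead would make the
filter a coin flip for focal blocks, whose smoothed mean sits near the
threshold by construction.) Both values are reported (`mean_diff`,
`smooth_mean_diff`). No region-level p-value is attached — the per-CpG
q-values are the only significance measure, matching the upstream tool's
behaviour. Because runs are defined by q-values alone and trimming only
removes end sites (nested in the threshold), the number of calls is
monotone non-increasing in both the minimum difference and the minimum
CpG count.

```{r}
library(methnome)
g <- simulate_genome(5e5, seed = 1)
dmrs <- plant_dmrs(g$sites, n_dmrs = 20, seed = 2)
meth <- simulate_methylomes(g$sites, dmrs, seed = 3)
calls <- call_dmrs(meth$table, c("mono_1", "mono_2"), c("mac_1", "mac_2"))
```

## NDR calling

`call_ndrs()` re-implements the NOMe-seq peak-calling chain: a two-state
binomial hidden Markov model segments the GCH methylation profile into
putative nucleosome-depleted regions and background; each putative NDR is
contrasted against its flanking background with a one-sided Fisher's exact
test; and empirical false-discovery rates from shuffled data gate the
final calls at eFDR < 0.01.

**HMM.** Emissions are `Bin(total_i, p_state)`; fitting is Baum–Welch
(`fit_hmm()`) from the deterministic start `p_open = 0.3`,
`p_closed = 0.02`, self-transitions 0.99 — no random restarts, so a fixed
input yields a fixed model; alternative starts can be supplied for
restarts. The log-likelihood is checked to be monotone non-decreasing (a
decrease beyond numerical tolerance is an internal error); iteration stops
at 100 rounds or an improvement below 1e-6. States are canonicalised so
`p_open > p_closed`. Decoding is Viterbi (`segment_gch()`); sites with
zero coverage are uninformative (emission probability 1 in both states).
On homogeneous (signal-free) data the two states converge toward a common
rate; the fit is flagged and the downstream gates discard everything.

**Fisher flank contrast.** Each flank spans `min(NDR width, 1000 bp)` of
background territory, clipped at chromosome bounds and at adjacent
putative NDRs. The 2x2 table is `[inside meth, inside unmeth; flank meth,
flank unmeth]` and the p-value is the exact hypergeometric upper tail
(one-sided: accessibility is definitionally *elevated* GCH methylation;
a two-sided test would admit anti-peaks). NDRs with an empty margin are
dropped and counted.

**Shuffle null and eFDR.** The null is built by permuting the per-site
`(meth, total)` pairs across GCH positions within each chromosome —
positions and the coverage multiset are preserved exactly, all spatial
signal is destroyed — and re-running segmentation and testing with the
fitted model, `n_shuffles = 20` times. For an observed p-value p,

    eFDR(p) = [(1 + #null <= p) / (S + 1)] / max(1, #observed <= p)

clipped to [0, 1] and made monotone non-decreasing in p (step-up: each
value is replaced by the minimum over all larger p). The add-one term is
the standard finite-sample permutation correction: without it, the single
best observed region beats every null draw with probability 1/(S+1) even
under a global null and would then claim an eFDR of exactly zero. With the
correction the smallest attainable eFDR for the k-th ranked call is
1/((S+1)·k), so under a global null no call can pass the 0.01 gate at all,
while a set of k >= 5 genuinely extreme regions (whose Fisher p-values lie
far below every null value) reaches eFDR = 1/(21·k) < 0.01 after
monotonisation. The flip side is a resolution floor: a dataset with fewer
than five detectable NDRs cannot clear eFDR < 0.01 at S = 20; raise
`n_shuffles` (the floor is 1/((S+1)·k)) in that regime.

## Region enrichment and overlap classes

`permutation_enrichment()` asks whether query regions overlap an
annotation more often than matched random regions. Each simulated set
mirrors the query set's length multiset region-by-region (the most literal
matching; not pooled), placements are uniform with chromosomes drawn
proportional to length, and a placement is rejection-resampled until it
holds at least 4 reference CpGs (reference CpG positions, not
coverage-dependent observed sites). The empirical p-value is the plain
exceedance fraction `n_exceed / n_sims` with ties counted as exceedances —
this k/n convention (not (k+1)/(n+1)) is pinned by the worked example
21/1,000,000 = 0.000021. No mappability or blacklist masking is applied
(toy genomes); pass a pre-masked genome if needed.

`classify_overlap()` assigns each query region one of five exhaustive,
mutually exclusive classes against two peak sets: `none`, `gained` (peak
only in state 2), `lost` (peak only in state 1), `shared_same` (borders
matching within `border_tol_bp`, default 0, at both ends) or
`shared_different_borders`.

## 5hmC from BS/oxBS pairs

In bisulfite data both 5mC and 5hmC read as cytosine; after oxidation only
5mC does. `estimate_5hmc()` therefore uses the per-site maximum-likelihood
difference: `5mC = oxbs_meth/oxbs_total`, `5hmC = max(0, bs_meth/bs_total
- 5mC)`, with a `clipped` flag when the raw difference was negative, and
delta-method standard errors (difference of independent proportions). The
joint constraint `5mC + 5hmC <= 1` is enforced by clipping 5hmC only; the
oxBS proportion is taken at face value. No hierarchical model and no
conversion-efficiency correction are applied (upstream filtering is
assumed); note that clipping makes the estimator upward-biased exactly at
truth zero — about half the sites clip there — which the `clipped` column
lets you quantify. `timecourse_summary()` aggregates estimates to
coverage-weighted region means per timepoint.

## Histone-signature clustering

`build_signal_matrix()` turns binned ChIP and input counts into
`log2((chip/chip_total + pc) / (input/input_total + pc))` per 25-bp bin
(pseudocount 1e-9 on the normalised scale), with each region body linearly
interpolated to 40 bins (regions scaled to a common length) and 1-kb
flanks contributing 40 unscaled bins each; bins beyond a contig edge
become `NA`. Replicates stay separate columns for clustering.
`cluster_regions()` runs k-means (k = 3, 10 restarts, best inertia) on the
full matrix after row-mean imputation, and canonicalises labels by
descending cluster size so a fixed seed gives reproducible, comparable
labels; inputs with fewer distinct profiles than clusters are handled
without k-means. `cluster_mark_tests()` summarises each (region, mark,
cell state) as the mean over that mark's bins and replicates — per-region
means, not per-bin values, enter the test — and applies a paired Student's
t-test per (cluster, mark), Bonferroni-corrected over all
`n_clusters x n_marks` tests at alpha 0.001. Degenerate clusters (< 2
regions) are skipped and flagged; an all-zero-difference cluster yields
p = 1 by convention rather than an error.

## Numerical choices and degenerate inputs

* Emission probabilities are clamped to [1e-6, 1 - 1e-6] and transition
  entries to [1e-9, 1 - 1e-9] during Baum–Welch; forward/backward uses
  scaling, Viterbi log-space arithmetic (ties broken toward the open
  state's predecessor, deterministically).
* Baum–Welch tolerates log-likelihood decreases only within 1e-8 relative;
  anything larger raises an internal error rather than returning a bad fit.
* The smoothing kernel includes every site within the distance radius the
  min-site expansion reached, with the radius inflated by 1 bp so boundary
  sites never receive an exactly-zero tricube weight.
* Empty inputs produce empty outputs (empty site table, empty `GRanges`),
  not errors; malformed files fail with the offending line number;
  `meth > total` is a validation error everywhere.
* Seeds: every stochastic step takes an explicit seed or derives
  per-stage seeds from `pipeline_config(rng_seed = ...)`; all derived
  seeds stay below 2^31.

## Problem sizes

The test and acceptance runs use deliberately desk-sized instances chosen
to make the statistical checks sharp: 0.5-Mb genomes with 20 planted DMRs
(30x, 2 vs 2) for methylation recovery, a 1-Mb genome with 10 planted
500-bp NDRs (20x) plus 20 shuffle re-runs for accessibility, 10^4-site
sequences for HMM parameter recovery, exhaustive 2x2 tables with margins
up to 30 for the Fisher oracle, 100 amplicon sites at 10^4 reads for the
5hmC estimator, and 114 regions for clustering. The headline counts of the
motivating study (e.g. 114 genome-wide DMRs, ~10^5 accessibility peaks)
are properties of controlled-access human data and are not reproduced
here; the package's claims are about recovering *planted* truth under the
stated count models.

## Known limitations

* The DMR statistic assumes approximate normality of smoothed differences;
  at coverage below ~10x with the default narrow kernel the normal
  reference becomes rough (the SE floor keeps it conservative).
* The eFDR resolution floor (above) limits sensitivity when very few true
  NDRs exist.
* `classify_overlap` with `border_tol_bp = 0` demands exact border
  equality for `shared_same`; real peak callers rarely reproduce borders
  exactly, so a nonzero tolerance is usually appropriate on real data.
* The enrichment sampler assumes the annotation is fixed and the query
  regions exchangeable with matched random regions; annotations that
  co-vary with CpG density beyond the >= 4-CpG floor are only partially
  matched.
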