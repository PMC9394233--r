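---
title: "Methods: single-CTC copy-number profiling with ctcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-CTC copy-number profiling with ctcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, the tunable parameters and their defaults, the simulation
model used for testing, and the numerical and design choices that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Problem setting and assumptions

A single circulating tumour cell yields a few picograms of DNA that
must be whole-genome amplified (WGA) before low-pass sequencing
(~2.5–15 M reads). The resulting binned coverage carries three nuisance
layers on top of the copy-number signal:

* a smooth, GC-correlated **wave** plus locus-specific representation
  bias that is largely *shared* between cells prepared with the same
  chemistry (restriction-site-dependent amplification is systematic per
  locus);
* strong per-bin **overdispersion** relative to Poisson counting noise;
* **dropout**: bins with no assigned reads at all ("empty bins").

The pipeline assumes that copy numbers are integral, that a cell is
pure (cellularity 1) so state centers sit at `log2(CN/2)`, that most of
the genome is diploid (the profile median defines the neutral
baseline — a cell with more than half its genome aberrant will be
mis-centred, a known limit of relative calling), and that a panel of
copy-number-neutral cells is available to estimate the shared bias.
Calls are relative gains and losses; absolute ploidy is out of scope.

## Stage-by-stage model

### Binning and normalization

The genome is tiled into fixed, non-overlapping, half-open bins
(default 100 kb; the resolution at which low-pass single-cell data
retain most bins at acceptable noise). Reads are assigned to the bin
containing their leftmost aligned base; paired data are counted once
per fragment via the leftmost mate. Default filters: MAPQ ≥ 20, no
duplicates/secondary/supplementary records — standard low-pass WGS
practice. Bins are unusable when their blacklist-overlap fraction
reaches 0.5 (configurable) or their mappability falls below a floor.

Counts on usable, non-zero bins are divided by a loess fit against GC
(span 0.65, degree 2, symmetric family — a robust local fit is the
standard operationalization of "corrects for GC content"), scaled to
median 1 and log2-transformed; the result is re-centred by subtracting
its median (with an even number of bins the median of the logs is not
the log of the median, so an explicit subtraction is needed to make the
median exactly 0). Two per-sample noise metrics are stored:

* `sigma_delta` = var(diff(y))/2 within chromosomes — the standard
  first-difference variance estimator, used for bin-size selection;
* `noise_scale` σ̂ = MAD(diff(y))/√2 (with the 1.4826 consistency
  factor) — a robust scale that ignores smooth waves and true CN steps,
  used by undo-splits pruning and the caller.

`profile_mad()` deliberately omits the 1.4826 factor: it mirrors the
raw-MAD convention in which single-cell 100-kb profiles score ~0.2–0.3,
so its values are comparable with published method-comparison tables.

### Calibration panel and dewaving

Each panel member is regressed (OLS with intercept, complete-case over
jointly non-missing usable bins) on all other members; its *wave
variance* is the residual variance. Members above the threshold
(default 0.05) are excluded in a single pass — no iteration — because
the procedure being modelled is a one-shot screen, and iterating could
cascade exclusions on small panels. At least six retained members are
recommended (a warning below that). Duplicate profiles make the design
singular; a ridge fallback (penalty 1e-6) keeps the operation defined.

Dewaving regresses the sample on the retained members and subtracts the
fitted component, then re-centres to median 0. Because the panel is
CN-neutral, the sample's CN structure is nearly orthogonal to the
regressors and survives; the shared wave and locus bias do not. OLS on
the member profiles is the entire model — whether the original
wave-correction tools weight bins or pre-smooth the panel is not
restated in the literature we operationalize, so the simplest testable
form is fixed here and isolated behind `dewave()` for substitution.
Sex chromosomes are excluded from the panel by default; a single-sex
panel with `autosomes_only = FALSE` supports calling chromosome X
(e.g. AR amplification in prostate cancer) against a male baseline.

### Segmentation

Circular binary segmentation with a permutation test. The statistic for
the arc (i, j] against the rest of the chromosome is the circularized
two-sample contrast `|mean(arc) − mean(rest)| / sqrt(1/k + 1/(n−k))`
(scale-free under permutation, so no variance estimate is needed). The
scan is exhaustive over all admissible (i, j) — compiled in C++ because
it is O(n²) per evaluation and sits inside the permutation loop — with
ties broken to the smallest (i, then j) for determinism. A split is
accepted when its permutation p-value over `n_permutations = 1000`
within-segment permutations (R's RNG, so seeded runs are bit-identical)
falls below `alpha = 0.01`; these two defaults are exposed because the
original tooling delegates them to its segmentation engine without
stating them. The permutation loop stops early as soon as significance
has become impossible, which is what makes flat chromosomes cheap.

`min_width = 10` bins is the minimum segment length ("clen = 10" in the
calibrated settings is read as a minimum accepted segment length — the
natural reading for suppressing short single-cell artefacts — and the
interpretation is confined to this one parameter). `undo_sd = 4`: after
segmentation, adjacent segments whose means differ by less than
4σ̂ are merged, smallest difference first, until stable. Merging uses
bin-weighted means, so the partition and weighted-mean invariants are
exact, and raising `undo_sd` can only reduce the segment count (the
merge sequences are nested prefixes).

### Calling

Each segment mean m with n bins is modelled as Gaussian around fixed
state centers `expected_center(CN, cellularity)` for CN = 1, 2, 3, 4
(loss, neutral, gain, amplification; CN 0 exists behind
`five_states = TRUE` and is floored at log2(0.05) to keep the log
finite). The SD is σ̂/√n, divided by `relSDlong = 2` for segments of at
least `long_threshold = 10` bins — the cited setting is a bare name, so
it is implemented as a divisor on the long-segment SD and isolated in
one function. The amplification component uses the CN 4 center with a
doubled SD on its right flank, because one fixed center cannot span
high-level amplicons. Only the mixing proportions are fitted, by EM
(deterministic initialization 0.1/0.7/0.15/0.05, convergence at 1e-8 or
500 iterations; the observed-data log-likelihood is asserted
non-decreasing at every step). Likelihoods are computed in log space
and rescaled per segment before the EM because long segments have tiny
SDs that would underflow ordinary densities. `call_cohort()` pools the
EM over all samples of a run — per-sample priors are a flag — since
single cells contribute few segments each. With σ̂ = 0 posteriors
collapse to the nearest center. Posteriors broadcast to member bins, so
a segment is the unit of calling.

### Condensing, distance and clustering

Maximal runs of bins over which every sample's call is constant become
condensed regions; region widths count informative breakpoints, not
base pairs (the heatmap deliberately does not draw chromosomes to
physical scale). The default distance is the bin-weighted posterior
concordance `1 − Σ w_r Σ_s p_A p_B / Σ w_r` — a soft distance, because
the clustering tool being modelled operates on call probabilities — with
hard-call Hamming as an option; average linkage by default, both
exposed. The soft distance is a semimetric: it is 0 on identical
samples only at certainty-1 posteriors. X and Y are excluded from
calling (hence clustering) by default so cohorts can mix donor sexes.

### QC layer

* Band QC: score = number of multiplex-PCR bands (7 informative for the
  modified multiplex on WGA products — the 8th requires undigested
  genomic DNA — 4 for the alternative kit); pass at score ≥ 5.
* Arm-distribution ratios: per-arm read fractions divided by the panel
  mean fraction, leave-one-out for panel members; acrocentric p arms
  and the sex chromosomes (13p, 14p, 15p, 21p, 22p, Xp, Xq, Yp, Yq) are
  excluded, leaving 39 of 48 arms. The failure flag fires when more
  than half the retained arms have a ratio below 0.1 or the top 3 arms
  hold more than half the retained reads (all four thresholds are
  config keys; they operationalize the qualitative description of
  failed reactions collapsing reads onto a few arms).
* Empty-bin rejection: absolute (fraction > 0.1) or relative (> 3x the
  cohort median) modes.
* Minimum depth: bin counts are binomially thinned — statistically
  equivalent to read subsampling for a counting pipeline, and fast —
  ten times per depth; each replicate is re-normalized (and dewaved
  when a panel is supplied) and Spearman-correlated with the full-depth
  profile over common non-missing bins. The recommendation is the
  smallest depth with mean r ≥ 0.9. The thinned replicates are *not*
  re-segmented: the correlation the rule uses is computed on per-bin
  profiles, which segmentation does not alter, so re-segmentation would
  only cost time inside the iteration loop.
* Paired Wilcoxon: incomplete pairs are dropped, then zero differences
  (signed-rank convention). Absolute differences are ranked at 8
  significant digits so that floating-point jitter in measured inputs
  cannot split true ties. The exact signed-rank distribution is used
  for n ≤ 25 when there are no ties — and also when the statistic is at
  an extreme (all differences one sign), where the exact p-value is
  provably tie-invariant; otherwise the normal approximation with
  tie-corrected variance and continuity correction applies.

## The synthetic-data generator

`simulate_cells()` draws bin counts with expectation proportional to
`(CN/2) · 2^{gc_slope · (gc − mean gc)} · 2^{wave}`, normalized to the
cell's total reads, then applies negative-binomial noise and dropout.
The wave is a per-chromosome sum of sinusoids (fundamental wavelength
160 bins, 3 harmonics, random phases) shared by every cell of a batch
and scaled to a log2 SD of 0.35 — reproducing the two defining features
of the real artefact: smoothness and cross-cell correlation, including
its GC link through the separate GC term. Defaults: negative-binomial
size 10 (per-bin log2 SD ≈ 0.46 at 1250 reads/bin, matching the
~0.2–0.3 raw MAD of WGA single cells), dropout 0.01.
`simulate_failed_wga()` concentrates arm weights on `n_active_arms`
arms (Dirichlet weights plus a small uniform background), emulating the
read collapse of failed amplifications.

What the generator does **not** emulate: locus-level representation
bias tied to actual restriction-site maps, chimeric reads, mapping
artefacts, replication-timing waves, or subclonal (non-integral)
mixtures within one cell. Passing tests therefore demonstrate that the
algorithms recover truth under the stated noise model, not that any
particular wet-lab protocol will achieve these error rates.

Quality tiers used in tests (and why): calibration-panel leukocytes are
simulated at size 60 — their leave-one-out wave variance then sits just
under the 0.05 retention gate, the regime a usable panel must occupy
(cells noisier than that are exactly the ones the screen exists to
remove; at size 10 every member fails it, which the panel-exclusion
test also exercises). Tumour cells keep the WGA-like default size 10.

## Test and acceptance problem sizes

Chosen as the smallest sizes at which each property is sharply
testable: a 4 x 500-bin toy genome for pipeline cohorts (2.5 M
reads/cell keeps the paper-scale 1250 reads/bin); 50 replicates of a
300-bin, 3-level profile at noise SD 0.25 for breakpoint recovery
(undo-splits disabled there, since a 4σ̂ undo threshold equals the 1.0
step size at that noise and the check targets the changepoint engine);
a 24 000-bin genome for the depth analysis so that 0.5 M reads lands at
~20 reads/bin, the regime where subsampling correlations actually
degrade; 33 flat cells at negative-binomial size 400 and wave SD 0.35
for the dewave segment-count comparison — at single-cell size 10 the
4σ̂ undo rule already prunes wave segments with or without dewaving
(both arms give one segment per chromosome and the comparison is
uninformative), so the wave-removal benefit is demonstrated where the
wave rises above four noise SDs, i.e. high-quality libraries.
Permutation counts in tests are 200–500 (acceptance threshold α = 0.01
needs ≥ 200); the shipped default stays 1000.

## Known limitations

* Breakpoints of single-copy events inside a chromosome are not
  recoverable at raw single-cell noise with the calibrated
  `undo_sd = 4` rule (the undo threshold, ~4 × 0.46 log2 units,
  exceeds a one-copy step); whole-chromosome and arm-level aneuploidies
  — the dominant single-cell CNV mode — and events in cleaner libraries
  are. This is a property of the calibrated settings, not of the
  segmentation engine, as the breakpoint-recovery tests show at noise
  SD 0.25.
* The mixture's fixed centers assume cellularity 1; admixed bulk-like
  inputs need the cellularity parameter, and states above CN 4 fold
  into the amplification component.
* Relative calling mis-centres genomes that are aberrant over most of
  their length.
* The condensed-region distance treats regions independently; long
  shared aberrations broken by one discordant sample weigh the same as
  the equivalent unbroken region set.
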