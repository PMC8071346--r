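---
title: "CNV detection from low-coverage WGS bin counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV detection from low-coverage WGS bin counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the statistical
model behind each stage, the parameters that matter, the numerical
choices, and what the synthetic data can and cannot tell you about real
samples.

## The read-count model

Low-coverage WGS (0.1–0.5×) cannot genotype variants, but the *number*
of reads falling in a genomic window estimates its copy number.
Sequencing is modeled as drawing `n` reads from the mappable genome of
length `lg`; a region of length `lc` receives a binomial count with
`p = lc/lg`, mean `np` and variance `np(1-p)`. Gain or loss of one copy
of a diploid region shifts the regional count to `n(p ± p/2)`, so the
standardized deviation is

    Z^2 = n lc / (4 (lg - lc)),

and inverting gives the minimal read count `n = 4 Z^2 (lg - lc)/lc` for
a target confidence `Z`, or the minimal detectable length
`lc = 4 Z^2 lg / (n + 4 Z^2)` for a given `n` (`zscore_for_reads()`,
`min_reads()`, `min_length()`). The default `lg` is 3.1e9 bp, the scale
of the human genome; it is a parameter because the *mappable* genome is
shorter and assay-dependent. These formulas ignore GC bias, mappability
loss and overdispersion, so they are floors: real data need somewhat
more reads, which is why the in-silico machinery below exists.

## Binning

Reads are counted in fixed windows (`bin_size` 20,000 bp) by their
0-based start position; mapping quality must be at least `mapq_min`
(40), and unmapped, secondary, supplementary and duplicate-flagged
records are dropped. Both mates of a pair are counted independently:
with start-position counting each mate is an independent, nearly
uniform draw, and fragment-level deduplication is already handled by
the duplicate flag. Terminal bins are kept truncated — index arithmetic
stays trivial and genuinely unusable stubs are removed later by
low-mean filtration. Mitochondrial and non-canonical contigs are
excluded from the grid by default.

Counts are then scaled so that each compartment (autosomes, chrX, chrY
— sex chromosomes separately, because their copy number differs between
sexes) sums to a fixed target. The target fixes the mean scaled bin
count at `m = 100`, making levels comparable across samples and the
single-copy level `L = m/2` a constant of the pipeline. A consequence
of per-compartment scaling is that whole-sex-chromosome aneuploidies
are invisible by construction; only sub-chromosomal X/Y events can be
seen.

## Normalization

**GC correction.** Bin counts depend smoothly on GC fraction through
amplification and sequencing chemistry. A per-sample `lowess` fit of
scaled count on GC (span 0.3, robust iterations) over autosomal bins
with defined GC gives a fitted curve `f(gc)`; each bin is multiplied by
`median(f)/f(gc)`. The correction is multiplicative — it preserves
non-negativity and the Poisson mean–variance relation, where a
subtractive correction would not. Fitting uses at most 20,000 bins
(every j-th usable bin in genome order); GC varies smoothly along the
genome, so this subsample covers the GC distribution, and a 20,000-point
LOESS curve is already noise-free — the cap only bounds run time. Bins
whose GC is undefined (defined-base fraction < 0.5) or whose fitted
value is non-positive pass through unchanged and are flagged. After
correction each compartment is re-scaled to its target: the
multiplicative correction drifts totals by a fraction of a percent, and
re-pinning keeps the scaled-sum invariant exact, which in turn makes
training profiles center at zero without a per-sample offset.

**Reference-panel PCA.** Recurrent artifacts — waves tied to batch,
chemistry, or population structure — are shared across samples and
therefore live in a low-dimensional subspace of the panel's bin-count
matrix. The model stores the first `n_components = 15` principal
components of the GC-corrected panel over *usable autosomal bins only*,
and subtracts each new sample's projection onto them. Two details
matter:

* The basis must be fitted after a provisional filtration pass.
  Unmappable (zero) and highly variable bins otherwise dominate the
  leading eigenvectors, and projecting a new sample onto such
  components injects their noise into clean bins instead of removing
  anything.
* The PCA is autosomal only, so chrX/chrY retain whatever panel-level
  artifact they carry. Sex-chromosome calls are correspondingly less
  precise; this is a known limitation, not a bug, and extending the
  basis to gonosomes with a sex-stratified panel would be the natural
  improvement.

**Centering and filtration.** Per-bin training means (PCA-denoised for
autosomes, GC-corrected for X/Y) are subtracted to give a profile
centered at zero. A bin is masked when its training mean falls below
`low_mean_frac = 0.25` × the compartment median (poor mappability),
exceeds `high_mean_frac = 2.0` × the median (repeats, systematic
inflation), or its training standard deviation exceeds
`high_var_frac = 3.0` × the median sd (erratic regions); undefined-GC
bins and an optional user exclusion table (reason `"manual"`) complete
the mask. The thresholds are scale-free multiples of robust statistics,
so they transfer across read depths; on the default synthetic genome
they mask roughly the fraction of the genome the masking is designed to
emulate (~13–15%, mostly the unmappable blocks). Filtration is monotone:
tightening any threshold can only grow the mask.

## Segmentation

Circular binary segmentation treats each chromosome's usable-bin series
as a circle and looks for the arc maximizing

    T(i,j) = |C_j - C_i| / (sd * sqrt(k (n-k) / n)),

where `C` are centered partial sums and `k` the arc length — the
standardized difference between the arc mean and the mean of its
complement. A split is accepted when a permutation test on `T` beats
`alpha = 0.01`, and the algorithm recurses on the resulting pieces. Runs
of usable bins separated by filtered gaps longer than `max_gap_bp`
(1 Mb) are segmented independently, so calls may bridge small masked
gaps but never a centromere-scale hole. Segment genomic coordinates
span first-bin start to last-bin end; `length_bp` for classification is
the sum of member-bin spans, so bridged gaps do not inflate a call's
length.

Numerical design of the engine (`src/cbs.cpp`):

* **Restricted arc family.** Exhaustive arc search is O(n²) and
  impossible inside a permutation loop at 150,000 bins. Both the
  observed scan and every permutation replicate maximize over the same
  family: all arcs of length ≤ `kshort` (12) bins or ≥ n − `kshort`,
  plus every arc whose endpoints lie among the `n_candidates` (50)
  smallest and largest centered partial sums. Because observed and
  permuted data are searched identically, the permutation test is exact
  for this statistic. Short arcs cover focal CNVs exhaustively; a
  sustained shift drives the partial-sum walk to an extreme at each of
  its boundaries, which is what the candidate search keys on. Segments
  of ≤ 100 bins are searched fully (all endpoint pairs).
* **Sequential stopping.** A split is rejected as soon as the lower
  confidence bound on the permutation p-value clears `alpha` (clean
  chromosomes settle in a few dozen replicates) and accepted when zero
  exceedances make the exact binomial upper bound fall below `alpha`
  (367 replicates at `alpha = 0.01`). Overwhelming statistics on long
  segments are accepted directly when a Bonferroni bound over the arc
  family with Gaussian tails is below `alpha/10`. Undecided borderline
  cases are settled by the p-value point estimate after 3,000
  replicates (resolution ±0.004, sufficient at `alpha = 0.01`).
* **Boundary refinement.** The greedy recursion occasionally leaves a
  cut one bin off. Each internal boundary is re-fitted within
  `refine_window = 2` bins by a two-segment Gaussian likelihood whose
  per-segment variance follows the Poisson relation (variance ∝ level +
  mean usable count). This matters: a single-copy deletion has half the
  variance of its flanks, so the likelihood-optimal cut is not the
  midpoint rule, and modeling this measurably improves exact-boundary
  recovery at low depth. Profiles without a count scale (arbitrary
  constructed series) fall back to least squares.
* **Degenerate inputs.** Constant segments (sd ≈ 0) never split;
  chromosomes with no usable bins are skipped; `rng_seed` makes the
  whole segmentation reproducible without touching the caller's RNG
  stream. `undo_sd` (off by default) merges adjacent segments whose
  mean difference is small in pooled-sd units, mirroring the common
  split-undo option.

Classification assigns the first matching rule of the five-level table
(magenta ≥ 75% of `L` and ≥ 200 kb; red ≥ 25%, ≥ 200 kb; orange ≥ 25%,
≥ 40 kb; yellow ≥ 12.5%, ≥ 40 kb; green otherwise). The percentage
denominator is the single-copy level `L = m/2` — the natural reference,
since a full single-copy event sits at 100% — and thresholds are
enforced in bp so non-default bin sizes behave sensibly. Classification
is monotone in |level| and length by construction.

## The in-silico accuracy framework

Real positive controls at every (length, depth) combination do not
exist, so accuracy is measured by simulation that re-uses real (or
synthetic) CNV-free samples: binomial thinning of bin counts emulates
downsampling the read stream (the two are distributionally identical
for start-position counts); a random bin-aligned autosomal window whose
bins are all unfiltered is multiplied by 0.5 or 1.5; and the caller
runs unchanged. A trial counts as *detected* when a non-green call of
matching sign overlaps the truth at all, *exact* when both boundaries
match, *within-one-bin* when both are within one bin. One CNV is
injected per artificial sample, so the planned trial count is exactly
`samples × variants × lengths × depths` (`plan_insilico_grid()`
enumerates it before execution). Because every reported metric is a
property of calls overlapping the injected region, the grid runner
segments only the injected chromosome — a pure speed optimization that
cannot change any reported fraction.

One property of this design worth knowing: each base sample is drawn
(or mapped) once and re-used for every injection, so its bin-level
noise is frozen. A ×1.5 duplication amplifies a frozen local shortfall
while a ×0.5 deletion halves it, which makes rare duplication misses at
unlucky (sample, locus) pairs the dominant failure mode near the
detection limit.

## The synthetic-data generator

`synthetic_spec()` defines the study conditions; `make_panel()` /
`make_case()` draw from per-bin expected counts

    rate = width × copy × mappability × gc_curve(GC) × exp(Σ_k loading_k · factor_k)

with Poisson noise (a negative-binomial `overdispersion` knob exists
for robustness experiments). The pieces and their defaults:

* a smooth GC track in [0.3, 0.7] (AR(1)-filtered noise, lag-1
  correlation 0.98) and a unimodal GC-rate curve peaking at GC 0.45
  with ~25% amplitude — the shape and size of typical library GC bias;
* `unmappable_fraction = 0.10` of bins at zero rate, placed in
  geometric blocks (mean 5 bins) to mimic centromeric/telomeric dead
  zones, plus `high_variance_fraction = 0.03` of bins with extra
  per-sample lognormal noise (sd 0.5 on the log scale) — together these
  drive the masked fraction to the expected ~13–15%;
* `artifact_rank = 3` smooth per-bin loading vectors (AR(1), lag-1
  0.95) with `artifact_scale = 0.015` — a 1.5% multiplicative
  cross-sample batch effect. The scale was set when the generator was
  designed so that the unremovable sex-chromosome component stays below
  calling thresholds, consistent with the generator's false-call guard
  (at most ~1 spurious call per CNV-free sample); larger values leave
  autosomes unaffected (the PCA absorbs them) but flood chrX/chrY with
  yellow calls;
* sex chromosomes at half the autosomal rate (one copy each);
* the default genome is a ~60 Mb toy (3 autosomes + X + Y, 3,000 bins)
  so the full test suite runs in minutes; genome-scale runs use
  `hg19_chrom_sizes()` (~155,000 bins).

What the generator does *not* emulate: mappability that varies
continuously (here bins are mappable or dead), reference biases and
alignment artifacts, real repeat structure, overdispersion beyond the
optional knob, mosaicism, and any X/Y copy-number variation between
samples. Passing tests therefore demonstrate that the pipeline recovers
planted signal under GC bias, low-rank artifacts and Poisson noise —
not that it handles every pathology of real libraries; the training-set
requirement (≥ 100 samples of the same type and protocol) is the
corresponding operational caveat for real data.

## Problem sizes used by the tests and the accuracy script

The test suite trains on the toy genome (100 samples × 3,000 bins) for
unit and property tests, and on an hg19-scale synthetic panel (100
samples × ~155,000 bins, 11 M reads each) for the end-to-end accuracy
checks, with 300 injection trials per configuration. The standalone
`scripts/acceptance.R` runs the same harness at 1,000 trials per
configuration (10 test samples × 100 CNVs). Detection is evaluated at
100 kb / 8 M reads, boundary exactness at 200 kb for 10 M and 5 M
reads. The recovery and false-call guards use 200 and 100 toy-scale
trials respectively.

## Known limitations

* Sub-chromosomal events only; whole sex-chromosome aneuploidies are
  removed by per-compartment scaling.
* chrX/chrY precision is lower than autosomal precision (no PCA there).
* Exact breakpoints are bin-quantized (20 kb); exon-level precision is
  out of reach by design, and at ~5 M reads a minority of 200 kb events
  is recovered one bin off even in clean synthetic data.
* The false-positive behavior on real data is characterized here only
  through the synthetic guard; low-rank artifacts sharper than the
  panel can represent would surface as calls.
* The permutation engine's restricted arc family can, in principle,
  miss a weak intermediate-length shift whose boundaries are not
  partial-sum extremes; strong shifts of any length are caught by the
  candidate search.
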