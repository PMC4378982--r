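---
title: "luxseq methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{luxseq methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

luxseq packages the computational core of a light-induction study design in
filamentous fungi: RNA-seq time courses without replicates (dark plus 30,
60 and 120 min of light, in several genotypes), ChIP-seq of light-activated
transcription factors against a dark or untagged control, MNase-seq of
nucleosome-protected fragments, and promoter motif analysis. This vignette
is the package's own account of the statistics it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open.

## Differential expression without replicates

Counts for gene *i* in sample *j* are modeled as negative binomial with
mean `mu[i] * s[j]` and a variance that is a smooth function of the mean.
Size factors `s[j]` are median-of-ratios: the median over genes (with
all-positive counts) of the ratio of a sample's count to the gene's
across-sample geometric mean. Genes in the lower 20% of mean normalized
expression are removed before testing.

With no replicates, the mean-variance relation is fitted *blind*: all
samples are treated as pseudo-replicates and the per-gene sample variance
of normalized counts is regressed on the log mean. Two estimator details
matter and both were chosen for calibration, verified by the type-I tests
in the suite:

* The fit is **robust**: genes are binned by quantiles of log mean and a
  local regression is drawn through per-bin *medians* of the variance. A
  least-squares fit is wrecked by the minority of genes with real
  condition effects (their across-sample variance is of order `mu^2` times
  the squared fold change), which would inflate the trend and destroy
  power.
* The bin medians are **bias-corrected**. At `m` samples the sample
  variance is roughly `sigma^2 * chisq(m - 1)/(m - 1)`, whose median is
  below its mean; the median is multiplied by
  `(m - 1)/qchisq(0.5, m - 1)`. Without this correction the trend is
  biased low at 3 degrees of freedom and the test becomes anticonservative
  (empirically P(p <= 0.05) was about 0.10 on null data instead of 0.05).
  Fitting log variance instead of variance has the same defect, which is
  why the regression is on the variance scale.

The fitted mapping is floored at the Poisson minimum `sigma^2 = mu`, made
nondecreasing, and extrapolated flat beyond the fitted range.

The test itself conditions two counts on their sum. With the common
normalized mean `mu0 = (k_t/s_t + k_c/s_c)/2`, the dispersion
`phi = (sigma^2(mu0) - mu0)/mu0^2` is taken scale-invariant, so condition
c has mean `mu0 * s_c` and variance `mu + phi * mu^2` at its own scale;
the design is ambiguous on whether the variance is evaluated at the raw or
normalized scale and the scale-invariant convention keeps the test
consistent across library sizes. The joint probability of a split (a, b)
with `a + b = k_t + k_c` is the product of the two NB point masses
(`dnbinom`, with a Poisson branch when `sigma^2 <= mu`), and the two-sided
p-value is the normalized sum of `f(a, b)` over all splits with
`f(a, b) <= f(k_t, k_c)`. Ties are included with a relative tolerance of
1e-12, so the observed term always counts and p is in (0, 1]. The empty
case `k_t = k_c = 0` returns p = 1. No multiple-testing correction is
applied anywhere: the published design gates raw p < 0.05 with a 2-fold
cutoff, and the calibration tests show that the combination controls the
family of null calls at about the nominal level.

A gene is light-inducible if any light timepoint beats both gates against
darkness. Classes operationalize the verbal archetypes: immediate-early
(at least 2-fold already at 30 min), early (fold profile maximal at 30 min
and non-increasing afterwards), late (the rest). The boundary between
early and late is verbal in the source design; the maximal-at-30 rule is
our fixed operationalization. Genotype dependence is the same exact test
applied across genotypes at matched light timepoints, with a direction
requirement (lower in a knock-out, higher in an over-expressor).

Fold changes are reported on normalized means with a pseudo-count of 0.5
on both sides (unstated upstream; avoids division by zero and shrinks
folds at tiny counts). Tests always run on raw integer counts with size
factors entering through the means, never on rescaled non-integer counts,
so the NB pmf stays well-defined.

## Peak calling

The genome is scanned with 150 bp windows advancing by 50 bp; a fragment
is counted in a window if its 5' position lies inside. Each treatment
window count is tested against `lambda = max(k_control, 0.5) * scale`
under a Poisson upper tail inclusive of the observed count, where `scale`
is the ratio of total mapped fragments. The 0.5 floor (our choice,
unstated upstream) prevents `lambda = 0` pathologies in empty control
windows. "4 continuous windows" is read as four step-50 (overlapping)
windows; a maximal run of at least four windows with p < 1e-5 becomes one
peak from the first window start to the last window start + 150. The
summit is the position of maximal per-base treatment coverage (leftmost on
ties).

The enrichment filter compares the peak's mean per-base coverage to the
genome: it must reach 1.5 times the genome-wide mean window coverage *and*
the 90th percentile of window coverage. The published phrasing is
ambiguous about what "general coverage" is; both reference statistics are
window-level and exposed in the configuration.

Peak-to-gene annotation anchors at the summit (deterministic; the source
does not state the anchor) and applies three rules: (1) every gene whose
strand-aware promoter window from 1000 bp upstream to 500 bp downstream of
the TSS contains the summit, boundaries inclusive; (2) otherwise the
nearest gene with the summit on its upstream side, unbounded; (3)
otherwise unannotated. ChIP is unstranded, so peaks are never
strand-distinguished.

Light-regulated binding sites are classified by an ordinary least-squares
regression of light on dark intensity with an 80% prediction interval.
Intensities enter as `log2(x + 1)` (scale unstated upstream; logs make
count residuals roughly homoscedastic). Sites above the upper band are
light-induced, below the lower band light-reduced. By construction about
20% of null sites fall outside their own 80% band, which is exactly the
calibration the acceptance test asserts. A collapsed band (zero residual
variance) classifies everything as unchanged via a small epsilon on the
comparisons.

## Nucleosome mapping

Paired-end fragments of 100-1000 bp are nucleosomal; fragments under
100 bp are candidate TF footprints; longer fragments are discarded. The
boundary length of exactly 100 bp is nucleosomal (the inclusive mapping
filter wins over the strict "greater than 100" phrasing; the boundary is a
config knob). Each nucleosomal fragment contributes +1 over the 50 bp
centered on its midpoint. Tracks are normalized so that the 90th
percentile of 150 bp-window mean coverage over nonzero windows equals 1
(window size matching the ChIP scan; whether the original percentile was
over bases or windows is unstated, window-level chosen). The operation is
scale-invariant and idempotent. Smoothing is a Gaussian kernel average
with a 30 bp bandwidth truncated at four bandwidths; 30 bp is our choice,
kept below half a nucleosome half-width so dyads are not displaced, and
edge weights renormalize so constants pass through.

The +1 nucleosome of a gene is the coverage maximum within 200 bp around
the TSS, ties broken toward the TSS and then downstream. Metagene profiles
average strand-aware slices of the normalized track over anchors out to
1500 bp; minus-strand anchors contribute mirrored. Per-nucleosome
occupancy is the area under the curve over 176 bp centered on the dyad.
The repeat length comes from the first autocorrelation maximum of the
profile past its first local minimum (searched in 100-400 bp; a peak
autocorrelation under 0.1 is reported as undefined, which is what white
noise produces), or from the median successive-dyad distance with a
bootstrap CI when dyads are given directly.

Occupancy at binding sites is reported as a ratio to a randomized
background: because binding-site-to-TSS distances are NB-distributed, the
background redraws the same number of distances from an NB fitted to the
observed distances by method of moments ("the same parameter" is otherwise
unspecified; moments are the transparent choice), placed on the
strand-aware side resampled from the observed sides of random TSSs. When
the moment fit is infeasible (variance at most the mean) the observed
distances are resampled instead, with a logged message. Footprint profiles
use the full extent of sub-nucleosomal fragments rather than a fixed 50 bp
(the 50 bp rule is stated only for nucleosomal tracks and footprints are
shorter than 50 bp would smear), normalized to the genome-wide mean
sub-nucleosomal coverage.

## Motif analysis

Scanning is exact degenerate (IUPAC) matching on both strands, with
palindromic patterns such as GATC reported once per site. Tandem spacing
tallies *all* within-region pairs of hits (the pairwise phrasing of the
design supports all-pairs, not adjacent-only) by center-to-center distance
within 300 bp regions centered on summits, against the same tally over
uniformly placed random regions. Center-to-center is the distance
convention (a gap convention is a config switch). The bipartite
GATA-factor motif is encoded as `MGATSNNNNNNMTGY` (a/c = M, c/g = S,
c/t = Y), with the six ambiguous positions measured edge-to-edge.

## The synthetic world

Generators are pure functions of their parameters and a seed, and every
planted feature is recorded in a truth table; pipelines are scored only
against that truth. The stated world:

* **Counts**: log-normal baseline means with expectation 50 (the depth at
  which the recovery criteria are posed) and log-SD 1; variance
  `mu + phi(mu) * mu^2` with `phi(mu) = 0.02 + 1/mu`, a smooth trend
  decreasing in the mean; 10% of genes planted light-induced, half early
  (folds 1/8/4/2 over DD/30/60/120) and half late (1/2/4/8), matching the
  verbal archetypes of peak-at-30-then-decay versus monotone rise.
* **ChIP**: fragment centers drawn with relative rate `fold` within half a
  fragment length of each planted summit, lengths normal (mean 150, SD 30)
  truncated at 50 bp; the control library is uniform. Enrichment as a rate
  multiplier (not mixture weights) is the simplest model that calibrates
  the Poisson window test.
* **MNase**: dyads at the stated repeat from each array anchor; fragment
  centers jittered N(0, 10) and lengths N(150, 10) truncated to
  [100, 1000] — the 10 bp jitter and length SD are artifact choices (the
  source reports only observed 140-150 bp fragments), picked so planted
  dyads are recoverable but not trivially exact. Footprint fragments are
  N(60, 10) under 100 bp. A uniform background mixes both classes.
* **Motifs**: exact substitution at stated positions; tandem pairs at
  spacing d are two copies d apart.

The generator has no sequencing-error, mappability or GC-bias model (the
replicated pipeline has none either), no fragment-length bias, and no
correlation between neighboring genes. A green recovery test therefore
establishes that the algorithms recover what they model, on data that
satisfies the model; it says nothing about robustness to artifacts real
libraries contain.

## Numerical choices and degenerate inputs

* Exact-test tie tolerance 1e-12 relative; Poisson branch when
  `sigma^2 <= mu * (1 + 1e-8)`.
* Dispersion floor `sigma^2 >= mu` applied at evaluation, plus a
  monotonicity pass (cumulative maximum over the fitted grid).
* Empty control windows: lambda floor 0.5.
* Collapsed prediction band: epsilon `1e-8 * (1 + |y|)` keeps exact ties
  inside.
* `k_t = k_c = 0` gives p = 1; all-zero tracks refuse to normalize; a
  zero-coverage +1 window skips the gene with an NA.
* Wiggle output drops a trailing partial span; round-trips are exact at
  step resolution.

## Known limitations

The blind mean-variance fit deliberately over-estimates dispersion when
many genes respond (the replicate-free situation it was designed for), so
power degrades as the responding fraction grows. Sensitivity of the
genotype comparison drops for weakly expressed genes at the depths of the
stated world. The repeat-length estimator needs several phased periods and
reports irregular promoters as undefined rather than guessing. The CLI
holds whole per-contig coverage vectors in memory, which is fine for
fungal-scale genomes but not for mammalian ones.
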