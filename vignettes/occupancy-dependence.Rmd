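---
title: "Classifying regulatory elements by PRC1-dependent PRC2 occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying regulatory elements by PRC1-dependent PRC2 occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(predep)
```

# The question and the measurement

Polycomb Response Elements (PREs) are ~1 kb DNA elements that recruit the
Polycomb repressive complexes PRC1 and PRC2 in *Drosophila*. When PRC1 is
genetically ablated, PRC2 occupancy (measured by E(z) ChIP-seq) collapses at
some PREs but persists at others. `predep` implements the comparative
ChIP-seq occupancy analysis needed to make that statement quantitative:
score each candidate element in each sequencing library, normalize across
libraries, contrast genotypes, classify elements, and — around binding-site
summits — ask whether the mutant loses signal preferentially at a distance
from the summit (the "tail" signal attributed to chromatin looping
contacts).

# The element score

ChIP-seq read-density tracks are per-base non-negative vectors. The score of
a 1 kb element in one library is the **highest mean over 6 consecutive
positions**:

$$S = \max_{i}\; \frac{1}{w}\sum_{j=i}^{i+w-1} x_j, \qquad w = 6 .$$

A window maximum rather than the interval mean makes the score robust to how
generously the element's boundaries were drawn: a sharp occupancy peak
anywhere inside the interval scores the same. The window length is a
parameter (`window`) defaulting to 6. Raw scores are depth-normalized to
reads per million (`raw * 1e6 / total_depth`); any constant scale cancels in
the genotype contrast, so the choice of $10^6$ is cosmetic.

Replicate libraries must agree before they are combined: the pipeline
computes Pearson's correlation between per-element replicate scores and
aborts below `qc_gate = 0.90` (override with `force = TRUE`). Normalized
replicate scores are then **averaged per genotype before** the contrast is
taken — contrasting per replicate and averaging afterwards would propagate
the noisier replicate into every element's contrast.

# The genotype contrast and classification

For mutant and control mean scores $m$ and $c$ the **relative difference**
is

$$\mathrm{RD} = \frac{2\,(m - c)}{m + c} \in (-2,\, 2),$$

with the companion ratio $m/c$. RD is antisymmetric under genotype swap,
bounded, and equals $-2$ at total signal loss. The symmetric form (rather
than $(m-c)/c$) is used because observed distributions extend below $-1$,
which $(m-c)/c$ cannot reach for a signal loss, and because RD and ratio are
then two scales of one axis: $\mathrm{RD} = 2(r-1)/(r+1)$ for $r = m/c$.

Elements are classified by fixed RD thresholds:

* $\mathrm{RD} < -1.0$ (ratio $< 1/3$) — *dependent*: PRC2 recruitment
  clearly requires PRC1;
* $\mathrm{RD} > -0.5$ (ratio $> 0.6$) — *independent*;
* otherwise *intermediate*.

Because chromatin input libraries are sequenced alongside, the same RD
computed on input tracks provides a processing-bias control; the pipeline
compares the ChIP and input RD distributions with a two-sided Wilcoxon rank
sum test (exact for small tie-free samples, normal approximation with tie
correction otherwise — the standard `wilcox.test` behaviour).

Before classification the catalog is filtered: elements overlapping an
exclusion interval (e.g. the deletion that removes the PRC1 genes in the
mutant line, `suz2_deletion()`) by at least 1 bp are removed, as are
elements whose control score falls in the lower 30% of the catalog's signal
**dynamic range** (`min + 0.3 * (max - min)`). The phrase "lower 30% of the
dynamic range" is ambiguous between a range fraction and a quantile; both
are implemented (`weak_method = "range"` is the default because it is the
literal reading; on right-skewed score distributions it removes far more
than 30% of elements, which is visible in the filter log).

# Peak calling

Significantly immunoprecipitated regions are **clusters of coordinates no
more than 500 bp apart whose values exceed three standard deviations above
the genomic mean**. The mean and SD are taken over the whole analyzed track
including zero-coverage bases, with the population (divide-by-$n$) SD —
choices recorded in the output metadata. The gap rule is interpreted as:
successive supra-threshold coordinates at distance $\le$ 500 bp share a
region (coordinates 500 apart merge; 501 apart split).

Given a list of replicate tracks, `call_peaks()` by default requires a
coordinate to pass its replicate's own threshold in **every** replicate
before clustering (`mode = "reproducible"`). A per-base 3-SD cut on a low,
near-Poisson background is individually permissive (for Poisson rates well
below 1 the achievable tail probability is ~$10^{-3}$ per base, i.e.
hundreds of one-base excursions per megabase), and such excursions are
irreproducible by construction, so requiring joint support is what makes
the rule usable; this is also why replicate experiments exist. Calling on
the replicate-averaged track remains available (`mode = "average"`).

The **summit** is the center (floor midpoint) of the 6 consecutive
coordinates with the highest counts inside the region, leftmost window on
ties; regions shorter than the window fall back to their midpoint with a
warning. Peaks are **isolated** when the nearest neighboring summit on the
same chromosome is strictly more than 10 kb away.

# Cumulative profiles and the distal-loss diagnostic

Around each isolated summit the $\pm$5 kb window is divided into 100 bp
bins; per-bin mean densities are computed per replicate, averaged across
replicates, then averaged across peaks. The mean profile is smoothed by
loess (span 0.1, degree 2, tricube weights, exact "direct" evaluation). Both
genotype curves are evaluated at 50 evenly spaced offsets, subtracted
(mutant − control), and the 50 differences are loess-smoothed with span 0.2.

The flat background reference is the mean of per-bin average counts over
999 randomly placed 100 bp bins that overlap no called peak region; bins may
overlap one another (a `replace = FALSE` mode exists for small genomes) and
placement is seed-reproducible.

Differencing has two modes. `scale = "none"` subtracts the curves as given.
The default `scale = "summit"` first subtracts each genotype's background
and divides by its own summit density, so the difference measures
*redistribution* of signal along the window rather than overall amplitude —
zero everywhere if the mutant profile is a scaled copy of the control, and
negative at distal offsets when tails are lost preferentially. Summit
densities for scaling are taken from the raw central profile bins
(`summit_density()`), not from the fitted curve: a span-0.1 loess flattens
a sharp summit spike and would understate the scale factor. The
`difference_summary()` diagnostic compares the mean absolute smoothed
difference over offsets 2–5 kb with its value at offset 0.

# The synthetic data generator

No sequencing data accompanies the analysis, so `simulate_tracks()`
generates tracks whose statistical structure carries everything the method
relies on, with known ground truth:

* a flat Poisson background (`background_rate = 0.5` reads/bp);
* 60 elements, 1 kb wide, placed on an even grid over a 2 Mb chromosome with
  seeded jitter, centers at least 25 kb apart (so isolation and background
  sampling are well defined), one third per dependence class;
* per element, a sharp 200 bp summit plateau with mean fold enrichment
  `A = 20` over background, log-normally heterogeneous across elements
  (`amplitude_sigma = 0.4`, mean-preserving) — heterogeneity is what gives
  replicate correlations and the dynamic-range filter their meaning;
* flanking "tails": a low-level looping-derived component with amplitude
  `tail_fraction = 0.1` of the summit enrichment that ramps up over
  `tail_rise = 1` kb, decays with half-life `tail_halflife = 2` kb and is
  truncated at `tail_extent = 5` kb. The onset ramp encodes that contacts
  immediately adjacent to the core are subsumed in the core's own
  crosslinked fragments; it is what places the maximal mutant-versus-control
  difference a few kb from the summit rather than at its edge;
* mutant expected summit coverage equals the control's times a per-class
  attenuation (defaults 0.1 / 0.4 / 0.9); tail attenuation may be set
  separately, and when it equals the summit attenuation the mutant
  enrichment profile is exactly proportional to the control's (uniform
  loss);
* two replicates per genotype, matched background-only input libraries,
  per-library depth factors, Poisson noise by default with a
  negative-binomial option (`dispersion`) because real coverage is
  overdispersed.

Two scale choices deserve explanation. First, `tail_fraction` and the tail
extent are set so that total enrichment is roughly a quarter of a control
library. Depth normalization — the method's own normalization — presumes
that enrichment is a minor fraction of reads; the synthetic chromosome
packs elements ~10× denser than a real genome does, so the per-element
flank mass must be correspondingly smaller than real browser tracks
suggest, or the genotype depth ratio would distort every element's
contrast. Second, counts are drawn independently per base
(`fragment_length = 1`), matching a "Poisson reads/bp" background
specification; setting `fragment_length > 1` instead draws fragment anchors
and piles them up, which autocorrelates values over the footprint the way
extended-read tracks are correlated (the marginal distribution stays
Poisson). The pileup mode is more realistic for peak-shape questions but
makes the 6-position window statistic effectively a single draw, which at
these coverage levels is dominated by noise — a useful reminder that the
window statistic implicitly assumes near-independent per-base sampling
relative to the window length.

What passing tests on these simulations show — and do not show. They show
the statistics, thresholds, clustering rules and smoothing behave as
specified, that classes are recoverable when the generative truth matches
the model, and that the distal-loss diagnostic fires only under genuinely
differential tail attenuation. They do not show robustness to mappability
artifacts, copy-number differences between lines, PCR duplicates, unequal
fragment-size distributions, or mis-specified element boundaries — none of
which the generator emulates.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open (BED convention) everywhere, including
  bedGraph I/O; one convention end to end removes off-by-one drift.
* Fragment-length estimation maximizes the plus/minus 5′-end density
  correlation over shifts `0..max_shift`; the smallest shift wins ties, so
  the estimate is deterministic.
* `significant_regions()` with SD 0 on a nonuniform track warns and falls
  back to thresholding at the mean; a flat track yields no regions.
* A zero signal dynamic range disables the weak-signal filter with a
  warning rather than removing everything.
* Loess fits require `floor(n * span) >= degree + 2` points per local
  window and error otherwise, naming the span.
* `relative_difference()` errors when both genotype means are zero; the
  ratio is `NA` when the control mean is zero.
* Random background bins are sampled with replacement by default; the
  no-self-overlap mode errors when the non-excluded territory cannot host
  the requested bins, reporting what is available.
* Bit-for-bit reproducibility: every stochastic step (simulation, background
  bin placement) takes an explicit seed, and report files contain no
  timestamps.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated data
at the study's scale: 2 Mb chromosomes, 60 elements, 8 libraries per
simulation, with 10-seed recovery sweeps and 20-seed profile-mechanism
sweeps. A full simulation plus scoring takes a few seconds on one CPU; the
whole suite runs in a couple of minutes.

# Known limitations

* The classifier applies fixed RD thresholds; it does not model count
  uncertainty per element, so elements near a threshold flip class under
  resampling.
* The weak-signal filter's range-fraction reading is sensitive to a single
  extreme element (it sets the range); the quantile variant is provided.
* Profile confidence bands are not computed by default; the pointwise
  bootstrap over peaks is straightforward but costs 500 profile rebuilds.
* With only two replicates, the reproducible peak-calling mode cannot
  distinguish a genuine single-replicate dropout from noise; it errs on the
  conservative side.
* The genomic background SD includes enriched bases, slightly inflating the
  peak threshold on small, signal-dense genomes; a quantile-trimmed
  alternative would lower it but is not what the rule states.
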