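# predep

Comparative ChIP-seq occupancy analysis at Polycomb Response Elements
(PREs), for researchers asking how strongly PRC2 recruitment at each
regulatory element depends on PRC1.

In *Drosophila* lines lacking PRC1 (Psc/Su(z)2) or PRC2 (Su(z)12), ChIP-seq
of the remaining complex shows that some elements lose nearly all occupancy
while others are untouched. `predep` turns per-base read-density tracks and
a catalog of 1 kb candidate elements into per-element dependence calls, and
quantifies whether occupancy around binding-site summits is lost
preferentially at a distance (the looping-derived "tail" signal) rather
than at the summit itself.

## The statistics at its core

* **Element score** — the highest mean over *w* = 6 consecutive positions
  of per-base read density inside the element, depth-normalized to reads
  per million. Replicates must correlate (Pearson r > 0.90) and are
  averaged per genotype.
* **Relative difference** — for mutant and control mean scores *m*, *c*:

  RD = 2(m − c) / (m + c) ∈ (−2, 2),

  with companion ratio m/c. Classification: RD < −1.0 → *dependent*,
  RD > −0.5 → *independent*, else *intermediate*. The same RD on input
  tracks is the processing-bias control (Wilcoxon rank sum comparison).
* **Peak calling** — clusters of coordinates no more than 500 bp apart
  whose values exceed 3 population SDs above the genomic mean; summit = the
  center of the best 6-coordinate window; peaks > 10 kb from their nearest
  neighbor are *isolated*. With replicate tracks, a coordinate must pass in
  every replicate (reproducible mode).
* **Cumulative profiles** — 100 bp bins over ±5 kb around isolated summits,
  replicate-averaged, loess-smoothed (span 0.1); genotype curves are
  evaluated at 50 even offsets, subtracted, and re-smoothed (span 0.2),
  after background subtraction and per-curve summit scaling. Background =
  mean over 999 random 100 bp bins outside called peaks.
* **Synthetic data** — a seeded generator produces coverage tracks with
  known ground truth (element classes, amplitudes, tail parameters) so the
  whole pipeline is testable end to end.

## Worked example

```r
library(predep)

sim <- simulate_tracks(simulation_config(seed = 1))
sim
#> <pre_simulation> 60 elements on 2,000,000 bp, 8 libraries (seed 1)
#>    dependent  independent intermediate
#>           20           20           20

res <- run_pipeline(sim$tracks, sim$catalog)

dplyr::select(tidy(res$classification),
              name, score_control, score_mutant, rd, ratio, dep_class)
#> # A tibble: 28 x 6
#>   name   score_control score_mutant      rd ratio dep_class
#>   <chr>          <dbl>        <dbl>   <dbl> <dbl> <chr>
#> 1 PRE001         11.6         12.7   0.0883 1.09  independent
#> 2 PRE003         11.6          2.00 -1.41   0.172 dependent
#> 3 PRE006         10.6          2.00 -1.37   0.188 dependent
#> 4 PRE008          9.64        10.3   0.0669 1.07  independent
#> 5 PRE009          9.84         1.93 -1.34   0.196 dependent
#> # i 23 more rows

glance(res$classification)[, 1:5]
#> # A tibble: 1 x 5
#>   n_total n_dependent n_intermediate n_independent fraction_dependent
#>     <int>       <int>          <int>         <int>              <dbl>
#> 1      28           8             10            10              0.286

res$profiles$summary
#> # A tibble: 1 x 3
#>   summit_abs distal_abs distal_to_summit_ratio
#>        <dbl>      <dbl>                  <dbl>
#> 1    0.00163    0.00241                   1.48
```

Reading: of the 60 simulated elements, 28 survive the exclusion and
weak-signal filters; their scores are reads-per-million window maxima, and
each row's RD/ratio drives the class call (PRE003 keeps 17% of its control
signal — clearly dependent; PRE001 is unchanged). The profile summary says
the summit-scaled mutant-minus-control difference around isolated peaks is
1.48× larger at 2–5 kb than at the summit — under the default simulation
classes lose summit and tail signal together, so the ratio stays near 1;
with differential tail attenuation it rises an order of magnitude.

`autoplot(res$classification)` draws the RD histogram with class
thresholds, and `plot_profile_comparison(res$profiles)` the genotype
curves, background lines and difference curve.

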