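---
title: "Detecting periodic lamina-associated domain dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting periodic lamina-associated domain dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladcycle)
```

## The problem

Lamina-associated domains (LADs) are broad, mostly heterochromatic genomic
regions that contact the nuclear lamina. After entrainment of the circadian
clock, LAD calls from lamin B1 ChIP-seq can be produced at each circadian
time point (CT) in biological replicates, raising two questions this package
addresses:

1. Do LAD borders oscillate with circadian-range periods (12--36 h), and can
   such oscillations be distinguished from random lamin--chromatin
   interactions?
2. Is periodic gene expression related to LAD geometry -- genes inside LADs,
   near LAD borders, or megabases away -- and to changes in gene-to-nearest-LAD
   distance over circadian time?

The package takes LAD calls (BED intervals per CT x replicate), stranded gene
annotations (BED6) and an FPKM expression matrix as inputs. Upstream steps
(read alignment, domain calling) are out of scope: LAD BED files are the
input contract.

## LAD border standardization

All interval arithmetic uses 0-based half-open coordinates (the BED
convention) and is backed by `GenomicRanges`. Overlapping or book-ended
intervals are merged during normalization, because domain callers emit
contiguous domains and book-ended fragments are indistinguishable in
coverage terms.

For each LAD, the **maximal footprint** (`cov_max`) is the union of that
LAD's coverage over every CT and replicate; it receives the reference value
1. Within a cov_max region $[S, E)$ of length $L$, a sample's fragments with
leftmost start $a$ and rightmost end $b$ give standardized border values

$$\mathrm{rel}_{5'} = 1 - \frac{a - S}{L}, \qquad
  \mathrm{rel}_{3'} = 1 - \frac{E - b}{L},$$

so 1 means the border reaches the cov_max limit and 0 means the LAD is
absent from that sample. Internal splits and fusions between $a$ and $b$ are
deliberately ignored: only the outermost extremities enter the series. Since
LADs are unstranded, 5' denotes the lower genomic coordinate. We normalize by
the full cov_max length $L$ (a border retracted by $d$ scores $1 - d/L$):
it is the unique linear-in-bp scale that satisfies both stated endpoints of
the 0--1 convention.

Borders are filtered for variability before rhythm fitting. The variability
criterion is exposed as a parameter (`min_sd` on the standardized values,
default: any variation at all) rather than fixed, since no principled
universal cutoff exists; analyses of real data should report the value used.

## The rhythm engine

Each border (and each gene's z-scored FPKM series) is tested with two
complementary detectors, whose p-values are merged by Fisher's method.

**JTK rank test.** For each candidate period $P \in \{12, 18, 24, 30, 36\}$ h
(2--6 sampling intervals) and each phase lag on the sampling grid, the
observed values are compared with the cosine reference
$\cos(2\pi (t - \mathrm{lag})/P)$ through the Jonckheere--Terpstra statistic
$J$ over the reference's tie groups. The null distribution of $J$ is exact:
the convolution of Mann--Whitney null distributions over successive groups,
computed by integer dynamic programming and cached per group-size signature.
The reported p-value is the one-sided upper tail of the best (minimum-p)
configuration, without multiplicity correction. Two consequences are
documented rather than hidden:

* The lag scan covers the whole cycle, so anti-phase signals are captured at
  the shifted lag; the one-sided tail on the maximized statistic is the
  coherent choice. At $n = 6$ time points the exact null is coarse (e.g. the
  best attainable p for a 24 h reference is $1/60$), which bounds the
  evidence a single short series can provide.
* Taking the minimum over $\sim$20 configurations without correction makes
  the test anticonservative under the null. This is a property of the
  published convention the engine reproduces; see *Calibration* below.

Ties among data values enter $J$ with weight $1/2$ against the
distinct-value exact null, which is slightly conservative; an all-tied
(constant) series carries no concordance information and returns $p = 1$.
Periods 0 and 6 h are excluded from the candidate set: 6 h equals the
sampling interval (no phase information at this resolution) and 0 h is not a
period; the candidate set is configurable.

**Lomb--Scargle periodogram.** The classical variance-normalized periodogram
with the phase-invariant $\tau$ offset is evaluated on a frequency grid
covering 12--48 h, oversampled 10x relative to the independent-frequency
spacing $1/T$ to refine the peak location. Peak significance uses the
extreme-value tail $p = 1 - (1 - e^{-z})^M$. $M$ is the number of
*independent* frequencies in the scanned range,
$M = \lfloor (f_{hi} - f_{lo})\,T \rfloor + 1$, and deliberately does not
grow with the oversampling factor: oversampled grid points are strongly
correlated, and counting them as independent trials would overwhelm the
bounded peak power of short series (at $n$ points the normalized power
cannot exceed $(n-1)/2$, i.e. 2.5 at $n = 6$, so an $M$ of ~20 would push
every p-value above 0.8 regardless of signal). With 6 points the
Lomb--Scargle component contributes little power on its own; its role in the
combination is to reward spectral concentration and to estimate a
real-valued period.

**Fisher combination and replicates.** $k$ p-values are merged through
$X = -2\sum \ln p_i \sim \chi^2_{2k}$. By default each replicate's
$\{p_{JTK}, p_{LS}\}$ pair is combined first (4 df), then the per-replicate
p-values are combined across the $k$ replicates with $2k$ df. The
alternative `"methods"` strategy stacks replicates as repeated time points,
yields one p-value per method, and combines the two with 4 df; it is
switchable in `rhythm_config()` because the two readings of the replicate
bookkeeping are both defensible and give similar rankings.

**Periods, phases, groups.** The reported period is the mean of the JTK and
LS periods (averaged across replicates first). Amplitude, base level and
phase come from a post-hoc least-squares cosine fit at the mean period on
replicate-averaged values; the phase is the time of the first maximum in
$[0, P)$. Periods are assigned to groups 12, 18, 24, 30 h, each $\pm 3$ h
(half the 6 h sampling resolution); exact midpoints (15, 21, 27 h) go to the
lower center. Phases snap to the quadrants $0, \pi/2, \pi, -\pi/2$; for the
12 h group only $0$ and $\pi$ are reported, because a 12 h cosine in
quadrature phase sampled every 6 h is identically zero -- indistinguishable
from a constant series (the engine returns $p = 1$ for it, and the test
suite asserts this).

### Calibration

On pure-noise series with 2 replicates of 6 points, the combined p-value is
anticonservative: roughly half of noise series fall below 0.05, and a few
percent below 0.005 (the package's tests assert the stringent-tail rate stays
below 5%). This is the price of the minimum-p scan and the dependence between
the two detectors, and it is why the stringent threshold of 0.005 -- not
0.05 -- should be used to call a border "periodic" in this design, with the
randomization test as an orthogonal guard. Thresholds of 0.005 (stringent)
and 0.05 (relaxed) are the defaults in `rhythm_config()`.

At these series lengths the 30 h group is the hardest to label correctly:
the periodogram peak of a 30 h cosine observed over a 30 h span lies within
one frequency-resolution element of 36 h, so the mean period can drift past
the 33 h window edge. Overall period-group recovery on the synthetic study
conditions (amplitude 0.4, noise sd 0.05, 2 replicates) is ~90%.

## Randomization test

Detected periodicity should be imposed by the order of CTs, not by random
lamin--chromatin interactions. The test shuffles the CT order globally --
the same permutations applied to every border, replicate pairing preserved --
three times by default, excluding the identity. Each shuffled series is
re-fitted; its significant period group (or "none") is compared with the
experimental one. If the experimental group differs from at least two
shuffled outcomes, the verdict passes. "Different" compares period-group
labels (including significant-to-none transitions): an exact-hour comparison
would be noise-dominated. A series that is not significant experimentally
has no periodicity to validate and never passes. Replicate labels are not
permuted, only CT order; permuting replicates would test replicate
exchangeability, not time-order dependence.

## Gene--LAD geometry

A gene belongs to a LAD when its transcription start site (a single bp;
`start` on +, `end - 1` on -) lies inside the LAD. Distances use replicate
intersects of LAD calls at each CT and respect strand: the 5' gene end is
measured to the nearest 3' LAD border and vice versa. A gene entirely inside
a LAD keeps the containing LAD excluded and is measured to the first
neighboring LAD on each side; a LAD overlapping (but not containing) a gene
gives distance 0 on that side; a side with no LAD on the chromosome is
missing. The headline per-gene distance is `min(d5, d3)` -- the only
reduction consistent with "nearest" -- but both sides are always emitted.
Distance variation between three CTs spanning two 12 h intervals is reported
as signed deltas with quadrant labels; genes lacking a distance at any of
the three CTs are excluded with a logged reason. Gene capture around LADs
uses a 2.5 Mb window on each side of the LAD footprint, with genes
overlapping the LAD itself reported separately.

## Expression classification

FPKM series are z-scored per gene across all samples before fitting, so
classification depends on waveform, not expression level. A gene is
"expressed" when FPKM exceeds a configurable threshold (default 0) in at
least one sample; others are excluded with a reason. Genes with combined
p below the stringent threshold are `periodic-<group>` (or `periodic-other`
outside every group window); `non-periodic` genes are those discordant with
every tentative cosine, $0.9999 < p < 1$ (both bounds strict, so an exactly
constant gene at $p = 1$ does not qualify). Significance comes from the
implemented analytic machinery, not from scrambling FPKM values; the CT-order
randomization module provides the permutation-style cross-check where needed.

## The synthetic-data generator

The generator emulates the study design so every stage is testable without
downloads: a toy genome (default 2 chromosomes x 60 Mb) with non-overlapping
base LADs (0.2--0.8 Mb, confined to the proximal 60% of each chromosome so
that "far" gene placements are always feasible); genes placed inside LADs,
near borders (within 2.5 Mb), or far (>= 5 Mb), with ground-truth labels;
and a 6 h x 30 h grid with 2 LAD replicates and 3 expression replicates --
the study conditions.

Border dynamics per (LAD, side) are `constant`, `noise`, or `cosine`:
$\mathrm{rel}(t) = \mathrm{clamp}(\mathrm{baseline} + A \cos(2\pi (t -
\phi)/P) + \varepsilon,\, 0,\, 1)$, with defaults baseline 0.5, amplitude
0.4 and replicate noise sd 0.05 (an 8:1 amplitude:noise ratio -- clean but
not noiseless oscillations whose excursions stay inside the unit interval,
so clamping is rare; clamp events are counted). Whole-LAD appearance and
disappearance is modelled by a cosine gate. Relative values are converted to
genomic borders by rounding half-up to whole bp, so the measurement chain
inverts the generator to within $1/L$ quantization (asserted in tests).
Expression series use the same cosine model on the FPKM scale (default base
10, amplitude 4, noise sd 1, i.e. 4:1 amplitude:noise), truncated at 0 with
truncation counted. Replicate noise is independent per replicate and side.
Every generator takes an explicit seed and is byte-reproducible.

What the generator does *not* emulate: autocorrelated biological drift
between CTs, replicate-specific biases, domain-caller artifacts (split/merge
instability, bin-size effects), and the NS-to-CT0 entrainment biology (the
NS sample is a simple retract-and-drop construction for gain/loss testing).
Passing tests on synthetic data therefore demonstrate correctness of the
measurement and inference chain under the stated model, not performance on
real ChIP-seq-derived LAD calls.

## Numerical and design choices

* Exact JTK nulls are cached per group-size signature; all computations are
  integer-exact until the final division.
* Degenerate inputs are handled explicitly: constant series give $p = 1$ and
  no period; empty interval sets give a missing Jaccard (not 0, which would
  fake "no overlap"); empty LAD sets give count 0 and missing median size.
* Ties in config scans break toward the first scanned configuration
  (periods ascending, lags ascending); group-assignment midpoints tie to the
  lower center. Both rules are asserted in tests.
* The pipeline writes no wall-clock timestamps, so identical configuration
  and seeds yield byte-identical output trees (asserted end to end).
* Problem sizes used by the test suite and the acceptance script -- 200
  labelled borders for recovery, 200 noise borders for calibration, 100
  LADs for inversion checks, 100 simulations for the randomization pass
  rate, a 20-LAD/90-gene default study -- were chosen as the smallest sizes
  at which the binomial tolerances of the asserted properties are
  informative.

## Known limitations

* Six time points is the floor of what these detectors can use; absolute
  p-values at this length are coarse (JTK) and anticonservative in
  combination (see *Calibration*). Rankings are more trustworthy than
  absolute rates; the stringent threshold plus randomization is the
  recommended calling rule.
* The 30 h period group inherits a downward power bias from spectral
  leakage at the edge of the observable band.
* Gene-distance rules treat a LAD strictly inside a gene as contributing to
  neither side; such configurations are vanishingly rare for real LADs
  (LADs are orders of magnitude larger than genes) but can be constructed.
* The engine assumes a shared, even time grid across replicates; missing
  cells are rejected rather than imputed.
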