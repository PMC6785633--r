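# ladcycle

Quantifies lamina-associated domain (LAD) dynamics across a circadian time
course and detects periodic oscillations in LAD border coverage and in gene
expression.

LADs are broad genomic regions in contact with the nuclear lamina, called
from lamin B1 ChIP-seq at each circadian time point (CT) and biological
replicate. `ladcycle` answers the question *do LAD borders, and the genes in
or near LADs, oscillate with circadian-range periods?* for anyone with LAD
BED files per CT × replicate, a stranded gene annotation (BED6) and an FPKM
matrix. It provides:

* **Interval algebra** on LAD calls (normalize, intersect, subtract, union,
  Jaccard), backed by `GenomicRanges`, with BED i/o.
* **Border standardization**: per-LAD maximal footprints (cov_max = the
  union of a LAD's coverage over all CTs and replicates, reference value 1)
  and standardized 5′/3′ border series: for a cov_max region `[S, E)` of
  length `L` and a sample's outermost fragment extent `[a, b)`,
  `rel5 = 1 − (a − S)/L`, `rel3 = 1 − (E − b)/L` (1 = border at the cov_max
  limit, 0 = LAD absent).
* **A rhythm engine**: JTK rank test (Jonckheere–Terpstra statistic against
  cosine references at candidate periods 12–36 h, exact permutation null by
  Mann–Whitney convolution) + Lomb–Scargle periodogram (12–48 h scan,
  peak significance `p = 1 − (1 − e^{−z})^M`) + Fisher combination
  (`−2Σ ln p ~ χ²(2k)`) across methods and replicates; period groups
  12/18/24/30 h (± 3 h) and phase quadrants 0, ±π/2, π.
* **A randomization test**: the CT order is shuffled globally three times;
  a border's periodicity is considered imposed by circadian time when it
  differs from at least two shuffled outcomes.
* **Gene–LAD geometry**: TSS-based LAD membership, strand-aware
  gene-to-nearest-LAD distances per CT (5′ gene end to nearest 3′ LAD
  border and vice versa), distance-variation quadrants, and gene capture
  within 2.5 Mb of LAD borders.
* **A synthetic-data generator** producing toy genomes, LAD time courses
  with injected cosine border dynamics (known period/phase/amplitude) and
  FPKM matrices with known labels, so the whole chain is testable without
  external data.

## Worked example

Fit one LAD border series (2 replicates, CT0…CT30 at 6 h) carrying a 24 h
oscillation, then validate it against shuffled CT orders:

```r
library(ladcycle)
g <- time_grid()           # CT0..CT30, 6 h spacing, replicates r1/r2
t <- g$times_h
set.seed(42)
mk <- function() pmin(pmax(0.5 + 0.4 * cos(2 * pi * (t - 6) / 24) +
                           rnorm(6, 0, 0.05), 0), 1)
m <- rbind(r1 = mk(), r2 = mk())   # standardized border values in [0, 1]

fit <- meta_fit(m, g, series_id = "LAD0007:5p")
fit[, c("series_id", "p_combined", "period_mean", "period_group",
        "phase_h", "amplitude")]
#>    series_id p_combined period_mean period_group phase_h amplitude
#> 1 LAD0007:5p     0.0038        24.2           24    5.87     0.394

v <- randomization_verdict(m, g, shuffle_ct_orders(g, 3, seed = 1),
                           series_id = "LAD0007:5p")
v[, c("experimental_group", "shuffle_groups", "n_discordant", "passes")]
#>   experimental_group shuffle_groups n_discordant passes
#> 1                 24   24,none,none            2   TRUE
```

The border is called periodic with a 24 h group (combined p = 0.0038, below
the stringent 0.005 threshold), its fitted phase (first maximum) is ≈ 6 h
with amplitude ≈ 0.39 — matching the injected signal — and the verdict
passes: two of three shuffled CT orders break the periodicity, so the rhythm
is imposed by the true time order.

The full chain — simulate a study, standardize borders, fit rhythms,
randomize, compute gene–LAD distances, classify expression, report — runs
as:

```r
run_pipeline(default_config(seed = 1), "out/")
```

or from a shell via the thin wrapper:

```sh
Rscript inst/scripts/ladcycle.R all --outdir out/ --seed 1
```

Each stage writes TSVs under `out/<stage>/`; `out/report/summary.tsv` counts
cov_max LADs, variable borders, periodic borders/LADs at the stringent
(0.005) and relaxed (0.05) thresholds, randomization passes, and periodic
genes. Outputs are byte-identical across runs with the same config and seed.

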