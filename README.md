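# clonetrace

Is the ability of a somatic cell to reprogramme to pluripotency decided
by chance, or inherited through cell division? Split-dish cellular
barcoding answers this at the lineage level: fibroblasts are tagged with
lentiviral 30-bp DNA barcodes at low MOI, allowed one population
doubling, split across four dishes, and reprogrammed. Sisters of one
progenitor land in different dishes 75% of the time, so a barcode
recovered from several dishes means clonally related cells reprogrammed
in parallel. Under purely stochastic reprogramming the expected number
of shared barcodes is

> T = N · C · E²

(N transduced cells, C the sister-split chance, E the reprogramming
efficiency). Observed sharing far above T implies the fate is heritable,
and the *heritability level* h — the probability that the sibling of a
reprogrammed cell is itself reprogrammed — can be estimated by fitting a
stochastic simulation of the whole experiment to the observed overlap
counts.

`clonetrace` implements the complete workflow for analysts of such
experiments:

* **Closed-form estimators** — Poisson MOI from infected fractions,
  mark–recapture library diversity, reprogramming efficiency, expected
  shared barcodes (`moi_from_gfp`, `estimate_diversity`,
  `reprogramming_efficiency`, `expected_shared`).
* **Barcode recovery from FASTQ** — signature demultiplexing, flank
  trimming, quality/length filters, greedy edit-distance clustering at
  80% identity (bit-parallel matcher in C++), singleton and cross-dish
  filters, overlap tables with spike-in control reporting
  (`extract_barcodes` and its parts).
* **An agent-based simulator** of seeding, infection (zero-truncated
  Poisson integrations), division, four-dish plating, loss of material
  and quota-driven reprogramming with heritable sister fate
  (`sim_params`, `run_simulation`).
* **Heritability grid fitting** — Kruskal–Wallis compatibility between
  simulated and observed shared counts over a loss × heritability grid,
  with exact permutation p values for singleton observations
  (`grid_fit`, `kw_test`).
* **A synthetic-data generator** producing FASTQ reads plus a
  ground-truth manifest, with controlled PCR bias, sequencing error and
  spike-ins (`generate_library`, `generate_ground_truth`,
  `generate_fastq`), so every stage is testable against known truth.

## Worked example

Simulate a scaled experiment with heritability 0.2, recover barcodes
from noisy reads, and fit h back:

```r
library(clonetrace)

lib    <- generate_library(20000, 30, seed = 101)
params <- sim_params(2000, moi = 0.6, diversity = 20000, loss = 0.2,
                     heritability = 0.2, mu = 80, si = 10)
truth  <- generate_ground_truth(params, lib, seed = 102)
fq     <- generate_fastq(truth, read_model(error_rate = 0.005,
                                           pcr_sigma = 0.3,
                                           mean_reads = 20),
                         dir = tempfile(), seed = 103)
res    <- extract_barcodes(fq$fastq)
print(res$overlap)
#> overlap_table
#>   barcodes in exactly k dishes: k=1: 170, k=2: 67, k=3: 12, k=4: 0
#>   shared (>= 2 dishes): 79
#>   distinct barcodes per dish: 86, 93, 88, 73
#>   spike-in controls detected: 2
```

The shared count (79 here) is the signal: barcodes seen in two or more
dishes. Fit the heritability at the true loss value:

```r
fit <- grid_fit(as_observed(res$overlap),
                sim_params(2000, 0.6, diversity = 20000, mu = 1, si = 0),
                d_grid = 0.2, h_grid = seq(0, 0.6, 0.1),
                replicates = 100, seed = 99)
print(fit)
#> heritability_fit (100 replicates per grid point, alpha = 0.05)
#>   minimal accepted heritability: 0.20
#>   d = 0.2: best-fit h = 0.20, accepted {0.2, 0.3}
```

The best fit is exactly the heritability the data were generated with:
about one in five siblings of a reprogrammed cell reprogrammes in
synchrony, far above the per-cell efficiency.

The numbered scripts under `analysis/` run the full set of analyses
(closed-form estimates, pipeline round-trip, library validation,
heritability fitting and the progeny-class decomposition) and write
their tables under `results/`. The methods vignette
(`vignettes/clonetrace-methods.Rmd`) documents the model, its
assumptions and the numerical choices.

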