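# helixscan

Contact-map analytics for strongly condensed (erythroid-like) genomes.

Mature nucleated erythrocytes of birds, reptiles and amphibians — and late
mammalian erythroblasts — fold their chromosomes unlike any typical
interphase cell: TADs and loops are gone, A/B compartments persist, and the
Hi-C map gains a *second diagonal*, a band of elevated contact frequency at
a fixed 10–30 Mb separation. The band is the fingerprint of a helical
loop-array scaffold: loci one helical turn apart touch, so the band sits at
`T = loop size × loops per turn`. `helixscan` packages the statistics
needed to quantify all of this from binned intra-chromosomal contact
matrices, together with a seeded synthetic map generator so that every
stage can be validated against planted ground truth without any sequencing
data.

The package is aimed at computational chromatin biologists who already have
binned cis contact matrices (text COO + bin tables; adapters for binary
containers are out of scope) and want reproducible, scriptable answers to:
is there a periodic long-range band, where is it, does it coexist with
compartments, are TADs present, and do replicates agree?

## What it computes

* **Balancing** — iterative correction (ICE): multiplicative per-bin
  weights `w` such that `w_i c_ij w_j` has uniform row sums over unmasked
  bins; low-coverage bins are masked by a coverage quantile rule
  (`balanceICE`).
* **P(s)** — mean balanced contact frequency per genomic separation `s`,
  raw per diagonal and aggregated on a geometric grid (10 bins/decade),
  genome-wide and per chromosome (chromosomes > 9 Mb), with the log-log
  derivative `d log10 P / d log10 s` (`computePs`, `psDerivative`).
* **Second diagonal** — smoothed `log10 P(s)` minus a two-point log-log
  chord baseline over a 5–50 Mb search window; the band is the maximal
  interior local maximum of the residual, called when its prominence
  exceeds `theta = 0.10 log10` (`detectSecondDiagonal`,
  `assessChromosomes`).
* **TADs** — TAD-separation score (z-scored multi-window insulation),
  boundary calls at score minima that drop `delta = 0.05` below their
  flanks, a P(s) TAD-shoulder metric over 10^5–10^6 bp, and aggregate
  corner-loop pileups with a central observed/expected enrichment
  (`tadSeparationScore`, `callTads`, `psShoulderMetric`, `apaPileup`).
* **Compartments** — PC1 of the Pearson correlation matrix of the
  observed/expected map (`compartmentPC1`).
* **Reproducibility** — HiCRep-style stratum-adjusted correlation, smoothed
  with `h = 3`, strata up to 5 Mb (`scc`).
* **Simulation** — expected maps
  `E(i,j) = D(s)·C(i,j)·Td(i,j)·H(s)` with power-law decay
  `D = (s/s0)^-α`, compartment checkerboard `C = 1 + c·e(i)e(j)`,
  TAD blocks `Td = 1 + t` (corner loops `+ℓ`), helical band
  `H = 1 + A·exp(-(s-T)²/2σ²)`, Poisson-sampled at a chosen depth, with
  full ground truth (`simulationConfig`, `presetConfig`, `simulateHiC`).
* **Pipeline** — `runPipeline()` chains simulate/load → SCC gate → merge →
  balance → P(s) → band → TADs → compartments and writes TSV/JSON reports.

## Worked example

Simulate a chicken-like erythrocyte chromosome (150 Mb, 100 kb bins,
200 kb loops, 75 loops per turn, 10 M contacts), balance it, and ask for
the band and the compartments:

```r
library(helixscan)

genome <- data.frame(chrom = "chr1", length = 150e6)
cfg <- presetConfig("erythrocyte", genome, binSize = 1e5, depth = 1e7,
                    seed = 1, loopSize = 2e5, loopsPerTurn = 75)
sim  <- simulateHiC(cfg)
mat  <- balanceICE(sim$matrices$chr1)
mat
#> ContactMatrix: chr1 (1.5e+08 bp), 1500 bins @ 1e+05 bp, balanced (30 masked bins)
#>   total counts: 9996861

detectSecondDiagonal(computePs(mat)$genome)
#> Second diagonal DETECTED at 15.30 Mb (prominence 0.135 log10, theta 0.10)
#>   search range: 5.0-50.0 Mb

pc1 <- compartmentPC1(mat, orientationRef = sim$truth@compartments$chr1)
cor(pc1@pc1, sim$truth@compartments$chr1, use = "complete.obs")
#> [1] 0.9935446
```

The detector localizes the planted helical turn (`T = 0.2 Mb × 75 =
15 Mb`) at 15.3 Mb with a prominence of 0.135 log10 units (≈ 36 %
enrichment over the decay baseline), and the compartment eigenvector
recovers the planted checkerboard with r = 0.99 on the *same* matrix — the
coexistence of band and compartments that distinguishes these maps from
mitotic ones.

## Layout

```
R/                 S4 classes, generics and the analysis modules
tests/testthat/    unit, property and end-to-end suites (all synthetic)
scripts/           acceptance.R (see above)
vignettes/         methods vignette: model, parameters, design choices
```
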