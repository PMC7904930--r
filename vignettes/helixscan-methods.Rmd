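---
title: "helixscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`helixscan` quantifies the large-scale organization of condensed erythroid
genomes from binned cis Hi-C matrices: distance decay, the helical-turn
"second diagonal" band, TAD-level structure (or its absence), A/B
compartments, and replicate agreement. This vignette documents the models
behind each statistic, the parameters that matter, the numerical choices,
and what the synthetic generator does and does not emulate.

## Data model and conventions

All coordinates are 0-based, half-open base pairs; bin `i` covers
`[i·b, min((i+1)·b, L))` for bin size `b` and chromosome length `L`, and a
position maps to bin `floor(pos / b)`. A `ContactMatrix` stores one
chromosome's symmetric non-negative count matrix plus optional balancing
weights; masked bins carry `NA` weights and are excluded from every
downstream mean, correlation and eigenvector. Only intra-chromosomal
matrices are modeled: every statistic in scope (P(s), band, insulation,
PC1, SCC) is a cis quantity, and trans pairs are dropped at binning with a
reported count.

## Balancing

`balanceICE()` is standard iterative correction: repeat
`w_i ← w_i / (r_i / mean(r))` with `r_i = w_i Σ_j c_ij w_j` until the
relative variance `var(r)/mean(r)²` falls to `tol` (default `1e-5`,
`maxIter = 200`; non-convergence is an error that reports the variance
reached). Two mask rules apply before iteration: zero-marginal bins are
always masked, and bins below the 2 % coverage quantile of the remaining
marginals are masked as well — the conventional guard against the
unstable weights that near-empty rows produce. The scalar gauge freedom is
fixed by `mean(w) = 1` over unmasked bins, which makes the weights (and
balanced values) invariant under global count scaling.

## P(s) and its derivative

For every raw diagonal `d > 0` the curve records the mean balanced value
over unmasked bin pairs (masked bins leave both numerator and
denominator). Chromosomes shorter than 9 Mb are excluded; the
genome-average curve pools pairs across passing chromosomes, i.e. it is
pair-count weighted, matching the behaviour of the usual expected-curve
implementations (an equal-weight average of per-chromosome curves is the
other defensible choice; pair weighting was picked and is stated here
because the two differ when chromosome lengths are very uneven).

Aggregation onto the plotting grid uses 10 geometric bins per decade,
anchored at integer powers of ten so the grid never depends on the data.
The representative distance of a bin is the **pair-weighted geometric mean
of its member distances**, not the midpoint of its edges: at small `s`
a geometric bin holds zero or one discrete diagonals, and edge midpoints
misplace those bins badly enough to distort the log-log derivative by
several tenths. With member-mean abscissas, an exact power law sampled on
the grid differentiates to exactly its exponent, and a noise-free
decay-only simulation recovers its configured exponent to within 0.05
across 10^5.5–10^7.5 bp — both are tested.

The derivative is the finite difference of `log10 P` against `log10 s`
between adjacent grid points, reported at inter-bin geometric midpoints,
with optional moving-average smoothing (window 1 by default; band
localization never relies on this coarse grid, see below).

P(s) is reported in arbitrary balanced units rather than normalized to a
probability; all downstream statistics are scale-free (chords, residuals
and derivatives in log space), so the overall scale cancels everywhere it
could matter.

## Second-diagonal detection

A helical loop array with loop size `ℓ` and `k` loops per turn places
loci one turn apart at genomic distance `T = ℓ·k`, visible as a band
parallel to the main diagonal and as a local hump on P(s). The detector
works on the **raw per-diagonal** curve because the question "15 or
17 Mb?" is finer than a 10-per-decade grid:

1. smooth `log10 P` with a fixed-width moving average (500 kb default,
   shrinking windows at the edges);
2. take a two-point chord baseline in log-log space between the smoothed
   values at the search-range ends (5–50 Mb by default);
3. the band is the maximal interior local maximum of the residual;
   `detected` requires prominence ≥ `theta = 0.10 log10` (≈ 26 %
   enrichment), with ties in the argmax broken toward smaller `s`.

The two-point chord was chosen over a flank power-law fit for robustness
and reproducibility: it makes no assumption beyond local log-log
linearity of the decay, and for a multiplicative Gaussian band the
power-law part cancels exactly, so the residual peaks at `T` by
construction. `theta` is exposed because no quantitative definition of an
"obvious" band exists in the literature this implements; 0.10 keeps the
false-detection rate on band-free simulations at or below 1-in-20 seeds
while detecting amplitude-0.4 bands with a wide margin (both properties
are tested).

One guard matters in practice: the detector only trusts distances up to
`maxSpanFraction = 2/3` of the curve extent. The last third of a
chromosome's P(s) rests on very few bin pairs, all touching the
chromosome ends and often lying in a single compartment block; those
diagonals routinely show upturns larger than a genuine band and would
otherwise either fake a detection or drag the chord baseline up and mask a
real one. With the guard, a planted 15 Mb band is recovered on a 40 Mb
chromosome, while a ~20 Mb chromosome becomes honestly marginal (the
search window collapses toward the band itself) — mirroring the
observation that the band stops being visible on short chromosomes.
Per-chromosome assessment additionally requires length ≥ twice the lower
search edge and ≥ 10 usable diagonals in range; shorter chromosomes are
reported as not assessable rather than "band absent".

## TAD-level statistics

**TAD-separation score.** For each window `w` in
`{100, 200, 300, 500} kb` and bin `i`, the mean balanced contact in the
`w × w` square straddling the diagonal at `i` (contacts crossing `i`);
each window's track is z-scored along the chromosome and tracks are
averaged. The window set is configurable and recorded, since only the
boundary-call `delta` is pinned by convention.

**Boundary calls.** Local minima whose score sits ≥ `delta = 0.05` (z
units) below the mean of their flanks (flank span = largest window), with
two extra rules: a minimum must be at least `minDepthZ = -1.5` deep in
absolute z — the delta test alone admits shallow noise dips, a job done
in insulation-based callers by an additional statistical test that this
package deliberately does not reproduce — and one boundary is kept per
insulation valley (greedy suppression by depth within the smallest
window), because a wide valley otherwise yields several calls a bin or
two apart. Both parameters are exposed. On synthetic fibroblast-class
maps these defaults recover planted boundaries at one-bin tolerance with
recall above 0.8; on TAD-free erythrocyte-class maps the only deep minima
are compartment sign flips, which is exactly how insulation callers
"find TADs" in erythroid data.

**Shoulder metric.** The maximal positive deviation of `log10 P` from the
chord joining the curve at 10^5 and 10^6 bp: TAD-scale compaction lifts
the curve inside that window, an erythroid curve is flat (metric ≈ 0).
On the log-log derivative the same physics appears as a deep dip at TAD
scale followed by a recovery, rather than a hump inside the window — the
tests assert that faithful signature.

**Corner pileups.** Windows of `±flank` around anchor bin pairs are cut
from the observed/expected matrix (expected = per-diagonal chromosome
mean), averaged entrywise, and summarized by the center pixel over the
mean of the four corner blocks. Corner blocks are `3 × 3` when the window
allows and shrink to `min(3, flank/b)` otherwise — with the conventional
10 kb flank at 10 kb bins the window is 3 × 3 and the normalizer degrades
to the corner pixels, so a larger flank (100 kb) is recommended for
stable enrichments. Windows clipped by chromosome ends are dropped and
counted. For anchors at planted corner loops on a noise-free map with no
TAD factor, the enrichment equals `1 + ℓ` exactly (tested); with a TAD
factor the corner blocks straddle the domain edge and the enrichment
exceeds the naive `(1+t+ℓ)/(1+t)` ratio.

## Compartments

`compartmentPC1()` follows the standard recipe: observed/expected by
per-diagonal means, Pearson correlation matrix of the O/E columns over
unmasked bins, leading eigenvector of the correlation (not covariance)
matrix. Empty far diagonals leave isolated `NA` pixels on unmasked bins;
these carry no checkerboard information and are set to the neutral O/E
value 1 before the correlation rather than paying for pairwise-complete
covariances. The eigenvector sign is arbitrary; without an external
orientation track (GC or gene density are deliberately not assumed — the
species this serves lack a uniform reference) the first non-zero entry is
made positive, and when a reference track is supplied the sign is chosen
to correlate positively with it. The orientation source is always
recorded. At least 20 unmasked informative bins are required; fewer is an
error, not a silent empty track.

## Replicate reproducibility

`scc()` implements the stratum-adjusted correlation: both matrices are
smoothed with a `(2h+1)²` mean filter (`h = 3` by default; shrinking
windows at matrix edges, no padding), Pearson `r_k` is computed per
diagonal offset `k` up to `maxDist = 5 Mb`, and the score is the
variance-weighted mean with `w_k = N_k·sd(a_k)·sd(b_k)`; zero-variance
strata are skipped and the per-stratum table is returned for audit. Raw
counts are the default input (the original algorithm's convention);
balanced values can be compared instead and the choice is recorded by the
caller. `scc(A, A) = 1` exactly, and the score is symmetric and invariant
under joint global scaling.

## The synthetic generator

The generator produces the statistical structure the analyses assume —
nothing more. Expected intensity factorizes per pixel as

```
E(i,j) = D(s) · C(i,j) · Td(i,j) · H(s),       s = |i-j|·b
D = (max(s, b)/s0)^-α          power-law decay (diagonal set to the s = b value)
C = 1 + c·e(i)e(j)             compartment checkerboard, e ∈ {±1}
Td = 1 + t (+ ℓ at corners)    TAD blocks and corner loops
H = 1 + A·exp(-(s-T)²/2σ²)     helical-turn band, T = loopSize·loopsPerTurn
```

scaled so the expected upper-triangle total equals `depth·L/150 Mb`, then
Poisson-sampled per pixel. Compartment labels alternate in blocks with
exponential lengths (mean 3 Mb); TAD lengths are uniform in 400 kb–1.2 Mb;
all draws are fully determined by the config seed, and ground truth
(profile, boundaries, loop anchors, period) is always emitted.

Defaults: `α = 1` (interphase-like decay), `s0 = b`, `A = 0.4`,
`σ = 1.5 Mb`, `c = 0.3`, `depth = 10⁷` per 150 Mb chromosome — a band
that is detectable but far from dominant at realistic sequencing depth.
The two presets encode the qualitative map classes the package exists to
separate: `erythrocyte` (t = ℓ = 0, A = 0.4, compartments on) and
`fibroblast` (t = ℓ = 1.5, A = 0, compartments on); the TAD/loop
strengths were fixed at preset-design time so that the classes are
unambiguous on every summary statistic (shoulder, boundaries, pileup,
band), since no quantitative amplitudes for either class are established.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: the band is imposed in
genomic-distance space rather than emerging from 3D polymer coordinates,
so only the period `T` is meaningful (loop size and loops-per-turn are
not separately identifiable, and no claim about scaffold geometry is
tested); noise is independent Poisson per pixel, without the correlated
coverage biases (mappability, GC, restriction-site density) that make
balancing genuinely hard on real maps; compartment structure is a hard
two-state checkerboard without sub-compartments; TADs are flat blocks
without nesting, stripes or extrusion anisotropy; and chromosomes are
featureless (no centromeres or arm-level structure, which the distance
cut in the detector partially stands in for).

## Numerical choices and degenerate inputs

Moving averages always use shrinking windows at boundaries, never
padding. Zero or missing `P` values become `NA` in log space and are
carried through NA-aware smoothing. Argmax ties break toward smaller `s`;
boundary suppression keeps the deeper minimum. All-zero matrices are
errors at balancing ("all bins masked") and at SCC ("all strata
degenerate"); curves without three positive bins refuse to
differentiate; search ranges are clipped to the usable extent with a
warning and error out only when empty. Every stochastic routine takes an
explicit seed and restores the caller's RNG state.

## Problem sizes

The test and acceptance suites run entirely on synthetic data at desk
scale, chosen as the smallest sizes at which each effect is
unambiguous: band recovery on single 150–180 Mb chromosomes at 100 kb
bins over five seeds; TAD analyses on 20 Mb chromosomes at 10 kb bins;
reproducibility on 60 Mb chromosomes at 100 kb; specificity on twenty
100 Mb band-free maps. A full run of the suite plus the acceptance script
completes in a few minutes on one CPU.

## Interface notes and limitations

The package's interface is its exported functions and `runPipeline()`;
file formats are deliberately plain text (chrom.sizes, 4-column pair TSV,
bin-table + COO matrices, BEDPE anchors, bedGraph tracks), and no binary
`.cool`/`.hic` readers are included. Band position is defined as the
residual argmax — published descriptions give ranges, not an estimator,
so this definition is ours and is stated in the output. Hierarchical
TADs, de novo loop calling, saddle statistics, trans contacts and
centromere-aware per-arm curves are out of scope.
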