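---
title: "Methods: partition statistics, linkage and infectious-titer estimation"
author: "dropletTiter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partition statistics, linkage and infectious-titer estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletTiter)
```

## The statistical model

Droplet digital PCR partitions a reaction into roughly 20,000 nanolitre
water-in-oil droplets and reads each droplet as positive or negative per
fluorescence channel. Under random partitioning, the number of target
copies in a droplet is Poisson with mean
$\lambda = c \cdot v_d$, where $c$ is the target concentration in the
reaction (copies/µL) and $v_d$ the droplet volume in µL. The negative
fraction then estimates $e^{-\lambda}$, giving the maximum-likelihood
estimator

$$\hat\lambda = -\ln\frac{n_{neg}}{n_{tot}}, \qquad
  \hat c = \frac{\hat\lambda}{v_d}.$$

`estimateLambda()` / `estimateConcentration()` implement exactly this;
`sampleTiter()` rescales the reaction concentration to the original sample
through the reaction volume, the sample volume and the dilution factor.
Dividing the resulting genome titer (vp/mL, one genome per particle) by an
independently measured infectious titer (iu/mL) yields the
preparation-specific genome-to-infectious ratio
(`genomeToInfectiousRatio()`).

In a duplex assay two targets are partitioned independently, so the
double-positive quadrant of the 2×2 droplet table
(`TwoChannelCounts`) is, under the null of no physical association,
$n_{tot}\,p_A p_B$ with $p_A, p_B$ the marginal positive fractions
(`expectedDoublePositives()`).

### Linkage

When the two targets ride on the same physical entity — here, an infected
cell carrying both the β-actin marker and the viral genome — double
positives exceed the random co-encapsulation expectation. We model three
Poisson species per droplet: free target A (mean $\lambda_a$), free target
B ($\lambda_b$) and a linked species carrying both ($\lambda_L$). The
three observable negative fractions give

$$\lambda_A = \lambda_a + \lambda_L,\quad
  \lambda_B = \lambda_b + \lambda_L,\quad
  \lambda_\cup = \lambda_a + \lambda_b + \lambda_L,$$

so $\hat\lambda_L = \hat\lambda_A + \hat\lambda_B - \hat\lambda_\cup$ —
the unique consistent plug-in estimator under random encapsulation
(`linkageLambda()`). Divided by the droplet volume it becomes the linkage
concentration in copies/µL (`linkage()`). Commercial analysis software
reports a statistic of the same name; we adopt the closed form above and
make no claim of numerical equivalence with any vendor implementation. The
signed estimate is mean-zero under independence and negative about half
the time in the null; the reported value is clipped at zero while the raw
value is retained in `DuplexResult` for calibration.

### The two infectious-titer estimators

With β-actin on channel A marking cell-containing droplets and the viral
target on channel B, two estimators of the infectious titer are available:

* **Double-positive counting** (`titerFromDoublePositives()`):
  $$\mathrm{Titer} = \frac{n_{A^+B^+}}{n_{A^+}}\cdot
    \frac{N_{cells}\cdot \mathrm{Dilution}}{V},$$
  with $N_{cells}$ the total cells infected, $V$ the inoculum volume (mL).
  Implemented exactly as printed, with no correction for random
  co-encapsulation: free-floating viral RNA that lands in a droplet with
  an uninfected cell creates a spurious double positive, so this estimator
  is biased upward under contamination — reproducing that divergence is
  the point of offering both methods.
* **Linkage** (`titerFromLinkage()`):
  $$\mathrm{Titer} = \frac{\mathrm{Linkage}}{c_{\beta\text{-actin}}}\cdot
    \frac{N_{cells}\cdot \mathrm{Dilution}}{V}.$$
  Free RNA of either species is partitioned independently of cells and so
  contributes no linkage; the estimator is robust to the contamination
  that breaks the first one.

Both count *infected cells*, not infectious units; at MOI ≤ 0.1 the two
agree within 5% (since $1-e^{-m}\approx m$), which is why recovery tests
run in that regime. An optional Poisson correction
($-\ln(1-\text{fraction})$) is available behind an explicit flag in
`infectedFractionToIu()`, default off, matching the uncorrected
convention of the estimators above.

## The synthetic droplet generator

`simulateVirusAssay()` and `simulateCellAssay()` stand in for the droplet
reader and the wet lab. They emulate:

* Poisson partitioning of genome copies at the concentration implied by
  the prep's infectious titer, its genome-per-infectious ratio, sample
  volume and dilution; two targets partition independently.
* Whole-cell encapsulation, either Poisson at
  `nCellsLoaded / nDroplets` or from the empirical cells-per-droplet
  distribution (60.4 / 28.3 / 8.5 / 2.8 % for 0–3 cells, renormalised),
  which is the default because microscopy shows cell loading is not
  Poisson-homogeneous.
* Infection of each cell independently with probability $1-e^{-MOI}$ —
  the source reports MOI but no cell-level model, so we adopt the standard
  Poisson virion-delivery model.
* Free-floating RNA from cell damage: reaction-wide Poisson totals
  partitioned independently of cells. For internal consistency the totals
  scale with the *realised* encapsulated-cell and infected-cell counts
  (equal in expectation to `nCellsLoaded × rate` under Poisson loading);
  the empirical occupancy distribution fixes the cells-per-droplet
  frequencies regardless of `nCellsLoaded`, and tying the debris totals to
  the realised count keeps contamination proportional to the cells
  actually present.
* A two-channel Gaussian amplitude model with optional uniform "rain"
  between the clusters (`renderAmplitudes()`), so that the thresholding
  path (`classifyEvents()`) can be exercised end to end.

It does **not** model PCR chemistry, annealing-temperature effects,
reverse-transcription efficiency, probe spectra, variable accepted-droplet
counts, or cluster drift. Passing tests therefore demonstrate the
correctness of the partition-statistical machinery under the stated
stochastic model, not robustness to instrument- or chemistry-level
artefacts in real data.

## Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| `nDroplets` | 20,000 | nominal droplet count of the emulated instrument class |
| `dropletVolumeNl` | 0.85 nL | nominal droplet volume for that class; never stated by the source experiments, so it is a single configurable constant that all concentration maths routes through |
| `reactionVolumeUl` | 20 µL | standard reaction size |
| `sampleVolumeUl` | 2 µL | the source does not report it; 2 µL per 20 µL reaction is a typical template fraction and is a free configuration parameter |
| `occupancyModel` | `"empirical"` | measured cell loading is over-dispersed relative to Poisson |
| `nCellsLoaded` | 2000 | upper end of the 1000–2000 cells/reaction working range |
| `freeActinRnaRate` | 1 copy/cell | reproduces the low end of the reported 2–10× β-actin overcount of the true cell number |
| `freeViralRnaRate` | 15 copies/infected cell | infected cells carry very high viral RNA copy numbers, so lysis debris plausibly exceeds actin debris; this magnitude reproduces the reported several-fold overestimate of the double-positive method |
| MOI grid | 0.074, 0.4, 2 | spans the poorly separated low end up to strong infection |

These defaults are the study conditions of the simulated experiments; the
free-RNA rates in particular were fixed once from the qualitative
observations above and are not tuned per analysis.

## Numerical choices

* **Confidence intervals.** Wilson score interval on the negative
  fraction, endpoints mapped through $-\ln$ (monotone decreasing, so the
  bounds swap), then scaled by droplet volume. Wilson behaves sensibly at
  extreme fractions where the Wald interval collapses; the per-well CI
  convention of instrument software is unpublished, so this choice is the
  package's own. The interval endpoints are pinned to exact 0/1 at
  all-negative and all-positive fractions so the log transform never picks
  up floating-point residue.
* **Saturation and empty wells.** An all-positive channel raises a typed
  saturation error (`dropletTiterSaturationError`) instead of returning
  infinity — downstream titer arithmetic must never silently propagate
  non-finite values. An all-negative channel returns $\hat\lambda = 0$
  with a one-sided interval.
* **Negative linkage.** Clipped to 0 for reporting; the raw signed value
  is kept because calibration tests need its null distribution.
* **Sparse quadrants.** Linkage is reported but flagged with a warning
  when any quadrant holds fewer than 10 droplets; the source notes linkage
  breaks down with poor droplet separation without quantifying "poor", so
  we surface rather than suppress.
* **Thresholding.** Fixed per-channel thresholds (midpoint of the cluster
  means by default); automatic two-cluster thresholding is out of scope
  because separability is achieved experimentally, not algorithmically.
* **Determinism.** Every simulation call takes one seed; scenario wells
  derive per-well seeds as `replicateSeed × 1009 + conditionIndex`
  (mod $2^{31}-1$), and a run manifest reproduces a run byte for byte.

## Design decisions taken where the source is open

* The three-species Poisson closed form is used for linkage because the
  vendor computation is not public; equivalence is not claimed.
* Eq-style titer formulas are implemented exactly as printed — in
  particular the double-positive estimator subtracts nothing — because the
  divergence between the two estimators under contamination is the
  phenomenon of interest.
* The 2.8% three-cell occupancy category is used as given; whether it
  truncates a longer tail is unknown, and at 1000–2000 loaded cells the
  Poisson alternative is available.
* The degradation-robustness assumption (proportional lysis of infected
  and uninfected cells leaves the linkage titer nearly unchanged) is
  *tested in simulation* at modest contamination, not proven: at large
  free-actin rates the β-actin concentration in the denominator inflates
  while linkage does not, biasing the linkage titer low. That same
  mechanism is why the simulated linkage titer modestly undershoots the
  configured truth when debris is present.

## Problem sizes

The test suite and the acceptance script run wells of 20,000 droplets
(200,000 for the large-sample consistency check), 3–20 replicates per
recovery scenario, and 500 draws for the interval-coverage and
null-calibration loops — sizes chosen so the whole suite completes in a
few minutes on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances.

## A worked example

```{r example}
cfg <- AssayConfig()
cellCfg <- CellAssayConfig(
  moi = 0.074,
  inoculumVolumeMl = inoculumVolumeForMoi(0.074, 1.73e7, 1, 2e6))
batch <- simulateCellAssay(cellCfg, cfg, seed = 1)
counts <- countBatch(batch)
counts

dup <- duplexAnalysis(counts, cfg@dropletVolumeNl)
dup

titerFromDoublePositives(counts, 2e6, 1, cellCfg@inoculumVolumeMl)
titerFromLinkage(dup, 2e6, 1, cellCfg@inoculumVolumeMl)
```

The double-positive estimate sits far above the configured
1.73 × 10⁷ iu/mL because free viral RNA co-encapsulates with uninfected
cells, while the linkage estimate stays close — the core finding the
package exists to quantify.

## Known limitations

* One well per call; no plate-layout or multi-well merging logic.
* No rain-reclassification algorithms; rain simply degrades round-trip
  classification as configured.
* The linkage formula assumes all three species are Poisson; strongly
  over-dispersed cell loading makes the infected-fraction estimate
  $\lambda_B/\lambda_A$ a slightly biased (few-percent) functional of the
  occupancy distribution.
* Titers are infected-cell based; far above MOI ≈ 0.1 they understate
  delivered infectious units unless the Poisson correction is enabled.
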