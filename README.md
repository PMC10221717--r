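# dropletTiter

Partition-Poisson quantification for droplet digital PCR (ddPCR) and
single-cell infectious-titer estimation of viral preparations, with a
synthetic droplet-data generator that emulates the instrument output.

## The problem

ddPCR splits a 20 µL reaction into ~20,000 nanolitre droplets and reads
each droplet as positive/negative per fluorescence channel. The genome
titer of a virus preparation follows from Poisson partition statistics,
but genome copies count damaged particles and naked RNA too, so the
genome titer alone cannot give the *infectious* titer. Encapsulating
whole infected cells together with a housekeeping marker (β-actin,
channel A) and the viral target (channel B) makes the infectious titer
estimable from droplet counts — if free-floating RNA from damaged cells
is handled correctly. This package implements that whole analysis chain
for virologists characterising (non-lytic or replication-deficient)
vector preparations, plus the simulator needed to validate it.

## The statistics

* Single target: `λ̂ = −ln(n_neg / n_tot)`, concentration `λ̂ / v_d`
  (droplet volume `v_d`, default 0.85 nL), Wilson score CI on the
  negative fraction mapped through `−ln`.
* Duplex: marginals estimated independently; expected double positives
  under random co-encapsulation `n·p_A·p_B`.
* Linkage (excess double positives): under a three-species Poisson model
  (free A, free B, linked AB), `λ̂_L = λ̂_A + λ̂_B − λ̂_∪`, converted to
  copies/µL. Free RNA contributes no linkage; cells carrying both
  targets do.
* Infectious titer, two ways:
  * double-positive counting:
    `Titer = (n_AB / n_A+) · N_cells · Dilution / V` — biased upward by
    free viral RNA;
  * linkage: `Titer = (Linkage / c_actin) · N_cells · Dilution / V` —
    robust to it.

## Worked example

Simulate an infected-cell assay at MOI 0.074 with a true titer of
1.73 × 10⁷ iu/mL and realistic free-RNA contamination, then estimate the
titer both ways:

```r
library(dropletTiter)
cfg     <- AssayConfig()
cellCfg <- CellAssayConfig(moi = 0.074,
             inoculumVolumeMl = inoculumVolumeForMoi(0.074, 1.73e7, 1, 2e6))
batch  <- simulateCellAssay(cellCfg, cfg, seed = 1)
counts <- countBatch(batch)
counts
#> TwoChannelCounts (n = 20000): A-only 6770 | B-only 3149 | AB 6190 | neg 3891

dup <- duplexAnalysis(counts, cfg@dropletVolumeNl)
dup
#> DuplexResult: A 1228 copies/uL, B 740.2 copies/uL
#>   double positives: 6190 observed vs 6051.7 expected under independence
#>   linkage: 42.59 copies/uL (raw lambda 0.0362)

titerFromDoublePositives(counts, 2e6, 1, cellCfg@inoculumVolumeMl)
#> TiterResult [double_positive]: 1.117e+08 iu/mL
titerFromLinkage(dup, 2e6, 1, cellCfg@inoculumVolumeMl)
#> TiterResult [linkage]: 8.105e+06 iu/mL
```

Only ~140 of the 6190 double-positive droplets are in excess of random
co-encapsulation, so direct double-positive counting overshoots the true
titer by ~6×, while the linkage estimate stays within a factor of ~2 —
the contrast the linkage method exists to fix. With contamination rates
set to zero the linkage estimate recovers the configured titer within a
few percent (see the tests and `vignettes/droplet-titer-methods.Rmd`).

`runScenario()` drives replicated end-to-end experiments
(`singleVirusGradientSpec()`, `duplexMixtureSpec()`,
`singleCellTiterSpec()`) and writes counts, results, summary and a
manifest that reproduces the run byte for byte. A thin CLI over the same
functions lives at `inst/scripts/droplet-tools.R`.

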