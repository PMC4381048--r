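# siaPCA

Nucleobase-preference profiling of RNA-binding protein domains from whole
2D NMR spectra.

## The problem

Scaffold-independent analysis (SIA) asks which base — A, C, G or U — a
protein domain prefers at one position of a single-stranded RNA. Four RNA
pools are made, identical except for the base fixed at the scanned
position (`NNNAN` fixes position 4 of a 5-mer to A), each is added to the
¹⁵N-labelled domain, and a 2D ¹H–¹⁵N correlation spectrum is recorded per
complex. Under fast exchange every amide peak sits at the
population-weighted average of its free and bound positions, so the pool
with the highest average affinity perturbs the spectrum most. The manual
read-out measures weighted chemical-shift perturbations
Δδ = √(Δδ_H² + (0.2·Δδ_N)²) for ~10 hand-picked peaks, normalizes per peak
by the largest value across the four pools, and averages — accurate, but
slow, and sensitive to which peaks are picked.

`siaPCA` implements the automated whole-spectrum alternative. The five
spectra of one position (free + four complexes) are stacked into a
5 × (n₁·n₂) matrix and decomposed by NIPALS PCA without centering, giving
five principal components with one projection per spectrum. The first
component absorbs the shared peak pattern and the dilution-driven
intensity offset; the binding-induced peak displacements land on the
second. Each pool is scored by the distance of its projection from the
free-protein projection on component 2,

    S(b) = | t_free − t_b |,

and the four pools are ranked by S. A variance-ratio diagnostic flags
ensembles (typically small domains with few shifting peaks) where the
variance spreads evenly across components and the automatic read-out
should not be trusted. The manual procedure, a ground-truth simulator, and
a rank/correlation comparison between the two routes are included.

## Worked example

```r
library(siaPCA)

cfg <- simulationConfig(nPositions = 1)   # 290 x 256 grid, 100 peaks, seed 42
sim <- simulateSIAExperiment(cfg)         # free + A/C/G/U planes, known truth
res <- pcaEnsemble(sim$stacks[[1]])

res
#> PCAResult: 5 components from 5 spectra (centering = none)
#>   variance %: 93.12, 4.38, 1.20, 0.72, 0.58

round(pcaPoolScore(res, 2), 3)
#>     A     C     G     U
#> 0.633 2.086 5.861 4.721
rankBases(pcaPoolScore(res, 2))
#> [1] "G" "U" "C" "A"
reliabilityCheck(res)$message
#> variance ratio PC2/PC3 = 3.64 (>= 1.50): PCA scoring reliable
```

The simulator was programmed with per-pool Kd 2 (G), 10 (U), 50 (C) and
250 µM (A) at 25 µM protein, i.e. preference G > U > C > A with fractions
bound 0.754/0.537/0.268/0.084 — the component-2 distances recover that
order. The intensity-dominated first component carries 93 % of the
variance (the bound samples are diluted to 0.9×), and the trailing
components stay near 1 % each. The manual route agrees:

```r
sia <- siaScores(sim$freePeaks, sim$boundPeaks[["1"]], sim$model$responsiveIds)
round(sia$scores, 3)
#>     A     C     G     U
#> 0.111 0.355 1.000 0.711
```

Batch runs are config-driven (`validateConfig()`, `runPipeline()`), with a
thin CLI at `inst/scripts/siapca` (verbs `validate`, `simulate`,
`analyze`, `compare`); outputs are per-position variance tables, scores,
rankings, reliability flags and method-comparison CSVs plus a JSON report.
Spectra are read and written in NMRPipe 2D format and in a bit-exact plain
matrix dialect; peak lists are CSV/TSV.

See `vignettes/whole-spectrum-sia.Rmd` for the model, parameter meanings,
numerical choices, and what the simulator does and does not emulate.

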