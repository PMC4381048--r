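---
title: "Whole-spectrum scoring of RNA nucleobase preference by NIPALS PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-spectrum scoring of RNA nucleobase preference by NIPALS PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siaPCA)
```

## The experiment and the two scoring routes

Scaffold-independent analysis (SIA) determines which nucleobase an
RNA-binding protein domain prefers at one position of a short RNA. Four
quasi-degenerate RNA pools are prepared, identical except that the scanned
position is fixed to A, C, G or U (pool `NNNAN` fixes position 4 to A in a
5-mer). Each pool is added to the ¹⁵N-labelled domain in an independent
assay and a 2D ¹H–¹⁵N correlation spectrum is recorded; because only one
base differs between pools, the pool producing the largest spectral change
reports the preferred base, through the pool's higher average affinity.

The classical, manual read-out tracks roughly ten well-resolved amide
peaks. For every tracked peak the weighted chemical-shift perturbation

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2},
\qquad \alpha = 0.2,$$

is measured against each pool, normalized per peak by the largest of the
four values, and the normalized values are averaged over peaks to give a
per-pool score in $[0, 1]$ (`siaScores()`). The $\alpha = 0.2$ weighting is
the community-standard rescaling of the ¹⁵N ppm range onto the ¹H one; it
is exposed as a parameter because published variants range from 0.1 to
0.25. Manual scoring is laborious and depends on which peaks are chosen:
`subsetSensitivity()` quantifies that bias by rescoring with different peak
subsets.

The whole-spectrum route avoids peak selection entirely. The five spectra
of one position — free protein plus the four complexes — are flattened into
a $5 \times (n_1 n_2)$ matrix (`buildDataMatrix()`) and decomposed by
principal component analysis (`nipalsPca()`). Each spectrum then has one
projection per component, and the separation of a pool's projection from
the free-protein projection on the second component ranks the pools
(`pcaPoolScore()`, `rankBases()`).

## Why the second component, and why no centering

By default the matrix is **not** centered. Five uncentered spectra span up
to five components, which is the decomposition the method expects: the
first component is then dominated by what all five spectra share — the
overall peak pattern, scaled by total intensity. Because adding the RNA
pool dilutes the sample (10 % at the default 0.9 dilution factor), the
free spectrum separates from the four bound ones on this first component,
which typically carries the overwhelming share of the variance. The
binding-induced peak displacements, which are what affinity ranking needs,
are the dominant *contrast among* the spectra once intensity is accounted
for, and land on the second component. Components three to five collect
pool-specific lineshape residue and noise, each a few percent at most.
Mean- or reference-centering are available as options; both reduce the
attainable rank to four and fold the dilution contrast into every
component, which is why they are not the default.

`reliabilityCheck()` guards the regime where this structure breaks: when
only a handful of resonances respond to RNA (small domains such as CCHC
zinc fingers, with a third of the amide count of an RRM), the variance
spreads evenly across components and the second component no longer tracks
the shifts. The check flags an ensemble when the component-2 variance
fraction is below 1.5 times the component-3 fraction. The factor 1.5 is a
heuristic operationalization of "evenly spread", chosen once; it is a
parameter, and flagged ensembles should be scored manually.

## The pool score

For a pool $b$ with projection $t_b$ and free-protein projection
$t_{free}$ on the chosen component, the package ranks pools by the
projection distance

$$S(b) = |t_{free} - t_b|,$$

and also reports the subtraction of absolute projections
$|t_{free}| - |t_b|$, the arithmetic conventionally quoted for this score.
The two agree (up to sign) whenever the reference projection is extremal
and all five projections share a sign. On an uncentered ensemble, however,
the component-2 projections are constrained to straddle zero — they are
orthogonal to the all-positive component-1 projections — so the
absolute-value subtraction stops being a separation once the strongest
pool crosses zero, while the distance form remains monotone in the
underlying shift magnitude. The ranking therefore uses $S(b)$; signs of
individual projections depend on an arbitrary orientation convention
(fixed here so the reference projection is non-negative) and carry no
information. `compareMethods()` correlates $S(b)$ on every component with
the mean weighted shift of the manual route, reproducing the diagnostic
that only component 2 correlates when the read-out is healthy.

## NIPALS implementation

Components are extracted sequentially: alternate
$p \leftarrow X^{\top}t / \|X^{\top}t\|$ and $t \leftarrow Xp$ until the
fixed point, record the component, deflate
$X \leftarrow X - t\,p^{\top}$, and repeat. For a spectra-as-rows matrix
this alternation is one multiplication of the 5-vector $t$ by the small
Gram matrix $G = XX^{\top}$, so the package iterates on $G$ at
$O(n^2)$ per step and reconstitutes $p$ once at convergence —
identical fixed point, but cheap enough to iterate to machine precision.
Convergence is declared on the eigen-residual
$\|Gu - \lambda u\| \le \mathrm{tol}\,\lambda$ (with $u = t/\|t\|$), which
bounds the actual eigenvector error; a stopping rule based on the change
between iterates stalls far from the solution when two eigenvalues are
close, which is routine for the noise-dominated trailing components. The
defaults are tol = 1e-12 and maxIter = 10000; hitting the cap is recorded
on the result and warned about, not an error, since trailing components of
a noise floor may legitimately wander between near-degenerate directions.
Exhausted (numerically zero) residuals yield zero-variance components with
orthonormal filler directions so the eigen-spectra always form an
orthonormal set. Variance fractions are sums of squared projections over
the total sum of squares of the (centered) input, matching the usual
"% variance" reading; projections are cross-checked against a
singular-value decomposition in the test suite.

## What the simulator emulates

`simulateSIAExperiment()` generates the full 5-position experiment with
known ground truth, so every scoring claim in the package is testable
against a programmed preference. Its model:

* **Binding.** Each pool is a single effective species with one
  dissociation constant; the fraction bound is the exact root of the 1:1
  binding quadratic (`fractionBound()`, computed with a cancellation-free
  discriminant so the tight-binding corner keeps full precision). This
  collapses the pool's quasi-degenerate sequence mixture into its average
  affinity, which is exactly the observable the assay reads.
* **Fast exchange.** Each responsive peak sits at the population-weighted
  average position: displaced by fraction-bound times its
  saturated-complex shift. Saturated shifts are drawn once per peak
  (sd 0.05 ppm ¹H, 0.25 ppm ¹⁵N) and shared across the four pools of a
  position, so pools differ only in fraction bound — the premise that
  larger shifts mean higher affinity, in its cleanest form.
* **Spectra.** Peaks are separable 2D Lorentzians (HWHM 0.02 ppm ¹H,
  0.15 ppm ¹⁵N — typical amide widths at 700 MHz) on a 290 × 256 grid
  covering the amide region (¹H 5.5–11.5 ppm, ¹⁵N 95–135 ppm). Bound
  spectra are scaled by the dilution factor 0.9, and i.i.d. Gaussian noise
  at 0.5 % of the maximum free-plane intensity is added, with per-plane
  seeds derived deterministically from the master seed.
* **Defaults as study conditions.** 100 peaks, 30 % responsive, per-pool
  Kd of 2/10/50/250 µM (preference G > U > C > A) at 25 µM protein and
  1:1 RNA:protein. With these settings component 1 carries ~93 % of the
  variance, component 2 a few percent, and components 3–5 about 1 % each.

Not modelled: exchange broadening (peak positions move but linewidths do
not change on binding), slow/intermediate exchange, titration series,
baseline or phase artefacts, and peak overlap statistics of any specific
real domain. Passing tests therefore demonstrate the scoring machinery and
its failure modes under controlled shift-driven changes, not performance
on any particular experimental spectrum set.

A deliberate consequence of realistic parameters: saturated shifts are
routinely several linewidths, so the map from fraction bound to
inter-spectrum distance is monotone but not linear. With very few
responsive peaks (small fixtures) a single large draw can invert the
distance order of two pools with adjacent affinities in the rendered data
itself; at the default peak density the programmed order is recovered in
all tested seeds, with and without noise.

## Numerical and design choices

* Grid axes follow the NMR convention: ppm decreases with point index,
  spacing sw/n; indexing formulas are documented 0-based.
* The matrix I/O dialect stores axis values at 17 significant digits and
  intensities as raw float64, so write-then-read is bit-exact; NMRPipe 2D
  stores float32, bounded by single-precision rounding. Only single real
  2D planes are read; pseudo-3D files must be split upstream.
* Ensemble validation requires identical grids and calibration within
  1e-6 ppm across the five planes; plane order is fixed [free, A, C, G, U].
* Rank ties are broken alphabetically (A < C < G < U) and flagged rather
  than hidden.
* Tracked peaks with zero shift in every pool are excluded from the manual
  average (they would otherwise contribute 0/0) and reported.
* Test and example simulations use a reduced 96 × 64 grid with 24 peaks
  where full realism is not needed; ranking-recovery and variance-structure
  checks run at the full default conditions (50-seed recovery, one PCA per
  position, completes in about a minute).

## Limitations

The score is comparative only: it ranks pools for one position and domain,
and neither its scale nor its sign converts to an absolute affinity. The
automatic read-out degrades exactly where the reliability flag fires —
sparse interfaces, few shifting peaks — and no alternative component is
selected automatically in that case because none has a defensible
relationship to the shifts; manual scoring is the fallback. Real-data
effects excluded from the simulator (exchange broadening above all) add
variance to component 2 and its neighbours and can only loosen, never
tighten, the separation between methods reported here.
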