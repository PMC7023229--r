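---
title: "Kohonen maps and counter-propagation networks for fullerene-derivative binding activity"
author: "fdQSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kohonen maps and counter-propagation networks for fullerene-derivative binding activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdQSAR)
```

## Scope

fdQSAR implements the cheminformatics workflow behind a screening study of
fullerene derivatives (FDs): given a compounds × proteins binding-score
matrix (docking-derived "Bscores", roughly 3900–8000) and a compounds ×
descriptors table of drug-like molecular properties, it reduces the protein
panel with a Kohonen self-organizing map, regresses average binding activity
from the descriptors with a counter-propagation neural network (CPANN),
selects a compact descriptor set with a small Kohonen map, and produces the
descriptive analyses around them (activity averages, deltas against pristine
C60, activity sectors, saturation labels, correlation tables, PCA loadings).
Out of scope by design: computing Bscores by docking, computing the
descriptors themselves (they are consumed as input columns), and chemical
structure handling.

## The SOM and CPANN model

A Kohonen map is an `nx × ny` planar grid of neurons, each holding a weight
vector in the input space. Training is sequential competitive learning. For
an object $x$ presented at epoch $t$:

1. the **winner** $c$ minimizes the Euclidean distance $\lVert x - w_j\rVert$
   over all neurons, with exact ties resolved to the smallest row-major
   index;
2. every neuron $j$ moves toward $x$:
   $w_j \leftarrow w_j + \eta(t)\, a\!\big(d(j,c),\, r(t)\big)\,(x - w_j)$,

where $d$ is the Chebyshev distance on the grid (square rings around the
winner, planar boundaries) and $a(d, r) = \max(0,\, 1 - d/(r+1))$ is a
triangular neighborhood: 1 at the winner, linearly decaying, zero beyond the
radius. Objects are presented once per epoch in a seed-determined order that
is reshuffled every epoch.

A CPANN couples this input layer to an **output layer** of identical
geometry holding one vector of (normalized) targets per neuron. The winner
is always chosen from the input layer only; the output weights receive the
same $\eta(t)\,a(\cdot)$ update toward the target $y$. A trained CPANN is
therefore a topology-smoothed lookup table: prediction returns the output
weights of the input-layer winner, and at most `nx * ny` distinct
predictions exist.

The source study prints the architecture settings (5 × 5 map for protein
reduction, 20 × 20 for the regression models, 2 × 2 for descriptor
selection, 100 learning epochs) but not the update equations, schedules,
initialization, or boundary handling. The forms above are the conventions of
the counter-propagation literature that the study builds on; because those
details are conventions, published map layouts cannot be reproduced
neuron-for-neuron, and no analysis here depends on a specific layout — only
on distances, selections and fit statistics.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epochs` | 100 | learning epochs; the study's printed setting |
| `etaStart`, `etaEnd` | 0.5, 0.01 | learning-rate schedule, linear in epoch; unitless |
| `radiusStart`, `radiusEnd` | `max(nx, ny) − 1`, 0 | neighborhood radius in grid units, linear in epoch; start covers the whole map, end localizes updates |
| `seed` | 1 | drives weight initialization (uniform in [0, 1]) and presentation order; fixed seed ⇒ bit-identical weights |

Inputs must be min-max normalized per column (`normalizeColumns()`), which is
why initial weights are drawn uniformly in $[0,1]$ and trained weights stay
within $[-0.1, 1.1]$ (every update is a convex move toward a point in
$[0,1]$). Constant columns are mapped to 0.5 and flagged as degenerate rather
than aborting a pipeline run; they carry no distance information either way.

## Fit statistics

Following QSAR convention, $R^2$ is the squared Pearson correlation between
observed and predicted values, and $Q^2$ the same computed only on held-out
leave-one-out predictions; the regression variant $1 - SS_{res}/SS_{tot}$ is
reported alongside (`r2ss`, `q2ss`) for transparency. RMSE is reported on the
normalized target scale, consistent with RMSE values near 0.2 printed next
to scores spanning thousands of units. Each LOO fold retrains from a seed
derived deterministically from the master seed and the fold index, so the
whole cross-validation is reproducible and exactly equal to a manual
fold-by-fold loop.

## Selection procedures

**Protein reduction.** Each protein is an object whose profile is its score
vector across all compounds. After training a 5 × 5 map, each occupied
neuron contributes its member with the smallest and the member with the
largest Euclidean distance to the neuron weight (ties broken by object ID),
so the reduced panel has at most 2 × occupied neurons members — at most 50
for a 5 × 5 map. The study reports 57 proteins surviving this step, which
exceeds that structural bound; the package implements the stated rule and
its bound rather than imitating the printed count, whose origin (possibly
ties or manual additions) is not documented.

**Descriptor selection.** The same rule on the transposed descriptor table
with a 2 × 2 map yields at most 8 descriptors; appending the two size
descriptors (`QPpolrz`, `TD`) gives the 10-descriptor consensus set. The
study calls the resulting model a "consensus model" without defining a
combination mechanism beyond the merged descriptor set, so the package fits
a single CPANN on the 10 descriptors. Exactly 8 descriptors emerge whenever
every neuron of the 2 × 2 map holds at least two descriptors and the
min/max picks do not coincide — the regime the acceptance checks construct
explicitly; degenerate occupancies legitimately return fewer.

**Classification rules.** Activity sectors: active above 5500, moderate in
(5000, 5500], low at or below 5000, with boundaries assigned to the lower
class and "low" unbounded below (the pristine C60 score of 3938.3 sits below
the nominal 4000 floor of the printed range). Saturation: zero sp3 atoms ⇒
unsaturated, more than 60 ⇒ saturated, otherwise ambiguous — only the outer
limits separate cleanly; stereo centers, though strongly correlated with sp3
counts, are accepted for reporting but never thresholded.

## The synthetic data generator

The study's 169 × 1117 score matrix lives in supplementary material and is
not bundled, so `generateDataset()` emulates its statistical shape with a
two-latent linear-Gaussian factor model:

* a **size** latent $s \sim U(0,1)$ per compound drives the six
  size-descriptor analogues (`QPpolrz`, `TD`, surface area, molecular
  weight, non-H atoms, rotatable bonds) as affine functions plus
  $N(0, \texttt{noiseSd})$ on the latent scale;
* an **aromaticity** latent $u$ drives the aromatic block, and $1 - u$ the
  sp3/stereo block; the block noise is derived analytically from the target
  cross-block correlation ($-0.85$ by default) via
  $|cc| = \mathrm{Var}(u) / (\mathrm{Var}(u) + \sigma^2)$;
* proteins fall into clusters (5 by default) with cluster-specific offsets
  and gains, jittered per protein, and
  $B_{ip} = \mathrm{offset}_p + \mathrm{gain}_p\, s_i + N(0,
  \texttt{noiseSd} \cdot \texttt{bscoreGain})$, anchored at offset 3900 and
  gain 4000 to echo the observed 4000–8000 range. Scores outside a generous
  plausible range are counted and reported, never clipped.

Count-like descriptors are rounded to non-negative integers after noise;
correlation targets are checked after rounding. `noiseSd = 0` switches all
stochastic noise off, making every column an exact affine function of its
latent. The default `noiseSd = 0.05` yields realized correlations matching
the reported regime (average score vs. polarizability ≈ 0.95–0.99,
aromatic vs. sp3 ≈ −0.85).

What the generator does **not** emulate: the true joint distribution of 27
real descriptors (heavy tails, discreteness beyond rounding, nonlinear
dependencies), protein families with qualitatively different response
shapes, or any docking physics. Passing tests on synthetic data therefore
demonstrate that the algorithms are implemented correctly and behave as
expected on data with the study's correlation structure — not that the
published model statistics would be reproduced on the original matrix, which
would also require the unpublished training schedules.

## Numerical choices

* Winner ties: smallest row-major index, making results independent of
  object order and platform.
* Schedules interpolate linearly including both endpoints; a single-epoch
  run uses the start values.
* Distance sums run in feature order in both the compiled core and the test
  oracles, so cross-checks can demand near-bit equality.
* Min/max selection ties: object ID order.
* PCA operates on the correlation matrix (descriptor units are
  incommensurable); each component's sign is fixed so its largest-magnitude
  loading is positive.
* Model persistence writes doubles as `%.17g` text, which round-trips IEEE
  doubles exactly.
* Pipeline artifacts print 6 significant digits; all internal computation is
  full precision. Per-stage seeds are derived from the master seed by a
  stage-name hash, so reordering stages cannot silently change results.

## Problem sizes used in the checks

The bundled tests exercise small maps (1 × 1 up to 6 × 6) for oracle
comparisons and property checks, and the acceptance checks run the full
study-scale configuration: 169 compounds × 27 descriptors on a 20 × 20 map
for 100 epochs, including complete leave-one-out loops (169 retrainings per
model), plus a 2000-compound sample for correlation calibration. These sizes
were chosen as the smallest that exercise each claim at its stated scale.

## Known limitations

* The published map layouts and the exact printed model statistics are not
  reproducible without the supplementary data and unpublished training
  details; the package reproduces the printed arithmetic (deltas, counts,
  thresholds) exactly and the model-quality regime qualitatively.
* Multi-target CPANNs (one output per protein) are supported by the data
  model but not exercised by the pipeline, which models the per-compound
  average score.
* No toroidal or hexagonal grids, Gaussian neighborhoods, or batch-SOM
  variants; no rotation methods on PCA; no significance testing on
  correlations.
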