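---
title: "Methods: lesion-aware connectome analysis with avmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-aware connectome analysis with avmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmnet)
```

## The scientific question

Focal brain lesions — here, unruptured arteriovenous malformations — can
impair cognition in two conceptually distinct ways: by destroying the
cortex they occupy, or by interrupting the long-range white-matter
pathways that pass through or near them. These imply different predictors:
in the first case lesion volume and local gray-matter damage should track
cognitive scores; in the second, measures of network integrity and
topology should, even when lesion volume does not. `avmnet` implements
the network side of this comparison as a tested pipeline over parcel-level
connectomes, with all the supporting machinery (lesion masking, metric
computation, robust regression) under one roof.

## Data model and construction choices

Connectivity is carried as a square symmetric matrix over a fixed parcel
atlas, with a logical *valid* mask for excluded nodes. Two rules keep the
graph code branch-free and were applied consistently:

* **Missingness lives in the mask, never in the weights.** A parcel with
  ≥ 50% lesion overlap (the boundary is inclusive) is flagged invalid;
  every metric restricts itself to the valid submatrix. NaN inside a
  weight matrix is a format error at read time.
* **Node order is atlas order everywhere.** Files are read and written in
  atlas order; nothing reorders nodes, so misalignment cannot happen
  silently.

Structural weights are inverse-node-volume normalised streamline counts
(`counts / (vol_i + vol_j)`), functional weights are Pearson correlations
between parcel time series. Negative functional correlations are zeroed
before thresholding and topology metrics: treating a negative correlation
as a "connection strength" has no defensible interpretation under
shortest-path or triangle-intensity metrics. Proportional thresholding
keeps the `ceiling(density * M)` strongest upper-triangle edges; ties at
the cutoff are broken toward the lexicographically smaller index pair so
the operation is deterministic across platforms and sort implementations.
Thresholding is applied to *topology metrics only* (efficiency,
clustering): mean-edge-weight summaries such as intra-DMN integrity, the
coupling profiles, and the diffusion model all use the unthresholded
weights, because deleting weak edges changes what those quantities mean
rather than denoising them.

## Graph topology

Global efficiency uses edge lengths `1/w`, Dijkstra shortest paths, and
the Latora–Marchiori convention that disconnected pairs contribute zero —
required so that removing a cut vertex yields a finite efficiency drop in
the virtual-lesion analysis. Clustering is the Onnela geometric-mean
triangle intensity with weights rescaled by the network maximum; the
network value averages over all valid nodes with degree-< 2 nodes
contributing zero. Strength ranks are dense with ties broken by lower
parcel id (and flagged, since a tie-broken rank order among equal
strengths is arbitrary); a degree-based rank is available as an option
because published "structural rank" values do not always say which was
used.

The virtual-lesion null removes a single uniformly drawn non-target node,
1000 draws by default, with the add-one-corrected one-sided p-value
`(1 + #{null ≥ obs}) / (n_null + 1)`. This matches the granularity limit
`p ≥ 1/(n_null+1)` and is calibrated: under random targets on
Erdős–Rényi graphs the empirical rejection rate at α = 0.05 stays at or
below nominal (tested over 200 runs).

## The Network Diffusion Model

Pathological load spreads by the heat equation on the symmetric
normalized Laplacian, `x(t) = exp(−βLt) x(0)`. Implementation notes:

* The heat kernel is computed by eigendecomposition, which is exact up to
  floating point and lets one eigendecomposition serve the whole
  seed-by-time sweep. An explicit adaptive ODE integration serves as the
  independent oracle in the tests (agreement ≤ 1e-6 on random 20-node
  graphs); conservation of the zero-mode projection and the semigroup
  property are tested at 1e-10.
* Only the product `βt` enters the kernel, so `β` is fixed at 1 and the
  time grid is swept (default 0–10 in steps of 0.05, which brackets
  published peak times around 2.5 with room on both sides). This is
  asserted as an exact identity in the tests.
* `t = 0` returns the seed pattern exactly (special-cased, not through
  the eigenbasis).
* Isolated nodes get all-zero Laplacian rows: they neither emit nor
  absorb.
* The random-walk Laplacian is available behind a flag; the symmetric
  form is the default because the heat kernel then stays symmetric and
  the spectral computation exact.
* Empirical morphometry t-maps do not come with a canonical sign (a
  cohort can show net thickening rather than atrophy), so the fit
  reports the maxima for the map as given, for its negation, and for
  |R|. The epicenter is defined on the map as given; ties break toward
  the lower parcel id.

## The synthetic cohort generator

No patient imaging is distributed with the analysis, so the generator
produces data with the *statistical structure the analysis assumes*, and
its defaults are the package's study conditions:

* **Structure:** 90 nodes by default (360 supported; 90 keeps the full
  pipeline under a few seconds), placed uniformly in a unit cube, edge
  probability and weight decaying as `exp(−d/0.3)` with a lognormal
  multiplier, 10% of nodes given a 3× connection-odds boost
  (rich-club-like hubs), and a distance-MST union guaranteeing a single
  connected component. Target density 15%.
* **Function:** the correlation matrix of 500 draws from
  `x = γÃx + ε` with `Ã` rescaled to spectral radius 0.6. This linear-
  Gaussian choice is deliberate: its analytic covariance
  `(I−γÃ)^{-1}(I−γÃ)^{-T}` is a closed-form oracle for the tests, and
  node-wise structure–function coupling is monotone in γ (default 0.6).
* **Lesions:** grown voxel-by-voxel on a toy label volume (4³-voxel
  parcel blocks), filling the center parcel first and then expanding in
  deterministic breadth-first layers — so overlap proportions are exact
  and voxel counts conserve.
* **Atrophy:** forward diffusion from a known seed at `t* = 2.5`,
  standardized, plus Gaussian noise (`noise_sd` is therefore directly a
  noise-to-signal fraction).
* **Cohort:** 44 patients vs 72 controls, mirroring the study cohort the
  package is modelled on, with matching demographic distributions.
  Patients receive a white-matter integrity factor `q ~ U(0.3, 1)` that
  multiplicatively attenuates intra-lesion-network edges (attenuation,
  not deletion, keeps integrity continuous), and a lesion whose extent
  varies independently of `q`. The cognitive composite is
  `4q + 0.5·load + demographic terms + N(0,1)`: with load on the order
  of 0.01–0.05, the integrity effect is strong (standardized effect
  ≈ 0.6 among patients) and the lesion-volume effect is negligible by
  construction. This *is* the dissociation the analysis is designed to
  detect; the generator realises it, and the tests verify the pipeline
  finds it (integrity term significant in ≥ 90% of 50 replicates, lesion
  load not significant in ≥ 70%).

What the generator does **not** emulate: hemodynamics and BOLD physics,
realistic vascular geometry, spatial autocorrelation of cortical
morphometry, site/scanner effects, or any nonlinearity in the
brain–behaviour mapping. Passing tests therefore demonstrate that the
*pipeline recovers planted effects of the assumed form at realistic
sizes* — not that real AVM cohorts behave this way.

## Statistical machinery

Group comparisons follow the conventions under which published
demographic tables reproduce exactly: Welch's unequal-variance t from
summary statistics, Yates-corrected χ² for 2×2 tables, Mann–Whitney U
with exact enumeration for small tie-free samples and a tie- and
continuity-corrected normal approximation otherwise. Cognitive batteries
are z-scored against the control group, latency tests inverted at the z
level (`z → −z`, preserving the control-referenced scale, rather than a
raw reciprocal which would not), domain composites averaged (Verbal
Fluency intentionally contributes to both the Executive and Language
domains), and demographics removed by OLS residualization to
unit-variance residuals that are exactly orthogonal to the design.

Robust regression is Huber M-estimation (c = 1.345, MAD scale, IRLS) via
`MASS::rlm`; an exactly-fitting design short-circuits to the least-squares
solution, since zero residual scale makes the M-estimate coincide with
it. Edgewise comparisons Fisher-z transform the correlations first, test
the group term per upper-triangle edge against a shared covariate design
(vectorized across edges), and apply Benjamini–Hochberg FDR within the
edge family. The sensitivity sweep re-runs the key regressions across
densities 8–20% and lesion cut-offs, flagging a term robust only when
both sign and significance are grid-constant; a single-point grid is
flagged degenerate.

## Problem sizes and tolerances

The default test and acceptance runs use 90-node networks, 20–44 patients
per synthetic cohort, 50-replicate recovery/power studies, 200-replicate
robustness studies, and a 500-replicate type-I calibration — sizes chosen
so the full suite completes in well under a minute of compute per study
while leaving the Monte-Carlo margins far from their thresholds.
Numerical tolerances: matrix IO round-trips at 1e-12, oracle agreements
at 1e-10 (linear algebra) and 1e-6 (ODE integration), input symmetrization
at 1e-8.

## Known limitations

* The generator's lesion grows on a block-parcel toy volume; real lesion
  geometry (vascular territories, white-matter involvement) is out of
  scope, as is any MRI preprocessing.
* Coupling uses Spearman correlation of connectivity profiles only;
  communicability- or path-based coupling variants are not implemented.
* The NDM assumes linear, time-invariant spread on a static connectome
  and does not fit `β` by likelihood.
* Huber M-estimation is robust to response outliers, not to leverage
  points; the tests exercise exactly the response-contamination regime.
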