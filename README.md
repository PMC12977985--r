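# avmnet

Lesion-aware connectome analysis of cognitive impairment in unruptured
brain arteriovenous malformations (AVMs) — and, more generally, in any
cohort where focal lesions raise the question *is cognitive decline driven
by the lesion itself, or by the white-matter disconnection it causes?*

The package is written for neuroimaging researchers who already have
parcel-level connectivity matrices (e.g. over the 360-parcel HCP-MMP1
atlas) and want a tested, reproducible implementation of the network
side of that question: lesion-masked structural/functional network
construction, weighted graph topology, structure–function coupling,
Network Diffusion Model (NDM) epicenter mapping, virtual-lesion
resilience, and robust brain–behaviour statistics. A fully seeded
synthetic cohort generator stands in for patient MRI data, so every
stage is testable end to end on any machine.

## The models at the core

**Network Diffusion Model.** Pathology is assumed to spread along the
structural connectome according to the network heat equation

    x(t) = exp(−βLt) · x(0),    L = I − D^(−1/2) A D^(−1/2)

where `A` is the weighted structural adjacency, `D` its degree matrix and
`β` the diffusion constant (only the product `βt` is identifiable, so
`β = 1` and `t` is swept). `ndm_fit()` tests every cortical parcel as the
seed `x(0) = e_i`, correlates the simulated pattern at each diffusion time
with an empirical atrophy/deformation t-map, and ranks parcels by peak
Pearson R: the top-ranked seed is the putative *epicenter* of spread.

**Structure–function coupling.** For each node, the Spearman rank
correlation between its structural and functional connectivity profiles
(self-connections excluded); low values mean functional synchrony is
maintained through indirect or reorganised routes rather than direct
anatomical pathways.

**Virtual lesion.** Removal of a node, with the resulting drop in
weighted global efficiency (mean inverse shortest-path length, distances
`1/w`, disconnected pairs contributing 0) compared against a null of
random single-node removals: `p = (1 + #{null ≥ observed}) / (n_null + 1)`.

**Brain–behaviour statistics.** Control-referenced cognitive Z-scores and
domain composites, demographic residualization, OLS and Huber-M robust
regression (`c = 1.345`, IRLS), Welch t / Yates-corrected χ² /
Mann–Whitney U group tests, Benjamini–Hochberg FDR, edgewise Fisher-z FC
comparisons, and a sensitivity sweep over sparsity (8–20%) and
lesion-exclusion cut-offs.

## Worked example

Generate a 90-node synthetic connectome, diffuse pathology from parcel 49,
recover the epicenter from a noisy atrophy map, and probe its resilience:

```r
library(avmnet)

cfg     <- synth_config(n_nodes = 90, rng_seed = 7)
sc      <- gen_structural_connectome(cfg)
atrophy <- gen_atrophy_from_seed(sc, seed_parcel = 49, t_star = 2.5,
                                 noise_sd = 0.1)

fit <- ndm_fit(sc, atrophy)
summary(fit)
#> Network Diffusion Model epicenter fit
#>   atrophy metric: synthetic_diffusion
#>   global max R = 0.9941 at t = 2.45, seed parcel 49
#>   negated-map max R = 0.2880 (seed 83); max |R| = 0.9941
#>   top seeds:
#>  parcel_id    peak_r t_opt rank
#>         49 0.9940745  2.45    1
#>         82 0.9717878  3.60    2
#>         48 0.9464439  4.05    3

virtual_lesion(sc, fit$epicenter, n_null = 1000)
#> Virtual lesion of node 49
#>   E_base = 0.221412, E_removed = 0.219915 (delta = 0.6758%)
#>   one-sided p = 0.2338 vs 1000 random removals
```

The true seed (parcel 49) is recovered as the rank-1 epicenter at
essentially the planted diffusion time (`t = 2.45` on a 0.05-step grid vs
the planted 2.5), despite 10% noise. Its removal costs under 1% of global
efficiency and is indistinguishable from random node removal — an
epicenter of spread need not be a topological hub.

The whole analysis, from cohort synthesis through the dissociation
regressions (does white-matter integrity or lesion volume predict
cognition?), runs as one call:

```r
res <- run_pipeline(pipeline_config(rng_seed = 7), output_dir = "results")
res$report$cognition$integrity_model$OLS$p   # small: integrity predicts cognition
res$report$cognition$lesion_load_model$p     # large: lesion volume does not
```

A thin command-line wrapper with `synth` and `run` subcommands is
installed at `inst/cli/avmnet.R`.

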