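# clinezone

Spatiotemporal analysis of hybrid-zone clines from diploid microsatellite
genotypes.

`clinezone` is built for the question a two-era hybrid-zone study asks: has
the contact zone between two species moved or widened between sampling
periods? Its worked system is the contact zone between the chorus frogs
*Pseudacris fouquettei* (west) and *P. nigrita* (east) across the Pearl
River (Louisiana/Mississippi), sampled once in 1976 and again in 2001–2012
at the same 11 microsatellite loci, but every step is generic: the package
is aimed at population geneticists comparing cline structure between
sampling eras from genotype tables.

## What it computes

**Hybrid index.** Each individual gets a maximum-likelihood admixture
proportion *h* ∈ [0, 1] from parental allele frequencies (reference pool
*h* = 0, alternative pool *h* = 1), treating each allele copy as a draw from
the mixture *h·f*<sub>alt</sub> + (1 − *h*)·*f*<sub>ref</sub>:

    lnL(h) = Σ_copies ln[ h f_alt(a) + (1 − h) f_ref(a) ]

with a profile-likelihood 95% interval (1.92 log-unit drop) and two
classification rules (0.25 ≤ h ≤ 0.75, or a CI excluding both 0 and 1).

**Geographic clines.** Population mean *h* (*p̄*) against transect position
*x* is fitted with the Szymura–Barton sigmoid
μ(x) = 1/(1 + exp(−4(x − c)/w)) — centre *c*, width *w* (inverse maximum
slope) — optionally with exponential tails (per side: τ, δ) joined
value-continuously at x = c ± δ. The likelihood is the binomial
log-likelihood ratio against the saturated model with per-population weight
N. Fitting is random-walk Metropolis MCMC with covariance-tuned proposals
(plus a deterministic multi-start optimiser backing up the MLE), and the
five tail variants are compared by AIC weights and evidence ratios.

**Era comparisons.** Reciprocal constraint tests (refit one era with centre,
width or both truncated to the other era's 95% credibility interval; report
2LLR and ΔAIC) and stratified subsampling (match populations across eras,
equalise N, refit both eras, tally replicates with non-overlapping CrIs).

**Supporting statistics.** GenePop/CSV input, 4-km single-linkage site
pooling with a pairwise-FST guard, observed/expected heterozygosity,
G<sub>IS</sub>, effective and rarefied allele numbers, private alleles,
Monte-Carlo exact Hardy–Weinberg tests, genotypic LD G-tests,
Weir–Cockerham θ with permutation p-values, Holm correction throughout — and
a synthetic hybrid-zone generator with known truth for end-to-end
validation.

## Worked example

Refit the historical (1976) cline from the bundled published transect
positions, population mean hybrid indices and sample sizes:

```r
library(clinezone)
dh   <- pearl_river_cline_data("historical")
spec <- cline_model_spec("none", direction = "decreasing")
fit  <- fit_cline_mcmc(dh, spec, burnin = 5000, generations = 50000,
                       thin = 50, chains = 3, seed = 1)
fit
#> cline_fit [ none tails, decreasing ]
#>   center      257.532  (255.294 - 259.836)
#>   width        13.947  (10.253 - 25.810)
#>   lnL = -3.8935  k = 2  AIC = 11.7870
```

The centre sits at 257.5 km along the west–east transect (at the Pearl
River) and the width is ~14 km — a narrow tension zone. The same call on
`pearl_river_cline_data("recent")` gives centre 230.1 km with width 349.6 km
(credibility interval 256–788 km): the centre has not moved between eras but
the zone has become an order of magnitude wider. A constrained refit
quantifies this:

```r
con <- constrained_fit(dh, spec, constraints = list(width = c(232.372, 582.217)),
                       burnin = 5000, generations = 50000, thin = 50,
                       chains = 3, seed = 1)
reciprocal_constraint_test(fit, con)
#>   lnL_uncon lnL_con AIC_uncon AIC_con    LLR2    dAIC
#> 1   -3.8935 -30.214    11.787  62.428 -52.641 -50.641
```

Forcing the historical width into the recent credibility interval costs ~26
log-likelihood units (2LLR ≈ −53): the two eras' widths are incompatible.

Synthetic data with known truth exercises the full pipeline:

```r
sim <- simulate_hybrid_zone(simulation_config(), seed = 42)
pf  <- estimate_parental_frequencies(sim$genotypes, "P07", "P01")
cd  <- population_mean_h(hybrid_index(sim$genotypes, pf), sim$meta)
fit_cline_ml(cd, spec)$par
#>    center     width
#> 257.94812  15.07037     # truth: centre 257.5, width 14
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the bundled published inputs: the three no-tails cline
refits (historical; recent; recent excluding populations B–D), AIC model
selection across the five tail variants on the historical data, a
reciprocal width-constraint test, and the 4-km pooling of the 30 recent
collection sites (weighted population coordinates), then writes the results
manifest to `--out`.

See `vignettes/hybrid-zone-clines.Rmd` for the models, their assumptions,
and the numerical choices.
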