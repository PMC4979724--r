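---
title: "Hybrid-zone cline models and methods in clinezone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-zone cline models and methods in clinezone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`clinezone` analyses a hybrid zone sampled in two eras: microsatellite
genotypes in, per-individual hybrid indices, geographic cline fits, and
era-comparison tests out. This vignette is the package's own account of the
models it implements, the assumptions behind them, and the numerical and
design choices a maintainer would want justified. The worked system
throughout is the *Pseudacris fouquettei* / *P. nigrita* contact zone at the
Pearl River, whose published population summaries ship with the package
(`pearl_river_populations()` and friends), but nothing in the machinery is
specific to it.

## The hybrid index

An individual's hybrid index $h \in [0,1]$ is its admixture proportion
between two parental gene pools: a reference pool ($h = 0$) and an
alternative pool ($h = 1$). Given per-locus parental allele frequencies
$f_{\mathrm{ref}}$ and $f_{\mathrm{alt}}$, each of the individual's allele
copies $a$ is modelled as an independent draw from the mixture
$h\,f_{\mathrm{alt}}(a) + (1-h)\,f_{\mathrm{ref}}(a)$, so

$$\ln L(h) \;=\; \sum_{\text{copies } a} \ln\!\big[\,h f_{\mathrm{alt}}(a)
+ (1-h) f_{\mathrm{ref}}(a)\,\big].$$

This per-allele formulation (rather than per-genotype) is the standard
maximum-likelihood hybrid-index estimator for codominant markers; it assumes
Hardy–Weinberg proportions within the mixture and free recombination among
loci. $\ln L$ is a sum of logs of functions linear in $h$, hence concave, so
a single bounded scalar optimisation finds the global maximum; exact
likelihood ties are broken toward the boundary (an individual carrying only
alleles absent from one pool is called pure, not interior). The 95% interval
is the profile set $\{h : \ln L(h) \ge \ln L(\hat h) - 1.92\}$ — the
$\chi^2_1/2$ drop — intersected with $[0,1]$. The interval is what the two
classification rules consume:

* **cutoff** — hybrid iff $0.25 \le h \le 0.75$ (laboratory F1s between
  related chorus frogs scored $h$ between 0.5 and 0.75, motivating the
  published band);
* **ci** — hybrid iff the interval excludes both 0 and 1 (more liberal).

**Pseudocount.** Parental frequencies get an additive pseudocount
($10^{-6}$ by default) on every allele observed anywhere in the dataset.
Without it, an allele absent from both pools makes the likelihood
identically zero; with it, $\hat h$ moves by $O(10^{-5})$, far below the
profile-interval width at 11 loci. The pseudocount is a smoothing device,
not a model parameter; setting it to 0 makes the estimator error loudly
instead.

**Orientation.** The packaged Pearl River tables orient $h = 1$ as
*P. fouquettei*, the western species: the westernmost populations A and H1
have mean $h = 1$, and the fitted clines decrease eastward. Published
descriptions of this system are not uniform about which species is called
the reference; the population-table orientation is the internally
consistent one and is adopted throughout. Swapping pools maps
$h \mapsto 1-h$ and mirrors the interval (a tested invariant), so nothing
downstream depends on the choice beyond the sign convention.

## Geographic clines

Population mean hybrid index $\bar p$ is regressed on transect position $x$
(km) with the Szymura–Barton sigmoid. For an increasing cline,

$$s(x) = \frac{1}{1 + e^{-4 (x - c)/w}},$$

with centre $c$ (where $s = 1/2$) and width $w$ (inverse of the maximum
slope). Decreasing data — the Pearl River case, $h$ high in the west — use
the mirrored curve; the orientation is an explicit flag on the model
specification, never re-inferred per MCMC draw (which would make the
posterior multimodal by construction).

**Tails.** Beyond a distance $\delta$ from the centre, a tailed side follows
an exponential whose rate is scaled by $\tau \in [0,1]$, joined to the
central sigmoid *by value* at the junction $x = c \pm \delta$. For the lower
side of an increasing cline:

$$\mu(x) = s(c - \delta)\,
\exp\!\left[\frac{4\tau\,(x - c + \delta)}{w\,(1 + e^{-4\delta/w})}\right],
\qquad x < c - \delta,$$

and symmetrically on the upper side. $\tau = 0$ gives a flat tail at the
junction value; larger $\tau$ approaches the end frequency faster. Value
continuity at the junctions is enforced as the defining constraint and is a
unit test; the exact historical tail parameterisations in the literature
differ in details the data here cannot distinguish. Five variants are
offered: none (k = 2 free parameters), west tail, east tail, symmetric
tails (k = 4 each), asymmetric tails (k = 6). Tail sides are named
geographically (west = smaller $x$). With $\delta$ at least the distance
from the centre to the farthest data point the tail region is empty, so
every tailed model can reproduce the plain sigmoid exactly; the nesting
$\max \ln L(\text{tailed}) \ge \max \ln L(\text{no tails})$ is tested in
that form. (The pointwise identity "$\delta = 0$ reduces a tailed model to
the sigmoid" does *not* hold under a value-continuous parameterisation —
$\delta = 0$ puts the entire half-line into the tail — which is why the
nesting property, not the pointwise one, is the tested invariant.)

**End frequencies** $p_{\min}, p_{\max}$ are fixed at 0 and 1: the parental
reference populations define the scale of $h$, so the cline is a cline in
admixture itself, not in an allele frequency with internal polymorphism.

**Likelihood.** Populations contribute through the binomial log-likelihood
ratio against the saturated model,

$$\ln L = \sum_i N_i \left[\bar p_i \ln\frac{\mu_i}{\bar p_i}
+ (1-\bar p_i) \ln\frac{1-\mu_i}{1-\bar p_i}\right],$$

with $N_i$ the number of individuals, $0 \ln 0 = 0$, and $\mu$ clamped to
$[10^{-12}, 1-10^{-12}]$ so end populations with $\bar p$ exactly 0 or 1
stay finite. A perfect fit gives $\ln L = 0$, which makes fitted values
directly comparable across datasets; the location of the maximum is
invariant to the saturated-model constant and to uniform rescaling of all
$N_i$, so the choice of individuals (rather than allele copies) as the
effective count cannot move the centre/width estimates, only the absolute
log-likelihood scale. This choice reproduces the published near-zero
best-fit log-likelihoods.

**Fitting.** Random-walk Metropolis with a uniform prior over a bound box:
centre in the sampled span ±50 km; width in $(0, 2\,\mathrm{span}]$ — wide
because diffuse-cline posteriors genuinely extend beyond the sampled span;
$\tau \in [0,1]$; $\delta \in [0, \mathrm{span}]$. A pilot chain with
diagonal proposals estimates the parameter covariance; main chains (three
by default) use multivariate Gaussian proposals scaled by $2.38^2/d$ times
that covariance. The published protocol ($10^5$ burn-in, $10^6$ generations,
thinned every 100) is the default; tests and the acceptance script use
shorter chains, which is safe because the reported MLE is the better of the
best posterior draw and a deterministic 16-start Latin-hypercube L-BFGS-B
optimisation — point estimates do not depend on chain length, only the
credibility intervals do, and split-half quantile stability is reported as
a convergence diagnostic. Posterior intervals are central 2.5–97.5
percentiles pooled across chains; parameters whose interval presses against
the prior box (within 1% of its width) are flagged rather than silently
reported.

**Model selection** uses AIC $= 2k - 2\ln L_{\max}$, $\Delta$AIC, relative
likelihoods $e^{-\Delta/2}$, Akaike weights and evidence ratios. One caveat
worth stating plainly: sharp narrow-width ridges exist in the tailed-model
likelihood surfaces, and a finite MCMC sample systematically under-reports
their maxima. The multi-start optimiser here can reach higher tailed-model
likelihoods than an MCMC-only analysis reports; AIC comparisons between
tailed models are therefore sensitive to optimiser effort in a way the
no-tails fits (smooth, well-identified) are not.

## Era comparisons

**Reciprocal constraint tests.** One era's data are refit with centre,
width, or both truncated to the other era's 95% credibility interval —
implemented as truncated prior support on the same machinery, so a
degenerate interval $[v, v]$ fixes a parameter exactly. The statistics are
$2\mathrm{LLR} = 2(\ln L_{\mathrm{con}} - \ln L_{\mathrm{uncon}})$ and
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\mathrm{uncon}} -
\mathrm{AIC}_{\mathrm{con}}$. Each constrained parameter is *dropped from
the free-parameter count* in the constrained fit's AIC. This follows the
published constrained-AIC arithmetic, which decodes unambiguously as
$k_{\mathrm{eff}} = k - \#\text{constrained}$ (e.g. a width-constrained
two-parameter fit printed as $2 \cdot 1 - 2\ln L$); treating the constraint
as leaving $k$ unchanged would shift every constrained AIC by 2 per
parameter without changing any conclusion, but would not match the printed
tables.

**Stratified subsampling.** To separate sampling-design effects from real
change, each historical population is matched to a candidate set of recent
populations; per replicate one candidate is drawn per pair, individuals are
subsampled without replacement to the smaller N of each pair, mean $h$ is
recomputed, both eras are refit with the no-tails model, and a parameter
scores "significant" when the two 95% credibility intervals are disjoint
(deliberately conservative). Matching N per pair is adopted; the published
totals for the two easternmost-anchor choices are mutually consistent only
under per-pair matching, though the printed totals themselves cannot be
reproduced exactly without the archived genotypes (see Limitations).
Identical inputs in both era slots must and do yield zero significant
tallies — that null check is part of the acceptance suite.

## Transect projection

Coordinates are projected onto an ordinary least-squares line (latitude on
longitude) in a locally scaled planar frame: 1° latitude = 111.32 km,
longitude scaled by $\cos(\bar\phi)$. Projection is orthogonal in that
frame and positions are measured from the westernmost projection. Whether
the original analysis regressed latitude on longitude, the reverse, or
orthogonally is not stated in the source; on the Pearl River coordinates
the choice moves positions by a few km (the projection reproduces the
published distances to within 5 km, correlation > 0.9999). For exact
reproduction all fitting accepts published distances verbatim through
`load_printed_distances()`, so no cline result in the acceptance suite
depends on the projection choice.

## Site pooling

Collection sites within 4 km are merged by single-linkage closure
(connected components of the ≤ 4 km graph). The published groupings list
final pools but not the linkage rule; closure reproduces every published
pool from raw coordinates, which is the test. Pooled coordinates are
individual-count-weighted means. Isolated sites below 2 individuals are
excluded with a report (mirroring the published handling of a singleton
site); an optional guard computes pairwise Weir–Cockerham $\theta$ with
permutation p-values inside every merged pool and reports — not blocks —
merges that remain significant after Holm correction.

## Diversity statistics: conventions

* Expected heterozygosity uses Nei's small-sample correction
  $\frac{2n}{2n-1}(1 - \sum p^2)$ (the uncorrected gene diversity is a
  flag away); $G_{IS} = 1 - H_o/H_e$, reported missing when $H_e = 0$
  rather than coerced to 0.
* Allelic richness is rarefied hypergeometrically:
  $AR_g = \sum_a [1 - \binom{2n - n_a}{g}/\binom{2n}{g}]$, validated
  against exhaustive subsample enumeration on toy data.
* The Hardy–Weinberg exact test orders genotype configurations by Levene's
  conditional probability and estimates the p-value by Monte-Carlo
  shuffling of allele copies (the published analyses used a Markov-chain
  walker; same null, simpler convergence story, replicate count
  configurable). Tested against full enumeration on small biallelic
  samples.
* Linkage disequilibrium uses a genotypic contingency G statistic summed
  over populations with within-population permutation; pairwise
  differentiation uses Weir–Cockerham $\theta$ (the published software's
  internal estimator is unnamed; $\theta$ is the field standard and the
  permutation test is estimator-agnostic).
* "Sequential Bonferroni" is Holm's step-down procedure, applied table-wide
  for HWE and across pairs for FST (via `stats::p.adjust`, checked against
  a brute-force ordering oracle); plain Bonferroni is used across LD pairs,
  as in the original analysis.
* Private alleles are counted per species pool as strict set differences;
  whether hybrid-zone populations join a pool is the caller's choice via
  the assignment map (the published convention is not stated, so both are
  expressible).

## The synthetic generator: what it emulates, what it does not

`simulation_config()` states a world resembling the historical sampling
design: 7 populations at the published transect positions with the
published sample sizes, 11 loci with 4–12 alleles, a decreasing no-tails
cline (centre 257.5 km, width 14 km). Parental pools are built per locus
from a shared symmetric Dirichlet base tilted apart by a divergence
parameter (default 0.5), with 55% of alleles made private to one pool — the
private fraction is anchored on the published allele accounting (139 of 245
historical alleles private to one species). Individual admixture is drawn
$h_i \sim \mathrm{Beta}(qk, (1-q)k)$ around the population expectation $q$
with concentration $k = 20$ (sd ≈ 0.11 at $q = 0.5$, a spread consistent
with populations mixing parental, F1/F2 and backcross classes); genotypes
are mixture draws per allele copy; missing calls (2% default, settable per
locus) and optional null-allele dropout (apparent homozygotes) are masked
last.

What the generator does *not* emulate: pedigree structure (no distinct
hybrid classes, no linkage disequilibrium beyond admixture), mutation
models, spatial autocorrelation of individuals within populations, and
scoring artefacts other than simple dropout. A green end-to-end test
therefore establishes that the estimators recover a known admixture cline
from mixture-sampled genotypes at realistic sample sizes — not that they
are robust to pedigree structure or genotyping error beyond the masking
implemented. Within that world, credibility-interval coverage of the true
centre and width exceeds 85% over 50 replicate datasets (an acceptance
test); with weakly diverged pools (divergence well below the default, few
private alleles) the hybrid index is biased toward 0.5 and fitted widths
inflate — a real limitation of the index with overlapping parental pools,
visible here because the truth is known.

## Numerical choices, collected

* $\mu$ clamped at $10^{-12}$; $0\ln 0 = 0$; optimiser restarts from 16
  deterministic Latin-hypercube points (no RNG consumed).
* Profile-CI roots by bisection to $10^{-9}$; concavity of the index
  likelihood guarantees at most one root per side.
* All Monte-Carlo p-values use the add-one estimator $(\text{hits}+1)/
  (\text{reps}+1)$, so the permutation floor is $1/(\text{reps}+1)$, never 0.
* Every stochastic entry point takes an explicit integer seed; the caller's
  RNG state is saved and restored.
* Haversine distances on a 6371.0088 km sphere; at a 4 km pooling threshold
  the ellipsoidal error is sub-metre.

## Known limitations

* The raw two-era genotypes behind the published study are archived
  externally without a resolvable accession, so per-individual published
  results (hybrid proportions per population, diversity tables, subsampling
  tallies) cannot be recomputed here; the package recomputes everything the
  printed tables make recomputable (cline refits from mean-$h$ data, AIC
  and constraint arithmetic, pooled coordinates) and validates the
  remainder on synthetic truth.
* For the recent-era dataset excluding its three westernmost hybrid
  populations, the centre likelihood is nearly flat over ~15 km; the
  package reports the argmax, which can sit away from an MCMC-derived
  published point estimate while fitting the data marginally better. The
  acceptance suite checks that centre against the published credibility
  interval, not the published point.
* Tailed-model maximum likelihoods depend on optimiser effort (sharp
  ridges); treat close AIC calls between tailed variants with caution.
* Cline widths are not converted to dispersal/selection estimates, and
  per-locus (multi-locus genomic) clines are out of scope.
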