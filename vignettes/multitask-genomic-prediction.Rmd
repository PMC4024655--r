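---
title: "Multi-task spike-and-slab genomic prediction across populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task spike-and-slab genomic prediction across populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic prediction estimates an animal's additive genetic merit (its
breeding value) from genome-wide SNP genotypes, using a reference
population with both genotypes and phenotypes. Small populations — a
numerically minor dairy breed, say — yield poor accuracy on their own,
and the obvious remedy of pooling reference data across breeds is unsafe:
allele substitution effects differ between populations because of
different linkage phase between markers and causal loci (QTL), different
allele frequencies, and genuine effect heterogeneity.

`mtgp` implements a middle road: a *multi-task* Bayesian whole-genome
regression in which populations share the information about *which*
markers matter, while each population keeps its own estimate of *how
much* (and in which direction) each marker matters.

## The models

### Single-task spike-and-slab regression

For one population of $n$ animals and $m$ SNP markers,

$$y_i = \mu + \sum_{j=1}^m x_{ij} a_j + e_i,$$

with genotype codes $x_{ij} \in \{0,1,2\}$ counting copies of a reference
allele. Each marker effect has a spike-and-slab prior:

$$a_j \mid w, \sigma^2_a \sim (1-w)\,N(0, \sigma^2_a) + w\,\delta_0(a_j),$$

where $\delta_0$ is a point mass at zero and $w$ — the *exclusion*
probability — has a Uniform(0,1) prior. A latent indicator $\gamma_j$
makes the mixture explicit: $\gamma_j = 1$ puts $a_j$ in the normal slab,
$\gamma_j = 0$ pins it to zero. The intercept has a flat prior, residuals
are i.i.d. $N(0, \sigma^2_e)$, and both variance components have scaled
inverse chi-square priors, $\sigma^2_a \sim \chi^{-2}(v_a, s^2_a)$ and
$\sigma^2_e \sim \chi^{-2}(v_e, s^2_e)$.

### Pooling

The simple pooling comparator stacks all populations into one training
set, keeps a fixed population effect (one intercept per population), and
forces a single shared effect vector, indicator vector and variance pair
on everyone.

### Multi-task model

With $c$ populations and $n_k$ animals in population $k$,

$$y_{ik} = \mu_k + \sum_{j=1}^m x_{ijk} a_{jk} + e_{ik},$$

each population has its own intercept $\mu_k$, effects $a_{jk}$, effect
variance $\sigma^2_{ak}$ and residual variance $\sigma^2_{ek}$ — but a
**single indicator vector $\gamma$ is shared**:

$$a_{jk} \mid \gamma_j, \sigma^2_{ak} \sim
  \gamma_j N(0, \sigma^2_{ak}) + (1-\gamma_j)\,\delta_0(a_{jk}).$$

A marker is either "on" everywhere or "off" everywhere, so the small
population borrows evidence about marker relevance from the large one
without inheriting its effect sizes.

## The Gibbs sampler

All three models run through one compiled single-site Gibbs core
(`run_single_task()`, `run_pooled()`, `run_multi_task()`); with one
population they produce bitwise-identical chains under a shared seed.
One sweep:

1. For each marker $j$ (ascending index), sample $\gamma_j$ and the
   effects jointly: first $\gamma_j$ from its conditional with effects
   integrated out, then, if included, $a_{jk} \sim
   N(\hat\mu_{ajk}, \hat\sigma^2_{ajk})$ per population. The exclusion
   odds are
   $$q_j = \frac{w}{1-w} \prod_k
     \left(\frac{\mathbf{x}'_{jk}\mathbf{x}_{jk}\sigma^2_{ak}}{\sigma^2_{ek}} + 1\right)^{1/2}
     \exp\!\Big(-\tfrac12 \sum_k \hat\mu^2_{ajk}/\hat\sigma^2_{ajk}\Big),$$
   with $\hat\mu_{ajk} = \mathbf{x}'_{jk}\mathbf{y}^*_k /
   (\mathbf{x}'_{jk}\mathbf{x}_{jk} + \sigma^2_{ek}/\sigma^2_{ak})$ and
   $\hat\sigma^2_{ajk} = \sigma^2_{ek} /
   (\mathbf{x}'_{jk}\mathbf{x}_{jk} + \sigma^2_{ek}/\sigma^2_{ak})$,
   where $\mathbf{y}^*_k$ removes the intercept and all *other* marker
   effects; $P(\gamma_j = 1) = 1/(1+q_j)$.
2. $w \sim \mathrm{Beta}(m - \sum\gamma_j + 1, \sum\gamma_j + 1)$.
3. $\sigma^2_{ak} \sim \chi^{-2}\!\big(v_a + \sum\gamma_j,\;
   (v_a s^2_a + \sum_j \gamma_j a^2_{jk})/(v_a + \sum\gamma_j)\big)$.
4. $\sigma^2_{ek} \sim \chi^{-2}\!\big(v_e + n_k,\;
   (v_e s^2_e + \mathbf{e}'_k\mathbf{e}_k)/(v_e + n_k)\big)$.
5. $\mu_k \sim N(\bar{(\mathbf{y}_k - X_k \mathbf{a}_k)},
   \sigma^2_{ek}/n_k)$.

Marker effects are summarized as unconditional posterior means over all
recorded post burn-in samples (zeros included), and GEBV for a
validation animal is $\hat\mu_k + \sum_j x_{ij}\,\bar a_{jk}$.

### Numerical and design choices

* **Residual bookkeeping.** The sampler maintains
  $\mathbf{e}_k = \mathbf{y}_k - \mu_k \mathbf{1} - X_k \mathbf{a}_k$
  and updates it incrementally at every accepted change, recovering
  $\mathbf{x}'_{jk}\mathbf{y}^*_k$ as
  $\mathbf{x}'_{jk}\mathbf{e}_k + \mathbf{x}'_{jk}\mathbf{x}_{jk} a_{jk}$.
  A from-scratch recomputation audits the bookkeeping every
  `check_every` sweeps; test chains audit every sweep and require
  agreement within $10^{-8}$ relative to the phenotype scale.
* **Log-space odds.** $q_j$ is accumulated in logarithms; the product
  over populations overflows in double precision at realistic
  $\mathbf{x}'\mathbf{x}\,\sigma^2_a/\sigma^2_e$ ratios.
* **The $w$ posterior.** The exact conditional under a Uniform(0,1)
  prior is $\mathrm{Beta}(m-\sum\gamma+1, \sum\gamma+1)$; the package
  defaults to it (`w_form = "conjugate_plus_one"`). A
  `"as_printed"` mode draws $\mathrm{Beta}(m-\sum\gamma, \sum\gamma)$
  with parameters floored at $10^{-8}$, which is improper at the
  boundaries $\sum\gamma \in \{0, m\}$ without the floor; we read the
  missing $+1$ as a typographical omission but keep both forms.
* **$\hat\mu_{ajk}$ and the intercept.** One published form of the
  conditional mean omits the intercept inside $\mathbf{y}^*_k$; the
  sampler subtracts the current $\mu_k$ (the residual-based update does
  this automatically), which is the form consistent with the joint
  posterior.
* **Initialization.** $\gamma = 0$, $a = 0$, $\mu_k = \bar y_k$,
  $w = 0.5$, variances at their prior means $s^2 v/(v-2)$ — a
  reproducible prior-mean start.
* **Update order.** Ascending marker index, for determinism; a
  `shuffle_order` flag exists and is off by default.
* **Guards.** The chain aborts with a diagnostic if any variance leaves
  $[10^{-12}, 10^{12}]$.
* **Pooled variances.** Whether the pooled comparator should carry one
  or per-population residual variances is ambiguous; we chose the
  simplest reading (one $\sigma^2_a$, one $\sigma^2_e$), matching "the
  same across populations".
* **Prior scales.** With known (true or REML) variances, scales come
  from the scaled-inverse-chi-square mean: $s^2 = \sigma^2 (v-2)/v$,
  with defaults $v_a = 4$, $v_e = 10$. For the pooled model the package
  derives scales from the sample-size-weighted mean of the
  per-population variances.

## The simulator

Real multi-breed chip data cannot ship with a package, so `mtgp`
generates synthetic data that reproduces the *statistical structure* of
a two-breed design:

* **Two populations of unequal size** — defaults 458 and 2,298 animals,
  split 393/65 and 2,084/214 into training and validation. The split is
  random per population (a real study would split by birth year; the
  simulator has no pedigree).
* **Divergence** via the Balding–Nichols model: marker frequencies in
  each population are Beta-distributed around an ancestral
  Uniform(0.1, 0.9) frequency with divergence $F_{st}$ (default 0.1,
  a plausible between-breed value for cattle).
* **LD** via a latent Gaussian copula: each haplotype is a stationary
  AR(1) process over markers (coefficient $\varphi$, default 0.95)
  thresholded at the population frequency. $\varphi = 0.95$ gives
  adjacent-marker genotype correlations around 0.6–0.7, decaying
  geometrically — a caricature of chip LD with a single tuning knob.
* **QTL** drawn uniformly from every 8th marker (the analogue of
  drawing causal loci from a low-density chip nested in a dense panel),
  with per-population effects bivariate normal, zero mean, unit
  variance and correlation $\rho$ (study values 0.2 and 0.8).
* **Trait** with heritability 0.5: per population,
  $\sigma^2_a = \sum_j 2 p_j (1-p_j) \alpha^2_{jk}$ computed from
  realized QTL frequencies, $\sigma^2_e = \sigma^2_a (1-h^2)/h^2$
  (exactly $\sigma^2_a$ at $h^2 = 0.5$), and
  $y_i = \sum_j X_{ij}\alpha_{jk} + e_i$. The variance formula ignores
  LD between QTL — intentionally, since it is the definition of the
  target $h^2$ — so the realized variance of the true breeding values
  differs slightly from $\sigma^2_a$ when QTL are linked. If every
  effect is exactly zero the residual variance falls back to 1 so
  phenotypes stay stochastic.
* **Panels**: thinning to every 2nd/4th/8th marker mimics lower chip
  densities; QTL columns are removed from the panel by default, or
  guaranteed present with `include_qtl_in_panel`.

What the simulator does **not** emulate: empirical breed LD structure
and its decay heterogeneity, allele-frequency spectra after
ascertainment, genotyping error, imputation error, pedigree structure,
selection. Tests passing on synthetic data therefore validate the
samplers and the qualitative method ranking, not the numerical
accuracies attainable on real bovine data.

## Verification strategy

* Every full-conditional draw is checked against its closed-form
  moments (Beta, scaled inverse chi-square, normal) at $10^5$ draws.
* On a tiny two-population instance (6 animals each, 3 markers) with
  frozen variances, $w$ and intercepts, the effects can be integrated
  out analytically and the posterior over all $2^3$ indicator
  configurations enumerated exactly; the Gibbs inclusion frequencies
  must match within Monte Carlo tolerance.
* Hand-evaluated exclusion odds (e.g. $q = \sqrt3\,e^{-2/3}$ for one
  population with $\mathbf{x}'\mathbf{x} = 2$,
  $\mathbf{x}'\mathbf{y}^* = 2$, unit variances, $w = 1/2$) pin the
  formula, and its degenerate limits ($\sigma^2_a \to 0$ gives
  inclusion probability $1-w$; zero marker-residual covariance caps it
  at $1-w$) are asserted directly.
* The model reductions — multi-task with $c=1$, pooled with $c=1$, and
  single-task — must produce identical chains under a shared seed.

## Problem sizes

The package's replicated experiment (`run_experiment()`, and the
acceptance script) runs a desk-scale analogue of the full study: 2,000
markers, a 400/120 small population with an 800/200 large one, 5,000
Gibbs cycles with 1,000 burn-in, five replicates per scenario. These
sizes keep a full two-scenario comparison within minutes on one core
while preserving the qualitative pattern of interest: with few QTL and
correlated effects, the multi-task model lifts small-population accuracy
above single-task; with weakly correlated effects, pooling depresses
small-population accuracy and yields dispersion slopes $b(TBV, GEBV)$
below one (inflated GEBV), while the multi-task model stays close to
single-task calibration. Full-scale settings (50,000 cycles, hundreds of
thousands of markers) remain configurable but are not the defaults.

## Known limitations

* Mean imputation of missing genotypes (within population) is the only
  missing-data treatment; heavily missing markers should be removed by
  QC first.
* The near-duplicate QC scan compares marker pairs within a sliding
  window (default 100 adjacent markers) rather than all pairs; LD-driven
  duplicates are positional, and the all-pairs scan is quadratic in
  panel size. Pairs with fewer than 10 jointly observed samples are
  never declared duplicates.
* No convergence diagnostics beyond the scalar trace; burn-in is the
  user's choice.
* Additive effects only; no dominance or epistasis.
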