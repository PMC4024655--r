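# mtgp — multi-task Bayesian genomic prediction across populations

`mtgp` is an R package for whole-genome regression when reference data
come from *several* populations (breeds, lines, herds) of very unequal
size. Pooling the populations into one training set is hazardous —
marker effects differ between populations in size and even sign — while
analysing the small population alone wastes the large one. The package
implements a **multi-task spike-and-slab model** that shares a single
vector of latent SNP-inclusion indicators across populations while
letting every population keep its own effect sizes, intercept and
variance components:

```
y_ik = mu_k + sum_j x_ijk a_jk + e_ik
a_jk | gamma_j ~ gamma_j N(0, sigma2_ak) + (1 - gamma_j) delta_0
gamma_j | w ~ Bernoulli(1 - w),  shared by all populations k
```

with scaled inverse chi-square priors on both variance components, a
uniform prior on the exclusion probability `w`, and a single-site Gibbs
sampler (compiled core) over `(gamma, a, w, sigma2_a, sigma2_e, mu)`.
Two comparators ship alongside: per-population **single-task**
stochastic search variable selection, and **simple pooling** (population
fixed effect, one shared effect vector). Predictions are genomic
estimated breeding values, `GEBV = mu_k + X beta_k`, evaluated by
accuracy `r(GEBV, TBV)` and dispersion slope `b(TBV, GEBV) =
cov(TBV, GEBV)/var(GEBV)` (slopes below 1 mean inflated GEBV).

The package also provides genotype/phenotype I/O (native TSV and PLINK
additive RAW), marker QC (MAF, missingness, near-duplicate columns,
cross-population panel harmonization), a two-population genotype and
trait simulator (Balding–Nichols divergence, AR(1) latent-Gaussian LD,
correlated QTL effects, heritability 0.5), and a replicated experiment
driver. See the vignette `vignettes/multitask-genomic-prediction.Rmd`
for the model, the sampler and every numerical choice.

## Worked example

Simulate a small two-population study (400 + 800 training animals,
2,000 markers, 20 QTL with effect correlation 0.8, QTL genotyped), fit
all three models, and compare validation accuracy in the small
population:

```r
library(mtgp)

cfg <- sim_config(n_per_population = c(520, 1000), n_train = c(400, 800),
                  m_markers = 2000, n_qtl = 20, rho = 0.8,
                  include_qtl_in_panel = TRUE)
d <- simulate_study_data(cfg, seed = 3)

train <- function(g) impute_missing_to_mean(
  subset_genotypes(g, samples = intersect(rownames(g$codes), d$split$train)))
X <- lapply(d$panel, train)
y <- lapply(names(X), function(p)
  d$phenotypes$value[match(rownames(X[[p]]), d$phenotypes$sample_id)])
names(y) <- names(X)

prior <- prior_spec(s2_a = derive_scale(d$truth$sigma2_a, 4),
                    s2_e = derive_scale(d$truth$sigma2_e, 10))
chain <- gibbs_config(n_iter = 5000, burn_in = 1000, seed = 7)

fit_multi  <- run_multi_task(X, y, prior, chain)
fit_single <- run_single_task(X[1], y[1],
                              prior_spec(s2_a = prior$s2_a[1],
                                         s2_e = prior$s2_e[1]), chain)

val <- subset_genotypes(d$panel$pop1,
  samples = intersect(rownames(d$panel$pop1$codes), d$split$validation))
tbv <- d$truth$tbv$pop1
for (f in list(single = fit_single, multi = fit_multi)) {
  p <- predict_gebv(f, val)
  cat(f$method, " r =", round(accuracy_r(p$gebv, tbv[p$sample_id]), 3),
      " b =", round(slope_b(p$gebv, tbv[p$sample_id]), 3), "\n")
}
```

Output:

```
single  r = 0.879  b = 1.11
multi  r = 0.949  b = 1.01
```

The multi-task fit lifts small-population accuracy from 0.88 to 0.95
here: the 800 large-population animals tell the sampler *which* of the
2,000 markers carry signal, and the 400 small-population animals only
need to estimate the 20-odd selected effects. Both slopes sit near 1
(well-calibrated GEBV). `run_experiment()` repeats such comparisons
over replicates and scenarios and reports mean ± standard error of `r`
and `b` per method and population.

A thin command-line front end over the same functions is installed at
`inst/cli/mtgp.R` (subcommands `simulate`, `fit`, `predict`,
`evaluate`, `experiment`).

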