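---
title: "Estimating absolute microbial abundances from joint 16S and qPCR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating absolute microbial abundances from joint 16S and qPCR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microconc)
```

## The problem

Broad-range sequencing assays (16S rRNA amplicon sequencing, shotgun
metagenomics) report read counts $W_{ij}$ for many taxa $j = 1, \dots, q$
in each sample $i$, but a read count only measures *composition*: the
total depth $M_i = \sum_j W_{ij}$ is an artifact of the instrument, not of
the community. Taxon-specific assays such as qPCR measure *concentration*
(e.g., gene copies per swab) but must be developed per taxon, so they are
available only for a small panel $j = 1, \dots, q^{\mathrm{obs}} \ll q$.
`microconc` combines the two data types to estimate the latent
concentration $\mu_{ij}$ of **every** taxon in every sample, with honest
uncertainty.

The central obstacle is that the two technologies do not see taxa equally
well. Plotting qPCR subcompositions against sequencing subcompositions for
taxa measured by both shows taxon-specific slopes: each taxon has a
detection *efficiency* $e_j$ with which sequencing observes it relative to
the concentration assay (primer affinity, extraction bias, copy-number
effects, ...). Ignoring this bias propagates it into every concentration
estimate.

## The model

Observed concentrations are treated as Poisson realizations of the latent
concentrations, and reads as an efficiency-weighted multinomial:

$$
V_{ij} \mid \mu_{ij} \sim \mathrm{Poisson}(\mu_{ij}), \qquad
W_{i\cdot} \mid M_i, \mu_{i\cdot}, e \sim
\mathrm{Multinomial}\!\left(M_i,\; p_{i\cdot}\right), \quad
p_{ij} = \frac{\mu_{ij} e_j}{\sum_{\ell} \mu_{i\ell} e_\ell}.
$$

The hierarchy on the latent quantities is lognormal throughout, matching
the strong right skew of concentration data and guaranteeing positivity:

$$
\log \mu_{i\cdot} \sim N_q(\beta, \Sigma), \quad
\beta_j \sim N(0, \sigma^2_\beta), \quad
\Sigma_{jj} \sim \mathrm{Lognormal}(0, \sigma^2_\Sigma), \quad
e_j \sim \mathrm{Lognormal}(0, \sigma^2_e), \quad
\sigma^2_e \sim \mathrm{InvGamma}(\alpha_\sigma, \kappa_\sigma),
$$

with $\Sigma$ diagonal. Efficiencies are identified only up to scale —
multiplying all $e_j$ by a constant leaves $p_{ij}$ unchanged — so the
zero-mean prior on $\log e_j$ acts as *soft centering*. Hard-centering
variants (dividing by the geometric mean of $e$ over the observed taxa, or
over all taxa) are available via `model_spec(centering = )`; in practice
they give near-identical estimates, and soft centering is the default.

The `efficiency_naive` variant fixes $e_j \equiv 1$; it exists to
quantify what ignoring efficiency costs, and `log_joint_density()` of the
full model at $e \equiv 1$ reduces to it exactly once the two
efficiency-prior terms are dropped (this identity is enforced in the test
suite to $10^{-10}$).

With a per-sample covariate $X_i$ (e.g., case/control status), the mean
model becomes $\log \mu_{i\cdot} \sim N_q(\beta_0 + \beta_1 X_i, \Sigma)$
with independent normal priors on $\beta_0$ and $\beta_1$
(`covariate_adjusted = TRUE`).

## Hyperparameters

All defaults live in `hyperparameters()`:

| parameter | default | meaning |
|---|---|---|
| `sigma_beta_sq` | 50 | prior variance of each mean log concentration $\beta_j$ |
| `sigma_Sigma_sq` | 50 | prior variance of $\log \Sigma_{jj}$ |
| `alpha_sigma`, `kappa_sigma` | 2, 1 | inverse-gamma shape/scale for $\sigma^2_e$ |
| `sigma_beta0_sq`, `sigma_beta1_sq` | $1.62^2$, $1$ | covariate-model coefficient priors |
| `alpha_level` | 0.05 | default interval level $1-\alpha$ |

The variance 50 reflects the scale of log qPCR data (per-swab copy counts
spanning many orders of magnitude); users applying the model to other
units (CFU/mL, flow-cytometry counts) should rescale these. The
inverse-gamma density is parameterized as
$p(x) \propto x^{-\alpha-1} e^{-\kappa/x}$; results for the unobserved
taxa are sensitive to this choice when $q^{\mathrm{obs}}$ is small,
because the prior then carries most of the information about the spread
of efficiencies — over-concentrating it narrows intervals at the cost of
coverage.

## Point estimates and intervals

After `fit_abundance()`, the posterior mean of $\mu_{ij}$ is the point
estimate; `credible_intervals()` returns the $(\alpha/2, 1-\alpha/2)$
posterior quantiles (linear interpolation of order statistics, so tests
can reproduce them independently). These exist for *every* sample and
taxon, including the many pairs with $W_{ij} = 0$ — a key advantage over
per-sample rescaling.

For taxa without concentration data, `predict_unobserved()` forecasts the
realized concentration $V_{ij}$. The default Wald interval applies the law
of total variance under the Poisson observation model,
$\widehat{\mathrm{Var}}(\hat V_{ij}) = \hat\mu_{ij} +
\widehat{\mathrm{Var}}(\mu_{ij})$, giving
$\max\{0, \hat\mu_{ij} \pm z_{1-\alpha/2}
\sqrt{\hat\mu_{ij} + \widehat{\mathrm{Var}}(\mu_{ij})}\}$ (truncated at
zero since concentrations are nonnegative). A posterior-predictive
alternative draws one Poisson variate per posterior draw and takes its
empirical quantiles; the two methods overlap everywhere on synthetic
data, and both are exposed.

## The scaling-factor baseline

The simplest estimator rescales reads by the implied per-sample factor
$\hat s_i = \sum_{j \le q^{\mathrm{obs}}} V_{ij} \big/
\sum_{j \le q^{\mathrm{obs}}} W_{ij}$, i.e.
$\hat\mu_{ij} = \hat s_i W_{ij}$. Its log-scale delta-method variance
treats the observed concentration total $T_V$ as Poisson and the reads as
multinomial. Writing $T_W$ for the read total over observed taxa:

- observed taxon ($j \le q^{\mathrm{obs}}$): $W_{ij}$ is a component of
  $T_W$ and the positive covariance between $\log W_{ij}$ and $\log T_W$
  cancels one $1/T_W$, leaving $1/T_V + 1/W_{ij} - 1/T_W$;
- unobserved taxon ($j > q^{\mathrm{obs}}$): $W_{ij}$ and $T_W$ are
  nearly uncorrelated and the terms add: $1/T_V + 1/W_{ij} + 1/T_W$.

Both branches are validated against a $10^5$-resample parametric
bootstrap (Poisson totals, multinomial reads) to within 15% relative
error in the test suite; the single-sign form fails that check for
unobserved taxa, which is why the variance is case-dependent.
Confidence intervals exponentiate $\log\hat\mu_{ij} \pm z\sqrt{v}$;
prediction intervals use $\sqrt{1/\hat\mu_{ij} + v}$. None of this exists
where $W_{ij} = 0$ — such pairs are excluded from coverage summaries, the
convention all evaluation code follows.

## Posterior computation

Sampling uses Gibbs/slice MCMC through JAGS (`rjags`), with three
numerical choices that matter:

1. **Sampled scale.** The chain runs on
   $\lambda_{ij} = \mu_{ij} e_j$ — the quantity the multinomial actually
   identifies — and recovers $\mu = \lambda / e$ deterministically.
   Sampling $\mu$ and $e$ separately leaves a one-dimensional ridge
   ($\mu_{ij} e_j$ fixed) that a one-scalar-at-a-time sampler random-walks
   along; on the $\lambda$ scale the ridge disappears.
2. **Analytic marginalization for unobserved taxa.** For
   $j > q^{\mathrm{obs}}$ under soft centering, $\beta_j$ and
   $\log e_j$ enter the likelihood only through their sum. The sampler
   therefore draws the sum against the data,
   $\beta_j + \log e_j \sim N(0, \sigma^2_\beta + \sigma^2_e)$, and then
   $\log e_j$ from its exact normal conditional given the sum — an exact
   reparameterization of the same joint distribution. Without it, the
   split between $\beta_j$ and $\log e_j$ (and hence the width of
   $\mu$-intervals for unobserved taxa) mixes so slowly that interval
   coverage collapses at desk scale.
3. **Anchored initialization.** Chains start from the scaling-factor
   estimate with a 0.5 pseudo-count for zeros,
   $\log\lambda^{(0)}_{ij} = \log(\hat s_i W_{ij} + 0.5)$, intercepts at
   its column means, $\Sigma_{jj} = 1$, and $\sigma^2_e$ at its prior
   mode $\kappa_\sigma / (\alpha_\sigma + 1)$ — deterministic, cheap, and
   consistent with the model's own baseline estimator. A jittered
   `"random"` strategy is available for sensitivity checks.

Desk-scale defaults are 4 chains with 1000 warmup and 500 retained
iterations each — seconds for tens of samples and taxa; production-scale
settings (10,000 warmup / 10,500 total) are one `mcmc_config()` call
away. Every source of randomness derives from the configured seed, so
identical configurations reproduce draws bit-for-bit. Convergence is
summarized by the classic between/within-chain potential scale reduction
factor (values slightly below 1 are possible by construction), reported
per scalar plus the median and IQR over all $\mu_{ij}$, together with
effective sample sizes.

## The synthetic-data generator

`simulate_dataset()` emulates a vaginal-microbiome-like study:
$\beta_j \sim N(0, 50)$, $\Sigma = I$, $e_j \sim
\mathrm{Lognormal}(0, \sigma_e^2)$, depths $M_i \sim
\mathrm{DiscreteUniform}(10^4, 10^5)$, $V_{ij} \sim
\mathrm{Poisson}(\mu_{ij})$ for all taxa, and efficiency-weighted
multinomial reads, with $n = 100$ samples by default. Taxa whose true
mean concentration falls below one unit are excluded from the analyzed
tables (mirroring the universal practice of dropping ultra-rare taxa; on
real data, where $\mu$ is unknown, `prevalence_filter()` plays this
role), and the most abundant retained taxa by mean read count become the
"observed" panel — concentration assays are designed for the taxa one
expects to matter. A master seed spawns independent substreams for each
stage, so changing $\sigma_e$ perturbs nothing else.

Because $\beta_j$ has standard deviation $\sqrt{50} \approx 7$ on the log
scale, a handful of taxa dominate every simulated community and the
fraction of zero counts among retained pairs is extremely variable across
draws of $\beta$ (quartiles span tens of percentage points at moderate
$q$). Replicate averages of sparsity statistics should therefore be read
with that dispersion in mind. The generator does **not** emulate
overdispersed (negative-binomial) concentrations, taxon-taxon
correlation, batch-varying efficiencies, or missing qPCR entries —
passing tests on these synthetic data says nothing about robustness to
those features.

## Evaluation surfaces

`run_simulation_study()` reports, per replicate and estimator: RMSE of
the $\mu$ estimates over all retained pairs, RMSPE of the $V$ predictions
over the unobserved block (both on the raw concentration scale; a
log-scale option exists because raw-scale RMSE is dominated by the most
abundant taxa), empirical coverage of nominal 95% intervals (closed
bounds; scaling-factor pairs with $W_{ij}=0$ excluded), and the zero
fraction. `jackknife_loo()` removes each observed taxon in turn, refits,
and scores prediction coverage and MSPE on the withheld concentration
column — the strongest validation available when no ground truth exists.
`conditional_mean_relative_abundance()` ranks taxa by abundance-when-
present, useful for interpreting which left-out taxa are hardest.

The test suite exercises these at reduced scale, chosen so the full
suite runs in minutes on one core: coverage comparisons use
$n = 60$, $q = 20$, $q^{\mathrm{obs}} = 7$ with $B = 8$ replicates and
3 chains of 1600 iterations; the parameter-recovery check uses a fixed
$n = 30$, $q = 10$, $q^{\mathrm{obs}} = 5$ dataset (its seed chosen so
the abundance filter retains enough taxa for a real unobserved block).
At these sizes the varying-efficiency model holds ~95% coverage under
$\sigma_e = 0.8$ while the equal-efficiency variant collapses, and with
$\sigma_e = 0$ the hierarchical estimator is calibrated and beats the
scaling factor on RMSE.

## Known limitations

- **All-zero taxa at scale.** A taxon with no reads anywhere is informed
  only by the hierarchy; its posterior is extremely wide and the
  centered Gibbs sampler explores it slowly (a funnel between
  $\Sigma_{jj}$ and its $\log\mu$ column). At desk scale this depresses
  average $\mu$-coverage as $q$ grows with short chains; longer chains
  and more samples mitigate it, and the per-parameter R-hat table
  surfaces it.
- **Individual efficiencies are not predictable.** For a taxon without
  concentration data, the model can only place its efficiency within the
  fitted population distribution of efficiencies. A genuinely extreme
  taxon (several $\sigma_e$ from center) will have a biased $\mu$
  estimate whose interval may miss — averages over taxa are controlled,
  individual taxa are not.
- **Poisson concentrations.** qPCR technical replicates are often
  overdispersed; a negative-binomial observation model is a natural
  extension point (swap the `V` likelihood in the model builder), as are
  batch-dependent efficiencies
  ($e_{jk} \sim \mathrm{Lognormal}(\xi_j, \sigma^2_\xi)$ for batch $k$)
  and correlated taxa (non-diagonal $\Sigma$).
- **Missing concentrations.** `V` must be complete on the observed
  panel; rows with missing qPCR values are rejected rather than
  imputed.
- **Taxon matching is exact string equality** between the two tables;
  no fuzzy name resolution is attempted.
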