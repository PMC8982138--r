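# microconc

Joint modeling of relative and absolute microbial abundances.

## The problem

Microbiome studies routinely profile communities with broad-range
sequencing (e.g., 16S rRNA amplicons), which yields read counts
`W[i, j]` for many taxa but only measures *composition* — the sequencing
depth `M[i]` carries no information about how much bacteria was actually
there. Absolute abundance (concentration, e.g., 16S gene copies per
swab) is what matters for many clinical questions, but taxon-specific
assays such as qPCR are expensive to develop, so concentrations
`V[i, j]` are typically observed for only a small panel of
`qobs << q` taxa.

`microconc` jointly models both data types to estimate the latent
concentration `mu[i, j]` of **every** taxon in every sample:

    V[i,j] | mu[i,j]      ~ Poisson(mu[i,j])                 (j <= qobs)
    W[i,·] | M[i], mu, e  ~ Multinomial(M[i], p[i,·]),
                            p[i,j] = mu[i,j] e[j] / Σ_l mu[i,l] e[l]

where `e[j]` is the *efficiency* with which sequencing detects taxon `j`
relative to the concentration assay — real assays detect taxa unequally,
and ignoring that bias corrupts every concentration estimate. A
lognormal hierarchy (`log mu[i,·] ~ N(beta, Sigma)` with diagonal
`Sigma`; `e[j] ~ Lognormal(0, sigma_e^2)`, soft-centered for
identifiability; `sigma_e^2 ~ InvGamma`) completes the model, and MCMC
yields point estimates, credible intervals for `mu` (for all taxa,
including zero-count pairs), and prediction intervals for the unobserved
concentrations. A per-sample scaling-factor baseline
(`mu_hat = s_i W[i,j]` with `s_i = ΣV/ΣW` over the observed panel) with
delta-method intervals is included for comparison, along with a
synthetic-data generator, a replicated simulation-study runner, and
leave-one-taxon-out validation.

## Worked example

```r
library(microconc)

# a synthetic community: 30 samples, efficiencies spread sigma_e = 0.8;
# 15 simulated taxa of which 10 pass the abundance filter, 5 observed
cfg <- simulation_config(q = 15, qobs = 5, n = 30, sigma_e = 0.8, seed = 11)
sim <- simulate_dataset(cfg)
sim$paired
#> paired_abundance: 30 samples, 10 taxa ( 5 with observed concentrations )

fit <- fit_abundance(sim$paired, model_spec("varying_efficiency"),
                     mcmc_config(chains = 2, warmup_iters = 500,
                                 total_iters = 1000, seed = 5))
fit
#> abundance_fit (varying_efficiency): 1000 pooled draws over 2 chains; 30 samples x 10 taxa
#> median R-hat over mu: 1 (IQR 0.999-1.001)

truth <- aligned_truth(sim, "mu")
empirical_coverage(credible_intervals(fit), truth)
#> [1] 0.9666667

ne <- naive_estimate(sim$paired)
rmse(ne$mu_hat, truth)                              # scaling-factor baseline
#> [1] 19654.3
rmse(apply(fit$draws$mu, c(2, 3), mean), truth)     # hierarchical model
#> [1] 169.6

round(colMeans(fit$draws$e[, 1:5]), 2)   # posterior mean efficiencies
#> 0.99 1.51 0.76 3.02 1.34
round(sim$truth$e[sim$truth$observed_taxa], 2)      # truth
#> 0.79 1.20 0.60 2.42 1.10
```

The hierarchical fit covers 96.7% of the true concentrations at the
nominal 95% level and cuts RMSE by two orders of magnitude relative to
per-sample rescaling, because the baseline projects every taxon's
detection bias into its concentration estimate while the model absorbs
it into `e`. Efficiencies are identified only up to scale, so posterior
efficiencies recover the *pattern* (which taxa are over/under-detected)
rather than absolute values.

For real data, read the two tables and align them before fitting:

```r
counts <- read_count_table("W.csv")        # samples x taxa, header + id column
conc   <- read_concentration_table("V.csv")
paired <- align_tables(counts, conc)       # observed taxa moved to the front
fit    <- fit_abundance(paired)
pred   <- predict_unobserved(fit)          # concentrations for taxa without qPCR
```

A thin command-line interface wraps the same functions:
`exec/microconc simulate --q 40 --qobs 7 --seed 1 --out simdir` and
`exec/microconc fit --w-table W.csv --v-table V.csv --out fitdir` write
CSV artifacts (posterior summaries, efficiency summaries, convergence
diagnostics, prediction intervals) plus a JSON manifest of the resolved
configuration.

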