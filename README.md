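# prevsae — small-area estimation of survey prevalence

`prevsae` produces district- and constituency-level prevalence estimates
for binary health and social indicators from multistage household surveys
whose direct samples are far too small for stable area-level estimation.
It is written for survey statisticians and epidemiologists who need the
full chain from microdata to a publishable area-level series: model-based
prevalence with credible intervals, projected headcounts,
direction-adjusted ranks and deciles, and between-round change categories.

## The model

For individual *i* in cluster *j* in area *k* in state *l*:

    logit(pi_ijkl) = beta0 + f_l + v_kl + u_jkl

    f_l ~ N(0, sigma_f^2),  v_kl ~ N(0, sigma_v^2),  u_jkl ~ N(0, sigma_u^2)

a four-level random-intercept logistic model fitted in two stages:
first-order marginal quasi-likelihood (MQL1) for starting values, then
Metropolis-within-Gibbs MCMC (with parameter expansion for the cluster
variance) for fully Bayesian inference. Cluster-level predicted
probabilities — posterior draws of `invlogit(beta0 + f + v + u)` — borrow
strength across clusters sharing a district and state; area prevalence is
the simple average of its clusters' probabilities, summarized by the
posterior mean and the 2.5th/97.5th percentiles. See the methods vignette
(`vignettes/small-area-estimation.Rmd`) for priors, adaptation,
identification moves, and every convention the published methodology
leaves open.

Everything runs on synthetic multistage data from the built-in generator
(`simulate_survey()`, `simulate_geometry()`, `simulate_projections()`), so
the whole pipeline is testable without any microdata access.

## Worked example

```r
library(prevsae)

cfg <- sim_config(n_states = 6L, districts_per_state = 4L,
                  clusters_per_district = 6L, individuals_per_cluster = 30L,
                  seed = 7)
sv    <- simulate_survey(cfg)
md    <- model_data(sv$records)
start <- fit_mql1(md)
#> sae_params: beta0 = -0.3412, sigma2_f = 0.2609, sigma2_v = 0.1148, sigma2_u = 0.1890

draws <- run_mcmc(md, start, mcmc_config(seed = 8))
#> sae_draws: 4500 retained draws, 144 clusters; 1 parameter(s) with ESS < 250
#>    beta0 sigma2_f sigma2_v sigma2_u
#>  -0.4251   0.6804   0.1637   0.2641

pred <- predict_cluster_probs(draws, md)
membership <- unique(sv$records[, c("cluster_id", "district_id")])
names(membership) <- c("cluster_id", "area_id")
est <- aggregate_area(pred, membership, round_label = "2021")
head(as.data.frame(est)[, 1:5], 4)
#>   area_id prevalence lo95 hi95 n_clusters
#> 1  S01D01       70.6 64.2 76.7          6
#> 2  S01D02       62.2 55.2 69.0          6
#> 3  S01D03       66.3 59.6 72.5          6
#> 4  S01D04       77.6 71.8 82.8          6
```

`est` is the model-based area series: district S01D01's prevalence is
70.6% with 95% credible interval (64.2, 76.7), estimated from its 6
sampled clusters after partial pooling. MQL1 starting values (above) are
deliberately rough — attenuated toward zero — and only seed the chain;
the posterior means are the estimates. Headcounts, ranks and the direct
national cross-check:

```r
shares <- weighted_sample_share(sv$records)
den <- compute_denominator(shares$share, 114273000)
compute_headcount(est$prevalence[match(shares$area_id, est$area_id)], den)[1]
#> 3328812        # 70.6% of S01D01's 4,716,245 projected persons

rk <- rank_areas(est, indicator_meta("ind1", direction = "lower_is_better"))
head(as.data.frame(rk)[order(rk$rank), c("area_id", "prevalence", "rank", "decile")], 3)
#>    area_id prevalence rank decile
#> 8   S02D04       22.5    1      1
#> 18  S05D02       25.2    2      1
#> 24  S06D04       26.5    3      2

direct_weighted_prevalence(sv$records)
#> 41.62324       # design-weighted national mean, %
```

Rank 1 is the best area after adjusting for the indicator's normative
direction (here lower prevalence is better). The end-to-end pipeline —
two survey rounds, reassignment, fitting, prediction, indicators, change
classification and the five-sheet workbook — is one call
(`run_pipeline(run_config(...))`) or one CLI invocation:

```sh
Rscript -e 'prevsae::sae_cli()' all --config config.json --seed 1 --out out/
```

with subcommands `simulate`, `assign`, `fit`, `predict`, `aggregate`,
`rank`, `change`, `export`, `all`.

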