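# multimorbnet

Network analysis of multimorbidity from binary chronic-disease indicators.

Survey studies of ageing populations record, per respondent, a few dozen 0/1
chronic-condition indicators plus demographics. `multimorbnet` turns such a
cohort into:

1. a **pairwise conditional-dependence network** over the diseases — an
   Ising-type Markov random field estimated by nodewise L1-penalized
   logistic regression (one lasso-penalized regression of each disease on
   all the others, per-node penalty by cross-validated deviance or refit
   EBIC, AND-rule aggregation of the two directed coefficients per pair);
2. **multimorbidity patterns** — communities of the network found by
   fast-greedy (CNM) modularity maximisation;
3. **bridging diseases** — conditions ranked by six centrality metrics
   (degree, closeness, betweenness, PageRank, eigenvector, HITS hub score),
   betweenness first, because high-betweenness diseases sit on the shortest
   paths that connect otherwise separate patterns;
4. **person-level phenotypes** — assignment of each person to the patterns
   they carry (at least `min_count` diseases of a community) and the derived
   *complex (multisystem)* phenotype (two or more patterns at once), with
   pooled two-proportion z-tests comparing pattern prevalence between men
   and women;
5. **odds ratios** — gender-stratified logistic regression of the complex
   phenotype on the bridging diseases with age/income/education controls,
   reported as OR with 95% Wald intervals and significance stars.

In symbols, the estimated model is
`p(x) ∝ exp(Σ_s h_s x_s + ½ Σ_{s≠t} W_st x_s x_t)` over `x ∈ {0,1}^p`, whose
full conditionals are logistic; the nodewise coefficients estimate `W`
directly. A planted-structure synthetic-cohort generator (Gibbs sampling
from block-and-bridge Ising designs with calibrated marginal prevalences)
stands in for survey data, so the whole pipeline is testable against known
ground truth.

## Worked example

Simulate a 2,000-person cohort from the default 32-disease design (five
disease blocks, two bridge nodes — hypertension D1 and hepatic dysfunction
D19 — and four isolates), estimate the network, and ask for the patterns and
the bridges:

```r
library(multimorbnet)

cohort <- simulate_cohort(default_design(), n = 2000, seed = 7) |>
  filter_multimorbid(min_diseases = 2)

fit <- fit_nodewise(cohort, mgm_config(seed = 7, lambda_selection = "ebic"))
fit
#> <mgm_fit: 32 diseases, n = 1611, rule = AND, 58 edges>

communities <- detect_communities(fit$network)
communities
#> <community_partition: 10 communities, Q = 0.6818>

rank_bridges(compute_centralities(fit$network), top_k = 3)
#>  # A tibble: 3 x 8
#>    rank disease degree closeness betweenness pagerank eigenvector hub_score
#>   <int> <chr>    <int>     <dbl>       <dbl>    <dbl>       <dbl>     <dbl>
#> 1     1 D7           7    0.163           78   0.0534      1         1
#> 2     2 D1           9    0.156           66   0.0417      0.626     0.626
#> 3     3 D21          4    0.0909          52   0.0327      0.0354    0.0354
```

The five planted blocks come back as communities (plus singletons for the
isolated conditions, hence 10 communities), and the modularity of the
partition is 0.68. The top of the betweenness ranking contains the planted
bridge hypertension (D1, rank 2 in this particular replicate — the
multimorbidity filter applied above slightly reshapes the sample, and
cervical pain D7 edges it out here); across the 50-replicate experiment in
the test-suite a true bridge ranks first in at least 90% of runs.

Assign persons to patterns, derive the complex phenotype and quantify the
bridging effect:

```r
assignment <- assign_patterns(cohort, communities, min_count = 2)
mean(assignment$complex_flag)
#> [1] 0.2476723

reg <- fit_logistic(cohort, assignment,
                    model_spec(predictors = c("D1", "D19")))
tidy(reg)
#>  # A tibble: ... (disease rows shown)
#>   stratum term     OR CI_low CI_high stars
#> 1 M       D1     6.22   4.18    9.26 ***
#> 2 M       D19    3.37   1.48    7.66 **
#> 3 F       D1     5.54   3.82    8.05 ***
#> 4 F       D19    5.28   2.52   11.08 ***
```

About a quarter of the filtered cohort holds two or more patterns, and the
two planted bridge diseases carry strong adjusted odds ratios for that
complex phenotype in both genders (demographic controls — age group, income
quartile, education — are included; their rows are omitted above).

`run_pipeline(pipeline_config(seed = 1), "out/")` executes the whole chain —
simulate (or read a cohort CSV), filter, fit pooled and per-gender networks,
detect communities, compute centralities, assign patterns, compare
prevalences, regress — and writes networks (GraphML + TSV edge list),
partition JSON, centrality/assignment/comparison/regression CSVs and a
manifest; identical config and seed give byte-identical outputs.

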