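# pseudopace

Pseudotime trajectories and Epigenetic Pacemaker models for DNA-methylation
aging.

## The problem

DNA methylation at age-associated CpG sites changes rapidly early in life and
progressively slows with age.  Epigenetic clocks hide this nonlinearity by
construction: they are trained to predict chronological age, which forces a
linear relationship between the predictor and time.  `pseudopace` implements
two complementary, form-free ways of ordering methylation profiles along the
aging process, and then asks — *after* the ordering is made — which analytic
function of age best describes it:

1. **Pseudotime trajectory inference.**  Samples (beta-value profiles at
   selected age-associated CpGs) are embedded with PCA, clustered with a
   Gaussian mixture model whose cluster count and covariance family are
   chosen by BIC, a minimum spanning tree is built over the cluster centers,
   a principal curve smooths the resulting single-lineage path, and each
   sample's pseudotime is the arc length from the start of the curve to its
   orthogonal projection.  Held-out samples are projected onto the frozen
   embedding and curve — no chronological age is used anywhere.
2. **The Epigenetic Pacemaker (EPM).**  Each site is modelled as
   `m_ij = m_i0 + r_i * s_j + e_ij`, with site intercepts/rates and
   per-sample epigenetic states `s_j` estimated by alternating exact
   least-squares updates (conditional EM), initialized at chronological age.

The two orderings are then compared (they should be — and are — strongly
linearly correlated), and the pseudotime-vs-age relationship is fitted with
five candidate forms: quadratic `a + bx + cx²`, logarithmic `a + b log x`,
square-root `a + b√x`, exponential `a(1 − e^{−bx})`, and the sum of two
exponentials `a(1 + c − e^{−bx} − c·e^{−dx})`, ranked by Gaussian AIC
(with RMSE and R² reported).  Exponential rates are translated into
doubling times `ln(2)/b` for comparison with the Gompertz mortality law
`μ(x) = α·e^{βx}` (human β ≈ 0.08/yr): a rate of 0.1/yr doubles every
6.93 years, 0.04/yr every 17.33 years.

Because real 450k cohorts are large GEO downloads, the package ships a
first-class synthetic-cohort generator (`sim_config()`, `simulate_cohort()`)
that emulates their statistical structure — a sum-of-two-exponentials latent
aging state driving linear per-site responses on the beta scale, two probe
design types, Gaussian beta noise, and age-stratified train/validation/test
splits — with the generating truth retained for parameter-recovery tests.

## Worked example

```r
library(pseudopace)
cfg <- sim_config(n_samples = 600, n_sites = 800, seed = 42)
report <- run_pipeline(pipeline_config(simulation = cfg, seed = 42))
print(report)
#> <pipeline_report> seed 42 | 744 sites selected | k = 5 (full-free)
#>   trajectory R2 (train/validation): 1.0000 / 1.0000
#>   test pseudotime vs EPM state: r = 0.9997 (p < 1e-300)
#>   trend winner by AIC: double_exponential
#>   doubling time (exponential_b): 18.95 years
#>   doubling time (double_exponential_b): 336290887.30 years
#>   doubling time (double_exponential_d): 17.81 years

pt <- report$pseudotime$test
truth <- report$truth$latent_states[names(pt)]
cat(sprintf("PCC(test pseudotime, generating latent state) = %.4f\n", cor(pt, truth)))
#> PCC(test pseudotime, generating latent state) = 0.9960

report$trend_table[, c("form", "aic", "rmse", "r_squared")]
#>                 form      aic      rmse r_squared
#> 1 double_exponential -988.136 0.0604923  0.999385
#> 2        exponential -939.845 0.0650492  0.999288
#> 3          quadratic  235.103 0.3317021  0.981497
#> 4        square_root  588.742 0.5435819  0.950309
#> 5        logarithmic  839.248 0.7697806  0.900349
```

Reading the output: 744 of 800 simulated sites pass the |PCC| > 0.4
age-correlation filter on the training split; BIC picks a 5-component
full-covariance mixture; the trajectory predicts its own assignment
perfectly on train/validation; test-set pseudotime tracks both the EPM
epigenetic state (r = 0.9997) and the hidden generating state (r = 0.996)
without ever seeing age.  The sum of two exponentials wins the form
comparison, as it should — the generator's latent trend is one.  The slow
fitted rate here collapses toward 0 (hence the absurd doubling time for
`b`; over 0–99 years a near-zero rate is indistinguishable from a linear
term), while the fast rate's doubling time (17.8 years) is the
interpretable one.

A command-line interface wraps the same stages
(`simulate`, `run-all`, `fit-trajectory`, `predict-pseudotime`,
`fit-trends`):

```sh
Rscript inst/cli/pseudopace.R simulate --out cohort/ --n-samples 300 --seed 7
Rscript inst/cli/pseudopace.R run-all --in cohort/ --out run/ --seed 7
```

## Documentation

Every exported function carries roxygen documentation; the methods vignette
(`vignettes/methylation-pseudotime.Rmd`) describes the models, the synthetic
world, numerical choices, and known limitations.
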