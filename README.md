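# btdcm

Bayesian estimation of **extended transition diagnostic classification
models** (TDCMs) for longitudinal cognitive diagnosis data.

## What problem does this solve?

Diagnostic classification models (DCMs) measure which discrete skills
("attributes") a respondent has mastered from binary test items, via a
known item-by-attribute Q-matrix.  In longitudinal designs — typically a
pre/post intervention study — the additional question is how mastery
*changes*.  `btdcm` couples:

* the **LCDM** item model: for item *j* and latent profile class *c*,
  `P(Y = 1) = sigma(delta_jc' lambda_j)` with intercept, main-effect and
  (optional) interaction parameters over the item's required attributes,
  and strict monotonicity enforced by positive main effects; and
* a **trajectory-level transition model**: each attribute's full mastery
  path over the `T` time points is one of `2^T` *transition types* `r`,
  modelled by a per-attribute multinomial logistic regression
  `P(z = r) ∝ exp(x_r' gamma_r)` with the never-mastered type as a
  zero-constrained baseline.  Respondent-level covariates (an intervention
  indicator, demographics, scores) can be attached to exactly the
  trajectory types of interest.

Estimation is a three-step Gibbs sampler made fully conjugate by
**Pólya-gamma data augmentation** (profiles → item parameters → transition
coefficients), with truncated-normal updates for the monotone item main
effects.  The package targets psychometricians and applied education /
biostatistics researchers running pre–post diagnostic assessments; it also
ships a simulator for the standard benchmark designs, a parameter-recovery
harness, and posterior-predictive goodness-of-fit tools (match %, AUC,
Brier score, conditional transition-probability tables).

See `vignettes/extended-tdcm-methods.Rmd` for the model, priors, numerical
choices and limitations.

## Worked example

Simulate the benchmark Setting 1 (I = 800 respondents, J = 21 items,
K = 3 attributes, T = 2 time points, balanced treatment applied to the
0→1 "gain" transition), fit it, and inspect recovery:

```r
library(btdcm)
design <- make_design(1, seed = 1)          # fixes the true lambda / gamma
dat    <- simulate_dataset(design, seed = 2)
td     <- transition_design(design$dims, dat$X, design$covariate_map)
fit    <- run_gibbs(dat$Y, design$Q, td,
                    sampler_config(M = 2000, burn = 500, seed = 3,
                                   quiet = TRUE),
                    include_interactions = FALSE)
print(fit)
summary(fit)[c(1, 2, 43, 44), ]
```

```
tdcm_draws: 1500 stored draws (M=2000, burn=500) | 42 item params, 12 transition params | 35.1 s
                 parameter   mean    sd   q2.5  q97.5
1      lambda[1]:intercept -1.722 0.113 -1.957 -1.502
2         lambda[1]:main:1  1.984 0.138  1.698  2.259
43 gamma[1]:r2:(Intercept)  0.511 0.168  0.175  0.844
44   gamma[1]:r2:treatment  1.452 0.178  1.116  1.809
```

The generating values for those four parameters were −1.73, 2.06, 0.57 and
1.50: the item intercept/main effect and the attribute-1 gain intercept
and treatment slope are all recovered inside their 95% intervals, and the
positive treatment slope (posterior mean ≈ 1.45) is the estimated
intervention effect on the log-odds of mastering attribute 1.

Transition coefficients convert directly into conditional transition
probabilities per covariate scenario:

```r
transition_probability_table(fit, scenarios = data.frame(treatment = 0:1))
```

```
 attribute scenario           cell  mean     sd
         1        1 P(0->0|start0) 0.376 0.0392
         1        1 P(0->1|start0) 0.624 0.0392
         1        2 P(0->1|start0) 0.876 0.0187
         1        2 P(1->0|start1) 0.474 0.0404
 ...
```

Untreated non-masters of attribute 1 gain it with posterior probability
0.62; treated ones with 0.88.  Cells sharing an initial state share one
normaliser per draw, so their posterior sds are identical by construction.
Loss probabilities are unchanged by treatment because the covariate map
applies the treatment to the gain type only.

Goodness of fit:

```r
ppc   <- ppc_simulate(fit, n_rep = 200, seed = 4)
match_percentage(dat$Y, ppc, by = "time")
predictive_auc_brier(dat$Y, posterior_cell_probs(fit))$auc_range
```

```
 time match_pct        time   min_auc   max_auc
    1      65.3           1     0.742     0.906
    2      61.2           2     0.716     0.895
```

Posterior-predictive replicates reproduce ~61–65% of individual response
cells (the theoretical ceiling for a Bernoulli cell with probability p is
p² + (1−p)², not 100%), and per-item AUCs span 0.72–0.91.

## Command line

```sh
Rscript inst/exec/tdcm simulate --config cfg.json --out outdir
Rscript inst/exec/tdcm fit --responses outdir/responses.csv \
    --qmatrix outdir/qmatrix.csv --covariates outdir/covariates.csv \
    --config fit.json --out fitdir
Rscript inst/exec/tdcm recover --config recover.json --out recdir
```

Configs are JSON or YAML; e.g. `{"setting": 1, "seed": 7}` for `simulate`,
`{"M": 2000, "burn": 500, "covariate_map": {"2": ["treatment"]}}` for
`fit`.  Input CSVs: responses with columns `item<j>_t<t>`, a 0/1 Q-matrix
with attribute-name header, numeric covariates; all outputs (draws,
summaries, goodness-of-fit, manifest with the master seed) are plain CSV /
JSON.

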