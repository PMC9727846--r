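# imputeclass

Simulation framework for studying how imputed numerical missing data affect
binary classification, built around breast-cancer recurrence prediction.

Clinical datasets routinely lose predictor values to equipment faults,
attrition, and non-response. Before trusting a classifier trained on imputed
data, an analyst wants to know how much the imputation step costs in
discriminative ability and accuracy — and whether that cost depends on how
much data is missing, on the missingness mechanism, and on the imputation
algorithm. `imputeclass` answers this with a controlled factorial simulation
for statisticians and epidemiologists benchmarking missing-data workflows.

## The simulation

A complete cohort of N = 693 patients is drawn from a 6-variate normal with
fixed mean vector and covariance matrix summarising a breast-cancer cohort
(age, heart rate, respiratory rate, body mass index, body surface area, and
a latent recurrence score μ₆ = 0.31, Σ₆₆ = 0.2). The sixth variable is
dichotomized (draw > 0.5 → recurrence) into the binary outcome, giving
prevalence ≈ 0.335. The pipeline then:

1. **Amputes** predictors under MCAR or MAR at 15/30/45/60% incomplete rows.
   MAR selection is logistic in a standardized weighted-sum score of each
   row's observed variables, so missingness depends only on observed values.
2. **Imputes** with six algorithms, each implemented from its definition:
   - `SMEAN` — series mean;
   - `HD` — hot deck, donor minimising D(i,j) = maxₖ |z_ik − z_jk| on
     standardized predictors;
   - `KNN` — k nearest donors under D_ij = Σ w_k τ_ijk / Σ w_k with
     τ_ijk = |x_ik − x_jk| / r_k (range-normalized), imputing their mean;
   - `MICE` — chained equations with Bayesian normal linear regression,
     m = 5 completions;
   - `PMM` — predictive mean matching: nearest-predictive-mean donors,
     drawn from a pool of 5, m = 5;
   - `EMB` — bootstrap EM: multivariate-normal parameters estimated by EM
     on M = 5 bootstrap resamples, missing cells drawn from the conditional
     normal under each.
3. **Classifies** recurrence with binary logistic regression
   (logit ρᵢ = β₀ + Σⱼ βⱼXⱼᵢ, IRLS, strict 0.5 cut-off), LDA
   (δₖ(x) = xᵀΣ⁻¹μₖ − ½μₖᵀΣ⁻¹μₖ + log πₖ), and QDA
   (δₖ(x) = −½(x−μₖ)ᵀΣₖ⁻¹(x−μₖ) − ½log|Σₖ| + log πₖ), on a stratified
   70/30 train/test split; multiple imputations are pooled by averaging
   predicted probabilities.
4. **Evaluates** imputation RMSE (pooled over all predictor cells and per
   missing cell), correct-classification accuracy (%), and rank-based AUC,
   averaged over replicates across the 4 × 2 × 6 = 48-condition grid.

## Worked example

```r
library(imputeclass)

d <- generate_complete(simulation_spec(), seed = 1)
d
#> Complete dataset: 693 x 6, outcome prevalence 0.387

inc <- ampute(d, ampute_spec("MAR", 0.30), seed = 2)
inc
#> Incomplete dataset: 693 x 6, MAR, 28.9% incomplete rows (5.8% cells)
mechanism_diagnostics(inc)
#> Missingness: 28.9% of rows, 5.8% of cells
#> Score association test: p = 2.004e-15 (reject MCAR at alpha = 0.05)

res <- impute_missing(inc, imputer_config("pmm"), seed = 3)
res
#> PMM imputation: 5 completed datasets, 200 cells imputed

run_condition(d, pct = 0.30, mechanism = "MAR",
              imputer_cfg = imputer_config("pmm"), seed = 4)
#>   missing_pct mechanism imputer classifier rmse_pooled rmse_per_missing
#> 1         0.3       MAR     PMM        BLR        4.12             16.8
#> 2         0.3       MAR     PMM        LDA        4.12             16.8
#> 3         0.3       MAR     PMM        QDA        4.12             16.8
#>   accuracy   auc n_missing_cells
#> 1     67.3 0.667             207
#> 2     67.3 0.667             207
#> 3     66.8 0.638             207
```

The realized incomplete-row rate (28.9%) sits within binomial error of the
30% target; the MAR diagnostic rejects value-independence, as it should.
PMM's per-missing-cell RMSE (16.8) reflects the pooled raw scales of the
five predictors, and the pooled RMSE (4.12) scales it by the fraction of
cells amputed. Accuracy near 67% and AUC near 0.6 on a single 208-row test
set carry Monte-Carlo noise of roughly ±3 percentage points and ±0.045
respectively — which is why the package averages over replicates.

The full study is one call (about two minutes at 50 replicates):

```r
grid <- run_grid(grid_config(replicates = 50))
summary(grid)
plot(grid)
write_grid_csv(grid, "results")
```

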