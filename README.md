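# rpsurv — rank-product consensus outlier detection for censored survival data

In survival studies with gene-expression covariates ($p \gg n$), which
patients look like outliers depends on which Cox model you fit: every
variable-selection route (lasso, elastic net, stepwise AIC, curated gene
lists) yields a different sub-model, and each sub-model nominates different
residual extremes. `rpsurv` resolves this by consensus. Each sub-model ranks
every observation by its martingale residual

$$\hat r_i = \delta_i - \hat H_0(t_i)\,e^{\hat\beta^\top x_i} \in (-\infty, 1],$$

(rank 1 = most negative = strongest long-term survivor), the per-model ranks
are combined with the rank product $RP_i = \prod_{j=1}^k R_{ij}$, and $RP_i$
is referred to its null distribution under random uniform rankings. Small
Benjamini–Hochberg q-values mark observations that are discrepant no matter
which sub-model one trusts. Four null p-value routes are provided: exact
tail counting, rigorous recursive upper/lower bounds with a geometric-mean
approximation, a log-domain Gamma(k, 1) approximation, and permutation.

The package is aimed at biostatisticians screening high-dimensional censored
cohorts for influential observations — long-term survivors or early deaths
whose follow-up contradicts their covariate-predicted risk.

## Worked example

Simulate a study-shaped cohort with two planted tenfold-discrepant long-term
survivors, fit three disjoint 50-gene sub-models, and run the consensus:

```r
library(rpsurv)

coh <- generate_cohort(synthetic_spec(
  n = 260, p = 800, seed = 101,
  outliers = list(list(type = "long_survivor", count = 2,
                       discrepancy_factor = 10))))
gn    <- coh$data$gene_names
inf   <- gn[coh$truth$beta_true != 0]           # the risk signature
noise <- setdiff(gn, inf)
sets <- list(A = c(inf[1:5],   noise[1:45]),
             B = c(inf[6:10],  noise[46:90]),
             C = c(inf[11:16], noise[91:134]))

fit <- rp_outliers(coh$data, gene_sets = sets)
fit
#> Rank product consensus over 3 sub-models, 260 observations (method: exact)
#> Outliers at q <= 0.05: S157, S004, S183, S185
#>
#> Top of the consensus table:
#>  sample_id     time status rank_A rank_B rank_C       rp log_rp  p_value
#>       S157 7851.257      0      6     10      2      120  4.787 1.08E-04
#>       S004 4858.646      0      5      7      5      175  5.165 1.75E-04
#>       S183 7960.682      0      7     25      1      175  5.165 1.75E-04
#>       S185 3854.518      0     39      1     14      546  6.303 7.26E-04
#>       S232 1361.192      0      2    108      8     1728  7.455 2.62E-03
#>  q_value outlier
#>   0.0152    TRUE
#>   0.0152    TRUE
#>   0.0152    TRUE
#>   0.0472    TRUE
#>   0.1223   FALSE

coh$truth$outlier_ids
#> [1] "S183" "S157"
```

Reading the output: every row is one patient; `rank_A..C` are its residual
ranks in the three sub-models, `rp` their product, and `p_value`/`q_value`
refer the product to the uniform-rankings null with FDR control over the 260
tests. Both planted samples (S183, S157) are flagged; S004 and S185 are
*natural* long-term survivors of the simulation — censored after 3800–4900
days with above-average predicted risk — which is exactly the kind of
observation the consensus is designed to surface.

Other entry points: `fit_cox_ph()` / `martingale_residuals()` (Eq. above),
`select_penalized()` / `stepwise_aic()` / `union_gene_sets()` (sub-model
construction), `rp_pvalues()` (standalone rank-product test on any rank
matrix), `run_resampling()` (the 100-model random-gene-subset consensus),
`run_full_analysis()` (file-to-file pipeline from a YAML config), and a thin
command-line wrapper in `inst/scripts/rp-pipeline.R` with `simulate`, `run`,
`rp-test` and `resample` subcommands. The methods vignette
(`vignettes/rank-product-consensus.Rmd`) documents the statistics, the
generator and the design decisions.

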