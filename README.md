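# resilgrey

Grey clustering and attribute-hierarchy weighting for emergency-resilience
evaluation scales.

Community health institutions need to know how well their grassroots medical
workers would hold up in a public health emergency — not just what they know,
but whether they can resist, absorb and recover from the shock. The
instruments built for that question are weighted three-level indicator
scales: a handful of first-level domains (professional quality,
psychological capital, emergency attitude), second-level contents beneath
them, and third-level Likert items that respondents actually answer.
`resilgrey` implements the complete statistical chain such scales rest on,
for the methodologists who build them and the analysts who apply them:

* **Delphi statistics** — Kendall's coefficient of concordance with tie
  correction (`kendalls_w`) and mean/CV indicator screening
  (`screen_indicators`) for expert consultation rounds.
* **AHM weighting** — indicator weights from Saaty 1–9 pairwise comparison
  matrices via the Attribute Hierarchy Model (`ahm_weights`, `weight_tree`),
  which converts each judgment `b_ij = k` into paired attribute measures
  `u_ij = βk/(βk+1)`, `u_ji = 1/(βk+1)` and takes scaled row sums
  `w_i = 2/(n(n−1)) Σ_j u_ij` — no eigenvector, no consistency requirement.
  Classical AHP eigenvector weights and the consistency ratio are computed
  as diagnostics (`ahp_eigen_weights`), and experts pool by element-wise
  geometric mean (`aggregate_experts`).
* **Grey evaluation** — the scoring model (`grey_eval`): whitening weight
  functions over four grey classes (excellent/good/medium/poor; three
  upper-limit and one lower-limit function) turn ratings into class
  memberships `n_e = Σ_i f_e(x_i)`, normalized into clustering coefficient
  vectors `r_e = n_e/N`, aggregated up the weighted tree and scored against
  grade values (1.0, 0.8, 0.6, 0.4). Grey relational grades against the
  ideal respondent, `γ_i(k) = (Δmin + ρΔmax)/(Δ_i(k) + ρΔmax)`, come from
  `grey_relational_score`.
* **Survey handling** — response loading/validation, validity filtering with
  reason codes (`filter_valid`), recovery rates (`recovery_rate`).
* **Group comparisons** — rank-based tests of scores across covariate groups
  with Bonferroni-adjusted pairwise post-hocs (`compare_by_factor`).
* **Synthetic data with ground truth** — latent-trait Likert cohorts with
  planted group effects and planted invalid records (`simulate_cohort`),
  noisy Saaty panels from true weights (`simulate_panel`), Delphi rounds
  with controlled concordance (`simulate_delphi`).

The published 3/13/46-indicator resilience scale for grassroots medical
workers ships as a packaged fixture (`resilience_scale()`), and
`run_pipeline()` chains every stage from one YAML config with a
reproducibility manifest.

## Worked example

Score a simulated cohort against the packaged scale, with a planted
exercise-habit effect of 0.5 latent SD, and test for it:

```r
library(resilgrey)

tree <- resilience_scale()
print(tree)
#> Indicator tree: 3 first-level, 13 second-level, 46 third-level
#>   x1 (0.346) Professional quality
#>     x11 (0.465) Communication skills [3 items]
#>     ...

cohort <- simulate_cohort(cohort_spec(
  n_respondents = 417, n_invalid = 70, seed = 2024,
  group_effects = list(exercise_habit = c(stable = 0.5))), tree)
filt <- filter_valid(cohort, validity_rule())
filt$excluded_count                 #> 70
recovery_rate(417, nrow(filt$valid))#> 83.2

fit <- grey_eval(filt$valid, tree)
print(fit)
#> Grey clustering evaluation: 347 respondents, 46 leaf indicators
#> Overall composite score: 0.653  [median 0.617 (QR 0.120)]
#>   x1   0.652  median 0.617 (QR 0.122)  Professional quality
#>   x2   0.652  median 0.617 (QR 0.113)  Psychological capital
#>   x3   0.662  median 0.629 (QR 0.129)  Emergency attitude

compare_by_factor(fit$respondent_scores[, "overall"], filt$valid,
                  "exercise_habit")
#> Group comparison by 'exercise_habit' (Kruskal-Wallis): statistic = 26.926, p = 1.423e-06
#>       group   n    median       iqr
#>        none  92 0.5986074 0.1205436
#>  occasional 122 0.6000259 0.1069764
#>      stable 133 0.6446213 0.1054277
#> Pairwise rank-sum tests (bonferroni-adjusted):
#>      group1     group2            p  p_adjusted
#>        none occasional 9.706490e-01 1.00000e+00
#>        none     stable 4.194834e-05 1.25845e-04
#>  occasional     stable 3.039287e-06 9.11786e-06
```

Reading the output: the composite score is the grade-value-weighted class
membership of each node, so 0.653 sits in the "medium" band of the 0.4–0.8
attainable range of the default scheme; the planted exercise-habit effect
surfaces as the `stable` group's higher median (0.645 vs 0.599/0.600) and a
Kruskal–Wallis p of 1.4e-06 whose pairwise contrasts isolate the `stable`
group. The filtering step recovers exactly the 70 planted invalid records,
giving the 83.2% recovery rate.

Weights themselves can be re-derived from (simulated or real) expert
matrices:

```r
panel <- simulate_panel(panel_spec(tree_sibling_groups(tree),
                                   n_experts = 25, judgment_noise_sd = 0.1,
                                   seed = 1))
tree2 <- weight_tree(tree, panel, beta = 2)
mean(abs(tree2$weight - tree$weight))  #> ~0.03 (Saaty quantization floor)
```

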