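# segfam

Complex segregation analysis of binary traits in extended pedigrees, in the
regressive multivariate logistic framework.

Segregation analysis asks what mode of inheritance best explains how a
disease runs through families: no genetic effect at all, shared familial
environment, a Mendelian major gene (dominant, recessive, codominant,
additive), or transmission that deviates from Mendel's rules. `segfam`
implements the full machinery for a binary trait: each individual carries a
latent three-state *type* `u ∈ {AA, AB, BB}` with Hardy–Weinberg founder
frequencies driven by the component-A frequency `q_A`; a parent of type `u`
transmits component A with probability `τ_u` (Mendelian transmission is
`τ = (1, 0.5, 0)`); and the probability that individual *i* is affected is
the cumulative logistic

    γ_i = exp(θ_i) / (1 + exp(θ_i)),
    θ_i = β_u + δ_FO·z_father + δ_MO·z_mother + δ_SS·Σ z_preceding_sibs
              + δ_FM·z_spouse + ξ'x_i,

where `z = 1` for an affected relative, `0` for an unaffected one, and the
term is dropped when the relative is absent or of unknown status. Family
likelihoods are computed exactly by Elston–Stewart peeling over the latent
types (C++ backend), with classical single-proband ascertainment correction.
Fourteen named hypotheses — four sporadic/familial-association models, the
general and homogeneous-general transmission models, environmental,
tau-AB-free, and six Mendelian variants — are fitted by constrained
multistart maximum likelihood and compared by likelihood-ratio tests against
the general model and by AIC (`-2lnL + 2k`, smaller is better).

The package was built around a nine-family ankylosing-spondylitis
segregation study (315 members, 74 affected) whose raw pedigrees were never
deposited; its printed comparison tables ship with the package
(`published_model_stats()`, `study_sample_counts()`) and a
genotype-dropping simulator of singly ascertained multiplex families
(`simulate_study()`) provides ground truth for every stage.

## Worked example

Replaying the published nine-family comparison from its printed `-2lnL` and
parameter counts recomputes every likelihood-ratio p-value and AIC:

```r
library(segfam)
library(dplyr)

stats <- filter(published_model_stats(), stage == "transmission")
replay_comparison(stats, "general")
#> Segregation model comparison (best by AIC: homogeneous_general )
#> # A tibble: 10 × 6
#>    model_id             neg2lnL n_estimated p_vs_general   AIC converged
#>  1 sporadic_equal_assoc    285.           2     1.57e-17  289. TRUE
#>  2 general                 194.           8    NA         210. TRUE
#>  3 homogeneous_general     194.           7     5.97e- 1  208. TRUE
#>  4 environmental           204.           5     1.21e- 2  214. TRUE
#>  5 tau_ab_free             196.           6     2.36e- 1  208. TRUE
#>  6 codominant              254.           5     4.92e-13  264. TRUE
#>  7 dominant                254.           4     2.41e-12  262. TRUE
#>  ...
```

Read: the sporadic model is overwhelmingly rejected against the general
model (p ≈ 2e-17 — a major gene is segregating), the environmental
no-transmission model is rejected (p = 0.012), every Mendelian variant is
rejected (p < 1e-11), and only the homogeneous-general (p = 0.60) and
tau-AB-free (p = 0.24) transmission models survive — evidence for
transmission of a major effect that does not follow Mendelian ratios.

Simulating a study-like sample and fitting one model:

```r
ped <- simulate_study(sim_config(n_families = 9, seed = 1))
summarize_sample(ped)[, c("n_families", "n_members", "n_affected", "mean_size")]
#>   n_families n_members n_affected mean_size
#> 1          9       322         61      35.8

fit <- fit_model(ped, "dominant", n_starts = 5, seed = 1)
fit
#> <seg_fit> dominant
#>   -2lnL = 270.9032, 4 estimated parameter(s), converged: TRUE
#>   estimates:
#>     beta_AAB       -1.225
#>     beta_BB        -17.05
#>     q_A            0.3557
#>     delta          0.4312
```

`tidy(fit)` and `glance(fit)` return broom-style tibbles;
`autoplot(compare_models(fits))` draws the AIC comparison;
`run_fit()` performs the full two-stage analysis (familial-association
structure first, transmission models second) on a pedigree tibble or a
LINKAGE/PLINK PED file, and `run_simulate()` writes a simulated dataset
with its truth tables. A thin command-line wrapper lives at
`inst/scripts/segfam.R`.

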