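---
title: "Complex segregation analysis of a binary trait with segfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex segregation analysis of a binary trait with segfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfam)
```

## The model

`segfam` implements complex segregation analysis for a binary trait observed
on extended pedigrees, in the regressive multivariate logistic formulation.
Each individual carries an unobserved three-state *type*
$u \in \{AA, AB, BB\}$, a generalization of a biallelic genotype. Three
parameter groups define the probability model:

* **Type frequencies.** Founders draw their type from Hardy–Weinberg
  proportions $(q_A^2,\; 2q_A(1-q_A),\; (1-q_A)^2)$, where $q_A$ is the
  population frequency of component $A$.
* **Transmission.** A parent of type $u$ transmits component $A$ to each
  offspring independently with probability $\tau_u$. Mendelian transmission
  is $(\tau_{AA}, \tau_{AB}, \tau_{BB}) = (1, 1/2, 0)$; letting the
  $\tau$'s move away from these values is what turns a genotype into a
  "type" and makes non-Mendelian hypotheses testable.
* **Susceptibility.** Given its type and the already-realized phenotypes of
  designated relatives, individual $i$ is affected ($t_i = 1$) with
  probability $\gamma_i = e^{\theta_i}/(1 + e^{\theta_i})$, where

  $$\theta_i = \beta_{u_i}
     + \delta_{FO} z_i^{father} + \delta_{MO} z_i^{mother}
     + \delta_{SS} \textstyle\sum_{j \prec i} z_j^{sib}
     + \delta_{FM} z_i^{spouse}
     + \xi^\top x_i .$$

  The $\beta_u$ are baseline susceptibility logits per type; the $\delta$'s
  are familial-association coefficients (father–offspring,
  mother–offspring, sib–sib over *preceding* sibs in birth order, and
  spousal); $z = 1$ for an affected relative, $0$ for an unaffected one,
  and the term is omitted entirely when the relative is absent or of
  unknown status (raw-indicator regressive coding). Covariate effects
  $\xi$ are supported but none are used in the default analyses.

The directed regressive ordering — parents and earlier sibs before each
individual — makes the joint phenotype distribution well defined: it is the
product of the per-individual conditional logistic terms.

The likelihood of a family sums this joint density over all latent type
assignments. Because the $\delta$-terms involve only *observed* phenotypes,
the penetrance of each (individual, type) pair is a fixed number once the
data are in hand, and the sum over types factorizes along the pedigree.
`pedigree_loglik()` evaluates it exactly by variable elimination
(Elston–Stewart peeling, implemented in C++): founder priors, one
transmission factor per non-founder, and per-individual penetrances are
multiplied and summed out member by member, childless members first and
married-in founders just before their partners, so intermediate tables
never exceed four members ($3^4$ states) in an outbred pedigree. Each
elimination step rescales by its maximum, so penetrances as small as
$e^{-700}$ (the boundary fits print baseline logits like $-154.7$) are
handled without underflow. Pedigrees whose loops would force larger tables
are rejected with an error; the target families are outbred.
`brute_force_loglik()` re-derives the same quantity by explicit $3^n$
enumeration (up to 12 members) with its own arithmetic and serves as the
independent oracle in the test suite; the two agree to below $10^{-10}$ on
hundreds of random instances.

## Ascertainment

Families enter such studies through a single affected proband.
`pedigree_loglik(..., ascertainment = "proband")` applies the classical
single-ascertainment correction: it subtracts the log marginal probability
that the proband is affected, computed from the same pedigree with every
other phenotype set to unknown. Under the package's missing-data
convention that denominator is $\sum_u P(u_{pb})\,\gamma(\beta_u)$ — the
regressive terms vanish because all the proband's relatives are unknown in
the conditioning event.

Two consequences deserve emphasis:

* The simulator's ascertainment stream is designed so this correction is
  *exact*: a candidate member is drawn uniformly and the family is kept only
  if the candidate is affected, which makes a family's acceptance
  probability proportional to its fraction of affected members and leaves
  the proband uniform among the affected given acceptance. Conditioning on
  the proband's phenotype is then the correct conditional likelihood.
* The correction equals the true marginal only when the fitted association
  terms match the generative ones. If the data were generated with
  $\delta = 0$ and a model with free $\delta$ is fitted under proband
  conditioning, the resulting pseudo-likelihood is improperly normalized
  for $\delta \neq 0$ and measurably inflates $\hat\delta$ and $\hat q_A$.
  This is a property of the standard correction itself, not of the
  optimizer; the package's recovery and calibration experiments therefore
  fit the association structure that matches their generating truth, and
  analyses of real data should read $\hat\delta$ under proband conditioning
  with this caveat in mind.

## The fourteen models

`build_model_spec()` encodes the named hypotheses as constraint sets over
the full parameter vector; `fit_model()` maximizes the adjusted
log-likelihood over the free parameters. With the equal-association
structure the free-parameter counts are: sporadic models 1–4 (no
transmission, one baseline $\beta$, association structures none / equal /
parents-vs-sibs / free); general (8: three $\beta$'s, $q_A$, three
$\tau$'s, $\delta$); homogeneous general (7: $\tau_{AB}$ is determined by
requiring the transmitted-component frequency to be stationary across
generations, $q_A^2\tau_{AA} + 2q_A(1-q_A)\tau_{AB} + (1-q_A)^2\tau_{BB} =
q_A$; parameter points whose solved $\tau_{AB}$ leaves $[0,1]$ are
penalized rather than silently clipped); environmental (5:
$\tau_{AA}=\tau_{AB}=\tau_{BB}=q_A$, no transmission of type);
tau-AB-free (6: $\tau_{AA}=1$, $\tau_{BB}=0$, $\tau_{AB}$ free — the
non-Mendelian alternative); Mendelian codominant (5), dominant and
recessive (4 each, equating two $\beta$'s), additive (4,
$\beta_{AB}=(\beta_{AA}+\beta_{BB})/2$), decreasing and increasing (5
each, monotone $\beta$ orderings via log-gap reparameterization). The
spousal association $\delta_{FM}$ is fixed at zero throughout — with
singly ascertained data there is typically too little marital information
to estimate it — though the parameter exists in `seg_params()` so the
machinery supports it.

Model comparison uses the likelihood-ratio test against the general model
(chi-square with d.f. = difference in estimated-parameter counts, the
statistic floored at zero) and AIC $= -2\ln L + 2k$. `compare_models()`
selects the AIC-minimal model, breaking ties by parsimony and then by
supplied order. A numerical tie tolerance (0.05 by default) matters here
for a structural reason: the dominant and recessive constraint sets are
exact images of each other under relabeling of the types ($AA
\leftrightarrow BB$ leaves both the Hardy–Weinberg prior family and
Mendelian transmission invariant), so their maximized likelihoods coincide
and any AIC difference between them is optimizer noise. The published
comparison table for the motivating study shows exactly this signature —
its recessive column is the relabeled dominant solution ($q_A = 0.93$,
$\beta_{AA}$ at the negative boundary).

## Optimization choices

Free probabilities are optimized on the logit scale, susceptibility logits
on their natural scale with box bounds $[-500, 50]$ (wide enough to
represent effectively-zero penetrance without overflowing the log-domain
evaluation), association coefficients in $[-50, 50]$, and monotone gaps as
log-drops. `fit_model()` runs L-BFGS-B from a data-informed start (the
baseline logit at the sample prevalence) plus Latin-hypercube starts under
a deterministic seed — 20 starts by default; the heavy Monte-Carlo
experiments below use 1–3 with a warm start where a nested solution is
available. Refitting with the same seed is bit-for-bit reproducible.
`n_estimated` is always the free-parameter count of the model
specification; boundary contact is reported per parameter
(`boundary_flags`) rather than absorbed into the degrees of freedom, since
published tables that adjust d.f. post hoc end up with AIC cells
inconsistent with their own $-2\ln L$ rows.

## The synthetic-data generator

No raw pedigrees are deposited with the motivating study, so
`simulate_study()` provides ground truth for every stage. It emulates the
study's design: families grown from a founder couple by a two-parameter
branching process (each individual in a non-final generation mates with
probability 0.65 with an unrelated founder spouse; each mating yields a
Poisson(2.8) sibship; 3–5 generations), latent types dropped founders-first
from Hardy–Weinberg and the $\tau$ rule, phenotypes generated sequentially
by the regressive model, and single ascertainment by the
candidate-proband stream described above with the study's inclusion rule
(at least 5 affected, at least 15 members) plus a practicality cap of 55
members. Under the dominant-column truth these defaults were calibrated to
put accepted families on the study's reported size scale (mean 35.0); the
size spread comes out somewhat wider than the study's reported SD of 8.7 —
a branching process cannot match both moments exactly, and only these
moments are targeted. What the generator does *not* emulate:
overlapping generations, assortative mating, sex-linked effects,
age-dependent onset, or the "unknown phenotype" members real studies carry
— so passing recovery tests demonstrate correctness of the machinery under
the model's own assumptions, not robustness to their violation.

## Problem sizes used by the tests and acceptance script

These sizes are the package's own choices, balancing Monte-Carlo precision
against desk-scale runtimes:

* peeling vs enumeration: 200 random pedigrees of up to 12 members
  (tolerance $10^{-10}$);
* sporadic recovery: 2,000 singletons, checked against the analytic
  logit-of-prevalence MLE;
* dominant recovery: 200 ascertained families at the published dominant
  point estimates ($q_A = 0.17$, carrier susceptibility 0.31, phenocopies
  absent, $\delta = 0$ — the published column prints no association
  estimate, so the pure major-gene case is simulated), fitted with the
  matching no-association dominant model; $\hat q_A$ within $\pm 0.05$;
* model-selection consistency: 50 replicates of 60 families; dominant must
  be AIC-best among dominant/recessive/environmental/sporadic in at least
  80% (with the relabeling tie rule above);
* null calibration: 400 replicates of 14 three-generation families
  simulated under an interior homogeneous-general truth; the
  homogeneous-vs-general LRT must reject at the 5% level in 5% ± 3% of
  replicates. The general model is warm-started from the homogeneous
  solution, which guarantees the likelihood ordering and keeps the test
  statistic clean of optimizer noise.

## Known limitations

* Inbred pedigrees (loops) are rejected rather than peeled.
* The single-ascertainment correction ignores the study's secondary
  inclusion rules (minimum affected count, size window); selecting on a
  minimum number of affected members biases $\hat q_A$ upward under
  proband-only conditioning, which is one reason published point estimates
  from such designs should be read cautiously.
* Free association parameters under proband conditioning inherit the
  normalization bias described above.
* No standard errors are reported for estimates (the motivating study
  reports none); inference is by LRT and AIC only.
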