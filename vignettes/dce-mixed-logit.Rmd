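---
title: "Designing and analysing a discrete choice experiment with dcemixl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing a discrete choice experiment with dcemixl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcemixl)
```

## The problem

Multidrug-resistant tuberculosis (MDR-TB) patients take directly observed
therapy (DOT) for many months; programmes increasingly deliver it in the
community rather than at a facility. A community-based DOT (CB-DOT) model can
be configured along several dimensions, and a discrete choice experiment
(DCE) is the standard stated-preference instrument for asking patients which
configuration they would actually choose. `dcemixl` implements the complete
quantitative workflow of such a DCE around a worked example with three
attributes:

* **DOT provider** — family member (reference), community health worker
  (CHW), expert client (a recovered MDR-TB patient);
* **location** of treatment delivery — workplace (reference), home;
* **additional support** — SMS reminder (reference), phone-call reminder,
  travel voucher.

Respondents answer eight choice tasks, each pairing two hypothetical care
models with an opt-out ("neither"). Attributes are dummy coded: each
non-reference level gets a 0/1 indicator (`c_chw`, `c_expert`, `l_home`,
`s_phcall`, `s_tvouch`), and the reference coefficients are constrained to
zero. The opt-out is normalised to zero utility; an alternative-specific
constant (`asc`) on the designed alternatives captures the propensity to
choose any care model over none.

## The model

Respondent $i$'s utility for alternative $j$ in task $t$ is

$$U_{ijt} = x_{ijt}'\beta_i + \varepsilon_{ijt}, \qquad
  \varepsilon_{ijt} \sim \text{iid Gumbel},$$

so conditional on $\beta_i$ the choice probabilities are multinomial logit.
The mixed (random-parameters) logit lets the attribute coefficients vary
across respondents,

$$\beta_{ik} \sim N(\mu_k, \sigma_k^2) \text{ independently}, \qquad
  \text{ASC fixed},$$

which captures both the average direction of preference ($\mu$) and its
heterogeneity ($\sigma$). The panel likelihood of respondent $i$ integrates
the product of their task probabilities over the mixing distribution; the
integral has no closed form and is simulated with $R$ draws:

$$\widehat{\ell}_i = \log \frac{1}{R} \sum_{r=1}^{R}
  \prod_t P_{it}\bigl(\text{chosen} \mid \mu + \sigma \odot z_{ir}\bigr).$$

`mixlogit()` maximises $\sum_i \widehat{\ell}_i$ by BFGS. Independent normal
mixing (diagonal covariance) is assumed throughout, matching the
per-coefficient SDs the model is meant to report; correlated coefficients,
non-normal mixing and WTP-space estimation are out of scope.

### Numerical choices

* **Draws.** Quasi-random Halton sequences, one prime base per random
  coefficient (2, 3, 5, 7, 11 for the five indicators), 1000 draws per
  respondent by default, the first 10 elements discarded, and respondent $i$
  taking the $i$-th contiguous block of the common sequence. The draws are
  deterministic — estimation consumes no RNG — so refitting the same data
  reproduces the same estimates exactly. These conventions (burn-in,
  blocking, unscrambled bases) follow common econometric practice; where a
  published analysis states only its draw count, its exact estimates cannot
  be targeted and parameter recovery on simulated data is the appropriate
  correctness standard.
* **Gradient.** The analytic simulated score is used: with panel weights
  $w_{ir} = \operatorname{softmax}_r(\sum_t \log P_{it})$, the score of
  $\mu$ is $\sum_{i,r} w_{ir} \sum_t (x_{\text{chosen}} - \bar{x}_{it,r})$
  and the score of $\sigma_k$ multiplies the same sums by $z_{irk}$. This is
  exact for the simulated objective and roughly an order of magnitude faster
  than finite differences, which matters for the recovery and subgroup
  simulations below. The Hessian used for standard errors is a central
  finite difference of this analytic gradient.
* **Starting values and convergence.** The conditional logit (the
  $\sigma = 0$ special case, fitted first with the same engine) provides
  starting means; every SD starts at 0.1. Convergence requires the BFGS
  iteration to terminate (relative tolerance `1e-10`, at most 500
  iterations) with a gradient below `1e-5 * (1 + |logLik|)`. The likelihood
  is invariant to the sign of any $\sigma_k$, so SDs are reported as
  absolute values; per-task probabilities use log-sum-exp stabilisation.
* **Inference.** Standard errors are from the inverse numeric Hessian (not
  sandwich); 95% intervals are estimate ± 1.96 SE; p-values use the normal
  approximation, with SD rows testing $\sigma_k = 0$. A singular Hessian
  flags the fit and suppresses SEs rather than failing.
* **Degenerate inputs.** Indicator columns with no variation inside any
  task carry no choice information and are dropped with a warning;
  apparent separation (a coefficient diverging past ±15) clears the
  convergence flag with a diagnostic instead of crashing.

## Design construction and evaluation

`design_metrics()` evaluates a candidate design by the multinomial-logit
information matrix at a prior coefficient vector (zero by default, the
utility-neutral point at which all alternatives in a task are equally
likely):

$$I(\beta) = \sum_t X_t'\,(\operatorname{diag}(p_t) - p_t p_t')\,X_t,$$

with the D-criterion $\det(I/t)^{1/K}$ taken over the $K = 5$ dummy-coded
parameters (the ASC is excluded from $K$). Published D-efficiency figures
depend on unstated conventions — coding, priors, treatment of the opt-out
and constant — so rather than chase any particular vendor's number the
package fixes a fully stated, testable definition: efficiency is the
D-criterion divided by that of the utility-neutral orthogonal ideal, whose
per-task information is $\max_m (m/J)(1 - m/J)$ per parameter ($2/9$ for two
designed alternatives plus opt-out). By Hadamard's inequality this bound
cannot be exceeded, so the score lies in $(0, 1]$; passing `reference =`
another design normalises against that design instead (a design referenced
against itself scores exactly 1). `search_design()` runs a seeded
coordinate-exchange search — propose one level change, keep it if the
criterion rises — which is deterministic given its seed and never returns a
design worse than its start. Profiles may repeat across tasks; identical
alternatives within a task are rejected.

The worked example's eight published choice sets ship as a plain-text
fixture (`study_design()`), and `orme_sample_size()` implements the
rule-of-thumb respondent count $N > 500c/(ta)$ with ceiling rounding both
before and after the non-response inflation — both-stage ceilings never
undershoot the bound and reproduce the worked example's 104.

## What the synthetic cohort emulates — and what it does not

No individual-level choice data are distributed with the package, so the
synthetic-data module is a first-class component: it generates cohorts from
the *published summaries* (the design, the estimated preference weights, and
the covariate marginals — 43/103 female, 42/103 aged 20–34, 40/103 HIV
positive, 31/102 under six months on treatment with one missing value) and
every downstream stage is exercised against them.

By default `draw_respondents()` fixes category counts at their rounded
expectations and permutes them across respondents (`exact = TRUE`), so a
103-respondent cohort reproduces the published stratum sizes — 2472
long-format rows, HIV strata of 1512 and 960 rows, treatment-duration strata
of 744 and 1704 rows with one respondent excluded for a missing value.
`exact = FALSE` gives fully independent Bernoulli draws instead. Choices are
sampled from the multinomial-logit probabilities implied by each
respondent's realised coefficients, with the uniform stream keyed by task id
so a task's simulated choice depends only on its own alternatives.

The generator deliberately simplifies real stated-preference behaviour:
covariates are independent of each other and (unless a preference-shift hook
is supplied) of preferences; there is no attribute non-attendance, no
lexicographic or inattentive responding, no item non-response, and the
mixing distribution matches the estimator's assumption exactly. Passing
recovery tests therefore certifies the estimation machinery — not the
behavioural adequacy of the mixed logit for any real cohort.

## Post-estimation

* `relative_importance()` — the range method: each attribute's range is the
  spread of its level coefficients (reference included at 0) and importance
  is the range as a share of the summed ranges. On the worked example's
  two-decimal coefficient means this gives 36.2% (support), 33.5%
  (location) and 30.3% (provider). Two-decimal inputs are the shipped
  fixture deliberately: importance shares are quoted from rounded published
  coefficients, and full-precision inputs shift the support share to 36.1%.
  Point estimates only, matching the usual presentation.
* `utility_score()` / `rank_profiles()` — substitutes profiles into
  $V = \text{constant} + \sum_k x_k \beta_k$ and ranks all 18 full-factorial
  combinations (dense ranks, lexicographic tie-break). The ranking always
  enumerates the full factorial; published rank tables sometimes print a
  subset with transcription inconsistencies, and the equation — not any
  printed row — is authoritative here.
* `subgroup_analysis()` — split-sample estimation on a binary covariate
  with the independent-samples Wald statistic
  $z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$ per coefficient mean. Published
  subgroup p-values computed by unstated tests are therefore not exact
  targets; the test's operating characteristics (size and power) are
  verified by simulation instead. All SDs are re-estimated freely in each
  stratum; respondents with a missing covariate are excluded listwise and
  counted.

## Simulation scales used by the test suite

Statistical guarantees are verified at problem sizes chosen to make the
full suite run in minutes on a single core while keeping each check
well-powered; these are the package's own choices of experimental scale:

* mean and SD recovery: 10 seeded cohorts of 1000 respondents on the
  study design, 200 Halton draws, each generating parameter within 3
  Monte-Carlo standard errors of the replicate mean, with pooled 95% CI
  coverage in [0.85, 1];
* subgroup test size: 100 seeded cohorts of 200 respondents split into
  identical strata of 100 (40 draws), per-coefficient rejection rates
  inside the binomial 95% band around 0.05;
* subgroup test power: 10 seeded cohorts of 1000 respondents per stratum
  with a one-unit home-preference shift, requiring rejection in at least 8;
* draw stability: refitting one 250-respondent cohort with 100 versus 1000
  draws moves every mean by less than 0.05 utility units;
* exact identities (brute-force likelihood oracle, conditional-logit
  collapse, information-matrix summation) at tolerances of 1e-10 or
  tighter on small instances.

## Reproducible pipeline

`run_pipeline()` chains design → simulation → estimation → post-estimation
from a single configuration (R list or YAML file) with one root seed from
which every stage seed is derived. All outputs (`design.csv`,
`choices.csv`, `result.json`, `importance.json`, `ranking.csv`,
`subgroups.json`) are stamped with the seed and a configuration hash, and a
rerun with the same configuration is byte-identical apart from the
timestamps in `run.log`. A thin command-line wrapper
(`inst/scripts/dce`) exposes the same stages as subcommands.

```{r pipeline, eval = FALSE}
bundle <- run_pipeline(pipeline_config(n_respondents = 103, seed = 1),
                       out_dir = "dce_out")
writeLines(render_tables(bundle))
```

## Known limitations

* Independent normal mixing only; no correlated coefficients, lognormal or
  triangular mixing, latent classes, or WTP-space parametrisation.
* D-efficiency is defined under the package's stated convention; values
  produced by other software under other conventions are not comparable
  digit for digit.
* The Wald subgroup test compares stratum fits estimated independently; it
  does not pool information or constrain nuisance parameters across strata.
* Utility-score ranking orders profiles by point estimates without
  propagating estimation uncertainty into the ranks.
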