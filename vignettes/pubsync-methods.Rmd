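---
title: "Methods: scoring, hormone QC, agreement, and group factor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, hormone QC, agreement, and group factor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

`pubsync` implements an integrated analysis of early pubertal maturation in
9–10-year-olds as measured in large epidemiological cohorts: perceived
physical development from the Pubertal Development Scale (PDS, reported by
caregiver and by the youth), salivary sex-steroid levels (DHEA and
testosterone in both sexes, 17-β estradiol in females), anthropometry, and
their integration into latent maturation factors via Bayesian group factor
analysis (GFA). Because the motivating cohort data are access-controlled,
the package ships a synthetic cohort generator that emulates the relevant
data structure end to end, so every stage is testable offline.

# PDS scoring

Each PDS item is rated 1 ("has not begun yet") to 4 ("seems complete");
menarche is yes/no, coded 4/1 when it enters averages. Responses left
blank, "I don't know", or "Refuse to answer" are missing, with the subtype
preserved for reporting.

* **Average PDS** — mean of the five sex-appropriate items. A respondent
  with more than one missing item gets no score; with exactly one missing
  item the mean of the remaining four is used (mean-of-available, no
  imputation). The alternative reading — a fixed denominator of five —
  would bias scores downward for incomplete respondents, so it was not
  adopted.
* **Gonadal / adrenal scores** — gonadal: growth spurt, breast, menarche
  (females) or growth spurt, voice, facial hair (males); adrenal: body
  hair and skin. Any missing constituent leaves the score undefined.
* **Category score** — males sum body hair + voice + facial hair (3–12):
  prepubertal = 3; early = 4–5 *with no 3-point response*; mid = 6–8
  *with no 4-point response*; late = 9–11; post = 12. The parenthetical
  constraints are implemented as escalation (a 3-point response at sum
  4–5 escalates to mid; a 4-point response at sum 6–8 escalates to late):
  this is the only reading under which they are not redundant, and it is
  the only one that keeps the category monotone under item-wise increase
  (verified exhaustively in the tests). Females sum body hair + breast
  (2–8) and menarche overrides: with menarche the category is late (sum
  ≤ 7) or post (sum 8) regardless of how small the sum is; without it,
  pre = 2, early = 3, mid > 3. A missing menarche response leaves the
  category undefined but counts as an ordinary missing item for the
  average score.

# Anthropometrics

Height and weight are means of up to three repeated measures. BMI z-scores
use the LMS transformation `z = ((x/M)^L − 1)/(L·S)` (log branch at
`L = 0`) against an age- and sex-specific reference table, with lookup at
the nearest half-month row. The package bundles a **synthetic** LMS
reference (smooth curves with magnitudes typical of BMI-for-age at 102–138
months) so that tests require no download; production analyses should
load the real CDC 2000 table through the same CSV reader. Weight status
uses percentile cut-offs (5th/85th/95th), with the 85th-percentile
boundary implemented as `[85th, 95th)` to make the four categories
exhaustive and mutually exclusive; boundary comparisons are done on the z
scale so exact cut-point values classify deterministically.

# Hormone quality control

One value per child per analyte, produced by a decision tree: the session
must pass three ordered gates (recorded sex matches sex at birth; a sample
was collected; it was processed); each duplicate replicate is invalid if
absent, below the analyte's lower limit of sensitivity (testosterone
1 pg/ml, DHEA 5 pg/ml, estradiol 0.1 pg/ml), or flagged as problematic by
a research assistant. Both replicates valid → mean; one → that replicate;
none → missing, with a provenance code at every leaf. Values above the
calibrator range are retained but flagged (`out_of_range_high`) since the
tree prescribes no upper-range exclusion; a switch can drop them.
Duplicate pairs with CV above 15% warn but keep the mean, as no
discordance rule is prescribed. Session covariates are emitted in minutes:
collection time since midnight, collection duration, and time to freezer,
plus caffeine/exercise flags; they are *reported for downstream models*,
never applied as corrections.

# Caregiver–youth agreement

Both statistics are implemented from first principles.

* **Weighted Cohen's kappa**: disagreement weights
  `w_ij = (|i−j|/(K−1))^d` with quadratic (`d = 2`, default) or linear
  weights; expected disagreement from marginal products; large-sample SE
  (Fleiss–Cohen–Everitt form) for the CI. The default is quadratic
  because the source analyses do not state the scheme and quadratic
  weighting is the common default for ordinal scales; the active scheme
  is carried in every output row.
* **Polychoric correlation**: two-step ML — thresholds from inverse-normal
  marginal cumulative proportions, then a 1-D likelihood maximization for
  the latent correlation over (−0.999, 0.999). The bivariate-normal CDF is
  computed by 64-node Gauss–Legendre quadrature of the conditioning
  integral (cross-checked in tests against an independent library and
  against a grid-search oracle). SE from the numerical second derivative
  at the optimum. When an entire margin category is empty a +0.5
  continuity correction keeps thresholds finite. Two-step (not joint) ML
  was chosen because it is standard, stable, and directly testable
  against a grid oracle.

Continuous summary scores are discretized to their observed value grid
before agreement is computed, and menarche is treated as binary (K = 2).

# Group factor analysis

For blocks `m` (physical items; hormone levels), the model is
`x_i^(m) = W^(m) z_i + ε_i^(m)` with `z_i ~ N(0, I_K)`,
`ε ~ N(0, τ_m^{-1} I)`, loadings `w^(m)_{dk} ~ N(0, α_{mk}^{-1})`, and
Gamma(0.01, 0.01) hyperpriors on the ARD precisions `α` and per-block
noise precisions `τ` (per-block noise is the smallest model consistent
with the design; `noise = "variable"` switches to per-variable
precisions).
Inference is a blocked Gibbs sampler: scores (joint normal per subject),
loadings (joint normal per variable, covariance shared within a block),
then conjugate Gamma updates for `α` and `τ`.

Numerical choices that matter:

* **Warm start.** Scores and loadings are initialized from an SVD of the
  concatenated blocks. From a small random start the ARD hierarchy can
  shut a factor off before it picks up moderate structure and the chain
  locks at a degenerate mode.
* **Basis alignment across draws.** Factor solutions are identified only
  up to sign/rotation; kept draws are aligned to the first kept draw by
  orthogonal Procrustes before averaging, otherwise posterior means wash
  toward zero.
* **Variance explained.** The reported per-factor variance explained is
  the posterior mean of the per-draw statistic
  `‖Z_k‖² ‖W_k‖² / Σ_m ‖X^(m)‖²` on standardized data. Computing it from
  the posterior-mean scores instead would shrink it severely for weakly
  determined scores. Factors with more than 10% variance explained are
  retained, ordered descending (LF1 is the largest).
* **Factor dimension.** `fit_gfa()` defaults to K = total variable count
  and lets ARD prune. For the cohort-scale puberty analysis the pipeline
  uses `k_init = 4` — the extracted rank in this age range — because with
  7–8 free factor dimensions the chain can transiently split the physical
  factor into two sub-threshold pieces at some seeds; at K = 4 the
  solution is stable across seeds at 6,000 sweeps (3,000 burn-in,
  thinning 5), the package defaults.
* Variables are z-scored before fitting; hormone levels enter on their
  raw (not log) scale by default since the upstream analysis does not
  state a transformation — a log option is available, and ordinal PDS
  codes (and menarche 4/1) enter as numeric values.

# Stability procedures

* **Replicate runs** (default 10 seeds) are aligned with a Hungarian-style
  assignment maximizing summed |correlation| of stacked loadings, signs
  fixed to the reference run; medians and 2.5/97.5 percentiles summarize
  the aligned stack.
* **Split-half**: disjoint random halves, independent fits, factors
  matched across halves, Tucker congruence per factor; φ ≥ 0.90 flags
  replication (no criterion is prescribed upstream; 0.90 is the
  conventional "fair similarity" bound for congruence).
* **Covariate extensions**: BMIz, then + SES, then + race/ethnicity enter
  as additional blocks; each successive covariate block is residualized
  on the previously entered covariate blocks ("pre-residualized" is
  ambiguous upstream — this reading residualizes only covariate blocks,
  never the puberty blocks, and is labelled as an interpretation in
  output metadata). Reported is the congruence of the puberty-block
  loadings of the top factors against the base model.
* **Synchrony profiles**: LF1/LF2 posterior-mean scores, classified by
  sign quadrant (scores are centered by construction; a median split is
  available): both high = synchronous high, both low = synchronous low,
  high LF1 (hormones) with low LF2 = hormone-led asynchrony, the reverse
  = physical-led asynchrony.

# The synthetic cohort generator

The generator defines the study conditions for all tests. Defaults: 4,000
children (≈2,000 per sex), ages 108–131 months, US-like race/ethnicity,
income and education margins. A latent maturation score is linear in age
(0.025/month), female (+0.7), BMIz (+0.25) and small race/income offsets,
with standard-normal residual. Ordinal items are thresholded item-specific
latents (loading × maturation + standard-normal noise) — exactly the
polychoric model, so the agreement module's assumptions hold by
construction; "I don't know"/refusal is missing-at-random per item and
reporter (youth height ≈ 38%, caregiver ≈ 4%, matching the order of
magnitude seen in practice), and youth latents are shifted upward (+0.3)
so youth report more mature levels. Menarche is logistic in maturation
(intercept −4.9, slope 1.0, ≈3% prevalence among females). Hormones are
log-normal in maturation plus a *shared within-child hormone latent*;
the shared slopes are calibrated so a maximum-likelihood two-factor
cross-check on generated data reproduces the published factor strengths
(hormone-led ≈ 23–31%, physical-led ≈ 15–17% of total variance) — this
makes the androgen–androgen correlation higher (≈0.8) than typically
observed (~0.5), a deliberate trade-off documented here; marginal
item–hormone correlations stay near the reported 0.10–0.34 band.
Duplicate replicates carry 5% multiplicative CV, are censored below the
assay lower limit (emitted as the code `"BLQ"`, never as a number), and
sessions include realistic defect rates (sex-mismatch 0.5%, not collected
5%, not processed 2%, RA flags 1%).

What the generator does **not** emulate: longitudinal trajectories,
family/twin correlation beyond a shared label, site effects beyond a
label, non-normal latent structure, informative missingness, or assay
batch effects. Passing tests therefore demonstrate correctness of the
procedures under the stated generative model, not robustness to every
feature of real cohort data.

# Problem sizes used by the test suite

Unit tests fit planted-factor problems at n = 80–500 with 2,000–3,000
sweeps; the recovery study uses 20 replicates at n = 500 (blocks 5 + 3,
SNR 10, group-sparse truth); the pipeline study uses the default cohort
(≈2,000 per sex) with 10 replicate fits per sex at 12,000 sweeps (6,000
burn-in — the replication study asks finer questions of the posterior
than a single fit, so it gets a longer chain) plus a split-half. These sizes give stable Monte-Carlo margins for
every assertion while keeping the whole suite desk-scale.

# Known limitations

* The Gibbs sampler reports no formal convergence diagnostic beyond the
  log-likelihood trace; pathological inputs (near-duplicate blocks) can
  still trap it in split-factor modes at large K.
* The polychoric SE is the profile-likelihood curvature; it ignores
  threshold-estimation uncertainty (standard for two-step estimators).
* Weighted-kappa CIs are asymptotic; a seeded bootstrap is available.
* The QC tree treats a single assayed (non-duplicate) sample as a single
  valid replicate, the natural reading of the duplicate rule.
* With `n_children = 0` the generator returns a typed empty shell whose
  columns are all character; types match the populated schema only for
  non-empty cohorts.
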