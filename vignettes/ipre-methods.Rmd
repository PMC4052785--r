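---
title: "Integrated prognosis risk estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated prognosis risk estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipre)
```

## The problem

Breast cancer prognosis classification splits patients into a *poor
prognosis* group — metastasis or recurrence observed within five years of
follow-up — and a *good prognosis* group — progression-free beyond five
years. Gene signatures derived from single microarray studies overfit their
training cohort, so `ipre` works on integrated multi-platform cohorts: the
larger sample size is the point, and the price is that expression values
from different platforms and protocols must first be made comparable.

The pipeline has five stages: integration, gene scoring, signature
selection, risk modeling, evaluation. This vignette describes each model,
its assumptions, the tunable parameters, and the numerical decisions taken
where the design was genuinely open.

## Integration

Probe-level matrices are collapsed to gene level by averaging the probes
mapped to each gene; Affymetrix control probes (ids starting `AFFX`) and
unmapped probes are dropped and logged. Every gene row is then min–max
normalized to $[0,1]$ *within its cohort*:
$$e'_i{}^{(g)} = \frac{e_i^{(g)} - e^{\min(g)}}{e^{\max(g)} - e^{\min(g)}}.$$
Normalizing per cohort, before intersection, is what makes values from
different platforms commensurable; training and testing cohorts are always
normalized separately so no test-set information leaks into training. The
transform is idempotent, so feeding already-normalized data through the
pipeline is harmless.

Decisions worth stating:

* **Constant genes** ($e^{\max} = e^{\min}$) are set to 0 everywhere and
  flagged rather than dropped, keeping the matrix shape stable; the scoring
  stage excludes flagged genes by default because their dichotomization
  pattern is an artifact of the zero fill.
* **Gene order after intersection is lexicographic**, so integrated results
  do not depend on platform row order.
* **Labels** follow the five-year rule: poor iff an event occurred at
  $\mathrm{TTP} \le 5$ years, good iff follow-up passed 5 years
  progression-free. A sample censored before five years carries no
  five-year information and is excluded (with a warning) rather than forced
  into either group.
* **Balancing** of the two prognosis groups — training on equal group sizes
  reduces bias toward the majority class — is uniform undersampling of the
  majority without replacement, under an explicit seed. The minority group
  is never touched: 897 poor with 1,371 good becomes 897 + 897 = 1,794.

## Virtual-chromosome scoring

Each gene $g$ is scored over the labeled samples by
$$\mathrm{VC}(g) = \tau_1\,\alpha(g) + \tau_2\,\beta(g), \qquad
\tau_1 = 1,\ \tau_2 = -1.0011 .$$

The *correlation factor* $\alpha = (p - q)/N$ counts concordance between
dichotomized expression and dichotomized outcome: a sample is concordant
when it progresses within five years with expression below 0.5, or stays
progression-free with expression at or above 0.5. Boundary conventions:
expression exactly 0.5 counts as overexpressed, and $\mathrm{TTP} = 5$
belongs to the early-progression group.

The *penalized factor* $\beta = 1 - |\bar e_{\text{poor}} - \bar
e_{\text{good}}|$ works on the actual normalized values: a large
between-group separation makes $\beta$ small, and since $\tau_2 < 0$,
a small penalty raises the score. Both components are computed on the
normalized scale, where the 0.5 threshold is meaningful.

$\tau_1, \tau_2$ are configuration with the published defaults. $\tau_2$ is
treated as an opaque constant; no procedure for re-deriving it is provided.

A consequence users should understand: with $\tau_2 \approx -1$, a gene's
score is positive only when its concordance exceeds its penalty,
$\alpha > |\tau_2|\,\beta$. For group-shifted Gaussian expression with
shift $d$ and noise $\sigma$ this means approximately
$2\Phi(d/2\sigma) - 1 > |\tau_2|(1 - d)$ — a *sharp threshold* in
$d/\sigma$. Genes just below it score slightly negative no matter how many
samples are available, which matters for selection (next section).

## Signature selection

Genes are sorted by VC descending (exact ties broken lexicographically by
gene id, so the ranking is permutation-invariant), and the robustness score
of each length-$m$ prefix is
$$R_m = \frac{1}{\sqrt m} \sum_{n=1}^{m} \mathrm{VC}_n .$$
The signature is the prefix at the maximum of $R_m$. The inverse square
root is the default weight, consistent with rank-aggregation practice where
the statistic behaves like a standardized prefix sum; a plain running mean
(`exponent = 1`) is available as an alternative. On exact ties the smaller
prefix wins. The profile is computed over all genes with no early
stopping.

Two analytic facts anchor the implementation: all-equal positive scores
give $R_m = c\sqrt m$, monotone increasing with argmax at the full list;
and the selected prefix always matches exhaustive search over all prefixes.

Because of the sharp-threshold behaviour of VC, selection is
*conservative*: when even the best genes score near or below zero, $R_m$
peaks after a handful of genes and the signature is small. The package
never forces a particular signature size — size is an outcome, not a
parameter.

The **mScore** of a sample is its mean normalized expression over the
signature genes, a value in $[0,1]$. When some signature genes are missing
from a test matrix (platform differences), the mean is taken over the genes
present, with a warning; failing hard would make cross-platform application
impossible.

## The logistic risk model

Clinical covariates are encoded as: grade I–II $\to$ 0, III $\to$ 1; tumour
size $< 2$ cm $\to$ 0, $[2, 4)$ cm $\to$ 0.55, $\ge 4$ cm $\to$ 1; ER, PR,
HER2 negative $\to -1$, positive $\to +1$; the mScore enters unchanged as
$X_6$. The size coding's published bins leave 3–4 cm unassigned; the middle
bin absorbs the gap so the coding is total. Missing ER or PR status is
imputed from the dichotomized receptor gene expression (ESR1 for ER, PGR
for PR; normalized value $\ge 0.5$ means positive, the same over/under
convention as scoring; threshold configurable). Recorded statuses are never
overridden, and HER2 is never imputed.

The model is a maximum-likelihood logistic regression of the poor outcome
(poor = 1) on all candidate covariates, with *backward elimination*: the
covariate with the largest Wald $P$ above $\alpha = 0.05$ is removed, one
per refit, until every retained covariate has $P \le 0.05$. Elimination
terminates in at most as many refits as there are candidates, and the trace
is recorded. The risk score is the linear predictor
$\mathrm{RS} = \beta_0 + \sum_n \beta_n X_n$, and the decision rule is
$\mathrm{RS} \ge \varepsilon \Rightarrow$ poor, with the boundary value
itself classified poor. The published fit ships as the preset
`ipre_2014()` with $\varepsilon = -1.480$.

When refitting, the cutoff is chosen by scanning a grid (step 0.001 by
default) over the observed risk-score range and maximizing the *F-value*,
interpreted as the F1 score — the harmonic mean of precision and
sensitivity with poor as the positive class. Ties prefer higher
specificity (sparing good-prognosis patients aggressive therapy is the
stated priority), then the smaller cutoff. The search matches exhaustive
evaluation at every midpoint between sorted scores.

Degenerate inputs are errors, not silent repairs: missing covariate values,
fewer than two samples per class, collinear covariates (named in the
error), and perfect separation, where the maximum-likelihood coefficients
diverge. In the pipeline wrapper `run_pipeline()`, the separation case gets
a documented fallback: a strongly informative signature can separate the
training classes linearly, and the wrapper then uses the mScore alone as
the risk score ($\mathrm{RS} = -X_6$, low signature expression = high
risk) with the cutoff still chosen by the F-value search, recording the
fallback in `model$fallback`. This keeps the end-to-end pipeline defined
for all inputs while `fit_risk_model()` itself stays strict.

Fitted models serialize to JSON (intercept, coefficients, cutoff, retention
threshold, trace) so a fit is reusable as a preset.

## Evaluation

With poor as the positive class: sensitivity $tp/(tp+fn)$, specificity
$tn/(tn+fp)$, accuracy $(tp+tn)/(tp+tn+fp+fn)$ — the denominator is always
the cell sum, never an externally stated cohort size — and the F-value as
above. A metric with a zero denominator is reported as `NA`, not 0. Each
proportion gets a Wald 95% interval $\hat p \pm z\sqrt{\hat p(1-\hat
p)/n}$, $z = 1.959964$, *unclipped*: a near-zero proportion legitimately
prints a small negative lower bound, and $\hat p \in \{0, 1\}$ prints a
degenerate interval. AUC is the rank-sum concordance with ties counted
one half, identical to the trapezoidal area under the ROC curve and to the
$O(n^2)$ pairwise count. Survival machinery — Kaplan–Meier curves, the
two-sided unstratified log-rank test (1 df), Cox proportional-hazards
ratios with Wald intervals — delegates to the `survival` package. When a
classifier is nearly perfect on synthetic data, all events can fall in one
predicted arm; the Cox likelihood is then monotone and the reported hazard
ratio diverges, which is the estimator's honest behaviour, not a bug.

`random_signature_null()` draws $k$ gene sets of the signature's size
uniformly without replacement (default $k = 1000$) and evaluates each with
a caller-supplied function, giving the RAND benchmark against which a
signature's outcome association should always be compared — random
signatures of identical size are a surprisingly strong baseline in breast
cancer transcriptomics.

## The synthetic study

`simulate_cohorts()` generates what the pipeline assumes: several cohorts
("platforms") with overlapping but unequal gene subsets, a planted block of
prognostic genes, clinical covariates that drive the outcome, and follow-up
consistent with the five-year rule. Defaults: 3 cohorts × 300 samples,
1,000 genes of which 50 are planted, between-group shift (`effect`) 0.3 on
the normalized scale, within-group noise 0.15, poor fraction 0.4, 10% of
ER/PR statuses masked, 5% censored decoys, seed 20140514.

Per cohort: grade is drawn I/II/III at 0.30/0.45/0.25, tumour size
log-normal around 2.2 cm, ER/PR/HER2 positive at 0.70/0.60/0.20 — typical
breast cancer marginals. The poor outcome is Bernoulli from a logistic
model on the *encoded* covariates whose intercept is solved numerically so
the expected poor fraction hits the target; the default log-odds leave
grade at exactly 0, a deliberately null covariate for testing backward
elimination. TTP is uniform on $(0, 5]$ with an event for poor samples and
uniform on $(5, 12]$ for good samples, who get a late event with
probability 0.25 so both survival arms carry events; censored decoys get
TTP below five years without an event and must be excluded by labeling.
Planted genes are Gaussian with means $0.5 \mp \mathrm{effect}/2$ by group,
clipped to $[0,1]$ (the clip rate is returned; about 0.1% at defaults).
`ESR1` and `PGR` track the true receptor statuses (means 0.35/0.65) so
imputation is exercisable end to end. Everything is reproducible bit for
bit under the seed.

What the generator deliberately does *not* emulate: probe-level noise and
saturation, batch effects beyond what min–max normalization absorbs,
correlated gene modules, and expression that influences outcome only
indirectly. Planting expression *conditional on the outcome label* makes
the signature unrealistically informative: passing end-to-end tests shows
the machinery composes correctly and recovers planted structure, not that
real cohorts would yield comparable accuracy.

Two consequences of the default configuration deserve emphasis, since both
are visible in the package's own tests:

* At `effect = 0.3`, `noise_sd = 0.15`, planted genes sit just *below* the
  VC sign threshold ($2\Phi(1) - 1 \approx 0.683 < 1.0011 \times 0.7$), so
  the robustness maximum cuts a signature of only a handful of genes and
  recall of the planted set is low — the conservative small-signature
  regime described above. At `effect = 0.9`, `noise_sd = 0.05` the planted
  block scores far above zero and selection recovers it essentially
  completely.
* Because planting is conditional on the outcome, an $m$-gene signature
  separates the groups by about $2\sqrt m$ within-group standard
  deviations of the mScore; for $m \gtrsim 9$ the training classes are
  typically linearly separable and the maximum-likelihood logistic fit
  degenerates, which is exactly when `run_pipeline()`'s documented
  mScore-only fallback engages.

## Problem sizes and numerical conventions

The test suite works at deliberately small scales: oracle comparisons use
up to 20 genes × 30 samples against plain-loop reimplementations of the
formulas, cutoff search is checked against exhaustive threshold evaluation
at up to 50 samples, AUC against the pairwise count at up to 200, and the
simulation-based checks use cohorts of 50–400 samples with the end-to-end
run at the full default configuration (900 samples, 1,000 genes).
`scripts/acceptance.R` runs the default study once, plus a 1,000-draw RAND
null, in well under a minute.

Floating-point conventions: exact-identity checks (component arithmetic,
prefix sums) are asserted to $10^{-12}$; the idempotence of normalization
likewise. Sorting ties are resolved deterministically everywhere (gene id
for ranks, first index for profile maxima, higher specificity then smaller
cutoff for thresholds), so no result depends on input order or platform
quirks.

## Known limitations

* The weight $\tau_2 = -1.0011$ is used as given; its provenance is not
  reproducible from first principles, and the VC sign threshold it induces
  makes signature size sensitive to the effect-to-noise ratio near
  $d/2\sigma \approx 1$.
* Backward elimination with Wald $P$ values is a greedy heuristic; it is
  not guaranteed to find the best subset, and under quasi-separation Wald
  statistics are unreliable (the Hauck–Donner effect) — the strict
  separation error exists precisely to surface that case.
* Accuracy-style metrics with Wald intervals are reported as computed,
  without continuity correction or clipping; for very small cells an exact
  binomial interval would be preferable, but is not what this protocol
  specifies.
* Duplicate samples across cohorts are not detected automatically; an
  exclusion list is honored when supplied.
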