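---
title: "Case-based diagnostic retrieval with external case characteristics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-based diagnostic retrieval with external case characteristics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbrecc)
```

## The problem

Case-based reasoning (CBR) supports a clinician facing a new patient by
retrieving the most similar previously diagnosed cases from a hospital
archive and presenting them, with their outcomes, as decision support.
For breast-cancer diagnosis from fine-needle aspirate (FNA) findings, a
stored case couples clinical content (age, tumour consistency, clump
thickness, FNA specimen type, number of swabs) with a confirmed diagnosis
(benign or malignant). Pure content similarity, however, ignores that cases
differ in *provenance*: a case contributed by a highly specialised
physician who signs it with their real name and that other physicians rate
as exemplary is a better template for decision making than an anonymous,
poorly documented one. `cbrecc` implements a three-phase engine that
combines both signals.

## The three phases

### Phase I — naive Bayes triage

A naive Bayes classifier is fitted on the labelled archive: class priors
$P(Y)$ are the class frequencies, and each internal feature contributes a
class-conditional $P(x_i \mid Y)$, Gaussian for numeric/ordinal features and
a Laplace-smoothed multinomial for binary/categorical ones. The posterior

$$P(Y \mid x) \propto P(Y)\, \prod_i P(x_i \mid Y)$$

is evaluated in log space with log-sum-exp normalization; ties go to benign.
Phase I plays two roles: it assigns an incoming (unlabelled) query to the
benign or malignant sub-base, and it can optionally re-partition the stored
archive. By default the stored archive is partitioned by its *recorded*
diagnoses — re-labelling already-confirmed cases with a classifier that is
itself imperfect would corrupt the case base — while queries, which have no
label, are always triaged by the model. Both behaviours are exposed
(`partition_on = "label"` / `"nb"`) because either reading of the protocol
is defensible.

Two numerical guards are deliberate: the Laplace count defaults to
$\alpha = 1$ so unseen levels get the smoothed zero-count probability
$\alpha / (n_c + \alpha L)$ rather than zero, and Gaussian variances are
floored at $10^{-9} (\text{domain width})^2$ so constant features cannot
produce infinite densities. How continuous attributes enter the model is a
genuinely open design point; Gaussian class-conditionals are the default
because they need no binning decisions, and a per-feature categorical mode
is available after discretization.

### Phase II — weighted KNN retrieval

The content similarity of a query case $I$ and stored case $R$ is the
weighted mean of per-feature local similarities over the internal features:

$$\mathrm{sim}(I, R) = \frac{\sum_i w_i \,\mathrm{sim}(f_i^I, f_i^R)}{\sum_i w_i},
\qquad
\mathrm{sim}(a, b) = \begin{cases}
1 - |a - b| / (\text{upper} - \text{lower}) & \text{numeric/ordinal}\\
\mathbf{1}[a = b] & \text{binary/categorical.}
\end{cases}$$

Feature weights default to 1: no published weighting is available for this
attribute set, uniform weights are the only non-arbitrary choice, and the
schema makes them overridable (they can also be elicited from an expert
panel with the same machinery used for the ECC weights). Retrieval is an
exhaustive scan of the class-matched sub-base — exact, deterministic, and
entirely adequate at the $10^3$-case scale this engine targets. Ties in
similarity are broken by ascending case id so that results are reproducible.

The retrieved neighbourhood can be collapsed to a single outcome score

$$S_p = \frac{\sum_{p'} w_{p'}\, d(p, p')^{-1}\, y_{p'}}{\sum_{p'} w_{p'}\, d(p, p')^{-1}},$$

a distance-weighted convex combination of the neighbour labels with
$d = 1 - \mathrm{sim}$. An exact match ($d = 0$) short-circuits $S_p$ to that
case's label rather than introducing an $\varepsilon$ guard — this keeps the
"nearest case wins" semantics without a magic constant. Where $S_p$ is
thresholded into a class we use $S_p > 0.5 \Rightarrow$ malignant, with the
exact tie going to benign, matching the Phase-I tie-break.

K is chosen by stratified K-fold cross-validation over a grid (default
1–25, 10 folds): each held-out case is classified by the $S_p$ rule against
the training folds, and the smallest K attaining the maximal mean accuracy
is selected — small K is preferred because the retrieval list shown to a
clinician should be short and the CV profile is typically flat near the
optimum. Grid points exceeding the smallest per-class training count are
skipped with a warning rather than silently truncated.

### Phase III — ECC fusion and re-ranking

External case characteristics (ECC) — physician specialty score 1–10,
willingness to reveal the real name $\{0,1\}$, case quality score 1–10 —
are combined into a provenance score $P_t = \sum_i w_i \tilde x_i$. The
values are first normalized to $[0,1]$ by their *declared domains*
($\tilde x = (x - \text{lower})/(\text{upper} - \text{lower})$, so a 1–10
score maps to $(x-1)/9$). This normalization is a deliberate
interpretation: the fused scores must live on the same $[0,1]$ scale as the
similarity for the harmonic mean to be meaningful, and anchoring at the
declared domain (rather than, say, $x/10$) uses exactly the information the
schema declares. The rule is documented here because the alternative
readings produce systematically different $P_t$.

Similarity and provenance are fused by the binary harmonic mean

$$SP_t = \frac{2\, S_t\, P_t}{S_t + P_t}, \qquad
\min(S_t, P_t) \le SP_t \le \sqrt{S_t P_t} \le \tfrac{S_t + P_t}{2},$$

with $SP_t = 0$ when both arguments are 0. The harmonic mean's penalty
mechanism is the point: it pulls the fused score toward the *weaker*
component, so a case ranks high only when it is both similar in content and
well-sourced, and a case with $P_t = 0$ is annihilated regardless of
similarity. Re-ranking sorts by $SP_t$ descending, keeping both rank columns
so the promotion effect is visible; ties are broken by higher similarity
(content dominates provenance at equal fusion) and then ascending id.

### Eliciting the ECC weights

The weights $w_i$ come from an expert panel: $m$ doctors score the $n$ ECC
attributes 1–10, each attribute's weight is its mean score divided by the
sum of mean scores, and panel agreement is checked with Kendall's
coefficient of concordance

$$W = \frac{12 \sum_j (R_j - m(n+1)/2)^2}{m^2(n^3 - n) - m \sum_i T_i},$$

with within-rater mid-ranks, the standard tie correction
$T_i = \sum (t^3 - t)$, and significance from the large-sample
$\chi^2 = m(n-1)W$ approximation on $n-1$ degrees of freedom — the standard
approach for panels of this size. A trimmed variant removes one maximum and
one minimum score per item before averaging (it requires at least four
raters); concordance is always computed on the untrimmed panel, since
agreement should be judged on what the raters actually said. A panel whose
item means stand in ratio $8:2:10$ yields weights $(0.4, 0.1, 0.5)$ —
specialty, willingness, quality — and the bundled
`synthetic_expert_scores.csv` is a synthetic panel constructed to have
exactly those means.

## Evaluation drivers

`confusion()` / `classification_metrics()` use the standard definitions
with malignant (1) as the positive class: FP = benign predicted malignant,
FN = malignant predicted benign. `roc_curve()` sweeps thresholds over the
distinct scores (ties grouped) and integrates by the trapezoid rule, which
makes the AUC identical to the Mann–Whitney concordance probability; the
tests verify this equality against explicit pair counting.
`holdout_experiment()` splits stratified at a test fraction (default 1/3)
with `floor(fraction * n)` test cases per stratum — on a 950/264 archive
that is $316 + 88 = 404$ test cases — and reports metrics, ROC and AUC for
the naive Bayes triage, a plain-KNN baseline, or the combined
NB-then-KNN pipeline, where the training base seen by KNN is re-labelled by
the naive Bayes model (`relabel = FALSE` keeps the recorded labels).
Metrics with zero denominators are reported as 0 and flagged rather than
propagated as `NaN`.

## The synthetic generator

The clinical archive the engine was designed around is not publicly
available, so `simulate_casebase()` generates bases with its coarse
statistical shape: 1,214 cases with 950 benign / 264 malignant (exactly,
in `exact_counts` mode), features inside the declared domains (age 10–95,
consistency 1–5, clump thickness 0–22 cm, FNA type 1–5, swabs 1–10, ECC
scores 1–10, willingness $\{0,1\}$). Internal features are truncated
normals (rounded for ordinals) whose class means are separated by
`class_separation` within-class standard deviations, with the standard
deviation fixed at one tenth of the domain width; binary internal features
use a logistic separation of the same scale. The default
`class_separation = 2` produces the moderate class overlap typical of real
diagnostic features; 0 makes the classes exchangeable and 6–8 makes them
essentially separable. ECC values are drawn independently of the clinical
content by default — provenance does not depend on pathology — with an
`ecc_correlation` knob for sensitivity analyses only.

What the generator does *not* emulate: real feature dependence structure
(features are conditionally independent given the class, which favours
naive Bayes by construction), measurement error, missingness, or the true
marginal shapes of the clinical features. Tests passing on synthetic data
therefore validate the *machinery* — oracle equivalences, invariances,
determinism, recovery of planted structure — not clinical performance on
any real archive. For the same reason the generator is never tuned to
reproduce published accuracy figures: that would be circular.

`simulate_expert_scores()` blends a latent item quality with per-cell rater
noise (`concordance` interpolating between pure noise and perfect
agreement), rounds, and clips to 1–10; at `concordance = 1` all raters
reproduce the item ranking exactly (Kendall's $W = 1$), and at 0 the
median $W$ of a $10 \times 10$ panel sits well below 0.2.

## Numerical and interface choices

* **Out-of-range values at normalization time** are clipped to the training
  range, not rejected: new queries may legitimately exceed training
  extremes (a new oldest patient). Constant features normalize to the
  mid-point `shift + scale/2`, avoiding division by zero deterministically.
* **The correlation filter** (`select_low_correlation_subset()`) is greedy
  forward selection in declared feature order with an absolute Pearson
  threshold (default 0.9); zero-variance features have no defined
  correlation and are treated as uncorrelated with a warning. The result
  depends only on the declared order, never on case order.
* **Which attributes to binarize** is left to the caller; the default
  pipeline binarizes nothing beyond already-binary fields, since no
  published rule specifies otherwise.
* **Seeds are mandatory** for every stochastic operation (splits, folds,
  generators), and the CLI writes a manifest with the configuration and MD5
  checksums of every output, so a run is reproducible byte for byte.
* **Schema flexibility**: the attribute set is user-declared, not
  hard-coded. Two bundled schemas cover the two attribute-set variants that
  appear in practice — the core FNA set with ECC ([fna_schema()]) and an
  extended set with gender, clump mobility and a cell grade
  ([retrieval_schema()]) — rather than resolving the discrepancy by fiat.
* **Ids are opaque strings**; integer indices are one special case.
  Case-base files are comma-separated UTF-8 with a `.` decimal mark and the
  id column first.

## Problem sizes used in the test suite

The suite validates oracle equivalence on many small random instances
(naive Bayes on bases of up to 30 cases; retrieval on bases up to 200;
Kendall's W on panels up to 12×12; AUC on up to 100 scores) and pipeline
recovery on archives of 1,214 cases, with the null-model calibration run at
400 cases over 20 seeds. These sizes were chosen so the full suite
exercises every contract in under a minute on a single core while keeping
Monte-Carlo standard errors small relative to the tested effects.

## Known limitations

* Naive Bayes assumes class-conditional independence; correlated clinical
  features will degrade its calibration (though often not its ranking).
* The local similarity for ordinal grades treats adjacent grades as equally
  spaced; a clinically informed distance could replace it per schema.
* Kendall's W significance uses the $\chi^2$ approximation, which is
  anticonservative for very small panels ($n < 5$ items); exact permutation
  p-values are not implemented.
* The engine does not adapt retrieved solutions (case adaptation) and does
  not update the case base; it stops at ranked recommendation, which is
  where the decision-support boundary lies.
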