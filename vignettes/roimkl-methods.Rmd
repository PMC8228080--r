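---
title: "ROI-level multiple kernel learning for task fMRI group classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-level multiple kernel learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roimkl)
```

## The problem

Children with developmental dyslexia (DD) show weakened responses along
the visual magnocellular/dorsal pathway. Two visual fMRI tasks probe this
system: full-field sinusoidal gratings engineered to drive the
magnocellular (M) or parvocellular (P) pathway preferentially, and a
coherent-motion (CM) task at three coherence levels (6%, 15%, 40%). From
each subject's first-level GLM, five contrast maps are taken (M-vs-B,
P-vs-B, CML6/15/40-vs-B), averaged within each cortical region of an
atlas parcellation (180 regions per hemisphere), and adjusted for two
confounds (performance IQ and an inattention score). The question is
whether this 360-region, five-contrast profile separates children with
DD from typical readers (TRs), and which regions carry the
discrimination.

`roimkl` implements that analysis end to end and, because the underlying
subject data are not publicly available, ships a synthetic-cohort
generator so every stage can be exercised and validated on data with
known ground truth.

## The classifier

For ROI $m$, the five contrast means are concatenated into one vector,
z-scored with training-set moments, and turned into a linear Gram matrix
$K_m$, trace-normalized to $\mathrm{tr}(K_m) = n_{\text{train}}$. The
multiple kernel learning (MKL) SVM combines them as
$K(\beta) = \sum_m \beta_m K_m$ with nonnegative weights constrained to
the $\ell_p$ unit ball, $\|\beta\|_p = 1$. Small $p$ (the default grid
uses 1.05 as a numerically safe stand-in for the group-lasso limit
$p \to 1$) drives most $\beta_m$ toward zero, so the surviving weights
identify the discriminative ROIs; large $p$ approaches uniform
weighting.

Fitting alternates two exact steps until
$\max_m |\Delta\beta_m| < 10^{-4}$ (or 200 alternations):

1. solve the standard C-SVM dual on $K(\beta)$ (an SMO working-set
   solver in compiled code, KKT tolerance $10^{-10}$ for the final
   model, $10^{-6}$ for intermediate alternations, warm-started across
   alternations);
2. update the weights in closed form,
   $\beta_m \propto \|w_m\|^{2/(p+1)}$ renormalized to the $\ell_p$
   ball, where
   $\|w_m\|^2 = \beta_m^2 (\alpha \circ y)^\top K_m (\alpha \circ y)$.

The dual optimum is convex in $\beta$, so the logged objective trace is
non-increasing; the tests assert this on every fit. The decision
function is $f(x) = \sum_i \alpha_i y_i \sum_m \beta_m K_m(x_i, x) + b$;
DD is coded $+1$ and a tied decision value ($f = 0$) is assigned to the
TR class. Since the cited origin of the classifier publishes no
equations, this $\ell_p$-norm formulation is the package's own concrete
realization of a sparsity-regularized kernel-weight learner; it is
validated against an exhaustive weight-grid search on small problems and
against an independent projected-gradient QP solver in the single-kernel
limit, where MKL must reduce to a plain SVM.

## Validation design

Hyperparameters $C \in \{2^{-5}, 2^{-3}, \dots, 2^{5}\}$ and
$p \in \{1.05, 4/3, 2, 4\}$ are chosen by double cross-validation: the
outer loop holds out one DD and one TR subject per fold (22 folds at the
study's 22+22 size; pairs formed by a seeded permutation within each
group, since the pairing rule itself is not prescribed), and a
stratified 10-fold inner loop on each outer-training set scans the grid,
ties broken toward smaller $C$, then smaller $p$. Standardization and
kernels are always rebuilt inside each outer-training set.
Confound residualization is, by default, fit once on the full pooled
sample before classification — the order of operations the original
analysis used — which leaks a small amount of test-set information into
the features; `mkl_cv()`/`nested_mkl_cv()` accept a `confounds` argument
that instead re-fits the residualization inside every training fold for
a leakage-free variant.

Significance comes from a permutation test: labels are shuffled
uniformly, outer folds re-formed so each still holds one subject of
each permuted label, and the cross-validated accuracy recomputed. The
protocol's 10,000 permutations re-run only the outer CV at fixed
(consensus) hyperparameters (`mode = "fixed"`); re-running the entire
grid search per permutation (`mode = "full"`) is exposed but costs two
orders of magnitude more. The p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, which is unbiased and
never zero. Accuracy is the test statistic (AUC is reported alongside);
because accuracy at these sample sizes is discrete, null p-values are
uniform-to-conservative, never anti-conservative — the test suite checks
exactly this one-sided property.

Consensus hyperparameters are the per-parameter mode across outer folds
(ties toward smaller values). Backward elimination then fixes them,
repeatedly scores the current ROI set with the outer CV, and removes the
ROI with the smallest fold-mean $\beta$ (ties: the lowest ROI index),
re-randomizing the fold pairing from a seed substream at each step so
the trace is reproducible without being tied to one split. Whether the
original procedure re-ran the full outer CV at every step is unstated;
re-running it is the safer reading and is what is implemented. The best
step is chosen by accuracy, then AUC, then fewer ROIs.

Because discriminative weights are not activation patterns, the selected
model's primal vector $w$ is mapped to forward weights
$a = \mathrm{Cov}(X)\, w / \mathrm{Var}(Xw)$ over the standardized
features (sample covariance, denominator $n-1$), computed from one
final model trained on all subjects with the consensus hyperparameters
and the selected ROI set — a table of one weight per (ROI, contrast)
admits no fold-wise definition. ROI weights are presented fold-averaged
and rescaled to a maximum of 1; forward weights are not rescaled.

## Synthetic cohorts: what they emulate, and what not

`simulate_cohort()` generates
$\text{value} = \text{ROI baseline} + \text{group effect} +
\text{confound loading} + \text{subject factor} + \varepsilon$, with
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. Defaults follow the study
conditions: 22 subjects per group, 360 ROIs, five contrasts; group
effects (TR minus DD, in units of Cohen's d) are planted in a chosen ROI
subset; the two confounds mimic the published group separation of the
block-design score (TR higher) and the DSM-IV inattention score (DD
higher), each loading on the features at 0.1 noise-SD per covariate SD —
a deliberately modest coupling that makes residualization consequential
without dominating the signal. Within-subject correlation among the
five contrasts is not reported for the real data; the generator defaults
to independence and exposes `subject_factor_sd` to induce a shared
subject factor. BOLD runs are HRF-convolved condition regressors (the
canonical double-gamma: peak 6 s, undershoot 16 s, unit dispersions,
ratio 1/6 — the field-standard default, as no HRF is named in the
protocol) plus optional linear drift (default off) and white noise; no
spatial structure, slice timing, or autocorrelated noise is simulated.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not robustness to fMRI physics the generator does not
emulate.

Task designs reproduce the protocol exactly: 28 gratings blocks
(8 M / 8 P / 12 blank; 14 s stimulation + 4 s question + 2 s
inter-stimulus, applied uniformly to all block types for simplicity)
with no two adjacent blocks of the same type, and 48 CM trials
(8 per coherence level crossed with expanding/contracting direction;
0.5 s fixation + 0.25 s stimulus + 4 s response + 4.25 s inter-stimulus)
with no coherence level in more than two adjacent trials. Sequences are
drawn by constrained sequential sampling with restarts, capped at
10,000 attempts (plain rejection over full shuffles is infeasible for
the gratings constraint, whose satisfying fraction is about $10^{-4}$).
Only the 0.25 s stimulus events are modeled in the CM design matrix —
the stimulus, not the response window, is the condition of interest —
and the gratings' brief target-detection patches are left unmodeled, as
the GLM description lists only task conditions, motion and outlier
volumes as predictors.

## Numerical choices and degenerate inputs

* Volume $i$ (1-based) is sampled at $(i-1) \cdot \mathrm{TR}$ seconds;
  TR defaults to 2 s.
* QC rules are strict inequalities: motion $> 2$ mm, intensity
  difference $> 2.5$ whole-run SDs (single pass, outliers included),
  run exclusion at $> 20\%$ overall or $> 30\%$ within one condition.
  The first volume is unflaggable — both rules compare to a previous
  volume.
* Zero-variance features are dropped from kernels with a warning;
  zero-variance covariates are dropped from residualization silently
  (they can explain nothing).
* Residualization adds the grand mean back so features keep their
  scale, and is idempotent to $10^{-10}$.
* Every stochastic stage derives its seed from one master seed via
  named substreams (`substream_seed()`), so stages are individually
  reproducible and the full pipeline is byte-identical across reruns.
* Elimination scores each set before removing from it, so a trace from
  $R$ ROIs with floor $f$ holds $R - f$ scored steps; the final
  $f$-ROI set is reached but not re-scored.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen to make the statistical
assertions sharp while keeping a full run in minutes: type-I error of
the permutation test is estimated from 200 null cohorts (22+22
subjects, 40 ROIs, 99 permutations, fixed mode at a representative
mid-grid configuration $C = 1$, $p = 2$ — the null property does not
depend on the hyperparameters, and mid-grid fits converge in the fewest
alternations) and compared against the 99% binomial interval around
0.05; parameter recovery plants three ROIs at $d = 1.5$ among 40 and
requires both the weight ranking and the backward elimination to
recover them in at least 80% of 20 seeded runs. The acceptance script
mirrors these conditions. The published headline numbers (65.9%
accuracy, the specific 11-ROI set, the printed correlation
coefficients) depend on the unavailable subject data and are treated as
output-shape references only; what is reproduced exactly are the
statistics recomputable from printed summary values — the Table-1 group
comparisons, the sex chi-square, and the Bonferroni threshold
$0.05/165 \approx 3\times10^{-4}$.

## Known limitations

* The exact optimization problem of the cited GL-MKL implementation is
  not recoverable; agreement is at the level of its described behavior
  (nonnegative sparse kernel weights, sparsity parameter $p$, SVM
  penalty $C$), not of a shared codebase.
* The published handedness chi-square (0.31) cannot be reproduced from
  its own printed counts (they give about 0.36 under either the
  corrected or uncorrected convention) and is excluded from the
  recomputation table's cross-check, as are t rows whose df (41/40/39)
  imply unprinted per-group sizes.
* Pearson correlations with behavior default to residualized features
  (pipeline-consistent); whether the original correlation analysis used
  residualized or raw means is unstated, so the raw route is one
  argument away.
* No surface-based (vertex/annot) atlas handling: any integer label
  vector or volume works, but real FreeSurfer annotation files must be
  converted upstream.
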