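---
title: "Modelling biased and ignorant diagnosticians"
author: "diagbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biased and ignorant diagnosticians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagbias)
```

## The model

Any dichotomous judgement — a laboratory assay, an imaging read, a
reviewer's verdict — is characterised by the conditional probabilities of
its two possible outputs given the two possible truths. `diagbias`
represents this as a column-stochastic 2×2 matrix with rows T+/T− (test
result) and columns Dx+/Dx− (true diagnosis): entries TP (sensitivity),
FP, FN, TN (specificity), with TP + FN = 1 and FP + TN = 1. This
orientation, rows = result and columns = diagnosis with unit column sums,
is fixed throughout the package and matches the conventional tabular
layout of test characteristics.

Three assumptions carry the whole analysis:

1. **Sequential testers compose by matrix multiplication.** If a first
   test's output is the input of a second tester, and the second tester's
   errors are conditionally independent of the truth given the first
   result, then the chain's overall characteristics are the product of
   the two matrices (later tester on the left). `compose()` implements
   the four bilinear products explicitly and never renormalises:
   column-stochasticity of the result is a theorem, not an adjustment,
   and the test suite asserts it emerges from the arithmetic alone.

2. **Bias and ignorance are themselves test matrices.** A tester's
   preference structure over outcomes is a matrix acting on the true
   result: the unbiased tester is the identity, and a symmetric bias of
   magnitude $b$ gives weight $b$ to false results,
   $\{1-b, b; b, 1-b\}$. Ignorance — the concordance between an
   amateur's and an expert's diagnoses — is a matrix of the same shape
   (not necessarily symmetric, e.g. 60/30) acting through the same
   algebra, which is why `apply_ignorance()` is numerically identical to
   `compose()` and differs only in the role label it demands. Unlike a
   physical test, these matrices may have diagonal entries below 0.5;
   the "sensitivity cannot drop below 50%" folk rule does not bind a
   biased human.

3. **Posteriors update by Bayes' formula with constant characteristics.**
   $PPV = p\,TP / (p\,TP + (1-p)\,FP)$, applied repetitively with each
   posterior becoming the next prior, and the same (possibly
   bias-degraded) matrix at every step.

The Youden index $J = TP - FP$ is the package's summary of
discriminatory power. It multiplies exactly under composition,
$J(AB) = J(A)J(B)$, which makes precise why a chain of testers is at
best as good as its weakest member, why one worthless link
($J = 0$, e.g. a 50% bias) destroys any chain, and why $J < 0$ (bias
beyond 50%) *inverts* the test so that positive results lower the
probability of the diagnosis while seemingly confirming its alternative.

## Parameters and their defaults

* **Sensitivity, specificity, bias, priors** — all dimensionless
  fractions in $[0,1]$ internally; percentages appear only at I/O
  boundaries (tables, JSON scenario files, the CLI), where they are
  divided by 100 on read. This removes a whole class of 0.9-vs-90
  mistakes; the CLI accepts fractions only under an explicit
  `--fraction` flag.
* **The canonical worked examples** use a primary test of 80%
  sensitivity / 90% specificity at a 20% prior (the bias ladder and the
  consecutive-testing curves) and 80%/95% at a 50% prior (the
  bias-inversion and ignorance scenarios); bias levels 0, 20, 40, 50,
  60, 80, 100% and the 60/30 ignorance matrix. These defining inputs
  are hard defaults of `reproduce_table1/2/3()` and
  `figure1_curves()`, regenerated from the constructors at every call so
  that a regression anywhere upstream breaks the table tests.
* **`max_tests`** — the chain-length search `min_positive_tests()`
  defaults to 1000 and returns an explicit "unreachable" sentinel
  (`n_tests = NA`) rather than an error, so sweeps can tabulate bias
  levels whose curves never cross the threshold. `figure1_curves()`
  defaults to 6 tests, the displayed range of the curve family.
* **Threshold comparison** is strict (`posterior > threshold`) at full
  precision, matching the reading of "over 90%" as an exceedance.

## Numerical choices

* **Validation tolerance** is $10^{-12}$ on the column sums. The
  constructors guarantee exactness by building the bottom row as
  $1 - \text{top row}$; the tolerance exists for matrices arriving from
  composition chains or external files.
* **Display rounding is half-up** (`round_percent()`), with a $10^{-9}$
  guard so that values representing exact halves round up regardless of
  the sign of their floating-point representation error. The historical
  tables are not internally consistent on .5 cells (one prints 20 for
  20.5, another 69 for 68.5), so the table-regeneration tests accept a
  ±1-point difference on cells that sit on a .5 boundary at full
  precision and demand exact agreement everywhere else.
* **Degenerate updates.** A zero denominator in Bayes' formula (the
  observed result is impossible under both weighted diagnoses, e.g.
  $p = 0$ with $FP = 0$) raises a classed undefined-posterior error
  rather than silently returning 0; $p = 0$ and $p = 1$ are absorbing
  whenever the denominator is positive.
* **The 30%-bias crossing.** With a 20% prior and the 80/90 test, a 20%
  bias needs 4 consecutive positive tests to exceed a 90% posterior and
  no bias needs 2. At 30% bias the full-precision posterior first
  exceeds 0.90 at **6** tests — but only just (0.9019, which still
  *prints* as 90%); the printed posterior first exceeds 90% at 7 tests.
  The package reports the full-precision crossing; the narrative claim
  "more than 6" corresponds to the printed-precision reading, and the
  acceptance tests pin down both numbers. This is the one place where
  the display convention changes a qualitative statement.

## Design decisions

* **Argument order**: `compose(second, first)` puts the later-acting
  (modifier) matrix on the left, matching "the product of the bias
  matrix with the test matrix"; `compose_chain()` folds left with the
  last observer leftmost. Matrix multiplication is associative, so the
  bracketing is immaterial and is tested as such. Heterogeneous chains
  (different matrices per link) are supported by `compose_chain()` even
  though the canonical Bayes chains assume identical consecutive tests;
  the chain functions that iterate Bayes' formula use one matrix
  throughout, as the canonical analyses do.
* **The alternative diagnosis** is the strict binary complement:
  `alternative_ppv() = 1 - ppv()`, the predictive value the same
  positive result assigns to Dx−. A multi-alternative extension is out
  of scope.
* **Negative-result updating** (`posterior_negative()`,
  $p\,FN/(p\,FN + (1-p)\,TN)$) is provided as clearly labelled plumbing
  so that `update_sequence()` can process mixed chains; the canonical
  analyses exercise only positive chains.
* **Curve output is data, not pixels.** `figure1_curves()` returns a
  data frame (and the CLI writes CSV); `plot_figure1()` is a thin
  optional base-graphics layer. Only textual claims about the curves
  (crossing points, flatness at 50% bias, complementarity of the two
  panels) are testable, and only those are asserted.

## What the random fixture generator does and does not emulate

`random_valid_matrix()` draws TP and FP independently uniform on
$[0,1]$, so about half of all draws have $J < 0$ — the property suite
therefore exercises the bias-inverted regime that real diagnostic tests
never visit, alongside the ordinary one. The generator (and the model)
deliberately idealises: testers in a chain are conditionally independent
given the truth (no correlated errors between, say, a resident and the
attending who trained them), consecutive tests are identically
distributed, matrix entries carry no sampling uncertainty, and priors
are taken as given (a tester biased in *assigning priors* is outside the
model). Passing tests therefore certify the algebra and its published
consequences, not the behaviour of correlated human teams on real data.

The property suite (seeded, 1000 random matrix pairs) checks at
$10^{-12}$: conservation of probability under composition, Youden
multiplicativity, the degradation bound
$|J(AB)| \le \min(|J(A)|, |J(B)|)$, equivalence of `compose()` with
brute-force enumeration of the joint outcome distribution, the
PPV/alternative-PPV complement, the fixed point at $J = 0$,
order-invariance of update sequences, and agreement of the iterative
chain with the closed-form $k$-test posterior
$p\,TP^k / (p\,TP^k + (1-p)\,FP^k)$.

## A short session

```{r example}
test <- make_test_matrix(0.80, 0.90)
biased <- compose(make_bias_matrix(0.2), test)
biased
ppv(0.20, test)    # one unbiased positive test: 20% -> 67%
ppv(0.20, biased)  # the same result read by a biased tester: 40%
min_positive_tests(0.20, biased, threshold = 0.90)
reproduce_table3()
```

## Limitations

Strictly dichotomous (no n×n generalisation), no confidence intervals on
matrix entries, no correlated-error model, no cost or effectiveness
weighting, no bias on pre-test probabilities. The model is a lens for
reasoning about judgement quality in quantitative terms, not a fitted
description of any particular tester.
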