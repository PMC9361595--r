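# diagbias

Quantitative modelling of how cognitive **bias** and **ignorance** degrade
the performance of a human diagnostician.

Clinicians, reviewers, and anyone else making dichotomous judgements act as
diagnostic tests: their judgement has a sensitivity and a specificity. A
tester who *prefers* certain outcomes (financial interest in a positive
finding, dread of an unpleasant diagnosis) or who only superficially
understands the diagnosis being tested for will systematically distort the
results that pass through them. `diagbias` makes that distortion
computable, for anyone teaching or studying clinical decision making.

## The model

A test is a column-stochastic 2×2 matrix of conditional probabilities,
rows = test result (T+, T−), columns = true diagnosis (Dx+, Dx−):

```
        Dx+            Dx−
T+   TP = Pr(T+|Dx+)   FP = Pr(T+|Dx−)        TP + FN = 1
T−   FN = Pr(T−|Dx+)   TN = Pr(T−|Dx−)        FP + TN = 1
```

TP is the sensitivity, TN the specificity. When a second tester interprets
the output of a first test, the chain's overall characteristics are the
matrix product (second tester on the left):

```
TPs = TP2·TP1 + FP2·FN1     FPs = TP2·FP1 + FP2·TN1
FNs = FN2·TP1 + TN2·FN1     TNs = FN2·FP1 + TN2·TN1
```

A tester's bias is itself such a matrix: an unbiased tester is the
identity (100% preference for true results); a bias of magnitude *b*
gives weight *b* to false results, `{1−b, b; b, 1−b}`. Ignorance — the
concordance between an amateur's and an expert's diagnoses — has the same
algebra. The Youden index J = TP − FP multiplies under composition, so a
chain is never better than its weakest link: J = 0 (e.g. a 50% bias)
destroys the test entirely, and J < 0 (bias beyond 50%) makes positive
results argue *against* the diagnosis.

Bayes' formula turns a pre-test probability *p* into the positive
predictive value after a positive result,

```
PPV = p·TP / (p·TP + (1−p)·FP)
```

and is applied repetitively over chains of consecutive results, each
posterior becoming the next prior.

## Worked example

A 20% bias acting on a test with 80% sensitivity and 90% specificity:

```r
library(diagbias)
biased <- compose(make_bias_matrix(0.2), make_test_matrix(0.80, 0.90))
biased
#> <test_matrix role="combined"> (column percentages)
#>    Dx+ Dx-
#> T+ 68  26
#> T- 32  74
#> fractions: tp=0.68 fp=0.26 fn=0.32 tn=0.74   youden=0.42
```

The bias has dragged sensitivity from 80% to 68% and specificity from 90%
to 74%. A single positive result now lifts a 20% prior only to 40%
(`ppv(0.20, biased)` = 0.3953) instead of 67%, and reaching diagnostic
near-certainty takes twice as many concordant tests:

```r
min_positive_tests(0.20, biased, threshold = 0.90)
#> 4 consecutive positive test(s) raise the prior 0.2000 above 0.9000 (posterior 0.9212)
```

The full seven-step bias ladder, from unbiased to fully inverted, with the
predictive values of the diagnosis (prior 20%) and of the alternative
diagnosis (prior 80%):

```r
reproduce_table2()
#> <table_report "table2"> (integer percents; *_frac columns hold full precision)
#>  bias tp fp fn tn  p ppv p_alt ppv_alt
#>     0 80 10 20 90 20  67    80      33
#>    20 68 26 32 74 20  40    80      60
#>    40 56 42 44 58 20  25    80      75
#>    50 50 50 50 50 20  20    80      80
#>    60 44 58 56 42 20  16    80      84
#>    80 32 74 68 26 20  10    80      90
#>   100 20 90 80 10 20   5    80      95
```

At 100% bias a positive result *lowers* the disease probability to 5% and
seemingly confirms the alternative diagnosis at 95% — the signature of a
bias-inverted tester.

`reproduce_table1()` (sequential two-tester scenarios),
`reproduce_table3()` (bias inversion and ignorance at a 50/50 prior) and
`figure1_curves()` (posterior trajectories over consecutive tests, per
bias level) regenerate the remaining worked examples; all computation is
carried at full precision with integer percents only at the display
boundary.

## Command line

A thin script over the same functions ships in `inst/cli/`:

```sh
diagbias ppv   --prior 20 --sens 80 --spec 90 --bias 20   # PPV 40% (0.3953)
diagbias chain --prior 20 --sens 80 --spec 90 --bias 20 --threshold 90   # 4
diagbias compose --primary 70,85 --secondary 80,90
diagbias reproduce --table 2 --out results/
diagbias run --scenarios inst/extdata/tables_scenarios.json
```

Values are percentages (use `--fraction` for fractions). Scenario files
are JSON; the shipped `inst/extdata/tables_scenarios.json` encodes all
the worked examples and documents the schema by example: each scenario
has a `name`, a `primary` matrix (`{"sens": 80, "spec": 90}`), an
optional `modifier` (`{"bias": 20}` or `{"tp": 60, "fp": 30, "role":
"ignorance"}`), a percent `prior`, and optional `results` / `threshold`
entries.

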