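# stageval

Evaluation of prostate cancer staging prediction models.

## The problem

Men diagnosed with localized prostate cancer face a treatment decision that
hinges on whether the tumour is organ-confined (OC) or non-organ-confined
(NOC — extracapsular extension, seminal vesicle invasion or lymph node
involvement). The true pathological stage is only known after radical
prostatectomy, so clinicians rely on pre-operative predictions built from
routine variables: serum PSA (ng/ml), clinical stage from digital rectal
exam (T1c / T2a, often not reported) and the biopsy Gleason score. The
best-known tool is the Partin lookup table, which maps (clinical stage, PSA
band, biopsy Gleason group) to stage probabilities.

`stageval` is for biostatisticians and clinical-modelling researchers who
want to ask: *how well can such variables possibly predict stage, and how
should a candidate model be judged?* It provides a complete, reproducible
pipeline:

1. **Synthetic cohorts** with the covariate structure of a real surgical
   series — 30% NOC prevalence (63/27/10 ECE/SVI/LNI within NOC),
   stage-conditional log-normal PSA (means 7.6 / 8.6, clipped to 0.7–40
   ng/ml), stage-conditional biopsy Gleason distributions, and a
   biopsy-to-prostatectomy Gleason transition with roughly 53% concordance,
   34% upgrading and 13% downgrading.
2. **Descriptive tables**: group comparisons (t-test / Mann-Whitney chosen
   by a Shapiro-Wilk check, chi-square for frequencies) and the Gleason
   concordance table.
3. **Staging classifiers under 5-fold cross-validation** — logistic
   regression, random forests, k nearest neighbours, and each clinical
   variable in isolation — pooling out-of-fold NOC probabilities so no
   patient is used to both develop and test a model.
4. **Three-pronged evaluation**:
   - *Discrimination*: sensitivity, specificity, Youden index
     (J = Se + Sp − 1), PPV, NPV, Brier score, and the AUC as the
     Mann-Whitney probability P(p̂(NOC patient) > p̂(OC patient));
   - *Calibration*: Loess-smoothed observed-vs-predicted curves with
     quantile-binned Wilson 95% error bars;
   - *Clinical utility*: decision curve analysis of net benefit,
     NB(Pt) = TP/n − (FP/n)·Pt/(1 − Pt), against treat-all and treat-none
     strategies over the threshold probabilities Pt where a staging model
     could matter (1–50%).
5. A **Partin-style table comparator** (`load_partin_table()` /
   `partin_predict()`); transcribe a published table into the documented
   CSV layout, or use the bundled synthetic toy table for testing.

## Worked example

```r
library(stageval)

co    <- sample_cohort(default_params(n = 603, seed = 2026))
folds <- assign_folds(co, k = 5, seed = derived_seed(2026, "folds"))
lr    <- cross_validated_predictions(co, model_spec("LOGISTIC"), folds)

discrimination_report(lr)
#>      model threshold sensitivity specificity youden   ppv   npv brier   auc
#> 1 LOGISTIC     0.311       0.697       0.641  0.338 0.468 0.824 0.197 0.668
```

At the Youden-optimal threshold (0.311) the cross-validated logistic model
identifies 69.7% of NOC patients and 64.1% of OC patients; the AUC of 0.668
says it ranks a random NOC patient above a random OC patient about two
times in three — informative, but far from clinically sufficient, which is
exactly the regime this framework is designed to expose.

```r
gleason_transition(co)
#> Gleason biopsy-vs-prostatectomy transition (n = 603, 0 excluded)
#>           <=6 3+4 4+3  8 9-10 Total
#> N         323 161  58 43   18   603
#> decrease    0  22  19 33    8    82
#> no_change 169  97  19  8   10   303
#> increase  154  42  20  2    0   218
#> Overall %: decrease 13.6 | no change 50.2 | increase 36.2

dc <- decision_curve(lr)
best_model_at(list(dc), 0.3)
#> [1] "LOGISTIC"
```

At a 30% threshold probability the model's net benefit (0.111 per patient)
clearly beats treating everyone as NOC (0.017) and treating no one (0).

`run_pipeline(default_config(out_dir = "run1"))` executes the whole study —
cohort, descriptive tables, all models, discrimination / calibration /
decision-curve CSVs and a hashed manifest — and is byte-reproducible from
its master seed. A thin command-line wrapper ships in
`inst/cli/run_study.R`.

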