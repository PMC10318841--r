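# metasample

Meta-research tooling for auditing **neuroimaging-based diagnostic
classifiers in psychiatry** — and, more generally, any coded corpus of
classification studies where the questions are: *who got sampled, how unequal
is that sampling, and how trustworthy are the reported accuracies?*

The package is aimed at meta-researchers and methodologists. It implements:

* **Sampling inequality.** Per-unit sampled populations (countries, or
  admin-1 regions within a country) are summarized by Lorenz curves, the Gini
  coefficient

  $$G=\frac{\sum_i\sum_j|y_i-y_j|}{2n^2\bar y},$$

  its **Dagum three-part decomposition** over labeled subgroups (e.g.
  MEDC/LEDC economic blocs) into within-group, net between-group and
  transvariation components with the exact identity $G=G_w+G_{nb}+G_t$, the
  **Theil entropy index**, and a seeded **permutation test** against an
  equal-allocation null (add-one p-values).
* **Performance synthesis.** Precision-weighted (inverse-variance) pooling of
  reported accuracies with bootstrap intervals; rank-sum contrasts between
  methodological strata (LOOCV vs k-fold, independent vs internal validation,
  cross- vs within-country testing) with Cohen's d and JZS Bayes factors;
  case–control skewness ratios.
* **Shared statistics.** Spearman + bootstrap CI, permutation correlation,
  Mann–Kendall trend (tie-corrected), exponential growth fits, JZS Bayes
  factors by numerical integration, and penalized-spline regression with an
  identifiable linear term (`mgcv` backend).
* **A five-item, five-star quality checklist** (sample representativeness,
  CV scheme, external validation, reporting transparency, data/model
  availability) as a rubric-as-data scoring engine with third-rater
  adjudication.
* **A synthetic corpus generator** with known effect structure, so every
  stage is testable end-to-end by parameter recovery.

## Worked example

```r
library(metasample)

corp <- generate_corpus(corpus_config(seed = 42))   # 476 synthetic studies
grouped <- aggregate_sample_by_unit(corp$evidence,
                                    unit_field = "sample_country",
                                    module_map = "economic_bloc")

dagum_decomposition(grouped)
#> Dagum-Gini decomposition (10 units, 2 modules)
#>   G_total          0.5633
#>   G_within         0.4680 (83.1%)
#>   G_between_net    0.0953 (16.9%)
#>   G_transvariation 0.0000 (0.0%)

gini_permutation_test(grouped, B = 9999, seed = 7)
#> Permutation test (gini): observed = 0.5633, p = 0.0001 (greater, B = 9999, seed = 7)
```

The decomposition says: for this corpus, sampling concentration is severe
(overall Gini 0.56 across the ten sampled countries), most of it arises
*within* the economic blocs (0.468), the rest is a net rich-bloc/poor-bloc
gap (0.095), and essentially none comes from distributional overlap. Under an
equal-allocation null the observed concentration is effectively impossible
(p = 1/10000).

Contrasting cross-validation schemes:

```r
ev <- corp$evidence
compare_groups(dplyr::filter(ev, cv_scheme == "LOOCV"),
               dplyr::filter(ev, cv_scheme %in% c("kfold", "nested_kfold")),
               seed = 1)
#> Rank-sum contrast on accuracy: W = 26,177, p = 2.44e-07, d = 0.542
#>   weighted means: A = 0.8974, B = 0.8036, BF10 = 1.06e+05
```

LOOCV studies report systematically higher accuracy than k-fold studies in
this corpus (the generator plants a +4-point LOOCV inflation; the weighted
gap is larger because inverse-variance weights emphasize near-ceiling
accuracies — both weighted and unweighted means are in the result object).

Scoring study quality:

```r
score_table(ev)
#> Quality scores for 476 studies: mean total 3.73, mean stars 1.99
#>   87.6% rated low quality (< 3 stars)
```

Every result object has `tidy()`/`glance()` methods and most have
`autoplot()` (Lorenz curves, permutation nulls, quality trends, spline fits).
`run_full_analysis()` chains all stages over an evidence table (or CSV path)
into a single seeded, machine-readable report; `write_run_report()` writes
the JSON + per-stage CSVs.

## Reading your own data

`read_evidence_table()` ingests a delimited evidence table (one coded study
per row; see `evidence_schema()` for the column inventory — seven mandatory
columns, everything else optional, unknown columns passed through).
Validation is strict or permissive; dropped rows are reported with reasons
via `evidence_violations()`. Unit-level sample tables are plain
`unit,value[,module]` CSVs.

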