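# cbrecc — case-based diagnostic retrieval with external case characteristics

`cbrecc` is an R implementation of a three-phase case-based reasoning (CBR)
engine for clinical decision support, designed around breast-cancer
diagnosis from fine-needle aspirate (FNA) findings. Given a new patient
case, it recommends the most relevant previously diagnosed cases from a
hospital archive, weighing both *what the case looks like* and *where it
came from*:

1. **Phase I — triage.** A naive Bayes classifier
   (posterior ∝ `P(Y) · Πᵢ P(xᵢ | Y)`, Gaussian or Laplace-smoothed
   multinomial conditionals) assigns the query to the benign or malignant
   sub-base and partitions the stored archive.
2. **Phase II — retrieval.** The K most similar cases are found by an
   exhaustive weighted local-similarity scan,
   `sim(I, R) = Σ wᵢ·sim(fᵢᴵ, fᵢᴿ) / Σ wᵢ`, with
   `sim(a, b) = 1 − |a − b| / range` for numeric/ordinal features and exact
   match for binary/categorical ones. K is chosen by stratified
   cross-validation; a distance-weighted fusion score
   `Sp = Σ w·d⁻¹·y / Σ w·d⁻¹` (with `d = 1 − sim`) collapses a
   neighbourhood to an outcome score.
3. **Phase III — re-ranking by external case characteristics (ECC).**
   Each retrieved case's provenance — physician specialty, willingness to
   reveal the real name, case quality score — is scored as
   `Pₜ = Σ wᵢ·x̃ᵢ` (values normalized to [0, 1] by their declared domains)
   and fused with the content similarity `Sₜ` by the **binary harmonic
   mean** `SPₜ = 2·Sₜ·Pₜ / (Sₜ + Pₜ)`, which penalizes imbalance: a case
   must be both similar and well-sourced to rank high. ECC weights are
   elicited from expert score panels (weight = mean score / sum of mean
   scores, optionally trimmed), with panel agreement checked by Kendall's
   coefficient of concordance W (mid-ranks, tie correction, χ² test).

The package also ships evaluation drivers (confusion metrics, ROC/AUC,
stratified holdout and CV), a synthetic case-base generator (real clinical
archives of this kind are not public), broom-style `tidy()`/`glance()`
methods and `autoplot()` graphics, and a command-line interface.

## Worked example

```r
library(cbrecc)

# a synthetic archive in the bundled clinical schema
base  <- simulate_casebase(n_cases = 300, class_separation = 2, seed = 7)

# elicit ECC weights from a 10-doctor score panel
panel <- as_score_matrix(read.csv(system.file(
  "extdata", "synthetic_expert_scores.csv", package = "cbrecc"), row.names = 1))
w <- elicit_weights(panel)
tidy(w)
#> # A tibble: 3 × 3
#>   item        mean_score weight
#>   <chr>            <dbl>  <dbl>
#> 1 specialty            8    0.4
#> 2 willingness          2    0.1
#> 3 quality             10    0.5
attr(w, "concordance")
#> Kendall's W = 1.0000 (m = 10 raters, n = 3 items)
#>   chi-square = 20.000, df = 2, p = 4.54e-05

# full three-phase run for one (unlabelled) query case
query <- base[12, setdiff(names(base), "class")]
res <- run_pipeline(base, query, fna_schema(), weights = w, k = 5, seed = 7)
attr(res, "triage")
#> # A tibble: 1 × 3
#>   id         p_benign p_malignant
#>   <chr>         <dbl>       <dbl>
#> 1 case_00012    0.995     0.00491
res
#> # A tibble: 5 × 6
#>   case_id    similarity ecc_score fused rank_without_ecc rank_with_ecc
#>   <chr>           <dbl>     <dbl> <dbl>            <int>         <int>
#> 1 case_00013      0.968     0.944 0.956                5             1
#> 2 case_00005      0.974     0.911 0.941                3             2
#> 3 case_00012      1         0.644 0.784                1             3
#> 4 case_00242      0.971     0.5   0.660                4             4
#> 5 case_00115      0.977     0.378 0.545                2             5
```

Reading the result: the query was triaged benign (posterior malignancy
0.005), so retrieval searched the benign sub-base. The query's own stored
copy (`case_00012`) is the most similar case (similarity 1), but its modest
provenance score (0.64) demotes it to rank 3 after fusion, while
`case_00013` — slightly less similar but contributed by a specialist and
rated exemplary (ECC 0.94) — is promoted from rank 5 to the top
recommendation. That promotion of well-sourced cases is exactly what the
harmonic-mean fusion is for.

Evaluation drivers report the usual quantities:

```r
rep <- holdout_experiment(base, fna_schema(), method = "nb", seed = 7)
rep
#> Holdout evaluation (nb): 201 train / 99 test
#>   accuracy 0.9899  precision 1.0000  recall 0.9524  F 0.9756  AUC 0.9982
sel <- select_optimal_k(base, fna_schema(), k_grid = 1:6, folds = 5, seed = 7)
sel
#> K selection by 5-fold stratified CV (seed 7)
#>   best K = 3 (accuracy 0.9800)
autoplot(sel)     # CV accuracy profile over K
autoplot(res)     # before/after re-ranking bump chart
```

## Command-line interface

A thin wrapper over the same functions, for scripted runs:

```sh
Rscript inst/cli/cbrecc.R simulate --n 1214 --seed 1 --out runs/sim
Rscript inst/cli/cbrecc.R evaluate --casebase runs/sim/casebase.csv --seed 1 --out runs/eval
Rscript inst/cli/cbrecc.R fuse --casebase runs/sim/casebase.csv \
    --query query.csv --k 5 --scores inst/extdata/synthetic_expert_scores.csv \
    --seed 1 --out runs/fuse
```

Every subcommand writes machine-readable outputs plus a `manifest.json`
(configuration echo and MD5 checksums); identical configuration and seed
reproduce every output byte for byte.

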