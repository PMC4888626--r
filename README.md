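# TissueRetrieval

Content-based retrieval of prostate tissue cases for diagnostic decision
support. Given a query tissue sample characterized by continuous
morphological features, the package retrieves the closest previously
reviewed cases from a reference database, where "closest" is learned
against a pathologist-defined gold standard of tissue similarity rather
than against Gleason grade alone.

The package is aimed at computational pathology groups building or
evaluating case-retrieval (CBIR) systems on graded tissue cohorts, and it
ships a synthetic cohort generator so every component can be exercised and
validated without access to clinical data.

## The method

**Tissue morphologic similarity (TMS).** Each sample *d* carries integer
scores `s_d^i` on nine morphologic criteria (gland crowding, gland
roundness, stromal reaction, nuclear grade, clefts, lumen/gland ratio,
gland continuity, cell separation, each scored 0–2 or 0–3, plus the
Gleason sum, 6–10). The similarity of two samples under criterion *i* is
distribution-weighted: with `h^i(s)` the number of database samples
scoring *s* on criterion *i* and `Z` a normalization factor (default the
database size *m*),

    TMS^i(d1, d2) = 1 − [ Σ_{s strictly between} h^i(s)
                          + ½ (h^i(s_d1^i) + h^i(s_d2^i)) ] / Z

so two samples far apart in the *score distribution* are dissimilar
regardless of the absolute score difference. The total similarity
`TMS(d1, d2) = Σ_i TMS^i(d1, d2)` ranges from 0 to 9 and is the gold
standard of retrieval relevance.

**Rank learning.** A linear ranking SVM is trained on feature-vector
differences `|f_q − f_d|` of sample pairs, with pairwise margin
constraints derived from TMS orderings, after balanced sub-sampling of
training pairs across `P = 10` equal-width TMS partitions. Retrieval
combines the two directional rankings of each query–candidate pair,

    Ranking(q, d_i; D) = RankSVM(q, d_i; D) + RankSVM(d_i, q; D \ d_i ∪ q)

with ties broken by the forward rank, and returns the top `T = 5`
candidates. A two-stage feature search (individual-performance forward
scan, then sequential floating forward selection) maximizes retrieval
NDCG under inner cross-validation.

**Evaluation.** Graded-relevance NDCG with gain `2^TMS − 1` and
logarithmic position discount; good-match precision curves over a
similarity-threshold grid `th_s = 0..8`; exact hypergeometric
random-chance baselines; and exact binomial upper-tail significance of
the observed good-match counts — all inside a leakage-safe K-fold
cross-validation harness (`K = 10`), with a kNN (`k = 5`) baseline.

## Worked example

```r
library(TissueRetrieval)

db <- simulateCohort(simConfig(m = 40, nFeatures = 10, coupling = 1.5,
                               noiseSd = 0.5, informativeFraction = 0.5,
                               seed = 42))
db
#> TissueCohort: 40 samples, 10 features, 9 criteria
#> Gleason sums: 6:5  7:14  8:6  9:5  10:10

sim <- similarityMatrix(db)
sim
#> TMSMatrix: 40 samples; pair TMS range [3.27, 6.35], mean 4.93

rep <- kfoldCrossValidate(db, evalConfig(K = 5), seed = 1)
rep
#> EvaluationReport: 40 queries, T = 5, K = 5
#>   kNN         ndcg_at_T 0.76 +/- 0.09
#>   kNN         ndcg_full 0.92 +/- 0.03
#>   RankingSVM  ndcg_at_T 0.70 +/- 0.13
#>   RankingSVM  ndcg_full 0.90 +/- 0.04

subset(reportCurves(rep), method == "RankingSVM" & th_s == 5)
#>        method th_s N_G fraction
#> 26 RankingSVM    5   1    1.000
#> 27 RankingSVM    5   2    0.950
#> 28 RankingSVM    5   3    0.675
#> 29 RankingSVM    5   4    0.450
#> 30 RankingSVM    5   5    0.175

subset(reportSignificance(rep), method == "RankingSVM" & th_s == 5 & N_G == 4)
#>        method th_s N_G N_q     p_value
#> 29 RankingSVM    5   4  18 0.003786308
```

Reading the output: the pairwise TMS distribution of the simulated cohort
is mid-dominated (mean 4.93 of a possible 9), as real graded cohorts are.
Cross-validated retrieval reaches a mean NDCG@5 of 0.70 for the learned
ranker on this small noisy cohort. Declaring a good match at similarity
threshold 5, 45 % of queries retrieve at least 4 good matches among their
top 5 — 18 of 40 queries, against a random-chance probability of 0.246
per query, binomial *p* ≈ 0.004.

A thin command-line front end over the same functions is installed at
`inst/scripts/tissueretrieve.R`:

```sh
Rscript inst/scripts/tissueretrieve.R simulate --out cohort.csv --m 30 --nfeatures 5
Rscript inst/scripts/tissueretrieve.R validate cohort.csv
Rscript inst/scripts/tissueretrieve.R retrieve cohort.csv --query-id S005 --top 5
Rscript inst/scripts/tissueretrieve.R evaluate cohort.csv --K 5 --out report.json
```

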