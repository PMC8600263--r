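# pascrosstalk

Crosstalk-aware pathway activity scores for prognostic subtyping of
expression cohorts with survival follow-up.

## The problem

Single-gene prognostic signatures transfer poorly between cohorts and
platforms. Pathway-level features are more stable, but most pathways share
genes ("crosstalk"), so naive pathway scores double-count the shared genes
and lose specificity. `pascrosstalk` implements a pipeline that

1. scores each pathway per sample with a rank-based **pathway activity
   score (PAS)**: every gene is dichotomized at its cohort median
   (strictly above → +1, otherwise → −1) and the pathway score is the mean
   of its genes' scores, so PAS ∈ [−1, +1] and depends only on within-gene
   ranks — identical across RNA-seq and microarray measurements of the
   same samples;
2. ranks pathways by univariate Cox proportional-hazards association with
   overall survival (score/log-rank test) and keeps the top *d* = 100 per
   cohort (**sure independence screening**);
3. factors every screened pathway pair (P<sub>i</sub>, P<sub>j</sub>) with
   |P<sub>i</sub> ∩ P<sub>j</sub>| ≥ 3 into three **crosstalk
   sub-pathways** — P<sub>i∩j</sub>, P<sub>i</sub> − (P<sub>i∩j</sub>),
   P<sub>j</sub> − (P<sub>i∩j</sub>) — and rescores them as features;
4. filters sub-pathway features at Benjamini–Hochberg **FDR < 0.01** per
   cohort and intersects the selections across adequately powered cohorts
   into the final feature panel;
5. splits the discovery cohort 4:1, discovers **moderate (G1) /
   aggressive (G2) subtypes** by K-means in panel-PAS space (k ∈ 2..6
   chosen by silhouette, Calinski–Harabasz and a prognostic concordance
   index), and names clusters by Kaplan–Meier survival;
6. trains a **KNN classifier** (5 neighbors, Minkowski power 2, leaf size
   30) on the training labels, validates it by stratified 10-fold CV, and
   predicts subtypes in held-out and external cohorts — always scoring PAS
   within the target cohort;
7. evaluates every cohort with Harrell's C-index, the IPCW Brier score,
   Kaplan–Meier/log-rank separation and ROC-AUC.

A first-class synthetic-data module generates multi-cohort studies with a
planted aggressive subtype (expression shift + proportional excess
hazard), controlled gene-set overlap, exponential event times, calibrated
uniform censoring and per-gene strictly increasing "microarray" transforms
— so every stage is testable against known ground truth without any
download.

## Worked example

The scripted analysis under `analysis/` simulates the default four-cohort
study (RNA-seq-like discovery cohort of 500 samples; microarray-like
validation cohorts of 60, 60 and 200; aggressive-subtype hazard ratio 3,
1.5 SD expression shift, 30% censoring), runs discovery and validates on
a fresh external cohort:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_discover.R
Rscript analysis/03_validate.R
```

Stage 2 prints (seed 20260927):

```
screened 20 pathways/cohort; crosstalk grew them to 50 features (cohort01)
FDR < 0.01 selections per cohort: 10, 0, 10, 10
cross-cohort panel: 10 features (intersected over cohorts 1, 4)
selected k = 2; training split 400/100; CV accuracy 1.000, AUC 1.000
   cohort c_index brier logrank_p auc t_star
 training   0.638 0.209  4.03e-23   1    363
     test   0.603 0.227  2.44e-05   1    335
 cohort02   0.589 0.236  1.97e-02   1    375
 cohort03   0.676 0.171  8.42e-07   1    363
 cohort04   0.629 0.200  1.01e-11   1    343
```

Reading this: the ten panel features are exactly the planted prognostic
pathways and their crosstalk sub-pathways; K-means selects k = 2 and the
two clusters separate survival in every cohort (log-rank p), with
concordance around 0.6 for the binary subtype risk and Brier error near
0.2 at each cohort's median follow-up; the classifier recovers the
cluster labels perfectly (AUC 1 on this synthetic signal). One 60-sample
cohort selects nothing at FDR < 0.01 — a cohort with ~40 events cannot
support that threshold, which is why the panel intersection uses the
event-rich cohorts and the small ones serve as external validation
(see the methods vignette). Stage 3 then classifies a never-seen external
cohort with accuracy 1.000 against the planted truth and shows that a
strictly increasing per-gene distortion of its expression changes zero
calls.

In code, the same flow is three calls:

```r
library(pascrosstalk)
study <- generate_multi_cohort_study(default_study_configs(seed = 1))
res   <- run_discovery(study$cohorts, study$gene_sets, seed = 1)
pred  <- run_predict(res, study$cohorts[[4]]$expr, study$cohorts[[4]]$surv)
```

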