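# psntopo

Graph-topological feature extraction and outcome classification for
patient omics cohorts.

## What it does, and for whom

Predicting a binary clinical outcome (death from disease, disease
progression) from expression profiles is a "small n, large p" problem: a
few hundred patients, tens of thousands of genes or transcripts.
`psntopo` is for computational biologists who want to attack this with a
*patient similarity network* (PSN): instead of feeding (selected) genes
into a classifier, each cohort is turned into a weighted graph whose nodes
are patients, and each patient is summarized by graph-topological scores.
Because every cohort — whatever its platform or feature count — maps to
the same small topological feature space, models trained on one cohort
can be applied unchanged to another, e.g. across microarray and RNA-seq
measurements of the same disease.

## Method core

For a cohort with expression matrix *X* (features × samples):

1. **Screening** — per-feature two-sample Wilcoxon rank-sum test against
   the outcome on *training samples only*; keep features with raw
   *P* < 0.05 (top 5% smallest-*P* as fallback).
2. **PSN inference** — Pearson correlation *r<sub>ij</sub>* between all
   patient profiles, rescaled by the signed WGCNA soft threshold
   *a<sub>ij</sub>* = ((1 + *r<sub>ij</sub>*)/2)<sup>β</sup>, with β the
   smallest power ∈ 1..20 whose weighted-degree distribution is
   approximately scale-free (log–log fit R² ≥ 0.8). The graph is fully
   connected, positively weighted, and built over training *and* test
   samples (transductive; labels never enter).
3. **Topology** — 12 per-patient centralities (weighted degree,
   closeness, current-flow closeness/betweenness, eigenvector, Katz,
   HITS, PageRank, load, weighted clustering, and two iterative "peeling"
   variants), plus optional binary module memberships from spectral
   clustering and a weighted blockmodel. Features are z-scored on the
   training partition.
4. **Models** — small MLPs (1–4 hidden ReLU layers, widths {2,4,8},
   softmax, class-weighted cross-entropy, dropout, batch 32, 1000 epochs,
   10 seeded replicates per configuration) grid-searched against SVM
   (cost/γ = 2<sup>2p</sup>, p ∈ −4..4) and random forest (100–10,000
   trees) baselines; scored by balanced accuracy
   bACC = (sensitivity + specificity)/2 on a stratified 50/25/25
   train/evaluation/validation split; groups compared by one-way ANOVA +
   Tukey HSD at *p* < 0.01.
5. **Transfer** — a frozen model is applied to an external cohort's own
   PSN centralities (extracted with the training pipeline's β and
   standardized within the external cohort); module features are
   cohort-specific and do not transfer.

See `vignettes/psntopo-methods.Rmd` for assumptions, numerical choices
and limitations.

## Worked example

Everything below is synthetic and seeded — no external data needed.

```r
library(psntopo)

cfg <- run_config(
  synthetic = cohort_config(n_samples = 200, effect_size = 1.5, seed = 1),
  grids = list(dnn = list(hidden_sizes = list(c(8L, 4L), c(8L))),
               svm = list(kernel = "rbf", cost = svm_param_grid(),
                          gamma = 0.25),
               rf  = list(n_trees = c(100L, 1000L))),
  replicates = 5, seed = 1)
report <- run_pipeline(cfg)
print(report)
best_model(report$records, scope = "family")[,
  c("family", "params", "bacc_eval", "bacc_valid")]
```

```
run_report: 29 records over 1 configuration(s)
  best synthetic|centralities         bACC(valid) = 0.838  [arch=[8,4] opt=adam lr=0.001 drop=0.3]
  family                                params bacc_eval bacc_valid
1    dnn arch=[8,4] opt=adam lr=0.001 drop=0.3    0.8125     0.8375
2     rf                             ntree=100    0.5125     0.4875
3    svm kernel=rbf cost=0.00390625 gamma=0.25    0.6625     0.7625
```

Reading this: the cohort has 200 patients (prevalence 0.2, class-
informative shift 1.5 SD). From its PSN, the best two-layer MLP on the 12
centrality features reaches balanced accuracy 0.84 on the held-out
validation quarter, the best SVM 0.76, and the random forest collapses
toward majority voting under the 4:1 imbalance — the qualitative ordering
the method is designed to exhibit. The `29 records` are one row per
(configuration, replicate): 2×5 DNN runs, 9 SVM grid points (convex, run
once), 2×5 RF runs.

A thin command-line front end over the same functions is provided at
`inst/cli/psntopo.R` (`simulate`, `select`, `graph`, `topo`, `run`
subcommands).

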