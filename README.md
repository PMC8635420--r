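# kgdti

Drug–target interaction (DTI) prediction that fuses a biomedical knowledge
graph with classical structural chemistry, for computational drug-discovery
researchers who need rankings of candidate interactions under realistic
evaluation regimes — including the *cold start for proteins*, where the test
targets have no known interactions at training time.

## The method

A biomedical knowledge graph is a set of triples *(h, r, t)* over typed
entities (drugs, proteins, diseases, pathways). The pipeline has three
stages:

1. **Knowledge-graph embedding (DistMult).** Every entity and relation gets
   a vector in ℝᵈ, trained so that true triples outscore corrupted ones
   under the bilinear score

   *f_r(h, t) = hᵀ diag(r) t = Σᵢ rᵢ hᵢ tᵢ*,

   i.e. RESCAL with the relation matrix restricted to a diagonal. Training
   minimizes logistic loss against η filtered uniform corruptions per
   positive, with L2 regularization and Adam.

2. **PCA reduction.** Drug-entity and protein-entity embeddings are reduced
   separately; the reduced width is a hyperparameter.

3. **Neural factorization machine (NFM).** Each pair is encoded as
   PCA(drug KGE) ‖ PCA(protein KGE) ‖ drug fingerprint ‖ protein CTD
   descriptors, and scored as

   *ŷ(x) = w₀ + Σᵢ wᵢxᵢ + pᵀ z_L*,

   where the network part embeds every scalar feature as *xᵢvᵢ*, pools all
   pairs through Bi-Interaction pooling
   *f_BI = Σ_{i<j} (xᵢvᵢ) ⊙ (xⱼvⱼ)* (computed with the O(nk) identity
   ½[(Σᵢxᵢvᵢ)² − Σᵢ(xᵢvᵢ)²]), and passes the pooled vector through a stack
   of fully connected layers to the prediction weights *p*. A logistic link
   turns ŷ into an interaction probability.

Structural featurization is hashed circular (Morgan-style) fingerprints for
drugs and the 147 composition/transition/distribution (CTD) descriptors for
protein sequences. Because DTI data are sparse, evaluation uses 1:10
positive:negative sampling and treats AUPR as the primary metric, with three
cross-validation scenarios: **warm** (train/test share drugs and proteins),
**cold drug**, and **cold protein** (test entities absent from training
interactions but present in the KG).

The package also ships the supporting analyses: betweenness-centrality
reports for spotting noisy "identifier" hub nodes worth pruning
(`centrality_report()`, `remove_nodes()`), a leakage audit proving that no
test interaction ever reaches embedding training, and a synthetic benchmark
generator with a planted low-rank interaction signal so the whole pipeline
is testable offline.

## Worked example

```r
library(kgdti)

bench <- synth_generate(synth_config(drugs = 60, proteins = 50,
                                     n_positives = 300, seed = 42))
bench
#> <synth_benchmark> 60 drugs x 50 proteins | 300 positive DTIs | 952 triples

synth_audit(bench)$protein_fraction
#> [1] 0.831            # supporting edges are ~83% protein-related

centrality_report(bench$kg, 3)
#> # A tibble: 3 × 6
#>   entity type    degree betweenness betweenness_norm  rank
#> 1 hub1   hub         50       2785.           0.173      1
#> 2 dis20  disease     20        502.           0.0312     2
#> 3 p037   protein     18        463.           0.0287     3

plan <- make_folds(bench$positives, "cold_protein", k = 5, ratio = 10,
                   seed = 42)
fold <- plan$folds[[1]]
fit <- dti_fit(fold$train, bench$kg, dti_config(seed = 42),
               drug_features = bench$drug_features,
               protein_features = ctd_table(bench$proteins))
fit
#> <dti_pipeline> mode: kge_nfm | fields: drug_kge=8 protein_kge=8
#>   drug_struct=64 protein_struct=147

pred <- dti_predict(fit, fold$test)
round(c(auroc = auroc(fold$test$label, pred$probability),
        aupr  = aupr(fold$test$label, pred$probability)), 3)
#> auroc  aupr
#> 0.620 0.195
nrow(leakage_audit(fit, fold$test[fold$test$label == 1, ]))
#> [1] 0
```

The test proteins here have *no* interactions in training: every score comes
from their KG annotations plus the pair's structural descriptors. An AUPR of
0.195 is roughly twice the 0.09 positive prevalence of the 1:10 test set;
AUROC 0.62 is well above the 0.5 chance level. The leakage audit confirms
the embedding stage never saw a test interaction. (This is a deliberately
small example; the larger planted benchmark used by the acceptance script
reaches cold-protein AUPR around 0.20 versus 0.13 for a structure-only
ablation, and warm-start AUROC around 0.73.)

`cross_validate()` runs the full k-fold protocol and returns per-fold
metrics with box-plot summaries (`tidy()`, `glance()`, `autoplot()`).
A thin CLI over the same functions lives at `inst/exec/kgdti`
(subcommands `kg-stats`, `synth`, `evaluate`).

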