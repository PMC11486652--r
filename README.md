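# lnmeta

Lupus nephritis (LN) — the renal involvement of systemic lupus
erythematosus — is heterogeneous at the cellular level, and candidate
diagnostic or vaccine-target genes have been sought by combining
single-cell transcriptomics with machine-learning panels. `lnmeta`
implements that analysis chain as a tested R package for computational
immunologists:

1. **Meta-program discovery.** Consensus non-negative matrix factorization
   (cNMF) of a leukocyte expression matrix: replicate factorizations
   `X ≈ W H` minimizing `‖X − WH‖_F` by multiplicative updates, density
   filtering and clustering of replicate spectra, component-number
   diagnostics (stability/error over k), and consolidation of correlated
   programs into meta-programs (MP1..MPn) by hierarchical clustering on
   `1 − r`.
2. **Nonoverlapping gene modules.** A dual-ranking assignment: genes are
   ranked within each factor and factors within each gene; a factor's
   module collects genes in rank order while the factor remains the gene's
   rank-1 factor, yielding pairwise-disjoint modules.
3. **Predictive panels.** Meta-program × curated-gene-set intersections
   are fed to every combination of 7 feature selectors × 14 classifiers
   drawn from 12 algorithm families (LASSO, Ridge, elastic net, stepwise
   logistic ×3, componentwise boosting, LDA, PLS-logistic, random forest,
   GBM, XGBoost, SVM, naive Bayes), trained on pooled z-scored training
   cohorts and ranked by the concordance index
   `C = P(score_case > score_control) + ½·P(tie)` (= AUROC for binary
   labels) on validation cohorts.
4. **Clinical association.** Case/control rank-sum tests with BH
   adjustment, Spearman correlation with the glomerular filtration rate,
   ordinal pathological-stage (ISN/RPS II–IV) comparisons with a trend
   statistic, and hypergeometric over-representation against gene-set
   collections.

A synthetic-data generator with known ground truth (negative-binomial
single-cell counts with planted cell types and gated activity programs;
Gaussian bulk cohorts with a planted disease score, GFR and stage
couplings) drives recovery-style tests of every stage, so the whole chain
is verifiable without any data downloads.

## Worked example

The `analysis/` scripts run the full workflow on the synthetic substrate
(roughly ten minutes in total on one CPU, most of it the k scan in
stage 3 and the 784-model sweep in stage 4):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_nmf_metaprograms.R
Rscript analysis/04_train_models.R
Rscript analysis/05_clinical_associations.R
```

Stage 3 prints the component-number diagnostics and the recovery of the
four planted programs:

```
suggested k = 4 (max stability)
consensus: kept 118/120 components, relative error 0.506
nonoverlapping modules: program1(27), program2(30), program3(28), program4(26)
best-match r to planted spectra: program1=0.91, program2=0.92, program3=0.91, program4=0.88
```

i.e. the stability diagnostic identifies the planted component number, and
each consensus spectrum correlates ≥ 0.88 with its planted counterpart
(the modules are slightly smaller than the planted 30-gene blocks because
the stop-rule ends a module at the first gene claimed by another factor).
Stage 4 ranks all selector × classifier × panel combinations:

```
usable panels: MP1xprogram1(27), MP1xprogram3(3), MP2xprogram2(30), MP2xprogram3(4), MP3xprogram3(28), MP3xprogram4(3), MP4xprogram4(26)
trained 784 models (24 failed on degenerate panels)
top five combinations by validation C-index:
                        model        panel n_selected mean_cindex mean_validation_cindex
                  naive_bayes MP1xprogram1         27   0.9208333              0.9155556
 stepglm_backward+naive_bayes MP1xprogram1         22   0.9200000              0.9116667
                      enet+rf MP1xprogram1         13   0.9547222              0.9094444
          stepglm_backward+rf MP1xprogram1         22   0.9544444              0.9094444
                    lasso+svm MP1xprogram1         11   0.9375000              0.9088889
```

The disease-relevant panel (the meta-program matching the program whose
genes carry the planted bulk signal) rises to the top with validation
C-index ≈ 0.92. Stage 5 confirms the clinical couplings on that panel:

```
case/control: 108 of 108 gene-cohort tests significant and up
GFR: median r = -0.62 (100% of correlations negative)
ORA of module program1: top set program1 (p_adj = 5.8e-45)
```

The same chain is available as a single call,
`run_pipeline(demo_config(seed = 1))`, which writes stamped TSV/GMT
outputs and a JSON manifest.

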