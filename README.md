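# kgdx — knowledge-graph embedded clinical indicators for disease prediction

Routine physical-examination panels (glucose, lipids, liver enzymes, ...)
carry diagnostic signal that clinicians read *relative to reference ranges*:
what matters is not the raw number but how far it sits outside the normal
interval. `kgdx` builds that medical knowledge into a prediction model:

1. **Knowledge graph** — each indicator's measurement axis is discretized
   into value entities, and every (indicator, value) pair becomes a triple
   *(indicator, severity band, value)*, where the band is one of seven
   ordered categories from *severely low* to *severely high* around the
   reference interval `[low, high]` (e.g. *(triglycerides, normal,
   0.45 mmol/L)*).
2. **Translational embeddings** — entities and the seven band relations are
   embedded with TransE, TransH, or TransR so that `l_h + l_r ≈ l_t`,
   trained by margin-ranking with negative sampling and evaluated by link
   prediction (Mean Rank, Hit@10).
3. **Patient encoding** — a record becomes the `k × m` relation matrix with
   column `j` equal to `e_value(j) − e_indicator(j)`; missing values map to
   `<UNK>`, off-grid values to `<HIGHEST>`/`<LOWEST>`.
4. **Classifier** — two stacked self-attention layers
   (`V · softmax(KᵀQ/√D_k)`, column-normalized), convolution filters of
   window widths 2/3/4 (100 each) with max-over-positions pooling, and a
   two-unit softmax output trained with cross-entropy.

The package also provides SMOTE rebalancing, stratified k-fold
cross-validation, attention-weight export for interpretability, a synthetic
cohort generator with a band-driven disease rule (so the whole pipeline is
testable without hospital data), and a Bayes-ceiling oracle for recovery
benchmarks. The embedding and classifier training loops are implemented in
RcppArmadillo and are bit-reproducible from a seed.

## Worked example

```r
library(kgdx)

ranges <- list(
  reference_range("triglycerides", 0.45, 1.81, "mmol/L"),
  reference_range("fasting_glucose", 3.9, 6.1, "mmol/L")
)
band_of(7.1, ranges[[2]])
#> [1] "generally_high"

graph <- build_graph(ranges)
graph$catalog
#> <entity_catalog> 2 indicators, 385 value entities, 3 specials, 7 relations

emb <- train_trans(graph$triples, graph$catalog, "TransH", dim = 32,
                   config = trans_config(epochs = 300, seed = 1))
evaluate_ranking(emb, graph$triples[1:50, ], graph$catalog, side = "head")
#> <ranking_result> MR = 1.70, Hit@10 = 98.0% (N = 50)

E <- encode_record(list(triglycerides = 2.9, fasting_glucose = NA),
                   graph$catalog, emb)
dim(E)   # k x m relation matrix; the glucose column uses the <UNK> entity
#> [1] 32  2
```

A Mean Rank of 1.70 means the true indicator is essentially always the
best-scoring head among all 390 entities; Hit@10 is the percentage of test
triples ranked in the top ten.

End to end on the synthetic benchmark cohort (4000 patients, 11 indicators,
3 causal indicators whose elevation drives a deterministic label):

```r
spec <- strong_signal_spec(seed = 7)
syn <- gen_ranges(spec$m, seed = 7)
cohort <- gen_cohort(syn, spec)
ex <- run_experiment(syn, cohort$patients, model = "TransH", dim = 32,
                     trans_cfg = trans_config(epochs = 100),
                     sac_cfg = sac_config(epochs = 30),
                     split = "holdout", seed = 7)
ex
#> <kgdx_experiment> TransH/knowledge encoder, holdout split
#>   link prediction: MR 1681.1, Hit@10 0.0%
#>   classification: accuracy 0.9363, recall 0.9202, F1 0.9354

expected_bayes_accuracy(cohort)   # ceiling of any classifier on this cohort
#> [1] 0.9965
```

The classifier recovers the band-driven rule to within a few points of the
Bayes ceiling from the knowledge encoding alone. (Link-prediction ranks on
this larger graph are dominated by the hundreds of near-correct value
entities per band — see the methods vignette.)

A thin command-line front end over the same functions is available at
`inst/cli/kgdx.R` (`build-kg`, `simulate`, `run` subcommands).

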