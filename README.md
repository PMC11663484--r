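# metannot

Interpretable annotation of unstructured biomedical metadata to controlled
ontology terms.

Public repositories such as GEO describe samples and studies in free text,
which makes the data hard to find and reuse: nothing links "Primary tumor,
left lung, RNA-seq" to the tissue term it obviously describes. `metannot`
trains one interpretable classifier per disease or tissue/cell-type
ontology term (MONDO, Uberon/CL) on curated examples and then scores any
plain biomedical text — including text whose informative words were never
seen during training. It is aimed at curators and data-reuse pipelines
that need per-term probabilities *and* an explanation of where each
probability came from.

## The model

A preprocessed document is a TF-IDF vector over entity features (words,
phrases, or clusters of embedding-similar words/phrases):

    x_df = tf(d, f) * idf(f),   idf(f) = ln((1 + N) / (1 + df(f))) + 1,

with L2 row normalization and training-time IDF frozen for prediction.
For every ontology term *t*, a one-vs-rest elastic-net logistic regression

    min_b  -(1/N) Σ_d ℓ(y_dt, b0 + x_d'b) + λ [ α|b|₁ + (1-α)/2 |b|₂² ]

is fit (no class re-weighting — the per-term prior is part of the signal),
with (C, α) tuned by stratified CV on mean auPRC. The L1 component prunes
the model down to the words that mark the term, so the largest positive
coefficients read as a keyword list.

At prediction time, an entity absent from the training features is
embedded (pluggable deterministic backend; a word2vec-format text table by
default) and mapped to the training feature with the highest cosine
similarity; every such mapping is recorded in a trace so the final
probability is explainable token by token. Evaluation utilities implement
prior-normalized `log2(auPRC/prior)`, pairwise term-discrimination auROC
with semantic-similarity bins, term-name ablation, ontology information
content, and shuffle-normalized accuracy/F1.

## Worked example

The package ships a deterministic synthetic-corpus generator so the whole
pipeline runs offline: 500 GEO-like training documents, five terms with
planted keywords at priors from 0.10 down to 0.02, and a test set whose
positives carry only *synonyms* of the keywords, never the keywords
themselves.

```r
library(metannot)

fx     <- generate_corpus(fixture_spec(seed = 1))
prov   <- table_provider(fx$embeddings)
space  <- build_feature_space(fx$train, "word", min_df = 2, provider = prov)
x      <- tfidf_transform(fx$train, space)
models <- fit_term_models(x, fx$train_labels)

summary(models[["TERM:0001"]], k = 5)
#> Elastic-net logistic term model
#>   term:        TERM:0001
#>   features:    215 (13 nonzero)
#>   train prior: 0.1 (50 of 500 positive)
#>   hyperparams: C = 1, alpha = 0.5
#>   top predictive features:
#>     kw1a                 6.6168
#>     kw1c                 5.7558
#>     kw1b                 4.6789
#>     word102              0.1721
#>     word043              0.1637
```

The three planted keywords dominate the coefficients — the model has
learned exactly the signal that was planted, and the near-zero background
weights show the elastic net discarding noise. Scoring a test document
that contains only unseen synonyms:

```r
doc <- fx$test[[23]]                     # a positive written with synonyms
vt  <- vectorize_new(doc, space, provider = prov)
explain_prediction(models[["TERM:0001"]], vt$vector, trace = vt$trace,
                   instance_id = doc$instance_id)
#> <prediction TE0023 -> TERM:0001: p = 0.3662>
#>   kw1a                 +0.8633
#>   kw1c                 +0.7664
#>   kw1b                 +0.6462
#>   word002              +0.0252
#>   word059              +0.0201
#>   OOV mappings:
#>     syn1a -> kw1a (cos 0.902)
#>     syn1b -> kw1b (cos 0.949)
#>     syn1c -> kw1c (cos 0.924)
```

The trace shows the mechanism: each unseen synonym was routed to its
nearest training keyword by embedding cosine similarity, and those mapped
features carry essentially all of the logit. The probability (0.37) is far
above the 0.10 prior, which is what ranking cares about. Evaluating all
five models on the full synonym-only test set:

```r
vc <- vectorize_corpus(fx$test, space, provider = prov)
evaluate_models(models, vc$matrix, fx$test_labels, g = fx$ontology)
#>     term_id n_pos prior auprc log2_auprc_over_prior ic
#> 1 TERM:0001    20  0.10     1              3.321928  3
#> 2 TERM:0002    16  0.08     1              3.643856  3
#> 3 TERM:0003    12  0.06     1              4.058894  3
#> 4 TERM:0004     8  0.04     1              4.643856  3
#> 5 TERM:0005     4  0.02     1              5.643856  3
```

auPRC 1 means perfect ranking; `log2(auPRC/prior)` equals its theoretical
maximum `-log2(prior)` for every term, and the `ic` column is each term's
information content (3 bits: leaves of an 8-term toy ontology). Disabling
the mapping (`min_sim = 1.0`) collapses auPRC to the prior — the embedding
projection is causally responsible for the transfer.

See the vignette (`vignettes/annotating-metadata.Rmd`) for the full
account of the model, the tunable parameters, and the evaluation
methodology.

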