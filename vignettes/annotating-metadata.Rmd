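---
title: "Annotating biomedical metadata to ontology terms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating biomedical metadata to ontology terms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metannot)
```

## The problem

Public omics repositories describe samples and studies in free text. A
record might say "Primary tumor, left lung, adenocarcinoma, RNA-seq" — a
human reads "lung" and "adenocarcinoma" instantly, but nothing in the
record is machine-queryable against controlled vocabularies such as the
Uberon/CL tissue and cell-type ontologies or the MONDO disease ontology.
`metannot` trains one binary classifier per ontology term that maps such
free text to a probability of the term applying, keeps the classifiers
interpretable (the features *are* words), and copes with prediction-time
vocabulary the training corpus never saw.

Two description levels are modelled separately, because they carry
different information: **sample-level** records (per-specimen; reliably
state the tissue of origin) and **study-level** records (per-experiment
summaries; state the disease under study). Tissue/cell-type models are
meant for sample text and disease models for study text, but any plain
text can be scored.

## The model

For a corpus of $N$ preprocessed documents, each document $d$ is
represented as a TF-IDF vector over a fixed set of entity features
$f = 1, \dots, p$:

$$x_{df} = \mathrm{tf}(d, f) \cdot \mathrm{idf}(f), \qquad
  \mathrm{idf}(f) = \ln\!\frac{1 + N}{1 + \mathrm{df}(f)} + 1,$$

followed by L2 normalization of each row ($x_d \mapsto x_d / \lVert x_d
\rVert_2$; an all-zero row stays zero). $\mathrm{tf}$ is the raw count of
the feature's member entities in the document and $\mathrm{df}$ the number
of documents containing any member. The smoothed-log IDF variant and the
L2 row norm are fixed bit-exactly so that models are reproducible; the
corpus-level IDF weights are **frozen at training time** and reused
verbatim at prediction, which is required for model compatibility.

Entity features come in four types: single **words**, contiguous
multi-word **phrases** (n-grams, default $n \in \{2,3\}$), and **clusters**
of embedding-similar words or phrases, each cluster acting as one feature
whose tf is the summed count of its members and whose embedding is the
member centroid. Clusters are built by average-linkage agglomerative
clustering on cosine distance, cut at $1 - s$ for a similarity threshold
$s$ (default $0.9$). Candidate entities must appear in at least `min_df`
documents (default 2).

For each ontology term $t$, a one-vs-rest logistic regression with an
elastic-net penalty is fit:

$$\hat\beta_t = \arg\min_\beta \; -\tfrac1N \sum_d \ell(y_{dt},
  \beta_0 + x_d^\top \beta) + \lambda \left[ \alpha \lVert \beta \rVert_1
  + \tfrac{1 - \alpha}{2} \lVert \beta \rVert_2^2 \right].$$

Logistic regression is used because its probabilities are reasonably
calibrated; the L1 component prunes the feature set down to the words that
genuinely mark the term, which is what makes the model readable — the
largest positive coefficients are, in effect, the term's keyword list
(`top_features()`, `plot()`). Regularization strength is expressed as the
familiar inverse-strength $C$, converted internally to the solver's
per-observation scale $\lambda = 1/(nC)$.

**No class re-weighting or resampling is applied.** Ontology terms are
extremely imbalanced (a rare disease may have ten positive studies among
thousands), and resampling would distort the probability estimates that
downstream ranking relies on; the per-term prior is part of the signal.

### Hyperparameter tuning

`tune_hyperparameters()` runs stratified $k$-fold cross-validation
(default $k = 5$, reduced to the positive or negative count when smaller,
so every fold retains both classes) over a grid of $C \in \{0.01, 0.1, 1,
10\}$ and $\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$, selecting the
combination with the highest mean auPRC across folds; ties keep the
earliest grid row, and fold assignment is deterministic given the seed.
Terms with fewer than two positives (or negatives) cannot be tuned and
fall back to the package defaults $C = 1$, $\alpha = 0.5$ — rare terms are
still modelled, not dropped.

### Out-of-vocabulary projection

New text routinely contains informative entities absent from the training
features ("gastrectomy" when the model learned "gastric"). At prediction,
every entity is first resolved by exact membership; an unseen entity is
embedded by a pluggable deterministic backend and mapped to the training
feature with the highest cosine similarity of embeddings, provided that
similarity reaches `min_sim` (default 0 — always map to the nearest
feature; raise it to suppress far-fetched mappings). Exact ties (within
$10^{-12}$, since mathematically equal cosines computed along different
code paths differ in the last ulp) resolve to the lexicographically
smallest feature id, so results never depend on storage order. Every
mapping is recorded in a trace `(entity, feature, similarity)` attached to
the prediction, so each probability can be explained all the way back to
the input words. Multi-word spans without their own embedding are embedded
as the mean of their known word vectors. The default backend is a
word2vec-format text table (`load_embedding_table()` +
`table_provider()`); any object honouring the provider contract
(deterministic `embed()`, fixed dimension, may report unknown) can stand
in, e.g. a transformer encoder.

## Evaluation methodology

* **Prior-normalized auPRC.** auPRC is computed as average precision (no
  trapezoidal interpolation, which is optimistic); tied scores are
  processed as one block so that every positive in the block receives the
  block-end precision — with all scores tied the result is exactly the
  prior. Performance is reported as $\log_2(\mathrm{auPRC}/\mathrm{prior})$:
  0 is random, $-\log_2(\mathrm{prior})$ is perfect, and terms with
  different imbalances become comparable. A degenerate all-positive task
  is defined as 0.
* **Pairwise term discrimination.** For a pair of terms, the focal term's
  model scores instances of both; the auROC (Mann–Whitney $U/(n_A n_B)$,
  ties half) measures whether its own instances outrank the competitor's.
  Pairs can be stratified into equal-count quantile bins of semantic
  similarity (cosine of term-name embeddings, `similarity_bins()`);
  instances labelled to both terms are excluded.
* **Term-name ablation.** `term_name_ablation()` deletes every contiguous
  token subsequence equal to the tokenized term name or a synonym,
  scanning greedily left to right and iterating to a fixed point (removal
  can butt two halves of a mention together), which guarantees
  idempotence. Retraining on the ablated corpus asks whether models depend
  on literal term mentions or on surrounding context.
* **Shuffle-normalized accuracy/F1.** For external corpora evaluated by
  top-$k$/bottom-$k$ calls (`topk_calls()`, default $k = 10$), observed
  accuracy and F1 are divided by their means over label-preserving
  permutations **of the predicted calls** (1000 by default, seeded) and
  log2-transformed; 0 is chance. Permuting predictions rather than truth
  matters for F1 when call counts are unequal; predictions were chosen
  because they are the quantity under test. An undefined F1 is taken as 0
  with additive smoothing $\varepsilon = 10^{-9}$ before the ratio.
* **Term specificity.** The information content of a term is
  $-\log_2(|\mathrm{desc}(t)|/|T|)$ with descendants **including the term
  itself** — otherwise leaves would have infinite IC — over is-a edges
  only (`part_of` can be enabled). Base 2 matches the bits-style log2
  metrics used elsewhere in the package.

## Text normalization choices

URLs are removed first (scheme and `www.` spans), the text is lowercased,
and maximal runs of `[a-z0-9]` become tokens; everything else is a
separator. This is deliberately simple and language-agnostic: it is
reproducible, keeps digit-bearing tokens like "covid19" intact, and makes
tokenization idempotent. A compact built-in English stopword list is
removed by default (configurable); no stemming or lemmatization is applied
— inflected forms are distinct features and the elastic net decides which
ones matter. Field selection per level defaults to `title, source_name,
characteristics, description` (samples) and `title, summary,
overall_design` (studies); the choice of fields measurably affects
classifiers, so it is exposed in every reader.

## The synthetic benchmark

`generate_corpus()` produces a fully offline testbed that emulates the
statistical structure the pipeline must handle, not the semantics of real
metadata: short documents over a Zipf-skewed background vocabulary,
per-term planted keywords present in each positive independently with
probability 0.8, extreme and **exactly allocated** class imbalance
(`round(prevalence * n)` positives, never Bernoulli draws, so a 10/500
task is constructible deterministically), a toy rooted ontology, and a toy
embedding table in which each prediction-time synonym lies within cosine
0.9 of its training keyword and at most 0.3 from every other (enforced by
rejection resampling). The default study conditions are five terms with
training priors 0.10, 0.08, 0.06, 0.04 and 0.02 over 500 training
documents — the rarest term has 10 positives — with three keywords and
three synonyms per term, a 200-word background vocabulary, and
negative-binomial document lengths (mean 30, dispersion 8). Test positives
carry **only synonyms**, never the training keywords, so held-out transfer
isolates the embedding-mapping mechanism.

What passing on this benchmark shows: the TF-IDF algebra, the solver, the
OOV mapping and the metrics behave correctly under realistic imbalance and
vocabulary shift. What it does not show: robustness to real GEO field
semantics, misspellings, negation ("no tumor"), mislabelled gold
standards, or genuinely ambiguous terms — those require curated corpora.

## Numerical choices and degenerate inputs

* Solver: glmnet coordinate descent, threshold $10^{-7}$, max $10^5$
  passes, warm-started along a short decreasing lambda path ending at the
  target. On near-separable data a weak pure-L1 penalty can defeat any
  threshold; fits retry with a relaxed threshold (two decades at a time,
  with a warning) and, during tuning, a candidate whose solver still fails
  is disqualified from the grid rather than aborting the search. A
  directly requested fit that cannot converge is an error.
* Empty documents, documents with no known entity, and fully unmappable
  documents yield zero vectors (probability `plogis(intercept)`), never
  NaN or errors.
* Quantile bins assign ranks stably (ties keep enumeration order, the
  earlier pair taking the lower bin), so bin sizes differ by at most one.
* Every stochastic routine (fold assignment, shuffles, the generator)
  takes an explicit integer seed and restores the caller's RNG state.

## Problem sizes used by the shipped checks

The test-suite and `scripts/acceptance.R` run the generator at its default
conditions (500 training documents, five terms, priors down to 10/500),
with held-out corpora of 500 documents drawn from the same process under a
disjoint seed for keyword-recovery and ablation analyses, and 1000 test
documents for the synonym-transfer experiment — the larger test set keeps
at least 20 positives for the rarest term, which is what makes the
"collapses to the prior when mapping is disabled" control statistically
stable. Keyword recovery is replicated over 20 seeds.

## Limitations

One linear model per term means cross-term structure is only used through
optional label propagation (`propagate_labels()`, true-path rule), not
joint training. Probabilities are not recalibrated across terms. Phrase
extraction is plain n-grams; no character n-grams or subword units, so a
misspelled keyword is invisible unless the embedding backend knows it. The
OBO reader handles `[Term]` stanzas with is-a (optionally part-of)
relations; it is not an OWL reasoner.
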