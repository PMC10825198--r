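---
title: "Methods: classifying seizure semiology text into epileptogenic-zone categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying seizure semiology text into epileptogenic-zone categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezloc)
```

## The problem

In drug-resistant focal epilepsy, surgery can abolish seizures if the
epileptogenic zone (EZ) — the cortical region whose removal stops the
seizures — is identified correctly. During presurgical work-up,
epileptologists watch long-term video-EEG recordings and write free-text
descriptions of each seizure's semiology: the observable signs and their
chronological evolution. These descriptions carry localizing and
lateralizing information, but reading them reliably requires years of
experience.

`ezloc` implements a shallow-learning pipeline that turns such free-text
seizure descriptions (Italian clinical prose, in the bundled resources)
into numerical representations and classifies them along three binary
axes:

* **side** — left vs right hemisphere (positive class `left`);
* **localization** — temporal vs extra-temporal (positive class
  `extra_temporal`);
* **sublocalization** — frontal vs posterior origin, defined only for
  extra-temporal patients (positive class `posterior`).

Because real seizure-description corpora are intimately personal clinical
records and are not publicly shareable, the package ships a synthetic
corpus generator that reproduces the *structural* statistics such corpora
exhibit, so that every stage of the pipeline is exercised and tested
end-to-end on data that can be regenerated from a seed.

## Text normalization

Raw descriptions pass through a fixed four-step normalization
(`clean_text()`, `tokenize()`, `lemmatize()`, `remove_stopwords()`):

1. **Cleaning.** Bracketed spans (internal annotations, electrode
   montages) are deleted with their brackets; then any token containing a
   digit is deleted whole (dates, times, electrode names such as "B2");
   remaining punctuation becomes whitespace; clinical abbreviations are
   expanded (`aass` → "arti superiori", `aoo` → "occhi aperti", map
   extensible via a two-column TSV); the result is lowercased. The order
   matters and is fixed: brackets are removed first so punctuation
   removal cannot destroy the span delimiters. The whole-token digit rule
   was chosen over deleting digit characters only, because the noise
   being targeted (dates, electrode labels) is token-shaped; this is the
   one place where a character-level alternative would change the token
   stream, and the choice is isolated in `clean_text()` should a
   sensitivity analysis be wanted. Accented letters are preserved — the
   corpora are Italian.
2. **Tokenization** by whitespace.
3. **Lemmatization** through a pluggable dictionary (surface form →
   lemma) with identity fallback. A full morphological tagger is a
   third-party product; a dictionary lexicon keeps the package
   self-contained and deterministic, and the lexicon file can be replaced
   wholesale by a site's own resource.
4. **Stop-word removal** against a pluggable list (articles,
   prepositions, auxiliaries).

Two corpus-level exclusion filters (`filter_corpus()`) mirror how seizure
corpora are assembled: descriptions with fewer than 20 tokens — counted
*after* cleaning but *before* stop-word removal, anchoring the rule to
the cleaning phase — and descriptions that refer back to previous
seizures rather than describing one. Reference detection is a
configurable lemma co-occurrence pattern (default: `simile` and
`precedente` both present). In clinical practice this exclusion is an
editorial judgement; automating it requires auditability, so every
excluded id is recorded in the filter report and the report totals always
reconcile (`n_input = retained + short + reference`).

## Document representations

Three representations feed the classifiers.

**Bag of words (`bw`).** A mixed n-gram count representation: character
n-grams (n = 2, 3), extracted within tokens so fragments never span a
word boundary, and word n-grams (n = 1..4). The total feature budget
(100, 200 or 300 in the standard sweep) is split 20% character / 80%
word; within each group candidates are ranked by total corpus occurrence
count with lexicographic tie-breaks, and the top of each budget is
retained. Character fragments buy robustness to the misspellings endemic
to hurriedly written clinical notes; word n-grams preserve local context
that a pure unigram model discards. Counts are raw — scaling happens in
the experiment loop's standardization step. The inventory is fitted on
learning-set documents only.

**Embedding pooling (`mean`, `tfidf`).** A skip-gram
negative-sampling word embedding (`train_embedding()`) is trained on the
learning-set seizure descriptions, optionally augmented with unlabeled
EMR anamnesis excerpts whose fuller sentences improve the contexts the
model sees. Defaults follow the tuned operating point for this corpus
scale: dimension 100, 10 negative samples, 300 epochs, window 3, minimum
word count 2 (dropping hapaxes and one-off misspellings). Skip-gram was
chosen over CBOW as the default because it behaves better on small
corpora; both are implemented and the choice is a parameter. Training is
single-threaded with an internal deterministic RNG: a fixed seed gives
bit-identical vectors. Documents are pooled either by the unweighted
mean of their in-vocabulary token vectors (`pool_mean()`), or by a
TF-IDF-weighted average (`pool_tfidf()`) with smoothed idf
`ln((1+N)/(1+df)) + 1` and weight normalization by the total weight —
the smoothing avoids division by zero, gives unseen terms a finite
default, and makes the tfidf pooling reduce exactly to the mean pooling
under uniform weights. Out-of-vocabulary tokens are skipped; an all-OOV
document maps to the zero vector with a logged warning rather than an
error, so held-out transforms can never crash mid-experiment.

**Intrinsic evaluation.** Before a trained embedding is trusted to build
document vectors, `eval_embedding()` inspects it directly: nearest
neighbours by cosine similarity (`most_similar()`), analogy solving by
the additive 3CosAdd rule with query-word exclusion (`solve_analogy()` —
the additive rule formalizes the proportional analogy a : a\* = b : b\*,
and the multiplicative variant is deliberately out of scope), and
outlier detection as the word with the lowest mean cosine to the rest of
its group (`detect_outlier()`). All ties break lexicographically, making
every evaluator a pure function of the vectors.

## The experiment protocol

`run_nested_cv()` implements repeated stratified nested
cross-validation over seizure documents:

* the data are shuffled with the repetition seed (defaults `0, 1, 2` —
  the repetition index), then split into k = 10 stratified outer folds;
* inside each outer fold, the representation is refit on the training
  portion only (n-gram inventory and idf table are fold-local; the
  embedding itself is trained once per learning set, as the two-dataset
  design prescribes — a known, documented source of mild optimism
  inherited from that design);
* features are standardized (per-feature center/scale, fitted on the
  training portion; constant features get unit scale);
* hyperparameters are selected by an inner 10-fold stratified grid
  search maximizing weighted F1, then the winner is refit on the full
  training portion and scored on the test fold.

Folds stratify over documents, not patients, treating each seizure
description as an independent event (different ictal episodes, often
different documenting clinicians); a patient-grouped split is available
at the corpus level via `split_by_patient()`, which is also how the
learning/holdout division is made — whole patients, never individual
seizures, so no patient straddles the generalization boundary.
`evaluate_holdout()` refits each representation/model combination on the
full learning set and scores it once on the held-out patients, asserting
via content digests that no fitted object changed when holdout data
passed through it.

Four classifier families are compared: sparse L1-penalized logistic
regression (glmnet; the inverse-regularization grid
{0.01, 0.1, 1, 10, 100} maps to `lambda = 1/(C·n)` and is fitted along a
warm-started decreasing lambda path with `thresh = 1e-5` — the
convergence tolerance conventional for classification solvers — which is
orders of magnitude faster than cold fits at tiny penalties and equally
deterministic), and SVMs with linear, RBF and degree-3 polynomial
kernels (e1071/libsvm; cost grid {0.01, 0.1, 1, 10, 100}, RBF width grid
of the scale heuristic `1/(p·var(x))` plus {1e-3, 1e-2, 1e-1, 1}). The
grids are standard log-spaced ranges and are configurable per
`model_spec()`.

**Metrics.** All results are reported as accuracy plus support-weighted
precision, NPV, specificity and F1 (`compute_weighted_metrics()`), with
the fixed positive classes `left` / `extra_temporal` / `posterior`. A
ratio with zero denominator contributes zero and flags the fold record —
this occurs only in degenerate folds missing a class. Per-trial medians
over folds, then the mean and SD of those medians across repetitions,
are the headline aggregates; confusion counts are summed across folds
and averaged across repetitions.

## The synthetic corpus generator

`generate_corpus()` emulates the structure of a seizure-description
corpus without any clinical content:

* **Patient grouping.** Seizure counts per patient follow a negative
  binomial truncated to [1, 17] with parameters (mu = 3.506,
  size = 0.727) obtained by moment-matching the truncated distribution
  to mean 4.39 and SD 3.63 — the documented moments of such corpora.
* **Labels.** Patient-level draws: P(left) = 0.5,
  P(extra-temporal) = 0.58, P(frontal | extra-temporal) = 0.64,
  mirroring the reported seizure-level class proportions.
* **Signal.** Each task has three-lemma marker vocabularies per class,
  disjoint between opposing classes. A content-token slot becomes a
  marker with probability `marker_rate × signal` (defaults 0.12 × π); at
  π = 0 no marker is emitted and the text is independent of the labels,
  while at π = 1 every labeled document is guaranteed at least one
  marker per task, making the construction exactly linearly separable.
* **Style and noise.** Five clinician style profiles
  (gamma-perturbed Zipf weights over a 65-lemma background vocabulary)
  model writer variability; inflected surface variants exercise the
  lemmatizer; raw-text noise is injected at configurable per-document
  rates — digit dates, bracketed annotations like "(elettrodo B2)",
  bare electrode names, clinical abbreviations — plus a 2% per-token
  adjacent-character-swap misspelling rate.

`generate_emr_corpus()` produces the unlabeled auxiliary corpus: 5–20×
longer documents over the same background vocabulary with fuller
sentence structure and, by construction, no marker lemmas anywhere —
emulating the editorial removal of conclusion sections that would reveal
the EZ location. `plant_filter_violations()` rewrites chosen documents
into known filter violations so the exclusion filters can be checked
against ground truth, and `generate_analogy_corpus()` plants an additive
analogy through co-occurrence templates (shared base contexts plus a
common relation context for the second member of each pair), so the
embedding trainer itself — not hand-written vectors — is exercised by
the analogy tests.

What the generator deliberately does **not** model: clinically plausible
semiology, discourse structure, temporal ordering of signs,
within-patient correlation of wording beyond the style profile, and
label noise. Passing tests on this corpus therefore demonstrate that the
pipeline's machinery is correct and leak-free and that it recovers
planted signal of known strength; they say nothing about how much signal
real semiology carries — on real corpora, lateralization in particular
is known to be much harder than region localization.

## Numerical and design choices

* **Budget rounding**: the 20% character budget rounds half away from
  zero; exact for 100/200/300.
* **Tie-breaks**: every ranking (n-gram frequency, cosine neighbours,
  analogy and outlier argmax, inner-grid winner) resolves ties
  deterministically (lexicographic, or first in grid order).
* **Determinism**: generation, preprocessing, representation fitting and
  the glmnet/libsvm solvers are deterministic given the configuration
  seeds; the embedding trainer is single-threaded by design, trading
  wall-clock speed for bit-reproducibility.
* **Degenerate inputs**: empty cleaned documents yield empty token lists
  and zero feature rows; all-OOV documents pool to zero vectors with a
  warning; single-class inner folds are skipped in the grid-search mean;
  undefined metric ratios contribute zero with a flag.
* **Problem sizes in the test-suite**: the end-to-end signal-response
  check runs 120 patients (~530 documents), three repetitions of 10-fold
  nested CV per signal level, with embedding epochs at 50; these sizes
  make the suite complete in minutes while leaving every code path
  identical to a full-scale run, where the 300-epoch default applies.

## Known limitations

* The lemma lexicon and stop list are deliberately small bundled
  defaults; production use on real Italian clinical text should plug in
  a full lexicon and stop list via `normalization_resources()`.
* The embedding is trained once per learning set rather than per fold;
  CV estimates for `mean`/`tfidf` inherit the mild optimism of that
  design.
* Binary tasks only; multi-region localization and calibration are out
  of scope.
* The generator's marker mechanism makes class signal lexical and
  local; it cannot measure sensitivity to syntax-level or
  discourse-level cues.
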