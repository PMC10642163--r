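---
title: "Referral triage with Clinical Prioritisation Criteria: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Referral triage with Clinical Prioritisation Criteria: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpctriage)
```

## The triage model

A referral is a free-text letter requesting specialist outpatient
assessment. Triage assigns it an urgency category — 1 (seen within a
month), 2 (three months) or 3 (a year) — guided by Clinical
Prioritisation Criteria (CPC): per-condition, per-age-group documents
whose text is split into the findings that warrant each category.
`cpctriage` treats triage as two coupled text problems:

1. **Which condition?** If the referral carries a CPC label that
   matches a catalogued condition name for its age group (exact match
   after lowercasing, punctuation stripping and whitespace collapsing —
   deliberately no fuzzy matching, which could silently re-label a
   referral), the label is used as given. Otherwise the condition is
   predicted from the referral's medical terms. Age group is resolved
   from the patient's completed years at the submission date, with
   under-16 paediatric and 16-and-over adult (the common clinical
   convention; the cutoff is configurable).
2. **Which category?** The resolved condition's per-category text
   units, in one of three representations, are scored against the
   referral's terms with a single metric; similarities are maximised,
   distances minimised, and exact ties break toward the more urgent
   (lower) category — the patient-safety-conservative choice.
   Conditions that mandate a category (`fixed_category`, e.g. head and
   neck mass is always category 1) bypass the scoring.

The three CPC text representations are `criteria_words` (the cleaned
criteria document), `medical_terms` (NER-extracted terms) and
`keywords` (clinician-curated per-category keywords). For condition
prediction the three category units are concatenated into one combined
unit, always in category order 1, 2, 3: bag-of-terms metrics are
order-insensitive, but the edit-distance metric operates on joined
strings, so the order is pinned.

### Preprocessing

Referral text and criteria text pass through the same pipeline so that
their vocabularies stay comparable: lowercase; non-letters become
token breaks; stopwords (Snowball English list, replaceable) are
dropped; tokens are Porter-stemmed. The Porter (1980) algorithm is
implemented in the package and pinned so token-level examples are
stable. Medical-entity records (the output shape of a clinical NER
service: text, category, type, confidence in [0, 1]) are filtered to a
whitelist of diagnosis, medication, procedure and anatomical-direction
types, keeping entities with confidence ≥ 0.5 (boundary inclusive). A
deterministic longest-match dictionary extractor
(`extract_entities_lexicon()`) satisfies the same contract so the
pipeline runs without any cloud service; any extractor producing the
same record shape can be plugged in. A referral whose entity path
yields no tokens falls back to its cleaned raw text and is flagged
`degraded`, so similarity is never computed on an empty document while
any text exists.

### Condition predictors

**Similarity ensemble.** Each condition's combined text is scored as
`w1·Cos − w2·Euc + w3·Jac − w4·NLev`: similarities added, distances
subtracted. Cosine and Euclidean operate on raw term-frequency vectors
over the union vocabulary (no TF-IDF, no length normalisation —
deliberately plain frequency vectors), Jaccard on token sets, and the
Levenshtein term on the space-joined token strings, normalised by the
maximum possible edit distance `max(|a|, |b|)` so it lies in [0, 1].
The alternative `sum_len` normalisation (dividing by `|a| + |b|`, the
form the ensemble's closed formula prints) is retained as an option;
`max_len` is the default because it is the true maximum distance. Note
one structural caveat, flagged rather than repaired: Cos, Jac and NLev
are bounded but the raw Euclidean term is not, so with comparable
weights the Euclidean term can dominate on long documents. Weights are
estimated as each metric's category-assignment accuracy on the
labelled referrals (`estimate_weights()`), defaulting to equal weights
when no estimate is supplied.

**Token-level Levenshtein.** The single-metric Levenshtein ranking is
also offered at 1-gram granularity (`token_levenshtein_dist()`): every
token of one sequence is matched to its nearest token of the other
under normalised edit distance, and the two directed mean best-match
distances are averaged (a symmetric Monge–Elkan aggregate). This is
the variant that carries the clinical motivation for edit distance —
"blockednose" still nearly matches "blocked" — at the level where the
effect lives. A single edit distance over whole joined documents
dilutes exactly that signal: on synthetic corpora with a 0.3 per-term
typo rate the joined-document ranking collapses to near-random while
the token-level ranking stays essentially exact (the acceptance script
recomputes this margin against the Jaccard ranking). The joined-string
form remains the ensemble's Levenshtein term, as its printed formula
requires.

**KNN.** Unlabelled referrals take a similarity-weighted vote of their
ten nearest labelled referrals under `Euc_sim = exp(−Euc)`. Two
documented reading choices matter here. First, the printed conversion
`1/e^(−Euc)` *grows* with distance, contradicting its own description
as a similarity; it is implemented as `exp(−Euc)` (an erratum
correction). Second, "neighbours with similarity larger than 0":
`exp(−d)` is never exactly zero, so the rule is read at the token
level — a labelled referral sharing no vocabulary with the query has
zero similarity and cannot vote. Without that reading, many equidistant
zero-overlap rows of one frequent class can outvote the query's few
genuinely similar neighbours. A query with no token-sharing labelled
neighbour returns a no-prediction sentinel and the referral is flagged
unresolvable rather than guessed.

**Supervised and semi-supervised.** Features are unigram+bigram counts
of medical terms, dropping n-grams seen in fewer than 30 referrals or
more than 80% of them (the defaults for a corpus of thousands; both
thresholds must be lowered for small corpora, and `build_features()`
fails loudly when the vocabulary empties). The learner is an opaque
contract: fit, predict, per-class confidences summing to 1. The
default backend is regularised (multinomial) logistic regression via
glmnet, chosen because it is deterministic, sparse-friendly and fast;
linear SVM (e1071) and random forest (ranger) satisfy the same
contract. Three package-authored multiclass strategies wrap any binary
backend: one-vs-rest, one-vs-one (n(n−1)/2 pairwise problems), and
error-correcting output codes (unique binary code per class, one
problem per non-constant bit, decoding by L1 distance between
predicted bit probabilities and the codes). Three glmnet-specific
choices are the package's own: the model is fitted along glmnet's own
regularisation path and interpolated at the requested lambda (short
hand-picked paths break the warm-start optimiser); classes with a
single training example have their row duplicated once (the fit
requires two observations per class); and class intercepts are off by
default, because with a small, heavily imbalanced labelled pool the
intercepts act as class priors and swamp rare conditions that their
own vocabulary identifies perfectly — set
`hyperparameters = list(intercept = TRUE)` for prior-sensitive
behaviour. Self-training wraps any of these: train on the labelled
pool, pseudo-label unlabelled rows whose top-class confidence reaches
0.75 (deliberately above the plain 0.5 decision threshold), and repeat
until an iteration adds nothing or `max_iter` (default 10) is reached.
The labelled pool grows monotonically and every pseudo-label is
logged with its iteration and confidence.

**Seeded k-means.** One cluster per condition (k = 20 adult, 13
paediatric by default), Lloyd iterations with Euclidean assignment and
mean updates, centroids initialised from each condition's medical
terms and keywords vectorised into the corpus feature space — so
cluster membership *is* a condition prediction. Convergence is
declared when the largest centroid movement falls below `tol` (1e-4;
`max_iter` 300 — conventional values), an emptied cluster freezes its
centroid at the previous position, assignment ties break toward the
lexicographically smallest condition id, and the recorded
within-cluster sum of squares is non-increasing by construction.

### Feature-space geometry

Two wiring choices protect the feature-space predictors from raw-count
pathologies, and both live in the triage layer, not in the operations
themselves. Document vectors are L2-normalised for KNN and the
(semi-)supervised learners (`normalize_rows = TRUE`): under raw counts
the shortest document is everyone's nearest neighbour. Seeded k-means
keeps raw counts, as its sum-of-squares objective prescribes, but the
catalog seeds are deduplicated and rescaled to the mean document norm:
document-frequency filtering strips rare conditions' vocabulary from
the feature space, and an unscaled low-norm seed sits near the origin
and captures every row. Seeds whose vocabulary is entirely absent from
the corpus are dropped with a warning (they cannot anchor a cluster);
`seeded_kmeans()` itself still rejects zero seeds as an error when
called directly with token seeds.

### Evaluation

Historical categories are a noisy reference — real triage was not
fully consistent with the criteria — so the headline statistic is the
*level of agreement*: the fraction of referrals whose predicted
category equals the historical one, identically the trace of the 3×3
confusion matrix over n. Per-category precision (TP over column sum,
defined as 0 when a category is never predicted) and sensitivity (TP
over row sum) are reported with their unweighted means. Uniform random
ternary prediction agrees at 1/3, the floor against which any method
is read.

## The synthetic corpus generator

No real referral or criteria text is bundled. The generator emulates
the statistical structure the method depends on, with every parameter
fixed in `generator_config()`:

* **Catalog**: 20 adult and 13 paediatric conditions; each receives a
  disjoint core vocabulary of 12 pronounceable pseudo-words (stemmed
  to a fixpoint so the preprocessing pipeline is the identity on
  them), split 4/4/4 across the category units to form `keywords`;
  `medical_terms` adds one morphological variant per core term (a
  2–3 letter suffix, so variants are edit-close to their base but
  distinct tokens); `criteria_words` adds shared filler words — which
  is why it is expected to be the noisiest representation. With the
  default profile the conditions carry the real ENT condition names,
  and adult head and neck mass is marked `fixed_category = 1`.
* **Class imbalance**: sampling weights proportional to the historical
  labelled-corpus frequencies (e.g. adult chronic rhinosinusitis 214
  versus facial nerve palsy 2), including conditions with frequency
  zero that stay predictable but are never sampled; `uniform` and
  `custom` profiles are available. Adult share 0.673, the adult
  fraction of the real corpus.
* **Referrals**: 6–14 terms each; a `signal_fraction` (default 0.6 —
  referral letters carry substantial non-criteria vocabulary) comes
  from the true condition, deterministically split between the true
  category's keyword unit (at least one token whenever any signal is
  drawn, so the noise-free limit is exactly recoverable) and the
  condition-wide variant pool (variant usage is not category-specific
  in real text; this is also what gives same-condition referrals of
  different categories shared vocabulary); the rest is background.
  Signal terms receive one uniformly chosen single-character edit with
  probability `typo_rate` (default 0.05), the simplest mechanism that
  separates edit distance from token overlap.
* **Labels and noise**: each referral carries its condition name as a
  CPC label with probability 0.097; the historical category is
  *re-drawn uniformly* from {1, 2, 3} with probability
  `historical_noise` (default 0.3, chosen once as a realistic level of
  triage inconsistency), so the probability it actually differs is
  two-thirds of that — the semantics that make closed-form agreement
  expectations simple (perfect predictions against noise 0.5 agree at
  0.5 + 0.5/3 = 2/3).
* Dates are consistent with the age group, entity records (confidence
  1.0) accompany every term so both ingestion paths are exercised, and
  the whole corpus is byte-identical under a fixed seed.

What passing tests on this corpus do **not** show: real referrals have
grammar, negation, comorbidities, section structure and OCR noise;
real criteria text overlaps across conditions; real NER confidence
scores are informative rather than constant. Synthetic recovery is a
wiring and invariants oracle, not a clinical performance claim —
which is also why the generator's noise-free limit is required to be
*exactly* recoverable (any wiring error surfaces as agreement < 1).

## Numerical and degenerate-input conventions

* Empty documents: cosine 0, Jaccard of two empty sets 0, Euclidean of
  two empty vectors 0, normalised Levenshtein of two empty strings 0,
  token-level distance 1 when exactly one side is empty. Degenerate
  referrals therefore rank rather than crash.
* All argmax ties break deterministically: ascending condition id for
  CPC prediction, KNN votes and cluster assignment; lower (more
  urgent) category for category assignment.
* Stratified folds deal each class's shuffled members cyclically with
  a pointer carried across classes, so per-class counts *and* total
  fold sizes both differ by at most one — 1,689 rows in 5 folds yield
  a largest test fold of exactly 338.
* Every stochastic step takes an explicit seed; two runs with the same
  configuration are identical.

## Known limitations

* The unbounded Euclidean term can dominate the printed ensemble on
  long documents (see above); the per-metric and token-level rankings
  avoid this.
* Adult and paediatric models are always trained separately; a
  condition present in only one age group is invisible to the other.
* Conditions with no labelled examples cannot be predicted by KNN or
  the supervised families (KNN flags such referrals unresolvable);
  only the similarity and seeded k-means routes can reach them.
* The acceptance-scale corpora run at thousands of referrals (2,000
  for the noise-free recovery check, 5×300 for the robustness
  comparison, n-gram floors lowered accordingly); real-corpus scale
  (tens of thousands) is supported by the same code paths but not
  exercised in the test suite.
* Real-data agreement levels are not reproducible here because the
  clinical corpus is private; the package reproduces the method, its
  self-contained arithmetic and its qualitative orderings instead.
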