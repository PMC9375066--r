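---
title: "Naive-Bayes chemical named entity recognition: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naive-Bayes chemical named entity recognition: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bayescner` recognizes chemical named entities (CNEs) token by token.  The
classification unit is a *fragment of text* (FoT): a target token plus the
`window` nearest tokens on each side within the same document section,
represented as the **set** of distinct uppercase character n-grams of
length 1..`n_max` of its member tokens.  Grams never cross token
boundaries and carry no positional information; the representation is
deliberately sub-lexical, which is what lets the classifier generalize to
chemical names it has never seen (shared morphemes such as `CYCLO`,
`CHLOR`, `OATE`).

Fitting is counting.  For N training FoTs the sufficient statistics are
N_k (FoTs of class k), N_i (FoTs containing gram i) and N_ik, giving the
prior P(C_k) = N_k/N and conditionals P(C_k|g_i) = N_ik/N_i.  Seven
classes are counted: the five base entity types, their union CNE, and
NON_CNE.  A token overlapping no annotated span is a NON_CNE example; the
CHEMDNER types outside the five base classes (IDENTIFIER, MULTIPLE,
NO_CLASS) map to NON_CNE by default (`default_etype_map`), because the
recognizer is trained on the five named chemical types against everything
else.

Scoring uses the bounded B-statistic.  With S0_k = 2 P(C_k) − 1 and the
arcsine transform t(p) = arcsin(2p − 1),

S_k = sin( t(P(C_k)) + mean over informative grams of [ t(P(C_k|g_i)) − t(P(C_k)) ] ),
B_k = (S_k − S0_k) / (1 − S_k S0_k).

The transform bounds each gram's contribution by ±π/2, so conditionals of
exactly 0 or 1 (common with rare grams) cannot dominate, and no epsilon
flooring is needed.  The Möbius form maps (S_k, S0_k) ∈ [−1,1] × (−1,1)
into [−1, 1] and is strictly increasing in S_k, so B is a bounded,
prior-adjusted evidence score.

### Mean versus sum

The classical form of this estimator sums the arcsine terms; summing,
however, makes the argument of the sine wrap around the circle as soon as
descriptor sets grow, and averaging the contributions is the variant with
the better accuracy record for this estimator family.  The package
therefore averages by default, with the terms *centred on the prior* so
that an uninformative gram (P(C_k|g_i) = P(C_k)) contributes exactly zero
and an empty or fully-unseen descriptor set yields B_k = 0, the "no
information" value.  `cner(..., aggregate = "sum")` restores the literal
uncentred sum for comparison.

### Numerical conventions

* Grams unseen in training (N_i = 0) are skipped — equivalently they
  contribute the prior, which centring maps to zero.  Optional Laplace
  smoothing `(N_ik + α)/(N_i + 2α)` is available (`alpha`, default 0).
* The degenerate ratio 0/0 in B (S_k = S0_k = ±1, e.g. a single-class
  model) is defined as 0.
* Arguments of `asin` are clamped to [−1, 1] to absorb floating-point
  spill before the transform.
* Leave-one-out scoring decrements the FoT's own contributions
  (N−1; N_k−1 for its classes; N_i−1 and N_ik−1 for each gram of its
  descriptor set, once per FoT under set semantics, matching the fit) and
  is exactly equivalent to refitting without that FoT — the test suite
  verifies this against a literal retrain to 1e−12.
* Invariant accuracy uses the strict inequality of its defining formula
  (ties count 0); `ties = "midrank"` switches to the Mann–Whitney AUC
  convention.  On tie-free data the two agree exactly.

## Calibration and extraction

Raw B values are calibrated into Pc (probability of belonging to a CNE, a
function of B_CNE) and Pnc (of not belonging, a function of B_NON_CNE) —
two independent one-vs-rest fits, so Pc + Pnc need not sum to 1.  The
default method splits the B axis into `calib_bins = 20` equal-frequency
bins, takes per-bin empirical event frequencies, enforces monotonicity by
weighted pool-adjacent-violators, and interpolates linearly between bin
centres (constant beyond the ends, outputs clipped to [0, 1]).  A
least-squares polynomial alternative (`calib_method = "poly"`, degree 5)
is provided; both are approximations of the same distributional idea, and
published per-character probabilities obtained with other implementations
of the estimator are not expected to reproduce to the third digit.

Extraction keeps tokens with Pc − Pnc strictly above `threshold`
(default 0.3, the operating point with the best balance of recall,
precision and specificity for this estimator family), removes tokens hit
by token-level exclusion filters (pure numbers, punctuation-only tokens,
lone brackets — token classes that are over-represented in training and
score spuriously), groups maximal runs of surviving consecutive tokens
into candidate entities whose surface is the original text from first to
last token (inter-token hyphens and spaces preserved), and finally drops
whole candidates with encoding artefacts, unbalanced brackets, or a single
non-alphanumeric character.  Filters are plain data (`filter_rule`,
`read_filters`) and can be replaced wholesale.

### Which descriptor set does a token score carry?

A genuinely open design point.  The FoT-level score uses the union of the
target's and the context's grams; it is what cross-validation ranks
(recognition: *is this region chemical?*).  But the same union is shared
almost verbatim between an entity token and its immediate neighbours — at
window 1 the neighbour's FoT contains the entity token's grams — so
FoT-level scores cannot *delimit* an entity: calibrated on FoT scores, Pc
saturates near the entity/neighbour ratio and no token clears a
threshold of 0.3.  The per-character machinery (scoring a position by the
grams covering it) points the other way: evaluate a token by its **own**
grams, under a model whose counts were still formed with the context
window.  The package therefore thresholds target-token scores (`bt_*`
columns; the calibration is fitted on target-token leave-one-out B
values), while FoT-level B (`b_*`) remains the recognition score used for
per-class IA.  Both are returned by `predict()` and `score_tokens()`.

## Cross-validation

`loo_cv` scores every training FoT with its own contributions excluded —
a constant-cost exact leave-one-out.  `kfold_cv` (default k = 5) splits
*documents*, never individual FoTs, so context tokens of a test FoT are
never seen in training; folds come from a seeded shuffle and metrics are
pooled over folds (micro-aggregation, stable for rare classes).
Entity-level precision and recall use exact span matching (document,
section, start, end); an overlap mode exists but is not the default,
since exact matching is the stricter and unambiguous notion of "whole
entity recognized".

## The synthetic corpus

`generate_corpus` emulates the statistical structure the method needs,
not English:

* background prose drawn from a fixed common-word list plus punctuation
  and numerals;
* entities from per-class grammars — SYSTEMATIC names as chains of real
  chemical morphemes with optional head words ("…benzamide sulfate"),
  FORMULA as element/count strings, FAMILY as stem+plural, ABBREVIATION
  and TRIVIAL from small fixed lexicons (some multi-word);
* cue words ("inhibitor", "treated", "assay", …) throughout the prose
  (about a tenth of word draws) with a mild extra chance
  (`cue_prob = 0.3` per side) of flanking an entity, as in real
  pharmacological abstracts — deliberately *not* entity-exclusive, which
  would make cue grams look chemical;
* heavy class imbalance: `entity_rate = 0.06` of tokens inside entities
  (the ~1:14 merged-class imbalance of expert-annotated chemistry
  corpora), class mix proportional to the reference per-class training
  sizes, gold spans recorded at exact character offsets, entities always
  separated by at least one background token.

Defaults are 200 documents of 40–80 tokens (titles 5–9), seed 42 — about
13,000 tokens, a size chosen so the full 5-fold pipeline runs in seconds
while leaving hundreds of gold entities per run.  What passing tests on
this corpus show: the estimator, calibration and extraction machinery are
correct and the method separates chemically-shaped tokens from prose at
realistic imbalance.  What they do not show: performance on real abstracts
— real chemistry text has misspellings, hyphenation across lines,
ambiguous abbreviations colliding with common words, entity types the
grammar does not model (identifiers, multi-entity coordinations), and
entity/context correlations far richer than a cue lexicon.  Numbers from
the synthetic study are properties of the generator's separability, not
claims about any external corpus.

## Limitations

* Character n-grams cannot recognize entity classes whose members share no
  sub-lexical structure with the training set (one-off identifiers,
  arbitrary code names); such tokens fall back to B ≈ 0.
* Short abbreviations collide with uppercase fragments of ordinary words
  after case folding; they are the weakest class by construction.
* At window ≥ 1 the FoT-level score blurs entity boundaries by one token
  in each direction (see the design note above); boundary-exact extraction
  rests entirely on the target-token score.
* The default filters approximate a published exclusion list that is only
  summarized in the open literature; they are configurable data, not a
  fixed truth.
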