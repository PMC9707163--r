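---
title: "Mapping groups by linguistic style: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping groups by linguistic style: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stylemap)
```

## The problem and the model

Online communities differ not only in what they talk about but in *how*
they talk: the mixture of pronouns, articles, prepositions, hedges,
intensifiers and other function-word categories that make up a group's
linguistic style.  Because style is largely topic-free, it can be compared
across communities that discuss entirely different subjects, and the
relative positions of groups in "style space" track what kind of group each
one is — vocational, political, relational, and so on — and how that
changes over time.

`stylemap` operationalises this in four stages.

1. **Featurization.**  Every comment is scored against a LIWC-format
   category dictionary: the score for category $c$ on a document with $n$
   tokens is $100 \cdot m_c / n$, where $m_c$ counts tokens matching any of
   $c$'s patterns.  Matching is bag-of-words on lowercased tokens; a token
   may feed several categories; an exact literal entry takes precedence
   over wildcard stems for the same surface form.  The default style set
   has 41 categories (40 dictionary categories plus the computed
   "six letters or more" counter).

2. **Pairwise dissimilarity.**  For each unordered pair of groups a binary
   classifier is asked to tell the two groups' style vectors apart.  Both
   classes are randomly under-sampled to the size of the smaller group
   (rounded down to an even number), split 50:50 into balanced train and
   test halves, and an extremely-randomised-trees ensemble is fit.  The
   test-half AUC is the dissimilarity: 0.5 means the styles are
   indistinguishable, 1.0 perfectly separable.  With 15 groups this trains
   $\binom{15}{2} = 105$ classifiers.

3. **Geometry and clusters.**  The AUC matrix (diagonal set to 0) is
   embedded by classical (Torgerson) multidimensional scaling — squared
   dissimilarities are double-centered, $B = -\tfrac12 J D^{\circ 2} J$,
   and eigendecomposed — with the full eigenvalue spectrum kept for scree
   inspection.  The matrix is also clustered: Ward linkage treating the
   entries as Euclidean distances, and k-means (default $k = 5$) on the
   matrix rows, with a within-cluster-sum-of-squares elbow curve over
   $k = 2, \dots, 9$.

4. **Validation and tracking.**  Group-level means of a ten-category
   personal-values lexicon are regressed on the two embedding coordinates
   (one OLS per value, unstandardised slopes, t-based 95% CIs on $n - 3$
   df, raw p-values).  A focal group's yearly slices are re-embedded
   against a fixed set of anchor groups, Procrustes-aligned on the anchors
   to the earliest slice, and each coordinate is tested for monotone trend
   with Spearman's rank correlation.

## Assumptions worth stating

* AUC dissimilarities are *not* metric distances: they need not satisfy
  the triangle inequality and carry a chance floor of 0.5 between
  off-diagonal entries and the conventional 0 diagonal.  Classical MDS on
  such a matrix typically produces some negative eigenvalues.  The package
  reports them in the scree rather than repairing them (no
  additive-constant correction by default), and `embedding_stress()`
  quantifies the residual; `auc_to_distance()` offers the affine rescale
  $d = \max(0, 2\,\mathrm{AUC} - 1)$ for users who prefer a chance-zero
  scale.
* Ward on an AUC matrix treats the entries as Euclidean distances — the
  standard practice for clustering precomputed dissimilarities directly,
  but the merge heights are then only approximately variance increases.
* Per-document percentages are comparable across documents of different
  lengths; the minimum-word cleaning rule (50 tokens) keeps the
  denominators from being degenerate.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_words` | 50 | tokens after URL stripping | standard exclusion threshold for dictionary scoring; short posts have noisy percentages |
| `n_trees` | 100 | trees | conventional ensemble size; AUC estimates stabilise well before this at the sample sizes involved |
| `mtry` | `floor(sqrt(p))` | features/split | standard random-forest heuristic |
| `num_random_splits` | 1 | cut-points/feature | the classic extremely-randomised rule |
| `k_dims` | 2 | dimensions | the scree of real group matrices supports a planar solution |
| `k_clusters` | 5 | clusters | the theoretically motivated number of group types |
| k-means `restarts` | 10 | runs | k-means++ seeding plus 10 restarts reliably reaches the optimum at $n \approx 15$ rows |
| trajectory `min_per_class` | 100 | comments/class | AUC estimates on fewer than ~100 test items per class are too noisy to place a slice |

All randomness flows from one master seed; each pair, slice and restart
draws its own seed via `derive_seed(master, label)`, so results are
independent of execution order and reproducible from the run manifest.

## The synthetic generator

Validation needs corpora whose ground truth is known.  The generator
emits documents as bags of tokens drawn from disjoint per-category
vocabularies under a profile of emission probabilities (baseline 0.012 per
category, so roughly half of each document is "filler" that matches no
category), with lengths $50 + \mathrm{NB}(\mu = 60, \theta = 5)$ —
heavy-tailed like real comments and always passing the cleaning rule.  A
paired `.dic` file makes dictionary scoring exact by construction.

Archetype sets place five base profiles on a circle in a two-dimensional
plane of probability space (two disjoint 8-category blocks act as latent
style axes) and perturb them log-normally (sd 0.04) into within-type
groups.  The separation knob scales the circle radius; the default 0.4 is
calibrated so pairwise AUCs span roughly 0.55–0.98 — the span seen on real
group corpora — rather than saturating at 1.0, which would flatten the
planar geometry into a simplex and blur the scree.  Drift corpora
interpolate two profiles linearly across slices.

What the generator does *not* emulate: grammar and word order (irrelevant
to bag-of-words scoring), topical content, author-level dependence between
comments, bursty posting, vocabulary growth, and category correlations
induced by syntax.  Passing the recovery tests therefore shows the
*pipeline* is correct and well-calibrated under its own model; it does not
show that 41 style categories suffice to separate any particular pair of
real communities.

## Numerical choices

* **Even-down under-sampling.**  The per-class size is the smaller group's
  count rounded down to the nearest even integer, so the 50:50 split is
  integral.  This rule reproduces the published pairwise totals of the
  reference Reddit dataset from its per-group counts (one published
  diagonal cell contradicts it and is treated as a typo).
* **Positive class** is the lexicographically first group label; AUC is
  reported for that fixed orientation, and pair computation is
  canonicalised so the result cannot depend on argument order.
* **MDS sign convention**: each coordinate column is flipped so its
  largest-magnitude entry is positive — eigenvector signs are otherwise
  arbitrary and would break reproducibility.
* **`k > `(positive eigenvalue count)** is an error, except for the fully
  degenerate all-zero matrix, which embeds at the origin with a warning.
* **Ward tie-breaks** follow `hclust`; the test oracle breaks ties by
  lowest index pair, and fixtures avoid exact ties.
* **k-means** is written in-package (k-means++ seeding, Lloyd iterations,
  farthest-point repair of empty clusters) because the repair and seeding
  behaviour is part of the contract; `stats::kmeans` serves as an
  independent cross-check of the attained WSS in the tests.
* **Spearman p-values** are exact by full permutation enumeration for
  $n \le 9$ — which covers yearly trajectories, the method's use case —
  and use the $t$ approximation above that, where enumeration (`10! =
  3{,}628{,}800`+ permutations) buys no accuracy worth its cost.  Ties get
  average ranks.
* **Procrustes alignment** (rotation/reflection plus translation, no
  scaling) is fitted on the anchors only and applied to all points.  It is
  this package's answer to the axis indeterminacy of re-running MDS once
  per slice: without it, per-slice coordinates are incomparable.  No
  scaling is allowed because AUCs are already on a common scale.

## Open design decisions, and how they were resolved

* **Titles and bodies.**  When a record carries a `title` field it is
  concatenated in front of the body (one space); scoring operates on the
  combined text.  Scoring bodies alone is available by dropping the field.
* **Bot identification.**  "Self-identifying bot" is operationalised as an
  author name ending in `bot` (case-insensitive) plus a configurable
  blacklist — there is no canonical definition, and this catches the
  dominant convention on Reddit-style platforms.
* **k-means input.**  The literal object clustered is the symmetric AUC
  matrix's rows (including the diagonal entry).  Users who prefer to
  cluster the embedding can pass `coef(fit)` to `kmeans_rows()`.
* **Value scoring** uses the dictionary's ten categories directly, with
  the unweighted mean of per-post percentages as the group score (no
  length weighting).

## Problem sizes used by the test and acceptance suites

The suites run entirely on synthetic data: 15 groups × 120 documents for
structure recovery (105 classifiers, ~100-token documents), 20 replicate
null pairs at 1,000 comments per class for calibration, and an 8-slice
drift corpus against 14 anchors (203 classifiers) for trajectory recovery.
These sizes were chosen as the smallest at which the Monte-Carlo bands in
the assertions are comfortably stable; everything completes in a few
minutes on one CPU.

## Known limitations

* The bundled 41-category style lexicon is an open stand-in: same size and
  character as the licensed LIWC 2015 style set, but not the same word
  lists, so absolute percentages are not comparable with LIWC output.
  Users with a licensed dictionary should load it via `load_dictionary()`.
  The same applies to the bundled ten-category values lexicon.
* AUC dissimilarities compress near their ceiling: once two groups are
  perfectly separable the matrix no longer distinguishes "different" from
  "very different", and the embedding degrades toward a simplex.
* Group-level value regressions have as many observations as groups
  (15 in the reference design); their p-values are reported raw and should
  be read accordingly.
* A trajectory's focal point participates in each slice's embedding, so
  with few anchors its movement slightly distorts the anchor
  configuration; use 10+ anchors for stable alignment.
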