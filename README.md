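# stylemap

Maps online communities by *how* their members write rather than what they
write about, and tracks how a community's position in that map moves over
time.

## Who this is for

Computational social scientists and text-analytics practitioners who want
to compare many group corpora (forum communities, subreddits, mailing
lists) on linguistic **style** — the topic-free, function-word composition
of text — and who need the full pipeline: corpus cleaning, LIWC-format
dictionary scoring, classifier-based dissimilarities, a low-dimensional
map, cluster validation, value-lexicon regressions, and anchored temporal
trajectories, all seeded and reproducible.

## The method

For groups $g_1, \dots, g_n$ with cleaned comment corpora:

1. Each comment becomes a vector of 41 style-category percentages
   (LIWC-format dictionary scoring: category $c$ scores
   $100 \, m_c / n_{\text{tokens}}$).
2. Every unordered pair of groups is compared with a balanced
   extremely-randomised-trees classifier: both classes are under-sampled
   to the smaller group's size (rounded down to even), split 50:50, and
   the **test-set AUC** is the pairwise dissimilarity — 0.5 means
   indistinguishable styles, 1.0 perfect separation.  $\binom{n}{2}$
   classifiers give a symmetric dissimilarity matrix $D$.
3. Classical (Torgerson) MDS embeds $D$:
   $B = -\tfrac12 J D^{\circ 2} J$ is eigendecomposed, coordinates are the
   top-$k$ eigenvectors scaled by $\sqrt{\lambda}$, and the full
   eigenvalue scree (including negatives) is kept as a dimensionality
   diagnostic.
4. The matrix is clustered (Ward linkage; k-means on the matrix rows with
   a WSS elbow curve), group-level means of a ten-category personal-values
   lexicon are regressed on the two coordinates (one OLS per value), and a
   focal group's yearly slices are re-embedded against fixed anchors,
   Procrustes-aligned, and tested for monotone trend with Spearman's rank
   correlation.

## Worked example

Simulate 15 groups (5 archetypes × 3 groups), fit the map, and inspect
the recovered structure:

```r
library(stylemap)

lex  <- synthetic_style_lexicon()
arch <- make_archetype_set(n_types = 5, groups_per_type = 3, seed = 42,
                           lexicon = lex)
fit  <- style_map(arch$corpora, lexicon = lex, k_clusters = 5, seed = 42)

print(fit)
#> Style map of 15 groups ( 105 pairwise classifiers )
#>   2-D embedding captures 54.6% of the positive spectrum
#>   k-means (k = 5 ) WSS = 2.8268

summary(fit)
#> Style map: 15 groups, 105 pairwise models
#>   off-diagonal AUC range: [0.383, 0.976]
#>   leading eigenvalues: 1.3789, 1.1908, 0.4939, 0.4016, 0.2651
#>   embedding stress: 0.3431
#>   k-means clusters:
#>     1 : type4_g1, type4_g2, type4_g3
#>     2 : type1_g1, type1_g2, type1_g3
#>     3 : type2_g1, type2_g2, type2_g3
#>     4 : type3_g1, type3_g2, type3_g3
#>     5 : type5_g1, type5_g2, type5_g3

head(coef(fit), 4)
#>               dim1        dim2
#> type1_g1 0.4320337  0.03417666
#> type1_g2 0.4178542  0.02647900
#> type1_g3 0.4000380  0.11792512
#> type2_g1 0.2079258 -0.27777490
```

Reading the output: 105 pairwise classifiers were trained; the two leading
eigenvalues (1.38, 1.19) dominate the rest of the spectrum, supporting a
planar map; both k-means at $k = 5$ and a Ward cut at 5
(`cut_tree(fit$linkage, 5)`) recover the five generating archetypes
exactly; and groups of the same archetype sit together in the coordinates.
`plot(fit, type = "map")`, `"scree"`, `"dendrogram"` and `"elbow"` draw
the standard diagnostics.

Value regressions and temporal tracking follow the same pattern:

```r
vals <- style_values(fit, corpora, values_lexicon())  # 10 OLS rows
traj <- style_trajectory(focal_comments, anchors, lexicon = lex)
print(traj)   # per-slice coordinates + Spearman trend per axis
traj2011 <- exclude_slice(traj, "2011")               # re-test without a slice
```

A thin command-line front end over these functions lives in
`inst/scripts/stylemap-cli.R` (subcommands `simulate`, `clean`, `map`,
`values`, `track`).

## Bundled dictionaries

The proprietary LIWC 2015 dictionary cannot be redistributed, so
`inst/extdata/style41_standin.dic` provides an open stand-in style set of
the same size (40 function-word categories + the computed `sixltr`
counter), and `values10_standin.dic` an open ten-category personal-values
stand-in.  Holders of licensed or published dictionaries can load them
with `load_dictionary()` — the method is lexicon-agnostic.
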