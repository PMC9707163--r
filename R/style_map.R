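#' Fit a style map of a set of groups
#'
#' The package's central fitting function.  Takes one corpus (or feature
#' matrix) per group and produces the full cross-sectional map:
#' dictionary-based style featurization, one balanced
#' extremely-randomised-trees classifier per pair of groups whose test-set
#' AUC is the pairwise dissimilarity (`choose(n, 2)` models), classical MDS
#' embedding of the AUC matrix with the full eigenvalue scree, Ward
#' linkage of the matrix, k-means on its rows, and the WSS elbow curve.
#'
#' @param corpora named list with one element per group: either a cleaned
#'   comment data frame (see [clean_comments()]) or an already-featurized
#'   numeric matrix (documents x categories).  At least 3 groups.
#' @param lexicon `category_lexicon` used to featurize comment corpora;
#'   ignored for pre-featurized input.  Default [style_lexicon()].
#' @param categories style categories to use (default: all of `lexicon`).
#' @param k_dims embedding dimension (default 2).
#' @param k_clusters k for the k-means solution (default 5).
#' @param restarts k-means restarts (default 10).
#' @param config a [dissim_config()].
#' @param seed master seed; all pair-level randomness derives from it.
#' @param verbose log one line per trained pair.
#' @return an object of class `"style_map"` with components `dissimilarity`
#'   (AUC matrix), `embedding` (`style_embedding`), `linkage` (`hclust`),
#'   `kmeans` (`style_kmeans`), `wss` (elbow data frame), `n_docs`,
#'   `seed`, `config`, `call`.  Methods: `print`, `summary`, `coef`
#'   (coordinates), `plot`.
#' @export
#' @examples
#' lex <- synthetic_style_lexicon()
#' prof <- base_style_profile(lex)
#' corpora <- lapply(setNames(1:4, paste0("g", 1:4)), function(i) {
#'   make_profile_features(prof, 60, seed = i)
#' })
#' fit <- style_map(corpora, k_clusters = 2, config = dissim_config(n_trees = 25))
#' coef(fit)
style_map <- function(corpora, lexicon = style_lexicon(),
                      categories = lexicon$categories, k_dims = 2,
                      k_clusters = 5, restarts = 10,
                      config = dissim_config(), seed = 1L,
                      verbose = FALSE) {
  stopifnot(is.list(corpora), !is.null(names(corpora)))
  cl <- match.call()
  features <- lapply(corpora, function(x) {
    if (is.matrix(x)) x else featurize_group(x, lexicon, categories)
  })
  D <- build_matrix(features, config = config, seed = seed,
                    verbose = verbose)
  embedding <- classical_mds(D, k = k_dims)
  linkage <- ward_linkage(D)
  km <- kmeans_rows(D, k = min(k_clusters, nrow(D)), restarts = restarts,
                    seed = derive_seed(seed, "kmeans"))
  wss <- wss_curve(D, k_min = 2, k_max = min(9, nrow(D) - 1),
                   restarts = restarts, seed = derive_seed(seed, "wss"))
  structure(
    list(
      dissimilarity = D, embedding = embedding, linkage = linkage,
      kmeans = km, wss = wss,
      n_docs = vapply(features, nrow, integer(1)),
      seed = as.integer(seed), config = config, call = cl
    ),
    class = "style_map"
  )
}

#' @export
print.style_map <- function(x, ...) {
  n <- nrow(x$dissimilarity)
  cat("Style map of", n, "groups (", choose(n, 2), "pairwise classifiers )\n")
  ev <- x$embedding$eigenvalues
  pos <- ev[ev > 0]
  share <- sum(ev[seq_len(min(x$embedding$k, length(pos)))]) / sum(pos)
  cat(sprintf("  %d-D embedding captures %.1f%% of the positive spectrum\n",
              x$embedding$k, 100 * share))
  cat("  k-means (k =", x$kmeans$k, ") WSS =",
      format(x$kmeans$wss, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.style_map <- function(object, ...) {
  x <- object
  out <- list(
    n_groups = nrow(x$dissimilarity),
    n_pairs = choose(nrow(x$dissimilarity), 2),
    auc_range = range(x$dissimilarity[upper.tri(x$dissimilarity)]),
    eigenvalues = utils::head(x$embedding$eigenvalues, 5),
    stress = embedding_stress(x$embedding, x$dissimilarity),
    clusters = split(names(x$kmeans$cluster), x$kmeans$cluster),
    wss = x$wss
  )
  class(out) <- "summary.style_map"
  out
}

#' @export
print.summary.style_map <- function(x, ...) {
  cat("Style map:", x$n_groups, "groups,", x$n_pairs, "pairwise models\n")
  cat(sprintf("  off-diagonal AUC range: [%.3f, %.3f]\n",
              x$auc_range[1], x$auc_range[2]))
  cat("  leading eigenvalues:",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  embedding stress: %.4f\n", x$stress))
  cat("  k-means clusters:\n")
  for (k in names(x$clusters)) {
    cat("   ", k, ":", paste(x$clusters[[k]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.style_map <- function(object, ...) {
  object$embedding$coords
}

#' Plot a fitted style map
#'
#' @param x a `style_map`.
#' @param type `"map"` (2-D embedding scatter, coloured by k-means
#'   cluster), `"scree"` (MDS eigenvalues), `"dendrogram"` (Ward tree) or
#'   `"elbow"` (k-means WSS curve).
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.style_map <- function(x, type = c("map", "scree", "dendrogram",
                                       "elbow"), ...) {
  type <- match.arg(type)
  switch(type,
    map = {
      co <- x$embedding$coords
      cl <- x$kmeans$cluster[rownames(co)]
      graphics::plot(co[, 1], co[, 2], col = cl, pch = 19,
                     xlab = "Dimension 1", ylab = "Dimension 2",
                     main = "Style map", ...)
      graphics::text(co[, 1], co[, 2], labels = rownames(co), pos = 3,
                     cex = 0.8)
    },
    scree = {
      ev <- x$embedding$eigenvalues
      graphics::plot(seq_along(ev), ev, type = "b", xlab = "Rank",
                     ylab = "Eigenvalue", main = "MDS eigenvalue scree",
                     ...)
      graphics::abline(h = 0, lty = 3)
    },
    dendrogram = plot(x$linkage, main = "Ward linkage",
                      xlab = "", sub = "", ...),
    elbow = graphics::plot(x$wss$k, x$wss$wss, type = "b", xlab = "k",
                           ylab = "Within-cluster SS",
                           main = "k-means elbow", ...)
  )
  invisible(x)
}

#' Group-values analysis of a fitted style map
#'
#' Scores each group's corpus against a ten-category value lexicon and
#' regresses every value's group means on the two embedding coordinates
#' (one OLS per value).
#'
#' @param fit a `style_map` with a 2-D embedding.
#' @param corpora the named list of cleaned comment corpora (same labels as
#'   the fit).
#' @param value_lexicon a ten-category value lexicon
#'   (default [values_lexicon()]).
#' @return object of class `"style_values"`: list with `scores`
#'   (groups x 10 means) and `table` (a `value_table`).
#' @export
style_values <- function(fit, corpora, value_lexicon = values_lexicon()) {
  stopifnot(inherits(fit, "style_map"))
  if (fit$embedding$k != 2) {
    stop("value regressions require a 2-D embedding (k_dims = 2)",
         call. = FALSE)
  }
  scores <- score_values(corpora, value_lexicon)
  tab <- run_value_table(scores, stats::coef(fit))
  structure(list(scores = scores, table = tab), class = "style_values")
}

#' @export
print.style_values <- function(x, ...) {
  print(x$table, ...)
  invisible(x)
}

#' Temporal trajectory of a focal group against a fitted set of anchors
#'
#' Convenience wrapper for Study-3-style tracking: slices the focal corpus
#' by calendar year, featurizes the slices and the anchor corpora with the
#' same lexicon, and runs [anchored_trajectory()].
#'
#' @param focal_comments cleaned comment data frame of the focal group,
#'   with timestamps.
#' @param anchors named list of cleaned anchor corpora (or feature
#'   matrices).
#' @param lexicon `category_lexicon` for featurization.
#' @param categories style categories to use.
#' @inheritParams anchored_trajectory
#' @return a `style_trajectory`.
#' @export
style_trajectory <- function(focal_comments, anchors,
                             lexicon = style_lexicon(),
                             categories = lexicon$categories,
                             config = dissim_config(), seed = 1L, k = 2,
                             min_per_class = 100) {
  slices <- slice_by_period(focal_comments, "year")
  focal_feats <- lapply(slices, featurize_group, lexicon = lexicon,
                        categories = categories)
  anchor_feats <- lapply(anchors, function(x) {
    if (is.matrix(x)) x else featurize_group(x, lexicon, categories)
  })
  anchored_trajectory(focal_feats, anchor_feats, config = config,
                      seed = seed, k = k, min_per_class = min_per_class)
}

#' Run manifest of a fitted style map
#'
#' Machine-readable record of the configuration and derived seeds that
#' produced a fit; re-running with the same manifest inputs reproduces the
#' same outputs.
#'
#' @param fit a `style_map`.
#' @param path optional path to also write the manifest as JSON.
#' @return a list (invisibly written to `path` when given).
#' @export
run_manifest <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "style_map"))
  plans <- attr(fit$dissimilarity, "plans")
  man <- list(
    tool = paste0("stylemap ", as.character(utils::packageVersion("stylemap"))),
    master_seed = fit$seed,
    config = unclass(fit$config),
    groups = rownames(fit$dissimilarity),
    n_docs = as.list(fit$n_docs),
    pairs = lapply(plans, function(p) {
      list(group_a = p$group_a, group_b = p$group_b,
           n_per_class = p$n_per_class, n_total = p$n_total, seed = p$seed)
    })
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(man)
}
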