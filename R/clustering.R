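#' Ward agglomerative clustering of a dissimilarity matrix
#'
#' Hierarchical clustering under the Ward objective (merge the pair of
#' clusters with the smallest increase in within-cluster variance), with
#' the matrix entries treated as Euclidean distances and merged via the
#' Lance-Williams recurrence (`hclust` method `"ward.D2"`).  AUC
#' dissimilarities need not embed exactly in Euclidean space; the merge
#' heights are then approximate variance increases, which is the standard
#' practice when clustering such matrices directly.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return an `hclust` object (leaf labels from `D`'s dimnames).
#' @export
ward_linkage <- function(D) {
  check_dissim(D)
  if (nrow(D) < 2) stop("need at least 2 groups", call. = FALSE)
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

#' Merge table of a linkage tree
#'
#' @param tree an `hclust` object.
#' @return data frame with one row per merge: `step`, `cluster_a`,
#'   `cluster_b` (negative = leaf index, positive = earlier merge step),
#'   `height`, `new_size`.
#' @export
linkage_table <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  sizes <- integer(nrow(tree$merge))
  size_of <- function(code) {
    if (code < 0) 1L else sizes[code]
  }
  for (s in seq_len(nrow(tree$merge))) {
    sizes[s] <- size_of(tree$merge[s, 1]) + size_of(tree$merge[s, 2])
  }
  data.frame(
    step = seq_len(nrow(tree$merge)),
    cluster_a = tree$merge[, 1], cluster_b = tree$merge[, 2],
    height = tree$height, new_size = sizes
  )
}

#' Cut a linkage tree into a fixed number of clusters
#'
#' @param tree an `hclust` object.
#' @param n_clusters number of clusters, between 1 and the leaf count.
#' @return named integer vector of cluster assignments.
#' @export
cut_tree <- function(tree, n_clusters) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels %||% tree$order)
  if (n_clusters < 1 || n_clusters > n) {
    stop("n_clusters must be in [1, ", n, "]", call. = FALSE)
  }
  stats::cutree(tree, k = n_clusters)
}

# One k-means++ initialised Lloyd run; repairs empty clusters by re-seeding
# the point farthest from its assigned center.  Consumes the current RNG
# stream.
kmeanspp_lloyd <- function(X, k, max_iter = 100) {
  n <- nrow(X)
  sq_dist_to <- function(c) colSums((t(X) - c)^2)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- sq_dist_to(centers[1, ])
  for (j in seq_len(k - 1) + 1) {
    pick <- if (sum(d2) > 0) {
      sample.int(n, 1, prob = d2 / sum(d2))
    } else {
      sample.int(n, 1)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, sq_dist_to(centers[j, ]))
  }
  assign <- integer(n)
  for (iter in seq_len(max_iter)) {
    Dm <- vapply(seq_len(k), function(j) sq_dist_to(centers[j, ]),
                 numeric(n))
    Dm <- matrix(Dm, nrow = n)
    new_assign <- max.col(-Dm, ties.method = "first")
    cur_d2 <- Dm[cbind(seq_len(n), new_assign)]
    for (j in which(tabulate(new_assign, k) == 0)) {
      worst <- which.max(cur_d2)
      new_assign[worst] <- j
      cur_d2[worst] <- -Inf # a point can repair at most one empty cluster
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
  }
  wss <- sum((X - centers[assign, , drop = FALSE])^2)
  list(assign = assign, centers = centers, wss = wss)
}

#' k-means on the rows of a dissimilarity matrix
#'
#' Each group is represented by its row of the symmetric matrix (including
#' the diagonal entry under the active convention) as a Euclidean feature
#' vector; Lloyd iterations start from k-means++ seeding and the best of
#' `restarts` runs by within-cluster sum of squares is returned.  Empty
#' clusters are repaired by re-seeding the farthest point.  To cluster MDS
#' coordinates instead, pass `coef(fit)` as `D`.
#'
#' @param D symmetric dissimilarity matrix (or any numeric matrix whose
#'   rows are the objects to cluster).
#' @param k number of clusters.
#' @param restarts independent initialisations (default 10).
#' @param seed integer seed.
#' @return object of class `"style_kmeans"`: list with `k`, `cluster`
#'   (named assignments), `wss`, `centers`, `restarts`, `seed`.
#' @export
kmeans_rows <- function(D, k, restarts = 10, seed = 1L) {
  X <- as.matrix(D)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " exceeds number of rows (", n, ")",
                  call. = FALSE)
  stopifnot(k >= 1, restarts >= 1)
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- with_seed(derive_seed(seed, paste0("kmeans::", k, "::", r)),
                     kmeanspp_lloyd(X, k))
    if (is.null(best) || run$wss < best$wss - 1e-12) best <- run
  }
  cluster <- best$assign
  names(cluster) <- rownames(X)
  structure(
    list(k = as.integer(k), cluster = cluster, wss = best$wss,
         centers = best$centers, restarts = as.integer(restarts),
         seed = as.integer(seed)),
    class = "style_kmeans"
  )
}

#' @export
print.style_kmeans <- function(x, ...) {
  cat("k-means (k =", x$k, "): WSS =", format(x$wss, digits = 6), "\n")
  sizes <- table(x$cluster)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Within-cluster sum of squares curve (elbow diagnostic)
#'
#' Best WSS over restarts for each k in `k_min:k_max` (defaults 2 to 9).
#'
#' @inheritParams kmeans_rows
#' @param k_min,k_max range of cluster counts.
#' @return data frame with columns `k`, `wss`.
#' @export
wss_curve <- function(D, k_min = 2, k_max = 9, restarts = 10, seed = 1L) {
  n <- nrow(as.matrix(D))
  if (k_max > n) stop("k_max exceeds number of rows", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  wss <- vapply(ks, function(k) {
    kmeans_rows(D, k, restarts = restarts,
                seed = derive_seed(seed, paste0("wss::", k)))$wss
  }, numeric(1))
  data.frame(k = ks, wss = wss)
}
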