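#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric dissimilarity matrix by double-centering the squared
#' dissimilarities (`B = -1/2 J D^2 J`) and eigendecomposing `B`;
#' coordinates are the top-`k` eigenvectors scaled by the square roots of
#' their eigenvalues.  The full eigenvalue spectrum (including negative
#' values, which diagnose non-Euclidean input) is returned for scree
#' inspection.  A deterministic sign convention is applied: each coordinate
#' column is flipped so that its largest-magnitude entry is positive.
#'
#' @param D symmetric dissimilarity matrix with a zero diagonal.
#' @param k number of dimensions to retain (default 2).
#' @return an object of class `"style_embedding"`: list with `labels`,
#'   `coords` (n x k, dimnames set), `eigenvalues` (descending, length n),
#'   `k`.
#' @export
classical_mds <- function(D, k = 2) {
  check_dissim(D)
  if (max(abs(diag(D))) > 1e-8) {
    stop("classical MDS requires a zero diagonal; see dissim_config(diagonal=)",
         call. = FALSE)
  }
  stopifnot(k >= 1)
  n <- nrow(D)
  labels <- rownames(D) %||% paste0("g", seq_len(n))
  fit <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1), eig = TRUE))
  ev <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(ev), 0) * 1e-8
  n_pos <- sum(ev > tol)
  if (n_pos == 0) {
    warning("no positive eigenvalues (degenerate input); ",
            "returning all-zero coordinates")
    coords <- matrix(0, n, k)
  } else if (k > n_pos) {
    stop("k = ", k, " exceeds the number of positive eigenvalues (", n_pos,
         ")", call. = FALSE)
  } else {
    coords <- fit$points[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      if (coords[which.max(abs(coords[, j])), j] < 0) {
        coords[, j] <- -coords[, j]
      }
    }
  }
  dimnames(coords) <- list(labels, paste0("dim", seq_len(k)))
  structure(
    list(labels = labels, coords = coords, eigenvalues = ev, k = k),
    class = "style_embedding"
  )
}

#' @export
print.style_embedding <- function(x, ...) {
  cat("Classical MDS embedding:", length(x$labels), "groups in", x$k,
      "dimensions\n")
  pos <- x$eigenvalues[x$eigenvalues > 0]
  if (length(pos)) {
    share <- sum(x$eigenvalues[seq_len(min(x$k, length(pos)))]) / sum(pos)
    cat(sprintf("  top-%d eigenvalue share of positive spectrum: %.1f%%\n",
                x$k, 100 * share))
  }
  print(round(x$coords, 4))
  invisible(x)
}

#' Eigenvalue scree of a dissimilarity matrix
#'
#' Full descending spectrum of the double-centered squared-dissimilarity
#' matrix.  Negative eigenvalues are reported, never dropped: they indicate
#' the dissimilarities are not exactly Euclidean.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return numeric vector of eigenvalues, descending.
#' @export
scree <- function(D) {
  check_dissim(D)
  sort(suppressWarnings(stats::cmdscale(D, k = 1, eig = TRUE))$eig,
       decreasing = TRUE)
}

#' Residual stress of an embedding
#'
#' Normalised residual between the embedding's pairwise distances and the
#' input dissimilarities:
#' `sqrt(sum((dist(X) - D)^2) / sum(D^2))` over the upper triangle.
#'
#' @param embedding a `style_embedding`.
#' @param D the dissimilarity matrix it was fitted to.
#' @return non-negative number; 0 for Euclidean-realisable input.
#' @export
embedding_stress <- function(embedding, D) {
  check_dissim(D)
  dhat <- as.matrix(stats::dist(embedding$coords))
  ut <- upper.tri(D)
  sqrt(sum((dhat[ut] - D[ut])^2) / sum(D[ut]^2))
}

#' Orthogonal Procrustes alignment of one embedding onto another
#'
#' Finds the orthogonal transform (rotation, reflections allowed) and
#' optional translation that minimises the squared error over a set of
#' anchor points shared by the two embeddings, then applies it to *all*
#' points of the target.  No scaling is applied: AUC dissimilarities are on
#' a common scale across embeddings, so only the rotational/reflective
#' indeterminacy of classical MDS needs removing.
#'
#' @param reference embedding to align to.
#' @param target embedding to transform.
#' @param anchor_labels labels present in both embeddings used to fit the
#'   transform; default all shared labels.  At least `k + 1` required.
#' @param translate include an optimal translation (default TRUE).
#' @return object of class `"procrustes_alignment"`: list with `embedding`
#'   (the transformed target), `rotation`, `translation`, `disparity`
#'   (residual anchor sum of squares).
#' @export
procrustes_align <- function(reference, target,
                             anchor_labels = NULL, translate = TRUE) {
  stopifnot(inherits(reference, "style_embedding"),
            inherits(target, "style_embedding"))
  if (reference$k != target$k) {
    stop("embeddings have different dimension", call. = FALSE)
  }
  k <- reference$k
  anchor_labels <- anchor_labels %||%
    intersect(reference$labels, target$labels)
  if (!all(anchor_labels %in% reference$labels) ||
      !all(anchor_labels %in% target$labels)) {
    stop("anchor labels missing from one of the embeddings", call. = FALSE)
  }
  if (length(anchor_labels) < k + 1) {
    stop("need at least k + 1 = ", k + 1, " anchors, got ",
         length(anchor_labels), call. = FALSE)
  }
  X <- reference$coords[anchor_labels, , drop = FALSE]
  Y <- target$coords[anchor_labels, , drop = FALSE]
  cx <- if (translate) colMeans(X) else rep(0, k)
  cy <- if (translate) colMeans(Y) else rep(0, k)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  aligned <- sweep(sweep(target$coords, 2, cy) %*% R, 2, cx, `+`)
  dimnames(aligned) <- dimnames(target$coords)
  disparity <- sum((Xc - Yc %*% R)^2)
  out <- target
  out$coords <- aligned
  structure(
    list(embedding = out, rotation = R,
         translation = as.numeric(cx - cy %*% R), disparity = disparity,
         anchors = anchor_labels),
    class = "procrustes_alignment"
  )
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat("Procrustes alignment on", length(x$anchors),
      "anchors; disparity =", format(x$disparity, digits = 6), "\n")
  invisible(x)
}

#' Write embedding coordinates and eigenvalues as CSV
#'
#' @param embedding a `style_embedding`.
#' @param coords_path,eigen_path output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, a list of the written paths.
#' @export
write_embedding_csv <- function(embedding, coords_path, eigen_path = NULL) {
  if (!is.null(coords_path)) {
    df <- data.frame(label = embedding$labels, embedding$coords,
                     check.names = FALSE)
    utils::write.csv(df, coords_path, row.names = FALSE)
  }
  if (!is.null(eigen_path)) {
    utils::write.csv(
      data.frame(rank = seq_along(embedding$eigenvalues),
                 eigenvalue = embedding$eigenvalues),
      eigen_path, row.names = FALSE
    )
  }
  invisible(list(coords = coords_path, eigenvalues = eigen_path))
}
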