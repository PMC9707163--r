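# Independent oracles used by both the module tests and the acceptance
# suite.  Each recomputes a quantity from first principles, without touching
# the implementation path it checks.

# AUC by exhaustive enumeration of all positive/negative score pairs.
exhaustive_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Eigenvalues of the double-centered squared-dissimilarity matrix, by a
# direct dense construction of B = -1/2 J D^2 J and base eigen().
double_center_eigen <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  sort(eigen((B + t(B)) / 2, symmetric = TRUE)$values, decreasing = TRUE)
}

# Ward agglomeration recomputed from scratch at every step from point
# coordinates: at each step merge the pair of clusters with the smallest
# increase in within-cluster sum of squares (ties: lowest index pair).
# Returns the member sets in merge order and heights sqrt(2 * delta_SS),
# the scale hclust's "ward.D2" reports for Euclidean input.
ward_oracle <- function(X) {
  ss <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(sweep(X[idx, , drop = FALSE], 2,
              colMeans(X[idx, , drop = FALSE]))^2)
  }
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d_ss <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (is.null(best) || d_ss < best$d_ss - 1e-12) {
          best <- list(i = i, j = j, d_ss = d_ss)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, sqrt(2 * best$d_ss))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Member sets of an hclust tree in merge order.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    members <- function(code) {
      if (code < 0) -code else sets[[code]]
    }
    sets[[s]] <- sort(c(members(hc$merge[s, 1]), members(hc$merge[s, 2])))
  }
  sets
}

# Global k-means optimum by exhaustive search over all assignments.
exhaustive_kmeans_wss <- function(X, k) {
  n <- nrow(X)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < k) next
    wss <- 0
    for (j in unique(a)) {
      Xi <- X[a == j, , drop = FALSE]
      wss <- wss + sum(sweep(Xi, 2, colMeans(Xi))^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# Closed-form OLS via the normal equations with textbook SE / CI formulas.
ols_oracle <- function(y, coords) {
  X <- cbind(1, coords)
  n <- nrow(X)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- n - 3
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  tcrit <- qt(0.975, df)
  tss <- sum((y - mean(y))^2)
  rss <- sum(resid^2)
  r2 <- 1 - rss / tss
  f <- ((tss - rss) / 2) / (rss / df)
  list(
    b = as.numeric(beta), se = as.numeric(se),
    ci_lo = as.numeric(beta) - tcrit * se,
    ci_hi = as.numeric(beta) + tcrit * se,
    r2 = r2, p = pf(f, 2, df, lower.tail = FALSE)
  )
}

# Spearman permutation p by brute enumeration, recomputing rho with cor()
# for every permutation (independent of the rank-product shortcut).
spearman_perm_oracle <- function(values, times) {
  n <- length(values)
  perm_rows <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perm_rows(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  P <- perm_rows(seq_len(n))
  rho_obs <- cor(values, times, method = "spearman")
  rhos <- apply(P, 1, function(ix) {
    cor(values[ix], times, method = "spearman")
  })
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Small labelled Euclidean dissimilarity matrix from random planar points.
planar_dissim <- function(n, seed = 1, d = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  attr(D, "points") <- X
  D
}

# Evaluate expr under a fixed RNG seed (test-local convenience).
with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
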