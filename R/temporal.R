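#' Partition comments into calendar periods
#'
#' Splits a comment data frame by calendar period of `created_utc` in UTC,
#' with half-open intervals (a timestamp at midnight on 1 January belongs to
#' the new year).  Empty periods are omitted.
#'
#' @param comments comment data frame with a `created_utc` column (epoch
#'   seconds).
#' @param period currently only `"year"`.
#' @return named list of comment data frames, names sorted ascending.
#' @export
slice_by_period <- function(comments, period = c("year")) {
  period <- match.arg(period)
  t <- as.POSIXct(comments$created_utc, origin = "1970-01-01", tz = "UTC")
  key <- format(t, "%Y")
  out <- split(comments, key)
  out[order(names(out))]
}

#' Spearman rank trend test
#'
#' Spearman correlation with average-rank ties between a coordinate series
#' and time.  The two-sided p-value is exact — computed by full enumeration
#' of the permutation distribution — for n up to 9 (enumeration beyond that
#' is impractical and the t approximation is accurate); otherwise the
#' t approximation on n - 2 degrees of freedom is used.
#'
#' @param values numeric vector (e.g. one embedding coordinate per slice).
#' @param times numeric vector of the same length (e.g. years).
#' @return list with `rho`, `p`, `n`, `df` (= n - 2) and `method`.
#' @export
spearman_trend <- function(values, times) {
  n <- length(values)
  stopifnot(length(times) == n)
  if (n < 3) stop("need at least 3 points for a trend", call. = FALSE)
  if (stats::sd(values) == 0 || stats::sd(times) == 0) {
    stop("constant input: Spearman rho is undefined", call. = FALSE)
  }
  rx <- rank(values)
  ry <- rank(times)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    # Pearson on ranks: across permutations of rx only the cross sum varies
    P <- all_permutations(n)
    s <- matrix(rx[P], nrow = nrow(P)) %*% ry
    rhos <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, df = n - 2L, method = method)
}

# All permutations of 1..n as an n!-row matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i)) # i first, then a permutation of the rest
  }))
}

#' Anchored temporal trajectory of a focal group
#'
#' Tracks a focal group across time slices against a fixed set of anchor
#' groups.  Anchor-anchor AUCs are computed once and reused for every
#' slice, so any movement in the map is attributable to the focal group.
#' Per slice: focal-vs-anchor AUCs are computed (balanced to the pairwise
#' minimum), a full dissimilarity matrix is assembled, classical MDS is
#' run, and the slice embedding is Procrustes-aligned on the anchors to the
#' earliest included slice's embedding.  Trend per axis is a Spearman test
#' of the focal coordinate against time.
#'
#' @param focal_slices named list of feature matrices, one per time slice
#'   (names sortable as times, e.g. years).
#' @param anchors named list of feature matrices, one per anchor group (at
#'   least 3).
#' @param config a [dissim_config()].
#' @param seed master integer seed.
#' @param k embedding dimension (default 2).
#' @param min_per_class slices whose balanced per-class size against the
#'   smallest anchor falls below this are skipped with a warning
#'   (default 100).
#' @param focal_label label used for the focal group in the per-slice
#'   matrices.
#' @return object of class `"style_trajectory"`: list with `slices`,
#'   `times`, `coords` (slices x k), `trend` (per-axis [spearman_trend()]
#'   results), `anchor_labels`, `anchor_coords` (per slice), `disparity`
#'   (per slice), `anchor_matrix`, `embeddings`, `excluded`.
#' @export
anchored_trajectory <- function(focal_slices, anchors,
                                config = dissim_config(), seed = 1L, k = 2,
                                min_per_class = 100,
                                focal_label = "focal") {
  stopifnot(is.list(focal_slices), !is.null(names(focal_slices)),
            is.list(anchors), !is.null(names(anchors)))
  if (length(anchors) < 3) stop("need at least 3 anchors", call. = FALSE)
  if (focal_label %in% names(anchors)) {
    stop("focal_label collides with an anchor label", call. = FALSE)
  }
  a_labels <- names(anchors)
  D_aa <- build_matrix(anchors, config = config, seed = seed)

  slice_names <- names(focal_slices)[order(names(focal_slices))]
  keep <- character(0)
  coords <- NULL
  anchor_coords <- list()
  disparity <- numeric(0)
  embeddings <- list()
  reference <- NULL
  m <- length(a_labels)
  for (s in slice_names) {
    Fs <- focal_slices[[s]]
    npc_min <- min(vapply(anchors, function(A) {
      balanced_sample_size(nrow(Fs), nrow(A))
    }, integer(1)))
    if (npc_min < min_per_class) {
      warning("slice '", s, "' skipped: per-class size ", npc_min,
              " below minimum ", min_per_class)
      next
    }
    D <- matrix(if (config$diagonal == "zero") 0 else 0.5, m + 1, m + 1,
                dimnames = list(c(a_labels, focal_label),
                                c(a_labels, focal_label)))
    D[a_labels, a_labels] <- D_aa
    for (a in a_labels) {
      pseed <- derive_seed(seed, paste0("slice::", s, "::", a))
      auc <- pair_dissimilarity(Fs, anchors[[a]],
                                labels = c(focal_label, a),
                                config = config, seed = pseed)
      D[focal_label, a] <- D[a, focal_label] <- as.numeric(auc)
    }
    emb <- classical_mds(D, k = k)
    if (is.null(reference)) {
      reference <- emb
      aligned <- emb
      disp <- 0
    } else {
      al <- procrustes_align(reference, emb, anchor_labels = a_labels)
      aligned <- al$embedding
      disp <- al$disparity
    }
    keep <- c(keep, s)
    coords <- rbind(coords, aligned$coords[focal_label, ])
    anchor_coords[[s]] <- aligned$coords[a_labels, , drop = FALSE]
    disparity <- c(disparity, disp)
    embeddings[[s]] <- aligned
  }
  if (length(keep) == 0) stop("no slice met the minimum size", call. = FALSE)
  rownames(coords) <- keep
  names(disparity) <- keep
  times <- suppressWarnings(as.numeric(keep))
  if (anyNA(times)) times <- seq_along(keep)
  traj <- structure(
    list(slices = keep, times = times, coords = coords,
         trend = NULL, anchor_labels = a_labels,
         anchor_coords = anchor_coords, disparity = disparity,
         anchor_matrix = D_aa, embeddings = embeddings,
         excluded = character(0)),
    class = "style_trajectory"
  )
  traj$trend <- trajectory_trend(traj)
  traj
}

# Recompute the per-axis Spearman trend over non-excluded slices.
trajectory_trend <- function(traj) {
  use <- !(traj$slices %in% traj$excluded)
  if (sum(use) < 3) {
    return(structure(list(), note = "fewer than 3 slices: no trend"))
  }
  lapply(stats::setNames(seq_len(ncol(traj$coords)),
                         colnames(traj$coords)), function(j) {
    spearman_trend(traj$coords[use, j], traj$times[use])
  })
}

#' Exclude a time slice from a trajectory's trend statistics
#'
#' The slice's coordinates are retained for plotting, but the per-axis
#' Spearman trend is recomputed over the remaining slices and the exclusion
#' is recorded.  Use [include_slice()] to undo.
#'
#' @param trajectory a `style_trajectory`.
#' @param slice_label one of `trajectory$slices`.
#' @return the updated trajectory.
#' @export
exclude_slice <- function(trajectory, slice_label) {
  stopifnot(inherits(trajectory, "style_trajectory"))
  if (!slice_label %in% trajectory$slices) {
    stop("unknown slice '", slice_label, "'", call. = FALSE)
  }
  trajectory$excluded <- union(trajectory$excluded, slice_label)
  trajectory$trend <- trajectory_trend(trajectory)
  trajectory
}

#' @rdname exclude_slice
#' @export
include_slice <- function(trajectory, slice_label) {
  stopifnot(inherits(trajectory, "style_trajectory"))
  trajectory$excluded <- setdiff(trajectory$excluded, slice_label)
  trajectory$trend <- trajectory_trend(trajectory)
  trajectory
}

#' @export
print.style_trajectory <- function(x, ...) {
  cat("Anchored trajectory:", length(x$slices), "slices against",
      length(x$anchor_labels), "anchors\n")
  if (length(x$excluded)) {
    cat("  excluded from trend:", paste(x$excluded, collapse = ", "), "\n")
  }
  print(round(x$coords, 4))
  if (length(x$trend)) {
    for (ax in names(x$trend)) {
      tr <- x$trend[[ax]]
      cat(sprintf("  %s trend: rho(%d) = %.3f, p = %.4f (%s)\n",
                  ax, tr$df, tr$rho, tr$p, tr$method))
    }
  }
  invisible(x)
}

#' @export
plot.style_trajectory <- function(x, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2],
                 type = "b", xlab = colnames(x$coords)[1],
                 ylab = colnames(x$coords)[2],
                 main = "Focal group trajectory", ...)
  graphics::text(x$coords[, 1], x$coords[, 2], labels = x$slices, pos = 3,
                 cex = 0.8)
  anch <- x$anchor_coords[[1]]
  graphics::points(anch[, 1], anch[, 2], pch = 3, col = "grey40")
  graphics::text(anch[, 1], anch[, 2], labels = rownames(anch), pos = 1,
                 cex = 0.6, col = "grey40")
  invisible(x)
}

#' Write a trajectory and its trend summary
#'
#' @param trajectory a `style_trajectory`.
#' @param coords_path CSV of (slice, dim...) coordinates, or `NULL`.
#' @param trend_path JSON of per-axis trend statistics and exclusions, or
#'   `NULL`.
#' @return invisibly, the written paths.
#' @export
write_trajectory <- function(trajectory, coords_path, trend_path = NULL) {
  if (!is.null(coords_path)) {
    utils::write.csv(
      data.frame(slice = trajectory$slices, trajectory$coords,
                 check.names = FALSE),
      coords_path, row.names = FALSE
    )
  }
  if (!is.null(trend_path)) {
    jsonlite::write_json(
      list(trend = trajectory$trend, excluded = trajectory$excluded),
      trend_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(list(coords = coords_path, trend = trend_path))
}
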