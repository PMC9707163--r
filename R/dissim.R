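#' Balanced per-class sample size for a pairwise comparison
#'
#' Random under-sampling equalises the two classes at the size of the
#' smaller corpus, rounded down to the nearest even integer so that a 50:50
#' train/test split is integral.  The pairwise total is twice this value.
#'
#' @param n_a,n_b available comment counts in the two groups.
#' @return positive even integer: the per-class sample size.
#' @export
#' @examples
#' balanced_sample_size(91014, 25256) # 25256 -> pairwise total 50512
#' balanced_sample_size(17519, 54495) # 17518 (odd minimum rounded down)
balanced_sample_size <- function(n_a, n_b) {
  m <- min(n_a, n_b)
  if (m < 2) stop("need at least 2 comments per group", call. = FALSE)
  as.integer(m - m %% 2)
}

#' Configuration for pairwise classifier dissimilarities
#'
#' @param n_trees number of trees in the extremely-randomised-trees
#'   ensemble (default 100).
#' @param mtry number of candidate features per split; default
#'   `floor(sqrt(p))`.
#' @param num_random_splits random cut-points drawn per candidate feature
#'   (1 = the classic extremely-randomised rule).
#' @param diagonal diagonal convention for the assembled matrix: `"zero"`
#'   (default, required by the metric embedding) or `"half"` (the raw-AUC
#'   chance level 0.5).
#' @param min_per_class smallest acceptable per-class sample size.
#' @return an object of class `"dissim_config"`.
#' @export
dissim_config <- function(n_trees = 100, mtry = NULL, num_random_splits = 1,
                          diagonal = c("zero", "half"), min_per_class = 4) {
  diagonal <- match.arg(diagonal)
  stopifnot(n_trees >= 1, num_random_splits >= 1, min_per_class >= 2)
  structure(
    list(
      n_trees = as.integer(n_trees), mtry = mtry,
      num_random_splits = as.integer(num_random_splits),
      diagonal = diagonal, min_per_class = as.integer(min_per_class)
    ),
    class = "dissim_config"
  )
}

#' Sampling plan for one pairwise comparison
#'
#' @param group_a,group_b group labels.
#' @param n_per_class even per-class sample size.
#' @param seed integer seed for the under-sampling and split.
#' @return an object of class `"pair_plan"`.
#' @export
pair_plan <- function(group_a, group_b, n_per_class, seed) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 2 || n_per_class %% 2 != 0) {
    stop("n_per_class must be a positive even integer", call. = FALSE)
  }
  structure(
    list(group_a = group_a, group_b = group_b, n_per_class = n_per_class,
         n_total = 2L * n_per_class, seed = as.integer(seed)),
    class = "pair_plan"
  )
}

#' Balanced 50:50 train/test split for a group pair
#'
#' Draws `plan$n_per_class` rows uniformly without replacement from each
#' group, then assigns exactly half of each group's draw to the training
#' half and half to the test half, so both halves are class-balanced.
#' The split is deterministic given `plan$seed`.
#'
#' @param A,B feature matrices (rows = documents).
#' @param plan a [pair_plan()].
#' @return `list(train = list(x, y), test = list(x, y))` with `y` a factor
#'   with levels in lexicographic label order.
#' @export
train_test_split_pair <- function(A, B, plan) {
  stopifnot(inherits(plan, "pair_plan"))
  npc <- plan$n_per_class
  if (npc > nrow(A) || npc > nrow(B)) {
    stop("plan n_per_class (", npc, ") exceeds availability (",
         nrow(A), ", ", nrow(B), ")", call. = FALSE)
  }
  labels <- sort(c(plan$group_a, plan$group_b))
  lab_a <- plan$group_a
  lab_b <- plan$group_b
  half <- npc %/% 2L
  with_seed(plan$seed, {
    ia <- sample.int(nrow(A), npc)
    ib <- sample.int(nrow(B), npc)
    x_train <- rbind(A[ia[seq_len(half)], , drop = FALSE],
                     B[ib[seq_len(half)], , drop = FALSE])
    x_test <- rbind(A[ia[(half + 1):npc], , drop = FALSE],
                    B[ib[(half + 1):npc], , drop = FALSE])
    y <- factor(rep(c(lab_a, lab_b), each = half), levels = labels)
    list(train = list(x = x_train, y = y), test = list(x = x_test, y = y))
  })
}

#' AUC from classifier scores (Mann-Whitney formulation)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n1 * n0)`, computed via the
#' rank-sum identity with average ranks for ties.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels logical/0-1/two-level factor; `TRUE` (or the second level
#'   of a 0/1 coding) marks the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores) # average ranks handle ties as half-concordances
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit the extremely-randomised-trees ensemble on the train half and return
# test-half scores for the positive class.
fit_score_pair <- function(split, config, seed) {
  x_train <- as.data.frame(split$train$x)
  x_test <- as.data.frame(split$test$x)
  if (is.null(names(x_train)) || any(!nzchar(names(x_train)))) {
    names(x_train) <- names(x_test) <- paste0("f", seq_len(ncol(x_train)))
  }
  positive <- levels(split$train$y)[1] # lexicographically first label
  fit <- ranger::ranger(
    x = x_train, y = split$train$y,
    num.trees = config$n_trees,
    mtry = config$mtry %||% max(1L, floor(sqrt(ncol(x_train)))),
    splitrule = "extratrees",
    num.random.splits = config$num_random_splits,
    replace = FALSE, sample.fraction = 1,
    probability = TRUE, seed = seed, num.threads = 1
  )
  scores <- stats::predict(fit, data = x_test,
                           num.threads = 1)$predictions[, positive]
  list(scores = scores, is_positive = split$test$y == positive)
}

#' Pairwise group dissimilarity as classifier AUC
#'
#' Under-samples both groups to a common even size, splits 50:50 into
#' balanced train and test halves, fits an extremely-randomised-trees
#' classifier on the training half, and returns the AUC of its scores on
#' the test half.  An AUC near 0.5 means the two groups' style is
#' indistinguishable; near 1.0, perfectly separable.  The lexicographically
#' first label is the positive class.
#'
#' @param A,B feature matrices (documents x style categories).
#' @param labels length-2 character vector naming the two groups.
#' @param config a [dissim_config()].
#' @param seed integer seed for sampling, splitting and the ensemble.
#' @param n_per_class per-class size; default [balanced_sample_size()] of
#'   the row counts.
#' @return AUC in `[0, 1]`, with attribute `plan`.
#' @export
pair_dissimilarity <- function(A, B, labels = c("A", "B"),
                               config = dissim_config(), seed = 1L,
                               n_per_class = NULL) {
  stopifnot(inherits(config, "dissim_config"), length(labels) == 2,
            ncol(A) == ncol(B))
  if (labels[1] > labels[2]) {
    # canonical orientation: the result must not depend on argument order
    tmp <- A
    A <- B
    B <- tmp
    labels <- rev(labels)
  }
  n_per_class <- n_per_class %||% balanced_sample_size(nrow(A), nrow(B))
  if (n_per_class < config$min_per_class) {
    stop("per-class size ", n_per_class, " below minimum ",
         config$min_per_class, call. = FALSE)
  }
  if (all(apply(rbind(A, B), 2, function(c) length(unique(c)) == 1))) {
    warning("all features are constant; AUC computed on uninformative data")
  }
  plan <- pair_plan(labels[1], labels[2], n_per_class, seed)
  split <- train_test_split_pair(A, B, plan)
  sc <- fit_score_pair(split, config, seed)
  auc <- auc_from_scores(sc$scores, sc$is_positive)
  attr(auc, "plan") <- plan
  auc
}

#' Build the full pairwise dissimilarity matrix
#'
#' One classifier per unordered pair of groups (`choose(n, 2)` models).
#' Each pair's seed is derived from the master seed and the sorted label
#' pair, so the matrix is invariant to the order in which groups are
#' supplied (up to row/column permutation).
#'
#' @param groups named list of feature matrices, one per group (at least 3).
#' @param config a [dissim_config()].
#' @param seed master integer seed.
#' @param verbose print one log line per pair.
#' @return symmetric numeric matrix of AUCs with group labels as dimnames,
#'   diagonal per `config$diagonal`, and attributes `plans` (list of
#'   per-pair sampling plans) and `diagonal`.
#' @export
build_matrix <- function(groups, config = dissim_config(), seed = 1L,
                         verbose = FALSE) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  n <- length(groups)
  if (n < 3) stop("need at least 3 groups", call. = FALSE)
  sizes <- vapply(groups, nrow, integer(1))
  too_small <- names(sizes)[sizes < config$min_per_class]
  if (length(too_small)) {
    stop("group(s) below minimum size (", config$min_per_class, "): ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  labels <- names(groups)
  D <- matrix(if (config$diagonal == "zero") 0 else 0.5, n, n,
              dimnames = list(labels, labels))
  plans <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      key <- paste(sort(c(labels[i], labels[j])), collapse = "::")
      pseed <- derive_seed(seed, key)
      auc <- pair_dissimilarity(groups[[i]], groups[[j]],
                                labels = c(labels[i], labels[j]),
                                config = config, seed = pseed)
      D[i, j] <- D[j, i] <- as.numeric(auc)
      plans[[key]] <- attr(auc, "plan")
      if (verbose) {
        message(sprintf("pair %s: n_per_class=%d auc=%.4f seed=%d", key,
                        attr(auc, "plan")$n_per_class, auc, pseed))
      }
    }
  }
  attr(D, "plans") <- plans
  attr(D, "diagonal") <- config$diagonal
  D
}

#' Rescale AUCs to a chance-zero dissimilarity
#'
#' Optional affine transform `d = max(0, 2 * AUC - 1)` mapping the chance
#' level 0.5 to 0 and perfect separation to 1 (off-diagonal entries only).
#'
#' @param D an AUC dissimilarity matrix.
#' @return transformed matrix with a zero diagonal.
#' @export
auc_to_distance <- function(D) {
  check_dissim(D)
  out <- pmax(2 * D - 1, 0)
  diag(out) <- 0
  attr(out, "diagonal") <- "zero"
  out
}

#' Write a dissimilarity matrix as CSV
#'
#' @param D matrix from [build_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity_csv <- function(D, path) {
  utils::write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}
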