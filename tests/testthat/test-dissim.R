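test_that("balanced sampling takes the even-rounded minimum per class", {
  expect_equal(balanced_sample_size(10, 10), 10L)
  expect_equal(balanced_sample_size(91014, 25256), 25256L)
  expect_equal(balanced_sample_size(17519, 54495), 17518L) # odd -> even-down
  expect_equal(balanced_sample_size(3, 100), 2L)
  expect_error(balanced_sample_size(1, 100), "at least 2")
})

test_that("the 50:50 split is balanced, exact and seed-deterministic", {
  A <- matrix(rnorm(600), 200, 3)
  B <- matrix(rnorm(450), 150, 3)
  plan <- pair_plan("a", "b", 100, seed = 5)
  sp <- train_test_split_pair(A, B, plan)
  expect_equal(nrow(sp$train$x), 100)
  expect_equal(nrow(sp$test$x), 100)
  expect_equal(as.vector(table(sp$train$y)), c(50, 50))
  expect_equal(as.vector(table(sp$test$y)), c(50, 50))

  sp2 <- train_test_split_pair(A, B, plan)
  expect_identical(sp, sp2)

  # per-class 17518 -> 8759 per group per half
  expect_equal(17518L %/% 2L, 8759L)

  expect_error(
    train_test_split_pair(A, B, pair_plan("a", "b", 200, seed = 1)),
    "exceeds availability"
  )
  expect_error(pair_plan("a", "b", 101, 1), "even")
})

test_that("auc_from_scores matches exhaustive pair counting", {
  expect_equal(auc_from_scores(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_from_scores(rep(0.5, 8), rep(c(1, 0), 4)), 0.5)
  # hand-enumerable case: 2 concordant of 4 pairs
  expect_equal(auc_from_scores(c(0.3, 0.7, 0.5, 0.6), c(1, 1, 0, 0)), 0.5)
  expect_error(auc_from_scores(1:3, c(1, 1, 1)), "both classes")

  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), 2) # coarse grid to force ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_from_scores(scores, labels),
                 exhaustive_auc(scores, labels))
  }
})

test_that("auc_from_scores agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(60)
  labels <- rep(c(0, 1), 30)
  expect_equal(
    auc_from_scores(scores, labels),
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<")))
  )
})

test_that("same-profile pairs are at chance; shifted profiles are separable", {
  prof <- base_style_profile()
  cfg <- dissim_config(n_trees = 50)
  a <- make_profile_features(prof, 400, seed = 101)
  b <- make_profile_features(prof, 400, seed = 102)
  auc_null <- as.numeric(pair_dissimilarity(a, b, c("A", "B"), cfg,
                                            seed = 7))
  expect_gt(auc_null, 0.42) # Monte-Carlo band at n_per_class = 400
  expect_lt(auc_null, 0.58)

  # split-half of a single corpus is also at chance
  half <- as.numeric(pair_dissimilarity(a[1:200, ], a[201:400, ],
                                        c("A", "B"), cfg, seed = 8))
  expect_gt(half, 0.40)
  expect_lt(half, 0.60)

  shifted <- prof
  shifted$category_probs[1] <- 0.05
  b2 <- make_profile_features(shifted, 400, seed = 103)
  auc_shift <- as.numeric(pair_dissimilarity(a, b2, c("A", "B"), cfg,
                                             seed = 7))
  expect_gt(auc_shift, 0.75)
})

test_that("AUC grows with the divergence of the generating profiles", {
  prof <- base_style_profile()
  cfg <- dissim_config(n_trees = 50)
  a <- make_profile_features(prof, 300, seed = 31)
  aucs <- vapply(c(0, 0.015, 0.04), function(shift) {
    p2 <- prof
    p2$category_probs[1:4] <- p2$category_probs[1:4] + shift
    b <- make_profile_features(p2, 300, seed = 32)
    as.numeric(pair_dissimilarity(a, b, c("A", "B"), cfg, seed = 9))
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.03)) # non-decreasing within MC error
  expect_gt(aucs[3], aucs[1] + 0.2)
})

test_that("build_matrix yields a symmetric, order-invariant AUC matrix", {
  prof <- base_style_profile()
  groups <- lapply(stats::setNames(1:4, c("d", "b", "a", "c")),
                   function(i) make_profile_features(prof, 80, seed = i))
  cfg <- dissim_config(n_trees = 25)
  D <- build_matrix(groups, cfg, seed = 3)
  expect_equal(dim(D), c(4, 4))
  expect_length(attr(D, "plans"), choose(4, 2))
  expect_identical(D, t(D))
  expect_true(all(D[upper.tri(D)] >= 0 & D[upper.tri(D)] <= 1))
  expect_equal(unname(diag(D)), rep(0, 4))

  # permuting the input order permutes, but does not change, the matrix
  D2 <- build_matrix(groups[c("a", "b", "c", "d")], cfg, seed = 3)
  expect_equal(D2, D[rownames(D2), colnames(D2)],
               ignore_attr = TRUE)

  expect_error(build_matrix(groups[1:2], cfg, seed = 1), "at least 3")
  small <- c(groups, list(tiny = groups[[1]][1:2, ]))
  expect_error(build_matrix(small, cfg, seed = 1), "tiny")
})

test_that("half-diagonal convention and affine rescaling are available", {
  prof <- base_style_profile()
  groups <- lapply(stats::setNames(1:3, letters[1:3]),
                   function(i) make_profile_features(prof, 60, seed = i))
  D <- build_matrix(groups, dissim_config(n_trees = 10, diagonal = "half"),
                    seed = 2)
  expect_equal(unname(diag(D)), rep(0.5, 3))
  R <- auc_to_distance(D)
  expect_equal(unname(diag(R)), rep(0, 3))
  expect_true(all(R >= 0))
  expect_equal(R[1, 2], max(0, 2 * D[1, 2] - 1))
})

test_that("constant features warn but still yield an AUC", {
  A <- matrix(1, 40, 3)
  B <- matrix(1, 40, 3)
  expect_warning(
    auc <- pair_dissimilarity(A, B, c("A", "B"),
                              dissim_config(n_trees = 5), seed = 1),
    "constant"
  )
  expect_true(as.numeric(auc) >= 0 && as.numeric(auc) <= 1)
})
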