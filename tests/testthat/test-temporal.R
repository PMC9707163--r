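test_that("comments are partitioned into UTC calendar years", {
  utc <- function(y, m = 6, d = 15) {
    as.numeric(ISOdatetime(y, m, d, 12, 0, 0, tz = "UTC"))
  }
  df <- data.frame(
    id = as.character(1:10), author = "u", body = "text",
    created_utc = c(vapply(2011:2019, utc, numeric(1)), utc(2015)),
    group = "g"
  )
  slices <- slice_by_period(df)
  expect_equal(names(slices), as.character(2011:2019))
  expect_equal(nrow(slices[["2015"]]), 2)

  one <- slice_by_period(df[df$created_utc == utc(2013), ])
  expect_length(one, 1)

  # half-open convention: midnight Jan 1 belongs to the new year
  boundary <- df[1, ]
  boundary$created_utc <- as.numeric(ISOdatetime(2015, 1, 1, 0, 0, 0,
                                                 tz = "UTC"))
  expect_equal(names(slice_by_period(boundary)), "2015")
})

test_that("Spearman trends hit the monotone extremes", {
  up <- spearman_trend(c(1.2, 1.9, 2.3, 4.1, 5.5), 2011:2015)
  expect_equal(up$rho, 1)
  expect_equal(up$df, 3)
  down <- spearman_trend(c(5, 4, 3, 2, 1), 1:5)
  expect_equal(down$rho, -1)
  expect_error(spearman_trend(rep(2, 5), 1:5), "constant")
  expect_error(spearman_trend(1:2, 1:2), "at least 3")
})

test_that("exact permutation p-values match full enumeration", {
  cases <- list(
    list(v = c(2, 1, 4, 3, 5), t = 1:5),
    list(v = c(0.3, 0.1, 0.9, 0.2, 0.8), t = c(1, 2, 3, 4, 5)),
    list(v = c(3, 1, 2, 2, 5, 4), t = 1:6), # ties in values
    list(v = c(7, 3, 5, 1, 9, 2, 8), t = 1:7)
  )
  for (cs in cases) {
    got <- spearman_trend(cs$v, cs$t)
    expect_equal(got$method, "exact permutation")
    expect_equal(got$p, spearman_perm_oracle(cs$v, cs$t), tolerance = 1e-12)
    expect_equal(got$rho, cor(cs$v, cs$t, method = "spearman"),
                 tolerance = 1e-12)
  }
  # untied case also agrees with cor.test's exact p
  got <- spearman_trend(c(2, 1, 4, 3, 5), 1:5)
  ref <- cor.test(c(2, 1, 4, 3, 5), 1:5, method = "spearman")
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("large-n trends fall back to the t approximation", {
  set.seed(61)
  v <- rnorm(15)
  got <- spearman_trend(v, 1:15)
  expect_equal(got$method, "t approximation")
  ref <- cor.test(v, 1:15, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

make_test_trajectory <- function(drifting = TRUE, n_anchors = 4,
                                 n_slices = 5, n_docs = 100, seed = 301) {
  prof <- base_style_profile()
  anchors <- lapply(
    stats::setNames(seq_len(n_anchors), paste0("anchor", seq_len(n_anchors))),
    function(i) {
      p <- prof
      p$category_probs[i] <- p$category_probs[i] + 0.03
      make_profile_features(p, n_docs, seed = seed + i)
    }
  )
  slices <- lapply(stats::setNames(seq_len(n_slices),
                                   2012 + seq_len(n_slices) - 1), function(s) {
    p <- prof
    if (drifting) {
      w <- (s - 1) / (n_slices - 1)
      p$category_probs[1] <- p$category_probs[1] + 0.08 * w
    }
    make_profile_features(p, n_docs, seed = seed + 100 + s)
  })
  list(slices = slices, anchors = anchors)
}

test_that("anchored trajectories keep anchors fixed and track drift", {
  fx <- make_test_trajectory()
  traj <- anchored_trajectory(fx$slices, fx$anchors,
                              config = dissim_config(n_trees = 40),
                              seed = 5, min_per_class = 20)
  expect_s3_class(traj, "style_trajectory")
  expect_equal(traj$slices, as.character(2012:2016))
  expect_equal(dim(traj$coords), c(5, 2))

  # anchors held constant: with only 4 anchors a strongly moving focal
  # point distorts the centering, so the band is loose here; the 14-anchor
  # configuration is checked tightly in the acceptance suite
  anchor_sd <- apply(simplify2array(traj$anchor_coords), c(1, 2), sd)
  expect_lt(max(anchor_sd), 0.2)

  # drift along one profile axis shows up as a strong monotone trend
  rhos <- vapply(traj$trend, function(tr) tr$rho, numeric(1))
  expect_gte(max(abs(rhos)), 0.9)

  # anchor-anchor block identical to a standalone build (computed once)
  D_aa <- build_matrix(fx$anchors, dissim_config(n_trees = 40), seed = 5)
  expect_identical(traj$anchor_matrix, D_aa)
})

test_that("a focal group matching an anchor sits at that anchor, stably", {
  fx <- make_test_trajectory(drifting = FALSE)
  # re-generate slices from anchor 1's exact profile
  prof <- base_style_profile()
  p1 <- prof
  p1$category_probs[1] <- p1$category_probs[1] + 0.03
  slices <- lapply(stats::setNames(1:4, 2012:2015), function(s) {
    make_profile_features(p1, 80, seed = 900 + s)
  })
  traj <- anchored_trajectory(slices, fx$anchors,
                              config = dissim_config(n_trees = 40),
                              seed = 6, min_per_class = 20)
  a1 <- t(vapply(traj$anchor_coords, function(m) m["anchor1", ],
                 numeric(2)))
  gap <- sqrt(rowSums((traj$coords - a1)^2))
  spread <- max(dist(traj$anchor_coords[[1]]))
  expect_lt(max(gap), 0.45 * spread) # closer to its twin than to the field
})

test_that("undersized slices are skipped with a warning", {
  fx <- make_test_trajectory(n_slices = 3)
  fx$slices[["2012"]] <- fx$slices[["2012"]][1:10, ]
  expect_warning(
    traj <- anchored_trajectory(fx$slices, fx$anchors,
                                config = dissim_config(n_trees = 10),
                                seed = 7, min_per_class = 20),
    "2012.*skipped"
  )
  expect_equal(traj$slices, c("2013", "2014"))
})

test_that("slice exclusion recomputes the trend and is reversible", {
  fx <- make_test_trajectory(n_slices = 6)
  traj <- anchored_trajectory(fx$slices, fx$anchors,
                              config = dissim_config(n_trees = 40),
                              seed = 8, min_per_class = 20)
  n0 <- traj$trend$dim1$n
  excl <- exclude_slice(traj, traj$slices[1])
  expect_equal(excl$trend$dim1$n, n0 - 1)
  expect_equal(excl$excluded, traj$slices[1])
  back <- include_slice(excl, traj$slices[1])
  expect_equal(back$trend, traj$trend)
  expect_error(exclude_slice(traj, "1999"), "unknown slice")
})

test_that("excluding an anomalous first slice flips a trend's direction", {
  # constructed coordinates: 2011 breaks an otherwise decreasing series
  traj <- structure(
    list(
      slices = as.character(2011:2016), times = 2011:2016,
      coords = cbind(dim1 = c(-2.0, 0.9, 0.75, 0.5, 0.3, 0.1),
                     dim2 = c(0.1, 0.2, 0.15, 0.3, 0.25, 0.4)),
      trend = NULL, anchor_labels = character(0),
      anchor_coords = list(), disparity = numeric(0),
      anchor_matrix = NULL, embeddings = list(),
      excluded = character(0)
    ),
    class = "style_trajectory"
  )
  rownames(traj$coords) <- traj$slices
  traj$trend <- stylemap:::trajectory_trend(traj)
  expect_gt(traj$trend$dim1$p, 0.2) # anomaly masks the decline
  after <- exclude_slice(traj, "2011")
  expect_equal(after$trend$dim1$rho, -1)
  expect_lt(after$trend$dim1$p, 0.05)
  expect_equal(after$trend$dim1$n, 5)
})
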