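#' Group-level personal-values scores
#'
#' Scores every post of every group against a ten-category value lexicon
#' (per-post percentage of tokens matching each value's patterns) and
#' averages the per-post percentages within each group, unweighted by post
#' length.
#'
#' @param corpora named list of cleaned comment data frames (or character
#'   vectors of bodies), one per group.
#' @param value_lexicon a `category_lexicon` declaring exactly the ten
#'   canonical value categories (see [value_category_names()]).
#' @return numeric matrix (groups x 10) of mean percentages, rows in input
#'   group order, columns in canonical value order.
#' @export
score_values <- function(corpora, value_lexicon = values_lexicon()) {
  stopifnot(is.list(corpora), !is.null(names(corpora)),
            inherits(value_lexicon, "category_lexicon"))
  want <- value_category_names()
  if (!setequal(value_lexicon$categories, want)) {
    stop("value lexicon must declare exactly the ten value categories: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, length(corpora), length(want),
                dimnames = list(names(corpora), want))
  for (g in names(corpora)) {
    x <- corpora[[g]]
    n_posts <- if (is.data.frame(x)) nrow(x) else length(x)
    if (n_posts == 0) {
      stop("group '", g, "' has zero posts", call. = FALSE)
    }
    out[g, ] <- colMeans(featurize_group(x, value_lexicon, want))
  }
  out
}

#' OLS regression of one value on two embedding coordinates
#'
#' Fits `value ~ dim1 + dim2` with an intercept by ordinary least squares
#' over the n groups, reporting unstandardised slopes, standard errors,
#' two-sided t-based 95% confidence intervals (n - 3 residual df), R-squared
#' and the overall F-test p-value.
#'
#' @param value_means numeric vector: one group-mean value score per group.
#' @param coords n x 2 matrix of embedding coordinates (same group order).
#' @return object of class `"value_regression"`: one-row data frame with
#'   columns `b1, se1, ci1_lo, ci1_hi, b2, se2, ci2_lo, ci2_hi, r_squared,
#'   p_value`.
#' @export
regress_value_on_coords <- function(value_means, coords) {
  coords <- as.matrix(coords)
  n <- length(value_means)
  stopifnot(nrow(coords) == n, ncol(coords) == 2)
  if (n < 4) stop("need at least 4 groups (n - 3 residual df)", call. = FALSE)
  df_fit <- data.frame(y = as.numeric(value_means),
                       d1 = coords[, 1], d2 = coords[, 2])
  fit <- stats::lm(y ~ d1 + d2, data = df_fit)
  if (fit$rank < 3) {
    stop("rank-deficient design: coordinates are collinear", call. = FALSE)
  }
  # summary.lm warns on exact fits; exact fits are valid input here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  tss <- sum((df_fit$y - mean(df_fit$y))^2)
  if (tss < 1e-24) {
    r2 <- 0
    p <- 1
  } else {
    r2 <- sm$r.squared
    f <- sm$fstatistic
    p <- stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }
  out <- data.frame(
    b1 = co["d1", 1], se1 = co["d1", 2],
    ci1_lo = ci["d1", 1], ci1_hi = ci["d1", 2],
    b2 = co["d2", 1], se2 = co["d2", 2],
    ci2_lo = ci["d2", 1], ci2_hi = ci["d2", 2],
    r_squared = as.numeric(r2), p_value = as.numeric(p),
    row.names = NULL
  )
  class(out) <- c("value_regression", "data.frame")
  out
}

#' Per-value regression table on embedding coordinates
#'
#' Runs one independent OLS regression per value category (ten in the
#' canonical set), each predicting the group-mean value score from the two
#' embedding coordinates.  P-values are reported raw, without multiple-
#' testing correction across the ten regressions.
#'
#' @param value_scores matrix from [score_values()] (groups x values).
#' @param coords n x 2 coordinate matrix with rows in the same group order
#'   (e.g. `coef()` of a [style_map()] fit).
#' @return data frame of class `"value_table"`, one row per value, with the
#'   slope/SE/CI columns of [regress_value_on_coords()] plus `value`.
#' @export
run_value_table <- function(value_scores, coords) {
  value_scores <- as.matrix(value_scores)
  coords <- as.matrix(coords)
  if (!is.null(rownames(value_scores)) && !is.null(rownames(coords))) {
    if (!setequal(rownames(value_scores), rownames(coords))) {
      stop("group labels of scores and coordinates differ", call. = FALSE)
    }
    coords <- coords[rownames(value_scores), , drop = FALSE]
  }
  rows <- lapply(colnames(value_scores), function(v) {
    cbind(value = v,
          as.data.frame(regress_value_on_coords(value_scores[, v], coords)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("value_table", "data.frame")
  out
}

#' @export
print.value_table <- function(x, digits = 3, ...) {
  cat("Value regressions on embedding coordinates",
      "(raw p-values, no multiplicity correction):\n")
  print.data.frame(
    cbind(value = x$value,
          round(x[, setdiff(names(x), "value")], digits)),
    row.names = FALSE
  )
  invisible(x)
}

#' Write the value regression table as CSV
#'
#' @param table a `value_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_value_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
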