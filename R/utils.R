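#' Derive a reproducible child seed from a master seed and a string key
#'
#' All stage- and pair-level randomness in the package flows from one master
#' seed: each unit of work (a group pair, a time slice, a value of k) gets its
#' own seed derived deterministically from the master seed and a stable label.
#' This makes per-pair results independent of the order in which pairs are
#' computed.
#'
#' @param master integer master seed.
#' @param key character label identifying the unit of work.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "islam::sales")
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master), length(key) == 1)
  m <- 2147483629 # largest prime below 2^31
  h <- 2166136261 %% m
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% m
  }
  h <- (h + (as.numeric(master) %% m) * 48271) %% m
  as.integer(h + 1)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  expr
}

#' Tokenize text
#'
#' Canonical tokenizer used throughout the package: text is lowercased and
#' tokens are maximal runs of letters/digits with internal apostrophes
#' allowed; every other character separates tokens.  This makes the minimum
#' word-count cleaning rule and all dictionary matching deterministic.
#'
#' @param x character vector.
#' @return a list with one character vector of tokens per element of `x`.
#' @export
#' @examples
#' tokenize("Don't stop believing!")
tokenize <- function(x) {
  x <- tolower(as.character(x))
  m <- gregexpr("[\\p{L}\\p{N}]+(?:'[\\p{L}\\p{N}]+)*", x, perl = TRUE)
  out <- regmatches(x, m)
  lapply(out, function(t) t[t != ""])
}

#' Count words in a text
#'
#' @param body character vector of texts.
#' @return integer vector of token counts under [tokenize()].
#' @export
#' @examples
#' word_count("a b, c... d!") # 4
word_count <- function(body) {
  lengths(tokenize(body))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a symmetric dissimilarity matrix with the expected diagonal.
check_dissim <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("dissimilarity must be a square matrix", call. = FALSE)
  }
  if (max(abs(D - t(D))) > tol) {
    stop("dissimilarity matrix is not symmetric", call. = FALSE)
  }
  invisible(D)
}
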