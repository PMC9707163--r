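#' Category lexicons (LIWC-format dictionaries)
#'
#' A category lexicon maps token patterns to one or more named categories.
#' Patterns are either literals (`"the"`) or stems with a trailing wildcard
#' (`"happ*"`, matching any token with that prefix).  A token that matches a
#' literal entry takes its categories from that entry alone; otherwise it
#' collects the categories of every matching stem.  Lexicons may additionally
#' carry *computed* categories — predicates on the token itself (for example
#' "six letters or more") that LIWC-style scoring counts alongside
#' dictionary categories.
#'
#' @name category_lexicon
NULL

new_category_lexicon <- function(categories, literals, stems,
                                 computed = list(), source = NA_character_) {
  stopifnot(!anyDuplicated(categories))
  lit_env <- new.env(parent = emptyenv(), size = max(16L, length(literals)))
  for (tok in names(literals)) assign(tok, literals[[tok]], envir = lit_env)
  structure(
    list(
      categories = categories,
      literals = literals,
      literal_env = lit_env,
      stems = stems, # named list: stem -> integer category indices
      computed = computed, # named list: category -> function(tokens) logical
      source = source
    ),
    class = "category_lexicon"
  )
}

#' @export
print.category_lexicon <- function(x, ...) {
  cat("Category lexicon:", length(x$categories), "categories,",
      length(x$literals), "literal and", length(x$stems), "stem patterns")
  if (length(x$computed)) cat(",", length(x$computed), "computed")
  cat("\n")
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Load a LIWC-format `.dic` dictionary
#'
#' Parses the standard `.dic` dialect: a header delimited by lines containing
#' only `%`, with one `id name` pair per line, followed by body lines of the
#' form `word id id ...`.  A trailing `*` on a word marks a stem pattern.
#'
#' @param path path to the dictionary file.
#' @return a `category_lexicon`.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop("dictionary not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  delim <- which(trimws(lines) == "%")
  if (length(delim) < 2) {
    stop("not a .dic file: expected a %-delimited header in ", path,
         call. = FALSE)
  }
  header <- lines[(delim[1] + 1):(delim[2] - 1)]
  body <- if (delim[2] < length(lines)) lines[(delim[2] + 1):length(lines)] else character(0)

  ids <- integer(0)
  cats <- character(0)
  for (i in seq_along(header)) {
    ln <- trimws(header[i])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2 || is.na(suppressWarnings(as.integer(parts[1])))) {
      stop("malformed header line ", delim[1] + i, ": '", ln, "'",
           call. = FALSE)
    }
    id <- as.integer(parts[1])
    if (id %in% ids) {
      stop("duplicate category id ", id, " at line ", delim[1] + i,
           call. = FALSE)
    }
    ids <- c(ids, id)
    cats <- c(cats, parts[2])
  }
  if (anyDuplicated(cats)) {
    stop("duplicate category names in header", call. = FALSE)
  }
  if (length(body) && !length(cats)) {
    stop("dictionary body present but no categories declared", call. = FALSE)
  }
  if (!length(body)) {
    warning("dictionary '", basename(path), "' declares no patterns")
  }

  literals <- list()
  stems <- list()
  for (i in seq_along(body)) {
    ln <- trimws(body[i])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    word <- tolower(parts[1])
    ref <- suppressWarnings(as.integer(parts[-1]))
    if (length(ref) == 0 || anyNA(ref)) {
      stop("malformed body line ", delim[2] + i, ": '", ln, "'", call. = FALSE)
    }
    pos <- match(ref, ids)
    if (anyNA(pos)) {
      stop("undeclared category id ", paste(ref[is.na(pos)], collapse = ", "),
           " referenced at line ", delim[2] + i, call. = FALSE)
    }
    pos <- sort(unique(pos))
    if (endsWith(word, "*")) {
      stem <- substr(word, 1, nchar(word) - 1)
      stems[[stem]] <- sort(unique(c(stems[[stem]], pos)))
    } else {
      literals[[word]] <- sort(unique(c(literals[[word]], pos)))
    }
  }
  new_category_lexicon(cats, literals, stems, source = path)
}

#' Add a computed category to a lexicon
#'
#' Computed categories are predicates evaluated on each token (for example,
#' token length at least six); every token satisfying the predicate counts
#' toward the category, independently of dictionary matches.
#'
#' @param lexicon a `category_lexicon`.
#' @param name category name (must be new).
#' @param predicate function mapping a character vector of tokens to a
#'   logical vector.
#' @return the extended lexicon.
#' @export
add_computed_category <- function(lexicon, name, predicate) {
  stopifnot(inherits(lexicon, "category_lexicon"), is.function(predicate))
  if (name %in% lexicon$categories) {
    stop("category '", name, "' already declared", call. = FALSE)
  }
  lexicon$categories <- c(lexicon$categories, name)
  lexicon$computed[[name]] <- predicate
  lexicon
}

#' Bundled open style lexicon (41 categories)
#'
#' Loads the package's open stand-in style dictionary: 40 function-word and
#' style categories (pronoun subclasses, articles, prepositions, auxiliary
#' verbs, adverbs, conjunctions, negations, quantifiers, numbers, hedges,
#' intensifiers, netspeak, ...) plus the computed category `sixltr` (tokens
#' of six or more characters), for 41 style features in total.  It is a
#' stand-in of the same size and character as the proprietary LIWC 2015
#' style set, which cannot be redistributed; users holding a licensed LIWC
#' dictionary can load it with [load_dictionary()] for full fidelity.
#'
#' @return a `category_lexicon` with 41 categories.
#' @export
style_lexicon <- function() {
  path <- system.file("extdata", "style41_standin.dic", package = "stylemap")
  lex <- load_dictionary(path)
  add_computed_category(lex, "sixltr", function(tokens) nchar(tokens) >= 6)
}

#' Canonical names of the ten personal-values categories
#' @return character vector of length 10.
#' @export
value_category_names <- function() {
  c("achievement", "benevolence", "conformity", "hedonism", "power",
    "security", "self-direction", "stimulation", "tradition", "universalism")
}

#' Bundled open personal-values lexicon (10 categories)
#'
#' Loads the package's open stand-in value dictionary with the ten canonical
#' personal-values categories (achievement, benevolence, conformity,
#' hedonism, power, security, self-direction, stimulation, tradition,
#' universalism).  The word lists are the package's own small open lists;
#' users of a published values dictionary in `.dic` format can load it with
#' [load_dictionary()] instead.
#'
#' @return a `category_lexicon` with 10 categories.
#' @export
values_lexicon <- function() {
  load_dictionary(
    system.file("extdata", "values10_standin.dic", package = "stylemap")
  )
}

#' Write a lexicon's dictionary categories to a `.dic` file
#'
#' Computed categories have no word list and are omitted (with a message) —
#' they cannot be represented in the `.dic` format.
#'
#' @param lexicon a `category_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dic <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  dict_cats <- setdiff(lexicon$categories, names(lexicon$computed))
  if (length(lexicon$computed)) {
    message("omitting computed categories from .dic: ",
            paste(names(lexicon$computed), collapse = ", "))
  }
  idx <- match(dict_cats, lexicon$categories)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("%", con)
  writeLines(sprintf("%d\t%s", seq_along(dict_cats), dict_cats), con)
  writeLines("%", con)
  emit <- function(word, cat_pos) {
    keep <- match(cat_pos, idx)
    keep <- keep[!is.na(keep)]
    if (length(keep)) {
      writeLines(paste(c(word, keep), collapse = "\t"), con)
    }
  }
  for (w in names(lexicon$literals)) emit(w, lexicon$literals[[w]])
  for (s in names(lexicon$stems)) emit(paste0(s, "*"), lexicon$stems[[s]])
  invisible(path)
}

# Map unique tokens to a 0/1 incidence matrix over lexicon categories.
token_category_incidence <- function(tokens_unique, lexicon) {
  K <- length(lexicon$categories)
  M <- matrix(0, nrow = length(tokens_unique), ncol = K,
              dimnames = list(NULL, lexicon$categories))
  lit <- lapply(tokens_unique, function(t) {
    get0(t, envir = lexicon$literal_env, inherits = FALSE)
  })
  has_lit <- !vapply(lit, is.null, logical(1))
  for (i in which(has_lit)) M[i, lit[[i]]] <- 1
  if (length(lexicon$stems) && any(!has_lit)) {
    miss <- which(!has_lit)
    toks <- tokens_unique[miss]
    for (s in names(lexicon$stems)) {
      hit <- startsWith(toks, s)
      if (any(hit)) M[miss[hit], lexicon$stems[[s]]] <- 1
    }
  }
  for (cname in names(lexicon$computed)) {
    M[, cname] <- as.numeric(lexicon$computed[[cname]](tokens_unique))
  }
  M
}

#' Score one document against a lexicon
#'
#' Computes, for each category, 100 times the fraction of the document's
#' tokens matching any of the category's patterns (bag of words: token order
#' is ignored, one token may count toward several categories).
#'
#' @param body a single text.
#' @param lexicon a `category_lexicon`.
#' @param categories ordered subset of category names to report; default all.
#' @return named numeric vector of percentages in `[0, 100]`, with attribute
#'   `n_tokens`.
#' @export
score_document <- function(body, lexicon,
                           categories = lexicon$categories) {
  stopifnot(length(body) == 1)
  m <- featurize_group(body, lexicon, categories)
  v <- m[1, ]
  attr(v, "n_tokens") <- attr(m, "n_tokens")[1]
  v
}

#' Featurize a group corpus into style vectors
#'
#' One row per comment, one column per configured category; each entry is a
#' percentage of the comment's tokens.  All comments must have at least one
#' token (guaranteed upstream by the minimum-word-count cleaning rule).
#'
#' @param comments a comment data frame (with a `body` column) or a
#'   character vector of document texts.
#' @param lexicon a `category_lexicon`.
#' @param categories ordered subset of category names; default all.
#' @return numeric matrix (documents x categories) with attribute
#'   `n_tokens`; row names are comment ids when available.
#' @export
featurize_group <- function(comments, lexicon,
                            categories = lexicon$categories) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  missing_cat <- setdiff(categories, lexicon$categories)
  if (length(missing_cat)) {
    stop("unknown categories: ", paste(missing_cat, collapse = ", "),
         call. = FALSE)
  }
  bodies <- if (is.data.frame(comments)) comments$body else as.character(comments)
  ids <- if (is.data.frame(comments) && !is.null(comments$id)) {
    comments$id
  } else {
    NULL
  }
  n <- length(bodies)
  if (n == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = length(categories),
                  dimnames = list(NULL, categories))
    attr(out, "n_tokens") <- integer(0)
    return(out)
  }
  toks <- tokenize(bodies)
  n_tok <- lengths(toks)
  if (any(n_tok == 0)) {
    stop("document(s) with zero tokens at position(s) ",
         paste(utils::head(which(n_tok == 0), 5), collapse = ", "),
         "; clean the corpus first", call. = FALSE)
  }
  flat <- unlist(toks, use.names = FALSE)
  u <- unique(flat)
  M <- token_category_incidence(u, lexicon)[, categories, drop = FALSE]
  doc <- rep.int(seq_len(n), n_tok)
  counts <- rowsum(M[match(flat, u), , drop = FALSE], group = doc,
                   reorder = TRUE)
  out <- 100 * counts / n_tok
  dimnames(out) <- list(ids, categories)
  attr(out, "n_tokens") <- n_tok
  out
}
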