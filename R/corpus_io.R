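#' Read a per-group comment corpus
#'
#' Reads one comment per record from JSON Lines (one object per line) or CSV.
#' Required fields are `id`, `author`, `body`, `created_utc` and a group
#' label under either `group` or `subreddit`.  An optional `title` field, if
#' present, is concatenated in front of the body separated by one space.
#' Malformed records (missing required fields, unparseable lines) are
#' rejected individually and counted; the count is attached as the
#' `"read_report"` attribute.
#'
#' @param path path to the file.
#' @param format `"jsonl"`, `"csv"`, or `"auto"` (by file extension;
#'   `.jsonl`/`.json` is JSON Lines, anything else CSV).
#' @return a data frame with columns `id`, `author`, `body`, `created_utc`,
#'   `group`, in file order, with attribute `read_report` =
#'   `list(n_records, n_kept, n_malformed)`.
#' @export
read_comments <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl?|ndjson)$", path, ignore.case = TRUE)) {
      "jsonl"
    } else {
      "csv"
    }
  }
  required <- c("id", "author", "body", "created_utc")
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    ok <- vapply(recs, function(r) {
      is.list(r) && all(required %in% names(r)) &&
        ("group" %in% names(r) || "subreddit" %in% names(r))
    }, logical(1))
    n_records <- length(recs)
    recs <- recs[ok]
    df <- if (length(recs)) {
      data.frame(
        id = vapply(recs, function(r) as.character(r$id), character(1)),
        author = vapply(recs, function(r) as.character(r$author), character(1)),
        body = vapply(recs, function(r) {
          b <- as.character(r$body)
          if (!is.null(r$title) && nzchar(r$title)) paste(r$title, b) else b
        }, character(1)),
        created_utc = vapply(recs, function(r) as.numeric(r$created_utc),
                             numeric(1)),
        group = vapply(recs, function(r) {
          as.character(r$group %||% r$subreddit)
        }, character(1)),
        stringsAsFactors = FALSE
      )
    } else {
      empty_comments()
    }
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    n_records <- nrow(raw)
    if (!("group" %in% names(raw)) && "subreddit" %in% names(raw)) {
      raw$group <- raw$subreddit
    }
    missing_col <- setdiff(c(required, "group"), names(raw))
    if (length(missing_col) && n_records > 0) {
      stop("csv is missing required column(s): ",
           paste(missing_col, collapse = ", "), call. = FALSE)
    }
    if (n_records == 0) {
      df <- empty_comments()
    } else {
      body <- as.character(raw$body)
      if ("title" %in% names(raw)) {
        has_title <- !is.na(raw$title) & nzchar(raw$title)
        body[has_title] <- paste(raw$title[has_title], body[has_title])
      }
      ok <- !is.na(raw$id) & !is.na(raw$author) & !is.na(body) &
        !is.na(suppressWarnings(as.numeric(raw$created_utc))) & !is.na(raw$group)
      df <- data.frame(
        id = as.character(raw$id)[ok],
        author = as.character(raw$author)[ok],
        body = body[ok],
        created_utc = as.numeric(raw$created_utc)[ok],
        group = as.character(raw$group)[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  rownames(df) <- NULL
  attr(df, "read_report") <- list(
    n_records = n_records, n_kept = nrow(df),
    n_malformed = n_records - nrow(df)
  )
  df
}

empty_comments <- function() {
  data.frame(
    id = character(0), author = character(0), body = character(0),
    created_utc = numeric(0), group = character(0), stringsAsFactors = FALSE
  )
}

#' Cleaning rules for comment corpora
#'
#' Configuration for [clean_comments()].  Defaults reproduce the standard
#' exclusion rules for Reddit-style comment dumps: self-identifying bots,
#' deleted authors, deleted/removed bodies, URL-only posts, URL stripping,
#' and a minimum word count of 50.
#'
#' @param min_words minimum token count (after URL stripping) for a comment
#'   to survive; default 50.
#' @param bot_suffix treat any author whose name ends in `"bot"`
#'   (case-insensitive) as a self-identifying bot.
#' @param bot_authors additional author names (exact match) to treat as bots.
#' @param deleted_authors author sentinels marking deleted accounts.
#' @param deleted_bodies body sentinels marking deleted/removed posts.
#' @return an object of class `"clean_rules"`.
#' @export
clean_rules <- function(min_words = 50,
                        bot_suffix = TRUE,
                        bot_authors = character(0),
                        deleted_authors = "[deleted]",
                        deleted_bodies = c("[deleted]", "[removed]")) {
  stopifnot(min_words >= 0)
  structure(
    list(
      min_words = min_words, bot_suffix = bot_suffix,
      bot_authors = bot_authors, deleted_authors = deleted_authors,
      deleted_bodies = deleted_bodies
    ),
    class = "clean_rules"
  )
}

# schemeful URLs and bare www. prefixes
url_regex <- function() "(?i)\\b(?:https?://|www\\.)[^\\s]+"

#' Clean a comment corpus
#'
#' Applies the exclusion rules in a fixed order, attributing each removed
#' comment to the first matching rule: (1) bot author, (2) deleted author,
#' (3) deleted/removed body, (4) URL-only body; then URLs are stripped from
#' the survivors and (5) comments with fewer than `rules$min_words` tokens
#' are removed.  Cleaning is idempotent.
#'
#' @param comments a comment data frame as returned by [read_comments()].
#' @param rules a [clean_rules()] object.
#' @return `list(comments = <surviving data frame, URLs stripped>,
#'   report = <cleaning_report>)`.  The report counts removals per rule and
#'   satisfies `output_count = input_count - sum(removed)`.
#' @export
clean_comments <- function(comments, rules = clean_rules()) {
  stopifnot(inherits(rules, "clean_rules"))
  n <- nrow(comments)
  if (n == 0) {
    report <- new_cleaning_report(0L, integer(5))
    return(list(comments = comments, report = report))
  }
  author <- comments$author
  body <- comments$body

  is_bot <- author %in% rules$bot_authors
  if (isTRUE(rules$bot_suffix)) {
    is_bot <- is_bot | grepl("bot$", author, ignore.case = TRUE)
  }
  is_deleted_author <- author %in% rules$deleted_authors
  is_deleted_body <- trimws(body) %in% rules$deleted_bodies
  stripped <- gsub(url_regex(), " ", body, perl = TRUE)
  had_url <- stripped != body
  wc <- word_count(stripped)
  is_url_only <- had_url & wc == 0 &
    !nzchar(gsub("[[:space:][:punct:]]", "", stripped))
  is_short <- wc < rules$min_words

  # first matching rule wins
  rule_mat <- cbind(
    bot = is_bot, deleted_author = is_deleted_author,
    deleted_body = is_deleted_body, url_only = is_url_only,
    min_words = is_short
  )
  first_rule <- apply(rule_mat, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else 0L
  })
  removed <- vapply(seq_len(ncol(rule_mat)), function(j) {
    sum(first_rule == j)
  }, integer(1))
  names(removed) <- colnames(rule_mat)

  keep <- first_rule == 0L
  out <- comments[keep, , drop = FALSE]
  out$body <- trimws(gsub("[ \t]+", " ", stripped[keep]))
  rownames(out) <- NULL
  list(comments = out, report = new_cleaning_report(n, removed))
}

new_cleaning_report <- function(input_count, removed) {
  if (is.null(names(removed))) {
    names(removed) <- c("bot", "deleted_author", "deleted_body",
                        "url_only", "min_words")
  }
  structure(
    list(
      input_count = as.integer(input_count),
      removed = as.integer(removed) |> stats::setNames(names(removed)),
      output_count = as.integer(input_count - sum(removed))
    ),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$input_count, "comments in,",
      x$output_count, "kept\n")
  for (r in names(x$removed)) {
    cat(sprintf("  %-16s %d removed\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' Write a cleaning report as JSON
#'
#' @param report a cleaning report from [clean_comments()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(
    list(
      input_count = report$input_count,
      removed = as.list(report$removed),
      output_count = report$output_count
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Write a comment corpus as JSON Lines
#'
#' @param comments comment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comments <- function(comments, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(comments))) {
    writeLines(jsonlite::toJSON(as.list(comments[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
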