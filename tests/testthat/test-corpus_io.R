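test_that("word_count follows the canonical tokenizer", {
  expect_equal(word_count(""), 0L)
  expect_equal(word_count("don't stop believing"), 3L)
  expect_equal(word_count("a b, c... d!"), 4L)
  expect_equal(word_count(c("one two", "")), c(2L, 0L))
  # apostrophes are internal only: leading/trailing quotes separate
  expect_equal(tokenize("'tis the day's end'")[[1]],
               c("tis", "the", "day's", "end"))
})

test_that("JSONL corpora are read record by record with malformed counting", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a1","author":"u1","body":"hello world","created_utc":1500000000,"subreddit":"g1"}',
    '{"id":"a2","author":"u2","body":"second record","created_utc":1500000001,"subreddit":"g1"}',
    '{"id":"a3","author":"u3","body":"third","created_utc":1500000002,"subreddit":"g2"}'
  ), path)
  df <- read_comments(path, "jsonl")
  expect_equal(nrow(df), 3)
  expect_equal(df$group, c("g1", "g1", "g2"))
  expect_equal(attr(df, "read_report")$n_malformed, 0)

  # record missing "body" is rejected, the rest kept
  writeLines(c(
    '{"id":"a1","author":"u1","created_utc":1,"subreddit":"g1"}',
    '{"id":"a2","author":"u2","body":"ok","created_utc":2,"subreddit":"g1"}'
  ), path)
  df <- read_comments(path, "jsonl")
  expect_equal(nrow(df), 1)
  expect_equal(attr(df, "read_report")$n_malformed, 1)

  # empty file
  writeLines(character(0), path)
  df <- read_comments(path, "jsonl")
  expect_equal(nrow(df), 0)
  expect_equal(attr(df, "read_report")$n_records, 0)
})

test_that("CSV corpora are read and titles are concatenated to bodies", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    id = c("x1", "x2"), author = c("u1", "u2"),
    title = c("A title", ""),
    body = c("and a body", "plain body"),
    created_utc = c(10, 20), subreddit = c("g1", "g1")
  ), path, row.names = FALSE)
  df <- read_comments(path, "csv")
  expect_equal(df$body, c("A title and a body", "plain body"))
  expect_error(read_comments(tempfile(), "csv"), "not found")
})

test_that("cleaning applies each exclusion rule with first-match attribution", {
  mk <- function(body, author = "regular_user") {
    data.frame(id = paste0("c", seq_along(body)), author = author,
               body = body, created_utc = 1, group = "g",
               stringsAsFactors = FALSE)
  }
  long_body <- paste(rep("word", 60), collapse = " ")
  short_body <- paste(rep("word", 49), collapse = " ")

  out <- clean_comments(mk(short_body))
  expect_equal(out$report$removed[["min_words"]], 1)
  expect_equal(out$report$output_count, 0)

  out <- clean_comments(mk(long_body, author = "[deleted]"))
  expect_equal(out$report$removed[["deleted_author"]], 1)

  out <- clean_comments(mk(long_body, author = "AutoModeratorBot"))
  expect_equal(out$report$removed[["bot"]], 1)

  out <- clean_comments(mk("[removed]"))
  expect_equal(out$report$removed[["deleted_body"]], 1)

  out <- clean_comments(mk("https://x.y/z"))
  expect_equal(out$report$removed[["url_only"]], 1)

  # 60 tokens + one URL: kept, URL stripped, 59 tokens remain
  with_url <- paste(c(rep("word", 59), "https://example.com/a"),
                    collapse = " ")
  out <- clean_comments(mk(with_url))
  expect_equal(out$report$output_count, 1)
  expect_equal(word_count(out$comments$body), 59L)
  expect_false(grepl("http", out$comments$body))

  # a deleted author whose body is also short is attributed to the author
  # rule (first match wins) and counted exactly once
  out <- clean_comments(mk(short_body, author = "[deleted]"))
  expect_equal(out$report$removed[["deleted_author"]], 1)
  expect_equal(out$report$removed[["min_words"]], 0)
  expect_equal(out$report$input_count,
               out$report$output_count + sum(out$report$removed))
})

test_that("cleaning is idempotent and monotone in the word threshold", {
  lex <- synthetic_style_lexicon()
  corp <- make_group_corpus(base_style_profile(lex), 30, seed = 8,
                            lexicon = lex)
  corp$body[1] <- paste(corp$body[1], "see https://a.b/c too")
  corp$body[2] <- "www.only-a-link.com"
  corp <- rbind(corp, within(corp[3, ], author <- "[deleted]"))

  once <- clean_comments(corp)
  twice <- clean_comments(once$comments)
  expect_identical(once$comments, twice$comments)
  expect_equal(twice$report$output_count, twice$report$input_count)

  counts <- vapply(c(10, 50, 80, 200), function(mw) {
    clean_comments(corp, clean_rules(min_words = mw))$report$output_count
  }, integer(1))
  expect_true(all(diff(counts) <= 0))

  # every survivor satisfies every rule
  surv <- once$comments
  expect_true(all(word_count(surv$body) >= 50))
  expect_false(any(grepl("bot$", surv$author, ignore.case = TRUE)))
  expect_false(any(surv$author == "[deleted]"))
  expect_false(any(grepl("https?://|www\\.", surv$body)))
})

test_that("cleaning an empty corpus yields an empty, zero-count report", {
  out <- clean_comments(read_comments(withr::local_tempfile(
    fileext = ".jsonl", lines = character(0))))
  expect_equal(out$report$input_count, 0)
  expect_equal(out$report$output_count, 0)
  expect_equal(nrow(out$comments), 0)
})

test_that("cleaning reports serialize as JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  rep <- clean_comments(data.frame(
    id = "1", author = "u", body = "short", created_utc = 1, group = "g"
  ))$report
  write_cleaning_report(rep, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$input_count, 1)
  expect_equal(parsed$removed$min_words, 1)
})
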