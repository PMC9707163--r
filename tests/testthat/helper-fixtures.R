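# Ten-category value lexicon fixture with disjoint literal vocabularies
# (v<k>w<i> words), built in code at test time.
value_fixture_lexicon <- function() {
  cats <- value_category_names()
  path <- tempfile(fileext = ".dic")
  con <- file(path, "w")
  writeLines("%", con)
  writeLines(sprintf("%d\t%s", seq_along(cats), cats), con)
  writeLines("%", con)
  for (k in seq_along(cats)) {
    writeLines(sprintf("v%dw%d\t%d", k, 1:3, k), con)
  }
  close(con)
  on.exit(unlink(path))
  load_dictionary(path)
}
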