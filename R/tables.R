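#' Published per-group comment counts of the reference Reddit mapping
#' dataset
#'
#' Cleaned comment counts for the 15 subreddit communities of the reference
#' dataset this method was developed on (three communities for each of five
#' group types: vocational, ethnic/religious, political, relational,
#' stigmatised).  These counts drive the balanced pairwise sampling
#' arithmetic: the per-class size for a pair is the smaller group's count
#' rounded down to an even number, and the pairwise total is twice that
#' (see [balanced_sample_size()] and [pairwise_total()]).
#'
#' @return named integer vector of length 15; the names are subreddit
#'   labels.
#' @export
#' @examples
#' sum(reddit_group_counts()) # 1779098 comments in total
reddit_group_counts <- function() {
  c(
    Entrepreneur = 91014L, Teachers = 98797L, sales = 25256L,
    asianamerican = 17519L, islam = 54495L, Christianity = 356604L,
    Conservative = 134767L, Libertarian = 356963L, Feminism = 15386L,
    daddit = 17389L, breakingmom = 87323L, relationships = 103382L,
    asktransgender = 207527L, homeless = 7748L, stopdrinking = 204928L
  )
}

#' Published yearly comment counts of the focal transgender community
#'
#' Cleaned per-year comment counts (2011-2019) for r/asktransgender in the
#' reference dataset; the 2019 figure covers January-October only.
#'
#' @return named integer vector (names are years).
#' @export
asktransgender_yearly_counts <- function() {
  c(`2011` = 15620L, `2012` = 31823L, `2013` = 51596L, `2014` = 84294L,
    `2015` = 149808L, `2016` = 183092L, `2017` = 201570L,
    `2018` = 207589L, `2019` = 177139L)
}

#' Pairwise total sample size under balanced under-sampling
#'
#' Twice the balanced per-class size: both groups contribute
#' `balanced_sample_size(n_a, n_b)` comments each.
#'
#' @param n_a,n_b available comment counts.
#' @return even integer total.
#' @export
#' @examples
#' pairwise_total(91014, 25256) # 50512
pairwise_total <- function(n_a, n_b) {
  2L * balanced_sample_size(n_a, n_b)
}

#' Full matrix of pairwise totals for a set of group counts
#'
#' @param counts named vector of per-group comment counts (default the
#'   reference dataset's).
#' @return symmetric integer matrix of pairwise totals; the diagonal holds
#'   `pairwise_total(n, n)` (a group against itself).
#' @export
pairwise_total_table <- function(counts = reddit_group_counts()) {
  n <- length(counts)
  out <- matrix(0L, n, n, dimnames = list(names(counts), names(counts)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- pairwise_total(counts[i], counts[j])
    }
  }
  out
}
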