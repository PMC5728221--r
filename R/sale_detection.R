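# Sale-promotion detection: selling-argument lexicon matching combined with
# the topic-theme signal, then deduplication and hyperlink extraction.

#' The selling-argument lexicon
#'
#' Promotional terms that signal commercial intent ("buy", "discount",
#' "price", ...). The shipped file contains a small core plus a clearly
#' marked extension list; both are lowercase single tokens.
#'
#' @param path lexicon file (UTF-8, one term per line, `#` comments);
#'   defaults to the shipped list.
#' @return Character vector of lowercase terms.
#' @export
selling_lexicon <- function(path = system.file("extdata",
                                               "selling_lexicon.txt",
                                               package = "opiwatch",
                                               mustWork = TRUE)) {
  terms <- read_term_file(path)
  if (length(terms) == 0L) stop("selling lexicon is empty")
  if (any(grepl("\\s", terms))) stop("selling lexicon terms must be single tokens")
  terms
}

#' Match selling arguments in a tokenized document
#'
#' Exact token-level matches (case-insensitive, not substrings): "pricey"
#' does not match "price".
#'
#' @param tokens character token vector (already lowercased by the
#'   tokenizer; lowercasing is applied defensively anyway).
#' @param lexicon character vector of lowercase terms.
#' @return Character vector of matched lexicon terms (unique, sorted).
#' @export
match_selling_arguments <- function(tokens, lexicon) {
  sort(unique(lexicon[lexicon %in% tolower(tokens)]))
}

#' Detect sale-promotion tweets in the candidate pool
#'
#' A candidate is retained iff it matches at least one selling argument OR
#' its argmax topic carries the online-pharmacy theme (`rule = "or"`,
#' the default, maximizes recall for a surveillance funnel; `rule = "and"`
#' requires both signals). Each retained tweet carries its evidence.
#'
#' @param corpus full corpus tibble.
#' @param candidate_ids character ids of the non-news candidate pool.
#' @param token_docs named list of character token vectors.
#' @param assigned_topic named integer vector of argmax topics per doc.
#' @param summaries labeled `topic_summaries`.
#' @param lexicon selling-argument terms.
#' @param rule `"or"` (default) or `"and"`.
#' @return Tibble of class `sale_tweets`: `tweet_id`, `text`,
#'   `matched_terms` (list), `topic_id`, `theme`, `urls` (list).
#' @export
detect_sale_tweets <- function(corpus, candidate_ids, token_docs,
                               assigned_topic, summaries, lexicon,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  cand <- corpus[corpus$tweet_id %in% candidate_ids, , drop = FALSE]
  matched <- lapply(token_docs[cand$tweet_id], match_selling_arguments,
                    lexicon = lexicon)
  topic <- unname(assigned_topic[cand$tweet_id])
  theme <- summaries$theme[match(topic, summaries$topic_id)]
  has_kw <- lengths(matched) > 0L
  is_pharm <- !is.na(theme) & theme == "online_pharmacy"
  keep <- if (rule == "or") has_kw | is_pharm else has_kw & is_pharm
  out <- tibble::tibble(
    tweet_id = cand$tweet_id,
    text = cand$text,
    matched_terms = unname(matched),
    topic_id = topic,
    theme = theme,
    urls = lapply(seq_len(nrow(cand)), function(i) {
      unique(c(cand$urls[[i]], extract_urls(cand$text[[i]])))
    })
  )[keep, , drop = FALSE]
  class(out) <- c("sale_tweets", class(out))
  out
}

#' Unique link-bearing sale tweets
#'
#' Collapses duplicates/retweets among the detected sale tweets (same
#' canonical key as [collapse_duplicates()]) and keeps only representatives
#' that carry at least one hyperlink.
#'
#' @param sale_tweets a `sale_tweets` tibble.
#' @param corpus the corpus tibble the sale tweets came from (for timestamps
#'   and retweet flags).
#' @return List with `unique` (sale-tweet tibble of link-bearing
#'   representatives), `n_unique` (unique sale tweets before the link
#'   requirement) and `map` (the duplicate-cluster map).
#' @export
unique_link_tweets <- function(sale_tweets, corpus) {
  if (nrow(sale_tweets) == 0L) {
    return(list(unique = sale_tweets[0, , drop = FALSE], n_unique = 0L,
                map = NULL))
  }
  sub <- corpus[match(sale_tweets$tweet_id, corpus$tweet_id), , drop = FALSE]
  coll <- collapse_duplicates(sub)
  reps <- sale_tweets[match(coll$unique$tweet_id, sale_tweets$tweet_id), ,
                      drop = FALSE]
  with_link <- lengths(reps$urls) > 0L
  list(unique = reps[with_link, , drop = FALSE],
       n_unique = nrow(reps),
       map = coll$map)
}

#' Export detected sale tweets as CSV
#'
#' Columns: `tweet_id`, `matched_terms` (semicolon-joined), `topic_id`,
#' `theme`, `urls` (semicolon-joined).
#'
#' @param sale_tweets a `sale_tweets` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_sale_tweets <- function(sale_tweets, path) {
  df <- data.frame(
    tweet_id = sale_tweets$tweet_id,
    matched_terms = vapply(sale_tweets$matched_terms, paste,
                           character(1), collapse = ";"),
    topic_id = sale_tweets$topic_id,
    theme = sale_tweets$theme,
    urls = vapply(sale_tweets$urls, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
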