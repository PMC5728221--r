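# Topic summarization and theme labeling ("news" vs "online pharmacy").
#
# Theme labels are human-in-the-loop in a real surveillance run (a manual
# label file); a transparent lexicon-overlap heuristic is provided so the
# full funnel can run unattended, e.g. in tests.

THEMES <- c("news", "online_pharmacy", "other", "unlabeled")

#' Top-weighted words of one topic
#'
#' The `n` highest-weight tokens in descending weight order; ties are broken
#' lexicographically by token. When `n >= M` all tokens are returned.
#'
#' @param phi_row length-M probability vector over the vocabulary.
#' @param vocab a `vocabulary`.
#' @param n number of words (default 10).
#' @return Tibble with columns `token`, `weight`.
#' @export
top_words <- function(phi_row, vocab, n = 10L) {
  stopifnot(n >= 1L)
  ord <- order(-phi_row, vocab$tokens, method = "radix")
  keep <- ord[seq_len(min(n, length(phi_row)))]
  tibble::tibble(token = vocab$tokens[keep], weight = phi_row[keep])
}

#' Summarize all topics
#'
#' One summary per topic: its top-weighted words, a theme slot initialized
#' to `"unlabeled"`, and the label source.
#'
#' @param est a `btm_estimates`.
#' @param vocab a `vocabulary`.
#' @param n_words words per summary (default `config$top_words` = 10).
#' @return Tibble of class `topic_summaries` with columns `topic_id`
#'   (1-based), `top_words` (list of tibbles), `theme`, `label_source`.
#' @export
summarize_topics <- function(est, vocab, n_words = 10L) {
  tw <- lapply(seq_len(est$K), function(k) top_words(est$phi[k, ], vocab, n_words))
  out <- tibble::tibble(
    topic_id = seq_len(est$K),
    top_words = tw,
    theme = rep("unlabeled", est$K),
    label_source = rep(NA_character_, est$K)
  )
  class(out) <- c("topic_summaries", class(out))
  out
}

#' Default heuristic theme lexicons
#'
#' News and sale term lists shipped with the package (UTF-8, one term per
#' line, `#` comments).
#'
#' @return List with character vectors `news` and `sale`.
#' @export
default_theme_lexicons <- function() {
  list(
    news = read_term_file(system.file("extdata", "news_lexicon.txt",
                                      package = "opiwatch", mustWork = TRUE)),
    sale = selling_lexicon()
  )
}

#' Attach theme labels to topic summaries
#'
#' A manual label file (or data frame `topic_id,theme`) always wins. Topics
#' it does not cover fall back to the heuristic when lexicons are given:
#' theme = argmax lexicon overlap with the topic's top words ("news" wins
#' ties), `"other"` when both overlaps are zero.
#'
#' @param summaries a `topic_summaries` tibble.
#' @param label_file path to a CSV `topic_id,theme`, or a data frame.
#' @param lexicons list with `news` and `sale` term vectors (see
#'   [default_theme_lexicons()]).
#' @return The summaries with `theme` and `label_source` filled in.
#' @export
apply_theme_labels <- function(summaries, label_file = NULL, lexicons = NULL) {
  if (!is.null(label_file)) {
    lab <- if (is.data.frame(label_file)) label_file else
      read.csv(label_file, stringsAsFactors = FALSE)
    stopifnot(all(c("topic_id", "theme") %in% names(lab)))
    bad_theme <- setdiff(lab$theme, THEMES)
    if (length(bad_theme) > 0L) {
      stop("unknown theme(s) in label file: ", paste(bad_theme, collapse = ", "))
    }
    unknown <- setdiff(lab$topic_id, summaries$topic_id)
    if (length(unknown) > 0L) {
      stop("label file references unknown topic_id(s): ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(lab$topic_id, summaries$topic_id)
    summaries$theme[idx] <- lab$theme
    summaries$label_source[idx] <- "manual_file"
  }
  if (!is.null(lexicons)) {
    todo <- which(summaries$theme == "unlabeled")
    for (i in todo) {
      toks <- summaries$top_words[[i]]$token
      n_news <- length(intersect(toks, lexicons$news))
      n_sale <- length(intersect(toks, lexicons$sale))
      summaries$theme[i] <-
        if (n_news == 0L && n_sale == 0L) "other"
        else if (n_news >= n_sale) "news" else "online_pharmacy"
      summaries$label_source[i] <- "heuristic"
    }
  }
  summaries
}

#' Partition documents into news and non-news
#'
#' A document is "news" iff its argmax posterior topic carries the news
#' theme; everything else (including topics labeled other/online_pharmacy,
#' and unlabeled topics, with a warning) forms the candidate pool for sale
#' detection.
#'
#' @param doc_posteriors matrix from [infer_corpus_topics()] (rows = docs).
#' @param summaries labeled `topic_summaries`.
#' @return List with `news_ids`, `candidate_ids` (character vectors of doc
#'   ids), `assigned_topic` (named integer vector) and counts `n_news`,
#'   `n_candidates`.
#' @export
partition_by_theme <- function(doc_posteriors, summaries) {
  if (any(summaries$theme == "unlabeled")) {
    warning("unlabeled topics present; treating their documents as non-news")
  }
  assigned <- max.col(doc_posteriors, ties.method = "first")
  names(assigned) <- rownames(doc_posteriors)
  theme_of <- summaries$theme[match(assigned, summaries$topic_id)]
  is_news <- theme_of == "news"
  list(news_ids = rownames(doc_posteriors)[is_news],
       candidate_ids = rownames(doc_posteriors)[!is_news],
       assigned_topic = assigned,
       n_news = sum(is_news),
       n_candidates = sum(!is_news))
}

#' Export topic summaries as a long CSV
#'
#' Columns: `topic_id`, `rank`, `token`, `weight`, `theme`, `label_source`.
#'
#' @param summaries a `topic_summaries` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_topic_summaries <- function(summaries, path) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    tw <- summaries$top_words[[i]]
    data.frame(topic_id = summaries$topic_id[i],
               rank = seq_len(nrow(tw)),
               token = tw$token,
               weight = tw$weight,
               theme = summaries$theme[i],
               label_source = summaries$label_source[i],
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
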