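# Corpus ingestion, normalization, tokenization and deduplication.
#
# A "corpus" throughout the package is a tibble with columns:
#   tweet_id   character, nonempty, unique
#   text       character, nonempty
#   created_at POSIXct (UTC), NA when absent
#   is_retweet logical
#   urls       list of character vectors (possibly empty)

#' Assemble a tweet corpus tibble
#'
#' Low-level constructor used by [read_corpus()] and the synthetic generator.
#' Validates the corpus invariants: nonempty unique ids and nonempty text.
#'
#' @param tweet_id character vector of identifiers.
#' @param text character vector of tweet texts.
#' @param created_at POSIXct timestamps (UTC); `NA` allowed.
#' @param is_retweet logical vector.
#' @param urls list of character vectors of embedded URLs.
#' @return A corpus tibble.
#' @export
tweet_corpus <- function(tweet_id, text,
                         created_at = as.POSIXct(rep(NA, length(tweet_id))),
                         is_retweet = rep(FALSE, length(tweet_id)),
                         urls = rep(list(character()), length(tweet_id))) {
  tweet_id <- as.character(tweet_id)
  text <- as.character(text)
  if (any(!nzchar(tweet_id)) || anyNA(tweet_id)) {
    stop("tweet_id must be nonempty")
  }
  if (anyDuplicated(tweet_id)) {
    stop("tweet_id must be unique within a corpus")
  }
  if (any(!nzchar(text)) || anyNA(text)) {
    stop("text must be nonempty")
  }
  tibble::tibble(
    tweet_id = tweet_id,
    text = text,
    created_at = as.POSIXct(created_at, tz = "UTC"),
    is_retweet = as.logical(is_retweet),
    urls = urls
  )
}

# Parse one decoded JSON object into a one-row record list, or NULL if the
# required fields are missing. Accepts the package's native dialect
# (id/text/created_at/retweeted/urls) and Twitter API v1.1 names
# (id_str, entities.urls[].expanded_url, retweeted_status presence).
parse_tweet_object <- function(obj) {
  if (!is.list(obj)) return(NULL)
  id <- obj$id
  if (is.null(id)) id <- obj$id_str
  if (is.null(id) || length(id) != 1L || !nzchar(as.character(id))) return(NULL)
  text <- obj$text
  if (is.null(text) || length(text) != 1L || is.na(text) || !nzchar(text)) return(NULL)

  ts <- NA
  if (!is.null(obj$created_at)) {
    raw <- as.character(obj$created_at)
    ts <- tryCatch(
      as.POSIXct(raw, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                "%Y-%m-%d")),
      error = function(e) NA)
    if (is.na(ts)) {
      # Twitter v1.1 style: "Wed Jun 01 12:00:00 +0000 2015"
      ts <- suppressWarnings(as.POSIXct(strptime(raw, "%a %b %d %H:%M:%S %z %Y",
                                                 tz = "UTC")))
    }
  }

  rt <- isTRUE(obj$retweeted) || !is.null(obj$retweeted_status)

  urls <- character()
  if (!is.null(obj$urls)) {
    urls <- as.character(unlist(obj$urls, use.names = FALSE))
  } else if (!is.null(obj$entities$urls)) {
    urls <- vapply(obj$entities$urls, function(u) {
      v <- u$expanded_url
      if (is.null(v)) v <- u$url
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
    urls <- urls[!is.na(urls)]
  }

  list(tweet_id = as.character(id), text = as.character(text),
       created_at = ts, is_retweet = rt, urls = urls)
}

#' Read a JSONL tweet corpus
#'
#' One JSON object per line with at least `id` (or `id_str`) and `text`.
#' Optional fields: `created_at` (ISO-8601 or Twitter v1.1 format),
#' `retweeted` (logical; presence of `retweeted_status` also marks a retweet)
#' and `urls` (array; `entities.urls[].expanded_url` is also understood).
#' Malformed lines are skipped with a warning; the number of skipped lines is
#' attached as attribute `n_skipped`.
#'
#' @param path path to a JSONL file.
#' @return A corpus tibble in file order.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  n_skip <- 0L
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    rec <- parse_tweet_object(obj)
    if (is.null(rec)) {
      n_skip <- n_skip + 1L
    } else {
      recs[[i]] <- rec
    }
  }
  if (n_skip > 0L) {
    warning(sprintf("skipped %d malformed line(s) in %s", n_skip, path))
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    out <- tweet_corpus(character(), character(),
                        created_at = as.POSIXct(character(), tz = "UTC"),
                        is_retweet = logical(), urls = list())
  } else {
    out <- tweet_corpus(
      vapply(recs, `[[`, character(1), "tweet_id"),
      vapply(recs, `[[`, character(1), "text"),
      created_at = as.POSIXct(vapply(recs, function(r) as.numeric(r$created_at),
                                     numeric(1)),
                              origin = "1970-01-01", tz = "UTC"),
      is_retweet = vapply(recs, `[[`, logical(1), "is_retweet"),
      urls = lapply(recs, `[[`, "urls")
    )
  }
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write a corpus as JSONL
#'
#' Inverse of [read_corpus()] for the package's native dialect.
#'
#' @param corpus a corpus tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    obj <- list(id = corpus$tweet_id[[i]], text = corpus$text[[i]])
    if (!is.na(corpus$created_at[[i]])) {
      obj$created_at <- format(corpus$created_at[[i]], "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")
    }
    obj$retweeted <- corpus$is_retweet[[i]]
    obj$urls <- corpus$urls[[i]]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Keyword-filter a corpus
#'
#' Case-insensitive substring match (mirroring a streaming-API track filter,
#' not a token match); order preserved. Idempotent.
#'
#' @param corpus a corpus tibble.
#' @param keyword nonempty string.
#' @return The matching subset of `corpus`.
#' @export
keyword_filter <- function(corpus, keyword) {
  stopifnot(is.character(keyword), length(keyword) == 1L, nzchar(keyword))
  keep <- grepl(tolower(keyword), tolower(corpus$text), fixed = TRUE)
  corpus[keep, , drop = FALSE]
}

#' Default English stopword list
#'
#' Reads the frozen stopword file shipped with the package (UTF-8, one term
#' per line, `#` comments).
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  read_term_file(system.file("extdata", "stopwords_en.txt",
                             package = "opiwatch", mustWork = TRUE))
}

# Shared reader for term-per-line lexicon files.
read_term_file <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(sub("#.*$", "", x))
  tolower(x[nzchar(x)])
}

#' Normalize and tokenize tweet text
#'
#' Lowercases; removes a leading `"RT @handle:"` prefix, URLs and
#' `@`-mentions; splits on unicode word characters; drops stopwords and
#' tokens shorter than `min_len`. Repeated tokens are preserved.
#'
#' @param text character vector of tweet texts.
#' @param stopwords character vector; defaults to the shipped English list.
#' @param min_len minimum token length retained (default 2).
#' @return A list of character token vectors, one per input text.
#' @export
normalize_and_tokenize <- function(text, stopwords = default_stopwords(),
                                   min_len = 2L) {
  text <- tolower(text)
  text <- sub("^rt @\\S+\\s*", "", text)
  text <- gsub("https?://\\S+", " ", text)
  text <- gsub("@[a-z0-9_]+", " ", text, perl = TRUE)
  toks <- regmatches(text, gregexpr("[\\p{L}\\p{N}_]+", text, perl = TRUE))
  lapply(toks, function(tk) {
    tk <- tk[nchar(tk) >= min_len]
    tk[!(tk %in% stopwords)]
  })
}

#' Tokenize a whole corpus
#'
#' @param corpus a corpus tibble.
#' @inheritParams normalize_and_tokenize
#' @return Named list of token vectors keyed by `tweet_id`.
#' @export
tokenize_corpus <- function(corpus, stopwords = default_stopwords(),
                            min_len = 2L) {
  setNames(normalize_and_tokenize(corpus$text, stopwords, min_len),
           corpus$tweet_id)
}

#' Build a vocabulary from tokenized documents
#'
#' Tokens occurring at least `min_count` times are mapped to contiguous
#' indices `1..M`, ordered by descending corpus frequency with lexicographic
#' tie-breaks, so the mapping is deterministic.
#'
#' @param docs list of character token vectors.
#' @param min_count minimum corpus frequency (default 1).
#' @return An object of class `vocabulary`: list with `tokens` (character,
#'   position = index) and `index` (named integer lookup).
#' @export
build_vocabulary <- function(docs, min_count = 1L) {
  stopifnot(min_count >= 1L)
  all_tokens <- unlist(docs, use.names = FALSE)
  if (length(all_tokens) == 0L) stop("empty vocabulary: no tokens in corpus")
  freq <- table(all_tokens)
  freq <- freq[freq >= min_count]
  if (length(freq) == 0L) {
    stop("empty vocabulary after min_count = ", min_count, " thresholding")
  }
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  tokens <- names(freq)[ord]
  structure(list(tokens = tokens,
                 index = setNames(seq_along(tokens), tokens)),
            class = "vocabulary")
}

#' @export
length.vocabulary <- function(x) length(x$tokens)

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> M =", length(x$tokens), "tokens:",
      paste(head(x$tokens, 8L), collapse = ", "),
      if (length(x$tokens) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Map token documents to vocabulary index documents
#'
#' Out-of-vocabulary tokens (below `min_count` at vocabulary construction)
#' are dropped. Indices are 1-based.
#'
#' @param docs named list of character token vectors.
#' @param vocab a `vocabulary`.
#' @return Named list of integer index vectors.
#' @export
docs_to_indices <- function(docs, vocab) {
  lapply(docs, function(tk) {
    idx <- vocab$index[tk]
    as.integer(idx[!is.na(idx)])
  })
}

#' Extract hyperlinks from text
#'
#' All http/https substrings, in order of appearance, with trailing sentence
#' punctuation trimmed.
#'
#' @param text character vector.
#' @return List of character URL vectors (a single character vector when
#'   `text` has length 1).
#' @export
extract_urls <- function(text) {
  m <- regmatches(text, gregexpr("https?://[^[:space:]]+", text))
  out <- lapply(m, function(u) sub("[].,;:!?\"')]+$", "", u))
  if (length(text) == 1L) out[[1]] else out
}

# Canonical duplicate key: case removed, "RT @handle:" prefix removed, URLs
# removed (shortened-link variants of one ad collapse together), whitespace
# squeezed.
canonical_key <- function(text, strip_urls = TRUE) {
  x <- tolower(text)
  x <- sub("^rt @\\S+\\s*", "", x)
  if (strip_urls) x <- gsub("https?://\\S+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Collapse duplicate and retweeted tweets
#'
#' Groups records by a canonical text key (case, `"RT @handle:"` prefix and,
#' by default, URLs removed). One representative is retained per cluster:
#' retweets are never chosen over a non-retweet, then the earliest timestamp
#' wins, then input order.
#'
#' @param corpus a corpus tibble.
#' @param strip_urls remove URLs from the canonical key (default TRUE).
#' @return List with `unique` (corpus tibble of representatives, in order of
#'   each cluster's first appearance), `map` (tibble `tweet_id`, `cluster_id`,
#'   `representative`) and `clusters` (list of member id vectors keyed by
#'   representative id).
#' @export
collapse_duplicates <- function(corpus, strip_urls = TRUE) {
  n <- nrow(corpus)
  if (n == 0L) {
    return(list(unique = corpus,
                map = tibble::tibble(tweet_id = character(),
                                     cluster_id = integer(),
                                     representative = character()),
                clusters = list()))
  }
  key <- canonical_key(corpus$text, strip_urls = strip_urls)
  cluster_id <- match(key, unique(key))
  is_rt <- corpus$is_retweet | grepl("^rt @", tolower(corpus$text))
  ts <- as.numeric(corpus$created_at)
  ts[is.na(ts)] <- Inf
  # representative: non-retweet first, then earliest, then input order
  rep_idx <- vapply(seq_len(max(cluster_id)), function(cl) {
    idx <- which(cluster_id == cl)
    ord <- order(is_rt[idx], ts[idx], idx)
    idx[ord[1L]]
  }, integer(1))
  map <- tibble::tibble(
    tweet_id = corpus$tweet_id,
    cluster_id = cluster_id,
    representative = corpus$tweet_id[rep_idx[cluster_id]]
  )
  clusters <- split(corpus$tweet_id, map$representative)
  clusters <- clusters[unique(map$representative)]
  list(unique = corpus[rep_idx, , drop = FALSE], map = map,
       clusters = clusters)
}
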