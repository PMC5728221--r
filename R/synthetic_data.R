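# Synthetic tweet-corpus generator with planted ground truth: known topic
# structure, a dominant news theme, a small minority of sale-promotion
# tweets carrying selling arguments and hyperlinks, and planted duplicates
# and retweet variants. Every pipeline stage is testable against the
# recorded truth without any platform data.

#' Synthetic corpus configuration
#'
#' Defaults emulate the composition of a keyword-filtered fentanyl tweet
#' stream: short documents (5-15 tokens), one dominant news topic holding
#' 97.3% of the corpus, and 2.7% of the non-news remainder carrying planted
#' sale promotions.
#'
#' @param K_true number of generating topics (>= 2 when themes are planted).
#' @param M vocabulary size.
#' @param n_docs number of base documents.
#' @param len_min,len_max document length range (uniform).
#' @param alpha_true Dirichlet parameter for the non-news topic proportions;
#'   `Inf` gives exactly equal proportions (the symmetric limit), the usual
#'   choice for recovery benchmarks.
#' @param beta_true Dirichlet parameter for topic-word distributions.
#' @param news_topic_ids topics carrying the news theme (1-based).
#' @param news_fraction fraction of documents drawn from news topics.
#' @param sale_fraction fraction of non-news documents planted as sale
#'   promotions.
#' @param dup_rate fraction of documents duplicated verbatim.
#' @param retweet_rate fraction of documents duplicated as retweet variants.
#' @param url_pool URLs sampled for planted sale tweets.
#' @param lexicon_terms selling arguments sampled for planted sale tweets.
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(K_true = 5L, M = 100L, n_docs = 2000L,
                         len_min = 5L, len_max = 15L,
                         alpha_true = 1, beta_true = 0.1,
                         news_topic_ids = 1L, news_fraction = 0.973,
                         sale_fraction = 0.027,
                         dup_rate = 0.05, retweet_rate = 0.05,
                         url_pool = c("https://rx-shop.example/fnt1",
                                      "https://pills-now.example/order",
                                      "https://ads.example/post/771"),
                         lexicon_terms = c("buy", "discount", "price"),
                         seed = 1L) {
  stopifnot(K_true >= 1L, M >= 2L, n_docs >= 1L,
            len_min >= 1L, len_max >= len_min,
            alpha_true > 0, beta_true > 0,
            news_fraction >= 0, news_fraction <= 1,
            sale_fraction >= 0, sale_fraction <= 1,
            dup_rate >= 0, retweet_rate >= 0, dup_rate + retweet_rate <= 1,
            length(news_topic_ids) == 0L ||
              (all(news_topic_ids >= 1L) && all(news_topic_ids <= K_true)))
  if (sale_fraction > 0 && length(news_topic_ids) >= K_true) {
    stop("K_true must exceed the number of news topics when sale tweets are planted")
  }
  structure(list(K_true = as.integer(K_true), M = as.integer(M),
                 n_docs = as.integer(n_docs),
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 alpha_true = alpha_true, beta_true = beta_true,
                 news_topic_ids = as.integer(news_topic_ids),
                 news_fraction = news_fraction,
                 sale_fraction = sale_fraction,
                 dup_rate = dup_rate, retweet_rate = retweet_rate,
                 url_pool = url_pool, lexicon_terms = lexicon_terms,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a base synthetic corpus
#'
#' Per document: a topic is drawn from the true global distribution (news
#' topics share `news_fraction` of the mass; the rest is spread over the
#' remaining topics by a Dirichlet draw), tokens are drawn iid from that
#' topic's word distribution, and the token sequence is rendered as text.
#' When duplicates or retweets are to be planted, base documents are made
#' unique under the canonical duplicate key (chance collisions are
#' resampled), so the planted ones are the only duplicates in the corpus.
#'
#' @param cfg a [synth_config()].
#' @return List with `corpus` (tibble) and `truth` (list: `theta_true`,
#'   `phi_true`, `doc_topics`, `sale_ids`, `clusters`, `words`).
#' @export
generate_corpus <- function(cfg) {
  set.seed(cfg$seed)
  K <- cfg$K_true
  M <- cfg$M
  words <- sprintf("w%0*d", max(2L, nchar(M)), seq_len(M))

  theta_true <- numeric(K)
  news <- cfg$news_topic_ids
  non_news <- setdiff(seq_len(K), news)
  nf <- if (length(news) == 0L) 0 else cfg$news_fraction
  if (length(non_news) == 0L) {
    theta_true[news] <- 1 / length(news)
  } else {
    if (length(news) > 0L) theta_true[news] <- nf / length(news)
    # alpha_true = Inf is the symmetric-Dirichlet limit: equal proportions
    w <- if (is.infinite(cfg$alpha_true)) {
      rep(1 / length(non_news), length(non_news))
    } else {
      as.vector(rdirichlet(1, rep(cfg$alpha_true, length(non_news))))
    }
    theta_true[non_news] <- (1 - nf) * w
  }
  phi_true <- rdirichlet(K, rep(cfg$beta_true, M))

  z <- sample.int(K, cfg$n_docs, replace = TRUE, prob = theta_true)
  lens <- cfg$len_min +
    sample.int(cfg$len_max - cfg$len_min + 1L, cfg$n_docs, replace = TRUE) - 1L
  draw_text <- function(i) {
    paste(words[sample.int(M, lens[i], replace = TRUE, prob = phi_true[z[i], ])],
          collapse = " ")
  }
  text <- vapply(seq_len(cfg$n_docs), draw_text, character(1))
  if (cfg$dup_rate + cfg$retweet_rate > 0) {
    # the duplicate-cluster ground truth is only exact if base documents are
    # unique under the canonical key, so resample chance collisions
    for (iter in seq_len(100L)) {
      dup <- duplicated(canonical_key(text))
      if (!any(dup)) break
      text[dup] <- vapply(which(dup), draw_text, character(1))
    }
    if (anyDuplicated(canonical_key(text))) {
      stop("could not generate a collision-free corpus; increase M or beta_true")
    }
  }

  ids <- sprintf("t%06d", seq_len(cfg$n_docs))
  corpus <- tweet_corpus(
    ids, text,
    created_at = as.POSIXct("2015-06-01 00:00:00", tz = "UTC") +
      60 * (seq_len(cfg$n_docs) - 1L)
  )
  truth <- list(theta_true = theta_true, phi_true = phi_true,
                doc_topics = setNames(z, ids),
                sale_ids = character(),
                clusters = setNames(as.list(ids), ids),
                words = words)
  list(corpus = corpus, truth = truth)
}

#' Plant sale-promotion tweets
#'
#' Selects `round(sale_fraction * n_non_news)` non-news documents and
#' appends one selling argument and one URL from the pool to each; the
#' planted ids are recorded in the ground truth.
#'
#' @param corpus corpus tibble from [generate_corpus()].
#' @param truth matching ground-truth list.
#' @param cfg the [synth_config()].
#' @return List with updated `corpus` and `truth`.
#' @export
plant_sale_tweets <- function(corpus, truth, cfg) {
  non_news_ids <- names(truth$doc_topics)[
    !(truth$doc_topics %in% cfg$news_topic_ids)]
  n_plant <- round(cfg$sale_fraction * length(non_news_ids))
  if (n_plant == 0L) return(list(corpus = corpus, truth = truth))
  planted <- sort(sample(non_news_ids, n_plant))
  idx <- match(planted, corpus$tweet_id)
  terms <- sample(cfg$lexicon_terms, n_plant, replace = TRUE)
  urls <- sample(cfg$url_pool, n_plant, replace = TRUE)
  corpus$text[idx] <- paste(corpus$text[idx], terms, urls)
  corpus$urls[idx] <- Map(c, corpus$urls[idx], urls)
  truth$sale_ids <- planted
  list(corpus = corpus, truth = truth)
}

#' Plant duplicates and retweet variants
#'
#' Appends `round(dup_rate * n)` verbatim copies and
#' `round(retweet_rate * n)` `"RT @synth_user: "` variants of sampled
#' documents, with later timestamps and fresh ids; the duplicate-cluster map
#' is recorded in the ground truth (representative = the original document).
#'
#' @inheritParams plant_sale_tweets
#' @return List with updated `corpus` and `truth`.
#' @export
plant_duplicates <- function(corpus, truth, cfg) {
  n <- nrow(corpus)
  n_dup <- round(cfg$dup_rate * n)
  n_rt <- round(cfg$retweet_rate * n)
  if (n_dup + n_rt == 0L) return(list(corpus = corpus, truth = truth))
  src_dup <- sample(corpus$tweet_id, n_dup, replace = TRUE)
  src_rt <- sample(corpus$tweet_id, n_rt, replace = TRUE)
  t0 <- max(corpus$created_at, na.rm = TRUE)

  mk <- function(src, prefix, rt) {
    k <- length(src)
    if (k == 0L) return(NULL)
    i <- match(src, corpus$tweet_id)
    tweet_corpus(
      sprintf("%s%05d", prefix, seq_len(k)),
      if (rt) paste0("RT @synth_user: ", corpus$text[i]) else corpus$text[i],
      created_at = t0 + 60 * seq_len(k) + if (rt) 1 else 0,
      is_retweet = rep(rt, k),
      urls = corpus$urls[i]
    )
  }
  dup_rec <- mk(src_dup, "dup", FALSE)
  rt_rec <- mk(src_rt, "rt", TRUE)
  extra <- rbind(dup_rec, rt_rec)
  extra_src <- c(src_dup, src_rt)

  for (j in seq_len(nrow(extra))) {
    s <- extra_src[j]
    truth$clusters[[s]] <- c(truth$clusters[[s]], extra$tweet_id[j])
    truth$doc_topics[extra$tweet_id[j]] <- truth$doc_topics[[s]]
  }
  list(corpus = rbind(corpus, extra), truth = truth)
}

#' Generate a full synthetic corpus with all plants applied
#'
#' Convenience wrapper: [generate_corpus()], then [plant_sale_tweets()],
#' then [plant_duplicates()], all under the config seed.
#'
#' @param cfg a [synth_config()].
#' @return List with `corpus` and `truth`.
#' @export
simulate_corpus <- function(cfg) {
  g <- generate_corpus(cfg)
  g <- plant_sale_tweets(g$corpus, g$truth, cfg)
  plant_duplicates(g$corpus, g$truth, cfg)
}

#' Match estimated topics to true topics
#'
#' Optimal one-to-one assignment minimizing the summed total-variation
#' distance between matched topic-word rows (exhaustive over permutations
#' for `K <= 8`, greedy beyond).
#'
#' @param phi_true,phi_est K x M row-stochastic matrices.
#' @return List with `perm` (estimated topic matched to each true topic),
#'   `tv` (per-pair total-variation distances) and `mean_tv`.
#' @export
match_topics <- function(phi_true, phi_est) {
  if (!all(dim(phi_true) == dim(phi_est))) {
    stop("phi_true and phi_est must have identical dimensions")
  }
  K <- nrow(phi_true)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    D[i, j] <- 0.5 * sum(abs(phi_true[i, ] - phi_est[j, ]))
  }
  if (K <= 8L) {
    perms <- all_permutations(K)
    costs <- vapply(perms, function(p) sum(D[cbind(seq_len(K), p)]),
                    numeric(1))
    perm <- perms[[which.min(costs)]]
  } else {
    perm <- integer(K)
    avail <- rep(TRUE, K)
    for (i in order(apply(D, 1L, min))) {
      j <- which(avail)[which.min(D[i, avail])]
      perm[i] <- j
      avail[j] <- FALSE
    }
  }
  tv <- D[cbind(seq_len(K), perm)]
  list(perm = perm, tv = tv, mean_tv = mean(tv))
}

# All permutations of 1..n as a list (n! entries; used for n <= 8).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
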