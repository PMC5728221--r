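# Biterm Topic Model: biterm extraction, collapsed Gibbs sampling, parameter
# estimation, document-level inference, and an exhaustive posterior oracle.
#
# The model treats the corpus as a bag of biterms (unordered word pairs
# co-occurring in a tweet). A topic k is drawn for each biterm from a global
# distribution theta, and both words from that topic's word distribution
# phi[k, ]. Dirichlet priors: theta ~ Dir(alpha), phi[k, ] ~ Dir(beta).

#' BTM configuration
#'
#' Defaults follow common surveillance practice for short-text corpora:
#' 40 topics, symmetric Dirichlet priors alpha = 1 on topic proportions and
#' beta = 0.01 on topic-word distributions, 1000 Gibbs sweeps with the first
#' 500 discarded, 10 summary words per topic.
#'
#' @param K number of topics (>= 1).
#' @param alpha Dirichlet prior on the global topic distribution (> 0).
#' @param beta Dirichlet prior on topic-word distributions (> 0).
#' @param n_sweeps total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging counts
#'   (`n_sweeps > burn_in >= 0`).
#' @param seed RNG seed; `NULL` to use the current RNG state.
#' @param top_words number of words per topic summary.
#' @return An object of class `btm_config`.
#' @export
btm_config <- function(K = 40L, alpha = 1, beta = 0.01,
                       n_sweeps = 1000L, burn_in = 500L,
                       seed = NULL, top_words = 10L) {
  stopifnot(K >= 1L, alpha > 0, beta > 0,
            n_sweeps > burn_in, burn_in >= 0L, top_words >= 1L)
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 top_words = as.integer(top_words)),
            class = "btm_config")
}

#' Extract biterms from one tokenized document
#'
#' All unordered pairs of tokens at distinct positions; the whole tweet is a
#' single context window. Pairs are canonicalized to `w1 <= w2`; repeated
#' tokens yield repeated (and same-word) biterms. A document of length L
#' yields `L*(L-1)/2` biterms.
#'
#' @param doc integer vector of 1-based vocabulary indices.
#' @return Integer matrix with columns `w1`, `w2` (0 rows when `length(doc) < 2`).
#' @export
extract_biterms <- function(doc) {
  doc <- as.integer(doc)
  L <- length(doc)
  if (L < 2L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("w1", "w2"))))
  }
  pairs <- utils::combn(L, 2L)
  a <- doc[pairs[1L, ]]
  b <- doc[pairs[2L, ]]
  cbind(w1 = pmin(a, b), w2 = pmax(a, b))
}

#' Extract biterms from a tokenized corpus
#'
#' @param docs list of integer index vectors (see [docs_to_indices()]).
#' @return List with `biterms` (matrix, columns `w1`, `w2`), `doc_of`
#'   (character vector: source document id per biterm) and `n_docs`.
#' @export
corpus_biterms <- function(docs) {
  per_doc <- lapply(docs, extract_biterms)
  counts <- vapply(per_doc, nrow, integer(1))
  ids <- names(docs)
  if (is.null(ids)) ids <- as.character(seq_along(docs))
  list(biterms = do.call(rbind, per_doc),
       doc_of = rep(ids, counts),
       n_docs = length(docs))
}

#' Initialize the Gibbs state
#'
#' Each biterm's topic is drawn uniformly from `1..K` using the seeded RNG;
#' count tables are derived from the assignment.
#'
#' @param biterms integer matrix (columns `w1`, `w2`).
#' @param M vocabulary size.
#' @param config a [btm_config()] (its `seed`, when non-NULL, seeds the RNG).
#' @return An object of class `btm_state`: list `z` (1-based topic per
#'   biterm), `n_k` (length K), `n_wk` (M x K), `M`, `K`.
#' @export
init_state <- function(biterms, M, config) {
  B <- nrow(biterms)
  if (is.null(B) || B == 0L) stop("cannot initialize BTM state: no biterms")
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$K
  z <- sample.int(K, B, replace = TRUE)
  n_k <- tabulate(z, nbins = K)
  n_wk <- matrix(0L, nrow = M, ncol = K)
  for (b in seq_len(B)) {
    n_wk[biterms[b, 1L], z[b]] <- n_wk[biterms[b, 1L], z[b]] + 1L
    n_wk[biterms[b, 2L], z[b]] <- n_wk[biterms[b, 2L], z[b]] + 1L
  }
  structure(list(z = z, n_k = n_k, n_wk = n_wk, M = as.integer(M), K = K),
            class = "btm_state")
}

#' Full conditional of one biterm's topic
#'
#' Evaluates, for a biterm `(w1, w2)` currently removed from the counts,
#' `P(z = k | rest)` proportional to
#' `(n_k + alpha) * (n_w1k + beta) * (n_w2k + beta) /
#'  ((n_.k + M*beta) * (n_.k + 1 + M*beta))` with `n_.k = 2 n_k`,
#' normalized over topics.
#'
#' @param n_k topic biterm counts (biterm removed).
#' @param n_wk M x K word-topic counts (biterm removed).
#' @param w1,w2 1-based word indices.
#' @param config a [btm_config()].
#' @return Length-K probability vector.
#' @export
biterm_conditional <- function(n_k, n_wk, w1, w2, config) {
  M <- nrow(n_wk)
  d <- 2 * n_k + M * config$beta
  w <- (n_k + config$alpha) *
    (n_wk[w1, ] + config$beta) * (n_wk[w2, ] + config$beta) / (d * (d + 1))
  w / sum(w)
}

#' Run collapsed Gibbs sweeps
#'
#' Resamples every biterm once per sweep in fixed (input) order, drawing from
#' the full conditional; all randomness comes from R's RNG stream.
#'
#' @param state a `btm_state`.
#' @param biterms the biterm matrix the state was built from.
#' @param config a [btm_config()]; only `alpha`/`beta`/`K` are used here.
#' @param n_sweeps number of sweeps to run (default 1).
#' @return The updated `btm_state`.
#' @export
gibbs_sweep <- function(state, biterms, config, n_sweeps = 1L) {
  res <- btm_gibbs_cpp(biterms - 1L, state$M, state$K,
                       config$alpha, config$beta,
                       as.integer(n_sweeps), as.integer(n_sweeps),
                       state$z - 1L,
                       track_assign = FALSE, track_loglik = FALSE)
  structure(list(z = res$z + 1L, n_k = res$n_k, n_wk = res$n_wk,
                 M = state$M, K = state$K),
            class = "btm_state")
}

#' Point estimates from a Gibbs state
#'
#' `theta[k] = (n_k + alpha) / (B + K alpha)`;
#' `phi[k, w] = (n_wk + beta) / (2 n_k + M beta)`. Counts may be posterior
#' averages (non-integer).
#'
#' @param state a `btm_state` (or list with `n_k`, `n_wk`, `M`, `K`).
#' @param config a [btm_config()].
#' @return Object of class `btm_estimates`: `theta` (length K), `phi` (K x M).
#' @export
btm_estimate <- function(state, config) {
  B <- sum(state$n_k)
  K <- state$K
  M <- state$M
  theta <- (state$n_k + config$alpha) / (B + K * config$alpha)
  denom <- 2 * state$n_k + M * config$beta
  phi <- t((state$n_wk + config$beta) /
             matrix(denom, nrow = M, ncol = K, byrow = TRUE))
  structure(list(theta = theta, phi = phi, K = K, M = M),
            class = "btm_estimates")
}

#' Fit a Biterm Topic Model
#'
#' Extracts biterms from the tokenized corpus, initializes topic assignments
#' with the seeded RNG, runs `n_sweeps` collapsed Gibbs sweeps, and forms the
#' point estimate from counts averaged over post-burn-in sweeps. Diagnostics
#' include the per-sweep corpus log-likelihood trace.
#'
#' @param docs named list of integer index vectors (1-based, see
#'   [docs_to_indices()]).
#' @param M vocabulary size.
#' @param config a [btm_config()].
#' @return Object of class `btm_fit`: `estimates`, final `state`,
#'   `config`, `diagnostics` (list with `loglik`, `n_biterms`, `n_docs`,
#'   `n_kept_sweeps`).
#' @export
btm_fit <- function(docs, M, config = btm_config()) {
  cb <- corpus_biterms(docs)
  if (is.null(cb$biterms) || nrow(cb$biterms) == 0L) {
    stop("corpus yields no biterms (all documents shorter than 2 tokens)")
  }
  state <- init_state(cb$biterms, M, config)
  res <- btm_gibbs_cpp(cb$biterms - 1L, M, config$K,
                       config$alpha, config$beta,
                       config$n_sweeps, config$burn_in,
                       state$z - 1L,
                       track_assign = FALSE, track_loglik = TRUE)
  avg_state <- list(n_k = res$n_k_mean, n_wk = res$n_wk_mean,
                    M = as.integer(M), K = config$K)
  est <- btm_estimate(avg_state, config)
  final_state <- structure(list(z = res$z + 1L, n_k = res$n_k,
                                n_wk = res$n_wk, M = as.integer(M),
                                K = config$K),
                           class = "btm_state")
  structure(list(estimates = est, state = final_state, config = config,
                 diagnostics = list(loglik = res$loglik,
                                    n_biterms = nrow(cb$biterms),
                                    n_docs = cb$n_docs,
                                    n_kept_sweeps = res$n_kept)),
            class = "btm_fit")
}

#' @export
print.btm_fit <- function(x, ...) {
  cat("<btm_fit> K =", x$config$K,
      "| M =", x$estimates$M,
      "| biterms =", x$diagnostics$n_biterms,
      "| sweeps =", x$config$n_sweeps,
      sprintf("(burn-in %d)\n", x$config$burn_in))
  invisible(x)
}

#' Document-level topic posterior
#'
#' `P(z = k | d) = sum_b P(z = k | b) P(b | d)` with `P(b | d)` uniform over
#' the document's biterms and `P(z = k | b)` proportional to
#' `theta[k] * phi[k, w1] * phi[k, w2]`. Single-token documents fall back to
#' the unigram posterior `P(z = k | w)` proportional to `theta[k] * phi[k, w]`;
#' empty documents get the uniform vector and are flagged unassigned.
#'
#' @param doc integer vector of 1-based vocabulary indices.
#' @param est a `btm_estimates`.
#' @return Length-K probability vector; attribute `unassigned` is TRUE for
#'   empty documents.
#' @export
infer_doc_topics <- function(doc, est) {
  K <- est$K
  doc <- as.integer(doc)
  if (length(doc) == 0L) {
    p <- rep(1 / K, K)
    attr(p, "unassigned") <- TRUE
    return(p)
  }
  if (length(doc) == 1L) {
    w <- est$theta * est$phi[, doc]
    p <- w / sum(w)
    attr(p, "unassigned") <- FALSE
    return(p)
  }
  bt <- extract_biterms(doc)
  w <- est$theta * est$phi[, bt[, 1L], drop = FALSE] *
    est$phi[, bt[, 2L], drop = FALSE]           # K x B
  w <- sweep(w, 2L, colSums(w), "/")
  p <- rowMeans(w)
  p <- p / sum(p)
  attr(p, "unassigned") <- FALSE
  p
}

#' Topic posteriors for a whole corpus
#'
#' @param docs named list of integer index vectors.
#' @param est a `btm_estimates`.
#' @return Matrix (documents x K) with row names from `names(docs)` and a
#'   logical attribute `unassigned` per document.
#' @export
infer_corpus_topics <- function(docs, est) {
  post <- matrix(NA_real_, nrow = length(docs), ncol = est$K,
                 dimnames = list(names(docs), NULL))
  unassigned <- logical(length(docs))
  for (i in seq_along(docs)) {
    p <- infer_doc_topics(docs[[i]], est)
    unassigned[i] <- isTRUE(attr(p, "unassigned"))
    post[i, ] <- p
  }
  attr(post, "unassigned") <- setNames(unassigned, names(docs))
  post
}

#' Exact per-biterm topic marginals by exhaustive enumeration
#'
#' Test oracle: sums the collapsed joint probability over all `K^B`
#' assignments. The joint is computed from first principles via the
#' Dirichlet-multinomial integrals,
#' `log P(z) = sum_k lgamma(n_k + alpha) + sum_{w,k} lgamma(n_wk + beta)
#'             - sum_k lgamma(2 n_k + M beta)` (up to a constant),
#' independently of the sampler's conditional.
#'
#' @param biterms integer matrix (columns `w1`, `w2`, 1-based).
#' @param M vocabulary size.
#' @param config a [btm_config()].
#' @param max_states refuse instances with more than this many assignments.
#' @return B x K matrix of exact marginal probabilities.
#' @export
exact_posterior_small <- function(biterms, M, config, max_states = 1e6) {
  B <- nrow(biterms)
  K <- config$K
  if (K^B > max_states) {
    stop("instance too large for exhaustive enumeration: K^B = ", K^B)
  }
  alpha <- config$alpha
  beta <- config$beta
  n_states <- K^B
  logp <- numeric(n_states)
  marg <- matrix(0, nrow = B, ncol = K)
  z <- integer(B)  # 0-based digits
  for (s in seq_len(n_states)) {
    # decode state s-1 in base K
    v <- s - 1L
    for (b in seq_len(B)) {
      z[b] <- v %% K
      v <- v %/% K
    }
    n_k <- tabulate(z + 1L, nbins = K)
    n_wk <- matrix(0L, nrow = M, ncol = K)
    for (b in seq_len(B)) {
      k <- z[b] + 1L
      n_wk[biterms[b, 1L], k] <- n_wk[biterms[b, 1L], k] + 1L
      n_wk[biterms[b, 2L], k] <- n_wk[biterms[b, 2L], k] + 1L
    }
    logp[s] <- sum(lgamma(n_k + alpha)) + sum(lgamma(n_wk + beta)) -
      sum(lgamma(2 * n_k + M * beta))
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  for (s in seq_len(n_states)) {
    v <- s - 1L
    for (b in seq_len(B)) {
      marg[b, (v %% K) + 1L] <- marg[b, (v %% K) + 1L] + p[s]
      v <- v %/% K
    }
  }
  marg
}

#' Long-run Gibbs assignment frequencies
#'
#' Companion to [exact_posterior_small()]: runs the sampler and returns the
#' per-biterm empirical topic frequencies over post-burn-in sweeps.
#'
#' @inheritParams exact_posterior_small
#' @param n_sweeps,burn_in sampling schedule (post-burn-in samples =
#'   `n_sweeps - burn_in`).
#' @return B x K matrix of empirical assignment frequencies.
#' @export
gibbs_assignment_freq <- function(biterms, M, config,
                                  n_sweeps = 60000L, burn_in = 10000L) {
  state <- init_state(biterms, M, config)
  res <- btm_gibbs_cpp(biterms - 1L, M, config$K,
                       config$alpha, config$beta,
                       as.integer(n_sweeps), as.integer(burn_in),
                       state$z - 1L,
                       track_assign = TRUE, track_loglik = FALSE)
  res$assign_freq
}

#' Dump a fitted model to JSON
#'
#' Versioned schema containing the configuration, vocabulary, theta, phi and
#' (optionally) per-document topic posteriors. Deterministic: identical fits
#' produce byte-identical files.
#'
#' @param fit a `btm_fit`.
#' @param vocab the `vocabulary` the model was fitted on.
#' @param path output path.
#' @param doc_posteriors optional matrix from [infer_corpus_topics()].
#' @return `path`, invisibly.
#' @export
write_btm <- function(fit, vocab, path, doc_posteriors = NULL) {
  obj <- list(
    schema_version = "opiwatch-btm-1",
    config = unclass(fit$config),
    vocabulary = vocab$tokens,
    theta = fit$estimates$theta,
    phi = fit$estimates$phi,
    diagnostics = list(n_biterms = fit$diagnostics$n_biterms,
                       n_docs = fit$diagnostics$n_docs)
  )
  if (!is.null(doc_posteriors)) {
    obj$doc_ids <- rownames(doc_posteriors)
    obj$doc_posteriors <- unname(doc_posteriors)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a model dump written by [write_btm()]
#'
#' @param path path to the JSON dump.
#' @return List with `config` (a `btm_config`), `vocab`, `estimates`
#'   (`btm_estimates`) and, when present, `doc_posteriors`.
#' @export
read_btm <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema_version, "opiwatch-btm-1")) {
    stop("unrecognized model dump schema: ", obj$schema_version)
  }
  cfg <- do.call(btm_config, obj$config[c("K", "alpha", "beta", "n_sweeps",
                                          "burn_in", "seed", "top_words")])
  vocab <- structure(list(tokens = obj$vocabulary,
                          index = setNames(seq_along(obj$vocabulary),
                                           obj$vocabulary)),
                     class = "vocabulary")
  est <- structure(list(theta = obj$theta, phi = obj$phi,
                        K = cfg$K, M = length(obj$vocabulary)),
                   class = "btm_estimates")
  out <- list(config = cfg, vocab = vocab, estimates = est)
  if (!is.null(obj$doc_posteriors)) {
    dp <- obj$doc_posteriors
    rownames(dp) <- obj$doc_ids
    out$doc_posteriors <- dp
  }
  out
}
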