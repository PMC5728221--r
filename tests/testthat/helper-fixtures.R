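# Shared fixture builders; everything is generated in code.

toy_corpus <- function(texts, ids = sprintf("t%02d", seq_along(texts)),
                       is_retweet = rep(FALSE, length(texts)),
                       minutes = seq_along(texts)) {
  tweet_corpus(ids, texts,
               created_at = as.POSIXct("2015-06-01", tz = "UTC") + 60 * minutes,
               is_retweet = is_retweet)
}

write_jsonl <- function(lines, dir = tempdir()) {
  path <- tempfile("tweets", tmpdir = dir, fileext = ".jsonl")
  writeLines(lines, path)
  path
}

# A small, well-separated two-topic estimate for inference tests.
toy_estimates <- function(theta = c(0.5, 0.5),
                          phi = rbind(c(0.8, 0.2), c(0.3, 0.7))) {
  structure(list(theta = theta, phi = phi,
                 K = length(theta), M = ncol(phi)),
            class = "btm_estimates")
}

toy_vocab <- function(tokens) {
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "vocabulary")
}
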