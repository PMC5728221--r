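test_that("read_corpus parses valid lines in order and skips malformed ones", {
  path <- write_jsonl(c(
    '{"id":"a","text":"first tweet"}',
    '{"id":"b","text":"second tweet","created_at":"2015-06-01T10:00:00"}',
    '{"id":"c","text":"third tweet","retweeted":true}'
  ))
  corp <- read_corpus(path)
  expect_equal(corp$tweet_id, c("a", "b", "c"))
  expect_equal(attr(corp, "n_skipped"), 0L)
  expect_true(corp$is_retweet[[3]])
  expect_equal(format(corp$created_at[[2]], "%H:%M"), "10:00")

  path2 <- write_jsonl(c(
    '{"id":"a","text":"ok"}',
    'not json at all{{{',
    '{"id":"b","text":"also ok"}'
  ))
  expect_warning(corp2 <- read_corpus(path2), "skipped 1")
  expect_equal(corp2$tweet_id, c("a", "b"))
  expect_equal(attr(corp2, "n_skipped"), 1L)

  empty <- write_jsonl(character())
  expect_equal(nrow(read_corpus(empty)), 0L)
  expect_error(read_corpus(tempfile("nope")), "cannot read")
})

test_that("read_corpus understands the Twitter v1.1 field dialect", {
  path <- write_jsonl(paste0(
    '{"id_str":"99","text":"rt body","retweeted_status":{"id_str":"1"},',
    '"entities":{"urls":[{"url":"https://t.co/x","expanded_url":"https://long.example/page"}]},',
    '"created_at":"Wed Jun 03 12:00:00 +0000 2015"}'
  ))
  corp <- read_corpus(path)
  expect_equal(corp$tweet_id, "99")
  expect_true(corp$is_retweet)
  expect_equal(corp$urls[[1]], "https://long.example/page")
  expect_equal(format(corp$created_at, "%Y-%m-%d %H:%M", tz = "UTC"),
               "2015-06-03 12:00")
})

test_that("corpus round-trips through write_corpus/read_corpus", {
  corp <- toy_corpus(c("alpha beta", "gamma delta https://x.example/1"))
  corp$urls[[2]] <- "https://x.example/1"
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(back$tweet_id, corp$tweet_id)
  expect_equal(back$text, corp$text)
  expect_equal(back$urls, corp$urls)
})

test_that("keyword_filter is case-insensitive, order-preserving and idempotent", {
  corp <- toy_corpus(c("fentanyl seized", "opioid crisis", "Fentanyl kills"))
  hit <- keyword_filter(corp, "fentanyl")
  expect_equal(hit$tweet_id, c("t01", "t03"))
  expect_identical(keyword_filter(hit, "fentanyl"), hit)
  expect_error(keyword_filter(corp, ""), "nzchar")

  # property: idempotence and order preservation on generated corpora
  set.seed(101)
  words <- c("fentanyl", "news", "buy", "pills", "crisis")
  for (i in 1:20) {
    texts <- vapply(1:30, function(j) {
      paste(sample(words, sample(2:5, 1), replace = TRUE), collapse = " ")
    }, character(1))
    corp_i <- toy_corpus(texts)
    f1 <- keyword_filter(corp_i, "buy")
    expect_identical(keyword_filter(f1, "buy"), f1)
    expect_true(!is.unsorted(match(f1$tweet_id, corp_i$tweet_id)))
  }
})

test_that("normalize_and_tokenize applies the stated normalization rules", {
  out <- normalize_and_tokenize("RT @bob: Buy FENTANYL now! https://t.co/x")[[1]]
  expect_equal(out, c("buy", "fentanyl", "now"))
  expect_equal(normalize_and_tokenize("!!!")[[1]], character())
  expect_equal(normalize_and_tokenize("price price price")[[1]],
               c("price", "price", "price"))
  # stopwords and short tokens dropped
  expect_equal(normalize_and_tokenize("the pill is a K9")[[1]], c("pill", "k9"))
  # mentions mid-text removed
  expect_equal(normalize_and_tokenize("ping @alice about pills")[[1]],
               c("ping", "pills"))
})

test_that("build_vocabulary orders by frequency then lexicographically", {
  v <- build_vocabulary(list(c("a", "b"), "a"))
  expect_equal(v$tokens, c("a", "b"))
  expect_equal(unname(v$index[c("a", "b")]), c(1L, 2L))
  v2 <- build_vocabulary(list(c("a", "b"), "a"), min_count = 2)
  expect_equal(v2$tokens, "a")
  expect_error(build_vocabulary(list(c("a", "b"), "a"), min_count = 3),
               "empty vocabulary")
  # tie broken lexicographically
  v3 <- build_vocabulary(list(c("zeta", "alpha")))
  expect_equal(v3$tokens, c("alpha", "zeta"))
})

test_that("vocabulary mapping is a bijection and round-trips", {
  set.seed(7)
  docs <- replicate(40, sample(letters, sample(3:8, 1), replace = TRUE),
                    simplify = FALSE)
  v <- build_vocabulary(docs)
  expect_equal(unname(v$index[v$tokens]), seq_along(v$tokens))
  expect_false(anyDuplicated(v$tokens) > 0)
  idx <- docs_to_indices(stats::setNames(docs, seq_along(docs)), v)
  expect_true(all(unlist(idx) >= 1) && all(unlist(idx) <= length(v)))
})

test_that("extract_urls finds http(s) links in order", {
  expect_equal(extract_urls("buy now https://t.co/abc123"),
               "https://t.co/abc123")
  expect_equal(extract_urls("no link here"), character())
  expect_equal(extract_urls("a https://x.com b http://y.net"),
               c("https://x.com", "http://y.net"))
  expect_equal(extract_urls("end of sentence https://x.com/page."),
               "https://x.com/page")
})

test_that("collapse_duplicates clusters by canonical key and partitions the corpus", {
  corp <- toy_corpus(c("buy here", "buy here"))
  coll <- collapse_duplicates(corp)
  expect_equal(nrow(coll$unique), 1L)
  expect_equal(sort(coll$clusters[[1]]), c("t01", "t02"))

  # RT prefix and URL variants collapse; non-retweet representative
  corp2 <- toy_corpus(c("RT @u: buy here https://a", "buy here https://b"),
                      minutes = c(1, 2))
  coll2 <- collapse_duplicates(corp2)
  expect_equal(nrow(coll2$unique), 1L)
  expect_equal(coll2$unique$tweet_id, "t02")

  corp3 <- toy_corpus(c("one", "two", "three"))
  coll3 <- collapse_duplicates(corp3)
  expect_equal(coll3$unique$text, corp3$text)

  # property: cluster sizes always sum to corpus size
  set.seed(33)
  for (i in 1:10) {
    base <- sprintf("msg %d %s", 1:15, sample(letters, 15))
    texts <- sample(c(base, base[sample(15, 5)]))
    corp_i <- toy_corpus(texts)
    coll_i <- collapse_duplicates(corp_i)
    expect_equal(sum(lengths(coll_i$clusters)), nrow(corp_i))
    expect_equal(nrow(coll_i$map), nrow(corp_i))
  }
})

test_that("earliest non-retweet is the cluster representative", {
  corp <- tweet_corpus(
    c("rt1", "late", "early"),
    c("RT @x: same ad", "same ad", "same ad"),
    created_at = as.POSIXct("2015-06-01", tz = "UTC") + c(10, 300, 100),
    is_retweet = c(TRUE, FALSE, FALSE)
  )
  coll <- collapse_duplicates(corp)
  expect_equal(coll$unique$tweet_id, "early")
})
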