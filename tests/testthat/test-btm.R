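test_that("extract_biterms forms all unordered position pairs", {
  bt <- extract_biterms(c(1L, 2L, 3L))
  expect_equal(nrow(bt), 3L)
  expect_equal(unname(bt), cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)))
  expect_equal(nrow(extract_biterms(5L)), 0L)
  expect_equal(nrow(extract_biterms(integer())), 0L)
  # repeats at distinct positions are kept, incl. same-word biterms
  bt2 <- extract_biterms(c(2L, 2L, 3L))
  expect_equal(unname(bt2[order(bt2[, 1], bt2[, 2]), ]),
               cbind(c(2L, 2L, 2L), c(2L, 3L, 3L)))
  # a doc of length L yields choose(L, 2) biterms, canonicalized w1 <= w2
  for (L in c(4L, 9L)) {
    doc <- sample.int(10L, L, replace = TRUE)
    bt_l <- extract_biterms(doc)
    expect_equal(nrow(bt_l), L * (L - 1) / 2)
    expect_true(all(bt_l[, 1] <= bt_l[, 2]))
  }
})

test_that("init_state is seeded, consistent and conserves counts", {
  bt <- extract_biterms(c(1L, 2L, 3L, 1L))
  cfg <- btm_config(K = 2, n_sweeps = 10, burn_in = 5, seed = 5)
  s1 <- init_state(bt, 3L, cfg)
  s2 <- init_state(bt, 3L, cfg)
  expect_identical(s1, s2)
  expect_equal(sum(s1$n_k), nrow(bt))
  expect_equal(colSums(s1$n_wk), 2 * s1$n_k)

  cfg1 <- btm_config(K = 1, n_sweeps = 2, burn_in = 1, seed = 1)
  s3 <- init_state(bt, 3L, cfg1)
  expect_true(all(s3$z == 1L))
  expect_equal(s3$n_k, nrow(bt))

  expect_error(init_state(matrix(integer(), ncol = 2), 3L, cfg), "no biterms")
})

test_that("the full conditional matches its closed form", {
  cfg <- btm_config(K = 2, alpha = 1, beta = 0.01, n_sweeps = 2, burn_in = 1)
  # biterm (w1, w2) removed; topic 1 empty, topic 2 holds one (w1, w2) biterm
  n_k <- c(0, 1)
  n_wk <- rbind(c(0, 1), c(0, 1))
  p <- biterm_conditional(n_k, n_wk, 1L, 2L, cfg)
  expect_equal(p, c(0.014446, 0.985554), tolerance = 1e-4)
  # fully symmetric counts give a symmetric conditional
  p_sym <- biterm_conditional(c(2, 2), rbind(c(2, 2), c(2, 2)), 1L, 2L, cfg)
  expect_equal(p_sym, c(0.5, 0.5))
})

test_that("gibbs sweeps conserve counts and respect the seeded RNG stream", {
  set.seed(17)
  docs <- replicate(15, sample.int(6L, sample(3:6, 1), replace = TRUE),
                    simplify = FALSE)
  cb <- corpus_biterms(stats::setNames(docs, seq_along(docs)))
  cfg <- btm_config(K = 3, n_sweeps = 10, burn_in = 0, seed = 9)
  st <- init_state(cb$biterms, 6L, cfg)
  B <- nrow(cb$biterms)
  for (i in 1:5) {
    st <- gibbs_sweep(st, cb$biterms, cfg)
    expect_equal(sum(st$n_k), B)
    expect_equal(colSums(st$n_wk), 2 * st$n_k)
    expect_true(all(st$n_wk >= 0))
  }
})

test_that("point estimates follow the smoothed count formulas", {
  cfg <- btm_config(K = 2, alpha = 1, beta = 0.01, n_sweeps = 2, burn_in = 1)
  st <- list(n_k = c(3, 1), n_wk = matrix(c(2, 4, 1, 1), nrow = 2),
             M = 2L, K = 2L)
  est <- btm_estimate(st, cfg)
  expect_equal(est$theta, c(2 / 3, 1 / 3))
  expect_equal(rowSums(est$phi), c(1, 1), tolerance = 1e-12)
  expect_true(all(est$phi > 0))
  # pure-prior limit: a topic with no counts has a uniform word distribution
  st0 <- list(n_k = c(4, 0), n_wk = matrix(c(4, 4, 0, 0), nrow = 2),
              M = 2L, K = 2L)
  est0 <- btm_estimate(st0, cfg)
  expect_equal(est0$phi[2, ], c(0.5, 0.5))
  # K = 1 degenerates to theta = 1
  cfg1 <- btm_config(K = 1, n_sweeps = 2, burn_in = 1)
  expect_equal(btm_estimate(list(n_k = 7, n_wk = matrix(14, 1, 1),
                                 M = 1L, K = 1L), cfg1)$theta, 1)
})

test_that("btm_fit is deterministic and satisfies the estimate invariants", {
  set.seed(3)
  docs <- replicate(30, sample.int(12L, sample(3:7, 1), replace = TRUE),
                    simplify = FALSE)
  docs <- stats::setNames(docs, sprintf("d%02d", seq_along(docs)))
  cfg <- btm_config(K = 4, n_sweeps = 60, burn_in = 30, seed = 21)
  f1 <- btm_fit(docs, 12L, cfg)
  f2 <- btm_fit(docs, 12L, cfg)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$state, f2$state)
  expect_equal(sum(f1$estimates$theta), 1, tolerance = 1e-9)
  expect_equal(rowSums(f1$estimates$phi), rep(1, 4), tolerance = 1e-9)
  expect_true(all(f1$estimates$phi > 0))
  expect_length(f1$diagnostics$loglik, 60L)
  expect_equal(f1$diagnostics$n_kept_sweeps, 30L)
  expect_error(btm_fit(list(a = 1L, b = 2L), 3L, cfg), "no biterms")
})

test_that("document inference mixes per-biterm posteriors", {
  est <- toy_estimates()  # theta (.5,.5); phi rows (.8,.2) / (.3,.7)
  # doc (1,2): P(k|b) prop to .5*.8*.2 = .08 and .5*.3*.7 = .105
  p <- infer_doc_topics(c(1L, 2L), est)
  expect_equal(as.numeric(p), c(0.08, 0.105) / 0.185, tolerance = 1e-12)
  # unigram fallback for single-token docs
  p1 <- infer_doc_topics(1L, est)
  expect_equal(as.numeric(p1), c(0.8, 0.3) / 1.1, tolerance = 1e-12)
  # empty docs: uniform and flagged
  p0 <- infer_doc_topics(integer(), est)
  expect_equal(as.numeric(p0), c(0.5, 0.5))
  expect_true(attr(p0, "unassigned"))
  # K = 1 gives [1] for any doc
  est1 <- structure(list(theta = 1, phi = matrix(c(.6, .4), 1), K = 1L, M = 2L),
                    class = "btm_estimates")
  expect_equal(as.numeric(infer_doc_topics(c(1L, 2L, 2L), est1)), 1)
  # a doc whose biterms all favor topic 1 has argmax 1
  p_doc <- infer_doc_topics(c(1L, 1L, 1L), est)
  expect_equal(which.max(p_doc), 1L)
})

test_that("infer_corpus_topics returns row-stochastic posteriors with flags", {
  est <- toy_estimates()
  docs <- list(a = c(1L, 2L), b = integer(), c = 2L)
  post <- infer_corpus_topics(docs, est)
  expect_equal(rownames(post), c("a", "b", "c"))
  expect_equal(unname(rowSums(post)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(attr(post, "unassigned")), c(FALSE, TRUE, FALSE))
})

test_that("exhaustive posterior oracle handles symmetric small instances", {
  cfg <- btm_config(K = 2, alpha = 1, beta = 0.01, n_sweeps = 2, burn_in = 1)
  # |B| = 1: pure-prior marginal is uniform over topics
  m1 <- exact_posterior_small(cbind(w1 = 1L, w2 = 2L), 2L, cfg)
  expect_equal(as.numeric(m1), c(0.5, 0.5))
  # two biterms on disjoint words, symmetric priors: marginals symmetric
  m2 <- exact_posterior_small(cbind(w1 = c(1L, 3L), w2 = c(2L, 4L)), 4L, cfg)
  expect_equal(rowSums(m2), c(1, 1), tolerance = 1e-12)
  expect_equal(m2[1, ], rev(m2[1, ]))
  expect_equal(m2[1, ], m2[2, ])
  expect_error(
    exact_posterior_small(cbind(w1 = rep(1L, 25), w2 = rep(2L, 25)), 2L, cfg),
    "too large")
})

test_that("gibbs long-run frequencies agree with the enumeration oracle", {
  # quick version of the sampler-correctness check (full one in acceptance)
  bt <- cbind(w1 = c(1L, 1L, 2L), w2 = c(2L, 3L, 3L))
  cfg <- btm_config(K = 2, alpha = 1, beta = 0.01,
                    n_sweeps = 25000, burn_in = 5000, seed = 13)
  exact <- exact_posterior_small(bt, 3L, cfg)
  freq <- gibbs_assignment_freq(bt, 3L, cfg,
                                n_sweeps = 25000L, burn_in = 5000L)
  tv <- 0.5 * rowSums(abs(exact - freq))
  expect_true(all(tv < 0.03))
})

test_that("model dumps round-trip through JSON", {
  set.seed(5)
  docs <- replicate(12, sample.int(8L, 4, replace = TRUE), simplify = FALSE)
  docs <- stats::setNames(docs, sprintf("d%02d", seq_along(docs)))
  vocab <- toy_vocab(sprintf("tok%02d", 1:8))
  cfg <- btm_config(K = 3, n_sweeps = 30, burn_in = 10, seed = 2)
  fit <- btm_fit(docs, 8L, cfg)
  post <- infer_corpus_topics(docs, fit$estimates)
  path <- tempfile(fileext = ".json")
  write_btm(fit, vocab, path, doc_posteriors = post)
  back <- read_btm(path)
  expect_equal(back$estimates$theta, fit$estimates$theta, tolerance = 1e-12)
  expect_equal(back$estimates$phi, fit$estimates$phi, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$vocab$tokens, vocab$tokens)
  expect_equal(back$doc_posteriors[, 1], post[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$config$K, 3L)
  expect_error(read_btm(write_jsonl('{"schema_version":"other"}')),
               "schema")
})
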