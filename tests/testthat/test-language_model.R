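commands <- default_sentences()

test_that("trigram counts over the four command phrases are exact", {
  lm <- fit_trigram(commands, k_smooth = 0)
  expect_length(lm$vocabulary, 10)
  expect_equal(ngram_count(lm, "Land", "Here"), 2)  # "Land Here" + "Do Not Land Here"
  expect_equal(ngram_count(lm, "Up", "Pick"), 0)
  expect_equal(ngram_count(lm, "Pick", "Us", "Up"), 1)
  expect_equal(ngram_count(lm, "Here"), 2)
  expect_error(fit_trigram(list()), "nonempty")
  expect_error(fit_trigram(list(c("Land", "Mars")),
                           vocabulary = lm$vocabulary),
               "outside vocabulary")
})

test_that("unsmoothed log-probabilities match the count-and-multiply oracle", {
  lm <- fit_trigram(commands, k_smooth = 0)
  expect_equal(ngram_logprob(lm, c("Land", "Here")), log(1 / 4))
  for (s in commands)
    expect_equal(ngram_logprob(lm, s), oracle_logprob(commands, s, k = 0))
  vocab <- lm$vocabulary
  set.seed(31)
  for (i in 1:20) {
    words <- sample(vocab, sample(2:5, 1), replace = TRUE)
    expect_equal(ngram_logprob(lm, words), oracle_logprob(commands, words, 0))
  }
  expect_error(ngram_logprob(lm, c("Land", "Mars")), "out-of-vocabulary")
})

test_that("smoothed probabilities stay oracle-exact and logprob is nonpositive", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  set.seed(32)
  for (i in 1:10) {
    words <- sample(lm$vocabulary, sample(2:5, 1), replace = TRUE)
    lp <- ngram_logprob(lm, words)
    expect_equal(lp, oracle_logprob(commands, words, 0.01))
    expect_lte(lp, 0)
  }
  # an observed continuation outranks an unseen one under the same history
  p_up <- silentspeech:::trigram_prob(lm, "Pick", "Us", "Up")
  p_here <- silentspeech:::trigram_prob(lm, "Pick", "Us", "Here")
  expect_gt(p_up, p_here)
})

test_that("smoothed conditionals sum to one over every observed history", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  events <- c(lm$vocabulary, "</s>")
  for (key in names(lm$hist2)) {
    h <- strsplit(key, "\t", fixed = TRUE)[[1]]
    tot <- sum(vapply(events, function(w)
      silentspeech:::trigram_prob(lm, h[1], h[2], w), 0))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("candidate enumeration bounds, dedupes and truncates hypotheses", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  r1 <- mk_ranking(c(Land = 0.6, Pick = 0.3))
  r2 <- mk_ranking(c(Here = 0.7, Up = 0.2))
  hyps <- enumerate_candidates(list(r1, r2), top_m = 2, K = 10, model = lm,
                               prune_threshold = 0)
  expect_lte(length(hyps), 4)
  keys <- vapply(hyps, function(h) paste(h$words, collapse = " "), "")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(enumerate_candidates(list(r1, r2), top_m = 2, K = 1,
                                        model = lm,
                                        prune_threshold = 0)[[1]]$words,
                   c("Land", "Here"))
  expect_error(enumerate_candidates(list(r1), top_m = 2, K = 0, model = lm),
               "K must be")
  expect_error(enumerate_candidates(list(), 2, 3, lm), "nonempty")
})

test_that("combined confidence is the length-normalized log-linear mixture", {
  hyp <- structure(list(words = c("Pick", "Us", "Up"), lm_logprob = -2,
                        snn_logconf = -4), class = "sentence_hypothesis")
  expect_equal(combined_confidence(hyp, lambda = 0.5), -1)
  expect_equal(combined_confidence(hyp, lambda = 1), -2 / 3)
  expect_equal(combined_confidence(hyp, lambda = 0), -4 / 3)
  expect_error(combined_confidence(hyp, lambda = 2), "lambda")
  hyp$words <- character(0)
  expect_error(combined_confidence(hyp), "no words")
})

test_that("correction falls back to the raw sequence when all paths are pruned", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  # "Up Us" reverses every attested transition; with an aggressive threshold
  # nothing survives the filter
  r1 <- mk_ranking(c(Up = 0.9))
  r2 <- mk_ranking(c(Us = 0.9))
  out <- correct_sentence(list(r1, r2), lm, K = 3, top_m = 1,
                          prune_threshold = 0.5)
  expect_true(attr(out, "fallback"))
  expect_identical(as.character(out), c("Up", "Us"))
})

test_that("correction never emits out-of-vocabulary words and respects K", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  set.seed(33)
  for (i in 1:10) {
    n_win <- sample(3:6, 1)
    rankings <- lapply(seq_len(n_win), function(j) {
      cls <- sample(c(lm$vocabulary, "NOISE"), 3)
      conf <- sort(runif(3), decreasing = TRUE)
      mk_ranking(stats::setNames(conf / sum(conf), cls), window_index = j)
    })
    out <- correct_sentence(rankings, lm, K = 4, top_m = 2)
    expect_true(all(as.character(out) %in% lm$vocabulary))
    hyps <- attr(out, "hypotheses")
    if (!is.null(hyps)) expect_lte(length(hyps), 4)
  }
})

test_that("a trained sentence decoded correctly is a fixed point of correction", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  rankings <- list(mk_ranking(c(Pick = 0.8, Land = 0.1)),
                   mk_ranking(c(Us = 0.7, Up = 0.2)),
                   mk_ranking(c(Up = 0.9, Us = 0.05)))
  out <- correct_sentence(rankings, lm, K = 5, top_m = 2)
  expect_identical(as.character(out), c("Pick", "Us", "Up"))
  expect_false(attr(out, "fallback"))
})

test_that("the count table serializes and reloads exactly", {
  lm <- fit_trigram(commands, k_smooth = 0.01)
  path <- withr::local_tempfile(fileext = ".txt")
  write_trigram(lm, path)
  back <- read_trigram(path)
  expect_identical(back$vocabulary, lm$vocabulary)
  expect_equal(back$k_smooth, lm$k_smooth)
  for (tab in c("c1", "c2", "c3", "hist2"))
    expect_identical(back[[tab]][sort(names(back[[tab]]))],
                     lm[[tab]][sort(names(lm[[tab]]))])
  set.seed(34)
  words <- sample(lm$vocabulary, 4, replace = TRUE)
  expect_identical(ngram_logprob(back, words), ngram_logprob(lm, words))
})
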