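cos_dist <- function(a, b) 1 - sum(a * b) / sqrt(sum(a * a) * sum(b * b))

test_that("word banks are deterministic, distinct and validated", {
  cfg <- tiny_synth()
  vocab <- default_vocabulary()
  b1 <- make_word_bank(vocab, cfg)
  b2 <- make_word_bank(vocab, cfg)
  expect_identical(b1$templates, b2$templates)
  expect_length(b1$templates$emg, 10)   # NOISE has no template
  expect_length(b1$templates$eeg, 10)
  words <- names(b1$templates$emg)
  for (i in seq_along(words)[-1])
    for (j in seq_len(i - 1))
      expect_gt(cos_dist(b1$templates$emg[[words[i]]],
                         b1$templates$emg[[words[j]]]), 0)
  expect_error(make_word_bank(character(0), cfg), "nonempty")
  expect_error(make_word_bank(c("A", "A"), cfg), "duplicate")
})

test_that("a degenerate word instance equals the template exactly", {
  cfg <- tiny_synth(noise_sd = 0, amp_jitter = 0, time_warp = 0)
  bank <- make_word_bank(c("Alpha", "Bravo"), cfg)
  rec <- synth_word_recording(bank, "Alpha", cfg, rep_seed = 5L)
  expect_identical(rec$emg, bank$templates$emg$Alpha)
  expect_identical(rec$eeg, bank$templates$eeg$Alpha)
  expect_error(synth_word_recording(bank, "Delta", cfg, 1L), "unknown word")
})

test_that("word instances stay closer to their own template than to others", {
  cfg <- tiny_synth()
  bank <- make_word_bank(tiny_vocab, cfg)
  for (seed in 1:5) {
    rec <- synth_word_recording(bank, "Alpha", cfg, rep_seed = seed)
    len <- min(length(rec$emg), cfg$word_duration)
    x <- rec$emg[seq_len(len)]
    tpl <- bank$templates$emg$Alpha[seq_along(x)]
    d_own <- cos_dist(x, tpl)
    for (other in c("Bravo", "Charlie"))
      expect_lt(d_own, cos_dist(x, bank$templates$emg[[other]][seq_along(x)]))
  }
})

test_that("NOISE instances are uncorrelated with every template", {
  cfg <- tiny_synth(word_duration = 400L)
  bank <- make_word_bank(tiny_vocab, cfg)
  rec <- synth_word_recording(bank, "NOISE", cfg, rep_seed = 9L)
  for (w in c("Alpha", "Bravo", "Charlie")) {
    tpl <- bank$templates$emg[[w]][seq_along(rec$emg)]
    expect_lt(abs(cor(rec$emg, tpl)), 0.25)
  }
  expect_identical(rec$kind, "noise")
})

test_that("sentence length follows the crossfade arithmetic", {
  cfg <- synth_config(word_duration = 800L, crossfade = 100L,
                      pad_noise = 200L, time_warp = 0, noise_sd = 0.1,
                      amp_jitter = 0, seed = 1L)
  bank <- make_word_bank(c("Alpha", "Bravo"), cfg)
  rec <- synth_sentence_recording(bank, c("Alpha", "Bravo"), cfg, 1L)
  expect_length(rec$emg, 2 * 200 + 1600 - 100)   # 1900
  expect_identical(rec$label, "Alpha Bravo")
  expect_identical(rec$pad, 200L)
  expect_error(synth_sentence_recording(bank, character(0), cfg, 1L),
               "nonempty")
})

test_that("zero-crossfade, zero-noise sentences are exact concatenations", {
  cfg <- tiny_synth(noise_sd = 0, amp_jitter = 0, time_warp = 0,
                    crossfade = 0L, pad_noise = 0L)
  bank <- make_word_bank(c("Alpha", "Bravo"), cfg)
  rec <- synth_sentence_recording(bank, c("Alpha", "Bravo"), cfg, 1L)
  expect_identical(rec$emg,
                   c(bank$templates$emg$Alpha, bank$templates$emg$Bravo))
})

test_that("coarticulation makes the boundary differ from naive concatenation", {
  cfg <- tiny_synth(noise_sd = 0, amp_jitter = 0, time_warp = 0,
                    crossfade = 30L, pad_noise = 0L)
  bank <- make_word_bank(c("Alpha", "Bravo"), cfg)
  rec <- synth_sentence_recording(bank, c("Alpha", "Bravo"), cfg, 1L)
  naive <- c(bank$templates$emg$Alpha, bank$templates$emg$Bravo)
  n <- cfg$word_duration
  boundary <- rec$emg[(n - 29):n]   # the blended overlap region
  expect_gt(cos_dist(boundary, bank$templates$emg$Alpha[(n - 29):n]), 0)
  expect_gt(cos_dist(boundary, bank$templates$emg$Bravo[1:30]), 0)
  expect_false(isTRUE(all.equal(rec$emg, naive[seq_along(rec$emg)])))
})

test_that("synth_corpora produces the study corpus shapes deterministically", {
  cfg <- synth_config(seed = 11L)
  out <- synth_corpora(config = cfg)
  kinds <- vapply(out$corpus_a$recordings, `[[`, "", "kind")
  expect_equal(sum(kinds == "word"), 1500)     # 10 words x 150 reps
  expect_equal(sum(kinds == "noise"), 150)     # the noise class
  expect_length(out$corpus_b$recordings, 400)  # 4 sentences x 100 reps
  expect_equal(unname(table(out$corpus_a$split)["train"]), 1155)
  out2 <- synth_corpora(config = cfg)
  expect_identical(out$corpus_a$recordings[["A_Us_001"]]$emg,
                   out2$corpus_a$recordings[["A_Us_001"]]$emg)
  expect_error(synth_corpora(c("Alpha", "NOISE"), list("Alpha", "Bravo"),
                             tiny_synth()),
               "out-of-vocabulary")
})

test_that("more noise never increases average template-instance similarity", {
  sims <- vapply(c(0.1, 0.5, 1.5), function(sd) {
    cfg <- tiny_synth(noise_sd = sd, time_warp = 0, amp_jitter = 0)
    bank <- make_word_bank(c("Alpha", "Bravo"), cfg)
    mean(vapply(1:20, function(s) {
      rec <- synth_word_recording(bank, "Alpha", cfg, rep_seed = s)
      1 - cos_dist(rec$emg, bank$templates$emg$Alpha)
    }, 0))
  }, 0)
  expect_true(all(diff(sims) <= 0))
})
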