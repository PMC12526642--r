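test_that("window enumeration matches the closed form and brute force", {
  expect_equal(slide(700, window_spec(700, 380))$start, 0)
  win <- slide(2500, window_spec(700, 380))
  expect_equal(win$start, c(0, 380, 760, 1140, 1520))
  expect_equal(win$end - win$start, rep(700, 5))
  expect_error(slide(699, window_spec(700, 380)), "shorter")
  expect_error(window_spec(700, 0), "stride")
  expect_error(window_spec(700, 701), "stride")
  set.seed(2)
  for (i in 1:25) {
    W <- sample(5:60, 1)
    S <- sample.int(W, 1)
    L <- W + sample.int(10 * S, 1)
    starts <- slide(L, window_spec(W, S))$start
    brute <- Filter(function(s) s + W <= L, seq(0, L, by = S))
    expect_equal(starts, brute)
    expect_equal(length(starts), floor((L - W) / S) + 1)
  }
})

test_that("positional labels follow majority overlap with noise fallback", {
  sentence <- recording("s1", "sentence", "Alpha Bravo",
                        emg = rnorm(2000), pad = 0L)
  spec <- window_spec(700, 380)
  win <- assign_window_labels(sentence, spec)
  # speech span [0, 2000), word intervals [0, 1000) and [1000, 2000)
  expect_identical(win$label[win$start == 0], "Alpha")     # full overlap
  expect_identical(win$label[win$start == 760], "Bravo")   # 240 vs 460
  # a window wholly inside leading pad is NOISE
  padded <- recording("s2", "sentence", "Alpha Bravo",
                      emg = rnorm(2800), pad = 800L)
  win2 <- assign_window_labels(padded, spec)
  expect_identical(win2$label[win2$start == 0], "NOISE")
  # labels are total and monotone in word index
  for (w in list(win, win2)) {
    expect_false(any(is.na(w$label)))
    idx <- match(w$label, c("Alpha", "Bravo"))
    expect_true(all(diff(idx[!is.na(idx)]) >= 0))
  }
  expect_error(assign_window_labels(
    recording("w", "word", "Alpha", emg = rnorm(800)), spec),
    "not a sentence")
})

test_that("ties in overlap go to the earlier word", {
  # window [650, 1350) overlaps both word intervals by exactly 350
  sentence <- recording("s1", "sentence", "Alpha Bravo",
                        emg = rnorm(2000), pad = 0L)
  win <- assign_window_labels(sentence, window_spec(700, 650))
  expect_identical(win$label[win$start == 650], "Alpha")
})

test_that("collapse_repeats removes adjacent duplicate runs only", {
  expect_identical(collapse_repeats(c("Pick", "Us", "Us", "Up")),
                   c("Pick", "Us", "Up"))
  expect_identical(collapse_repeats(c("Land", "Here")), c("Land", "Here"))
  expect_identical(collapse_repeats(c("Do", "Do", "Not", "Not", "Land",
                                      "Here", "Here")),
                   c("Do", "Not", "Land", "Here"))
  expect_identical(collapse_repeats(character(0)), character(0))
  expect_identical(collapse_repeats(c("Up", "Us", "Up")),
                   c("Up", "Us", "Up"))   # non-adjacent repeats survive
})

test_that("retraining guards the reference-set contract", {
  w <- tiny_world()
  cfg <- tiny_encoder(epochs = 2L)
  model <- pretrain(w$corpus_a, w$refs, cfg, modality = "emg")
  # zero epochs: unchanged model
  m0 <- retrain(model, w$corpus_b, w$refs, tiny_spec(),
                config = list(epochs = 0L))
  probe <- rnorm(100)
  expect_identical(encode(m0, probe), encode(model, probe))
  # mutated reference set is rejected
  refs_mut <- w$refs
  refs_mut$recordings$Alpha[[1]]$emg[1] <-
    refs_mut$recordings$Alpha[[1]]$emg[1] + 1
  refs_mut$digest <- silentspeech:::signal_digest(
    unlist(lapply(refs_mut$recordings, function(rs)
      lapply(rs, function(r) c(r$emg, r$eeg))), recursive = FALSE))
  expect_error(retrain(model, w$corpus_b, refs_mut, tiny_spec()),
               "modified")
  # untrained model cannot be retrained
  expect_error(retrain(snn_model(cfg, "emg"), w$corpus_b, w$refs,
                       tiny_spec()), "pretrained")
})

test_that("a sentence tiled from one word decodes to that word everywhere", {
  vocab <- c("Alpha", "Bravo")
  synth <- synth_config(n_word_reps = 10L, n_sentence_reps = 1L,
                        word_duration = 120L, noise_sd = 0.15,
                        amp_jitter = 0.05, time_warp = 0, crossfade = 0L,
                        pad_noise = 0L, seed = 5L)
  corp <- synth_corpora(vocab, list(c("Alpha", "Bravo")), synth)
  refs <- build_reference_set(corp$corpus_a)
  model <- pretrain(corp$corpus_a, refs, tiny_encoder(seed = 5L, epochs = 6L),
                    modality = "emg")
  tiled <- synth_sentence_recording(corp$bank, rep("Alpha", 4), synth, 99L)
  dec <- infer_word_sequence(model, tiled, refs, tiny_spec())
  expect_length(dec$rankings, nrow(slide(480, tiny_spec())))
  expect_true(all(dec$raw_words == "Alpha"))
  expect_identical(collapse_repeats(dec$raw_words), "Alpha")
})
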