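test_that("cosine distance hits its identity, orthogonal and antipodal limits", {
  e1 <- c(1, 0, 0)
  e2 <- c(0, 1, 0)
  expect_equal(cosine_distance(e1, e1), 0)
  expect_equal(cosine_distance(e1, e2), 1)
  expect_equal(cosine_distance(e1, -e1), 2)
  expect_error(cosine_distance(c(0, 0, 0), e1), "zero")
  expect_error(cosine_distance(e1, c(1, 0)), "lengths")
})

test_that("contrastive loss matches its closed form and limits", {
  expect_equal(contrastive_loss(0, 1), 0)
  expect_equal(contrastive_loss(1.2, 0, m = 1), 0)
  expect_equal(contrastive_loss(0, 0, m = 0.5), 0.25)
  expect_error(contrastive_loss(0.5, 2), "0 or 1")
  expect_error(contrastive_loss(0.5, 1, m = 0), "margin")
  d <- runif(50, 0, 2)
  y <- rbinom(50, 1, 0.5)
  l <- contrastive_loss(d, y, m = 0.8)
  expect_true(all(l >= 0))
  expect_equal(l, y * d^2 + (1 - y) * pmax(0, 0.8 - d)^2)
})

test_that("encoding is deterministic, unit-norm and length-checked", {
  model <- snn_model(tiny_encoder(), "emg")
  x <- rnorm(100)
  e1 <- encode(model, x)
  e2 <- encode(model, x)
  expect_identical(e1, e2)
  expect_equal(sqrt(sum(e1^2)), 1, tolerance = 1e-6)
  expect_length(e1, 16)
  expect_error(encode(model, rnorm(99)), "input_length")
})

test_that("both Siamese twins are the same function", {
  model <- snn_model(tiny_encoder(), "emg")
  x <- rnorm(100)
  pair <- encode_pair(model, x, x)
  expect_identical(pair$left, pair$right)
  expect_equal(pair$distance, 0)
})

test_that("reference sets hold shots_per_class medoid-like recordings per class", {
  w <- tiny_world()
  refs <- w$refs
  expect_length(refs$ids, 5 * length(tiny_vocab))
  for (cl in tiny_vocab)
    expect_length(refs$recordings[[cl]], 5)
  # never an augmented recording
  all_parents <- unlist(lapply(refs$recordings, function(rs)
    vapply(rs, `[[`, "", "parent_id")))
  expect_true(all(is.na(all_parents)))
  # deterministic
  expect_identical(build_reference_set(w$corpus_a)$ids, refs$ids)
})

test_that("reference selection errors when a class lacks experimental shots", {
  w <- tiny_world()
  # drop all experimental Charlie train recordings to starve the class
  keep <- vapply(w$corpus_a$recordings, function(r)
    !(r$label == "Charlie" && is.na(r$parent_id) &&
        w$corpus_a$split[r$id] == "train"), TRUE)
  crippled <- corpus(w$corpus_a$recordings[keep], tiny_vocab,
                     w$corpus_a$split[keep])
  expect_error(build_reference_set(crippled), "Charlie")
})

test_that("classify_segment agrees with a brute-force average-distance oracle", {
  w <- tiny_world()
  model <- snn_model(tiny_encoder(), "emg")
  refs <- embed_references(model, w$refs)
  seg <- w$corpus_a$recordings[[1]]
  rk <- classify_segment(model, fit_to <- list(
    emg = silentspeech:::fit_length(seg$emg, 100)), refs)
  emb <- encode(model, fit_to)
  brute <- vapply(tiny_vocab, function(cl) {
    mean(vapply(w$refs$recordings[[cl]], function(r) {
      cosine_distance(emb, encode(model, list(
        emg = silentspeech:::fit_length(r$emg, 100))))
    }, 0))
  }, 0)
  expect_equal(rk$avg_distance, unname(sort(brute)), tolerance = 1e-10)
  expect_identical(rk$class[1], names(which.min(brute)))
  expect_equal(sum(rk$confidence), 1, tolerance = 1e-9)
})

test_that("equal average distances break ties by vocabulary order", {
  refs <- list(classes = c("Bravo", "Alpha"), shots_per_class = 1L,
               recordings = list(Bravo = list(1), Alpha = list(1)))
  refs$class_means <- rbind(Bravo = c(1, 0), Alpha = c(1, 0))
  rk <- silentspeech:::ranking_from_embedding(c(1, 0), refs, tau = 0.1)
  expect_identical(rk$class, c("Bravo", "Alpha"))  # listed vocabulary order
  expect_equal(rk$avg_distance[1], rk$avg_distance[2])
})

test_that("pretraining separates two synthetic classes and logs falling loss", {
  vocab <- c("Alpha", "Bravo")
  synth <- synth_config(n_word_reps = 10L, n_sentence_reps = 1L,
                        word_duration = 120L, noise_sd = 0.3,
                        amp_jitter = 0.1, time_warp = 0.05, crossfade = 20L,
                        pad_noise = 30L, seed = 7L)
  corp <- synth_corpora(vocab, list(c("Alpha", "Bravo")), synth)
  refs <- build_reference_set(corp$corpus_a)
  cfg <- tiny_encoder(seed = 7L, epochs = 8L)
  model <- pretrain(corp$corpus_a, refs, cfg, modality = "emg")
  log <- model$log
  expect_equal(nrow(log), 8)
  expect_lte(log$loss[8], log$loss[1])
  expect_equal(evaluate_words(model, corp$corpus_a, refs, split = "train"), 100)
  # serialization round-trip reproduces embeddings exactly
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  probe <- rnorm(100)
  expect_identical(encode(model, probe), encode(back, probe))
})

test_that("a new class added to the reference set is recognized without retraining", {
  vocab4 <- c("Alpha", "Bravo", "Charlie", "Delta")
  synth <- tiny_synth(noise_sd = 0.1)
  corp <- synth_corpora(vocab4, list(c("Alpha", "Bravo")), synth)
  sub_vocab <- c("Alpha", "Bravo", "Charlie")
  keep <- vapply(corp$corpus_a$recordings, function(r)
    r$label %in% sub_vocab, TRUE)
  corp3 <- corpus(corp$corpus_a$recordings[keep], sub_vocab,
                  corp$corpus_a$split[keep])
  refs <- build_reference_set(corp3)
  model <- pretrain(corp3, refs, tiny_encoder(epochs = 4L), modality = "emg")
  # store Delta references only; no retraining
  delta_ids <- names(which(vapply(corp$corpus_a$recordings, function(r)
    r$label == "Delta", TRUE)))[1:5]
  refs4 <- add_reference_class(refs, "Delta",
                               corp$corpus_a$recordings[delta_ids])
  refs4 <- embed_references(model, refs4)
  hits <- vapply(6:25, function(i) {
    rec <- synth_word_recording(corp$bank, "Delta", synth, rep_seed = 1000L + i)
    rk <- classify_segment(model, list(
      emg = silentspeech:::fit_length(rec$emg, 100)), refs4)
    rk$class[1] == "Delta"
  }, TRUE)
  expect_gt(mean(hits), 1 / 4)   # well above 4-class chance
})
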