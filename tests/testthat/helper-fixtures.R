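# Small, fast fixtures used across the unit tests. Everything is generated
# in code under fixed seeds; nothing is read from disk.

tiny_synth <- function(seed = 42L, ...) {
  args <- list(n_word_reps = 8L, n_sentence_reps = 6L, word_duration = 120L,
               noise_sd = 0.2, amp_jitter = 0.1, time_warp = 0.05,
               crossfade = 20L, pad_noise = 40L, seed = seed)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

tiny_encoder <- function(seed = 42L, ...) {
  args <- list(input_length = 100L, kernel_size = 7L, padding = 3L,
               n_conv_blocks = 2L, channels = c(4L, 8L), n_pool_bins = 4L,
               embedding_dim = 16L, epochs = 3L, lr = 5e-3,
               batch_size = 32L, pairs_per_epoch = 128L,
               decimation = c(emg = 1L, eeg = 2L), seed = seed)
  do.call(encoder_config, utils::modifyList(args, list(...)))
}

tiny_spec <- function() window_spec(width = 100L, stride = 60L)

tiny_vocab <- c("Alpha", "Bravo", "Charlie", "NOISE")
tiny_sentences <- list(c("Alpha", "Bravo"), c("Bravo", "Charlie"))

# full tiny pipeline state: corpora, augmented train split, reference set
tiny_world <- function(seed = 42L, vocab = tiny_vocab,
                       sentences = tiny_sentences, synth = tiny_synth(seed)) {
  corp <- synth_corpora(vocab, sentences, synth)
  plan <- augment_plan(per_recording_count = 2L, seed = seed)
  corpus_a <- augment_corpus(corp$corpus_a, plan)
  refs <- build_reference_set(corpus_a)
  list(synth = synth, bank = corp$bank, corpus_a = corpus_a,
       corpus_b = corp$corpus_b, refs = refs, plan = plan)
}

# a candidate_ranking fixture; confidences given as a named vector in rank
# order (top-1 first)
mk_ranking <- function(conf, window_index = NA_integer_) {
  out <- data.frame(class = names(conf),
                    avg_distance = seq(0.1, by = 0.15,
                                       length.out = length(conf)),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  attr(out, "window_index") <- window_index
  class(out) <- c("candidate_ranking", class(out))
  out
}

# independent count-and-multiply trigram oracle (plain loops, no shared code
# with the implementation)
oracle_logprob <- function(train_sentences, words, k = 0) {
  vocab <- unique(unlist(train_sentences))
  V1 <- length(vocab) + 1
  pad <- function(s) c("<s>", "<s>", s, "</s>")
  seqs <- lapply(train_sentences, pad)
  cnt3 <- function(a, b, d) {
    tot <- 0
    for (s in seqs) {
      n <- length(s)
      for (i in seq_len(n - 2))
        if (s[i] == a && s[i + 1] == b && s[i + 2] == d) tot <- tot + 1
    }
    tot
  }
  cnt_hist <- function(a, b) {
    tot <- 0
    for (s in seqs) {
      n <- length(s)
      for (i in seq_len(n - 2))
        if (s[i] == a && s[i + 1] == b) tot <- tot + 1
    }
    tot
  }
  p <- pad(words)
  lp <- 0
  for (i in 3:length(p)) {
    num <- cnt3(p[i - 2], p[i - 1], p[i]) + k
    den <- cnt_hist(p[i - 2], p[i - 1]) + k * V1
    lp <- lp + if (num > 0 && den > 0) log(num / den) else -Inf
  }
  lp
}
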