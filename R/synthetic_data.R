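#' Synthetic corpus generator configuration
#'
#' Controls the seeded generator that emulates the shapes of the two study
#' corpora: an isolated-word corpus (150 repetitions of each of 10 words plus
#' a noise class) and a continuous-sentence corpus (100 repetitions of each of
#' 4 command phrases). Word classes are fixed band-limited template waveforms;
#' instances vary by amplitude jitter, time warping and additive noise, and
#' sentences blend consecutive words with a linear crossfade so that naive
#' concatenation of isolated words does not reproduce the sentence signal
#' (the coarticulation effect).
#'
#' @param n_word_reps repetitions per word class (default 150).
#' @param n_sentence_reps repetitions per sentence (default 100).
#' @param word_duration word template length in samples (default 800,
#'   about 0.2 s at 4096 Hz).
#' @param noise_sd additive Gaussian noise SD, relative to the unit-RMS
#'   templates. Scalar, or length-2 `c(emg, eeg)` for per-modality SNR.
#' @param amp_jitter amplitude jitter fraction; each instance is scaled by
#'   `1 + U(-amp_jitter, amp_jitter)`.
#' @param time_warp time warp fraction in `[0, 0.3]`; each instance is
#'   linearly resampled to `word_duration * (1 + U(-time_warp, time_warp))`.
#' @param crossfade coarticulation overlap between consecutive words in a
#'   sentence, in samples; must be smaller than `word_duration`.
#' @param pad_noise leading/trailing non-speech noise samples on sentences.
#' @param sampling_rate sampling rate in Hz.
#' @param seed master seed; the whole generator is deterministic given it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_word_reps = 150L, n_sentence_reps = 100L,
                         word_duration = 800L, noise_sd = 0.35,
                         amp_jitter = 0.15, time_warp = 0.1,
                         crossfade = 150L, pad_noise = 300L,
                         sampling_rate = 4096, seed = 1L) {
  if (n_word_reps <= 0L || n_sentence_reps <= 0L || word_duration <= 0L)
    abort_validation("all counts must be > 0")
  if (crossfade >= word_duration)
    abort_validation("crossfade must be smaller than word_duration")
  if (time_warp < 0 || time_warp > 0.3)
    abort_validation("time_warp must lie in [0, 0.3]")
  if (length(noise_sd) == 1L) noise_sd <- c(emg = noise_sd, eeg = noise_sd)
  else names(noise_sd) <- c("emg", "eeg")
  structure(list(n_word_reps = as.integer(n_word_reps),
                 n_sentence_reps = as.integer(n_sentence_reps),
                 word_duration = as.integer(word_duration),
                 noise_sd = noise_sd, amp_jitter = amp_jitter,
                 time_warp = time_warp, crossfade = as.integer(crossfade),
                 pad_noise = as.integer(pad_noise),
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# modality-specific frequency bands (Hz): EMG-like 20-450, EEG-like 1-40
synth_bands <- list(emg = c(20, 450), eeg = c(1, 40))

# one band-limited random template: a sum of random-phase sinusoids,
# normalized to unit RMS
make_template <- function(n, band, sampling_rate, n_components = 12L) {
  t <- (seq_len(n) - 1L) / sampling_rate
  freqs <- stats::runif(n_components, band[1L], band[2L])
  phases <- stats::runif(n_components, 0, 2 * pi)
  amps <- stats::runif(n_components, 0.3, 1)
  x <- numeric(n)
  for (i in seq_len(n_components))
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  x / sqrt(mean(x^2))
}

#' Build the per-class template bank
#'
#' One fixed template waveform per vocabulary word per modality. The
#' `"NOISE"` class, if present, receives no template (noise instances are
#' drawn directly). Identical seeds produce bit-identical banks.
#'
#' @param vocabulary nonempty character vector of class names.
#' @param config a [synth_config()].
#' @return a `word_bank` with `templates$emg` / `templates$eeg` (named lists
#'   of numeric vectors), `word_duration` and `seed`.
#' @export
make_word_bank <- function(vocabulary, config = synth_config()) {
  if (length(vocabulary) == 0L)
    abort_validation("vocabulary must be nonempty")
  if (anyDuplicated(vocabulary))
    abort_validation("duplicate class names in vocabulary: ",
                     paste(unique(vocabulary[duplicated(vocabulary)]), collapse = ", "))
  words <- setdiff(vocabulary, "NOISE")
  templates <- with_seed(config$seed, {
    lapply(stats::setNames(nm = c("emg", "eeg")), function(mod) {
      stats::setNames(lapply(words, function(w) {
        make_template(config$word_duration, synth_bands[[mod]],
                      config$sampling_rate)
      }), words)
    })
  })
  structure(list(templates = templates, vocabulary = vocabulary,
                 word_duration = config$word_duration, seed = config$seed),
            class = "word_bank")
}

# draw one jittered/warped/noisy instance of a word, both modalities;
# returns list(emg=, eeg=) of equal length
synth_word_instance <- function(bank, word, config) {
  warp <- if (config$time_warp > 0)
    stats::runif(1, -config$time_warp, config$time_warp) else 0
  n_out <- max(2L, as.integer(round(config$word_duration * (1 + warp))))
  gain <- 1 + if (config$amp_jitter > 0)
    stats::runif(1, -config$amp_jitter, config$amp_jitter) else 0
  out <- list()
  for (mod in c("emg", "eeg")) {
    if (word == "NOISE") {
      out[[mod]] <- stats::rnorm(n_out, 0, config$noise_sd[[mod]])
    } else {
      tpl <- bank$templates[[mod]][[word]]
      x <- if (n_out == length(tpl)) tpl else
        stats::approx(seq_along(tpl), tpl, n = n_out)$y
      noise <- if (config$noise_sd[[mod]] > 0)
        stats::rnorm(n_out, 0, config$noise_sd[[mod]]) else 0
      out[[mod]] <- gain * x + noise
    }
  }
  out
}

#' Synthesize one isolated-word recording
#'
#' An instance of the class template with amplitude jitter, time warping and
#' additive Gaussian noise, in both modalities. `"NOISE"` yields a pure noise
#' trace. With all variability parameters at zero the instance equals the
#' template exactly.
#'
#' @param bank a [make_word_bank()] bank.
#' @param word class name present in the bank's vocabulary.
#' @param config a [synth_config()].
#' @param rep_seed per-repetition seed.
#' @param id recording id.
#' @return an `ssr_recording` of kind `"word"` (or `"noise"`).
#' @export
synth_word_recording <- function(bank, word, config = synth_config(),
                                 rep_seed = 1L, id = NULL) {
  if (!word %in% bank$vocabulary)
    abort_validation("unknown word: ", word)
  inst <- with_seed(rep_seed, synth_word_instance(bank, word, config))
  recording(id = id %||% sprintf("%s_r%d", word, rep_seed),
            kind = if (word == "NOISE") "noise" else "word",
            label = word, emg = inst$emg, eeg = inst$eeg,
            sampling_rate = config$sampling_rate)
}

#' Synthesize one continuous-sentence recording
#'
#' Word instances are drawn as in [synth_word_recording()] and joined by
#' overlap-add with a linear crossfade of `config$crossfade` samples at each
#' boundary, then padded with `config$pad_noise` samples of pure noise on
#' both sides. The blended boundary regions reproduce the key property of
#' coarticulated speech signals: concatenating isolated word signals does not
#' reconstruct the sentence. Total length is
#' `2 * pad_noise + sum(instance lengths) - crossfade * (n_words - 1)`.
#'
#' @param bank a [make_word_bank()] bank.
#' @param words character vector of words, all present in the bank.
#' @param config a [synth_config()].
#' @param rep_seed per-repetition seed.
#' @param id recording id.
#' @return an `ssr_recording` of kind `"sentence"`, with `pad` recorded.
#' @export
synth_sentence_recording <- function(bank, words, config = synth_config(),
                                     rep_seed = 1L, id = NULL) {
  if (length(words) == 0L)
    abort_validation("sentence word list must be nonempty")
  missing <- setdiff(words, bank$vocabulary)
  if (length(missing))
    abort_validation("words not in bank vocabulary: ",
                     paste(missing, collapse = ", "))
  out <- with_seed(rep_seed, {
    insts <- lapply(words, function(w) synth_word_instance(bank, w, config))
    cf <- config$crossfade
    res <- list()
    for (mod in c("emg", "eeg")) {
      sig <- insts[[1L]][[mod]]
      if (length(insts) > 1L) for (i in 2L:length(insts)) {
        nxt <- insts[[i]][[mod]]
        if (cf > 0L) {
          n0 <- length(sig)
          ramp <- seq(0, 1, length.out = cf + 2L)[2L:(cf + 1L)]
          tail_idx <- (n0 - cf + 1L):n0
          blended <- sig[tail_idx] * (1 - ramp) + nxt[1L:cf] * ramp
          sig <- c(sig[seq_len(n0 - cf)], blended, nxt[(cf + 1L):length(nxt)])
        } else {
          sig <- c(sig, nxt)
        }
      }
      if (config$pad_noise > 0L) {
        sd_mod <- config$noise_sd[[mod]]
        pad <- stats::rnorm(config$pad_noise * 2L, 0, sd_mod)
        sig <- c(pad[seq_len(config$pad_noise)], sig,
                 pad[config$pad_noise + seq_len(config$pad_noise)])
      }
      res[[mod]] <- sig
    }
    res
  })
  recording(id = id %||% sprintf("s_%s_r%d", paste(words, collapse = "-"), rep_seed),
            kind = "sentence", label = paste(words, collapse = " "),
            emg = out$emg, eeg = out$eeg,
            sampling_rate = config$sampling_rate, pad = config$pad_noise)
}

#' Synthesize paired word and sentence corpora
#'
#' Generates the full test bed: an isolated-word corpus with `n_word_reps`
#' instances per vocabulary class (including the `"NOISE"` class) and a
#' sentence corpus with `n_sentence_reps` instances per sentence. A
#' stratified 70/30 train/test split is assigned per class and per sentence.
#' Everything is deterministic given `config$seed`.
#'
#' @param vocabulary class names (word classes plus optionally `"NOISE"`).
#' @param sentences list of word-sequence character vectors.
#' @param config a [synth_config()].
#' @param train_fraction train share of the split (default 0.7).
#' @return list with elements `corpus_a` (words) and `corpus_b` (sentences),
#'   both `ssr_corpus`, plus the `bank`.
#' @export
synth_corpora <- function(vocabulary = default_vocabulary(),
                          sentences = default_sentences(),
                          config = synth_config(), train_fraction = 0.7) {
  for (s in sentences) {
    bad <- setdiff(s, vocabulary)
    if (length(bad))
      abort_validation("sentence uses out-of-vocabulary word(s): ",
                       paste(bad, collapse = ", "))
  }
  bank <- make_word_bank(vocabulary, config)
  seeds <- seed_stream(config$seed,
                       length(vocabulary) * config$n_word_reps +
                         length(sentences) * config$n_sentence_reps + 2L)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  recs_a <- list()
  split_a <- character(0)
  for (w in vocabulary) {
    n_train <- round(config$n_word_reps * train_fraction)
    for (r in seq_len(config$n_word_reps)) {
      id <- sprintf("A_%s_%03d", w, r)
      recs_a[[id]] <- synth_word_recording(bank, w, config, next_seed(), id = id)
      split_a[id] <- if (r <= n_train) "train" else "test"
    }
  }
  corpus_a <- corpus(recs_a, vocabulary, split_a)

  recs_b <- list()
  split_b <- character(0)
  for (k in seq_along(sentences)) {
    n_train <- round(config$n_sentence_reps * train_fraction)
    for (r in seq_len(config$n_sentence_reps)) {
      id <- sprintf("B_s%d_%03d", k, r)
      recs_b[[id]] <- synth_sentence_recording(bank, sentences[[k]], config,
                                               next_seed(), id = id)
      split_b[id] <- if (r <= n_train) "train" else "test"
    }
  }
  corpus_b <- corpus(recs_b, vocabulary, split_b)

  list(corpus_a = corpus_a, corpus_b = corpus_b, bank = bank)
}
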