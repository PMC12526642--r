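#' Moving-window specification
#'
#' Fixed-width, fixed-stride windows slid across a continuous sentence
#' signal. The defaults (width 700 samples, stride 380 samples) overlap so
#' transitional information between words is preserved.
#'
#' @param width window width W in samples (> 0).
#' @param stride stride S in samples, `0 < S <= W`.
#' @return a `window_spec` list.
#' @export
window_spec <- function(width = 700L, stride = 380L) {
  width <- as.integer(width); stride <- as.integer(stride)
  if (width <= 0L) abort_validation("window width must be > 0")
  if (stride <= 0L || stride > width)
    abort_validation("stride must satisfy 0 < stride <= width")
  structure(list(width = width, stride = stride), class = "window_spec")
}

#' Enumerate moving windows over a recording
#'
#' Windows start at `0, S, 2S, ...` while `start + W <= length`; trailing
#' samples shorter than one window are discarded. Coordinates are 0-based
#' half-open.
#'
#' @param recording_length signal length in samples, at least `spec$width`.
#' @param spec a [window_spec()].
#' @return data frame with columns `start`, `end` (one row per window).
#' @export
slide <- function(recording_length, spec = window_spec()) {
  if (recording_length < spec$width)
    abort_validation("recording length ", recording_length,
                     " is shorter than the window width ", spec$width)
  starts <- seq.int(0L, recording_length - spec$width, by = spec$stride)
  data.frame(start = starts, end = starts + spec$width)
}

#' Assign positional ground-truth labels to sentence windows
#'
#' Under the assumption of evenly spaced words, the speech span of the
#' sentence (its full extent minus the leading/trailing pad regions) is
#' divided into one equal interval per word. Each window is labeled with the
#' word whose interval overlaps it the most (ties to the earlier word); a
#' window overlapping no word interval by at least
#' `min_overlap_fraction * width` is labeled `"NOISE"`.
#'
#' @param sentence an `ssr_recording` of kind `"sentence"`.
#' @param spec a [window_spec()].
#' @param pad leading/trailing non-speech samples excluded from the speech
#'   span; defaults to the recording's own `pad` field.
#' @param min_overlap_fraction minimum word overlap as a fraction of the
#'   window width (default 0.5).
#' @return data frame with columns `start`, `end`, `label`.
#' @export
assign_window_labels <- function(sentence, spec = window_spec(),
                                 pad = NULL, min_overlap_fraction = 0.5) {
  if (sentence$kind != "sentence")
    abort_validation("recording '", sentence$id, "' is not a sentence")
  words <- label_words(sentence$label)
  n <- length(words)
  if (n == 0L) abort_validation("sentence has no words")
  pad <- pad %||% sentence$pad %||% 0L
  L <- rec_length(sentence)
  win <- slide(L, spec)
  span0 <- pad
  span1 <- L - pad
  bounds <- span0 + (span1 - span0) * (0:n) / n
  lab <- character(nrow(win))
  for (i in seq_len(nrow(win))) {
    ov <- pmax(0, pmin(win$end[i], bounds[-1L]) - pmax(win$start[i], bounds[-(n + 1L)]))
    j <- which.max(ov)   # ties resolve to the earlier word
    lab[i] <- if (ov[j] >= min_overlap_fraction * spec$width) words[j] else "NOISE"
  }
  win$label <- lab
  win
}

#' Retrain a pretrained model on sentence windows
#'
#' Contrastive fine-tuning on (window crop, reference) pairs cut from the
#' train split of the sentence corpus (experimental and augmented), with
#' match labels derived from [assign_window_labels()]. The reference set
#' must be the unchanged set used at pretraining; mutation is a validation
#' error. Reference embeddings are recomputed with the updated encoder.
#'
#' @param model a pretrained `ssr_model`.
#' @param corpus_b sentence `ssr_corpus`.
#' @param refs the pretraining reference set.
#' @param spec a [window_spec()].
#' @param config optional overrides of the training hyperparameters
#'   (a named list, e.g. `list(epochs = 8, lr = 1e-3)`).
#' @return the retrained `ssr_model`. With `epochs = 0` the model is
#'   returned unchanged.
#' @export
retrain <- function(model, corpus_b, refs, spec = window_spec(),
                    config = list()) {
  if (is.null(model$refs_digest))
    abort_validation("model must be pretrained before retraining")
  if (!identical(model$refs_digest, refs$digest))
    abort_validation("reference set was modified between pretraining and retraining")
  cfg <- model$config
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (cfg$epochs <= 0L) return(model)
  train_ids <- corpus_ids(corpus_b, split = "train", kind = "sentence")
  if (length(train_ids) == 0L)
    abort_validation("empty retraining set")
  signals <- list(); labels <- character(0)
  for (id in train_ids) {
    rec <- corpus_b$recordings[[id]]
    win <- assign_window_labels(rec, spec)
    for (i in seq_len(nrow(win))) {
      seg <- list()
      for (m in model$modalities)
        seg[[m]] <- fit_length(rec_samples(rec, m)[(win$start[i] + 1L):win$end[i]],
                               cfg$input_length)
      signals[[length(signals) + 1L]] <- seg
      labels <- c(labels, win$label[i])
    }
  }
  anchors <- list(signals = signals, labels = labels)
  train_contrastive(model, anchors, refs, cfg, "retrain")
}

#' Decode the raw word sequence of a sentence signal
#'
#' Slides the moving window across the sentence, classifies every window
#' against the reference set, and returns the per-window candidate rankings
#' together with the raw word sequence: the top-1 class of each window in
#' window order, with `"NOISE"` predictions dropped (adjacent repeats are
#' not yet collapsed; see [collapse_repeats()]).
#'
#' @param model a trained `ssr_model`.
#' @param sentence an `ssr_recording` at least one window long.
#' @param refs the reference set.
#' @param spec a [window_spec()].
#' @return list with `rankings` (list of `candidate_ranking`, one per
#'   window) and `raw_words` (character vector).
#' @export
infer_word_sequence <- function(model, sentence, refs, spec = window_spec()) {
  refs <- ensure_embedded(model, refs)
  win <- slide(rec_length(sentence), spec)
  signals <- lapply(seq_len(nrow(win)), function(i) {
    seg <- list()
    for (m in model$modalities)
      seg[[m]] <- fit_length(rec_samples(sentence, m)[(win$start[i] + 1L):win$end[i]],
                             model$config$input_length)
    seg
  })
  emb <- embed_batch(model, signals)
  rankings <- lapply(seq_len(nrow(win)), function(i)
    ranking_from_embedding(emb[i, ], refs, model$config$tau, window_index = i))
  top1 <- vapply(rankings, function(r) r$class[1L], "")
  list(rankings = rankings, raw_words = top1[top1 != "NOISE"])
}

#' Collapse adjacent repeated words
#'
#' Runs of the same word are reduced to a single occurrence, preserving
#' order (e.g. `c("Pick", "Us", "Us", "Up")` becomes
#' `c("Pick", "Us", "Up")`).
#'
#' @param words character vector.
#' @return character vector without adjacent duplicates.
#' @export
collapse_repeats <- function(words) {
  if (length(words) <= 1L) return(words)
  words[c(TRUE, words[-1L] != words[-length(words)])]
}

#' Dump per-window decode results as TSV
#'
#' Audit output: one row per window with its top-1 class, average cosine
#' distance and confidence.
#'
#' @param rankings list of `candidate_ranking` as from
#'   [infer_word_sequence()].
#' @param spec the [window_spec()] used.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_decode_dump <- function(rankings, spec, path) {
  rows <- do.call(rbind, lapply(seq_along(rankings), function(i) {
    r <- rankings[[i]]
    data.frame(window_index = i, start = (i - 1L) * spec$stride,
               end = (i - 1L) * spec$stride + spec$width,
               top1 = r$class[1L], avg_distance = r$avg_distance[1L],
               confidence = r$confidence[1L])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
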