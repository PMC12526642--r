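BOS <- "<s>"
EOS <- "</s>"

ng_key <- function(...) paste(..., sep = "\t")

#' Fit a smoothed trigram language model
#'
#' Counts all 1/2/3-grams over the training sentences with doubled
#' start-of-sentence tokens and an end-of-sentence token, and applies add-k
#' smoothing at query time:
#' `P(w | h) = (c(h, w) + k) / (c(h) + k * (V + 1))`,
#' where the predicted event ranges over the vocabulary plus the
#' end-of-sentence token.
#'
#' @param training_sentences nonempty list of word-sequence character
#'   vectors (or space-joined strings).
#' @param k_smooth add-k constant (default 0.01). `k = 0` gives unsmoothed
#'   maximum-likelihood estimates.
#' @param vocabulary optional word vocabulary; defaults to the words of the
#'   training sentences.
#' @return a `trigram_model`.
#' @export
fit_trigram <- function(training_sentences, k_smooth = 0.01,
                        vocabulary = NULL) {
  if (length(training_sentences) == 0L)
    abort_validation("training corpus must be nonempty")
  sent <- lapply(training_sentences, function(s)
    if (length(s) == 1L && grepl(" ", s)) label_words(s) else as.character(s))
  vocab <- vocabulary %||% unique(unlist(sent))
  for (s in sent) {
    bad <- setdiff(s, vocab)
    if (length(bad))
      abort_validation("sentence word(s) outside vocabulary: ",
                       paste(bad, collapse = ", "))
    if (length(s) == 0L) abort_validation("empty sentence in training corpus")
  }
  c1 <- new.env(parent = emptyenv())
  c2 <- new.env(parent = emptyenv())
  c3 <- new.env(parent = emptyenv())
  hist2 <- new.env(parent = emptyenv())
  bump <- function(env, key, by = 1) {
    assign(key, (get0(key, envir = env) %||% 0) + by, envir = env)
  }
  for (s in sent) {
    padded <- c(BOS, BOS, s, EOS)
    n <- length(padded)
    for (i in seq_len(n)) bump(c1, padded[i])
    for (i in seq_len(n - 1L)) bump(c2, ng_key(padded[i], padded[i + 1L]))
    for (i in seq_len(n - 2L)) {
      bump(c3, ng_key(padded[i], padded[i + 1L], padded[i + 2L]))
      bump(hist2, ng_key(padded[i], padded[i + 1L]))
    }
  }
  structure(list(vocabulary = vocab, k_smooth = k_smooth,
                 c1 = as.list(c1), c2 = as.list(c2), c3 = as.list(c3),
                 hist2 = as.list(hist2)),
            class = "trigram_model")
}

#' @export
print.trigram_model <- function(x, ...) {
  cat(sprintf("<trigram_model> vocabulary of %d words, %d distinct trigrams, k = %g\n",
              length(x$vocabulary), length(x$c3), x$k_smooth))
  invisible(x)
}

#' Query raw n-gram counts
#'
#' @param model a `trigram_model`.
#' @param ... 1 to 3 word tokens (boundary tokens `"<s>"` / `"</s>"`
#'   allowed).
#' @return the raw count (0 for unseen n-grams).
#' @export
ngram_count <- function(model, ...) {
  toks <- c(...)
  tab <- switch(length(toks), model$c1, model$c2, model$c3)
  if (is.null(tab)) abort_validation("n-gram order must be 1, 2 or 3")
  (tab[[do.call(ng_key, as.list(toks))]]) %||% 0
}

# smoothed conditional P(w | h1, h2); w may be the end token
trigram_prob <- function(model, h1, h2, w) {
  k <- model$k_smooth
  V1 <- length(model$vocabulary) + 1L
  ch <- (model$hist2[[ng_key(h1, h2)]]) %||% 0
  cw <- (model$c3[[ng_key(h1, h2, w)]]) %||% 0
  denom <- ch + k * V1
  if (denom == 0) return(0)
  (cw + k) / denom
}

#' Trigram log-probability of a word sequence
#'
#' `sum(log P(w_i | w_{i-2}, w_{i-1}))` over the sentence padded with two
#' start tokens, including the final end-of-sentence transition. With
#' `k = 0` an unseen transition yields `-Inf`.
#'
#' @param model a `trigram_model`.
#' @param words character vector of in-vocabulary words.
#' @return log-probability (<= 0).
#' @export
ngram_logprob <- function(model, words) {
  bad <- setdiff(words, model$vocabulary)
  if (length(bad))
    abort_validation("out-of-vocabulary word(s): ", paste(bad, collapse = ", "))
  padded <- c(BOS, BOS, words, EOS)
  lp <- 0
  for (i in 3L:length(padded)) {
    p <- trigram_prob(model, padded[i - 2L], padded[i - 1L], padded[i])
    lp <- lp + if (p > 0) log(p) else -Inf
  }
  lp
}

# TRUE if the sequence contains a trigram transition that is both unseen
# (raw count 0) and improbable after smoothing
has_pruned_trigram <- function(model, words, prune_threshold) {
  padded <- c(BOS, BOS, words, EOS)
  for (i in 3L:length(padded)) {
    raw <- (model$c3[[ng_key(padded[i - 2L], padded[i - 1L], padded[i])]]) %||% 0
    if (raw == 0 &&
        trigram_prob(model, padded[i - 2L], padded[i - 1L], padded[i]) < prune_threshold)
      return(TRUE)
  }
  FALSE
}

#' Enumerate and filter sentence hypotheses from window rankings
#'
#' Expands all paths through the per-window top-`top_m` non-noise
#' candidates. Each path is collapsed ([collapse_repeats()]) into a word
#' sequence, scored with the trigram model and with the sum of its windows'
#' log-confidences, filtered (paths containing a trigram with raw count 0
#' and smoothed probability below `prune_threshold` are discarded),
#' deduplicated by word sequence (keeping the highest classifier
#' confidence), ranked by per-word-normalized LM log-probability and
#' truncated to the top `K`.
#'
#' @param rankings nonempty list of `candidate_ranking` data frames.
#' @param top_m candidates kept per window (>= 1).
#' @param K hypothesis cutoff (>= 1).
#' @param model a `trigram_model`.
#' @param prune_threshold smoothed-probability floor for unseen trigrams.
#' @return list of `sentence_hypothesis` objects (fields `words`,
#'   `lm_logprob`, `snn_logconf`), best-ranked first.
#' @export
enumerate_candidates <- function(rankings, top_m = 3L, K = 5L,
                                 model, prune_threshold = 0.02) {
  if (length(rankings) == 0L)
    abort_validation("rankings must be nonempty")
  if (top_m < 1L) abort_validation("top_m must be >= 1")
  if (K < 1L) abort_validation("K must be >= 1")
  per_win <- lapply(rankings, function(r) {
    r <- r[r$class != "NOISE", , drop = FALSE]
    utils::head(r, top_m)
  })
  counts <- vapply(per_win, nrow, 0L)
  if (any(counts == 0L)) return(list())
  if (prod(counts) > 2e5)
    abort_validation("candidate lattice too large (", prod(counts), " paths)")
  grid <- do.call(expand.grid, lapply(counts, seq_len))
  hyps <- list()
  for (p in seq_len(nrow(grid))) {
    path_words <- character(length(per_win))
    logconf <- 0
    for (w in seq_along(per_win)) {
      j <- grid[p, w]
      path_words[w] <- per_win[[w]]$class[j]
      logconf <- logconf + log(max(per_win[[w]]$confidence[j], 1e-300))
    }
    words <- collapse_repeats(path_words)
    if (length(words) == 0L) next
    if (has_pruned_trigram(model, words, prune_threshold)) next
    key <- paste(words, collapse = " ")
    if (is.null(hyps[[key]]) || logconf > hyps[[key]]$snn_logconf) {
      hyps[[key]] <- structure(
        list(words = words, lm_logprob = ngram_logprob(model, words),
             snn_logconf = logconf, combined = NA_real_),
        class = "sentence_hypothesis")
    }
  }
  if (length(hyps) == 0L) return(list())
  norm_lm <- vapply(hyps, function(h) h$lm_logprob / length(h$words), 0)
  ord <- order(-norm_lm, names(hyps))
  unname(hyps[ord][seq_len(min(K, length(hyps)))])
}

#' Combined confidence of a sentence hypothesis
#'
#' Length-normalized log-linear mixture of LM and classifier evidence:
#' `combined = (lambda * lm_logprob + (1 - lambda) * snn_logconf) / n_words`.
#'
#' @param hyp a `sentence_hypothesis` carrying `lm_logprob` and
#'   `snn_logconf`.
#' @param lambda mixture weight in `[0, 1]` (default 0.5).
#' @return the combined confidence (a log-scale score).
#' @export
combined_confidence <- function(hyp, lambda = 0.5) {
  if (lambda < 0 || lambda > 1)
    abort_validation("lambda must lie in [0, 1]")
  n <- length(hyp$words)
  if (n == 0L) abort_validation("hypothesis has no words")
  (lambda * hyp$lm_logprob + (1 - lambda) * hyp$snn_logconf) / n
}

#' Correct a decoded sentence with the trigram model
#'
#' Runs [enumerate_candidates()] on the window rankings and returns the
#' hypothesis with the highest [combined_confidence()], breaking ties by LM
#' log-probability and then lexicographically. If every candidate is
#' filtered out, the uncorrected sequence (top-1 per window, noise dropped,
#' repeats collapsed) is returned with attribute `fallback = TRUE`.
#'
#' @param rankings list of `candidate_ranking` data frames.
#' @param model a `trigram_model`.
#' @param K,top_m,prune_threshold as in [enumerate_candidates()].
#' @param lambda mixture weight of [combined_confidence()].
#' @return character word vector with attributes `fallback` (logical) and
#'   `hypotheses` (the scored candidates).
#' @export
correct_sentence <- function(rankings, model, K = 5L, top_m = 3L,
                             lambda = 0.5, prune_threshold = 0.02) {
  hyps <- enumerate_candidates(rankings, top_m = top_m, K = K, model = model,
                               prune_threshold = prune_threshold)
  if (length(hyps) == 0L) {
    top1 <- vapply(rankings, function(r) r$class[1L], "")
    out <- collapse_repeats(top1[top1 != "NOISE"])
    attr(out, "fallback") <- TRUE
    return(out)
  }
  comb <- vapply(hyps, combined_confidence, 0, lambda = lambda)
  lm <- vapply(hyps, `[[`, 0, "lm_logprob")
  keys <- vapply(hyps, function(h) paste(h$words, collapse = " "), "")
  best <- order(-comb, -lm, keys)[1L]
  for (i in seq_along(hyps)) hyps[[i]]$combined <- comb[i]
  out <- hyps[[best]]$words
  attr(out, "fallback") <- FALSE
  attr(out, "hypotheses") <- hyps
  out
}

#' Serialize / load a trigram model as a plain-text count table
#'
#' One line per n-gram: the tab-joined tokens, a tab, and the count. The
#' first lines carry the vocabulary and smoothing constant. Round-trips
#' exactly.
#'
#' @param model a `trigram_model`.
#' @param path file path.
#' @return `write_trigram` returns `path` invisibly; `read_trigram` the
#'   restored model.
#' @export
write_trigram <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#vocabulary\t", paste(model$vocabulary, collapse = "\t")), con)
  writeLines(paste0("#k_smooth\t", sprintf("%.17g", model$k_smooth)), con)
  for (tab in c("c1", "c2", "c3", "hist2")) {
    entries <- model[[tab]]
    for (key in sort(names(entries)))
      writeLines(paste0(tab, "\t", key, "\t",
                        sprintf("%.17g", entries[[key]])), con)
  }
  invisible(path)
}

#' @rdname write_trigram
#' @export
read_trigram <- function(path) {
  lines <- readLines(path)
  vocab <- strsplit(lines[1L], "\t")[[1L]][-1L]
  k <- as.numeric(strsplit(lines[2L], "\t")[[1L]][2L])
  tabs <- list(c1 = list(), c2 = list(), c3 = list(), hist2 = list())
  for (line in lines[-(1:2)]) {
    parts <- strsplit(line, "\t")[[1L]]
    tab <- parts[1L]
    count <- as.numeric(parts[length(parts)])
    key <- paste(parts[2L:(length(parts) - 1L)], collapse = "\t")
    tabs[[tab]][[key]] <- count
  }
  structure(list(vocabulary = vocab, k_smooth = k, c1 = tabs$c1,
                 c2 = tabs$c2, c3 = tabs$c3, hist2 = tabs$hist2),
            class = "trigram_model")
}
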