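#' Isolated-word test accuracy
#'
#' Fraction of test-split word recordings whose top-1 class equals the
#' label, in percent. Asserts that the test split is disjoint from the
#' reference set.
#'
#' @param model a trained `ssr_model`.
#' @param corpus_a isolated-word `ssr_corpus`.
#' @param refs the reference set.
#' @param split which split to evaluate (default `"test"`).
#' @return accuracy in percent.
#' @export
evaluate_words <- function(model, corpus_a, refs, split = "test") {
  ids <- corpus_ids(corpus_a, split = split)
  if (split == "test") ids <- setdiff(ids, refs$ids)
  if (length(ids) == 0L)
    abort_validation("empty ", split, " set")
  refs <- ensure_embedded(model, refs)
  recs <- corpus_a$recordings[ids]
  signals <- lapply(recs, segment_signals, modalities = model$modalities,
                    input_length = model$config$input_length)
  emb <- embed_batch(model, signals)
  pred <- refs$classes[max.col(emb %*% t(refs$class_means),
                               ties.method = "first")]
  truth <- vapply(recs, `[[`, "", "label")
  100 * mean(pred == truth)
}

# per-slot accuracy of a collapsed prediction against the label sequence:
# exact-position matches for equal lengths, otherwise LCS hits / n_slots
slot_accuracy_one <- function(pred, truth) {
  if (length(truth) == 0L) return(NA_real_)
  if (length(pred) == length(truth)) mean(pred == truth)
  else lcs_length(pred, truth) / length(truth)
}

#' Sentence-level test accuracies
#'
#' Decodes every test-split sentence with the moving window and reports
#' three surfaces, in percent:
#' \describe{
#'   \item{window_accuracy}{per-window top-1 class vs the positional
#'     ground-truth label of [assign_window_labels()];}
#'   \item{slot_accuracy}{per ground-truth word slot of the final collapsed
#'     (and, if `lm` is given, LM-corrected) sequence -- exact-position
#'     matches when lengths agree, otherwise longest-common-subsequence hits
#'     over the number of slots;}
#'   \item{sentence_accuracy}{exact match of the final sequence.}
#' }
#'
#' @param model a trained `ssr_model`.
#' @param corpus_b sentence `ssr_corpus`.
#' @param refs the reference set.
#' @param spec a [window_spec()].
#' @param lm optional `trigram_model`; when supplied, sentences are
#'   corrected with [correct_sentence()] before slot/sentence scoring.
#' @param K,top_m,lambda,prune_threshold LM correction parameters.
#' @param split which split to evaluate (default `"test"`).
#' @return list with `window_accuracy`, `slot_accuracy`,
#'   `sentence_accuracy` (percent) and the per-sentence `details` data
#'   frame.
#' @export
evaluate_sentences <- function(model, corpus_b, refs, spec = window_spec(),
                               lm = NULL, K = 5L, top_m = 3L, lambda = 0.5,
                               prune_threshold = 0.02, split = "test") {
  ids <- corpus_ids(corpus_b, split = split, kind = "sentence")
  if (length(ids) == 0L)
    abort_validation("empty ", split, " set")
  refs <- ensure_embedded(model, refs)
  win_hits <- 0L; win_total <- 0L
  slot_acc <- numeric(0)
  sent_hits <- logical(0)
  details <- list()
  for (id in ids) {
    rec <- corpus_b$recordings[[id]]
    truth <- label_words(rec$label)
    gt <- assign_window_labels(rec, spec)
    dec <- infer_word_sequence(model, rec, refs, spec)
    top1 <- vapply(dec$rankings, function(r) r$class[1L], "")
    win_hits <- win_hits + sum(top1 == gt$label)
    win_total <- win_total + length(top1)
    final <- if (is.null(lm)) collapse_repeats(dec$raw_words)
      else as.character(correct_sentence(dec$rankings, lm, K = K,
                                         top_m = top_m, lambda = lambda,
                                         prune_threshold = prune_threshold))
    slot_acc <- c(slot_acc, slot_accuracy_one(final, truth))
    sent_hits <- c(sent_hits, length(final) == length(truth) &&
                     all(final == truth))
    details[[id]] <- data.frame(id = id, truth = rec$label,
                                predicted = paste(final, collapse = " "))
  }
  list(window_accuracy = 100 * win_hits / win_total,
       slot_accuracy = 100 * mean(slot_acc),
       sentence_accuracy = 100 * mean(sent_hits),
       details = do.call(rbind, details))
}

#' Experiment configuration
#'
#' Bundles every knob of a full three-model comparison: synthetic corpus
#' generation, augmentation, encoder training, moving-window decoding and
#' LM correction.
#'
#' @param synth a [synth_config()].
#' @param encoder an [encoder_config()].
#' @param plan an [augment_plan()].
#' @param spec a [window_spec()].
#' @param modalities subset of `c("emg", "eeg", "fusion")`.
#' @param vocabulary,sentences corpus definition.
#' @param retrain_overrides hyperparameter overrides for the sentence
#'   retraining stage: either a flat named list applied to every modality,
#'   or a list keyed by modality (the defaults give the slower-converging
#'   EEG branch a larger step budget).
#' @param k_smooth,K,top_m,lambda,prune_threshold LM parameters.
#' @param seed master seed; overrides the seeds inside `synth`, `encoder`
#'   and `plan` so one integer reproduces the whole run.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(),
                              encoder = encoder_config(),
                              plan = augment_plan(),
                              spec = window_spec(),
                              modalities = c("emg", "eeg", "fusion"),
                              vocabulary = default_vocabulary(),
                              sentences = default_sentences(),
                              retrain_overrides = list(epochs = 8L, lr = 5e-3,
                                                       pairs_per_epoch = 1536L,
                                                       batch_size = 128L),
                              k_smooth = 0.01, K = 5L, top_m = 3L,
                              lambda = 0.5, prune_threshold = 0.02,
                              seed = 1L) {
  bad <- setdiff(modalities, c("emg", "eeg", "fusion"))
  if (length(bad))
    abort_validation("invalid config field 'modalities': ",
                     paste(bad, collapse = ", "))
  seeds <- seed_stream(seed, 3L)
  synth$seed <- seeds[1L]
  encoder$seed <- seeds[2L]
  plan$seed <- seeds[3L]
  structure(list(synth = synth, encoder = encoder, plan = plan, spec = spec,
                 modalities = modalities, vocabulary = vocabulary,
                 sentences = sentences,
                 retrain_overrides = retrain_overrides,
                 k_smooth = k_smooth, K = K, top_m = top_m, lambda = lambda,
                 prune_threshold = prune_threshold, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full Model A / B / C experiment
#'
#' For each requested modality: synthesizes (or accepts) the word and
#' sentence corpora, augments the train splits, builds the 5-shot reference
#' set, pretrains Model A on isolated words, evaluates it on words and on
#' sentence windows, retrains Model B with the moving window on sentences,
#' and evaluates Model C as Model B plus trigram-LM correction. Leakage is
#' guarded: train ids, test ids and reference ids are pairwise disjoint.
#'
#' @param config an [experiment_config()], or a path to a YAML file with
#'   (nested) fields of the same names.
#' @param corpora optional precomputed `list(corpus_a =, corpus_b =)`; by
#'   default generated from `config$synth`.
#' @param keep_models return the trained models in the report (default
#'   FALSE).
#' @param quiet suppress progress messages.
#' @return an `experiment_report`: a list with the accuracy table
#'   (`$accuracy`, one row per modality), per-run details, the config and
#'   seed. Identical configs and seeds give identical reports.
#' @export
run_experiment <- function(config = experiment_config(), corpora = NULL,
                           keep_models = FALSE, quiet = TRUE) {
  if (is.character(config)) config <- load_experiment_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(corpora)) {
    say("synthesizing corpora (seed %d)", config$synth$seed)
    corpora <- synth_corpora(config$vocabulary, config$sentences, config$synth)
  }
  corpus_a <- corpora$corpus_a
  corpus_b <- corpora$corpus_b
  refs <- build_reference_set(corpus_a)
  # leakage guard: reference, train and test id sets pairwise disjoint
  a_train <- setdiff(corpus_ids(corpus_a, split = "train"), refs$ids)
  a_test <- corpus_ids(corpus_a, split = "test")
  stopifnot(length(intersect(a_train, a_test)) == 0L,
            length(intersect(refs$ids, a_test)) == 0L,
            length(intersect(corpus_ids(corpus_b, split = "train"),
                             corpus_ids(corpus_b, split = "test"))) == 0L)
  say("augmenting train splits")
  corpus_a_aug <- augment_corpus(corpus_a, config$plan)
  plan_b <- config$plan
  plan_b$seed <- config$plan$seed + 1L
  corpus_b_aug <- augment_corpus(corpus_b, plan_b)
  lm <- fit_trigram(config$sentences, k_smooth = config$k_smooth,
                    vocabulary = setdiff(config$vocabulary, "NOISE"))
  rows <- list()
  runs <- list()
  for (mod in config$modalities) {
    say("[%s] pretraining Model A", mod)
    ecfg <- config$encoder
    model_a <- if (mod == "fusion")
      pretrain(corpus_a_aug, refs, ecfg, modality = "fusion")
    else pretrain(corpus_a_aug, refs, ecfg, modality = mod)
    word_acc <- evaluate_words(model_a, corpus_a_aug, refs)
    say("[%s] Model A word accuracy: %.2f%%", mod, word_acc)
    sent_a <- evaluate_sentences(model_a, corpus_b, refs, config$spec)
    say("[%s] Model A window accuracy in sentences: %.2f%%", mod,
        sent_a$window_accuracy)
    say("[%s] retraining Model B", mod)
    ro <- config$retrain_overrides
    if (!is.null(ro[[mod]]) && is.list(ro[[mod]])) ro <- ro[[mod]]
    model_b <- retrain(model_a, corpus_b_aug, refs, config$spec, ro)
    sent_b <- evaluate_sentences(model_b, corpus_b, refs, config$spec)
    say("[%s] Model B window accuracy: %.2f%%, sentence accuracy: %.2f%%",
        mod, sent_b$window_accuracy, sent_b$sentence_accuracy)
    sent_c <- evaluate_sentences(model_b, corpus_b, refs, config$spec,
                                 lm = lm, K = config$K, top_m = config$top_m,
                                 lambda = config$lambda,
                                 prune_threshold = config$prune_threshold)
    say("[%s] Model C sentence accuracy: %.2f%%", mod,
        sent_c$sentence_accuracy)
    rows[[mod]] <- data.frame(
      modality = mod,
      model_a_word = word_acc,
      model_a_window = sent_a$window_accuracy,
      model_a_slot = sent_a$slot_accuracy,
      model_b_window = sent_b$window_accuracy,
      model_b_slot = sent_b$slot_accuracy,
      model_b_sentence = sent_b$sentence_accuracy,
      model_c_sentence = sent_c$sentence_accuracy)
    runs[[mod]] <- list(sent_a = sent_a, sent_b = sent_b, sent_c = sent_c,
                        models = if (keep_models)
                          list(a = model_a, b = model_b))
  }
  structure(list(accuracy = do.call(rbind, c(rows, make.row.names = FALSE)),
                 runs = runs, config = config, seed = config$seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> accuracies (%):\n")
  print(x$accuracy, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param report an `experiment_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(seed = report$seed, accuracy = report$accuracy)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# build an experiment_config from a YAML file; unknown fields error with
# their path so config typos surface early
load_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- list(synth = synth_config, encoder = encoder_config,
                plan = augment_plan, spec = window_spec)
  args <- list()
  for (nm in names(raw)) {
    if (nm %in% names(known)) {
      fn <- known[[nm]]
      ok <- names(formals(fn))
      bad <- setdiff(names(raw[[nm]]), ok)
      if (length(bad))
        abort_validation("invalid config field '", nm, ".", bad[1L], "'")
      args[[nm]] <- do.call(fn, raw[[nm]])
    } else if (nm == "sentences") {
      args$sentences <- lapply(raw$sentences, label_words)
    } else if (nm %in% names(formals(experiment_config))) {
      args[[nm]] <- raw[[nm]]
    } else {
      abort_validation("invalid config field '", nm, "'")
    }
  }
  do.call(experiment_config, args)
}
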