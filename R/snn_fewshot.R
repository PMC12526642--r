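#' Siamese encoder configuration
#'
#' Hyperparameters of the 1-D convolutional Siamese encoder and its
#' contrastive training. The convolution kernel size is 7 with padding 3
#' (so each convolution preserves length); each of the `n_conv_blocks`
#' blocks is convolution -> ReLU -> stride-2 average pooling. The block
#' output is average-pooled to `n_pool_bins` temporal bins, flattened and
#' projected to an L2-normalized embedding.
#'
#' @param input_length encoder input length in samples (default 700, the
#'   moving-window width).
#' @param kernel_size convolution kernel size (odd; default 7).
#' @param padding convolution padding; must equal `(kernel_size - 1) / 2`.
#' @param n_conv_blocks number of conv blocks (default 3).
#' @param channels per-block output channel counts.
#' @param n_pool_bins temporal bins of the pre-embedding average pool.
#' @param embedding_dim embedding dimension (default 64).
#' @param margin contrastive margin m (default 1.0).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size pairs per optimization step.
#' @param pairs_per_epoch contrastive pairs sampled per epoch.
#' @param tau softmax temperature converting average cosine distances into
#'   classification confidences.
#' @param decimation named per-modality front-end decimation factors
#'   (non-overlapping average pooling applied before the first convolution).
#'   The defaults match each modality's bandwidth at the 4096 Hz sampling
#'   rate: EMG content reaches ~450 Hz so a factor 2 keeps it oversampled,
#'   while EEG content below ~40 Hz allows a factor 8, which widens the conv
#'   stack's receptive field to the slow-wave time scale.
#' @param seed seed for initialization and pair sampling.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(input_length = 700L, kernel_size = 7L, padding = 3L,
                           n_conv_blocks = 3L, channels = c(6L, 12L, 24L),
                           n_pool_bins = 8L, embedding_dim = 64L,
                           margin = 1.0, lr = 3e-3, epochs = 5L,
                           batch_size = 128L, pairs_per_epoch = 1024L,
                           tau = 0.1, decimation = c(emg = 2L, eeg = 8L),
                           seed = 1L) {
  if (kernel_size %% 2L == 0L)
    abort_validation("kernel_size must be odd")
  if (padding != (kernel_size - 1L) %/% 2L)
    abort_validation("padding must equal (kernel_size - 1) / 2")
  if (embedding_dim <= 0L)
    abort_validation("embedding_dim must be > 0")
  if (length(channels) != n_conv_blocks)
    abort_validation("channels must have n_conv_blocks entries")
  structure(list(input_length = as.integer(input_length),
                 kernel_size = as.integer(kernel_size),
                 padding = as.integer(padding),
                 n_conv_blocks = as.integer(n_conv_blocks),
                 channels = as.integer(channels),
                 n_pool_bins = as.integer(n_pool_bins),
                 embedding_dim = as.integer(embedding_dim),
                 margin = margin, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 pairs_per_epoch = as.integer(pairs_per_epoch),
                 tau = tau, decimation = decimation,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Create an untrained unimodal Siamese encoder
#'
#' @param config an [encoder_config()].
#' @param modality `"emg"` or `"eeg"`.
#' @return an `ssr_model`.
#' @export
snn_model <- function(config = encoder_config(), modality = c("emg", "eeg")) {
  modality <- match.arg(modality)
  arch <- make_arch(modality, config$input_length, config$kernel_size,
                    config$padding, config$channels, config$n_pool_bins,
                    head_layers = integer(0),
                    embedding_dim = config$embedding_dim,
                    decimation = config$decimation)
  structure(list(version = 1L, type = "unimodal", modalities = modality,
                 config = config, arch = arch,
                 params = init_params(arch, config$seed),
                 log = NULL, refs_digest = NULL),
            class = "ssr_model")
}

#' @export
print.ssr_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<ssr_model %s [%s]> %d parameters, embedding dim %d%s\n",
              x$type, paste(x$modalities, collapse = "+"), np,
              x$config$embedding_dim,
              if (is.null(x$log)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$log))))
  invisible(x)
}

param_digest <- function(model) {
  s <- vapply(model$params, function(p) sum(p), 0)
  sprintf("%.12g", sum(s) + sum(s * seq_along(s)))
}

# z-score each row; constant rows are left at zero
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  m <- m - mu
  sd <- sqrt(rowMeans(m * m))
  sd[sd < 1e-12] <- 1
  m / sd
}

# assemble per-modality (n x input_length) z-scored input matrices from a
# list of signal lists; signals must already be input_length long
stack_inputs <- function(signals, modalities) {
  out <- list()
  for (m in modalities) {
    out[[m]] <- zscore_rows(do.call(rbind, lapply(signals, `[[`, m)))
  }
  out
}

# extract the modality signals of one recording fitted to input_length
segment_signals <- function(rec, modalities, input_length) {
  out <- list()
  for (m in modalities) out[[m]] <- fit_length(rec_samples(rec, m), input_length)
  out
}

as_segment <- function(segment, modalities) {
  if (inherits(segment, "ssr_recording"))
    return(lapply(stats::setNames(nm = modalities), function(m)
      rec_samples(segment, m)))
  if (is.numeric(segment)) {
    if (length(modalities) != 1L)
      abort_validation("a fusion model needs both modalities; pass a named list or recording")
    return(stats::setNames(list(as.numeric(segment)), modalities))
  }
  if (is.list(segment)) {
    for (m in modalities)
      if (is.null(segment[[m]]))
        abort_validation("segment is missing required modality '", m, "'")
    return(segment[modalities])
  }
  abort_validation("unsupported segment type")
}

#' Encode a fixed-length segment
#'
#' Runs the encoder on one segment and returns its L2-normalized embedding.
#' The caller is responsible for padding/cropping to
#' `model$config$input_length`; a wrong length is a validation error. The
#' segment is z-scored per modality before encoding. Inference is
#' deterministic: identical inputs give identical embeddings.
#'
#' @param model an `ssr_model`.
#' @param segment numeric vector (unimodal model), named list with the
#'   model's modalities, or an `ssr_recording`.
#' @return unit-norm numeric embedding vector.
#' @export
encode <- function(model, segment) {
  seg <- as_segment(segment, model$modalities)
  for (m in model$modalities)
    if (length(seg[[m]]) != model$config$input_length)
      abort_validation("segment length ", length(seg[[m]]),
                       " != input_length ", model$config$input_length)
  inputs <- stack_inputs(list(seg), model$modalities)
  as.numeric(net_forward(model$arch, model$params, inputs)$emb)
}

#' Encode a pair through the two Siamese twins
#'
#' The two branches of a Siamese network share all weights, so both twins
#' are literally the same function; this helper makes that property
#' assertable by returning both twin outputs.
#'
#' @param model an `ssr_model`.
#' @param left,right segments as in [encode()].
#' @return list with unit-norm embeddings `left` and `right` and their
#'   cosine `distance`.
#' @export
encode_pair <- function(model, left, right) {
  el <- encode(model, left)
  er <- encode(model, right)
  list(left = el, right = er, distance = cosine_distance(el, er))
}

# batch embedding of a list of recordings/segments (internal, fast path)
embed_batch <- function(model, signal_list, batch = 512L) {
  n <- length(signal_list)
  out <- matrix(0, n, model$config$embedding_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    inputs <- stack_inputs(signal_list[i:j], model$modalities)
    out[i:j, ] <- net_forward(model$arch, model$params, inputs)$emb
    i <- j + 1L
  }
  out
}

#' Cosine distance between two embeddings
#'
#' `d = 1 - <a, b> / (|a| |b|)`, ranging over `[0, 2]`: 0 for identical
#' directions, 1 for orthogonal, 2 for antipodal vectors.
#'
#' @param a,b numeric vectors of equal length; zero vectors are rejected.
#' @return cosine distance in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b))
    abort_validation("embedding lengths differ")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na < 1e-12 || nb < 1e-12)
    abort_validation("cosine distance undefined for zero vectors")
  1 - sum(a * b) / (na * nb)
}

#' Contrastive loss
#'
#' `L = y * d^2 + (1 - y) * max(0, m - d)^2`: matched pairs (`y = 1`) are
#' pulled together, mismatched pairs (`y = 0`) are pushed beyond the margin
#' `m`. Vectorized over `d` and `y`.
#'
#' @param d nonnegative distance(s).
#' @param y match label(s) in `{0, 1}`.
#' @param m positive margin (default 1).
#' @return nonnegative loss value(s).
#' @export
contrastive_loss <- function(d, y, m = 1.0) {
  if (!all(y %in% c(0, 1)))
    abort_validation("match labels y must be 0 or 1")
  if (any(d < 0))
    abort_validation("distances must be nonnegative")
  if (m <= 0)
    abort_validation("margin must be positive")
  y * d^2 + (1 - y) * pmax(0, m - d)^2
}

#' Build the few-shot reference set
#'
#' Selects `shots_per_class` representative train-split recordings per
#' vocabulary class (including the noise class): the recordings with the
#' highest mean raw-signal cosine similarity to the other candidates of
#' their class (a medoid-like, deterministic criterion). Augmented variants
#' are never eligible. The selected recordings are meant to be excluded from
#' the contrastive training pool; [pretrain()] enforces that.
#'
#' @param corp the isolated-word `ssr_corpus`.
#' @param shots_per_class references per class (default 5).
#' @param seed unused; selection is deterministic. Kept for interface
#'   stability.
#' @return a `reference_set` with fields `classes`, `shots_per_class`,
#'   `recordings` (named list class -> recordings), `ids` and a content
#'   `digest` used to detect mutation between training stages.
#' @export
build_reference_set <- function(corp, shots_per_class = 5L, seed = NULL) {
  classes <- corp$vocabulary
  chosen <- list()
  for (cl in classes) {
    ids <- corpus_ids(corp, split = "train", experimental_only = TRUE)
    ids <- ids[vapply(corp$recordings[ids], `[[`, "", "label") == cl]
    if (length(ids) < shots_per_class)
      abort_validation("class '", cl, "' has only ", length(ids),
                       " experimental train recordings; need ", shots_per_class)
    len <- min(vapply(corp$recordings[ids], rec_length, 0L))
    sig <- do.call(rbind, lapply(corp$recordings[ids], function(r) {
      c(if (!is.null(r$emg)) fit_length(r$emg, len),
        if (!is.null(r$eeg)) fit_length(r$eeg, len))
    }))
    nrm <- sqrt(rowSums(sig * sig))
    nrm[nrm < 1e-12] <- 1e-12
    sig <- sig / nrm
    G <- tcrossprod(sig)
    score <- (rowSums(G) - diag(G)) / max(1L, length(ids) - 1L)
    ord <- order(-score, ids)
    chosen[[cl]] <- corp$recordings[ids[ord[seq_len(shots_per_class)]]]
  }
  ids <- unlist(lapply(chosen, function(rs) vapply(rs, `[[`, "", "id")),
                use.names = FALSE)
  all_sig <- unlist(lapply(chosen, function(rs)
    lapply(rs, function(r) c(r$emg, r$eeg))), recursive = FALSE)
  structure(list(classes = classes,
                 shots_per_class = as.integer(shots_per_class),
                 recordings = chosen, ids = ids,
                 digest = signal_digest(all_sig)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d classes x %d shots = %d references\n",
              length(x$classes), x$shots_per_class, length(x$ids)))
  invisible(x)
}

# reference signals fitted to the model input length, per class
ref_signal_list <- function(refs, model) {
  sig <- list(); labels <- character(0)
  for (cl in refs$classes) {
    for (r in refs$recordings[[cl]]) {
      sig[[length(sig) + 1L]] <-
        segment_signals(r, model$modalities, model$config$input_length)
      labels <- c(labels, cl)
    }
  }
  list(signals = sig, labels = labels)
}

#' Embed the reference set with a model
#'
#' Computes (or refreshes) the reference embeddings under the given encoder.
#' Needed after any training stage, since embeddings depend on the encoder
#' weights.
#'
#' @param model an `ssr_model`.
#' @param refs a [build_reference_set()] reference set.
#' @return `refs` with `embeddings` (matrix, one row per reference),
#'   `emb_labels`, per-class mean-embedding matrix `class_means` and the
#'   digest of the model that produced them.
#' @export
embed_references <- function(model, refs) {
  rs <- ref_signal_list(refs, model)
  emb <- embed_batch(model, rs$signals)
  means <- do.call(rbind, lapply(refs$classes, function(cl)
    colMeans(emb[rs$labels == cl, , drop = FALSE])))
  rownames(means) <- refs$classes
  refs$embeddings <- emb
  refs$emb_labels <- rs$labels
  refs$class_means <- means
  refs$model_digest <- param_digest(model)
  refs
}

ensure_embedded <- function(model, refs) {
  if (is.null(refs$embeddings) ||
      !identical(refs$model_digest, param_digest(model)))
    refs <- embed_references(model, refs)
  refs
}

# core contrastive training loop shared by pretrain and retrain.
# anchors: list(signals = list of per-modality signal lists, labels = chr)
train_contrastive <- function(model, anchors, refs, cfg, phase) {
  n <- length(anchors$labels)
  if (n == 0L)
    abort_validation("empty training set for phase '", phase, "'")
  if (cfg$epochs <= 0L) return(model)
  rs <- ref_signal_list(refs, model)
  ref_inputs <- stack_inputs(rs$signals, model$modalities)
  R <- length(rs$labels)
  ref_idx_by_class <- split(seq_len(R), rs$labels)
  anchor_inputs <- stack_inputs(anchors$signals, model$modalities)
  labels <- anchors$labels

  params <- model$params
  state <- adam_init(params)
  eseeds <- seed_stream(cfg$seed, cfg$epochs + 1L)
  log <- data.frame()
  same_class <- outer(labels, rs$labels, `==`)   # n x R pair match labels
  for (e in seq_len(cfg$epochs)) {
    pairs <- with_seed(eseeds[e], {
      ai <- sample.int(n, cfg$pairs_per_epoch, replace = TRUE)
      y <- as.numeric(stats::runif(cfg$pairs_per_epoch) < 0.5)
      ri <- vapply(seq_len(cfg$pairs_per_epoch), function(p) {
        if (y[p] == 1) {
          pool <- ref_idx_by_class[[labels[ai[p]]]]
          pool[sample.int(length(pool), 1L)]
        } else NA_integer_   # negatives are mined within the batch
      }, 0L)
      list(ai = ai, ri = ri, y = y)
    })
    epoch_loss <- 0
    nb <- 0L
    start <- 1L
    while (start <= cfg$pairs_per_epoch) {
      end <- min(start + cfg$batch_size - 1L, cfg$pairs_per_epoch)
      sel <- start:end
      B <- length(sel)
      inputs <- list()
      for (m in model$modalities)
        inputs[[m]] <- rbind(anchor_inputs[[m]][pairs$ai[sel], , drop = FALSE],
                             ref_inputs[[m]])
      fw <- net_forward(model$arch, params, inputs, want_cache = TRUE)
      a <- fw$emb[seq_len(B), , drop = FALSE]
      r_all <- fw$emb[B + seq_len(R), , drop = FALSE]
      # mismatched pairs use the hardest (closest) wrong-class reference,
      # chosen from the embeddings already computed for this batch
      ri <- pairs$ri[sel]
      neg <- which(is.na(ri))
      if (length(neg)) {
        dmat <- 1 - a[neg, , drop = FALSE] %*% t(r_all)
        dmat[same_class[pairs$ai[sel][neg], , drop = FALSE]] <- Inf
        ri[neg] <- max.col(-dmat, ties.method = "first")
      }
      r <- r_all[ri, , drop = FALSE]
      y <- pairs$y[sel]
      d <- 1 - rowSums(a * r)
      shortfall <- pmax(cfg$margin - d, 0)
      loss <- mean(y * d^2 + (1 - y) * shortfall^2)
      dd <- (2 * y * d - 2 * (1 - y) * shortfall) / B
      dA <- -dd * r
      dRp <- -dd * a
      dR <- matrix(0, R, ncol(a))
      acc <- rowsum(dRp, group = ri)
      dR[as.integer(rownames(acc)), ] <- acc
      grads <- net_backward(model$arch, params, fw$cache, rbind(dA, dR))
      st <- adam_step(params, grads, state, cfg$lr)
      params <- st$params
      state <- st$state
      epoch_loss <- epoch_loss + loss
      nb <- nb + 1L
      start <- end + 1L
    }
    # probe accuracy on a deterministic anchor subsample
    probe <- with_seed(eseeds[cfg$epochs + 1L],
                       sample.int(n, min(256L, n)))
    model$params <- params
    pe <- embed_batch(model, anchors$signals[probe])
    re <- embed_batch(model, rs$signals)
    means <- do.call(rbind, lapply(refs$classes, function(cl)
      colMeans(re[rs$labels == cl, , drop = FALSE])))
    pred <- refs$classes[max.col(pe %*% t(means), ties.method = "first")]
    acc <- mean(pred == labels[probe])
    log <- rbind(log, data.frame(phase = phase, epoch = e,
                                 loss = epoch_loss / nb, train_accuracy = acc))
  }
  model$params <- params
  model$log <- rbind(model$log, log)
  model
}

#' Pretrain the Siamese encoder on isolated words
#'
#' Contrastive training on (train recording, reference recording) pairs with
#' match label 1 iff same class, drawn from the isolated-word corpus
#' (experimental and augmented train recordings, excluding the reference
#' recordings themselves). Per-epoch mean loss and probe train accuracy are
#' logged in `model$log`.
#'
#' @param corpus_a isolated-word `ssr_corpus` (with split assigned).
#' @param refs reference set built from the same corpus.
#' @param config an [encoder_config()].
#' @param modality `"emg"` or `"eeg"` for a unimodal model, `"fusion"` for
#'   the paired EMG+EEG encoder.
#' @param fusion_config a [fusion_config()] when `modality = "fusion"`.
#' @return a trained `ssr_model` carrying the reference-set digest.
#' @export
pretrain <- function(corpus_a, refs, config = encoder_config(),
                     modality = c("emg", "eeg", "fusion"),
                     fusion_config = NULL) {
  modality <- match.arg(modality)
  model <- if (modality == "fusion")
    fusion_model(fusion_config %||% fusion_config(branch_config = config))
  else snn_model(config, modality)
  train_ids <- setdiff(corpus_ids(corpus_a, split = "train"), refs$ids)
  if (length(train_ids) == 0L)
    abort_validation("empty train split")
  recs <- corpus_a$recordings[train_ids]
  anchors <- list(
    signals = lapply(recs, segment_signals, modalities = model$modalities,
                     input_length = model$config$input_length),
    labels = vapply(recs, `[[`, "", "label")
  )
  model <- train_contrastive(model, anchors, refs, model$config, "pretrain")
  model$refs_digest <- refs$digest
  model
}

#' Classify a fixed-length segment against the reference set
#'
#' The segment is embedded and compared to all references: per class, the
#' cosine distances to that class's `shots_per_class` reference embeddings
#' are averaged, classes are ranked by ascending average distance (ties
#' broken by vocabulary order) and a confidence is assigned by a softmax
#' over `-avg_distance / tau`.
#'
#' @param model a trained `ssr_model`.
#' @param segment segment as in [encode()], of length `input_length`.
#' @param refs an embedded reference set (see [embed_references()]); if the
#'   embeddings are missing or stale they are recomputed.
#' @param window_index optional window index attached to the ranking.
#' @return a `candidate_ranking` data frame with columns `class`,
#'   `avg_distance`, `confidence`, sorted by ascending distance.
#' @export
classify_segment <- function(model, segment, refs, window_index = NA_integer_) {
  n_shots <- vapply(refs$classes, function(cl)
    length(refs$recordings[[cl]]), 0L)
  if (any(n_shots != refs$shots_per_class))
    abort_validation("reference set missing shots for class(es): ",
                     paste(refs$classes[n_shots != refs$shots_per_class],
                           collapse = ", "))
  refs <- ensure_embedded(model, refs)
  emb <- encode(model, segment)
  ranking_from_embedding(emb, refs, model$config$tau, window_index)
}

#' Add a new class to an existing reference set
#'
#' Few-shot extensibility: a new class becomes recognizable by storing its
#' reference recordings alone, with no retraining of the encoder.
#'
#' @param refs a `reference_set`.
#' @param class new class name.
#' @param recordings list of `shots_per_class` recordings of the class.
#' @return the extended `reference_set` (embeddings invalidated).
#' @export
add_reference_class <- function(refs, class, recordings) {
  if (class %in% refs$classes)
    abort_validation("class '", class, "' already in the reference set")
  if (length(recordings) != refs$shots_per_class)
    abort_validation("need exactly ", refs$shots_per_class, " recordings")
  refs$classes <- c(refs$classes, class)
  refs$recordings[[class]] <- recordings
  refs$ids <- c(refs$ids, vapply(recordings, `[[`, "", "id"))
  refs$embeddings <- NULL
  refs$model_digest <- NULL
  all_sig <- unlist(lapply(refs$recordings, function(rs)
    lapply(rs, function(r) c(r$emg, r$eeg))), recursive = FALSE)
  refs$digest <- signal_digest(all_sig)
  refs
}

ranking_from_embedding <- function(emb, refs, tau, window_index = NA_integer_) {
  avg_d <- as.numeric(1 - refs$class_means %*% emb)
  names(avg_d) <- refs$classes
  conf <- exp((-avg_d / tau) - max(-avg_d / tau))
  conf <- conf / sum(conf)
  ord <- order(avg_d, seq_along(refs$classes))
  out <- data.frame(class = refs$classes[ord], avg_distance = avg_d[ord],
                    confidence = conf[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "window_index") <- window_index
  class(out) <- c("candidate_ranking", class(out))
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned and carry the full configuration, so a loaded
#' model reproduces embeddings exactly.
#'
#' @param model an `ssr_model`.
#' @param path checkpoint path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `ssr_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version != 1L)
    abort_validation("unsupported checkpoint version")
  structure(obj, class = "ssr_model")
}

#' Write the training log as CSV
#'
#' @param model a trained `ssr_model`.
#' @param path output CSV path (columns phase, epoch, loss, train_accuracy).
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  if (is.null(model$log)) abort_validation("model has no training log")
  utils::write.csv(model$log, path, row.names = FALSE)
  invisible(path)
}
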