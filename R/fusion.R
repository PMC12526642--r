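#' Fusion encoder configuration
#'
#' The paired EMG+EEG encoder runs each modality through its own
#' convolutional branch (the same block structure as the unimodal encoder),
#' concatenates the flattened branch features and passes them through a
#' shared multi-layer head that produces the L2-normalized joint embedding.
#'
#' @param branch_config an [encoder_config()] shared by both branches
#'   (kernel, channels, pooling, training hyperparameters).
#' @param head_layers hidden layer sizes of the shared fusion head.
#' @param embedding_dim output embedding dimension; defaults to the branch
#'   config's.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(branch_config = encoder_config(),
                          head_layers = 128L, embedding_dim = NULL) {
  structure(list(branch_config = branch_config,
                 head_layers = as.integer(head_layers),
                 embedding_dim = as.integer(embedding_dim %||%
                                              branch_config$embedding_dim)),
            class = "fusion_config")
}

#' Create an untrained EMG+EEG fusion encoder
#'
#' @param config a [fusion_config()].
#' @return an `ssr_model` of type `"fusion"`. It refuses to run with a
#'   missing modality: fusion never silently degrades to unimodal.
#' @export
fusion_model <- function(config = fusion_config()) {
  bc <- config$branch_config
  arch <- make_arch(c("emg", "eeg"), bc$input_length, bc$kernel_size,
                    bc$padding, bc$channels, bc$n_pool_bins,
                    head_layers = config$head_layers,
                    embedding_dim = config$embedding_dim,
                    decimation = bc$decimation)
  cfg <- bc
  cfg$embedding_dim <- config$embedding_dim
  structure(list(version = 1L, type = "fusion", modalities = c("emg", "eeg"),
                 config = cfg, fusion = config, arch = arch,
                 params = init_params(arch, bc$seed),
                 log = NULL, refs_digest = NULL),
            class = "ssr_model")
}

#' Encode a paired EMG+EEG segment with a fusion model
#'
#' Both segments must be present and of length `input_length`; a missing
#' modality is a validation error.
#'
#' @param model a fusion `ssr_model`.
#' @param emg_segment,eeg_segment numeric vectors of length `input_length`.
#' @return unit-norm embedding vector.
#' @export
encode_fused <- function(model, emg_segment, eeg_segment) {
  if (model$type != "fusion")
    abort_validation("encode_fused requires a fusion model")
  if (is.null(emg_segment) || is.null(eeg_segment))
    abort_validation("fusion model requires both EMG and EEG segments")
  if (length(emg_segment) != length(eeg_segment))
    abort_validation("EMG and EEG segment lengths differ")
  encode(model, list(emg = as.numeric(emg_segment),
                     eeg = as.numeric(eeg_segment)))
}
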