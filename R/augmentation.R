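#' Shift a signal with mean-padding
#'
#' Moves the signal content by `offset` samples; the vacated positions are
#' filled with the mean of the original (pre-shift) signal. Output length
#' equals input length. Positive offsets move content to the right (padding
#' at the head), negative to the left (padding at the tail).
#'
#' @param signal numeric vector.
#' @param offset integer shift in samples; `abs(offset) < length(signal)`.
#' @return shifted numeric vector of the same length.
#' @export
shift_pad <- function(signal, offset) {
  n <- length(signal)
  offset <- as.integer(offset)
  if (abs(offset) >= n)
    abort_validation("|offset| must be smaller than the signal length")
  if (offset == 0L) return(signal)
  mu <- mean(signal)
  if (offset > 0L) c(rep(mu, offset), signal[seq_len(n - offset)])
  else c(signal[(1L - offset):n], rep(mu, -offset))
}

#' Crop a signal
#'
#' Returns the half-open slice `[start, start + length)` in 0-based
#' coordinates.
#'
#' @param signal numeric vector.
#' @param start 0-based start sample.
#' @param length number of samples, at least 1.
#' @return numeric vector of `length` samples.
#' @export
crop <- function(signal, start, length) {
  n <- base::length(signal)
  start <- as.integer(start); length <- as.integer(length)
  if (length < 1L)
    abort_validation("crop length must be >= 1")
  if (start < 0L || start + length > n)
    abort_validation("crop window [", start, ", ", start + length,
                     ") out of range for signal of length ", n)
  signal[(start + 1L):(start + length)]
}

#' Resample a signal by linear interpolation
#'
#' Linear interpolation on the normalized index grid; the first and last
#' samples are preserved exactly. Used for both upsampling and downsampling.
#'
#' @param signal numeric vector of length >= 2.
#' @param target_length desired output length, >= 2.
#' @return numeric vector of `target_length` samples.
#' @export
resample_linear <- function(signal, target_length) {
  target_length <- as.integer(target_length)
  if (length(signal) < 2L)
    abort_validation("signal must have at least 2 samples")
  if (target_length < 2L)
    abort_validation("target_length must be >= 2")
  if (target_length == length(signal)) return(signal)
  stats::approx(seq_along(signal), signal, n = target_length)$y
}

#' Corpus augmentation plan
#'
#' Describes the pool of shift / crop / upsample / downsample operators from
#' which augmented variants are drawn. Offsets and crop windows are given as
#' fractions of each recording's length so one plan applies to words and
#' sentences alike.
#'
#' @param shift_fractions candidate shift offsets as fractions of the
#'   recording length (positive = right).
#' @param crops list of `c(start_fraction, length_fraction)` pairs, fractions
#'   in `(0, 1]`.
#' @param resample_factors candidate resampling ratios (> 0); < 1 compresses
#'   (downsample), > 1 stretches (upsample).
#' @param per_recording_count augmented variants per train recording
#'   (default 4, one per operator family, cycling).
#' @param seed seed for the deterministic expansion of the plan.
#' @return an `augment_plan` list.
#' @export
augment_plan <- function(shift_fractions = c(-0.08, -0.04, 0.04, 0.08),
                         crops = list(c(0, 0.85), c(0.15, 0.85)),
                         resample_factors = c(0.9, 1.1),
                         per_recording_count = 4L, seed = 1L) {
  if (any(resample_factors <= 0))
    abort_validation("resample factors must be > 0")
  for (cr in crops)
    if (any(cr[2L] <= 0) || cr[2L] > 1 || cr[1L] < 0 || cr[1L] + cr[2L] > 1)
      abort_validation("crop fractions must satisfy 0 <= start, 0 < length, start + length <= 1")
  structure(list(shift_fractions = shift_fractions, crops = crops,
                 resample_factors = resample_factors,
                 per_recording_count = as.integer(per_recording_count),
                 seed = as.integer(seed)),
            class = "augment_plan")
}

# one operator application; restores the original length afterwards
# (mean-pad or centre-crop) so window labeling and encoder input stay valid
apply_operator <- function(x, op) {
  n <- length(x)
  y <- switch(op$family,
    shift = shift_pad(x, as.integer(round(op$param * n))),
    crop = crop(x, as.integer(round(op$param[1L] * n)),
                max(2L, as.integer(round(op$param[2L] * n)))),
    resample = resample_linear(x, max(2L, as.integer(round(op$param * n))))
  )
  fit_length(y, n)
}

#' Augment the train split of a corpus
#'
#' Appends `per_recording_count` augmented variants of every train-split
#' recording, each tagged with its parent id. Both modalities of a paired
#' recording receive the same operator chain so EMG/EEG alignment is
#' preserved. Test-split recordings are never touched or used.
#'
#' @param corp an `ssr_corpus`.
#' @param plan an [augment_plan()].
#' @return the extended `ssr_corpus`; augmented recordings are assigned to
#'   the train split.
#' @export
augment_corpus <- function(corp, plan = augment_plan()) {
  if (plan$per_recording_count == 0L) return(corp)
  train_ids <- corpus_ids(corp, split = "train")
  if (length(train_ids) == 0L) return(corp)
  families <- c("shift", "crop", "resample_down", "resample_up")
  seeds <- seed_stream(plan$seed, length(train_ids))
  new_recs <- list()
  new_split <- character(0)
  for (i in seq_along(train_ids)) {
    rec <- corp$recordings[[train_ids[i]]]
    ops <- with_seed(seeds[i], {
      pick1 <- function(v) v[sample.int(length(v), 1L)]
      down <- plan$resample_factors[plan$resample_factors < 1]
      up <- plan$resample_factors[plan$resample_factors > 1]
      if (!length(down)) down <- plan$resample_factors
      if (!length(up)) up <- plan$resample_factors
      lapply(seq_len(plan$per_recording_count), function(j) {
        fam <- families[((j - 1L) %% length(families)) + 1L]
        switch(fam,
          shift = list(family = "shift", param = pick1(plan$shift_fractions)),
          crop = list(family = "crop",
                      param = plan$crops[[sample.int(length(plan$crops), 1L)]]),
          resample_down = list(family = "resample", param = pick1(down)),
          resample_up = list(family = "resample", param = pick1(up))
        )
      })
    })
    for (j in seq_along(ops)) {
      op <- ops[[j]]
      id <- sprintf("%s_aug%d", rec$id, j)
      new_recs[[id]] <- recording(
        id = id, kind = rec$kind, label = rec$label,
        emg = if (!is.null(rec$emg)) apply_operator(rec$emg, op),
        eeg = if (!is.null(rec$eeg)) apply_operator(rec$eeg, op),
        sampling_rate = rec$sampling_rate, pad = rec$pad,
        parent_id = rec$id)
      new_split[id] <- "train"
    }
  }
  corpus(c(corp$recordings, new_recs), corp$vocabulary,
         c(corp$split, new_split))
}
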