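#' Default command vocabulary
#'
#' The ten command words of the four-phrase corpus, plus the `"NOISE"` class
#' used for silent/non-speech segments.
#'
#' @return character vector of 11 class names.
#' @export
default_vocabulary <- function() {
  c("Need", "Medical", "Assistance", "Land", "Here",
    "Do", "Not", "Pick", "Us", "Up", "NOISE")
}

#' Default command sentences
#'
#' The four command phrases decoded by the pipeline, as word-token vectors.
#'
#' @return list of character vectors.
#' @export
default_sentences <- function() {
  list(
    c("Need", "Medical", "Assistance"),
    c("Land", "Here"),
    c("Do", "Not", "Land", "Here"),
    c("Pick", "Us", "Up")
  )
}

#' Construct a labeled biosignal recording
#'
#' A recording holds one or both modalities (single-channel EMG and/or EEG)
#' sampled at a common rate, together with its class label. Word recordings
#' carry a single word label; sentence recordings carry a space-joined word
#' sequence; noise recordings carry the `"NOISE"` label.
#'
#' @param id unique recording identifier.
#' @param kind one of `"word"`, `"sentence"`, `"noise"`.
#' @param label class name, or space-joined word sequence for sentences.
#' @param emg,eeg numeric amplitude vectors (either may be `NULL`, not both).
#' @param sampling_rate sampling rate in Hz (default 4096).
#' @param pad number of leading/trailing non-speech samples (sentences only);
#'   used by positional window labeling.
#' @param parent_id id of the source recording for augmented variants.
#' @return an object of class `ssr_recording`.
#' @export
recording <- function(id, kind, label, emg = NULL, eeg = NULL,
                      sampling_rate = 4096, pad = 0L, parent_id = NA_character_) {
  kind <- match.arg(kind, c("word", "sentence", "noise"))
  if (is.null(emg) && is.null(eeg))
    abort_validation("recording '", id, "': at least one modality must be present")
  if (!is.null(emg) && !is.null(eeg) && length(emg) != length(eeg))
    abort_validation("recording '", id, "': EMG and EEG lengths differ (",
                     length(emg), " vs ", length(eeg), ")")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    abort_validation("recording '", id, "': sampling_rate must be > 0")
  if (kind != "noise" && (!nzchar(label) || is.na(label)))
    abort_validation("recording '", id, "': label must be nonempty")
  structure(
    list(id = as.character(id), kind = kind, label = as.character(label),
         emg = if (!is.null(emg)) as.numeric(emg),
         eeg = if (!is.null(eeg)) as.numeric(eeg),
         sampling_rate = sampling_rate, pad = as.integer(pad),
         parent_id = as.character(parent_id)),
    class = "ssr_recording"
  )
}

#' @export
print.ssr_recording <- function(x, ...) {
  mods <- c(if (!is.null(x$emg)) "EMG", if (!is.null(x$eeg)) "EEG")
  n <- length(x$emg %||% x$eeg)
  cat(sprintf("<ssr_recording %s> %s '%s' [%s] %d samples @ %g Hz\n",
              x$id, x$kind, x$label, paste(mods, collapse = "+"),
              n, x$sampling_rate))
  invisible(x)
}

rec_length <- function(rec) length(rec$emg %||% rec$eeg)

rec_samples <- function(rec, modality) {
  x <- rec[[modality]]
  if (is.null(x))
    abort_validation("recording '", rec$id, "': modality '", modality, "' absent")
  x
}

#' Construct a corpus of recordings
#'
#' A corpus bundles recordings with the class vocabulary and a train/test
#' split assignment. Validation rejects any label (or any word of a sentence
#' label) outside the vocabulary, naming the offending recording.
#'
#' @param recordings list of [recording()] objects.
#' @param vocabulary ordered character vector of class names.
#' @param split named character vector `id -> "train"|"test"`; defaults to
#'   everything in train.
#' @return an object of class `ssr_corpus`.
#' @export
corpus <- function(recordings, vocabulary = default_vocabulary(), split = NULL) {
  ids <- vapply(recordings, `[[`, "", "id")
  if (anyDuplicated(ids))
    abort_validation("duplicate recording ids: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (rec in recordings) {
    words <- if (rec$kind == "sentence") label_words(rec$label) else rec$label
    bad <- setdiff(words, vocabulary)
    if (length(bad))
      abort_validation("recording '", rec$id, "': label word(s) not in vocabulary: ",
                       paste(bad, collapse = ", "))
  }
  if (is.null(split)) {
    split <- rep("train", length(ids))
    names(split) <- ids
  }
  if (!all(split %in% c("train", "test")))
    abort_validation("split assignments must be 'train' or 'test'")
  if (!all(ids %in% names(split)))
    abort_validation("split assignment missing for some recordings")
  names(recordings) <- ids
  structure(list(recordings = recordings, vocabulary = vocabulary,
                 split = split[ids]),
            class = "ssr_corpus")
}

#' @export
print.ssr_corpus <- function(x, ...) {
  kinds <- table(vapply(x$recordings, `[[`, "", "kind"))
  cat(sprintf("<ssr_corpus> %d recordings (%s); vocabulary of %d classes; %d train / %d test\n",
              length(x$recordings),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              length(x$vocabulary),
              sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

corpus_ids <- function(corp, split = NULL, kind = NULL, experimental_only = FALSE) {
  ids <- names(corp$recordings)
  if (!is.null(split)) ids <- ids[corp$split[ids] == split]
  if (!is.null(kind))
    ids <- ids[vapply(corp$recordings[ids], `[[`, "", "kind") %in% kind]
  if (experimental_only)
    ids <- ids[is.na(vapply(corp$recordings[ids], `[[`, "", "parent_id"))]
  ids
}

#' Write a corpus to a directory
#'
#' Emits a tab-separated manifest (`manifest.tsv`) plus one single-column
#' amplitude CSV per modality per recording. Amplitudes are written with 17
#' significant digits so that [read_corpus()] round-trips values exactly.
#' The vocabulary is recorded on a `# vocabulary:` comment line at the top of
#' the manifest.
#'
#' @param corp an `ssr_corpus`.
#' @param dir output directory (created if missing).
#' @return path to the written manifest, invisibly usable by [read_corpus()].
#' @export
write_corpus <- function(corp, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop("cannot write to directory: ", dir, call. = FALSE)
  write_sig <- function(x, path) {
    writeLines(c("amplitude", sprintf("%.17g", x)), path)
  }
  rows <- lapply(corp$recordings, function(rec) {
    emg_file <- eeg_file <- ""
    if (!is.null(rec$emg)) {
      emg_file <- paste0(rec$id, "_emg.csv")
      write_sig(rec$emg, file.path(dir, emg_file))
    }
    if (!is.null(rec$eeg)) {
      eeg_file <- paste0(rec$id, "_eeg.csv")
      write_sig(rec$eeg, file.path(dir, eeg_file))
    }
    data.frame(id = rec$id, kind = rec$kind, label = rec$label,
               sampling_rate = rec$sampling_rate,
               emg_file = emg_file, eeg_file = eeg_file,
               split = unname(corp$split[rec$id]),
               pad = rec$pad, parent_id = rec$parent_id,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), kind = character(), label = character(),
               sampling_rate = numeric(), emg_file = character(),
               eeg_file = character(), split = character(),
               pad = integer(), parent_id = character())
  path <- file.path(dir, "manifest.tsv")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# vocabulary: ", paste(corp$vocabulary, collapse = " ")), con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a corpus from a manifest
#'
#' Parses the manifest written by [write_corpus()]: a tab-separated table with
#' columns `id`, `kind`, `label`, `sampling_rate`, `emg_file`, `eeg_file` and
#' optional `split`, `pad`, `parent_id` columns. Referenced files are
#' single-column CSVs of amplitudes (optional `amplitude` header). A missing
#' or empty modality file yields an absent modality.
#'
#' @param manifest_path path to the manifest TSV.
#' @param vocabulary vocabulary override; by default taken from the manifest's
#'   `# vocabulary:` header line, falling back to [default_vocabulary()].
#' @return an `ssr_corpus`.
#' @export
read_corpus <- function(manifest_path, vocabulary = NULL) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  first <- readLines(manifest_path, n = 1L)
  if (is.null(vocabulary) && startsWith(first, "# vocabulary:"))
    vocabulary <- label_words(trimws(sub("# vocabulary:", "", first, fixed = TRUE)))
  manifest <- utils::read.delim(manifest_path, sep = "\t", comment.char = "#",
                                stringsAsFactors = FALSE,
                                colClasses = c(id = "character", label = "character"))
  dir <- dirname(manifest_path)
  read_sig <- function(f) {
    if (is.na(f) || !nzchar(f)) return(NULL)
    path <- file.path(dir, f)
    if (!file.exists(path)) return(NULL)
    lines <- readLines(path)
    if (length(lines) && identical(lines[1L], "amplitude")) lines <- lines[-1L]
    as.numeric(lines)
  }
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    recording(id = row$id, kind = row$kind, label = row$label,
              emg = read_sig(row$emg_file), eeg = read_sig(row$eeg_file),
              sampling_rate = row$sampling_rate,
              pad = if ("pad" %in% names(manifest)) row$pad else 0L,
              parent_id = if ("parent_id" %in% names(manifest))
                row$parent_id else NA_character_)
  })
  split <- if ("split" %in% names(manifest) && nrow(manifest)) {
    s <- manifest$split; names(s) <- manifest$id; s
  }
  corpus(recs, vocabulary = vocabulary %||% default_vocabulary(), split = split)
}
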