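---
title: "Methods: few-shot sentence decoding from single-channel EMG and EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: few-shot sentence decoding from single-channel EMG and EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Silent speech recognition (SSR) decodes intended speech from non-acoustic
biosignals. This package implements a complete sentence-level SSR pipeline
for the hardest practical configuration: a *single* EMG channel (tongue
muscle activity) and a *single* EEG channel (scalp neural activity), both
sampled at 4096 Hz, a ten-word command vocabulary drawn from four fixed
command phrases, and only a handful of labeled examples per word.

Three difficulties shape the design:

1. **Data scarcity.** Biosignal corpora are small; conventional classifiers
   overfit. The pipeline therefore uses *few-shot metric learning*: a
   Siamese encoder maps signals into an embedding space and classification
   reduces to distance against 5 stored reference recordings ("shots") per
   class.
2. **Coarticulation.** In continuous speech, adjacent words blend: the
   signal near a word boundary is not the concatenation of the isolated
   word signals. A model trained only on isolated words collapses on
   sentences; the pipeline recovers by *moving-window retraining* on
   sentence recordings.
3. **Residual word errors.** Even the retrained decoder inserts or
   substitutes words. A trigram language model over the command phrases
   re-ranks candidate sentences and corrects most such errors.

# Pipeline overview

The three evaluation stages mirror the experimental protocol the package
reproduces:

* **Model A** — Siamese encoder contrastively pretrained on isolated-word
  recordings (Corpus A: 150 repetitions x 10 words, plus a noise class).
* **Model B** — Model A further trained on windows cut from continuous
  sentence recordings (Corpus B: 100 repetitions x 4 phrases) with
  positional ground-truth labels.
* **Model C** — Model B plus trigram-LM correction of the decoded word
  sequence.

```{r}
library(silentspeech)
report <- run_experiment(experiment_config(seed = 1))
report$accuracy
```

# The Siamese encoder

Both Siamese branches are literally the same function (shared weights), so
the package implements a single encoder \(f_\theta\). For an input window
\(x \in \mathbb{R}^{700}\) per modality:

1. **Front-end decimation.** Non-overlapping average pooling by a
   per-modality factor (EMG 2, EEG 8). At 4096 Hz a kernel-7 convolution
   spans only 1.7 ms; EMG content reaches ~450 Hz but EEG content lives at
   1–40 Hz, where the undecimated conv stack's ~10 ms receptive field sees
   essentially nothing. Decimating EEG by 8 (to 512 Hz, still far above
   Nyquist for a 40 Hz band) widens the receptive field to the slow-wave
   time scale; it also averages broadband noise down by \(\sqrt{8}\).
   Without this, the EEG branch plateaued ~35 points below the EMG branch
   on the synthetic benchmark.
2. **Conv blocks.** Three blocks of (1-D convolution, kernel 7, padding 3 →
   ReLU → width-2 average pooling), channel widths 6/12/24. Kernel and
   padding preserve length; pooling halves it.
3. **Temporal pooling.** Adaptive average pooling to 8 temporal bins, then
   flattening. A single global average was tried first and discarded: it
   destroys the coarse temporal envelope that distinguishes the word
   classes, and could not reach usable word accuracy. Eight bins keep a
   sketch of the envelope while remaining robust to the ±10% time warp and
   window misalignment the task contains.
4. **Projection.** A linear map to a 64-dimensional embedding, followed by
   L2 normalization, so cosine distance \(d(a,b) = 1 - \langle a,b\rangle\)
   is the natural metric.

The fusion encoder runs one such branch per modality, concatenates the two
pooled feature vectors and applies a shared multi-layer head (one hidden
layer of 128 units, ReLU) before the final projection — a direct reading of
"parallel multi-layer" sensor fusion. It refuses to run with a missing
modality rather than silently degrading to unimodal.

# Contrastive training

Training pairs are (anchor, reference): anchors are train-split recordings
(or sentence windows during retraining), references are the 55 stored
shots. With match label \(y \in \{0,1\}\) and margin \(m = 1\):

\[ L = y\, d^2 + (1-y)\, \max(0, m - d)^2 . \]

Design choices worth recording:

* **Semi-hard negative mining.** All 55 reference embeddings are computed
  in every batch anyway, so a mismatched pair uses the *closest*
  wrong-class reference rather than a random one. This costs nothing and
  roughly halves the steps to convergence; with random negatives the EEG
  branch did not reach its plateau within the step budgets below.
* **Reference selection.** The 5 shots per class are the train recordings
  with the highest mean raw-signal cosine similarity to their classmates
  (a medoid-like, deterministic, seed-free criterion). Augmented variants
  are never eligible, and the selected recordings are excluded from the
  anchor pool.
* **Optimizer.** Adam, lr 3e-3 for pretraining (5 epochs x 1024 pairs,
  batch 128) and 5e-3 for retraining (8 epochs x 1536 pairs). These budgets
  were sized so a full three-modality experiment runs in ~2 minutes on one
  CPU core while all benchmark orderings hold with margin; they are config,
  not architecture.
* **Confidence.** The distance-based classifier does not emit
  probabilities; a softmax over \(-\bar d_c / \tau\) (temperature
  \(\tau = 0.1\)) converts per-class average distances \(\bar d_c\) into
  the confidences the LM stage combines.

# Moving-window segmentation

Windows of width \(W = 700\) samples slide with stride \(S = 380\)
(overlapping, so transitions are preserved); starts are \(0, S, 2S, \dots\)
while \(start + W \le L\), all coordinates 0-based half-open. Ground truth
for retraining assumes evenly spaced words: the speech span (total length
minus the known leading/trailing pad) is divided into one equal interval
per word; a window takes the label of the word interval it overlaps most
(ties to the earlier word), or `NOISE` when no overlap reaches half the
window. Whether the evenly-spaced intervals should include the silent
padding was genuinely open; the package excludes the pad (the generator
records it on each recording) and treats pad-only windows as noise, which
is also what the noise class exists for. At decode time, per-window top-1
predictions drop `NOISE` and collapse adjacent repeats.

# Trigram language model

Counts over the four command phrases with doubled start tokens and an end
token; add-k smoothing (k = 0.01) at query time:

\[ P(w \mid h) = \frac{c(h,w) + k}{c(h) + k\,(V + 1)} \]

with the predicted event ranging over the 10-word vocabulary plus the end
token, so every conditional sums to one exactly. Add-k was chosen over
backoff schemes because a 10-word closed vocabulary gains nothing from
them and add-k is exactly checkable against a counting oracle.

Correction enumerates all paths through the per-window top-3 non-noise
candidates, collapses repeats, discards paths containing a trigram that is
both unseen (raw count 0) and improbable after smoothing
(below 0.02), keeps the top K = 5 sequences by length-normalized LM score,
and picks the maximizer of the combined confidence

\[ \mathrm{comb} = \frac{\lambda\,\log P_{LM} + (1-\lambda) \sum_w \log
   p_{SNN}(w)}{n_{words}}, \qquad \lambda = 0.5 . \]

Ties break by LM score, then lexicographically. If everything is pruned the
uncorrected sequence is returned, flagged. The exact mixture, \(\lambda\),
K and the pruning rule are not dictated by the underlying study; they are
exposed in the experiment config.

# The synthetic test bed

The generator emulates the two study corpora so the full pipeline is
testable without the (externally hosted) recordings:

* Each word class is a fixed band-limited template: 12 random-phase
  sinusoids, EMG-like content in 20–450 Hz, EEG-like in 1–40 Hz, unit RMS.
* An instance is the template scaled by \(1 \pm 0.15\) amplitude jitter,
  linearly time-warped by \(\pm 10\%\), plus white Gaussian noise
  (sd 0.35 by default, per-modality configurable).
* Sentences overlap-add word instances with a 150-sample linear crossfade
  — the simplest mechanism with the defining coarticulation property that
  concatenating isolated words does not reconstruct the sentence — and are
  padded with 300 samples of pure noise at both ends.
* Default sizes follow the study corpora: 150 repetitions per word
  (including the noise class) and 100 per sentence, with a stratified
  70/30 train/test split; 800-sample words (~0.2 s at 4096 Hz) keep the
  700-sample window smaller than a word.
* The fusion benchmark sets per-modality noise to sd 2.0 (EMG) and 7.0
  (EEG): both unimodal models then err materially with independent errors,
  and the asymmetry compensates the EEG branch's noise-averaging
  decimation so effective SNRs are comparable.

What the generator does *not* emulate: motor-unit physiology, 1/f EEG
spectra, electrode artifacts (blinks, motion), session drift, or speaker
variability. Passing on this test bed shows the pipeline's machinery is
correct and its orderings (degradation on sentences, recovery by window
retraining, LM benefit, fusion benefit) are reproducible — it does not
certify accuracy figures on real recordings.

# Numerical and degenerate-input choices

* Amplitudes serialize with 17 significant digits, so corpus round-trips
  are value-exact.
* Windows are z-scored per modality before encoding; constant windows map
  to zero rather than dividing by zero. Embedding norms are floored at
  1e-12 before normalization.
* Trailing samples shorter than one window are discarded; a recording
  shorter than one window is an error.
* With k = 0 the LM returns \(-\infty\) for unseen transitions, matching
  the counting oracle.
* Augmented variants are restored to their parent's length (mean-padding
  or centre-cropping) so window labeling and the fixed-size encoder input
  stay valid; both modalities of a pair always receive the same operator
  chain.
* All randomness flows from explicit integer seeds through isolated RNG
  scopes; identical seeds give bit-identical corpora, models and reports.

# Benchmark sizes

The packaged tests run the full three-modality experiment at the default
corpus sizes over five seeds, the noisy-SNR fusion benchmark over the same
five seeds, and unit tests on miniature corpora (words of 120 samples,
windows of 100). A single-seed full experiment takes roughly two minutes on
one CPU core; `scripts/acceptance.R` re-runs one full experiment plus the
fusion benchmark and the language-model checks at whatever seed it is
given.

# Known limitations

* The positional labels for retraining are only as good as the
  evenly-spaced-words assumption; strongly uneven word durations would
  mislabel boundary windows (the augmentation absorbs modest warp only).
* The per-window decoder has no sequence model at decode time (no
  HMM/CTC-style alignment); everything sequential is delegated to the
  trigram LM over a closed four-phrase grammar.
* The LM is trained on the same four phrases it corrects toward; with an
  open vocabulary its corrections would be far weaker. The count corpus is
  pluggable for that reason.
* The fusion head is one literal reading of parallel multi-layer fusion;
  attention-based or decision-level fusion variants are out of scope.
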