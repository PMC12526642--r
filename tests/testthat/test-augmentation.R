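test_that("shift_pad fills vacated samples with the pre-shift mean", {
  expect_identical(shift_pad(c(1, 2, 3, 4), 0), c(1, 2, 3, 4))
  expect_equal(shift_pad(c(1, 2, 3, 4), 2), c(2.5, 2.5, 1, 2))
  expect_equal(shift_pad(c(1, 2, 3, 4), -1), c(2, 3, 4, 2.5))
  expect_error(shift_pad(c(1, 2, 3), 3), "smaller than")
  expect_error(shift_pad(c(1, 2, 3), -5), "smaller than")
  # length preserved; retained samples unchanged; constant stays constant
  x <- rnorm(50)
  y <- shift_pad(x, 7)
  expect_length(y, 50)
  expect_identical(y[8:50], x[1:43])
  expect_identical(shift_pad(rep(3, 10), 4), rep(3, 10))
})

test_that("crop returns the half-open 0-based slice", {
  expect_identical(crop(c(1, 2, 3, 4), 0, 4), c(1, 2, 3, 4))
  expect_identical(crop(c(1, 2, 3, 4), 1, 2), c(2, 3))
  expect_error(crop(c(1, 2, 3, 4), 1, 0), ">= 1")
  expect_error(crop(c(1, 2, 3, 4), 2, 3), "out of range")
})

test_that("resample_linear interpolates linearly and keeps endpoints", {
  expect_identical(resample_linear(c(0, 1), 2), c(0, 1))
  expect_equal(resample_linear(c(0, 1), 3), c(0, 0.5, 1))
  expect_equal(resample_linear(c(0, 2, 4), 2), c(0, 4))
  expect_error(resample_linear(c(0, 1), 1), "target_length")
  expect_error(resample_linear(c(1), 3), "at least 2")
  # exact on affine signals for any target length
  x <- 2.5 * (0:19) - 3
  for (n in c(5, 13, 20, 41)) {
    y <- resample_linear(x, n)
    expect_equal(y, seq(x[1], x[20], length.out = n))
  }
})

test_that("augment_corpus extends only the train split, deterministically", {
  set.seed(3)
  recs <- lapply(1:12, function(i)
    recording(sprintf("w%02d", i), "word", "Alpha", emg = rnorm(60),
              eeg = rnorm(60)))
  split <- c(rep("train", 10), rep("test", 2))
  names(split) <- sprintf("w%02d", 1:12)
  corp <- corpus(recs, vocabulary = c("Alpha", "NOISE"), split = split)
  plan <- augment_plan(per_recording_count = 3L, seed = 9L)
  aug <- augment_corpus(corp, plan)
  expect_length(aug$recordings, 12 + 10 * 3)
  new_ids <- setdiff(names(aug$recordings), names(corp$recordings))
  expect_true(all(aug$split[new_ids] == "train"))
  parents <- vapply(aug$recordings[new_ids], `[[`, "", "parent_id")
  expect_true(all(parents %in% sprintf("w%02d", 1:10)))  # no test parents
  # augmented variants keep the original length and both modalities
  for (id in new_ids) {
    expect_length(aug$recordings[[id]]$emg, 60)
    expect_length(aug$recordings[[id]]$eeg, 60)
  }
  expect_identical(augment_corpus(corp, plan)$recordings[new_ids],
                   aug$recordings[new_ids])
  expect_identical(augment_corpus(corp, augment_plan(per_recording_count = 0L)),
                   corp)
})

test_that("paired modalities receive the same operator chain", {
  # identical EMG and EEG signals must stay identical after augmentation
  rec <- recording("w1", "word", "Alpha", emg = sin(1:80), eeg = sin(1:80))
  corp <- corpus(list(rec), vocabulary = c("Alpha", "NOISE"))
  aug <- augment_corpus(corp, augment_plan(per_recording_count = 4L, seed = 1L))
  for (id in setdiff(names(aug$recordings), "w1"))
    expect_identical(aug$recordings[[id]]$emg, aug$recordings[[id]]$eeg)
})
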