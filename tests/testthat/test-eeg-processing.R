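test_that("band-pass filter preserves in-band tones, kills DC and stopband", {
  rec <- tone_recording(freqs = c(10, 60), amps = c(20, 15), dur = 4)
  rec$samples <- rec$samples + 50  # DC offset
  out <- bandpass_filter(rec, 1, 45)
  a10_in <- fft_amplitude(rec$samples[1, ] - 50, 10, 512)
  a10_out <- fft_amplitude(out$samples[1, ], 10, 512)
  expect_equal(a10_out / a10_in, 1, tolerance = 0.02)
  expect_lt(abs(mean(out$samples[1, ])), 0.5)
  a60 <- fft_amplitude(out$samples[1, ], 60, 512)
  expect_lt(20 * log10(a60 / 15), -20)
  expect_error(bandpass_filter(rec, 1, 400), "rate")
})

test_that("filtering is zero-phase for an in-band tone", {
  rec <- tone_recording(freqs = 10, amps = 30, dur = 2)
  out <- bandpass_filter(rec, 1, 45)
  cc <- stats::ccf(as.numeric(rec$samples[1, ]), as.numeric(out$samples[1, ]),
                   lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("rejection masks exactly the offending windows and is monotone", {
  rec <- tone_recording(freqs = 10, amps = 40, dur = 5)
  clean <- reject_bad_segments(rec, 100)
  expect_equal(sum(clean$mask$bad), 0L)
  spiked <- rec
  spiked$samples[1, round(2.3 * 512)] <- 150
  got <- reject_bad_segments(spiked, 100)
  expect_equal(which(got$mask$bad), 3L)   # the window covering t = 2.3 s
  # monotone: lowering the threshold can only add masked windows
  set.seed(12)
  noisy <- rec
  noisy$samples <- noisy$samples + matrix(rnorm(length(rec$samples), 0, 30),
                                          nrow = 1)
  m_strict <- which(reject_bad_segments(noisy, 60)$mask$bad)
  m_loose <- which(reject_bad_segments(noisy, 90)$mask$bad)
  expect_true(all(m_loose %in% m_strict))
  expect_error(reject_bad_segments(rec, -5), "> 0")
})

test_that("component cleanup removes a templated blink and spares clean data", {
  set.seed(5)
  n <- 4096
  t <- (0:(n - 1)) / 512
  signal <- 30 * sin(2 * pi * 10 * t)
  blink <- rep(0, n)
  for (s in seq(300, n - 300, by = 700)) blink[s:(s + 80)] <- 120 * sin(pi * (0:80) / 80)
  rec <- make_eeg_recording(rbind(signal + 0.1 * blink, signal * 0.6 + blink),
                            c("F3", "F4"), 512)
  out <- remove_artifact_components(rec, template = blink)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_lt(abs(cor(out$samples[1, ], blink)), 0.1)
  expect_lt(abs(cor(out$samples[2, ], blink)), 0.1)
  # signal content survives
  expect_gt(fft_amplitude(out$samples[1, ], 10, 512), 20)

  # nothing flagged: output ~= input
  rec2 <- make_eeg_recording(rbind(signal, 20 * sin(2 * pi * 17 * t + 1)),
                             c("F3", "F4"), 512)
  out2 <- remove_artifact_components(rec2)
  expect_equal(attr(out2, "n_removed"), 0L)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out2$samples - rec2$samples) / rms(rec2$samples), 0.05)

  # degenerate single channel: unchanged with warning
  rec1 <- make_eeg_recording(matrix(signal, 1), "Fz", 512)
  expect_warning(out1 <- remove_artifact_components(rec1), "single-channel")
  expect_identical(out1$samples, rec1$samples)
  expect_error(remove_artifact_components(rec2, n_components = 5), "exceeds")
})

test_that("average re-referencing zeroes the channel mean per sample", {
  a <- sin(2 * pi * 7 * (0:99) / 512)
  rec <- make_eeg_recording(rbind(a, -a), c("F3", "F4"), 512)
  out <- rereference_average(rec)
  expect_equal(out$samples, rec$samples, ignore_attr = TRUE)
  rec2 <- make_eeg_recording(matrix(c(1, 3), 2, 50), c("C3", "C4"), 512)
  out2 <- rereference_average(rec2)
  expect_equal(unname(out2$samples[, 1]), c(-1, 1))
  set.seed(3)
  rec4 <- make_eeg_recording(matrix(rnorm(4 * 200), 4), c("F3", "F4", "P3", "P4"), 512)
  out4 <- rereference_average(rec4)
  expect_lt(max(abs(colMeans(out4$samples))), 1e-10)
  expect_error(rereference_average(make_eeg_recording(matrix(0, 1, 10), "Cz", 512)),
               "skip")
})

test_that("epoching extracts, baselines, and skips edge/masked events", {
  fs <- 512
  rec <- make_eeg_recording(matrix(5, 1, fs * 6), "Cz", fs,
                            events = data.frame(sample = c(10, 1024, 2048, 2560),
                                                scene_id = c("e", "a", "b", "c"),
                                                repeat_idx = 1))
  expect_message(ep <- epoch_and_baseline(rec), "skipped at the record edge")
  expect_equal(ep$n_skipped_edge, 1L)
  expect_equal(dim(ep$epochs), c(3L, 1L, round(1.2 * fs)))
  expect_true(all(abs(ep$epochs) < 1e-12))  # constant channel zeroed by baseline
  expect_equal(ep$trials$scene_id, c("a", "b", "c"))
  # a masked window drops the overlapping epoch with a count
  rec$samples[1, 1040] <- 500
  rec <- reject_bad_segments(rec, 100)
  expect_message(ep2 <- epoch_and_baseline(rec))
  expect_equal(ep2$n_dropped_mask, 1L)
  expect_equal(ep2$trials$scene_id, c("b", "c"))
})

test_that("band power matches analytic tone ratios and flat-spectrum bin counts", {
  fs <- 512
  t <- (0:(fs * 4 - 1)) / fs
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 20 * t)
  rec <- make_eeg_recording(matrix(x, 1), "Cz", fs,
                            events = data.frame(sample = c(150, 800, 1400),
                                                scene_id = c("a", "b", "c"),
                                                repeat_idx = 1))
  ep <- epoch_and_baseline(rec, c(-200, 1000), c(-200, 0))
  bp <- band_power(ep, c(8, 12), c(13, 28))
  expect_equal(bp$p_alpha_all / bp$p_beta_all, rep(4, 3), tolerance = 0.02)
  # pure alpha tone: nothing in beta
  x2 <- sin(2 * pi * 10 * t)
  rec2 <- make_eeg_recording(matrix(x2, 1), "Cz", fs,
                             events = data.frame(sample = 600, scene_id = "a",
                                                 repeat_idx = 1))
  bp2 <- band_power(epoch_and_baseline(rec2), c(8, 12), c(13, 28))
  expect_lt(bp2$p_beta_all / bp2$p_alpha_all, 0.01)
  # white noise: mean band powers in the bin-count ratio 5/16 (flat spectrum)
  set.seed(9)
  n_ep <- 1000
  pa <- numeric(n_ep); pb <- numeric(n_ep)
  for (k in seq_len(n_ep)) {
    xr <- rnorm(round(1.5 * fs))
    recr <- make_eeg_recording(matrix(xr, 1), "Cz", fs,
                               events = data.frame(sample = 110, scene_id = "w",
                                                   repeat_idx = 1))
    bpr <- band_power(epoch_and_baseline(recr), c(8, 12), c(13, 28))
    pa[k] <- bpr$p_alpha_all; pb[k] <- bpr$p_beta_all
  }
  expect_equal(mean(pa) / mean(pb), 5 / 16, tolerance = 0.05)
  expect_error(band_power(ep, c(8.2, 8.4), c(13, 28)), "resolution")
})

test_that("band power is invariant to channel order and global sign flip", {
  set.seed(14)
  x <- matrix(rnorm(2 * 1024), 2)
  ev <- data.frame(sample = 300, scene_id = "s", repeat_idx = 1)
  bp_fwd <- band_power(epoch_and_baseline(
    make_eeg_recording(x, c("F3", "F4"), 512, ev)))
  bp_rev <- band_power(epoch_and_baseline(
    make_eeg_recording(x[2:1, ], c("F4", "F3"), 512, ev)))
  expect_equal(bp_fwd$p_alpha_all, bp_rev$p_alpha_all, tolerance = 1e-12)
  expect_equal(bp_fwd$p_alpha_left, bp_rev$p_alpha_left, tolerance = 1e-12)
  bp_neg <- band_power(epoch_and_baseline(
    make_eeg_recording(-x, c("F3", "F4"), 512, ev)))
  expect_equal(bp_fwd$p_alpha_all, bp_neg$p_alpha_all, tolerance = 1e-12)
})

test_that("end-to-end raw pipeline recovers targets within 2% for all trials", {
  bp <- bp_table(al = c(2, 5, 3.5), ar = c(4, 5, 2.5),
                 scene = c("s1", "s2", "s3"), rep_idx = rep(1, 3))
  cfg <- pipeline_config()
  rec <- synthesize_raw_eeg(bp, cfg)
  out <- preprocess_pipeline(rec, cfg)
  expect_equal(out$p_alpha_all / out$p_beta_all, (bp$p_alpha_left + bp$p_alpha_right) / 2,
               tolerance = 0.02)
  expect_equal(out$p_alpha_right / out$p_beta_right - out$p_alpha_left / out$p_beta_left,
               bp$p_alpha_right - bp$p_alpha_left, tolerance = 0.02)
})
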