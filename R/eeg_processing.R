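#' Construct an EEG recording
#'
#' Hemisphere tags are inferred from 10-20 electrode names: a recognized site
#' prefix followed by an odd digit is left, an even digit right, and a
#' trailing `z` midline. Unknown labels are an error unless an explicit
#' `hemispheres` override is supplied.
#'
#' @param samples numeric matrix, channels x time, in uV.
#' @param labels channel labels.
#' @param rate sampling rate in Hz.
#' @param events optional data.frame with `sample` (1-based index of the
#'   scene-onset sample), `scene_id`, and `repeat_idx`.
#' @param hemispheres optional named character vector overriding inference,
#'   values in `left`, `right`, `midline`.
#' @return object of class `landemo_eeg`.
#' @export
make_eeg_recording <- function(samples, labels, rate, events = NULL,
                               hemispheres = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(labels) != nrow(samples))
    stop("one label per channel row required")
  if (rate <= 0) stop("sampling rate must be > 0")
  hemi <- infer_hemisphere(labels, hemispheres)
  if (!is.null(events)) {
    events <- as.data.frame(events)
    if (!all(c("sample", "scene_id") %in% names(events)))
      stop("events need 'sample' and 'scene_id' columns")
    if (is.null(events$repeat_idx)) events$repeat_idx <- 1L
    if (any(events$sample < 1 | events$sample > ncol(samples)))
      stop("event sample index beyond record end")
    events <- events[order(events$sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(samples = samples, labels = labels, hemisphere = hemi,
                 rate = rate, events = events, mask = NULL),
            class = "landemo_eeg")
}

#' @export
print.landemo_eeg <- function(x, ...) {
  cat("<landemo_eeg> ", nrow(x$samples), " channel(s) x ", ncol(x$samples),
      " samples @ ", x$rate, " Hz; ",
      if (is.null(x$events)) 0L else nrow(x$events), " events",
      if (!is.null(x$mask)) paste0("; ", sum(x$mask$bad), " masked window(s)"),
      "\n", sep = "")
  invisible(x)
}

infer_hemisphere <- function(labels, override = NULL) {
  out <- character(length(labels))
  prefixes <- "Fp|AF|FC|FT|CP|TP|PO|F|C|T|P|O"
  pat <- paste0("^(", prefixes, ")([0-9]{1,2}|z)$")
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (!is.null(override) && lab %in% names(override)) {
      out[i] <- match.arg(override[[lab]], c("left", "right", "midline"))
      next
    }
    m <- regmatches(lab, regexec(pat, lab, ignore.case = TRUE))[[1]]
    if (!length(m))
      stop("cannot infer hemisphere for channel '", lab,
           "'; supply a hemispheres override (left/right/midline)")
    suffix <- tolower(m[3])
    out[i] <- if (suffix == "z") "midline"
    else if (as.integer(suffix) %% 2L == 1L) "left" else "right"
  }
  out
}

#' Zero-phase FFT band-pass filter
#'
#' Filters each channel in the frequency domain with a unit-gain passband and
#' raised-cosine transitions of `transition` Hz directly below `low` and above
#' `high`. Being applied symmetrically to the spectrum, the filter has exactly
#' zero phase (no group delay); the DC bin is always removed.
#'
#' @param rec a `landemo_eeg`.
#' @param low,high band edges in Hz; `0 < low < high < rate/2` required.
#' @param transition transition width in Hz (default 1).
#' @return filtered `landemo_eeg`.
#' @export
bandpass_filter <- function(rec, low, high, transition = 1) {
  fs <- rec$rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band for rate ", fs, ": need 0 < low < high < rate/2")
  n <- ncol(rec$samples)
  freq <- (0:(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  g <- numeric(n)
  g[freq >= low & freq <= high] <- 1
  lo0 <- max(low - transition, 0)
  rise <- freq >= lo0 & freq < low
  g[rise] <- 0.5 * (1 - cos(pi * (freq[rise] - lo0) / (low - lo0)))
  fall <- freq > high & freq <= high + transition
  g[fall] <- 0.5 * (1 + cos(pi * (freq[fall] - high) / transition))
  g[1] <- 0  # DC
  out <- rec
  out$samples <- t(apply(rec$samples, 1L, function(x) {
    Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  }))
  out
}

#' Mask windows containing over-threshold samples
#'
#' The record is tiled with fixed, non-overlapping 1-s windows; any window in
#' which any channel exceeds `threshold` uV in absolute value is masked (not
#' deleted). The mask propagates to epoching, where overlapping epochs are
#' dropped.
#'
#' @param rec a `landemo_eeg`.
#' @param threshold absolute amplitude threshold in uV (> 0).
#' @return the recording with `$mask` set: a list with `window` (samples per
#'   window), `bad` (logical per window), `threshold`.
#' @export
reject_bad_segments <- function(rec, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  win <- round(rec$rate)
  n <- ncol(rec$samples)
  n_win <- ceiling(n / win)
  bad <- logical(n_win)
  peak <- apply(abs(rec$samples), 2L, max)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * win + 1):min(w * win, n)
    bad[w] <- any(peak[idx] > threshold)
  }
  rec$mask <- list(window = win, bad = bad, threshold = threshold)
  rec
}

#' Remove artifact components by statistical-independence decomposition
#'
#' Channels are whitened and rotated to maximally independent components
#' (fixed-point symmetric ICA with a tanh contrast). A component is flagged as
#' artifact if its time course correlates with a supplied template beyond
#' `cor_threshold` in absolute value, or (with no template) if its excess
#' kurtosis exceeds `kurtosis_bound`. Flagged components are zeroed before
#' back-projection. With fewer than two channels the operation is a no-op
#' with a warning.
#'
#' @param rec a `landemo_eeg`.
#' @param n_components number of components (default: channel count).
#' @param template optional artifact reference time course (length = samples).
#' @param cor_threshold absolute correlation flag threshold (default 0.8).
#' @param kurtosis_bound excess-kurtosis flag threshold (default 5).
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed seed for the rotation initialization.
#' @return cleaned `landemo_eeg`; flagged component count in
#'   `attr(, "n_removed")`.
#' @export
remove_artifact_components <- function(rec, n_components = NULL,
                                       template = NULL, cor_threshold = 0.8,
                                       kurtosis_bound = 5, max_iter = 200,
                                       tol = 1e-6, seed = 1L) {
  X <- rec$samples
  p <- nrow(X)
  if (p < 2L) {
    warning("single-channel recording: independent-component cleanup skipped")
    return(rec)
  }
  if (is.null(n_components)) n_components <- p
  if (n_components > p) stop("n_components exceeds channel count")
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(X)
  C <- Xc %*% t(Xc) / n
  eig <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_components)
  K <- diag(1 / sqrt(eig$values[keep]), n_components) %*% t(eig$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  W <- with_stage_seed(seed, 505L,
    qr.Q(qr(matrix(stats::rnorm(n_components^2), n_components))))
  sym_decorrelate <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(gprime, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    if (max(abs(abs(rowSums(W1 * W)) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  S <- W %*% Z
  flagged <- logical(n_components)
  if (!is.null(template)) {
    if (length(template) != n) stop("template length must equal sample count")
    r <- apply(S, 1L, function(s) stats::cor(s, template))
    flagged <- abs(r) > cor_threshold
  } else {
    kurt <- apply(S, 1L, function(s) mean((s - mean(s))^4) / stats::var(s)^2 - 3)
    flagged <- kurt > kurtosis_bound
  }
  M <- W %*% K                      # unmixing: S = M Xc
  A <- solve(M)                     # mixing (square case)
  S[flagged, ] <- 0
  out <- rec
  out$samples <- A %*% S + mu
  dimnames(out$samples) <- dimnames(rec$samples)
  attr(out, "n_removed") <- sum(flagged)
  out
}

#' Re-reference to the average of all electrodes
#'
#' @param rec a `landemo_eeg` with at least two channels.
#' @return recording whose per-sample channel mean is zero.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$samples) < 2L)
    stop("average reference needs >= 2 channels; skip re-referencing for ",
         "single-channel records")
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples), "-")
  rec
}

#' Epoch around scene onsets and baseline-correct
#'
#' Extracts windows of `window` ms around each event (onset = time zero) and
#' subtracts, per epoch and channel, the mean over the `baseline` ms
#' sub-window. Epochs that would cross the record edge are skipped with a
#' count, as are epochs overlapping a rejection-mask window.
#'
#' @param rec a `landemo_eeg` with events (and optionally a mask from
#'   [reject_bad_segments()]).
#' @param window length-2 ms pair (default c(-200, 1000)).
#' @param baseline length-2 ms pair inside `window` (default c(-200, 0)).
#' @return object of class `landemo_epochs`: list with `epochs` (array trials
#'   x channels x samples), `rel` (sample offsets relative to onset), `rate`,
#'   `labels`, `hemisphere`, `trials` (scene/repeat labels), `n_skipped_edge`,
#'   `n_dropped_mask`.
#' @export
epoch_and_baseline <- function(rec, window = c(-200, 1000),
                               baseline = c(-200, 0)) {
  if (is.null(rec$events) || !nrow(rec$events))
    stop("recording has no events to epoch around")
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("baseline window must lie inside the epoch window")
  fs <- rec$rate
  i0 <- round(window[1] / 1000 * fs)
  i1 <- round(window[2] / 1000 * fs)
  rel <- i0:(i1 - 1L)
  b0 <- round(baseline[1] / 1000 * fs)
  b1 <- round(baseline[2] / 1000 * fs)
  base_sel <- rel >= b0 & rel < b1
  n <- ncol(rec$samples)
  p <- nrow(rec$samples)
  keep <- list(); lab <- list()
  n_edge <- 0L; n_mask <- 0L
  for (k in seq_len(nrow(rec$events))) {
    onset <- rec$events$sample[k]
    idx <- onset + rel
    if (idx[1] < 1L || idx[length(idx)] > n) {
      n_edge <- n_edge + 1L
      next
    }
    if (!is.null(rec$mask)) {
      wins <- unique((idx - 1L) %/% rec$mask$window + 1L)
      if (any(rec$mask$bad[wins])) {
        n_mask <- n_mask + 1L
        next
      }
    }
    ep <- rec$samples[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, base_sel, drop = FALSE])
    keep[[length(keep) + 1L]] <- ep
    lab[[length(lab) + 1L]] <- rec$events[k, c("scene_id", "repeat_idx")]
  }
  if (n_edge > 0L)
    message(n_edge, " epoch(s) skipped at the record edge")
  n_tr <- length(keep)
  epochs <- array(NA_real_, dim = c(n_tr, p, length(rel)))
  for (k in seq_len(n_tr)) epochs[k, , ] <- keep[[k]]
  trials <- if (n_tr) do.call(rbind, lab) else
    data.frame(scene_id = character(0), repeat_idx = integer(0))
  rownames(trials) <- NULL
  structure(list(epochs = epochs, rel = rel, rate = fs, labels = rec$labels,
                 hemisphere = rec$hemisphere, trials = trials,
                 n_skipped_edge = n_edge, n_dropped_mask = n_mask),
            class = "landemo_epochs")
}

#' Integrated alpha and beta band power per epoch and channel group
#'
#' The post-stimulus segment (relative samples >= 0) of each epoch is
#' Hann-windowed and Fourier-transformed; band power is the sum of one-sided
#' periodogram power over FFT bins whose center frequency lies in
#' `[low, high]` (closed), times the bin width (uV^2). Group values
#' (`left`, `right`, `all`) are the mean over the channels in the group;
#' midline channels contribute to `all` only.
#'
#' @param epochs a `landemo_epochs`.
#' @param alpha,beta Hz band pairs (defaults 8-12 and 13-28).
#' @return a `landemo_bandpower` data.frame, one row per trial.
#' @export
band_power <- function(epochs, alpha = c(8, 12), beta = c(13, 28)) {
  post <- epochs$rel >= 0
  nfft <- sum(post)
  fs <- epochs$rate
  df <- fs / nfft
  freqs <- (0:(nfft %/% 2)) * df
  sel_a <- which(freqs >= alpha[1] & freqs <= alpha[2])
  sel_b <- which(freqs >= beta[1] & freqs <= beta[2])
  if (!length(sel_a) || !length(sel_b))
    stop("a band contains no FFT bin at resolution ", signif(df, 4), " Hz")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
  wnorm <- sum(w^2)
  n_tr <- dim(epochs$epochs)[1]
  p <- dim(epochs$epochs)[2]
  band_tc <- matrix(NA_real_, n_tr, p)  # per-channel alpha
  band_tb <- matrix(NA_real_, n_tr, p)  # per-channel beta
  for (k in seq_len(n_tr)) {
    for (ch in seq_len(p)) {
      x <- epochs$epochs[k, ch, post] * w
      X <- stats::fft(x)[seq_along(freqs)]
      pxx <- 2 * Mod(X)^2 / (fs * wnorm)
      pxx[1] <- pxx[1] / 2
      if (nfft %% 2 == 0) pxx[length(pxx)] <- pxx[length(pxx)] / 2
      band_tc[k, ch] <- sum(pxx[sel_a]) * df
      band_tb[k, ch] <- sum(pxx[sel_b]) * df
    }
  }
  grp_mean <- function(m, sel) if (any(sel)) rowMeans(m[, sel, drop = FALSE]) else NA_real_
  left <- epochs$hemisphere == "left"
  right <- epochs$hemisphere == "right"
  bp <- data.frame(
    scene_id = epochs$trials$scene_id,
    repeat_idx = epochs$trials$repeat_idx,
    p_alpha_left = grp_mean(band_tc, left),
    p_beta_left = grp_mean(band_tb, left),
    p_alpha_right = grp_mean(band_tc, right),
    p_beta_right = grp_mean(band_tb, right),
    p_alpha_all = rowMeans(band_tc),
    p_beta_all = rowMeans(band_tb),
    stringsAsFactors = FALSE)
  attr(bp, "bands") <- list(alpha = alpha, beta = beta, resolution = df)
  class(bp) <- c("landemo_bandpower", "data.frame")
  bp
}

#' Preprocess a raw recording end to end
#'
#' Chains band-pass filtering, amplitude-threshold masking, optional
#' component cleanup, average re-referencing (only with more than two
#' channels: averaging a single left/right pair algebraically cancels the
#' hemispheric asymmetry the valence index measures), epoching with baseline
#' correction, and band-power extraction.
#'
#' @param rec a `landemo_eeg` with events.
#' @param config a `landemo_config`.
#' @param ica run component cleanup (default FALSE; the synthetic carriers
#'   need none).
#' @param rereference `"auto"` (default: only when > 2 channels), `TRUE`, or
#'   `FALSE`.
#' @return a `landemo_bandpower` data.frame.
#' @export
preprocess_pipeline <- function(rec, config = pipeline_config(), ica = FALSE,
                                rereference = "auto") {
  rec <- bandpass_filter(rec, config$bandpass[1], config$bandpass[2])
  rec <- reject_bad_segments(rec, config$amplitude_threshold)
  if (isTRUE(ica)) rec <- remove_artifact_components(rec)
  do_reref <- if (identical(rereference, "auto")) nrow(rec$samples) > 2L
              else isTRUE(rereference)
  if (do_reref) rec <- rereference_average(rec)
  ep <- epoch_and_baseline(rec, config$epoch_window, config$baseline_window)
  band_power(ep, config$alpha_band, config$beta_band)
}
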