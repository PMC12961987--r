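# Shared fixtures and the independent decision-model oracle.

# Literal, loop-by-loop transcription of the normalization / grey relational /
# entropy / VIKOR / obstacle formulas. Deliberately scalar and separate from
# the package's vectorized implementation.
oracle_decision <- function(X, directions, rho = 0.5, v = 0.5) {
  m <- nrow(X); k <- ncol(X)
  r <- matrix(0, m, k)
  for (j in 1:k) {
    lo <- min(X[, j]); hi <- max(X[, j])
    for (i in 1:m) {
      r[i, j] <- if (hi == lo) 0.5
      else if (directions[j] == "benefit") (X[i, j] - lo) / (hi - lo)
      else (hi - X[i, j]) / (hi - lo)
    }
  }
  rstar <- apply(r, 2, max)
  delta <- matrix(0, m, k)
  for (i in 1:m) for (j in 1:k) delta[i, j] <- abs(rstar[j] - r[i, j])
  dmin <- min(delta); dmax <- max(delta)
  eps <- matrix(1, m, k)
  if (dmax > 0)
    for (i in 1:m) for (j in 1:k)
      eps[i, j] <- (dmin + rho * dmax) / (delta[i, j] + rho * dmax)
  # entropy weights
  e <- numeric(k)
  for (j in 1:k) {
    cs <- sum(r[, j])
    acc <- 0
    for (i in 1:m) {
      p <- r[i, j] / cs
      if (p > 0) acc <- acc + p * log(p)
    }
    e[j] <- -acc / log(m)
  }
  d <- 1 - e
  d[abs(d) < 1e-14] <- 0
  w <- d / sum(d)
  S <- numeric(m); R <- numeric(m)
  for (i in 1:m) {
    terms <- numeric(k)
    for (j in 1:k) terms[j] <- w[j] * (1 - eps[i, j])
    S[i] <- sum(terms); R[i] <- max(terms)
  }
  Q <- numeric(m)
  for (i in 1:m) {
    qs <- if (max(S) > min(S)) (S[i] - min(S)) / (max(S) - min(S)) else 0
    qr <- if (max(R) > min(R)) (R[i] - min(R)) / (max(R) - min(R)) else 0
    Q[i] <- v * qs + (1 - v) * qr
  }
  O <- matrix(0, m, k)
  for (i in 1:m) {
    tot <- 0
    for (j in 1:k) tot <- tot + w[j] * (1 - eps[i, j])
    if (tot > 0) for (j in 1:k) O[i, j] <- w[j] * (1 - eps[i, j]) / tot
  }
  list(norm = r, eps = eps, weights = w, S = S, R = R, Q = Q, obstacle = O)
}

# The 3-scene hand-worked normalized matrix used across decision tests.
hand_norm <- function() matrix(c(1, 0, 0.5, 1, 0, 1), ncol = 2)

# A pure-tone recording: sum of sinusoids per channel.
tone_recording <- function(freqs, amps, phases = rep(0, length(freqs)),
                           dur = 4, rate = 512, labels = "F3",
                           n_channels = length(labels)) {
  t <- (0:(dur * rate - 1)) / rate
  x <- rep(0, length(t))
  for (k in seq_along(freqs)) x <- x + amps[k] * sin(2 * pi * freqs[k] * t + phases[k])
  make_eeg_recording(matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE),
                     labels, rate)
}

# FFT amplitude of a single frequency component.
fft_amplitude <- function(x, freq, rate) {
  n <- length(x)
  k <- round(freq * n / rate)
  2 * Mod(stats::fft(x)[k + 1]) / n
}

# Band-power table direct constructor for metric tests.
bp_table <- function(al, ar, bl = 1, br = 1, scene = "s1", participant = "P01",
                     rep_idx = seq_along(al)) {
  structure(data.frame(scene_id = scene, participant = participant,
                       repeat_idx = rep_idx,
                       p_alpha_left = al, p_beta_left = bl,
                       p_alpha_right = ar, p_beta_right = br,
                       p_alpha_all = (al + ar) / 2,
                       p_beta_all = (bl + br) / 2,
                       stringsAsFactors = FALSE),
            class = c("landemo_bandpower", "data.frame"))
}

# Zero-noise simulation config over explicit effects/sampling.
quiet_config <- function(...) {
  simulation_config(noise_sd_scene = 0, noise_sd_participant = 0,
                    noise_sd_trial = 0, age_effect = 0, gender_effect = 0, ...)
}
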