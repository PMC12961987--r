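#' Arousal index: all-channel alpha/beta power ratio
#'
#' The intensity dimension of the circumplex model, computed literally as
#' P(alpha)/P(beta) over the all-channel group. Note the printed formula has
#' alpha in the numerator (many EEG studies use beta/alpha); the ratio
#' direction here follows the source formula and is flagged in the docs.
#' Trials with zero beta power are undefined and returned as `NA` with a
#' warning (callers drop and log them).
#'
#' @param bp a `landemo_bandpower` data.frame.
#' @return numeric vector of arousal values, one per trial.
#' @export
arousal <- function(bp) {
  if (!all(c("p_alpha_all", "p_beta_all") %in% names(bp)))
    stop("band-power table lacks all-channel group columns")
  bad <- !(bp$p_beta_all > 0)
  if (any(bad))
    warning(sum(bad), " trial(s) with non-positive beta power: ",
            "arousal undefined, returned NA (dropped downstream)")
  out <- bp$p_alpha_all / bp$p_beta_all
  out[bad] <- NA_real_
  out
}

#' Valence index: right-minus-left hemispheric alpha/beta asymmetry
#'
#' E_VA = P(alpha)_right/P(beta)_right - P(alpha)_left/P(beta)_left.
#' Positive values indicate pleasant direction; the sign flips under
#' left/right exchange. Midline channels contribute to neither side.
#'
#' @param bp a `landemo_bandpower` data.frame.
#' @return numeric vector of valence values, one per trial.
#' @export
valence <- function(bp) {
  need <- c("p_alpha_left", "p_beta_left", "p_alpha_right", "p_beta_right")
  if (!all(need %in% names(bp)))
    stop("band-power table lacks hemisphere group columns: ",
         paste(setdiff(need, names(bp)), collapse = ", "))
  if (anyNA(bp$p_alpha_left) || anyNA(bp$p_alpha_right))
    stop("missing hemisphere group: recording needs channels tagged both ",
         "'left' and 'right'")
  bad <- !(bp$p_beta_left > 0 & bp$p_beta_right > 0)
  if (any(bad))
    warning(sum(bad), " trial(s) with non-positive beta power: ",
            "valence undefined, returned NA")
  out <- bp$p_alpha_right / bp$p_beta_right - bp$p_alpha_left / bp$p_beta_left
  out[bad] <- NA_real_
  out
}

#' Per-trial emotion scores from band powers
#'
#' @param bp a `landemo_bandpower` data.frame with `scene_id`, `repeat_idx`
#'   and (for multi-participant tables) `participant` columns.
#' @return data.frame with `scene_id`, `participant`, `repeat_idx`, `arousal`,
#'   `valence`; undefined trials are dropped with a message.
#' @export
emotion_scores <- function(bp) {
  a <- arousal(bp)
  v <- valence(bp)
  out <- data.frame(scene_id = bp$scene_id,
                    participant = bp$participant %||% "P01",
                    repeat_idx = bp$repeat_idx,
                    arousal = a, valence = v,
                    stringsAsFactors = FALSE)
  drop <- is.na(a) | is.na(v)
  if (any(drop)) {
    message(sum(drop), " undefined trial(s) dropped")
    out <- out[!drop, , drop = FALSE]
  }
  out
}

#' Aggregate trial scores to covariate-adjusted scene emotions
#'
#' Per scene, trials are first averaged over repeats within participant, then
#' averaged over participants. The covariate-adjusted mean applies a linear
#' age + gender adjustment evaluated at the panel covariate means: slopes are
#' estimated from within-scene-centered participant means (pooled OLS), so a
#' scene viewed by an unrepresentative participant subset is corrected toward
#' the panel composition. With zero covariate effects the adjusted means
#' equal the raw means. Dispersion is the SD over participant means. Scenes
#' whose trials were all rejected simply do not appear (logged); with a
#' single participant the adjustment is skipped with a warning.
#'
#' @param scores data.frame from [emotion_scores()].
#' @param covariates participant table with `participant`, `age`, `gender`.
#' @return data.frame, one row per scene: raw and adjusted means, SD and n
#'   per index.
#' @export
aggregate_scene_scores <- function(scores, covariates) {
  if (!all(scores$participant %in% covariates$participant))
    stop("covariate table does not cover all participants")
  # mean over repeats within participant
  key <- interaction(scores$scene_id, scores$participant, drop = TRUE)
  pm <- data.frame(
    scene_id = tapply(scores$scene_id, key, `[`, 1L),
    participant = tapply(scores$participant, key, `[`, 1L),
    arousal = as.numeric(tapply(scores$arousal, key, mean)),
    valence = as.numeric(tapply(scores$valence, key, mean)),
    n_trials = as.integer(tapply(scores$arousal, key, length)),
    stringsAsFactors = FALSE)
  ci <- match(pm$participant, covariates$participant)
  pm$age <- covariates$age[ci]
  pm$male <- as.numeric(covariates$gender[ci] == "male")
  age_ref <- mean(covariates$age)
  male_ref <- mean(covariates$gender == "male")

  multi <- length(unique(pm$participant)) > 1L
  slopes <- list(arousal = c(0, 0), valence = c(0, 0))
  if (multi) {
    center_by <- function(v) v - ave(v, pm$scene_id)
    Xa <- cbind(age = center_by(pm$age), male = center_by(pm$male))
    varying <- apply(Xa, 2L, function(c) any(abs(c) > 1e-12))
    if (any(varying)) {
      for (em in c("arousal", "valence")) {
        y <- center_by(pm[[em]])
        b <- rep(0, 2)
        fit <- stats::lm.fit(Xa[, varying, drop = FALSE], y)
        b[varying] <- fit$coefficients
        b[is.na(b)] <- 0
        slopes[[em]] <- b
      }
    }
  } else {
    warning("single participant: covariate adjustment skipped, raw means returned")
  }

  agg <- function(em) {
    b <- slopes[[em]]
    adj_vals <- pm[[em]] - b[1] * (pm$age - age_ref) - b[2] * (pm$male - male_ref)
    data.frame(
      scene_id = as.character(tapply(pm$scene_id, pm$scene_id, `[`, 1L)),
      raw = as.numeric(tapply(pm[[em]], pm$scene_id, mean)),
      adj = as.numeric(tapply(adj_vals, pm$scene_id, mean)),
      sd = as.numeric(tapply(pm[[em]], pm$scene_id, stats::sd)),
      stringsAsFactors = FALSE)
  }
  aa <- agg("arousal"); vv <- agg("valence")
  stopifnot(identical(aa$scene_id, vv$scene_id))
  out <- data.frame(scene_id = aa$scene_id,
                    arousal_raw = aa$raw, arousal_adj = aa$adj, arousal_sd = aa$sd,
                    valence_raw = vv$raw, valence_adj = vv$adj, valence_sd = vv$sd,
                    n_participants = as.integer(tapply(pm$participant, pm$scene_id, length)),
                    n_trials = as.integer(tapply(pm$n_trials, pm$scene_id, sum)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Emotional-benefit composite
#'
#' A single scene-level benefit score combining the two indices. The default
#' is the plain mean of the arousal and valence indices in their native
#' units, which keeps published per-unit effect sizes directly interpretable
#' on the composite; `normalize = TRUE` gives the mean of the range-normalized
#' indices instead (scale-free but sample-dependent).
#'
#' @param arousal,valence numeric vectors (same length).
#' @param normalize use range-normalized indices (default FALSE).
#' @return numeric composite vector.
#' @export
emotional_benefit <- function(arousal, valence, normalize = FALSE) {
  if (normalize) {
    nrm <- function(x) if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else rep(0.5, length(x))
    (nrm(arousal) + nrm(valence)) / 2
  } else {
    (arousal + valence) / 2
  }
}
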