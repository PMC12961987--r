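#' Merge scene emotions with scene indicators
#'
#' @param scenes `landemo_scenes` (or data.frame with `scene_id`).
#' @param emotions scene-emotion data.frame from [aggregate_scene_scores()].
#' @return data.frame with indicator columns plus emotion columns.
#' @export
merge_scene_emotions <- function(scenes, emotions) {
  sdf <- scene_data(scenes)
  i <- match(sdf$scene_id, emotions$scene_id)
  keep <- !is.na(i)
  cbind(sdf[keep, , drop = FALSE],
        emotions[i[keep], setdiff(names(emotions), "scene_id"), drop = FALSE])
}

# Build the adjustment data frame for a model: covariates named in
# `covariate_bins` are discretized into factors (capturing nonlinear,
# plateau, or step-shaped confounders); others enter linearly (numeric) or
# as factors (categorical).
build_covariate_frame <- function(df, covariates, covariate_bins = NULL) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
  out <- list()
  for (cv in covariates) {
    v <- df[[cv]]
    if (!is.null(covariate_bins) && cv %in% names(covariate_bins)) {
      w <- covariate_bins[[cv]]
      breaks <- seq(floor(min(v) / w) * w, ceiling(max(v) / w) * w + w, by = w)
      out[[cv]] <- cut(v, breaks = unique(breaks), include.lowest = TRUE, right = FALSE)
    } else if (is.numeric(v) && length(unique(v)) > 5L) {
      out[[cv]] <- v
    } else {
      out[[cv]] <- factor(v)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

check_full_rank <- function(fit) {
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al))
    stop("collinear covariate column(s): ", paste(rownames(al), collapse = ", "))
  invisible(fit)
}

#' Covariate-adjusted linear slope of an emotion index on an indicator
#'
#' Ordinary least squares of the emotion column on the indicator plus
#' covariates; reports the slope per indicator unit and per 10 units with a
#' two-sided 95% confidence interval.
#'
#' @param df merged scene data (see [merge_scene_emotions()]).
#' @param indicator indicator column name (continuous).
#' @param emotion emotion column name (e.g. `"arousal_adj"`).
#' @param covariates optional covariate column names.
#' @param covariate_bins optional named list of bin widths for covariates to
#'   enter as discretized factors.
#' @return list with `slope`, `slope_per_10`, `se`, `ci` (95%), `p`, `n`.
#' @export
slope_regression <- function(df, indicator, emotion, covariates = NULL,
                             covariate_bins = NULL) {
  if (nrow(df) < 10L) stop("slope regression needs >= 10 scenes")
  d <- data.frame(.y = df[[emotion]], .x = df[[indicator]])
  cf <- build_covariate_frame(df, covariates, covariate_bins)
  if (!is.null(cf)) d <- cbind(d, cf)
  fit <- stats::lm(.y ~ ., data = d)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, ".x", level = 0.95)
  list(slope = unname(sm[".x", "Estimate"]),
       slope_per_10 = unname(10 * sm[".x", "Estimate"]),
       se = unname(sm[".x", "Std. Error"]),
       ci = unname(ci[1, ]),
       p = unname(sm[".x", "Pr(>|t|)"]),
       n = nrow(d))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values: with p-values sorted ascending,
#' q_(i) = min_{j >= i} ( m p_(j) / j ), capped at 1. Monotone in p and
#' invariant to input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Step effect: adjusted mean difference across a stated threshold
#'
#' Difference of covariate-adjusted means (at-or-above minus below; the upper
#' side is closed, `x >= threshold`) with its standard error, from OLS of the
#' emotion on the threshold indicator plus covariates.
#'
#' @inheritParams slope_regression
#' @param threshold threshold in indicator units.
#' @param min_each minimum scene count required on each side (default 5).
#' @return list with `difference`, `se`, `p`, `n_above`, `n_below`,
#'   `threshold`.
#' @export
step_effect <- function(df, indicator, threshold, emotion, covariates = NULL,
                        covariate_bins = NULL, min_each = 5L) {
  above <- df[[indicator]] >= threshold
  n_above <- sum(above); n_below <- sum(!above)
  if (n_above < min_each || n_below < min_each)
    stop("both sides of the threshold must be populated: ",
         n_below, " below, ", n_above, " at/above (need >= ", min_each, " each)")
  d <- data.frame(.y = df[[emotion]], .above = as.numeric(above))
  cf <- build_covariate_frame(df, covariates, covariate_bins)
  if (!is.null(cf)) d <- cbind(d, cf)
  fit <- stats::lm(.y ~ ., data = d)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  list(difference = unname(sm[".above", "Estimate"]),
       se = unname(sm[".above", "Std. Error"]),
       p = unname(sm[".above", "Pr(>|t|)"]),
       n_above = n_above, n_below = n_below, threshold = threshold)
}

#' Scan candidate step thresholds with FDR control (exploratory mode)
#'
#' @inheritParams step_effect
#' @param thresholds numeric vector of candidate thresholds.
#' @return data.frame with one row per feasible threshold: difference, se,
#'   p, and BH-adjusted q.
#' @export
step_effect_scan <- function(df, indicator, thresholds, emotion,
                             covariates = NULL, covariate_bins = NULL,
                             min_each = 5L) {
  rows <- lapply(thresholds, function(th) {
    res <- tryCatch(step_effect(df, indicator, th, emotion, covariates,
                                covariate_bins, min_each),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(threshold = th, difference = res$difference, se = res$se,
               p = res$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no candidate threshold had both sides populated")
  out$q <- fdr_adjust(out$p)
  out
}

#' Optimal indicator interval for an emotion outcome
#'
#' Two complementary estimates of "where the response peaks":
#' \enumerate{
#'   \item Binned means on a `grid`-unit grid, smoothed with a 3-cell moving
#'     average; the reported interval is the maximal contiguous run of cells
#'     whose smoothed mean is within one standard error of the peak cell's
#'     (the SE of the peak-minus-cell difference, so sampling noise in either
#'     cell does not spuriously break the run).
#'   \item A two-breakpoint piecewise-linear (three independent segments)
#'     model fitted by exhaustive grid search over breakpoint pairs
#'     minimizing SSE; ties resolve toward the widest outer segments.
#' }
#' If covariates are given, the emotion is first residualized on them (mean
#' added back), removing confounded variance before binning and fitting.
#'
#' @inheritParams slope_regression
#' @param grid bin width in indicator units (default 5).
#' @return list with `interval` (c(low, high)), `peak_value`,
#'   `peak_bin_center`, `no_peak`, `saturated`, `breakpoints`, `segments`
#'   (per-segment slope/se/n), `bins` (bin table).
#' @export
optimal_interval <- function(df, indicator, emotion, grid = 5,
                             covariates = NULL, covariate_bins = NULL) {
  x <- df[[indicator]]
  y <- df[[emotion]]
  if (length(x) < 30L) stop("interval detection needs >= 30 scenes")
  if (diff(range(x)) < 3 * grid)
    stop("indicator spans fewer than 3 grid cells; use a finer grid")
  if (!is.null(covariates)) {
    cf <- build_covariate_frame(df, covariates, covariate_bins)
    fit <- stats::lm(y ~ ., data = cbind(data.frame(y = y), cf))
    y <- stats::residuals(fit) + mean(y)
  }
  breaks <- seq(floor(min(x) / grid) * grid, ceiling(max(x) / grid) * grid, by = grid)
  if (length(breaks) - 1L > length(x))
    stop("fewer scenes than bins; advise a coarser grid (current ", grid, " units)")
  bin <- cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE)
  bmean <- tapply(y, bin, mean)
  bsd <- tapply(y, bin, stats::sd)
  bn <- tapply(y, bin, length)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  occupied <- which(!is.na(bmean) & bn >= 1)
  sm <- rep(NA_real_, length(bmean))
  for (i in occupied) {
    nb <- intersect(c(i - 1L, i, i + 1L), occupied)
    sm[i] <- mean(bmean[nb])
  }
  peak <- occupied[which.max(sm[occupied])]
  bse <- ifelse(!is.na(bsd) & bn > 1, bsd / sqrt(bn), 0)
  diff_se <- sqrt(bse[peak]^2 + bse^2)
  within <- !is.na(sm) & sm >= sm[peak] - diff_se
  # maximal contiguous run (over occupied cells) containing the peak
  lo <- peak
  while (lo > 1L && isTRUE(within[lo - 1L])) lo <- lo - 1L
  hi <- peak
  while (hi < length(within) && isTRUE(within[hi + 1L])) hi <- hi + 1L
  no_peak <- all(within[occupied])
  interval <- if (no_peak) range(breaks) else c(breaks[lo], breaks[hi + 1L])

  seg <- segmented_fit(x, y, breaks)
  upper <- seg$segments$upper
  lower <- seg$segments$lower
  saturated <- !is.na(upper$slope) && !is.na(upper$se) && upper$se > 0 &&
    abs(upper$slope) < 2 * upper$se &&
    !is.na(lower$slope) && !is.na(lower$se) && abs(lower$slope) >= 2 * lower$se
  list(interval = unname(interval),
       peak_value = unname(sm[peak]),
       peak_bin_center = unname(centers[peak]),
       no_peak = no_peak,
       saturated = saturated,
       breakpoints = seg$breakpoints,
       segments = seg$segments,
       sse = seg$sse,
       bins = data.frame(center = centers, mean = as.numeric(bmean),
                         smoothed = as.numeric(sm), sd = as.numeric(bsd),
                         n = as.integer(bn)))
}

# Two-breakpoint piecewise-linear fit: three independently fitted OLS lines,
# exhaustive search over interior grid-line pairs. Scanning b1 ascending and
# b2 descending with strict improvement means exact SSE ties resolve to the
# widest outer segments (degenerate, e.g. purely linear, data put the
# breakpoints at the grid extremes).
segmented_fit <- function(x, y, breaks, min_pts = 3L) {
  cand <- breaks[-c(1L, length(breaks))]
  seg_ols <- function(sel) {
    n <- sum(sel)
    if (n < min_pts) return(NULL)
    xs <- x[sel]; ys <- y[sel]
    if (length(unique(xs)) < 2L)
      return(list(slope = NA_real_, se = NA_real_, n = n,
                  sse = sum((ys - mean(ys))^2)))
    fit <- stats::lm.fit(cbind(1, xs), ys)
    r <- fit$residuals
    sse <- sum(r^2)
    sxx <- sum((xs - mean(xs))^2)
    se <- if (n > 2L) sqrt(sse / (n - 2L) / sxx) else NA_real_
    list(slope = unname(fit$coefficients[2]), se = se, n = n, sse = sse)
  }
  best <- NULL
  for (b1 in cand) {
    for (b2 in rev(cand[cand > b1])) {
      s1 <- seg_ols(x < b1)
      s2 <- seg_ols(x >= b1 & x < b2)
      s3 <- seg_ols(x >= b2)
      if (is.null(s1) || is.null(s2) || is.null(s3)) next
      sse <- s1$sse + s2$sse + s3$sse
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(breakpoints = c(b1, b2), sse = sse,
                     segments = list(lower = s1, middle = s2, upper = s3))
      }
    }
  }
  if (is.null(best))
    stop("no breakpoint pair leaves >= ", min_pts, " points per segment")
  best
}

#' Pairwise element-association matrix with FDR-adjusted significance
#'
#' Pearson (default) or Spearman correlations between indicator and emotion
#' columns; p-values of the upper triangle are Benjamini-Hochberg adjusted,
#' and an edge list of associations passing `|r| >= min_r` and `q <= alpha`
#' is returned. Constant columns have undefined correlations; their pairs are
#' reported as missing.
#'
#' @param df scene-level data.frame.
#' @param columns column names to correlate (>= 2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_r minimum absolute correlation for the edge list (default 0.3).
#' @param alpha FDR level for the edge list (default 0.05).
#' @return object of class `landemo_assoc`: list with `r` (correlation
#'   matrix), `p`, `q` (matrices), `edges` (data.frame), `constant`
#'   (column names with undefined correlations).
#' @export
association_matrix <- function(df, columns, method = c("pearson", "spearman"),
                               min_r = 0.3, alpha = 0.05) {
  method <- match.arg(method)
  if (nrow(df) < 10L) stop("association matrix needs >= 10 scenes")
  m <- as.matrix(df[, columns, drop = FALSE])
  k <- ncol(m)
  if (k < 2L) stop("need >= 2 columns")
  const <- columns[apply(m, 2L, function(v) stats::sd(v) == 0)]
  R <- suppressWarnings(stats::cor(m, method = method))
  P <- matrix(NA_real_, k, k, dimnames = dimnames(R))
  diag(P) <- 0
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  pvals <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (columns[a] %in% const || columns[b] %in% const) next
    pvals[i] <- suppressWarnings(
      stats::cor.test(m[, a], m[, b], method = method, exact = FALSE)$p.value)
  }
  Q <- matrix(NA_real_, k, k, dimnames = dimnames(R))
  ok <- !is.na(pvals)
  qvals <- rep(NA_real_, length(pvals))
  if (any(ok)) qvals[ok] <- fdr_adjust(pvals[ok])
  for (i in seq_len(nrow(pairs))) {
    P[pairs[i, 1], pairs[i, 2]] <- P[pairs[i, 2], pairs[i, 1]] <- pvals[i]
    Q[pairs[i, 1], pairs[i, 2]] <- Q[pairs[i, 2], pairs[i, 1]] <- qvals[i]
  }
  sel <- ok & abs(R[upper.tri(R)]) >= min_r & qvals <= alpha
  edges <- data.frame(from = columns[pairs[sel, 1]],
                      to = columns[pairs[sel, 2]],
                      r = R[upper.tri(R)][sel],
                      q = qvals[sel],
                      stringsAsFactors = FALSE)
  structure(list(r = R, p = P, q = Q, edges = edges, constant = const,
                 method = method),
            class = "landemo_assoc")
}

#' Full threshold report for a set of effect requests
#'
#' @param df merged scene data.
#' @param requests list of request lists, each with `indicator`, `emotion`,
#'   `type` (`"slope"`, `"step"`, or `"interval"`), and type parameters
#'   (`threshold`, `grid`), plus optional `covariates`/`covariate_bins`.
#' @return data.frame report, one row per request, with BH-adjusted q over
#'   the slope/step p-values.
#' @export
threshold_report <- function(df, requests) {
  rows <- lapply(requests, function(rq) {
    base <- data.frame(indicator = rq$indicator, emotion = rq$emotion,
                       type = rq$type, estimate = NA_real_, se = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                       interval_low = NA_real_, interval_high = NA_real_,
                       stringsAsFactors = FALSE)
    if (rq$type == "slope") {
      r <- slope_regression(df, rq$indicator, rq$emotion, rq$covariates,
                            rq$covariate_bins)
      base$estimate <- r$slope; base$se <- r$se
      base$ci_low <- r$ci[1]; base$ci_high <- r$ci[2]; base$p <- r$p
    } else if (rq$type == "step") {
      r <- step_effect(df, rq$indicator, rq$threshold, rq$emotion,
                       rq$covariates, rq$covariate_bins)
      base$estimate <- r$difference; base$se <- r$se; base$p <- r$p
      base$ci_low <- r$difference - 1.96 * r$se
      base$ci_high <- r$difference + 1.96 * r$se
    } else if (rq$type == "interval") {
      r <- optimal_interval(df, rq$indicator, rq$emotion, rq$grid %||% 5,
                            rq$covariates, rq$covariate_bins)
      base$estimate <- r$peak_value
      base$interval_low <- r$interval[1]; base$interval_high <- r$interval[2]
    } else stop("unknown request type: ", rq$type)
    base
  })
  out <- do.call(rbind, rows)
  has_p <- !is.na(out$p)
  out$q <- NA_real_
  if (any(has_p)) out$q[has_p] <- fdr_adjust(out$p[has_p])
  out
}
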