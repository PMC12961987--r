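#' Range-normalize a criteria matrix
#'
#' Maps every criterion column to \[0, 1\] with the range (min-max) method.
#' Benefit columns use (x - min) / (max - min); cost columns are reversed,
#' (max - x) / (max - min), so that 1 is always "best". A constant column has
#' no range; it is mapped to 0.5 everywhere with a warning so that downstream
#' entropy weighting assigns it zero weight rather than failing.
#'
#' @param x numeric matrix or data.frame, scenes x criteria.
#' @param directions character vector, one of `"benefit"` or `"cost"` per
#'   column. Recycled if length 1.
#' @return object of class `landemo_norm`: list with `values` (matrix in
#'   \[0,1\]), `directions`, `col_min`, `col_max`, `constant` (logical per
#'   column).
#' @export
range_normalize <- function(x, directions = "benefit") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("criteria matrix must be numeric")
  if (nrow(x) < 2L) stop("range normalization needs >= 2 scenes (range undefined)")
  m <- ncol(x)
  directions <- match.arg(rep(directions, length.out = m),
                          c("benefit", "cost"), several.ok = TRUE)
  cmin <- apply(x, 2L, min)
  cmax <- apply(x, 2L, max)
  constant <- (cmax - cmin) == 0
  if (any(constant)) {
    warning("constant criterion column(s) mapped to 0.5: ",
            paste(colnames(x)[constant] %||% which(constant), collapse = ", "))
  }
  r <- x
  for (j in seq_len(m)) {
    if (constant[j]) {
      r[, j] <- 0.5
    } else if (directions[j] == "benefit") {
      r[, j] <- (x[, j] - cmin[j]) / (cmax[j] - cmin[j])
    } else {
      r[, j] <- (cmax[j] - x[, j]) / (cmax[j] - cmin[j])
    }
  }
  structure(list(values = r, directions = directions,
                 col_min = cmin, col_max = cmax, constant = constant),
            class = "landemo_norm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

norm_values <- function(norm) {
  if (inherits(norm, "landemo_norm")) norm$values else as.matrix(norm)
}

#' Optimal reference sequence of a normalized matrix
#'
#' The reference (ideal) value per criterion is the column maximum of the
#' normalized matrix; after direction-aware range normalization this is 1 for
#' every non-constant column and 0.5 for constant ones.
#'
#' @param norm `landemo_norm` or numeric matrix in \[0,1\].
#' @return numeric vector, one reference value per criterion.
#' @export
reference_sequence <- function(norm) {
  apply(norm_values(norm), 2L, max)
}

#' Grey relational coefficients against the ideal sequence
#'
#' For deviations d_ij = |r*_j - r_ij|, the coefficient is
#' eps_ij = (dmin + rho * dmax) / (d_ij + rho * dmax), with dmin and dmax the
#' global minimum and maximum deviation over all scenes and criteria, and rho
#' the distinguishing coefficient (default 0.5). If every scene equals the
#' ideal (dmax = 0) all coefficients are 1.
#'
#' @param norm `landemo_norm` or normalized matrix.
#' @param reference reference sequence; defaults to [reference_sequence()].
#' @param rho distinguishing coefficient in (0, 1].
#' @return object of class `landemo_gra`: list with `coefficients` (matrix in
#'   (0,1\]), `reference`, `rho`, `delta_min`, `delta_max`.
#' @export
grey_relational_coefficients <- function(norm, reference = NULL, rho = 0.5) {
  r <- norm_values(norm)
  if (is.null(reference)) reference <- reference_sequence(r)
  if (length(reference) != ncol(r))
    stop("reference sequence length must equal criterion count")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop("rho must be a scalar in (0, 1]")
  delta <- abs(sweep(r, 2L, reference, "-"))
  dmin <- min(delta)
  dmax <- max(delta)
  eps <- if (dmax == 0) {
    matrix(1, nrow(r), ncol(r), dimnames = dimnames(r))
  } else {
    (dmin + rho * dmax) / (delta + rho * dmax)
  }
  structure(list(coefficients = eps, reference = reference, rho = rho,
                 delta_min = dmin, delta_max = dmax),
            class = "landemo_gra")
}

gra_values <- function(gra) {
  if (inherits(gra, "landemo_gra")) gra$coefficients else as.matrix(gra)
}

#' Entropy weights of a normalized criteria matrix
#'
#' Shannon-entropy based objective weights: p_ij = r_ij / sum_i r_ij
#' (0 * log 0 taken as 0), e_j = -(1/log m) * sum_i p_ij log p_ij with m the
#' number of scenes, and w_j = (1 - e_j) / sum_j (1 - e_j). High-dispersion
#' criteria carry more weight; a constant (0.5-mapped) column has uniform p,
#' entropy exactly 1, and weight exactly 0.
#'
#' @param norm `landemo_norm` or normalized matrix.
#' @return numeric weight vector summing to 1.
#' @export
entropy_weights <- function(norm) {
  r <- norm_values(norm)
  m <- nrow(r)
  if (m < 2L) stop("entropy weights need >= 2 scenes")
  csum <- colSums(r)
  if (any(csum <= 0))
    stop("column sum(s) must be positive: ",
         paste(colnames(r)[csum <= 0] %||% which(csum <= 0), collapse = ", "))
  p <- sweep(r, 2L, csum, "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(m)
  d <- 1 - e
  # guard tiny negative divergence from rounding
  d[abs(d) < 1e-14] <- 0
  if (sum(d) == 0)
    stop("all criteria are maximally entropic (no information); ",
         "use equal weights explicitly if intended")
  w <- d / sum(d)
  names(w) <- colnames(r)
  w
}

#' VIKOR compromise scores from grey relational coefficients
#'
#' Group utility S_i = sum_j w_j (1 - eps_ij), individual regret
#' R_i = max_j w_j (1 - eps_ij), and the compromise score
#' Q_i = v (S_i - Smin)/(Smax - Smin) + (1 - v)(R_i - Rmin)/(Rmax - Rmin).
#' A degenerate denominator (all S equal, or all R equal) zeroes that term for
#' every scene, the continuity limit of equal scores. Lower Q is better; ranks
#' are ascending in Q with stable tie-breaking.
#'
#' The classical VIKOR compromise conditions (acceptable advantage
#' Q(2) - Q(1) >= 1/(m-1), and acceptable stability: the Q-best scene is also
#' best by S or R) are evaluated and reported but never alter the ranking.
#'
#' @param gra `landemo_gra` or coefficient matrix.
#' @param weights criterion weights summing to 1.
#' @param v decision coefficient in \[0, 1\] balancing group utility against
#'   individual regret (default 0.5).
#' @return object of class `landemo_vikor`: list with `S`, `R`, `Q`, `rank`,
#'   `level`, `v`, `weights`, `conditions`.
#' @export
vikor_scores <- function(gra, weights, v = 0.5) {
  eps <- gra_values(gra)
  m <- nrow(eps)
  if (m < 2L) stop("VIKOR needs >= 2 scenes")
  if (length(weights) != ncol(eps))
    stop("weights length must equal criterion count")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
    stop("v must be a scalar in [0, 1]")
  dev <- sweep(1 - eps, 2L, weights, "*")
  S <- rowSums(dev)
  R <- apply(dev, 1L, max)
  qs <- if (max(S) > min(S)) (S - min(S)) / (max(S) - min(S)) else rep(0, m)
  qr <- if (max(R) > min(R)) (R - min(R)) / (max(R) - min(R)) else rep(0, m)
  Q <- v * qs + (1 - v) * qr
  rank_q <- rank(Q, ties.method = "first")
  ord <- order(Q)
  dq <- 1 / (m - 1)
  acceptable_advantage <- if (m >= 2L) (Q[ord[2L]] - Q[ord[1L]]) >= dq else TRUE
  acceptable_stability <-
    rank(S, ties.method = "min")[ord[1L]] == 1L ||
    rank(R, ties.method = "min")[ord[1L]] == 1L
  res <- structure(list(S = S, R = R, Q = Q, rank = rank_q, v = v,
                        weights = weights,
                        conditions = list(acceptable_advantage = acceptable_advantage,
                                          acceptable_stability = acceptable_stability,
                                          dq = dq),
                        level = NULL),
                   class = "landemo_vikor")
  res$level <- assign_levels(res)
  res
}

#' Emotion quality levels I-IV from compromise scores
#'
#' Scenes are graded by quartiles of Q: the best quartile (lowest Q) is
#' Level I, the worst Level IV. Ties are broken stably by rank order, so equal
#' Q values split by input order. With fewer than 4 scenes the quartile rule is
#' undefined and all scenes are assigned Level II with a warning.
#'
#' @param result `landemo_vikor` result, or a numeric Q vector.
#' @return factor with levels `I`, `II`, `III`, `IV`, one per scene.
#' @export
assign_levels <- function(result) {
  q <- if (inherits(result, "landemo_vikor")) result$Q else as.numeric(result)
  m <- length(q)
  lv <- c("I", "II", "III", "IV")
  if (m < 4L) {
    warning("fewer than 4 scenes: quartile grading undefined, all assigned Level II")
    return(factor(rep("II", m), levels = lv))
  }
  r <- rank(q, ties.method = "first")
  idx <- ceiling(4 * r / m)
  factor(lv[idx], levels = lv)
}

#' Obstacle degrees: which criterion blocks each scene
#'
#' The obstacle degree of criterion j for scene i is its share of the scene's
#' total weighted deviation from the ideal:
#' O_ij = w_j (1 - eps_ij) / sum_j w_j (1 - eps_ij). Rows sum to 1 except for
#' scenes exactly at the ideal (all eps = 1), which get an all-zero row and a
#' `no_obstacle` flag.
#'
#' @param gra `landemo_gra` or coefficient matrix.
#' @param weights criterion weights (the entropy weights; the starred weight
#'   of the diagnosis formula is treated as the same vector).
#' @return object of class `landemo_obstacle`: list with `degrees` (matrix,
#'   rows summing to 1 or 0), `no_obstacle` (logical per scene), `weights`.
#' @export
obstacle_degrees <- function(gra, weights) {
  eps <- gra_values(gra)
  if (length(weights) != ncol(eps))
    stop("weights length must equal criterion count")
  dev <- sweep(1 - eps, 2L, weights, "*")
  tot <- rowSums(dev)
  no_obstacle <- tot == 0
  O <- dev
  O[!no_obstacle, ] <- dev[!no_obstacle, , drop = FALSE] / tot[!no_obstacle]
  O[no_obstacle, ] <- 0
  structure(list(degrees = O, no_obstacle = no_obstacle, weights = weights),
            class = "landemo_obstacle")
}

#' Run the full scene evaluation: normalize, GRA, entropy weights, VIKOR,
#' levels, obstacle degrees
#'
#' @param x raw criteria matrix or data.frame (scenes x criteria).
#' @param directions benefit/cost direction per column.
#' @param rho distinguishing coefficient (default 0.5).
#' @param v VIKOR decision coefficient (default 0.5).
#' @param weights optional externally supplied weights; default entropy
#'   weights of the normalized matrix.
#' @return list with `norm`, `gra`, `weights`, `vikor`, `obstacle`.
#' @export
evaluate_scenes <- function(x, directions = "benefit", rho = 0.5, v = 0.5,
                            weights = NULL) {
  norm <- range_normalize(x, directions)
  gra <- grey_relational_coefficients(norm, rho = rho)
  if (is.null(weights)) weights <- entropy_weights(norm)
  vik <- vikor_scores(gra, weights, v)
  obs <- obstacle_degrees(gra, weights)
  list(norm = norm, gra = gra, weights = weights, vikor = vik, obstacle = obs)
}

#' Assemble the decision matrix from scene indicators and emotion scores
#'
#' Joins the per-scene emotion indices (arousal, valence; benefit direction)
#' with the scene indicator columns, matching rows on `scene_id`. In
#' `"emotion_only"` mode only the two emotion indices are used.
#'
#' @param scenes a `landemo_scenes` object or data.frame with `scene_id` and
#'   indicator columns.
#' @param emotions data.frame with `scene_id` and the emotion columns.
#' @param mode `"joint"` (default) or `"emotion_only"`.
#' @param emotion_cols names of the emotion columns to use.
#' @return list with `values` (numeric matrix), `directions`, `scene_id`.
#' @export
build_decision_matrix <- function(scenes, emotions,
                                  mode = c("joint", "emotion_only"),
                                  emotion_cols = c("arousal_adj", "valence_adj")) {
  mode <- match.arg(mode)
  sdf <- scene_data(scenes)
  if (!all(emotion_cols %in% names(emotions)))
    stop("emotion columns missing: ",
         paste(setdiff(emotion_cols, names(emotions)), collapse = ", "))
  i <- match(sdf$scene_id, emotions$scene_id)
  if (anyNA(i)) stop("emotion scores missing for some scenes")
  emat <- as.matrix(emotions[i, emotion_cols, drop = FALSE])
  colnames(emat) <- sub("_adj$", "", emotion_cols)
  dirs <- rep("benefit", ncol(emat))
  if (mode == "joint") {
    meta <- scene_indicator_meta(scenes)
    imat <- as.matrix(sdf[, meta$id, drop = FALSE])
    emat <- cbind(emat, imat)
    dirs <- c(dirs, meta$direction)
  }
  list(values = emat, directions = dirs, scene_id = sdf$scene_id)
}
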