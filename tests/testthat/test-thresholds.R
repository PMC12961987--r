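test_that("slope regression is exact on deterministic linear data", {
  set.seed(1)
  n <- 60
  df <- data.frame(pav = runif(n, 0, 60), age = runif(n, 20, 70))
  df$arousal <- 5 - 0.047 * df$pav + 0.01 * df$age
  # noise-free fixture: lm warns about the perfect fit, which is the point
  r <- suppressWarnings(slope_regression(df, "pav", "arousal", covariates = "age"))
  expect_equal(r$slope_per_10, -0.47, tolerance = 1e-9)
  expect_true(r$ci[1] <= r$slope && r$slope <= r$ci[2])
  # duplicate covariate column: rank-deficient design
  df$age2 <- df$age
  expect_error(slope_regression(df, "pav", "arousal",
                                covariates = c("age", "age2")),
               "collinear")
  expect_error(slope_regression(df[1:5, ], "pav", "arousal"), ">= 10")
})

test_that("null slopes reject at ~5% under repeated simulation", {
  set.seed(77)
  reps <- 1000
  hits <- 0L
  for (k in seq_len(reps)) {
    x <- runif(30)
    y <- rnorm(30)
    hits <- hits + (slope_regression(data.frame(x = x, y = y), "x", "y")$p < 0.05)
  }
  expect_gt(hits / reps, 0.03)
  expect_lt(hits / reps, 0.07)
})

test_that("slope estimates concentrate with sample size", {
  true_slope <- -0.047
  bias_at <- function(n, seed) {
    set.seed(seed)
    ests <- replicate(60, {
      x <- runif(n, 0, 60)
      y <- 5 + true_slope * x + rnorm(n, 0, 0.5)
      slope_regression(data.frame(x = x, y = y), "x", "y")$slope
    })
    abs(mean(ests) - true_slope)
  }
  b200 <- bias_at(200, 5)
  b2000 <- bias_at(2000, 6)
  expect_true(b2000 <= b200 / 2 || b2000 < 2e-4)
})

test_that("BH adjustment matches hand computation and the reference oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (k in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- fdr_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    # order invariance
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), q[perm], tolerance = 1e-14)
    # monotone in sorted order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("step effect is exact on noise-free data and errors when one-sided", {
  set.seed(3)
  n <- 80
  df <- data.frame(sym = runif(n, 0, 4), age = runif(n, 20, 70))
  df$valence <- 0.1 + 0.18 * (df$sym >= 2) + 0.002 * df$age
  r <- suppressWarnings(step_effect(df, "sym", 2, "valence", covariates = "age"))
  expect_equal(r$difference, 0.18, tolerance = 1e-12)
  expect_error(step_effect(df, "sym", -1, "valence"), "populated")
  expect_error(step_effect(df, "sym", 9, "valence"), "populated")
})

test_that("null step effects stay within 2 SE in >= 93% of seeded reps", {
  set.seed(55)
  reps <- 200
  ok <- 0L
  for (k in seq_len(reps)) {
    df <- data.frame(x = runif(40, 0, 4), y = rnorm(40))
    r <- step_effect(df, "x", 2, "y")
    ok <- ok + (abs(r$difference) <= 2 * r$se)
  }
  expect_gte(ok / reps, 0.93)
})

test_that("step-effect scan applies BH across candidate thresholds", {
  set.seed(4)
  df <- data.frame(x = runif(200, 0, 4))
  df$y <- 0.3 * (df$x >= 2) + rnorm(200, 0, 0.2)
  sc <- step_effect_scan(df, "x", seq(0.5, 3.5, by = 0.5), "y")
  expect_true(all(sc$q >= sc$p - 1e-15))
  expect_lt(sc$q[sc$threshold == 2], 0.01)
})

test_that("optimal interval recovers a plateau peaked on [40, 60]", {
  set.seed(3)
  n <- 2000
  x <- runif(n, 10, 90)
  ef <- effect_spec("g", "arousal", "inverted_u", center = 50, half_width = 10,
                    drop_rate = 0.05)
  y <- 5 + landemo:::apply_effect(ef, x) + rnorm(n, 0, 0.2)
  r <- optimal_interval(data.frame(gvi = x, em = y), "gvi", "em", grid = 5)
  expect_lte(abs(r$interval[1] - 40), 5)
  expect_lte(abs(r$interval[2] - 60), 5)
  expect_false(r$no_peak)
})

test_that("interval degenerates correctly on monotone and flat data", {
  set.seed(10)
  x <- runif(400, 0, 100)
  mono <- data.frame(g = x, e = 0.5 * x)
  r <- optimal_interval(mono, "g", "e", grid = 5)
  expect_equal(r$interval, c(95, 100))           # collapses to the top cell
  expect_equal(r$breakpoints, c(5, 95))          # grid extremes
  flat <- data.frame(g = x, e = rep(2, 400))
  rf <- optimal_interval(flat, "g", "e", grid = 5)
  expect_true(rf$no_peak)
  expect_equal(rf$interval, c(0, 100))
  expect_error(optimal_interval(mono[1:10, ], "g", "e"), ">= 30")
  expect_error(optimal_interval(data.frame(g = runif(50, 0, 8), e = rnorm(50)),
                                "g", "e", grid = 5), "3 grid cells")
})

test_that("interval endpoints are equivariant to aligned affine rescaling", {
  set.seed(21)
  x <- runif(600, 10, 90)
  y <- -0.001 * (x - 50)^2 + rnorm(600, 0, 0.1)
  r1 <- optimal_interval(data.frame(g = x, e = y), "g", "e", grid = 5)
  r2 <- optimal_interval(data.frame(g = 2 * x + 10, e = y), "g", "e", grid = 10)
  expect_equal(r2$interval, 2 * r1$interval + 10)
  expect_equal(r2$breakpoints, 2 * r1$breakpoints + 10)
})

test_that("segmented fit recovers a discontinuous plateau-and-drop shape", {
  set.seed(12)
  x <- runif(1500, 10, 90)
  y <- ifelse(x < 40, 0.024 * (x - 40), ifelse(x < 70, 0, -2)) +
    rnorm(1500, 0, 0.05)
  r <- optimal_interval(data.frame(g = x, e = y), "g", "e", grid = 5)
  expect_equal(r$breakpoints, c(40, 70))
  expect_equal(r$segments$lower$slope, 0.024, tolerance = 0.25)
  expect_true(r$saturated)  # upper segment flat, lower segment sloped
})

test_that("association matrix: identity, planted correlation, null calibration", {
  set.seed(5)
  n <- 500
  z <- rnorm(n)
  a <- z
  b <- -0.73 * z + sqrt(1 - 0.73^2) * rnorm(n)
  df <- data.frame(a = a, b = b, c = a)
  am <- association_matrix(df, c("a", "b", "c"), min_r = 0.3)
  expect_equal(unname(diag(am$r)), c(1, 1, 1))
  expect_equal(am$r, t(am$r))
  expect_equal(unname(am$r["a", "c"]), 1)
  expect_equal(unname(am$r["a", "b"]), -0.73, tolerance = 0.06)
  expect_true(all(abs(am$r) <= 1))
  expect_true(nrow(am$edges) >= 2)

  set.seed(6)
  mean_r <- mean(replicate(1000, cor(rnorm(200), rnorm(200))))
  expect_lt(abs(mean_r), 0.01)

  # constant column: pairs reported missing, not an error
  df$k <- 1
  am2 <- association_matrix(df, c("a", "b", "k"))
  expect_true("k" %in% am2$constant)
  expect_true(is.na(am2$q["a", "k"]))
})

test_that("threshold report combines request types with shared FDR", {
  set.seed(30)
  n <- 120
  df <- data.frame(pav = runif(n, 0, 60), sym = runif(n, 0, 4))
  df$arousal_adj <- 5 - 0.047 * df$pav + rnorm(n, 0, 0.1)
  df$valence_adj <- 0.18 * (df$sym >= 2) + rnorm(n, 0, 0.1)
  rep_ <- threshold_report(df, list(
    list(indicator = "pav", emotion = "arousal_adj", type = "slope"),
    list(indicator = "sym", emotion = "valence_adj", type = "step", threshold = 2)))
  expect_equal(nrow(rep_), 2L)
  expect_equal(rep_$estimate[1], -0.047, tolerance = 0.02)
  expect_equal(rep_$estimate[2], 0.18, tolerance = 0.15)
  expect_true(all(rep_$q >= rep_$p))
})
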