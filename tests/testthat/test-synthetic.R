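test_that("archetype presets encode scene counts and village mixes", {
  expect_equal(archetype_preset("xiangmiao")$n_scenes, 54L)
  xq <- archetype_preset("xiaoqiyuan")
  expect_equal(xq$n_scenes, 128L)
  expect_equal(xq$sampling$vegetation_layers$prob[1], 0.64)
  expect_equal(archetype_preset("xiedian")$n_scenes, 94L)
  expect_error(archetype_preset("atlantis"), "presets")
  # custom with no effects: flat latent surface
  cfg <- quiet_config(archetype = "custom", n_scenes = 10, n_participants = 2,
                      seed = 1)
  sc <- simulate_scene_population(cfg)
  lat <- compute_latent_emotions(sc, cfg)
  expect_true(all(lat$scene_expected$arousal_expected ==
                    lat$scene_expected$arousal_expected[1]))
  expect_true(all(lat$trials$valence == lat$trials$valence[1]))
})

test_that("scene populations are deterministic and bounded", {
  cfg <- archetype_preset("xiangmiao", seed = 1)
  a <- simulate_scene_population(cfg)
  b <- simulate_scene_population(cfg)
  expect_identical(a$data, b$data)
  expect_true(all(a$data$gvi_pct >= 10 & a$data$gvi_pct <= 90))
  expect_true(all(a$data$symbol_density >= 0 & a$data$symbol_density <= 4))
  expect_true(all(a$data$vegetation_layers %in% 1:3))
  # a different seed changes the draw
  expect_false(identical(simulate_scene_population(
    archetype_preset("xiangmiao", seed = 2))$data, a$data))
})

test_that("large populations cover both flanks of the GVI peak interval", {
  cfg <- archetype_preset("xiangmiao", n_scenes = 10000, seed = 3)
  sc <- simulate_scene_population(cfg)
  g <- sc$data$gvi_pct
  expect_gt(mean(g < 40), 0.2)
  expect_gt(mean(g > 60), 0.2)
  expect_gt(mean(g >= 40 & g <= 60), 0.1)
})

test_that("latent effects reproduce printed per-unit magnitudes at zero noise", {
  sdf <- data.frame(scene_id = c("a", "b", "c", "d"), village = "custom",
                    hard_pavement_pct = c(0, 10, 0, 10),
                    symbol_density = c(1.9, 1.9, 2.1, 2.1))
  scenes <- scene_indicator_matrix(sdf)
  cfg <- quiet_config(
    archetype = "custom", n_scenes = 4, n_participants = 2,
    effects = list(
      effect_spec("hard_pavement_pct", "arousal", "linear", slope = -0.047),
      effect_spec("symbol_density", "valence", "step", threshold = 2, jump = 0.18)),
    seed = 1)
  lat <- compute_latent_emotions(scenes, cfg)
  ex <- lat$scene_expected
  expect_equal(ex$arousal_expected[2] - ex$arousal_expected[1], -0.47,
               tolerance = 1e-12)
  expect_equal(ex$valence_expected[3] - ex$valence_expected[1], 0.18,
               tolerance = 1e-12)
  # trials at zero noise equal the scene expectations
  i <- match(lat$trials$scene_id, ex$scene_id)
  expect_equal(lat$trials$arousal, ex$arousal_expected[i], tolerance = 1e-12)
})

test_that("effects referencing absent indicators are rejected", {
  sdf <- data.frame(scene_id = "a", village = "custom", gvi_pct = 50)
  sdf <- rbind(sdf, sdf); sdf$scene_id <- c("a", "b")
  scenes <- scene_indicator_matrix(sdf)
  cfg <- quiet_config(archetype = "custom", n_scenes = 2,
                      effects = list(effect_spec("water_visibility_pct",
                                                 "arousal", "linear", slope = 1)),
                      seed = 1)
  expect_error(compute_latent_emotions(scenes, cfg), "water_visibility_pct")
})

test_that("band-power synthesis inverts the emotion formulas exactly", {
  lat <- list(trials = data.frame(scene_id = c("s1", "s2"),
                                  participant = "P01", repeat_idx = 1:2,
                                  arousal = c(4, 2.5), valence = c(0, 3)))
  bp <- synthesize_band_powers(lat, NULL)
  expect_equal(bp$p_alpha_left, c(4, 1))
  expect_equal(bp$p_alpha_right, c(4, 4))
  expect_equal(bp$p_beta_left, c(1, 1))
  expect_equal(arousal(bp), c(4, 2.5))
  expect_equal(valence(bp), c(0, 3))
  # non-positive mapping is an error instructing baseline adjustment
  lat2 <- list(trials = data.frame(scene_id = "s", participant = "P01",
                                   repeat_idx = 1, arousal = 1, valence = 3))
  expect_error(synthesize_band_powers(lat2, NULL), "baseline")
})

test_that("round trip metrics -> aggregation reproduces latent table at zero noise", {
  cfg <- quiet_config(archetype = "custom", n_scenes = 15, n_participants = 4,
                      effects = list(effect_spec("gvi_pct", "arousal", "linear",
                                                 slope = 0.02),
                                     effect_spec("gvi_pct", "valence", "linear",
                                                 slope = 0.01)),
                      baseline_arousal = 5, seed = 9)
  ds <- simulate_dataset(cfg, mode = "band")
  agg <- aggregate_scene_scores(emotion_scores(ds$band_powers), ds$participants)
  i <- match(ds$latent$scene_expected$scene_id, agg$scene_id)
  expect_lt(max(abs(agg$arousal_adj[i] - ds$latent$scene_expected$arousal_expected)),
            1e-9)
  expect_lt(max(abs(agg$valence_adj[i] - ds$latent$scene_expected$valence_expected)),
            1e-9)
})

test_that("band powers are reproducible to 1e-12 under a fixed seed", {
  cfg <- archetype_preset("xiedian", n_scenes = 12, seed = 21,
                          n_participants = 3)
  a <- simulate_dataset(cfg, mode = "band")$band_powers
  b <- simulate_dataset(cfg, mode = "band")$band_powers
  expect_equal(a$p_alpha_all, b$p_alpha_all, tolerance = 1e-12)
  expect_equal(a$p_alpha_left, b$p_alpha_left, tolerance = 1e-12)
})

test_that("raw synthesis hits target band-power ratios within 2%", {
  bp <- bp_table(al = c(4, 2), ar = c(4, 2))
  cfg <- pipeline_config()
  rec <- synthesize_raw_eeg(bp, cfg)
  ep <- epoch_and_baseline(rec, cfg$epoch_window, cfg$baseline_window)
  out <- band_power(ep, cfg$alpha_band, cfg$beta_band)
  expect_equal(out$p_alpha_all / out$p_beta_all, c(4, 2), tolerance = 0.02)
})

test_that("injected artifacts are flagged downstream, and clean data are not", {
  # ~100 one-second windows; every hit must be masked by the rejection stage
  bp <- bp_table(al = rep(4, 67), ar = rep(4, 67),
                 scene = sprintf("s%03d", 1:67), rep_idx = rep(1, 67))
  cfg <- pipeline_config()
  rec <- synthesize_raw_eeg(bp, cfg, artifact_rate = 0.1, seed = 8)
  injected <- attr(rec, "artifact_windows")
  expect_gt(length(injected), 3)
  rec <- reject_bad_segments(rec, cfg$amplitude_threshold)
  expect_equal(which(rec$mask$bad), injected)
  # no noise, no artifacts: nothing masked
  clean <- synthesize_raw_eeg(bp[1:10, ], cfg)
  clean <- reject_bad_segments(clean, cfg$amplitude_threshold)
  expect_equal(sum(clean$mask$bad), 0L)
  expect_error(synthesize_raw_eeg(bp, cfg, artifact_rate = 1.5), "artifact_rate")
})

test_that("participant panel matches the cohort design", {
  cfg <- archetype_preset("xiangmiao", seed = 6)
  pp <- simulate_participants(cfg)
  expect_equal(nrow(pp), 50L)
  expect_equal(sum(pp$gender == "male"), 23L)
  expect_true(all(pp$age >= 22 & pp$age <= 66))
  expect_identical(pp, simulate_participants(cfg))
})

test_that("GVI arousal drop above 70 equals 42% of the analytic peak mean", {
  cfg <- archetype_preset("xiangmiao")
  gvi_step <- Filter(function(e) e$indicator == "gvi_pct" && e$form == "step",
                     cfg$effects)[[1]]
  base_eff <- Filter(function(e) e$target == "arousal" &&
                       e$indicator != "gvi_pct", cfg$effects)
  e_peak <- cfg$baseline_arousal +
    sum(vapply(base_eff, function(ef)
      landemo:::expected_effect(ef, cfg$sampling[[ef$indicator]]), numeric(1)))
  expect_equal(gvi_step$params$jump, -0.42 * e_peak, tolerance = 1e-10)
  expect_equal(gvi_step$params$threshold, 70)
})
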