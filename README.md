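# landemo

Quantifying the emotional response that traditional-village landscape
scenes evoke, from scene-locked EEG, and turning it into actionable scene
rankings and design thresholds. The package is aimed at environmental
psychophysiology and landscape-planning researchers who have (or want to
prototype against) scene-indicator tables and portable-EEG recordings
locked to scene presentations.

## What it computes

**Emotion indices.** Per trial, integrated alpha (8–12 Hz) and beta
(13–28 Hz) band powers give

- arousal: `E_AR = P(α) / P(β)` over all channels,
- valence: `E_VA = P(α)_R / P(β)_R − P(α)_L / P(β)_L` (right-minus-left
  hemispheric asymmetry),

after the standard preprocessing chain (1–45 Hz zero-phase band-pass,
±100 µV window masking, independence-based artifact component removal,
average reference, −200..1000 ms epochs, −200..0 ms baseline, Hann-window
FFT). Trials aggregate to covariate-adjusted (age, gender) scene means.

**Scene evaluation.** Indicators and emotion indices are range-normalized
(`r_ij = (f_ij − min f_j)/(max f_j − min f_j)`, cost criteria reversed),
compared against the ideal sequence by grey relational coefficients
`ε_ij = (Δmin + ρΔmax)/(Δ_ij + ρΔmax)` with ρ = 0.5, weighted by entropy
weights `w_j = (1 − e_j)/Σ(1 − e_j)`, and ranked by the VIKOR compromise
score

```
S_i = Σ_j w_j (1 − ε_ij)      R_i = max_j w_j (1 − ε_ij)
Q_i = v (S_i − S⁻)/(S⁺ − S⁻) + (1 − v)(R_i − R⁻)/(R⁺ − R⁻),  v = 0.5
```

with quartile emotion-quality Levels I–IV and per-scene obstacle degrees
`O_ij = w_j (1 − ε_ij) / Σ_j w_j (1 − ε_ij)` identifying which element most
hinders each scene.

**Thresholds.** Covariate-adjusted slopes with 95% CIs, step effects at
stated thresholds, optimal-interval detection (binned-mean run within 1 SE
of the peak + a two-breakpoint segmented fit), pairwise association
matrices, and Benjamini–Hochberg FDR control.

**Synthetic data.** Because no field data were deposited, a fully seeded
generator emulates the study design (three village archetypes with 54/128/94
scenes, 50 participants, 3 repeats) with the published effect structure
built in, in both band-power and raw-EEG modes. See the methods vignette
(`vignettes/landscape-emotion-methods.Rmd`) for the model, its assumptions,
and every numerical design choice.

## Worked example

```r
library(landemo)
cfg <- archetype_preset("xiangmiao", seed = 1)   # 54 scenes, preset effects
ds  <- simulate_dataset(cfg, mode = "band")
emo <- aggregate_scene_scores(emotion_scores(ds$band_powers), ds$participants)
dm  <- build_decision_matrix(ds$scenes, emo)
res <- evaluate_scenes(dm$values, dm$directions, rho = 0.5, v = 0.5)
```

The three best-ranked scenes and the level distribution:

```
          scene     Q level
 xiangmiao_0028 0.000     I
 xiangmiao_0035 0.083     I
 xiangmiao_0046 0.344     I

  I  II III  IV
 13  14  13  14
```

`Q = 0` marks the compromise-optimal scene (it minimizes both group utility
and individual regret); levels are Q quartiles, so 54 scenes split 13–14 per
level. Entropy weights on this draw concentrate on the high-dispersion
indicators (water visibility 0.472, vegetation layers 0.181), and obstacle
diagnosis names `water_visibility_pct` as the dominant obstacle for 52 of
54 scenes — on this seed the water-poor scenes are what keeps most scenes
away from the ideal.

A published-style dose-response check on the same data:

```r
df <- merge_scene_emotions(ds$scenes, emo)
slope_regression(df, "hard_pavement_pct", "arousal_adj",
                 covariates = c("gvi_pct", "vegetation_layers", "water_visibility_pct"),
                 covariate_bins = list(gvi_pct = 10, water_visibility_pct = 10))
#> hard-pavement slope per 10 pp: -0.454 (95% CI -0.500 to -0.407)
```

i.e. every 10-percentage-point increase in hard pavement lowers the arousal
index by ≈0.45 units on this 54-scene draw (the generator encodes −0.47).

A command-line mirror of the pipeline is installed as `exec/landemo`:

```sh
landemo all --archetype xiangmiao --seed 1 --out results/
```

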