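# pcnmf

Periodicity-coded NMF source separation and information retrieval for
long-duration soundscape recordings.

Fixed-point hydrophone observatories record years of single-channel audio
in which geophony (wind, rain, shipping), biophony (fish choruses,
cetacean vocalizations) and instrument noise overlap in time and
frequency. This package separates those sources *blindly* — with no
labeled training data — using one structural assumption: different sources
recur with different periodicities (daily, lunar, seasonal, or not at
all). It is aimed at ecoacousticians and marine-monitoring groups who need
per-source activity series, phenology summaries and event inventories from
long recordings.

## The method

1. **LTSA.** Each 30-s clip becomes one column of a long-term spectral
   average: `P(f) = 10·log10(mean_t S(f,t))` from a non-overlapping
   Hamming-windowed spectrogram (`build_ltsa()`).
2. **Prewhitening.** The per-bin 10th percentile `n10(f)` is subtracted,
   negatives clipped: `P̌(f,t) = max(P(f,t) − n10(f), 0)` (`prewhiten()`).
3. **PC-NMF.** Layer 1 factorizes the (15-min-patch folded) grid
   `P̌ ≈ W H` with every spectral feature held at Hoyer sparseness
   `(√n − ‖x‖₁/‖x‖₂)/(√n − 1) = 0.5`; layer 2 factorizes the unit-sum,
   DC-removed magnitude DFT of the activations to group features into
   sources by periodicity (`pcnmf()`). Indicators can be corrected
   manually (`adjust_indicators()`).
4. **Reconstruction.** Per-source grids by ratio masking,
   `P_s = P̌ ∘ (W_s H_s)/(W H)` (`separate()`).
5. **Phenology & diversity.** Normalized intensity series, time-lagged
   correlations with 1-day moving-max envelopes, diurnal/lunar/seasonal
   cycle splines; event detection (threshold 0.05, >10-min split, <1-min
   discard), PCA + k-means clustering scored by
   `R_k = 100·(1 − ΣD_i/D_1)`.

A synthetic-scene generator (`demo_scene()`, `generate_ltsa_scene()`,
`generate_wav_scene()`) provides ground-truthed data with the statistical
structure the method assumes, for testing and evaluation.

## Worked example

```r
library(pcnmf)

cfg   <- demo_scene(duration_days = 3,
                    sources = c("abiotic", "fish", "cetacean"),
                    seed = 7, n_freq = 40)
scene <- generate_ltsa_scene(cfg)
model <- pcnmf(scene$grid, n_features = 15, n_sources = 3,
               iterations = 300, seed = 7)
model
#> Periodicity-coded NMF model
#>   features: 15 (sparseness 0.5, patch 30 frames)
#>   sources: 3; feature counts per source: 11/2/2
#>   final layer-1 objective: 896.225 after 300 iterations

sep <- separate(model, scene$grid, iterations = 200, seed = 8)
cp  <- channel_purity(sep, scene$per_source)
lab <- names(scene$per_source)[cp$truth_of_channel]

ch   <- which(lab == "fish")                    # the fish channel
fish <- intensity_series(sep$sources[[ch]], time = scene$times,
                         source = "fish")
evaluate_detection(fish$value,
                   scene$truth$labels[, cp$truth_of_channel[ch]],
                   fpr = 0.05)
#> $tpr 0.962  $threshold 0.064  $fpr 0.05

cycle_model(fish, "diurnal")
#> Cycle model (diurnal) for 'fish'
#>   bins: 144/144 populated; statistic: 95th percentile
#>   peak phase: 19.93 h
```

The model learns 15 spectral features, groups them into three sources by
their periodicity, and the separated fish channel recovers 96% of true
chorus frames at a 5% false-positive budget; the diurnal spline peaks at
19.93 h, matching the scheduled 20:00 dusk chorus. `run_pipeline()` wires
all stages together (training subset, overrides, masking, events,
clustering, report with config hash).

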