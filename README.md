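# pcgbeam

Beamformed diastolic heart-sound analysis for detecting coronary artery
stenosis acoustics.

Turbulent flow through a stenosed coronary artery radiates a faint,
broadband murmur that is best heard in diastole, when coronary flow peaks.
`pcgbeam` implements the measurement chain for multichannel
phonocardiograms recorded by a small (2×2) chest-surface microphone array:

1. **Delay-and-sum beamforming** with geometry-derived sub-sample delays,
   `z(t) = Σ_m y_m(t − Δ_m)`, plus SNR-gain evaluation
   `G = SNR_o / SNR_i` with `SNR = 10·log10((σ_y² − σ_n²)/σ_n²)`;
2. **Diastolic-window isolation** — 128-ms (512-sample) windows placed
   100 ms after each second heart sound, normalized to unit mean energy
   and band-passed 65–500 Hz (Butterworth, order 5, zero-phase);
3. **Per-window features** — approximate entropy
   `ApEn(m, r, N) = Φ^m(r) − Φ^(m+1)(r)` with `m = 2`, `r = 0.1·SD`, and
   the band-energy ratio
   `Ratio = energy above 150 Hz / energy below 150 Hz`;
4. **Group comparison** — one-way ANOVA (explicit sums of squares) across
   pre-stent, post-stent and normal conditions with pairwise contrasts.

Because no patient recordings are public, the package ships a seeded
synthetic phonocardiogram generator (S1/S2 bursts, low-frequency
cardiohemic background, a 150–500 Hz diastolic turbulence murmur for
pre-stent subjects, array propagation, sensor noise) with exact
ground-truth annotations, so the whole chain is testable end to end. See
`vignettes/diastolic-heart-sound-analysis.Rmd` for the model, parameter
choices and design notes.

## Worked example

```r
library(pcgbeam)

# a full synthetic study: 8 diseased subjects recorded before and after
# stent placement, 2 normal subjects, 10 diastolic windows per recording
res <- run_study(config = study_config())
res
#> <pcg_study_result>
#>   180 segments from 10 subject(s)
#>   apen:
#>     pre_stent_vs_post_stent  p = 7.9e-42
#>     post_stent_vs_normal     p = 0.223
#>     pre_stent_vs_normal      p = 1.44e-20
#>   ratio:
#>     pre_stent_vs_post_stent  p = 3.72e-40
#>     post_stent_vs_normal     p = 0.22
#>     pre_stent_vs_normal      p = 1.92e-14

aggregate(cbind(apen, ratio) ~ condition, res$features, mean)
#>    condition      apen      ratio
#> 1     normal 0.5731615 0.02802999
#> 2 post_stent 0.5806836 0.03247934
#> 3  pre_stent 0.6679210 3.75041100
```

Reading the output: diastolic windows recorded **before** stenting carry
more energy above 150 Hz (mean ratio 3.75 vs 0.03) and are less regular
(mean ApEn 0.67 vs 0.58) than windows from the same subjects **after**
stenting — both contrasts overwhelmingly significant — while post-stent
windows are statistically indistinguishable from the clinically normal
subjects (p ≈ 0.22). That is the acoustic signature of removing a
turbulence source.

Individual stages are exported too:

```r
rec  <- generate_cohort(n_diseased = 1, n_normal = 0)$recordings[[1]]
bf   <- delay_and_sum(rec, compute_delays(rec$geometry))
segs <- condition_segments(
          extract_diastolic_segments(bf, detect_s2(bf, "ground_truth")))
segment_features(segs$segments[[1]])
```

A command-line interface (`inst/scripts/pcgbeam`) wraps the same
functions: `simulate`, `beamform`, `segment`, `features` and `study`
subcommands reading/writing WAV, CSV and JSON/YAML.

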