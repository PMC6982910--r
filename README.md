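# bruxsense

Signal-analysis toolkit for **occlusal-force biofeedback**: monitoring the
bite forces of bruxism patients through piezoresistive stress sensors
embedded in an occlusal stabilization splint (OSS), and grading how the
splint surface should be adjusted.

Because the physical splint is a research prototype, the package ships a
**simulator** that stands in for the hardware: it generates multichannel
voltage traces with known clench/grind episodes, per-episode covariates
(contact area, contact points, patient pain level), and three ordered
severity regimes. Everything downstream runs identically on simulated or
recorded traces.

## What it computes

The analysis chain mirrors the prototype's firmware + server stack:

1. **ADC coding** — voltages are quantized by a 10-bit converter with a
   3.6 V reference; the transfer equation is
   `volts = counts × 3.6 / 1024`, so 1024 counts ↔ 3.6 V.
2. **Event detection** — a sleep/wake state machine on the across-channel
   resultant force: wake after `debounce_on` consecutive samples above the
   dentist-set threshold, sleep after `debounce_off` below it, merge
   events closer than a refractory gap. The threshold can be reset
   remotely; every change is audit-logged ([`update_threshold()`],
   [`feedback_step()`]).
3. **Translation-invariant wavelet denoising** — the base denoiser `T`
   soft-thresholds all detail coefficients of a periodized DWT at the
   Donoho universal threshold λ = σ√(2 ln n); cycle spinning averages
   over circular shifts,
   `T̄(x) = Ave_h [ S_{-h} T(S_h x) ]`,
   which removes the shift-dependent pseudo-Gibbs artifacts of the
   decimated transform.
4. **Monitoring statistics** — per tumbling window and channel: AVG, MAX,
   MIN, σ (sd), ψ (variance), and the cross-channel covariance matrix φ
   (population normalization).
5. **Feature extraction** — the five per-window network inputs: mean
   occlusal-force magnitude, mean force duration, mean contact area,
   contact points, and the latest patient pain level; packed with the six
   per-sensor mean forces into 16-channel input blocks.
6. **Adjustment-level grading** — a 1-D inverted-bottleneck residual CNN
   (pointwise-expand → depthwise → pointwise-project with batch norm and
   ReLU6, identity skips; stages 32/64/128/256 channels with six
   bottleneck repeats each, GAP, FC 256→64→3) trained with momentum-0.9
   gradient descent, batch 128, an 80/20 group split. The three output
   levels map to occlusal-adjustment altitudes −0.5 / 0 / +0.5 mm.

The DWT, the network and its backpropagation are implemented in the
package itself (no external wavelet or deep-learning dependency) and are
verified in the test suite against independent brute-force oracles and
numerical differentiation.

## Worked example

```r
library(bruxsense)

p  <- simulation_params(duration = 300, severity_class = 2, seed = 7)
tr <- simulate_trace(p)
tr
#> <sensor_trace> 6 channel(s) x 30000 samples @ 100 Hz, 13 labeled episode(s)

ct <- adc_encode(tr, adc_config())          # 10-bit counts, 3.6 V reference
ev <- detect_events(ct, detector_config(threshold = 150))
nrow(ev)
#> [1] 13                                    # all 13 episodes recovered
head(ev[, c("start", "end", "duration", "mean_force")], 3)
#>   start  end duration mean_force
#> 1   304  477     1.73   369.8092
#> 2  2170 2441     2.71   382.0037
#> 3  2581 2751     1.70   350.2294

window_statistics(ct, 60)[[1]]
#> <monitoring_summary> [0.0, 60.0) s, 6 channel(s), mean avg 115.81 counts

estimate_sigma(tr$values[1, ])              # noise floor, volts
#> [1] 0.0494                                # true noise_sigma was 0.05
```

`duration` is in seconds from the half-open event bounds
(`(end − start) / sampling_rate`); `mean_force` is the mean
across-channel resultant in ADC counts — 370 counts ≈ 1.3 V. A full
session (denoise → encode → detect → featurize → grade) runs through
`run_session()`; see the methods vignette
(`vignettes/occlusal-biofeedback.Rmd`) for the model details, parameter
choices, and what the simulator does and does not emulate.

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript inst/cli/bruxsense simulate --class 2 --duration 300 --seed 7 --out trace.csv
Rscript inst/cli/bruxsense detect   --in trace.csv --threshold 150 --out events.jsonl
Rscript inst/cli/bruxsense denoise  --in trace.csv --wavelet db4 --shifts 32 --out clean.csv
```

(After installation the script is also at
`system.file("cli", "bruxsense", package = "bruxsense")`.)

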