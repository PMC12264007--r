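# spinefusi

Analysis of spinal-cord **functional ultrasound imaging (fUSI)** during
urodynamically controlled bladder filling and emptying — and a fully
seeded synthetic-data generator to validate every stage by parameter
recovery.

fUSI measures the power-Doppler (pD) signal — backscattered
blood-signal power after clutter rejection — as a proxy for local
blood volume, here at 0.1 mm pitch and 1 frame/s over a
12.8 mm × 9.1 mm field of view. During a cystometric fill/empty cycle
(5 min baseline; 600 ml saline at 90 ml/min; two hold periods; 7 min
40 s emptying; washout), some spinal-cord pixels rise and fall with
intravesical bladder pressure. The package implements the full chain
a study of this kind needs:

* **Clutter filtering** — SVD of the Casorati (space × time) matrix of
  200-frame compound blocks at 500 Hz; the largest singular components
  (tissue) are removed and pD is the residual power per pixel.
* **Rigid motion correction** — spectral cross-correlation to the
  baseline-mean template with upsampled-DFT sub-pixel refinement
  (≤ 0.1 px contract), Catmull-Rom constant-edge resampling.
* **Temporal smoothing** — delay-compensated Kaiser-windowed FIR
  lowpass, passband 0.04 Hz, ≥ 60 dB stopband attenuation.
* **%ΔSCBV** — percent pD change relative to the 5-min pre-filling
  baseline, per pixel.
* **Activation mapping** — pixel-wise Pearson r against %BP (percent
  pressure change relative to the first 30 s), Fisher z = atanh(r),
  two-sided t-based p-values, Benjamini–Hochberg FDR (α = 0.01), and
  top-5% positive/negative masks with attained r thresholds.
* **Pressure reconstruction** — transductive linear ε-insensitive SVR
  (dual SMO solver, compiled core):
  F(x) = x′β + b with β = Σₙ(aₙ − aₙ*)xₙ, trained on a seeded 80/20
  frame split (1254 → 1004/250), scored by MSE on [0,1]-normalized
  pressure, β projected back to image space.

## Worked example

```r
library(spinefusi)

protocol <- protocol_spec()                      # 1554 s study timeline
trace    <- simulate_bladder_pressure(protocol, seed = 7)
truth    <- phantom_truth(seed = 7)              # 91 x 128, planted regions
ph       <- generate_phantom(truth, trace, protocol)

pct <- percent_change(lowpass_filter(ph$stack))
bp  <- percent_bp(trace)

map <- top_fraction_masks(pearson_map(pct, bp), fraction = 0.05,
                          alpha = 0.01)
map
#> activation_map: 11648 analyzed px over 1254 frames; masks 583 pos /
#>   583 neg (r >= 0.284 / <= -0.281)

vec   <- vectorize(pct)
y     <- normalize_range(bp[vec$window], "01")
split <- split_80_20(length(vec$window), seed = 7)  # 1004 train / 250 test
model <- train_svr(vec$X[split$train_times, ], y[split$train_times],
                   seed = 7)
recon <- reconstruct_and_score(model, vec$X[split$test_times, ],
                               y[split$test_times], split$test_times)
recon
#> reconstruction_result: 250 test frames, MSE = 0.00047
```

The masks capture the planted pressure-coupled regions almost exactly
(Jaccard ≈ 0.997 against truth at the default coupling SNR ≈ 2.8),
and the held-out pressure curve is reconstructed with MSE ≈ 5 × 10⁻⁴
on the [0,1] scale. The attained r thresholds (here 0.28 / −0.28) are
data-dependent, exactly as in real recordings.

A full multi-subject run with per-subject artifacts (pressure CSV,
reconstruction CSV, NIfTI r/β maps, PNG overlays) and a group summary
(mean ± SE of peak %BP, peak ±%ΔSCBV, region r, MSE, β sums):

```r
res <- run_pipeline(run_config(list(n_subjects = 4, seed = 1,
                                    out_dir = "results/run")))
```

or from the command line:

```sh
Rscript inst/cli/spinefusi.R run --config run.json --seed 1 --out results/run
```

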