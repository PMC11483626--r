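# knottrack

Segmentation and tracking of single, highly curved, **self-intersecting
filaments** in fluorescence microscopy time series.

In motor gliding assays, a filament clamped at one end (for example a
microtubule pinned above surface-immobilized dynein) beats with wave-like,
millihertz oscillations and can bend so far that its 2-D projection
crosses itself. Trackers that assume rod-like, non-intersecting contours
take a short-cut through the crossing or fragment the filament there.
knottrack resolves these "knots" explicitly:

1. **Segmentation** — contrast saturation, median filtering, Otsu
   thresholding, Chan–Vese-style active-contour refinement, and thinning
   to a one-pixel skeleton.
2. **Branch identification** — a skeleton pixel is a branch point when
   its 3×3 Moore-neighborhood sum (center included) is ≥ 4.
3. **Graph mapping** — branch-pixel groups become branch vertices (Vb),
   the remaining segments filament vertices (Vf); edges are their
   attachments, with a self-merging loop contributing two parallel edges.
4. **Template matching** — candidate start-to-end paths are enumerated
   (segment vertices once, branch vertices revisitable, at most 10
   children per expansion) and each candidate contour is scored against
   the previous frame's resolved contour by dynamic time warping,

   D(i,j) = d(i,j) + min{ D(i−1,j−1), D(i−1,j), D(i,j−1) },

   with Euclidean local cost d; the minimal-score path wins.

Accuracy is quantified with a tolerance-based Dice index
(TP = detected pixels within 2 px of ground truth;
Dice = 2TP/(2TP+FP+FN)) and the discrete Fréchet distance, which is
sensitive to contour point ordering and is 0 only for identical curves.

The package also contains the full synthetic study: a traveling-wave
generator of beating clamped filaments, ψ(s,t) = ψ₀ + B·s/L +
A·(s/L)·sin(2π(s/λ − t/T)), rendered through diamond dilation (radius 2),
a 3×3 Gaussian PSF (σ = 2), and Gaussian noise at a chosen SNR in dB
(noise power = image variance / 10^(SNR/10)).

## Worked example

Simulate a knotting filament at SNR 10 dB, segment every frame, track it,
and benchmark against the known ground truth:

```r
library(knottrack)

p <- wave_params(length_um = 20, pixel_size_um = 0.1, amplitude_rad = 3.5,
                 wavelength_um = 15, period_s = 200, n_frames = 20, dt_s = 10)
frames <- synthesize_series(p, snr_db = 10, seed = 42)

skels <- lapply(frames, function(f) segment_frame(f$image))
first_clear <- which(!vapply(skels, function(s) s$is_branched, logical(1)))[1]
base <- frames[[1]]$truth_curve$points[1, ]
track <- track_series(skels[first_clear:20], start_rc = c(base[2], base[1]))
track
#> <filament_track> 16 frames: 16 resolved (12 branched), 0 skipped

head(track_stats(track, pixel_size_um = 0.1), 3)
#>   frame   length tip_angle_rad end_to_end
#> 1     1 19.99934      3.126668   8.758788
#> 2     2 19.80761      1.668387   9.044940
#> 3     3 20.13683      1.452828   8.826756

bench <- benchmark_track(track, lapply(frames[first_clear:20],
                                       function(f) f$truth_curve))
round(colMeans(bench[, -1]), 3)
#>        dice  frechet_px mean_err_px   sd_err_px
#>       0.989       2.985       0.384       0.278
```

Twelve of the sixteen tracked frames are self-intersecting, yet every
frame is resolved: the recovered 20 µm filament length is stable, the mean
pixel position error is ≈ 0.38 px (sub-pixel), and the tolerance-based
Dice against ground truth is 0.99. `write_stats_summary()` exports the
per-frame table (frame number, filament length, tip angle, end-to-end
distance) as a `statsSummary.txt` with a parameter header;
`tangent_kymograph()` and `power_spectrum()` quantify the beat — on the
120-frame study condition both the tip angle and the end-to-end distance
peak at 0.005 Hz, the generator's oscillation frequency.

Batch processing follows a two-step flow: describe each ROI on one line of
a parameter CSV (`read_params_csv()` / `write_optimized_csv()`), then
`run_batch()` segments, tracks, and writes `statsSummary.txt`,
`contours.csv`, and — when a ground-truth CSV is attached — a
`benchmark.csv` per ROI. Frames the enumeration cannot resolve can be
pinned down with `manual_override(frame, vertex_sequence)`. A thin
command-line wrapper with `sim`, `resolve`, and `bench` subcommands is
installed at `inst/cli/knottrack.R`.

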