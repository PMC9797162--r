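# detrack

Markerless tumor tracking (MTT) for lung radiotherapy follows the tumor on
treatment-time kV projections without implanted fiducials. Dual-energy (DE)
imaging makes the tumor visible behind ribs: alternating low/high-kVp
projections are combined by weighted logarithmic subtraction,

    I_DEST = ln I_H − w_ST · ln I_L        (soft-tissue image, w_ST = 0.42)
    I_DEB  = −ln I_H + w_B · ln I_L        (bone image,        w_B  = 0.70)

but bone removal amplifies quantum noise, so DE noise-reduction techniques —
simple smoothing (SS), anticorrelated noise reduction (ACNR), noise clipping
(NC), and NC-ACNR — interact with the band-pass (difference-of-Gaussians)
filter settings used by normalized-cross-correlation template tracking.
`detrack` is a laboratory for exactly that interaction, for medical-physics
researchers who want to study it with *known* ground truth:

* an analytic thorax phantom (lungs, ribs, vascular clutter, moving tumor)
  with exact parallel-beam projections, Poisson noise and a detector
  point-spread, so every simulated trajectory is exactly known;
* the DE subtraction and all four noise-reduction variants, implemented as
  published (3×3 median SS, 20×20-box ACNR high-pass with w_n = 0.35,
  17×17-median noise clipping);
* per-degree template generation, DoG band-pass filtering
  (σ_low = 0.2…0.8 mm, σ_high = 2…5 × σ_low), NCC matching with a
  missing-frame threshold;
* a constant-acceleration Kalman filter for ground-truth estimation from
  noisy tracks (the clinical fallback when no truth exists);
* tracking metrics — TSR (% of tracked frames within 2 mm, strict), RMSE
  over tracked frames, missing-frame percentage — plus paired Wilcoxon
  signed-rank comparisons between techniques over the full
  replicate × band-pass sweep.

## Worked example

Simulate a short noisy DE arc, apply ACNR, track the tumor, and score it
against the exact simulated trajectory:

```r
library(detrack)

phantom <- default_phantom()          # thorax + lungs + ribs + vessels + tumor
motion  <- motion_model()             # 8 mm SI / 2 mm lateral, 4 s breathing
acq     <- acquisition_spec(n_pairs = 150, seed = 7)

seqn  <- simulate_sequence(phantom, motion, acq)
bank  <- generate_templates(phantom)  # one template per degree
frames <- lapply(seq_along(seqn$frames), function(k)
  apply_technique(seqn$frames[[k]]$high, seqn$frames[[k]]$low, "ACNR",
                  angle_deg = seqn$meta$angle_deg[k]))

track <- track_sequence(frames, bank, search_config(),
                        bandpass_params(0.4, 1.6),
                        spec = phantom, motion = motion)
track_metrics(track, seqn$gt)
```

```
TSR 81.6% (<2 mm), RMSE 2.78 mm, missing 6.0% (141/150 tracked)
```

Read: of 150 frames, 9 fell below the NCC acceptance threshold (missing);
of the 141 tracked frames, 81.6% landed within 2 mm of the true tumor
position, and the root-mean-square error over tracked frames was 2.78 mm —
numbers in the range reported for clinical markerless lung-tumor tracking.
The same run with `"unprocessed"` instead of `"ACNR"` prints

```
TSR 86.0% (<2 mm), RMSE 2.35 mm, missing 28.7% (107/150 tracked)
```

— nearly five times the missing-frame rate at this band-pass setting:
the anticorrelated-noise correction's published benefit is exactly this
large reduction in frames the tracker must give up on, at the price of
attempting (and sometimes fumbling) the hard frames, which is why TSR
over tracked frames must always be read together with the missing rate
(see the methods vignette).

The full evaluation — every technique × band-pass cell × noise replicate —
is one call:

```r
cfg <- sweep_config(techniques = c("unprocessed", "ACNR"), n_replicates = 3,
                    acquisition = acquisition_spec(n_pairs = 150))
res <- run_sweep(cfg)
summarize_sweep(res)$best
compare_techniques(res, "ACNR", "unprocessed")
```

`vignettes/detrack-methods.Rmd` documents the models, the phantom design
and its calibration, all tunable parameters, and the known limitations
(including which clinical trends this phantom does and does not
reproduce).

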