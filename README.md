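# manifoldcine

Joint free-breathing, ungated cardiac cine and myocardial T1 mapping from
spiral inversion-recovery spoiled-GRE k-space data, by manifold (generative
network) reconstruction — with a built-in dynamic phantom and acquisition
simulator so the whole method can be exercised, validated and benchmarked
without scanner data.

The package is aimed at MR physics and image-reconstruction researchers who
want a self-contained, CPU-only reference implementation of this family of
methods: self-gating from k-space navigators, bandlimited latent
disentanglement, deep-image-prior-style dynamic reconstruction, and Bloch
fingerprint T1 quantification.

## The method

Data are acquired continuously with golden-angle (137.5°) spiral interleaves
under repeated inversion blocks (adiabatic inversion, 800 readouts at
TR 8 ms, flip 14°, 500 ms recovery delay; 6.9 s inversion period, 34 s per
slice). Binning 5 spirals per frame gives 800 frames at 40 ms resolution;
frames of the first block are discarded to avoid the start-up transient.
Each frame `x_t` is modeled as the output of a CNN generator driven by
three scalars — cardiac phase, respiratory phase, and the known inversion
signal `p_t`:

    x_t = G_ζ(z_card,t, z_resp,t, p_t),      b_t = A_t(x_t) + n_t

where `A_t` is the multichannel non-uniform Fourier operator on the frame's
interleaves. Reconstruction is two-step:

1. **Latent estimation.** A conditional variational autoencoder maps the
   k-space-center navigators (plus `p_t`) to 2-D latent tracks whose means
   are constrained to sparse sinusoidal combinations inside the
   physiological bands (cardiac 0.8–2 Hz, respiratory 0.1–0.6 Hz), with an
   l1 penalty on the band coefficients. This disentangles heartbeat and
   breathing even though the navigators are strongly modulated by the
   inversion pulses.
2. **Image reconstruction.** With the latents frozen, the generator
   parameters are trained against the entire measured k-t space
   (data-consistency + Jacobian smoothness penalty, stochastic frame
   batches).

T1 maps come from Bloch fingerprint matching: a dictionary of
frame-binned signal evolutions over a T1 grid (20–2500 ms, 5 ms steps) is
matched per pixel by maximal normalized inner product, either on a
generative sweep of `p` at fixed cardiac/respiratory phase, or on
retrospectively binned frames (data-consistent mode). Agreement is
summarized by R² and ICC(A,1).

## Worked example

Bloch-simulate a myocardial fingerprint, build a dictionary, and recover
T1 from a noisy measurement:

```r
library(manifoldcine)

timing <- sequence_timing()        # TR 8 ms, flip 14 deg, 800/block, 5 blocks
timing
#> IR spoiled-GRE timing:
#>   TR 8.000 ms, flip 14.0 deg, 800 readouts/block, delay 500 ms, 5 blocks
#>   inversion period 6.900 s, scan duration 34.000 s

dict <- build_dictionary(seq(0.02, 2.5, by = 0.005), timing)
fp   <- simulate_ir_spgr(1.05, 1, timing)          # "myocardium"
sched <- frame_schedule(timing, 5L)
s <- tapply(fp$signal, rep(sched$frame_index, each = 5), mean)
s <- s[!sched$discard]                              # discard block 1
set.seed(1)
noisy <- s + rnorm(length(s), 0, sqrt(mean(s^2)) / 10^(30/20))  # 30 dB SNR
tis   <- rep(dict$timepoint_ti_s, 4)
m <- match_fingerprints(noisy + 0i, dictionary_at_tis(dict, tis),
                        dict$t1_grid_s, tis)
m$t1_s
#> [1] 1.03
```

The estimate lands within 2% of the generating 1.05 s at this noise level.
The full pipeline (phantom simulation → latent estimation → generator
training → T1 maps → evaluation) runs with:

```r
cfg <- run_config(grid_size = 32L, n_samples_per_spiral = 150L,
                  noise_sigma = 0.097, seed = 1)
report <- cmd_run_all(cfg, "run")
```

which writes per-stage artifacts (dataset container, latent tracks + CSV,
trained generator, NIfTI T1 maps) plus `report/report.md` with latent
recovery scores, reconstruction NRMSE against the gridding baseline, and
the per-tissue T1 table. The same stages are available from the shell via
`inst/cli/manifoldcine.R` (`simulate`, `estimate-latents`, `reconstruct`,
`t1map`, `evaluate`, `run-all`, `calibrate`).

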