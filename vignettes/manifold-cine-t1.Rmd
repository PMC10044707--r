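---
title: "Joint free-breathing cardiac cine and T1 mapping: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint free-breathing cardiac cine and T1 mapping: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(manifoldcine)
```

# The reconstruction problem

A free-breathing, ungated cardiac acquisition collects golden-angle spiral
k-space continuously while the longitudinal magnetization is repeatedly
inverted. Every 6.9 s an adiabatic inversion pulse is followed by 800
spoiled-GRE spiral readouts (TR 8 ms, flip 14°) and a 500 ms recovery
delay; five such blocks give a 34 s single-slice scan. Binning five spirals
per frame yields 800 frames at 40 ms temporal resolution, each massively
undersampled on its own. Every frame mixes three sources of change: cardiac
motion (0.8–2 Hz), respiratory motion (0.1–0.6 Hz), and the
inversion-recovery contrast sweep.

The package models each frame $x_t$ as the output of a convolutional
generator driven by three scalars,

$$x_t = G_\zeta(z_{\mathrm{card},t},\, z_{\mathrm{resp},t},\, p_t),$$

where $p_t \in (0,1]$ is the known, fixed inversion signal (time since the
last inversion, normalized by the 6.4 s acquisition span of a block) and the
two motion latents are estimated from the data. The acquisition model per
frame is $b_t = A_t(x_t) + n_t$ with $A_t$ the multichannel non-uniform
Fourier operator on that frame's spiral interleaves. Reconstruction is a
two-step procedure: (1) estimate the latents from k-space navigators with a
bandlimited conditional VAE; (2) train $G_\zeta$ against the measured
k-space with the latents frozen.

# Signal model and dictionary

`simulate_ir_spgr()` tracks only $M_z$ between excitations (perfect
spoiling). Per block: inversion $M_z \leftarrow -\epsilon M_z$, then for
each readout relaxation over one TR, signal $M_z \sin\alpha$, and
excitation $M_z \leftarrow M_z\cos\alpha$; the recovery delay relaxes the
remainder. The inversion is treated as instantaneous with the first readout
one TR later, and the inversion efficiency $\epsilon$ defaults to 1
(adiabatic pulse) but is exposed.

Two consequences of this regime matter downstream. First, 800 excitations
saturate $M_z$ to its driven fixed point well within one block, so blocks
2..n are periodic to numerical precision and the first block alone carries
the start-up transient — which is why frames of block 1 are discarded
everywhere. Second, the apparent recovery time constant under saturation is
much shorter than T1, so most T1 discrimination lives in the early part of
each block plus the steady-state amplitude.

`build_dictionary()` samples, for each grid T1, the frame-binned (5-spiral
mean) signal of one periodic steady-state block; the recorded TI of a frame
is its temporal midpoint (20 ms for the first frame), which minimizes the
worst-case TI error across the frame's spirals. The default grid is
20–2500 ms in 5 ms steps: it must reach below the shortest reference sample
(~22 ms) and above blood (~2 s), and the step sits below the
noise-limited precision at 30 dB. Whether fingerprints should include the
approach to steady state is not determined by the protocol; the package
uses the periodic steady state (simulated with extra settle blocks), so
measured data retain small residual transients relative to the dictionary,
as they do in acquisition.

# Spiral encoding

`make_golden_spiral()` produces an Archimedean center-out interleave
reaching the Nyquist radius (|k| = 0.5 cycles/pixel) in `n_turns`
revolutions, rotated by 137.5° per interleave. The exact interleave
waveform of a scanner implementation is not reproducible from published
text; any smooth center-out spiral satisfying the radius and rotation
invariants is acceptable, and externally supplied coordinates can be loaded
through the same container.

`nufft_forward()`/`nufft_adjoint()` evaluate the non-uniform DFT *exactly*,
factorizing $e^{-i2\pi(k_x x + k_y y)}$ into two thin matrices and using
BLAS-level complex products. At the grid sizes this package targets
(16–64), the exact operator is faster to build than an approximate
gridding kernel, is its own adjoint test, and removes interpolation error
from every oracle comparison. Density compensation uses annular-area
weights per interleave (the ring a sample owns between radial midpoints,
divided by the interleaves sharing that radius); with at least $\pi \cdot
\mathrm{grid}$ interleaves, $A^H D A \approx I$ to a few percent.

# The synthetic phantom

`make_phantom()` builds anti-aliased ellipses: static torso and reference
vial, a liver and a myocardium/blood-pool pair that translate with
respiration, and cardiac contraction that shrinks the blood pool (the
myocardial outer wall follows with 40% of the amplitude, so the wall
thickens in systole). The contraction waveform is a sharpened raised
cosine, mimicking the systole/diastole asymmetry; respiration is rigid
translation (2 px minimum excursion — about 2 cm at desk resolution).
Motion frequencies default to 1.2 Hz and 0.25 Hz, inside the physiological
bands. A fixed smooth phase map makes the data genuinely complex, and
rendering happens *per spiral readout*, so intra-frame motion and contrast
evolution are really present in the k-space data while the reconstruction
treats each frame as one image — the binning error of the method is
faithfully simulated.

Blood-pool inflow is modeled explicitly because it is the mechanism that
makes the k-space center cardiac-sensitive in this sequence: the adiabatic
inversion is non-selective but the slice excitation is selective, so blood
flowing into the slice follows free inversion recovery instead of the
saturated in-slice curve and is far brighter. The blood signal is a mixture
of the two curves with a fresh fraction tracking the contraction waveform
(peak 0.6 at systole). Without this term the cardiac component of the
navigators is an order of magnitude too weak to gate on — and with it, the
blood pool nulls near $T_1\ln 2 \approx 1.1$ s, reproducing black-blood
contrast. The cost is a knowingly biased *blood* T1 (flow biases real
measurements too); myocardium is in-slice and unbiased, so quantitative
recovery statements focus on it.

Synthetic coil maps are six Gaussian-bump sensitivities on a ring (width
0.45 FOV — local, array-like; broad coils barely encode a 2 px
translation) with smooth per-coil phase; ESPIRiT-style estimation from data
is out of scope and measured maps can be substituted in the same array
format.

What passing tests on this phantom do *not* show: performance under
arrhythmia, bulk motion, B0 blurring, imperfect coil maps, or anatomy more
complex than ellipses. The phantom exists to make the method's own
contracts testable, not to claim in-vivo performance.

# Latent estimation (step 1)

The navigator of a frame is the k-space center: the first sample of each of
its spirals, averaged within the frame, split into real and imaginary parts
per coil, and z-scored per feature. How many central samples constitute
"the center" is not fixed by the protocol; one per spiral is the default
and the count is exposed.

The conditional VAE is deliberately small: encoder
(features + $p_t$) → 25–50–100–70 → ($z$, $\log\sigma^2$), decoder
($c_t$, $p_t$) → 70–100–50–25 → features, ReLU throughout, linear output.
A published description of this design pairs the listed widths with a
"three-input" network; the three inputs describe the decoder (2 latents +
$p$), and the listed widths are the hidden layers — the encoder input is
the navigator vector plus $p$. The loss is

$$\sum_t \frac{\|D(c_t,p_t)-b_t\|^2}{2\sigma^2} + \sum_t \mathrm{KL}_t
 + \lambda\|e\|_1 + \lambda_2\|d\|_1
 + w_b\big(\|z_\mathrm{card}-Ce\|^2 + \|z_\mathrm{resp}-Rd\|^2\big),$$

with $c_t = z_t + \sigma_t \odot \varepsilon$ (reparameterization), the KL
in closed form with $\Sigma_t$ read as diagonal *variances*, and $e =
(C^TC)^{-1}C^Tz_\mathrm{card}$, $d$ likewise, recomputed from the full
track every step (per-batch projections would make the sparsity penalty
depend on batch composition). $C$ and $R$ hold cosines and sines on
frequency grids inside 0.8–2 Hz and 0.1–0.6 Hz at the actual gapped frame
times, step $1/T$; the recovery delays make them non-orthogonal, so
projection uses the normal equations with a vanishing ridge. The band
constraint appears twice on purpose: as a soft penalty during training
(an exact hard constraint would leave the out-of-band component of the
encoder unpenalized by the $\ell_1$ term alone) and as a hard projection on
output — the returned tracks are $Ce$ and $Rd$. Assigning 0.8–2 Hz to the
cardiac latent and 0.1–0.6 Hz to the respiratory one follows physiology
(48–120 bpm hearts, 6–36 breaths/min).

Optimization is full-batch Adam (the track-level band projection wants full
batches anyway): 2000 epochs at $3\times10^{-3}$ with stepped decay, the
log-variance head initialized at $-4$ so early epochs are not dominated by
reparameterization noise. $\lambda$ follows the spectral-peak recipe — pick
the value whose cardiac spectrum has the best-defined peak, then freeze it
(`calibrate_vae_lambda()`). Too small a $\lambda$ reproduces the
characteristic failure mode of this sequence: a latent locks onto the
inversion-block repetition rate (1/6.9 s ≈ 0.145 Hz, inside the
respiratory band) instead of breathing. The synthetic-navigator defaults
are $\lambda = 0.1$, $\sigma = 0.25$; the full-pipeline navigators are
harsher (inflow-dominated, multiplicative IR modulation) and were
calibrated once to $\lambda = 1$, $\sigma = 0.12$, 3000 epochs.

# Image reconstruction (step 2)

The generator has eight mapping layers: a dense stem to an 8×8 feature
block, then seven 3×3 convolutions with leaky-ReLU (slope 0.1), nearest
upsampling by 2 ahead of early convolutions until the target grid, and a
two-channel tanh output (real, imaginary). Channel widths are planned so
the parameter count lands near 15× the pixel count (enforced to [10, 20]);
kernel sizes and upsampling positions beyond that are free choices. The
measured k-space is rescaled so the gridding reconstruction peaks at
modulus 0.9, keeping targets inside the tanh range; the scale is retained
on the model.

Training minimizes data consistency plus $\eta$ times a stochastic
Frobenius-norm estimate of the latent Jacobian. Batches come from a random
partition of all frames, reshuffled after every full sweep, so every frame
is visited equally often; $z$ and $p$ are frozen (training asserts the inputs are byte-identical
afterwards; nothing backpropagates into the track — the two-step structure
is the point). The Jacobian estimate probes random isotropic directions
$v$ and evaluates $\|(G(z+\epsilon v) - G(z-\epsilon v))/2\epsilon\|^2$;
for isotropic unit-variance $v$ its expectation is $\|J\|_F^2$, it is
exact for linear maps at any $\epsilon$, and — unlike a
Hutchinson/double-backprop estimator — its parameter gradient needs only
ordinary backpropagation through the two forward passes.

One numerical choice deserves emphasis: the data residual is weighted by
the density-compensation function (`precondition = TRUE`). Spiral sampling
piles thousands of samples near k = 0, so the unweighted loss is almost
entirely a low-frequency penalty and image detail converges impractically
slowly; dcf weighting approximates an image-domain error and cut the
well-posed benchmark's error by a factor of about three at equal step
count. The weights are positive, so the noiseless minimizer is unchanged;
the plain objective remains available.

# T1 mapping

A practical information limit is worth knowing: under this saturated
readout, small TI subsets carry little late-recovery information, so
matching on fewer than ~30 well-spread TIs is noise-limited at the long-T1
end (tens of grid steps of spread at 30 dB), while the full per-block
profile recovers every grid entry to within two steps. Retrospective bins
should therefore not be made narrower than the TI coverage they need.

Matching restores signed polarity by rotating each pixel's complex series
by the phase of its largest-TI sample (most recovered, $M_z > 0$), then
takes the real part and maximizes the normalized inner product against the
dictionary, ties toward the smaller T1. The generative mode fixes
$(z_\mathrm{card}, z_\mathrm{resp})$ — by default the median latents, the
most-visited phase — and sweeps $p$ over the frame-midpoint TIs of one
block (160 points; the sweep step is exposed). The binned mode selects
acquired frames inside a latent-space box and matches against the
sub-dictionary at those frames' TIs; fewer than four frames or TIs raises
an explicit bin-too-narrow error suggesting wider half-widths. Agreement
is summarized by $R^2$ and ICC(A,1) from the two-way ANOVA mean squares.

# Generative versus binned T1 at desk scale

The two T1 modes behave very differently at small scale, and the reason is
quantitative. The binned mode matches images generated at latent/contrast
combinations that actually occurred — the same points the training loss
constrains — and its myocardial medians land within ~5% of truth once the
generator fits the data well. The generative mode excites the model at one
fixed phase across *all* inversion times; most of those combinations never
occurred in the 34 s scan, so their values are interpolations across the
latent manifold. Two numbers explain why that is fragile here: the
saturated-readout dictionary is nearly collinear (normalized correlation
0.998 between the 1.05 s and 0.6 s atoms over a full block profile), and a
5% structured error in a pixel's curve already moves the matched T1 by
about 11%. Desk-scale interpolation error exceeds that, so generative maps
at 32×32 under-read substantially while binned maps do not — matching
ground-truth image curves, by contrast, recovers every region to within a
few percent, which localizes the gap in the generator's off-data
interpolation rather than in the matching chain. The Jacobian weight
(calibrated over a log grid; 0.05 kept) narrows but does not close this
gap; closing it needs the full-resolution, long-training regime.

# Problem sizes

All defaults were chosen so a single CPU core handles them comfortably: the
test suite exercises grids of 16–32 with the full 4000-spiral protocol and
reduced training budgets, and the shipped pipeline default is a 64×64 grid.
The same code paths scale up by raising the configuration values; nothing
is specialized to the small sizes.

# Known limitations

- The generator and VAE are trained per dataset (subject-specific); there
  is no cross-subject generalization and none is claimed.
- Blood T1 is intentionally flow-biased in the phantom (see above).
- Respiratory recovery from a 32×32 desk-scale dataset is the weakest link
  of the chain (sub-2-pixel motion under heavy inflow modulation); cardiac
  and contrast factors dominate the reconstruction quality.
- No B0/off-resonance model, no slice profile, no T2 or magnetization
  transfer effects, no eddy-current trajectory errors.
- The retrospective-binning mode inherits whatever bias the latent tracks
  carry; it is data-consistent only up to the trained generator's fit.
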