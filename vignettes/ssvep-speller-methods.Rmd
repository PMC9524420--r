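---
title: "Simulating and decoding a frequency-phase coded SSVEP speller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding a frequency-phase coded SSVEP speller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepkit)
```

## The problem

A steady-state visual evoked potential (SSVEP) speller presents a grid of
targets that flicker at distinct frequencies. When a user fixates one
target, their occipital EEG oscillates at that frequency and its harmonics,
so the attended target can be identified from a short EEG window. A dense
speller (40 targets) cannot give every target a well-separated frequency
inside the usable 8–16 Hz band, which is why modern systems use *hybrid
frequency–phase coding*: targets share a fine 0.2 Hz frequency grid and are
additionally separated by an equally spaced phase ramp.

`ssvepkit` implements this pipeline end to end: codebook construction,
stimulus waveform sampling, a forward simulator of multi-channel SSVEP
epochs, canonical-correlation decoding (plain, filter-bank, and
template-extended), and simulated-online evaluation with leave-one-out
cross-validation, accuracy, and the Wolpaw information transfer rate.

## Stimulus coding

Target $n$ (0-based) is assigned

$$f_n = f_0 + n\,\Delta f, \qquad
  \phi_n = (\phi_0 + n\,\Delta\phi) \bmod 2\pi .$$

Defaults are $f_0 = 8$ Hz, $\Delta f = 0.2$ Hz, $\phi_0 = 0$,
$\Delta\phi = \pi/2$, giving the classic 40-target grid spanning
8.0–15.8 Hz; target 22 is the 12.4 Hz stimulus. These four numbers are the
only equal-interval grid that places both commonly analyzed frequencies
(9 Hz and 12.4 Hz) on the grid while using phase intervals from
$\{0, \pi/2, \pi, 3\pi/2\}$; all four are user parameters.

The displayed luminance for a target is the sampled sine
$0.5\,(1 + \sin(2\pi f_n t + \phi_n))$ at the monitor frame rate — the
mapping to $[0,1]$ is a display convention, chosen so the mean luminance
over an integer number of cycles is exactly one half.

```{r codebook}
cb <- build_codebook()
cb[cb$index %in% c(0, 22, 39), ]
```

## The forward simulator

Real SSVEP recordings for this paradigm are not publicly deposited, so the
package ships a generator whose epochs have the statistical structure the
decoder assumes. Channel $c$ of an epoch for target $n$ carries

$$x_c(t) = g_c \sum_{k=1}^{H} k^{-d}\,
  \sin\!\left(2\pi k f_n t + k\phi_n\right) + \varepsilon_c(t),$$

with $H = 5$ harmonics decaying as $k^{-1}$ (defaults; the literature
agrees the response appears at the stimulation frequency and its harmonics
but not on exact amplitudes), occipital channel gains $g_c = 1$ for
O1/O2-type electrodes and $0.2$ elsewhere, and $1/f^\alpha$ Gaussian
background noise ($\alpha = 1$, standard EEG phenomenology) scaled so each
channel's signal-to-noise power ratio matches a requested `snr_db`. A
deterministic 50 Hz mains component and a constant response latency are
available but default to zero. Defaults for the acquisition match a typical
recording: 1 kHz sampling, the 21-channel 10–20 montage, 0.5–100 Hz band.

What the generator does **not** emulate: volume conduction and realistic
channel covariance, non-stationarity, eye-blink and muscle artifacts, and
inter-subject variability. Passing tests on synthetic sessions therefore
demonstrate the correctness of the decoding and evaluation machinery — not
the accuracy one would obtain on real EEG, whose published headline numbers
depend on the original subjects' recordings.

Every epoch is a deterministic function of `(code, duration, model, spec,
seed)`; sessions fan one master seed out to per-epoch child seeds with a
fixed multiplicative-congruential rule (`split_seed()`), so any stage can
be reproduced in isolation.

## Decoding

For a candidate frequency $f_m$ the reference set stacks harmonics
$\sin(2\pi k f_m t)$, $\cos(2\pi k f_m t)$, $k = 1..H$, evaluated at
$t = 1/F, \dots, P/F$. Canonical correlation analysis finds projections
$w_x, w_y$ maximizing the correlation between the projected EEG and the
projected reference; the decision is
$\hat f = \arg\max_m \rho_m$, ties broken toward the lowest index for
determinism.

Numerically, `cca_coefficient()` whitens the two covariance blocks by
Cholesky factors and takes the largest singular value of the whitened
cross-covariance. Each covariance diagonal receives a $10^{-10}$ *relative*
ridge: proportional ridging keeps $\rho$ exactly invariant under
per-channel rescaling while making short-window solves well-posed. If a
block is still not positive definite, one absolute ridge escalation
($10^{-6}$ of the mean channel variance) is attempted with a warning;
constant inputs raise an error. The test suite checks this solver against
an independent generalized-eigenproblem oracle to $10^{-8}$ on random
instances.

Two extensions are provided:

* **Filter-bank CCA** decomposes the epoch into sub-bands (defaults: lower
  edges 8, 16, 24, 32, 40 Hz, common upper edge 88 Hz) and combines
  per-band squared correlations with weights $w(b) = b^{-1.25} + 0.25$ —
  the standard construction in the filter-bank CCA literature; every
  element is configurable. A single full-band sub-band with unit weight
  reduces exactly to plain CCA ordering.
* **Template-extended CCA** averages training trials per target and scores
  $\rho_{\text{ref}}^2 + \rho_{\text{template}}^2$ with equal weight. The
  equal weighting is a documented choice; no canonical combination rule
  exists for this pairing.

Phase-coded targets sharing a frequency differ by a time shift of the
steady-state response. `phase_shift_template()` maps a zero-phase template
to phase $\phi$ by a circular shift of
$\operatorname{round}\!\big(\tfrac{(2\pi - \phi) \bmod 2\pi}{2\pi f} F\big)$
samples applied backward in time, which makes $\phi = 0$ the identity,
$2\pi$ equal to $0$, and reproduces $\sin(2\pi f t + \phi)$ exactly for
integer-sample shifts. Rounding to whole samples is deliberate —
sub-sample interpolation buys nothing at 1 kHz sampling.

## Zero-phase filtering

Band-pass steps (the acquisition band and the filter-bank sub-bands) use
Butterworth designs from the `signal` package applied forward–backward.
Plain forward–backward filtering leaves edge transients that are
substantial on short windows, and mirror-padding leaves a kink exactly at
the window boundary. The package instead extends each window by Burg
autoregressive linear prediction (order 20, 250 samples per side) before
filtering: the AR extension continues oscillatory content smoothly, and
Burg models are minimum-phase so the extrapolation always decays. With
this scheme a 10 µV DC offset is removed completely and a tone one octave
above the upper cutoff is attenuated below 1% RMS on a 2 s window.

## Simulated-online evaluation

`loo_cv()` emulates online operation causally: for each data length $L$
every epoch is truncated to its first $\operatorname{round}(L F)$ samples
and decoded; template decoders build their averages only from the
remaining trials. Plain CCA and FBCCA need no training, so cross-validation
degenerates to per-trial scoring — the "simulated online" and "offline"
views coincide under causal truncation, which is how the package
operationalizes both. Accuracy $p$ over $N$ targets gives bits per
selection

$$B = \log_2 N + p\log_2 p + (1-p)\log_2\frac{1-p}{N-1},$$

with $0\log 0 = 0$, and $\mathrm{ITR} = 60\,B/T$ bits per minute with
$T = L + t_{\text{gaze}}$. The gaze-shift allowance $t_{\text{gaze}}$
defaults to 0.5 s, the convention in the SSVEP-speller literature; it is
surfaced prominently because ITR scales as $1/T$, and any reported optimum
data length depends on it. The default sweep covers 0.5–4 s in 0.5 s
steps; the grid is fully configurable, and a finer grid (0.1 s steps below
1 s) is the way to probe the short-window ITR optimum, which real systems
report near 0.6 s.

```{r eval, eval = FALSE}
spec <- acquisition_spec(250, paste0("CH", 1:8), band = c(0.5, 100))
model <- ssvep_model(snr_db = 0, channel_gains = rep(1, 8))
es <- simulate_session(cb, trials_per_target = 3, duration = 4,
                       model = model, spec = spec, seed = 101)
report <- loo_cv(es, decoder_config("cca"), eval_config())
report$summary
```

At 0 dB per-channel SNR the decoder is already at ceiling for every window
length, so accuracy is flat at 1.0 and ITR is maximal at the shortest
window — the degenerate end of the accuracy/speed trade-off. Lowering
`snr_db` moves the system into the regime where accuracy still climbs with
data length while ITR peaks at an interior window.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full 40-target system
at a 250 Hz sampling rate with 4–8 channels and up to 3 trials per target
(120-trial sessions, mirroring the 4-target × 30-trial sessions of typical
protocols). These sizes were chosen so a complete run exercises every code
path at full target density; the mathematics is invariant to the sampling
rate as long as all modeled harmonics stay below Nyquist, and the package
defaults remain the full 1 kHz / 21-channel acquisition. The chance-level
check uses epochs whose evoked component is set 200 dB below the noise —
operationally pure noise through the identical generation path.

## Known limitations

* The synthetic noise is spatially white across channels; real EEG noise
  is spatially correlated, which CCA exploits less favorably. Absolute
  accuracies on synthetic sessions are therefore optimistic.
* Layouts (e.g. `AR-Pos1`…`AR-Pos4`) are metadata tags with an optional
  per-layout SNR offset; no stimulus geometry or optics is modeled.
* The EDF reader targets ordinary continuous EDF with a uniform sampling
  rate across retained signals; EDF+ annotations channels are skipped, and
  discontinuous (EDF+D) files are not supported.
* Template-extended decoding assumes phase-stable trials, which the
  simulator guarantees but real recordings only approximate (visual
  latency jitter).
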