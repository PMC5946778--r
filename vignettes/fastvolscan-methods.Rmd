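---
title: "Simulating fast volume-scanning light-sheet calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fast volume-scanning light-sheet calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dendrites meander through brain tissue in all three dimensions, while a
light-sheet microscope images a single thin plane. At the 50–100 volumes/s
needed to follow synaptic Ca²⁺ transients there is no time to step a stage
through a Z stack, so conventional fast light-sheet imaging is restricted to
the short stretches of dendrite that happen to lie in one plane. Fast volume
scanning removes that restriction: a galvo mirror sweeps the light sheet
along the detection axis while an electrically tunable lens (ETL) sweeps the
detection focal plane in synchrony, both driven by a 50 Hz sine. The camera
exposure is locked to exactly one sweep period (20 ms), so each frame is an
average intensity projection of one full Z sweep — an XYT stack whose
effective light-sheet thickness equals the sweep depth (20 µm here), at the
full 50 frames/s.

`fastvolscan` implements this acquisition scheme as an optical forward model
over synthetic dendrite phantoms with ground-truth Ca²⁺ events, together
with the downstream analysis (ΔF/F conversion, rise/decay fitting,
noise-based event acceptance) and recovery scoring. Everything is exercised
end to end by the numbered scripts under `analysis/`.

## The phantom

`make_dendrite()` builds a circular tube (radius 1 µm by default) around a
Catmull–Rom-smoothed random walk whose Z extent is configurable — the
phantom must be able to exceed the 20 µm sweep depth for the coverage
comparisons to be meaningful, so the demonstration scenario uses a 40 µm Z
span. Two dyes fill the tube: a structural channel of constant emission
density, and a Ca²⁺ indicator whose density is `baseline × (1 + ΔF/F(s, t))`
at arclength `s`.

A ground-truth event (`calcium_event()`) has the temporal profile of the
rise/decay (alpha) function

$$k(t) = b\,t\,e^{-c t},$$

which peaks at `b/(c·e)` at time `1/c` after onset. Away from its origin the
amplitude attenuates as `exp(-d / spread_um)` with arclength distance `d`,
and the onset is delayed by `delay_s_per_um · d`. These two spatial laws are
modelling choices, not literature results: localized dendritic transients
are known to arrive delayed and attenuated a short distance from their
origin, but their true spatial profile is not specified; exponential decay
and linear delay are the simplest monotone forms, and both constants are
exposed in the configuration. Overlapping events add linearly in ΔF/F, so a
double-peaked transient is represented as two events. Ground truth uses a
zero offset (`a = 0`); the fitted offset absorbs residual baseline error at
detection time.

## The optical forward model

No diffraction modelling is attempted — the instrument's PSF was never the
point, and no measured sheet thickness or depth of field is available. Both
axial profiles are unit-peak Gaussians: the sheet excites with
`exp(-(z - z_sheet)²/2σ_sheet²)` (default σ = 2 µm) and the detection arm
weights emission by `exp(-(z - z_focus)²/2σ_DOF²)` (default σ = 1.5 µm).
These defaults are nominal values chosen so that single-plane imaging
visibly truncates a 40 µm-Z phantom; they must not be read as measured
values. A pixel of an instantaneous subframe is the Z-quadrature of
`field × excitation × detection` on a stated Z grid (default step 0.5 µm;
the grid step must stay below the narrowest axial feature being rendered,
which matters when rendering 0.25 µm-σ beads), followed by a lateral
Gaussian blur whose σ grows linearly with the sheet-to-focus defocus
(0.5 µm of blur per µm of defocus by default). Blur kernels are
row-normalised so flat fields stay flat and photon flux is redistributed,
not lost.

A volume-scan frame is the arithmetic mean of K substep renders at times
spanning exactly one waveform period (K = 32 by default; convergence is
checked in the test suite by comparing against denser sampling, and K = 8
is the floor the camera model accepts). The 20 µm "sweep depth" is
interpreted as peak-to-peak, i.e. a sine amplitude of 10 µm. The exposure is
locked to exactly one period — a partial-cycle exposure is rejected as a
configuration error rather than modelled, because the average-projection
interpretation only holds for whole cycles. The ETL's magnification change
is ignored.

Noise follows the camera chain: Poisson shot noise on
`photon_scale × signal`, additive Gaussian read noise, rounding to integer
counts, clipping at zero. All draws descend from one seed, and a fixed seed
reproduces stacks bit for bit.

## Phase calibration

The ETL responds to its drive with a lag, modelled as a pure phase delay of
the focal-plane waveform (a first-order approximation; hysteresis and
thermal drift are out of scope). `calibrate_phase()` mirrors the bench
procedure: image sub-micron beads in agarose over a grid of candidate drive
phases (grid search, like the manual tuning it emulates) and pick the phase
that maximises image quality.

The quality score needs care. `sharpness_metric()` is the normalized
variance `var/mean²` — scale-invariant and appropriate for ranking single
renders of the same content by focus. But across *phases* of a volume scan
the content itself changes: with a large phase mismatch less total light is
collected (the background's dwell contribution shrinks, and isolated
"mirror flashes" — moments where sheet and focus cross at one bead's Z —
leave a single sharp spot), and a sparsity-loving, scale-invariant score can
rank those dark configurations above true synchrony. `calibrate_phase()`
therefore maximises plain image variance, the brightness-weighted
counterpart (`variance = normalized variance × mean²`): phase mismatch both
dims and blurs the projection, flat background adds to the mean but not the
variance, and the score then has a single dominant mode at the
lag-compensating phase. With this score, injected lags of 0–5 ms at 50 Hz
are recovered within one grid step. A single bead is genuinely ambiguous —
its mirror-phase flash is a real secondary maximum — so calibration (and
its unimodality test) uses a bead ensemble, which is also what the real
procedure images.

## Trace analysis and event detection

The analysis follows the standard ROI workflow. ROIs are pixel masks
(polygon JSON with even-odd rasterisation, 0-based pixel coordinates, origin
top-left; or constructed programmatically), one of which is a larger
background ROI placed away from the dendrite. Per frame, the ROI mean gives
the raw trace.

Photobleaching and ambient background are modelled by fitting
`p + q·e^(-r t)` to the background ROI trace (nonlinear least squares via
`minpack.lm`, with a log-space linear fallback on non-convergence and an
exact constant-input shortcut). The offset `p` is included because a pure
decay cannot represent an ambient floor. The fitted model — not the raw
background trace — is then subtracted from each ROI trace; dividing by the
normalised fit is available as an option for a multiplicative reading of
bleaching. F₀ is the mean of the corrected trace over an initial window
(default 1 s — a declared convention, since no F₀ definition is given for
the original analysis), and `ΔF/F = (corrected − F₀)/F₀`. An ROI whose F₀
is not positive is indistinguishable from background — out-of-focus
stretches of dendrite in single-plane mode routinely produce these — and is
reported as skipped rather than analysed.

Candidate nomination is entirely this package's design (only the acceptance
rule below is prescribed): windows open where the 3-frame boxcar-smoothed
ΔF/F exceeds 2.5 robust σ (1.4826·MAD of the whole trace) and close on
return, merging across gaps shorter than 0.3 s. Because the threshold
crossing necessarily trails the true onset, each window start is padded back
three frames before fitting, and fit windows are extended to at least 1.5 s
(truncated at the next candidate) with 0.3 s of pre-onset baseline — the
offset `a` is pinned by baseline samples and the rate `c` by the decay tail,
and windows clipped to the crossing region alone were found to roughly
double the parameter-recovery error.

Each candidate is fitted with `a + b·(t − t_on)·e^(-c·(t − t_on))` (flat `a`
before onset). The onset is grid-searched at frame resolution and held fixed
during the continuous `(a, b, c)` fit, which keeps the procedure
deterministic; a joint continuous refinement of the onset was tested and
bought no measurable accuracy. The event amplitude is the fitted curve's
peak above its offset, `b/(c·e)`, and time-to-peak is `1/c`.

Acceptance is the prescribed rule: an event is kept only if its fitted
amplitude strictly exceeds the noise estimate, namely the RMS of the ΔF/F
baseline over the 1 s directly preceding onset. The RMS is computed on the
mean-subtracted baseline (an uncentered RMS would conflate offset with
noise — a declared interpretation); a baseline shorter than 1 s is truncated
down to a floor of 0.25 s, below which the event is unscorable. Double
events are handled as two candidates, not a compound model.

`score_against_truth()` matches detected onsets to ground truth greedily
(closest pairs first, one-to-one, within a 0.2 s tolerance) and reports
precision, recall and per-match amplitude and time-to-peak errors, with the
convention that an empty detection list has precision 1.

## Study conditions and test scale

The simulated experiment follows the acquisition parameters of the source
setting: 50 Hz sweep, 20 ms exposure locked to one cycle (50 volumes/s,
500 frames per 10 s acquisition), ~20 µm sweep depth, structural stacks of
0.5 µm steps. The demonstration scenario (`inst/extdata/demo_config.yaml`)
images 6 s of a 40 µm-Z dendrite with a strong double event mid-dendrite
and a weaker confined event further along, at photon_scale 2 and read noise
1.5 counts — shot-noise-limited but comfortably detectable, which is where
the acceptance rule is informative.

Test problem sizes are deliberately modest so the whole suite stays fast:
phantoms of 30–60 µm rendered at 0.75 µm pixels, 1–2.5 s acquisitions, and
K = 8–16 substeps where the property under test does not concern temporal
sampling. Parameter-recovery statistics use trace-level simulation (kernel
plus Gaussian noise at SNR drawn from [3, 6], the admitted range being
SNR ≥ 3) over 100 seeds; the false-positive bound uses 500 noise-only 10 s
traces. The coverage property — the method's core claim — is checked on a
full image-level simulation: station ROIs every 4 µm of arclength, trace
SNR thresholded at 5, volume scan against the best of nine candidate single
planes.

## What passing tests do and do not show

The generator emulates geometry, two-channel dye fill, sweep-integrated
acquisition and camera noise. It does not emulate scattering in tissue,
light-sheet stripe artifacts, indicator binding kinetics or buffering,
diffusion, spines, or motion; ΔF/F amplitudes attenuate by a chosen
exponential law rather than by biophysics. Passing tests therefore show
that the acquisition bookkeeping, the forward model's internal consistency,
and the analysis chain's recovery of known ground truth hold — not that the
pipeline's numbers would transfer quantitatively to any real recording.

## Numerical choices and degenerate inputs

Worth stating explicitly: rectangle-rule Z quadrature on the stated grid
(tests compare one pixel against an independently coded 1D sum to 10⁻⁶);
midpoint substep times `(i − ½)/K` of a period, so no substep is double
counted at cycle boundaries; noise order Poisson → Gaussian → round → clip
at zero; 16-bit TIFF output with counts clipped at 65535 and a JSON sidecar
carrying frame interval, pixel size, mode, waveforms and seed; constant
background traces short-circuit to `(p = mean, q = 0, r = 0)`; zero-Z-span
configurations produce exactly planar dendrites; a zero-amplitude sweep
makes volume scan collapse to single-plane mode exactly, which is asserted
in the tests.
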