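---
title: "Methods: ripple stimuli, synthetic EEG, and the gamma band-power pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple stimuli, synthetic EEG, and the gamma band-power pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippleGamma)
```

# Scope

`rippleGamma` implements a complete analysis chain for comparing
stimulus-induced gamma-band responses between sensory modalities in scalp
EEG: synthesis of ripple ("auditory grating") stimuli, a synthetic-EEG
session generator with known injected effects, recording I/O and epoching,
a fully automated artifact-rejection cascade, multitaper spectral
estimation with baseline-normalized band-power change in decibels, and the
statistical comparisons built on top. Because suitable public recordings
with this exact task structure are not available, every stage is exercised
and validated on the package's own synthetic sessions, whose ground truth
is known by construction.

# Ripple stimuli

A ripple is a broadband sound whose spectral envelope is sinusoidal on the
logarithmic frequency axis. With density $\Omega$ (cycles/octave),
velocity $\omega$ (cycles/s), modulation depth $\Delta A$, and phase
$\Phi$ referenced to the low-frequency edge $f_0$, the envelope at
position $x = \log_2(f/f_0)$ octaves and time $t$ is

$$S(x, t) = 1 + \Delta A \,\sin\!\big(2\pi(\omega t + \Omega x) + \Phi\big).$$

With this sign convention and $\omega, \Omega > 0$ the constant-phase
contours obey $x = -(\omega/\Omega)\,t + c$: the envelope drifts downward
toward lower frequencies, which is the intended direction of motion. The
tone bank holds 80 carriers at 16 per octave starting at 250 Hz
($f_i = 250 \cdot 2^{i/16}$). The top carrier is
$250 \cdot 2^{79/16} \approx 7661$ Hz, so "250–8000 Hz" is the nominal
five-octave band label rather than an exact endpoint; the package treats
the tone count and spacing as authoritative. Whether an 81st carrier at
exactly 8000 Hz was ever intended cannot be decided from the printed
parameters; the 80-tone reading is used throughout.

Carrier starting phases are not part of the printed parameterization.
They are drawn uniformly from $[0, 2\pi)$ under a caller-supplied seed,
because coherent (zero) phases would concentrate energy into an impulsive
onset. The summed waveform gets 10 ms raised-cosine on/off ramps and is
peak-normalized to 0.9 full scale; absolute playback level is a property
of the reproduction chain, not of the waveform. The depth default is
$\Delta A = 0.9$, i.e. "90% modulation" read on the linear amplitude
scale of the envelope equation. The stimulus grid crosses
$\Omega \in \{0, 0.8, 1.6\}$ with $\omega \in \{0, 5, 10, 20\}$ — 12
conditions at 40 repeats (480 trials); the visual-task analogue is 2
spatial frequencies times 4 orientations at 25 repeats (200 trials).

# The synthetic-EEG generator

`simulate_session()` emulates the passive continuous-train paradigm:
800 ms stimuli separated by 700 ms (visual-like) or 800 ms
(auditory-like) gaps, 64-channel 10–10 montage at 1000 Hz, with event
markers at every onset.

**Background.** Each channel is independent Gaussian noise spectrally
shaped to $1/f^\alpha$ (flat below 1 Hz, $\alpha = 1$ by default, a
typical scalp-EEG exponent above 20 Hz) and scaled to 10 µV RMS. Shaping
is exact at every DFT bin, so the 56–86 Hz aperiodic slope used by the
rejection cascade is recoverable by construction.

**Band effects.** An injected effect multiplies the band component of the
background by $g = 10^{\Delta\mathrm{dB}/20}$ during the stimulus window
of each trial, under a 50 ms raised-cosine envelope. The band component is
extracted by frequency-domain filtering whose flat passband extends 2 Hz
(one analysis half-bandwidth) beyond the nominal band edges, with 2 Hz
raised-cosine skirts beyond that. Rescaling the same noise realization —
rather than adding independent noise — makes the true band-power change
exactly $\Delta$dB in the ramped-on part of the window, for increases and
suppressions alike, and the guard band makes the change unbiased when read
off a spectral estimate with ±2 Hz smoothing. The injected component is
amplitude-modulated band-limited noise, so spectra show a band-limited
elevation rather than a line. Default effect sizes are the study
conditions the generator emulates: visual-like sessions inject +1 dB
narrowband gamma (20–66 Hz) on the occipital analysis electrodes — the
magnitude of a robust grating-induced gamma response at the scalp — with
−1 dB alpha (8–12 Hz), a typical pronounced desynchronization; auditory-like
sessions inject +0.1 dB broadband high-gamma (70–150 Hz) on the
temporal/mastoid electrodes — an order of magnitude weaker, matching
scalp-level auditory high-gamma — with −0.3 dB widespread beta (14–26 Hz),
whose magnitude is not separately quantified at the source and was fixed
once as a moderate suppression.

**Artifacts.** Blinks are 250 ms pulses on the frontal leads (350 µV at
Fp1/Fp2 with ±20% variability, attenuated on AF and lateral frontal
sites) — large enough that the 1.6 Hz-high-passed trial RMS exceeds the
35 µV bound, as real blinks do at frontopolar sites; in eye-tracked
sessions they also leave a gap in the eye trace. Spikes are 60 ms,
500 µV transients hitting a random 12-electrode subset, emulating
movement/muscle bursts. Flat segments silence one designated channel over
a trial's screening window (RMS below the 1.5 µV floor). Artifact support
is confined to −500..1000 ms around the own trial so ground truth stays
exact: no artifact bleeds into a neighbouring trial's screening window.
The eye trace is smoothed fixational jitter (0.1° SD) plus step
excursions of 4° lasting 120 ms in a seeded subset of trials, placed
inside the checked −500..750 ms interval.

**What the generator does not emulate.** No volume conduction or
inter-channel correlation (channels are independent), no evoked/phase-locked
components, no biophysical head model, no condition tuning of the injected
effects, and stationary effect time courses (sustained over the stimulus
window). Passing tests therefore demonstrate that the pipeline measures
what it is pointed at — calibrated band-power changes and rule-violating
artifacts — not that it would be robust to every pathology of real scalp
data.

# Artifact-rejection cascade

Stages run in a fixed order, and the report records which stage flagged
each item: impedance (> 25 kΩ, strict), fixation breaks (any eye sample
outside the 5° square window or a blink during −500..750 ms), trial RMS
bounds (outside 1.5–35 µV after a zero-phase 4th-order Butterworth
high-pass at 1.6 Hz, on −500..1500 ms), per-frequency PSD outliers
(> 6 SD from the across-trial mean at any bin in 0–200 Hz),
consolidation (electrodes with > 30% bad trials discarded; trials bad on
> 10% of remaining electrodes, or on any surviving priority electrode,
join the common bad set), baseline-PSD slope (56–86 Hz power-law fit on
log–log axes; electrodes with slope < 0 discarded), manual exclusions
(user-supplied only, never automated), and the subject verdict (reject a
task when < 50% of its group electrodes survive). Every threshold
comparison is strict, exactly as stated.

Two implementation decisions deserve justification:

* **The 6-SD rule runs on log₁₀ of a 5-taper PSD.** The screen is
  specified as a deviation rule on per-trial PSDs. A per-trial
  single-taper PSD bin is approximately $\chi^2_2$ (exponential), for
  which $P(x > \bar{x} + 6s) = e^{-7} \approx 9\times10^{-4}$ *per bin*;
  over ~400 bins this would flag roughly a third of perfectly clean
  trials, rendering the rule unusable. Averaging over the standard
  multitaper family (time–bandwidth 3, 5 tapers) and taking log power
  brings the per-bin false rate to ~10⁻⁵, at which point the rule behaves
  as intended: a negligible false-flag rate with full sensitivity to
  genuine outliers. Both choices are configurable
  (`rejection_config(psd_nw=, psd_k=, psd_log=)`).
* **The candidate trial stays in the mean/SD.** Leave-one-out is not part
  of the printed rule. Including the candidate bounds the attainable
  standardized deviation at $(n-1)/\sqrt{n}$, so a single outlier among
  otherwise identical trials is detectable at $n = 41$
  ($40/\sqrt{41} = 6.25 > 6$) but not at $n = 30$
  ($29/\sqrt{30} = 5.29 < 6$). The acceptance suite checks this bound
  exactly; it holds under any monotone transform of power.

The PSD screen uses the raw (not high-passed) screening window, so slow
ocular artifacts remain visible to it. Frontal electrodes are not in
either priority set, so a blink confined to Fp/AF leads is flagged on
those electrodes without discarding the trial for the occipital/temporal
analysis — detection performance is therefore scored at the affected
electrodes (`cascade_confusion()`).

# Spectral estimation and ΔPower

All analysis spectra use discrete prolate spheroidal (Slepian) tapers,
computed from the classical tridiagonal eigenproblem (verified during
development against an independent implementation to ~1e-14). The
analysis default is the single taper with time–bandwidth 1. Windows
follow one half-open sample convention, `[start, end)` at 0-based sample
offsets: a (−500, 0) baseline and (250, 750) stimulus window at 1000 Hz
are exactly 500 samples each and adjacent windows never share a sample.
No zero-padding is applied, so the printed resolutions are exact grid
spacings: 500 ms windows give 2 Hz, the 250 ms spectrogram windows
(25 ms steps, timestamped at window centres) give 4 Hz.

The band-power change is
$\Delta\mathrm{Power} = 10\log_{10}\!\big(\sum_f ST(f) \big/ \sum_f BL(f)\big)$,
with power averaged across trials (and the selected electrodes) before
the band sum, and band endpoints inclusive on the grid (20–66 Hz spans 24
bins at 2 Hz). Bands: narrowband gamma 20–66 Hz, broadband high-gamma
70–150 Hz, alpha 8–12 Hz, beta 14–26 Hz. Narrower descriptions of the
gamma range (22–64 Hz, and slow/fast sub-bands near 20–34/36–66 Hz)
appear in descriptive use; the computational band is the 20–66 Hz one and
sub-bands can be passed as ordinary band arguments. The change
spectrogram divides by the arithmetic mean baseline power per frequency
(columns fully inside the baseline interval), so after trial averaging
baseline cells sit near 0 dB up to log-of-mean curvature, which is
negligible at the trial counts used. `best_electrode()` breaks exact ties
by canonical montage order and reports the tie.

# Statistics

Paired t tests per frequency bin report two-sided p values with
significance tiers at 0.05 and 0.01; no correction across bins is applied
— tiers are descriptive, per-bin statements, and should be read as such.
Group comparisons use Welch's unequal-variance t test with the
Welch–Satterthwaite degrees of freedom, reporting the variance ratio
F = var(a)/var(b) alongside. All SDs use n−1 denominators. The
condition-selectivity index is the coefficient of variation of
stimulus-period band power across conditions (SD/mean, computed per
electrode then averaged); because the phrase "ratio of average power … to
its standard deviation" also admits the reciprocal reading, the
mean-over-SD orientation is available behind
`condition_selectivity(orientation =)`, with SD/mean — the standard
coefficient of variation, matching the index's name — as the default.
Scalp maps draw per-electrode disks on a schematic 10–10 layout and
always emit the underlying CSV table, so no result depends on graphics.

# Numerical and degenerate-input choices

Zero variance of paired differences is reported as the degenerate case
(t = 0, p = 1 for identical inputs) with a warning rather than NaN.
PSD values are floored at the smallest positive double before log
transforms. The slope fit refuses non-positive power and ranges with
fewer than 3 bins. Epoching drops events whose window leaves the
recording, with a warning and decremented count. The eye-trace blink
sentinel is ±30°. BrainVision INT_16 files are written at 0.1 µV/bit,
matching 16-bit acquisition, so round-trips are exact to half a bit.

# Problem sizes used by the test and acceptance suites

Property-style checks run at sizes chosen to make their Monte-Carlo error
small relative to the asserted tolerances while keeping the suite quick:
injection recovery uses 200-trial single-condition sessions on a
4-electrode montage over 20 seeds per level (the pooled standard error is
then ~0.01–0.03 dB against a ±0.15 dB tolerance); the modality
dissociation runs the full 200/480-trial condition structures on the
analysis-electrode montages over 20 seeds per modality; cascade
sensitivity/specificity uses full-montage sessions at 15 repeats per
condition with default artifact rates. Null-calibration checks compare
band changes against 3× their analytic Monte-Carlo SE, and a 20-replicate
t test against zero at the 1% level. The acceptance script runs the two
default full-montage sessions end to end.

# Known limitations

The simulator's independence across channels means bipolar derivations
sum (rather than difference away) neighbouring activity, so bipolar
effect sizes are not calibrated to a physical head model — only their
signs are meaningful. The injected high-gamma magnitude (+0.1 dB) is at
the scale where single-session estimates have noticeable relative spread;
group-style inferences should pool sessions as the test suite does.
Manual electrode rejection is supported but deliberately has no automated
stand-in. The cascade's runtime is dominated by the per-trial multitaper
PSDs of the outlier screen; sessions are processed one electrode at a
time to keep memory flat on full-length recordings.
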