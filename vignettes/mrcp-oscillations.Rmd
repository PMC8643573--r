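---
title: "Movement-related cortical potentials and sensorimotor oscillations: methods"
author: "mrcposc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-related cortical potentials and sensorimotor oscillations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcposc)
```

## What this package analyses

Before a voluntary movement, a slow negative potential — the
movement-related cortical potential (MRCP), also called the
Bereitschaftspotential — builds up over (pre-)supplementary motor area and
primary motor cortex, approximated at the scalp by FC1/FC2 and Cz. Its
early shallow slope (NS1) reflects (pre-)SMA activation, the late steep
slope (NS2) reflects M1, and after the negative trough near movement onset
the potential rebounds toward baseline. In parallel, sensorimotor rhythms
desynchronize: band power in low beta (13--20 Hz) and high beta
(21--35 Hz) drops before and during movement (event-related
desynchronization, ERD), while pathological states can replace beta ERD
with theta (4--8 Hz) synchronization (ERS).

The pipeline implemented here analyses both phenomena around cued ankle
dorsiflexion, recorded with 17-channel 10--20 EEG at 250 Hz and bilateral
tibialis anterior (TA) / soleus (SOL) surface EMG at 1000 Hz. A 'ready'
auditory cue is followed 2 s later by 'go'; the movement onset is defined
electromyographically, and all EEG analysis is locked to that onset. The
analysis epoch spans $[-4, 4)$ s around onset (2000 samples at 250 Hz,
with $t = 0$ exactly at the sample nearest the detected onset); results
are reported over the 'Go' window $[-2, 4)$ s, the extra pre-onset buffer
existing only to serve as the oscillatory baseline.

## EMG onset detection

The EMG of the dominant-leg TA is band-passed 20--120 Hz (2nd-order
Butterworth, applied forward and backward so the filter is zero-phase),
and the Teager--Kaiser energy operator
$\psi[n] = x[n]^2 - x[n-1]\,x[n+1]$ is applied at the native 1000 Hz. The
energy is smoothed with a 50 ms moving average. Instead of the per-subject
manual threshold of typical laboratory practice, the threshold is set
automatically to median $+ k\cdot$MAD of the smoothed energy over the
concatenated pre-'ready' baselines (default $k = 8$; both statistics are
affinely equivariant, so the threshold scales with the square of the
signal amplitude exactly as the energy operator does). Onset is the first
time after 'go' at which the smoothed energy stays above threshold for at
least 50 ms.

Because an 8-MAD threshold is deliberately conservative, the raw crossing
lands some way up the burst's rising edge at low signal-to-noise ratios.
The detector therefore backtracks from the crossing along a lightly
smoothed (10 ms) energy series while it remains above baseline median
$+ 2\cdot$MAD; the first sample of that supra-baseline run is the reported
onset. On synthetic bursts this brings the median absolute onset error to
about 6 ms at 6 dB while leaving the false-detection rate on burst-free
trials at zero out of 200; error variance decreases monotonically with
SNR. Detection failure is a quality-control outcome recorded per trial,
never an exception.

## The two EEG preprocessing paths

Following standard practice for these two signal classes, the EEG is
processed twice from the raw recording: 0.05--5 Hz (3rd-order zero-phase
Butterworth) for the slow potentials, and 0.05--50 Hz for the
oscillations. Both paths then pass through extended-infomax ICA.

Because a reproducible pipeline cannot encode two experts inspecting
component maps, artifact components are rejected by two automated
criteria: absolute correlation above 0.8 between a component's time
course and the mean of FP1/FP2 (eye blinks project frontally), or a
25--50 Hz to 1--10 Hz spectral power ratio above 2 (broadband muscle
activity). Both cutoffs are configuration keys. The ICA itself is the
natural-gradient extended infomax rule with per-component
sub/super-Gaussian switching, annealing on oscillation, and a seeded
block permutation, so a run is reproducible; non-convergence passes the
data through untouched with a warning status in the report. On synthetic
sessions with injected 150 µV blinks the blink component is isolated with
correlation above 0.99 and its removal cancels more than 99% of
blink-window frontal variance, while blink-free sessions lose no
components.

For left-foot-dominant participants the lateral channel pairs are
mirror-swapped before any analysis so that the hemisphere contralateral
to the moving foot is consistent across subjects; midline channels are
untouched, and a second swap restores the original session.

Oscillation-path trials are discarded when either dominant-leg muscle
shows envelope activity above median $+ 8\cdot$MAD of its cross-trial
pre-cue baseline before the 'go' cue, or when the contralateral TA bursts
during the motor task ($[0, 4]$ s). A head-motion criterion would require
a motion channel the data model does not carry; the rejection report notes
that this rule was skipped.

## MRCP features

Five features are measured per trial on Cz (configurable): peak
negativity, the lowest value in the closed window $[-1, 1.5]$ s around
onset with ties broken earliest; its time; NS1
$= [x(t_p - 0.4) - x(t_p - 1.4)]/1\,\mathrm{s}$; NS2
$= [x(t_p) - x(t_p - 0.4)]/0.4\,\mathrm{s}$; and the rebound rate
$= [x(t_p + 1.5) - x(t_p)]/1.5\,\mathrm{s}$. Amplitudes at offsets are
read at the nearest sample — at 250 Hz the 4 ms quantization is far below
the feature time scales. If the epoch does not extend 1.5 s past the peak
the rebound is missing rather than an error. EMG features are the peak of
the dominant-TA envelope (20--120 Hz band-pass, full-wave rectification,
6 Hz zero-phase low-pass) in $[0, 4]$ s, its time, and the SOL-minus-TA
onset lag from each muscle's own half-excursion crossing; the MRCP-EMG
latency is the signed difference of the two peak times, negative when the
cortical peak leads.

A trial is an outlier when its negative trough lies outside $[-1.5, 2]$ s
(closed, the conservative reading of an ambiguous bracket). Because the
feature search window $[-1, 1.5]$ s is strictly inside the rejection
window, the rule is applied to the trough of the whole 'Go' window
$[-2, 4)$ s; otherwise it could never fire.

The temporal-consistency index (coefficient of variation) of a channel is
the mean over 'Go'-window time points of across-trial SD divided by
$\max(|\text{across-trial mean}|, 0.1\,\mu V)$; the floor prevents
blow-up at zero crossings of the mean waveform. The aggregation recipe
for this index is genuinely underdetermined — published values could also
arise from the CoV of per-trial peak amplitudes or peak times — so both
alternatives sit behind the `method` argument. Topographic values are the
grand-average amplitudes of all 17 channels at 13 points from $-2$ to
$4$ s in 0.5 s steps; scalp-map rendering is a plotting layer over that
table.

## Oscillation maps

Volume conduction is attenuated with the surface small Laplacian: the
mean of the four surrounding electrodes is subtracted from the centre
electrode, for Cz, FC1 and FC2. The 17-channel montage does not contain
the true orthogonal neighbours of FC1/FC2 (FCz, FC5/FC6, CPz are absent),
so the closest available montage members are used — Cz: C3, C4, Fz, Pz;
FC1: F3, Fz, C3, Cz; FC2: F4, Fz, C4, Cz — and the sets are replaceable
via the montage object.

Time-frequency power comes from convolution with complex Morlet wavelets
of five cycles on a 1--50 Hz grid at 1 Hz steps (the grid step is a
choice; the range and cycle count follow the recording convention). The
wavelets are $L_2$ (energy) normalized. Each epoch is decomposed over the
full $[-4, 4)$ s buffer, and every sample within 2.5 cycles of an epoch
edge is marked invalid per frequency, so the reported window is
edge-valid for $f \geq 2$ Hz and 1 Hz values are flagged rather than
silently reported.

ERD/ERS is computed by averaging power across trials first and then
normalizing each frequency row to percent change against its baseline
mean over $[-4, -2]$ s (a per-trial-normalization switch exists but the
single-baseline formulation is the default). Two details matter
numerically. First, the baseline mean per row uses only the edge-valid
part of the baseline window (falling back to the whole window for rows
with no valid sample): the zero-padded convolution attenuates power next
to the epoch edge, and letting those samples into the baseline deflates
it and biases every ERD value in the row upward. The baseline-zero
invariant — each row averages to zero over its baseline columns — holds
to machine precision over the columns actually used. Second, the map is
exactly invariant to rescaling all trial powers by a common factor, since
it is a ratio.

Band summaries average the map over a band's rows and a window's columns.
Default bands are theta 4--8, low-beta 13--20, high-beta 21--35 and broad
beta 12--35 Hz; an alternative preset draws the low/high-beta boundary as
12--21/21--35 Hz, since both conventions circulate.

## Resampling statistics

Within-group significance of an ERD map is assessed by bootstrap: trials
are resampled with replacement (default 1000 times), the full
average-then-normalize map is recomputed for each resample, and a pixel
is significant when its two-sided bootstrap interval excludes zero. The
interval is BCa — bias-corrected and accelerated, with the acceleration
from an analytic leave-one-out jackknife — rather than the plain
percentile interval: power averages over a couple of hundred trials are
still skewed enough that the percentile construction runs measurably
anti-conservative (about 7% empirical null exceedance at nominal 5% in
our calibration runs), while BCa restores near-nominal behaviour. The
percentile interval remains available via `ciType`. Pixels inside the
per-frequency edge margin are never flagged: attenuation by the epoch
boundary is not a brain effect.

Between-group differences use a permutation test: trial-to-group labels
are shuffled (default 1000 times), the difference of group ERD maps is
recomputed, and the two-sided pixel p-value is
$(1 + \#\{|d_{perm}| \geq |d_{obs}|\})/(n_{perm} + 1)$. Swapping the
groups negates the difference map and leaves the mask unchanged. As in
the underlying study design, no correction beyond the pointwise level is
applied by default — a known limitation for map-wide inference — and an
optional max-statistic familywise threshold is provided but off.

Feature tables are compared with classical one-way ANOVA at trial level
(the published degrees of freedom imply trials pooled across subjects;
subject-level aggregation is available but off by default), with Tukey
HSD computed only after a significant omnibus test. Empirical size at
$\alpha = 0.05$ is verified by simulation to lie in $[0.04, 0.06]$.

## The synthetic cohort generator

Every downstream stage is validated against generated sessions whose
structure is known exactly. Background EEG is $1/f$ noise (the minimal
realistic spectrum; no published noise model exists for this setting)
plus white sensor noise, defaults 2 and 0.5 µV SD. The MRCP is a
piecewise-linear template — lead-in, NS1 segment, NS2 segment reaching
the trough, rebound, return to baseline — spatially weighted across the
montage with maximum at Cz, so every feature has an exact analytic value
on noiseless data. Oscillations are band-limited Gaussian carriers whose
envelope is multiplied by $\sqrt{1 + pct/100}$ inside scheduled windows,
so the injected band-power change equals the requested percentage by
construction. EMG bursts are amplitude-modulated 20--120 Hz noise with a
20 ms rise to 80% of peak (ballistic dorsiflexion recruits abruptly; a
slow ramp would make millisecond-scale onset recovery impossible at low
SNR), envelope peak at $+0.4$ s, decay to zero by $+1.5$ s; the soleus
burst lags TA by a configurable delay. Blinks are 0.3 s raised-cosine
transients with a frontally dominant spatial pattern at Poisson times.

Two calibration choices make the generator's "by construction" claim hold
under the pipeline's own measurement. The carrier band is padded by about
2.5 spectral SDs of a five-cycle wavelet at each edge, and the scheduled
window by 2.5 temporal SDs, so that a wavelet reading of the *nominal*
band-by-window tile sees modulated carrier across its full integration
bandwidth; without the padding, edge rows and edge columns of the tile
mix modulated and unmodulated signal and a $-40\%$ injection reads back
near $-32\%$. Even with padding, the $1/f$ background inside the band and
smearing at the gain steps leave a residual dilution of one to three
percentage points, which is why recovery is asserted to $\pm 5$.

The default group profiles mirror the qualitative clinical contrasts the
pipeline is designed to resolve — healthy controls with the deepest
trough, steepest NS1 and strongest beta ERD; freezing-of-gait profiles
with flattened NS1, attenuated or absent low-beta ERD, added pre-movement
theta ERS, and (severe group) a delayed soleus onset. They are test
parameters for the generator, not estimates of any cohort. Cohort
generation is bit-reproducible from a single seed.

What the generator does **not** emulate: realistic head-volume
conduction (spatial weights are fixed maps), non-stationary background
(drifts, electrode pops), movement variability in burst shape, and any
freezing-of-gait episode structure. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated signal model,
not performance on clinical recordings.

## Parameter-recovery conventions

Two measurement details are worth flagging because they are easy to get
wrong. First, the 0.05 Hz high-pass of the slow-potential path attenuates
an isolated slow pulse substantially (the noiseless $-16$ µV template
reads $-10.9$ µV after it): a single MRCP's spectrum is concentrated at
DC, where the filter bites, even though its nominal "frequency content"
looks safely above 0.05 Hz. Published trough amplitudes are therefore
post-filter quantities, and recovery of *injected* amplitudes is checked
on epochs cut from unfiltered data. Second, reading a pointwise minimum
off a noisy average is biased downward (an extreme-value effect, about
$-0.4$ µV at 100 trials of 2 µV noise); `grandAverage(..., smoothS =
0.04)` applies a 40 ms moving average to the mean waveform before feature
reads, which removes most of that bias while perturbing the
piecewise-linear trough by well under 0.1 µV.

## Problem sizes and determinism

The validation suite uses 100-trial subjects for MRCP and onset recovery,
200 trials for ERD recovery and resampling calibration on a reduced
20-frequency by 40-bin grid with 500--1000 resamples, and 2000 replicates
for the ANOVA size check; these sizes put Monte-Carlo noise comfortably
below the asserted tolerances. Every stochastic step — generation, ICA,
bootstrap, permutation — takes an explicit seed, and the pipeline records
seeds, the config hash, package version and per-stage kept/rejected trial
counts in its run manifest; identical config and seed reproduce every
output table bit-exactly.

## Known limitations

EDF storage quantizes to 16 bits over a per-channel symmetric range
(about 0.5 mV resolution at typical EEG amplitudes — far below noise).
The ICA rejects only blink-like and broadband-EMG components; slow eye
movements and channel pops have no dedicated criterion. Pointwise
significance maps are uncorrected by default, matching the underlying
procedure. The 1 Hz row of time-frequency maps is edge-flagged over most
of the epoch and should not be interpreted. The head-motion trial
rejection of the original protocol has no counterpart here because the
data model carries no motion channel.
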