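# mrcposc

Joint EEG/EMG analysis of cued ankle dorsiflexion: movement-related
cortical potentials (MRCP) and sensorimotor event-related
(de)synchronization (ERD/ERS), with EMG-defined movement onsets.

## The problem

Before a self-initiated or cued movement, a slow negative cortical
potential (the Bereitschaftspotential) develops over (pre-)SMA and M1 —
at the scalp, FC1/FC2 and Cz — while sensorimotor beta rhythms
desynchronize. Both phenomena are informative about motor-circuit
pathology (e.g. freezing of gait in Parkinson's disease), but measuring
them reproducibly requires a long chain of steps: EMG-based onset
detection, two separate EEG filtering paths, artifact-component removal,
onset-locked epoching with quality control, single-trial feature
extraction, spatial filtering, wavelet time-frequency maps with baseline
normalization, and resampling statistics. This package implements that
chain end to end for 17-channel 10–20 EEG (250 Hz) with bilateral
tibialis-anterior/soleus EMG (1000 Hz), and ships a ground-truth
synthetic cohort generator so every stage is testable without any
recorded data.

## What it computes

* **Movement onset** from the dominant-leg TA: 20–120 Hz zero-phase
  band-pass, Teager–Kaiser energy `ψ[n] = x[n]² − x[n−1]x[n+1]`, 50 ms
  smoothing, automatic per-subject threshold (baseline median + 8·MAD)
  with a backtracking refinement. Median absolute error ≈ 6 ms at 6 dB
  SNR, zero false detections on 200 burst-free trials.
* **MRCP features** per trial on Cz: peak negativity (minimum in
  [−1, 1.5] s), its time, NS1 `[x(t_p−0.4) − x(t_p−1.4)]/1 s`,
  NS2 `[x(t_p) − x(t_p−0.4)]/0.4 s`, rebound rate
  `[x(t_p+1.5) − x(t_p)]/1.5 s`, EMG peak/latency features, and the
  [−1.5, 2] s peak-time outlier rule; grand averages, a
  temporal-consistency (coefficient-of-variation) index and topographic
  time series.
* **Oscillation maps**: surface small Laplacian on Cz/FC1/FC2,
  five-cycle Morlet power 1–50 Hz,
  `ERD%(f,t) = 100·(P(f,t) − B(f))/B(f)` against the [−4, −2] s
  baseline, band summaries (theta 4–8, low-beta 13–20, high-beta
  21–35 Hz), bootstrap (BCa) within-group significance masks and
  permutation between-group difference maps.
* **Group statistics**: one-way ANOVA with gated Tukey HSD on
  trial-level feature tables.
* **Synthetic cohorts**: 1/f + white background EEG, piecewise-linear
  MRCP templates, envelope-modulated band carriers realizing exact
  percent power changes, EMG bursts with configurable onset delay and
  TA–SOL lag, optional blinks — all bit-reproducible from one seed, with
  a full ground-truth record.

Sessions are read and written as EDF (16-bit) with a tab-separated cue
annotation sidecar and a YAML metadata sidecar.

## Worked example

```r
library(mrcposc)
gen <- generateCohort(defaultGroupProfiles()[c("HC", "PD_severeFOG")],
                      nSubjectsPerGroup = 1, nTrials = 8, seed = 1,
                      interTrialS = 12)
ses <- gen$sessions[["HC_01"]]
ses
#> RawSession HC_01 (HC, right foot dominant)
#>   EEG: 17 ch x 29000 samples @ 250 Hz (116.0 s)
#>   EMG: 4 ch x 116000 samples @ 1000 Hz
#>   cues: 8 ready/go pairs

onsets <- detectSessionOnsets(ses)
head(onsets, 3)
#>   subject_id trial onset_time_s detected threshold_used cue_go_time_s
#> 1      HC_01     1       22.434     TRUE       7.175777            22
#> 2      HC_01     2       34.422     TRUE       7.175777            34
#> 3      HC_01     3       46.418     TRUE       7.175777            46
```

Each detected onset sits a few hundred ms after its 'go' cue (the
injected reaction delay), and one automatic energy threshold serves the
whole subject. The slow-potential path then yields per-trial features:

```r
ep <- extractEpochs(ses, bandpassMRCP(eegData(ses), eegRate(ses)), onsets)
feats <- mrcpFeatures(ep)
feats[1:3, c("trial", "peak_negativity_uv", "peak_time_ms",
             "ns1_uv_per_s", "ns2_uv_per_s", "rebound_uv_per_s")]
#>   trial peak_negativity_uv peak_time_ms ns1_uv_per_s ns2_uv_per_s
#> 1     1             -12.47          692        -4.81        -4.50
#> 2     2             -12.47          256        -5.51       -15.03
#> 3     3             -12.75          692        -6.30        -8.82
#>   rebound_uv_per_s
#> 1             7.03
#> 2             3.95
#> 3             5.90
```

Negative troughs of −12 to −13 µV land 250–700 ms after onset with
negative pre-movement slopes and positive rebound — single-trial noise
around the injected HC template (−16.1 µV trough after the 0.05–5 Hz
filter reads near −12). The oscillation path gives baseline-normalized
maps and band summaries:

```r
epO <- extractEpochs(ses, bandpassOsc(eegData(ses), eegRate(ses)), onsets)
lap <- smallLaplacian(epO, "Cz")
maps <- lapply(seq_len(ncol(lap)), function(j)
  morletTFR(lap[, j], 250, times = epochTimes(epO), decim = 5,
            channel = "Cz"))
erd <- erdErs(maps)
erd
#> ERDMap Cz: 50 freqs x 400 times, baseline [-4, -2] s, 8 trials

b <- bandDefinitions()
c(low_beta_pre = bandSummary(erd, b[b$name == "low_beta", ], c(-1, 1)),
  theta_pre    = bandSummary(erd, b[b$name == "theta", ], c(-2, 0)))
#> low_beta_pre    theta_pre 
#>        -24.8         -2.8
```

An 8-trial average already shows the injected low-beta desynchronization
(−40% injected; an 8-trial estimate is noisy) and no theta change, as
scheduled for the healthy-control profile. `runPipeline(defaultConfig(),
"out/")` runs the whole chain — synthesis, onsets, both paths, features,
ERD maps, ANOVA tables — and writes every table plus a manifest with
seeds, config hash and per-stage trial bookkeeping. `plot(erd)` renders
the map; `inst/scripts/pipeline.R` wraps the same functions for shell
use.

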