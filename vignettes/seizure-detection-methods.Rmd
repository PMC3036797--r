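---
title: "Methods: patient-independent neonatal seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-independent neonatal seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neoseize)
```

## The problem

Electrographic seizures in newborns — most commonly after hypoxic–ischaemic
encephalopathy (HIE) — are clinically silent in the majority of cases and can
only be detected reliably from multi-channel EEG. Continuous expert review of
cot-side EEG is rarely available in a neonatal intensive care unit, so an
automated detector that flags seizure episodes with a controllable
false-alarm rate is of direct clinical value. `neoseize` implements such a
detector as a patient-independent classifier: the model never sees the
patient it is screening.

## The detection chain

Each bipolar EEG channel (the eight neonatal 10–20 derivations F4–C4, C4–O2,
F3–C3, C3–O1, T4–C4, C4–Cz, Cz–C3, C3–T3 by default) is processed
independently up to the channel-fusion step:

1. **Preprocessing.** A zero-phase second-order IIR notch (Q = 30) removes
   the 50 Hz mains component at the acquisition rate; the signal is then
   low-pass filtered (zero-phase Kaiser FIR, passband edge 12.8 Hz, ≥ 60 dB
   by 14.4 Hz) and decimated from 256 Hz to 32 Hz. Neonatal seizure activity
   lies below 13 Hz, with dominant frequencies between 0.5 and 6 Hz, so
   nothing of interest is lost. The signal is segmented into 8 s epochs with
   a 4 s hop (50 % overlap); only complete epochs are kept, so a record of
   `T` seconds yields `floor((T − 8)/4) + 1` epochs. A second counting
   convention — annotated duration divided by the hop, `training_epoch_count()`
   — is kept separately because the two differ (29 vs 30 epochs for 120 s)
   and both are useful: the first for real processing, the second for
   training-set bookkeeping.
2. **Features.** 55 per-epoch features: 28 spectral (total power 0–12 Hz,
   peak frequency, spectral edge frequencies at 80/90/95 %, eleven 2 Hz-wide
   sub-band powers with 1 Hz stride and their normalized counterparts,
   Daubechies-4 wavelet energy of the 1–2 Hz detail band), 23 temporal
   (curve length, extrema count, RMS, Hjorth activity/mobility/complexity,
   zero crossings of the epoch and its first two differences, Burg AR
   prediction-error variances for orders 1–9, skewness, kurtosis, Teager
   nonlinear energy, variances of the first two differences) and 4
   information-theoretic (amplitude-histogram Shannon entropy, SVD entropy
   and Fisher information of the delay-embedding singular spectrum, spectral
   entropy over 0–12 Hz). The PSD is a rectangular-window periodogram on the
   256-point FFT of the raw epoch; it conserves power exactly (Parseval),
   which the tests assert to 1e−9.
3. **Classification.** A soft-margin SVM with Gaussian kernel
   `K(u, v) = exp(−γ‖u − v‖²)`. Features are normalized anisotropically
   (per-feature mean/SD template fitted on training data and reused
   unchanged on test data). `(C, γ)` are chosen by stratified 5-fold
   cross-validation; the decision value `f` is mapped to a probability with
   the Platt sigmoid `P(seizure|f) = 1/(1 + exp(Af + B))`.
4. **Post-processing.** Per channel, the probability sequence is smoothed
   with a central moving-average filter (order 15, spanning 64 s at the 4 s
   hop), thresholded (`≥ θ`, θ ∈ [0, 1]), the per-channel binary decisions
   are fused with a logical OR (equivalently: MAX over the smoothed
   probabilities, then one threshold — the tests verify the identity), and
   each positive run is extended by a 40 s collar on each side.
5. **Scoring.** Consecutive positive epochs are joined into events
   (overlapping epoch spans merge). GDR is the percentage of reference
   seizures touched by at least one detection; FD/h counts detections with
   zero overlap with any reference seizure per hour. Sweeping θ from 0 to 1
   yields the GDR-vs-FD/h operating curve.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| epoch length / hop | 8 / 4 | s | resolves seizures ≥ 10 s against an abnormal background; 50 % overlap doubles the decision rate |
| anti-alias cutoff | 12.8 | Hz | upper edge of neonatal seizure content |
| MAF order | 15 | epochs | 64 s of context; suppresses isolated spurious epochs at the cost of sub-minute seizures |
| collar | 40 | s/side | recovers under-detected seizure onsets/offsets; also merges detections < 80 s apart |
| threshold θ | 0.5 | — | equal priors; swept for the operating curve |
| non-seizure sample | 10 000 | epochs | caps the class imbalance (~1:5) and the SVM problem size |
| `train_seizure_s` | 120 | s/patient | seizure rows come from a short channel-annotated excerpt per patient, mirroring how per-channel seizure annotations are produced in practice |
| C, γ grids | 2^(−2..12), 2^(−14..2) | — | wide log-2 grids; the CV criterion is out-of-fold AUC of decision values |

Design choices made where the procedure was genuinely open:

* **Sigmoid calibration** uses out-of-fold decision values from the 5-fold
  split rather than resubstitution scores, avoiding the known optimistic
  bias of fitting the sigmoid on the same data the SVM memorised.
* **Epoch labels** need ≥ 50 % of the epoch to overlap a per-channel seizure
  event (configurable); ties at the decision threshold count as seizure.
* **MAF boundaries** truncate and renormalize the window so constant series
  are invariant at the edges.
* **Collar semantics**: 40 s is applied per side; the total-80 s reading is
  available by configuration.
* **Wavelet energy**: an orthonormal 8-tap Daubechies-4 periodic DWT; the
  reported feature is the energy of the detail band whose nominal range at
  32 Hz is 1–2 Hz (fourth level; equivalently the fifth entry of the
  `[approximation, D7, D6, D5, D4, …]` coefficient list of a 7-level
  decomposition). Band-energy values from other DWT alignment conventions
  differ slightly; the transform here is verified orthonormal (band energies
  sum to the signal energy).
* **No class weighting** despite the imbalance; exposed in the configuration.
* **Degenerate epochs** (constant signal, zero power) return flagged zeros
  for ratio-type features instead of NaN, so downstream code never sees
  non-finite values — a fuzz test over thousands of random epochs asserts
  this.

## The synthetic data generator

Clinical neonatal EEG with expert annotations is not publicly available, so
the package ships a generator (`sim_config()`, `generate_dataset()`) whose
defaults define the study conditions used by the tests and the acceptance
script: 6 patients, 20 min of 8-channel 256 Hz EEG each, zero-mean 1/f
background at 20 µV RMS, seizures at 9 events/h (Poisson-placed,
non-overlapping, 60–180 s) as raised-cosine sharp-wave trains with 20 %
cycle jitter and slow amplitude modulation, dominant frequency 1–4 Hz, peak
amplitude 50–150 µV, confined to a random subset of 2–4 channels; roughly
one artifact per hour of each of the three clinically dominant classes
(electrode disconnect, respiration, movement), logged in a separate
ground-truth track. Background RMS and seizure amplitudes are engineering
choices — the corpus the detector was designed around publishes no
amplitude statistics — and are flagged as such.

What the generator does **not** emulate: sleep-state cycling and
trace-alternant backgrounds, inter-patient montage or impedance variation,
electro-clinical coupling, and the full morphological diversity of neonatal
seizures. Passing the end-to-end tests therefore shows that the chain is
correctly assembled and can separate rhythmic discharges from 1/f
background at realistic SNR — not that clinical performance figures carry
over. The generated seizures are deliberately easier than clinical ones
(a separability test asserts ≥ 95 % epoch accuracy from three features
alone), so the end-to-end leave-one-subject-out criterion of ≥ 90 % mean
GDR within 2 FD/h is a pipeline-integrity check, not a clinical claim.

## Problem sizes and numerics

The leave-one-subject-out study run by the tests and by
`scripts/acceptance.R` uses the 6 × 20 min generator defaults with a reduced
hyperparameter grid (`C ∈ 2^{0,6}`, `γ ∈ 2^{−7,−4,−1}`) and 2 000 sampled
non-seizure epochs — sizes chosen so the full study (six folds × five CV
folds of SVM training on ~2 500 × 55 matrices plus ~14 000 feature
extractions) completes in minutes while still exercising genuine model
selection. The wide default grids remain available for real use.

Numerical notes: the sigmoid fit is a Newton iteration with backtracking on
the regularized cross-entropy with smoothed targets `(N₊+1)/(N₊+2)` and
`1/(N₋+2)`; perfectly separable decision values trigger a warning rather
than divergence. `apply_sigmoid()` is evaluated in the overflow-safe form.
Decision values are computed from the stored support-vector expansion
(`f = Σᵢ αᵢyᵢ K(xᵢ, ·) − ρ`), which reproduces the solver's own values to
~1e−15 and makes serialized models (`save_model()`/`load_model()`)
reproduce decisions exactly. Zero-variance feature columns get SD 1 in the
normalization template (with a warning) so constant features pass through
centred. Tie-breaks: equal CV scores keep the first grid point in (γ, C)
order; decision-threshold ties count as seizure; equal-GDR operating points
prefer lower FD/h.

## Known limitations

* Event-based GDR/FD-h metrics ignore seizure burden; a detector can score
  well while under-estimating total seizure time (the collar mitigates but
  does not remove this).
* FD/h is not monotone in θ (events split and merge along the sweep), so
  operating-point selection scans the whole curve rather than bisecting.
* The EDF reader supports plain EDF (16-bit, ASCII headers), not EDF+
  embedded annotations.
* No artifact-rejection stage exists; artifacts are handled only implicitly
  by the non-seizure training class, which is faithful to the modelled
  system but means electrode-disconnect segments produce false detections.
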