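---
title: "Measuring beat-to-beat repolarization variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring beat-to-beat repolarization variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stvrepol)
```

## The statistic

Short-term variability (STV) of repolarization quantifies beat-to-beat
fluctuation of the repolarization duration. For per-beat determinants
$D_1 \dots D_N$ — QT intervals on the surface ECG or activation-recovery
intervals (ARI) on a unipolar intracardiac electrogram —

$$\mathrm{STV} = \frac{\sum_{n=1}^{N-1} |D_{n+1} - D_n|}{(N-1)\,\sqrt{2}}
\quad [\mathrm{ms}],$$

conventionally over $N = 31$ consecutive beats, so the denominator is
$30\sqrt{2}$. Geometrically this is the mean distance, perpendicular to the
line of identity, of the points $(D_n, D_{n+1})$ of a Poincaré plot. The
brackets denote the absolute value: a signed sum would measure drift, not
variability, and no signed mode is offered. For independent Gaussian
beat-to-beat jitter with standard deviation $\sigma$,
$E|D_{n+1}-D_n| = 2\sigma/\sqrt{\pi}$, hence
$E[\mathrm{STV}] = \sigma\sqrt{2/\pi}$ — the analytic anchor the validation
suite tests against ($\sigma = 5$ ms $\Rightarrow E[\mathrm{STV}] = 3.989$
ms).

Missing determinants (excluded ectopy neighbourhoods, unmeasurable beats)
break consecutiveness. `stv()` drops pairs spanning a gap and divides by the
retained pair count; alternatively `longest_clean_run()` implements the
strict convention of selecting 31 consecutive clean beats and refusing the
segment otherwise. Both modes exist because study practice selects clean
segments first and excludes within them second, and the two conventions
differ only in how aggressively they refuse degraded data.

## Automatic ARI measurement on the electrogram

The automatic method emulates what an implanted device could compute
continuously:

1. **Ventricular sensing** (`detect_senses()`) marks each beat: an upward
   crossing of the rectified signal above `threshold_frac` (default 0.5)
   times its 95th-percentile amplitude, refined to the local rectified
   maximum within 50 ms, with a refractory period suppressing re-triggers.
   A percentile rather than the absolute maximum keeps a single artefact
   spike from silencing real beats. Because the threshold is a percentile,
   a prominent T-wave always re-crosses it; the refractory period must
   therefore outlast the T-wave's upward crossing, which with
   repolarization intervals above 400 ms falls about 285 ms after the R
   peak (about 340 ms after a pacing stimulus, since sensing locks onto
   the taller artefact). The default refractory is **360 ms**: beyond both
   crossings, below the shortest targeted cycle length (~590 ms).
2. **Dynamic window** (`beat_window()`): `[sense + blanking, sense + RR −
   guard)`. The 200 ms blanking keeps the QRS out of the T-wave analysis;
   anchoring the window end at the beat's own RR minus a 50 ms guard keeps
   the next complex out at every heart rate. A window end proportional to
   RR was the plausible alternative; RR-minus-constant was chosen because
   the quantity to exclude (the next QRS plus sensing jitter) is of fixed
   duration, not rate-proportional. The last beat has no successor and
   uses the record's median RR.
3. **Offset detection** (`measure_ari()`): the first difference of the
   windowed samples is scaled to mV/s and squared — all points become
   positive and slope changes are emphasized, making detection independent
   of T-wave polarity and amplitude scale — and accumulated; the ARI
   offset is the earliest time at which the running area reaches
   `auc_fraction` (default 0.60) of the total, and ARI = offset − sense.

Numerical conventions: the squared difference between samples $k$ and
$k+1$ is treated as area accrued uniformly over that sampling interval, so
the cumulative area is continuous and piecewise linear with knots at the
sample times; the 60% crossing is interpolated linearly between knots.
This removes sampling-rate bias and makes the half-area point of a
symmetric bump its exact centre — a property the tests assert. A
sample-snapped mode (`interpolate = FALSE`) mirrors a device's running
accumulator, which would report the first sample at or past the target
area; whether a device interpolates is not observable from outside, so
both modes are provided and interpolation is the default. Degenerate
inputs: a zero-energy window yields a missing value flagged `noisy`;
windows with peak-to-peak amplitude under `t_amp_min_mV` (default 0.5 mV)
are flagged `low_t_amplitude`; beats whose window contains a detected
pacing spike are flagged `pacing_interference` — the artefact's enormous
squared slope would otherwise own the area integral.

## Fiducial segment averaging on the ECG

`measure_qt_fsa()` measures per-beat QT without per-beat landmark
detection, which would inject repetitive measurement error into exactly
the beat-to-beat differences STV depends on. Each beat is aligned against
the **average of the other beats** (leave-one-out, recomputed every
sweep — fidelity over speed at these problem sizes) by maximizing the
zero-mean unit-norm cross-correlation over integer-sample shifts within
`search_radius_ms` (default 20 ms), iterating until no shift changes or
`max_iters` sweeps. Ties break toward the smallest absolute shift, then
the negative one — a deterministic rule that keeps flat or symmetric
segments stable. The alignment runs three times: around the sense times
(yielding per-beat R times), around `R + q_onset` and around `R + t_end`,
where the landmark offsets come from an annotation, from simulator ground
truth, or from `estimate_landmarks()` (5%-of-peak departures of the
ensemble-average beat). Per-beat QT is the difference of the aligned
T-end and QRS-onset fiducials.

Two properties matter for STV. First, any *constant* landmark error moves
every beat equally and cancels from consecutive differences — the tests
assert that a deliberately mis-set template changes no beat-to-beat QT
difference. Second, shifts are integer samples (no sub-sample
interpolation), because the fiducials live on the sample grid; at 1200 Hz
this quantizes each fiducial to 0.83 ms, which is why a programmed 4 ms
T-end alternans is recovered as 4.17 ms (5 samples). Sub-sample alignment
is deliberately left out rather than half-done. An interactive workflow
would check alignment visually; a library cannot, so beats whose final
correlation falls below `min_corr` (default 0.8) are flagged `noisy`
instead.

## Quality gates and supporting measurements

* **Ectopy exclusion**: an ectopic beat perturbs its own repolarization,
  the preceding cycle length, and the restitution of the following beats;
  the ectopic, one beat before, and two after are excluded (clipped at
  series ends). The rule is idempotent and order-independent over multiple
  ectopics; a brute-force set comparison fuzz-tests it.
* **Pacing**: stimulus artefacts inside the T-wave make QT, QTc and both
  STV modalities unmeasurable; RR and ST-deviation remain reportable.
  `detect_pace_spikes()` identifies stimuli by their slope (3-sample
  smoothed rectified slope above 0.35 mV/ms, far above any physiological
  deflection at these amplitudes) *and* amplitude (above 1.5 times the
  channel's robust amplitude), so neither noise blips nor QRS complexes
  qualify.
* **ST-deviation**: mean amplitude over a 10 ms window at J + 60 ms minus
  a 20 ms PR-segment reference starting 80 ms before the sense, median
  across beats. The operating points are stated defaults — manual caliper
  practice fixes no rule — and the reference subtraction makes the
  measurement DC-invariant.
* **Channel selection**: electrogram poles are scanned in apical order;
  the first with median T-wave peak-to-peak ≥ 0.5 mV and |ST-deviation| ≤
  0.3 mV wins. The tip pole typically fails the ST criterion (injury
  current) and is passed over, mirroring catheter practice.
* **QTc**: Bazett, $QT/\sqrt{RR\,[\mathrm{s}]}$ — reported alongside STV
  precisely to show that rate-corrected duration does not carry the
  pre-arrhythmic signal.

## Agreement between modalities

`agreement_report()` follows the convention of correlating **percentage
changes from baseline** (Spearman, mid-ranks; exact p for n ≤ 9) while
running the Bland–Altman on the **raw ms values** (bias and
bias ± 1.96·SD limits). The mixed pairing is deliberate: percentage
change removes between-subject baseline differences for the correlation,
while a bias is only interpretable in ms. A flag (`ba_on = "percent"`)
switches the Bland–Altman to percentage changes, since the raw-vs-percent
choice is a genuine convention fork. The limits are symmetric about the
bias by construction (`loa_low + loa_high = 2·bias` to machine
precision), which is also the identity that reconstructs a lower limit
from a reported bias and upper limit.

## The synthetic generator: what it emulates, and what it does not

`synthesize_record()` builds each beat from closed-form templates — a
biphasic QRS (difference of two Gaussians, rectified maximum placed
exactly at the recorded R peak), an ST plateau with cosine ramps, and an
asymmetric raised-cosine T-wave whose support ends exactly at the true
repolarization offset — plus ectopic morphology (doubled QRS width,
inverted T, 0.6·RR coupling), pacing stimuli (Gaussian spikes of 0.8 ms
width and twice the QRS amplitude, 55 ms before the R peak, i.e. 25 ms
before QRS onset), and additive white Gaussian noise. Closed forms mean
every landmark used in construction is known exactly and exported, so
estimators are tested against construction truth rather than against
other estimators.

Defaults emulate the recordings the estimators target: EGM-style records
at 1000 Hz (poles I1–I3), ECG-style at 1200 Hz (leads V1–V3), cycle
lengths around 600–900 ms, repolarization intervals around 390–400 ms.
The repolarization default must exceed blanking + T-width + QRS-onset
lead (200 + 120 + 30 = 350 ms), otherwise the generated T-wave would
start inside the blanking period — a geometry in which no
area-under-the-curve method could work and which real signals with these
blanking settings do not present.

What the generator does **not** emulate: torso projection and lead
vectors, respiration and baseline wander, rate-dependent (restitution)
coupling of repolarization to the preceding RR, U-waves, ischaemic
morphology change beyond an ST shift, and coloured noise. Passing tests
therefore demonstrate correctness of the *algorithms* under controlled
signal statistics — landmark recovery, invariances, statistical
convergence — not field performance on clinical recordings, where
morphology instability and noise spectra are harsher.

Determinism: every stochastic function takes a `seed` and routes through
a local RNG scope, so identical configurations give bit-identical records
and the caller's RNG state is never touched.

## The demo scenarios

The ischaemia demo (`demo_ischaemia_scenario()`) ramps per-beat
repolarization jitter over 1, 2, 3, 4 ms across baseline → occlusion →
1 min before VT/VF → just before VT/VF, with growing ST-deviation. The
beat-to-beat jitter pattern is drawn **once** per modality and scaled by
the per-timepoint sigma — modelling ischaemia as amplifying a common
variability substrate — so the ground-truth STV is exactly proportional
to sigma and the scenario's rising STV trajectory holds by construction
for every seed, not just favourable draws. The paced scenario runs the
sinus/paced timepoint grid at +20 bpm above sinus rate and demonstrates
the missingness pattern: stimulus artefacts inside the analysis windows
suppress all T-wave metrics while RR and ST-deviation survive.

The simulated agreement cohort (`simulate_agreement_cohort()`) drives
both modalities from one latent per-subject-per-timepoint sigma with
wide, subject-level uniform fold changes (up to several-fold toward the
arrhythmia): acute-infarct cohorts are heterogeneous — interquartile
ranges of STV on the order of the medians — and it is that between-subject
spread which a rank correlation of percentage changes resolves. With
31-beat series, a single STV estimate carries ~16% relative sampling
error, which bounds the achievable correlation; at 8 subjects × 3
follow-up timepoints the simulated rho centres near 0.8.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 2000 simulated 31-beat
determinant series (direct Gaussian-recovery check, standard error of the
mean ≈ 0.015 ms); 40 full synthetic EGM records through sensing → ARI →
STV; 100 random smooth T-wave windows against a 100 kHz trapezoidal
integration oracle; 10,000 fuzz trials of the exclusion rule; and the
four- and six-timepoint pipeline scenarios at 33 beats per record. These
sizes put Monte-Carlo error well inside the asserted tolerances while
keeping the whole suite in the minutes range on a single core.

## Known limitations

* Integer-sample FSA shifts quantize QT to the sampling grid; at 1200 Hz
  this is the dominant error term for noise-free signals.
* The ARI tracking error grows if the T-wave approaches either window
  edge; configurations whose T-waves cross into blanking are rejected by
  the generator but cannot be detected on real data without a T-onset
  estimate.
* `estimate_landmarks()` assumes a single dominant T-wave in its search
  region; heavily biphasic averages may need an explicit template.
* The Spearman p-value uses the t-approximation for n > 9, adequate for
  the cohort sizes here but approximate.
* WFDB and EDF readers are not included; records enter via CSV (or are
  generated in code). The CSV format carries the sampling rate in a
  header comment and amplitudes in mV (µV inputs are rescaled).
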