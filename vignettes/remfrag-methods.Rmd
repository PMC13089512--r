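---
title: "Methods: sleep fragmentation analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep fragmentation analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remfrag)
```

remfrag implements the analysis chain of a within-subject experiment in which
REM sleep is selectively fragmented by wrist-applied vibrotactile stimulation:
sleep macrostructure and continuity statistics, stimulation-locked EEG
spectral analysis with cluster-based permutation inference, trial-level
autonomic reactivity (cardiac deceleration and electrodermal responses),
recognition-memory sensitivity, and the mixed-model contrast scheme that ties
the conditions (control, CTR; fragmentation, FRG) and sessions (baseline T0,
post-sleep T1, 48-h follow-up T2) together. Because raw recordings from such
experiments are rarely shareable, the package ships a synthetic cohort
generator with planted ground truth; every analysis stage is validated by
recovering what was planted.

## Sleep macrostructure and continuity

A hypnogram is a sequence of 30-s epochs labelled W, N1, N2, N3 or REM, with
lights-off/lights-on boundary markers. `score_macrostructure()` computes total
sleep time (TST), sleep-onset latency (SOL, to the first N1 or N2 epoch), wake
after sleep onset, sleep efficiency (TST/time-in-bed x 100), per-stage minutes
and percentages of TST, REM latency from sleep onset, and the number of
awakenings (wake bouts of at least one epoch between sleep onset and the final
awakening). Undefined quantities (no sleep, no REM) are returned as `NA` with
explicit flags rather than errors.

The REM fragmentation index (`rem_fragmentation_index()`) counts, per hour of
REM sleep: cortical arousals during REM, body movements during REM, and
interrupting bouts — maximal runs of non-REM/wake epochs with REM on both
sides. Two decisions were genuinely open. First, no cap is applied to the
duration of an interrupting bout; any non-REM excursion that returns to REM
counts once. Second, when an arousal is logged in the final REM epoch
immediately before a stage shift, the arousal and the bout are counted as one
interruption (the arousal takes precedence), since they are one physiological
event seen by two detectors.

Sleep continuity is summarized by the 5x5 Markov transition matrix
(`transition_matrix()`): `P[i, j]` is the fraction of epochs in stage `i`
followed by stage `j`, counted inside the in-bed window. Wake before sleep
onset is therefore included only insofar as it lies between lights-off and
lights-on; epochs after lights-on never contribute. Rows whose origin stage is
never visited are undefined rather than zero. `compare_transition_matrices()`
runs a paired t-test per cell with pairwise exclusion of undefined cells and
Bonferroni correction by the number of *computable* cells — not a fixed 25 —
so sparse designs do not pay for contrasts that were never performed. Cells
with fewer than two complete pairs or zero-variance differences are flagged
not-computable.

## Stimulation-locked epoch selection

`select_stim_epochs()` applies four exclusion rules in a fixed order:
stimulations outside REM are dropped first; then only the final stimulation of
each train is kept (it is the one that elicited the cortical response);
artifact-contaminated epochs are dropped third; and epochs in which the
stimulation was followed by a full awakening are dropped last. The order
matters when a train straddles a REM boundary: out-of-REM members are removed
before the "final in train" rule is evaluated, so the kept stimulation is the
last one delivered *in REM*. Trains are taken from the event log when present
and otherwise derived by a gap rule: an onset more than 40 s (the protocol's
suspension time) after the previous onset starts a new train. The
full-awakening rule uses the 15-s post-stimulus window as its horizon: any
wake epoch intersecting it excludes the epoch. Artifact marks are consumed as
input intervals; no automatic artifact detection is attempted.

## Time-frequency analysis

`morlet_ersp()` convolves each epoch (-3 to +15 s around stimulation onset)
with complex Morlet wavelets on a 5-40-Hz grid in 0.2-Hz steps and a 16-ms
time step, with the cycle count rising linearly from 7 at 5 Hz to 42 at
40 Hz — deliberately favouring frequency precision so adjacent bands separate
cleanly. The cycle ramp is anchored at 5 and 40 Hz even when a sub-grid is
analysed. Power is averaged across epochs per channel first; then
`baseline_db()` divides by the mean power of the same frequency in the
-2000 to -1000-ms pre-stimulus window and converts to decibels
(`10*log10(power/baseline)`). The baseline mean is computed on the
epoch-averaged power, matching the stated order "average, then correct".

Numerical choices: convolution runs in the frequency domain with zero padding
to a power of two; time points whose wavelet support (3 temporal SDs) extends
beyond the epoch are marked invalid and excluded from the baseline and all
statistics, rather than being zero-padded into them — zero padding would leak
into the 1-s baseline at the lowest frequencies. Zero baseline power flags the
channel-frequency pair and excludes it. `band_topography()` averages dB over
theta (5-7.8), alpha (8-11.8), sigma (12-15.8), beta (16-29.8) and low-gamma
(30-40 Hz) — inclusive bounds on the 0.2-Hz grid — in the 0-6-s window.

## Cluster-based permutation inference

All three tests (`tf_cluster_test()`, `topo_cluster_test()`,
`topo_cluster_correlation()`) share one engine: point-wise statistics are
thresholded at the two-tailed `cluster_alpha` (0.05), suprathreshold points of
equal sign are clustered — by full 2-D time-frequency adjacency joining across
frequencies, or by montage-derived channel adjacency — and each observed
cluster's mass (the sum of point-wise t values, the common default where mass
versus extent is not specified) is compared against the Monte Carlo
distribution of the maximum absolute cluster mass across permutations, giving
two-tailed family-wise control. Paired designs use exact sign flips of the
per-subject difference maps; the correlation test permutes the behaviour
vector and forms clusters from channels whose |r| exceeds the r corresponding
to `cluster_alpha` at the sample size, with r converted to t for the mass.
p-values use the add-one rule and cannot fall below `1/(n_perm + 1)`. For
each significant correlation cluster the correlation between the cluster-mean
signal and the behaviour is reported — the scatter statistic that accompanies
topographic maps.

Channel adjacency (`channel_adjacency()`) thresholds inter-electrode distance
at the smallest radius giving a median neighbour count of 6, a typical scalp
neighbourhood; isolated channels are flagged, not silently connected. Cluster
membership is invariant to channel reordering given the same montage.

## Autonomic reactivity

Inter-beat intervals are screened by `correct_ibi()`: a beat is an artifact
when it deviates from the median of its sliding 11-beat neighbourhood by more
than `max(min(4.5*QD, 0.3*median IBI), 120 ms)`, QD being half the IQR of
successive differences. The fractional cap keeps the criterion meaningful
when artifacts themselves inflate the difference distribution; the exact
constants are documented free parameters, and records with more than half
their beats flagged are rejected. Flagged beats are replaced by cubic-spline
interpolation.

`hrd()` computes heart-rate deceleration as the mean instantaneous heart rate
(60000/IBI, interpolated to a 10-Hz grid) in the 2 s before stimulus onset
minus the *minimum* in the 6 s after onset — "lowest heartbeat value" is read
as minimal instantaneous rate, i.e. maximal deceleration, so positive HRD
means deceleration. The interpolated-rate mean (not a raw beat average) is
used for the pre-stimulus window as well, so both terms live on the same grid.

`preprocess_eda()` block-averages to 10 Hz, applies a zero-phase second-order
1-Hz Butterworth (edge-replication padding, DC gain normalized to exactly 1)
and a 10-point (1-s) Gaussian smoothing window. `cda_scr()` then recovers the
phasic sudomotor driver by ridge-regularized non-negative deconvolution of
the trace with a peak-normalized Bateman impulse response (time constants
0.75 s and 2 s by default, configurable), after removing a linear tonic trend
fitted to the pre-stimulus segment. `CDA.SCR` is the mean driver in the
1-6-s response window; a trial "responds" when the reconstructed phasic
amplitude reaches 0.05 uS in that window. This is a deliberate simplification
of full continuous-decomposition analysis — the kernel constants are fixed
rather than optimized per subject — and the ridge penalty (0.002) is small
enough that recovered amplitudes shrink by only a few percent.
`screen_nonresponders()` excludes a subject from electrodermal analyses when
fewer than 20% of negative baseline (T0) trials responded in either
condition. `resting_hrv()` provides SDNN, RMSSD and mean heart rate as basic
resting indices.

## Recognition memory

`dprime()` implements `z(HitRate) - z(FalseAlarmRate)` with boundary
corrections: a hit rate of 1 becomes `1 - 1/(2*n_old)` and a false-alarm rate
of 0 becomes `1/(2*n_new)`. The two remaining corners (hit rate 0,
false-alarm rate 1) are corrected symmetrically — an extension beyond the two
cases the original rule names, chosen to keep d' finite and antisymmetric
under response-label swaps.

## Mixed models and planned contrasts

`fit_and_contrast()` fits `outcome ~ condition * session * stimulus_type`
with a random intercept per participant and, for reactivity outcomes, a
crossed random intercept per stimulus ID (the same stimuli recur across
sessions within a condition). F-tests use Satterthwaite denominator degrees
of freedom — the estimation tool behind the original analyses does not state
its method, so the choice is recorded on the result object. The nine planned
comparisons are the three session pairs within each condition and the
between-condition contrast at each session, averaged over stimulus type, with
p-values multiplied by 9 and capped at 1. Contrast vectors are built directly
on the fixed-effect design and tested with `lmerTest::contest1D`. Contrasts
are computed unconditionally, but the reporting hierarchy is recorded: a
significant three-way interaction subordinates the two-way interpretation,
and a non-significant Condition x Session interaction marks the contrasts as
exploratory. Singular fits with the full random structure are refitted
without the stimulus intercept and flagged.

## The synthetic cohort: what is planted, and what is not

`cohort_config()` fixes the study conditions: 17 subjects, two counterbalanced
conditions, 8-h nights of 30-s epochs, 28 reactivity trials (14 negative, 14
neutral) per session, and 40 OLD + 40 NEW recognition items per test.

*Hypnograms* are first-order Markov chains with condition-specific transition
matrices. The FRG matrix lowers REM->REM (0.835 vs 0.935) and raises REM->N1
(0.13 vs 0.03) and N1->REM, leaving wake transitions untouched — the
fragmentation signature of the motivating experiment. The default matrices
were calibrated once so that simulated cohorts land near the published
macrostructure pattern (FRG REM ~58 min / ~13% vs CTR ~96 min / ~22%; N1%
elevated in FRG; TST and efficiency preserved; fragmentation index several-fold
higher in FRG); they emulate the pattern, not the exact printed values.
*Stimulation protocols* replay the escalating scheme over each REM period:
3-s vibrations with 3-s pauses, intensity rising one of 7 steps per
unanswered stimulation under a configurable arousal-probability curve, 40-s
suspension after an elicited arousal with resumption at the previously
effective intensity, and a reset to minimum intensity at each new REM period
(the within-period resume rule follows the fuller protocol description).
Stage dynamics come from the Markov chain; the protocol simulator is
conditioned on them, so a stimulation overtaken by a stage change is logged
as `stage_shift` and not as an arousal — one event, counted once.

*EEG epochs* are 1/f background noise (exponent 1 by default) plus additive
band-limited noise bursts — not sinusoids, to avoid spectral-leakage
artifacts dominating the tests — whose per-bin power is calibrated against
the background spectrum so that the instantaneous power ratio during the
burst equals the planted dB effect. Bursts plateau over 0-6 s (2 s for
low-gamma) with 0.3-s cosine ramps, and their spectra are padded by 1.5
wavelet frequency-SDs into unplanted spectrum (to the gap midpoint between
two planted bands) so wavelet smoothing does not dilute the planted ratio at
band edges; the corresponding spillover just below 8 Hz mirrors what real
spectral smoothing does. Posterior channels (P*, PO*, O*) receive full
weight; anterior weights are band-specific (0.5 for alpha, 0.35 for
low-gamma, 0.9 elsewhere), emulating a posterior-dominant alpha signature and
centro-parieto-occipital low-gamma. Each subject's alpha effect is
3 dB + N(0, 1).

*Autonomic trials* integrate an instantaneous heart-rate curve with a planted
raised-cosine dip (onset 0.5 s, duration 4 s — the shape is unspecified in
the motivating work; only the minimum in the window matters for HRD) so each
IBI reflects the mean rate over its interval. Planted amplitudes follow the
habituation pattern: CTR 5 bpm at T0 dropping to 2.5 bpm at T1/T2, FRG flat
at 5 bpm (neutral stimuli at 60%). No published effect size exists for this
drop — the distributions are shown only graphically — so the default is a
free parameter chosen so the planted drop (2.5 bpm) is about twice the trial
noise standard error of a per-subject session mean (6/sqrt(28) ~ 1.13 bpm).
Trial amplitudes add subject (SD 1.5) and stimulus (SD 0.8) random
intercepts plus N(0, 6) trial noise; a trial whose realized amplitude is
negative shows no dip, so the measured HRD floors at ~0. EDA traces carry
Bateman-kernel SCRs at 1-3-s latency with configurable response
probabilities and amplitudes. *Recognition responses* come from an
equal-variance signal-detection model with planted d' per session (2, 1.6,
1.3 — memory declines over sessions regardless of condition).

*Coupling:* each subject's change in HRD from T0 to T1 in the FRG condition
is `1.9 x (alpha - 3) + noise`. With subject-level alpha SD 1, coupling noise
SD 1.02 and the unavoidable trial-averaging noise of two 28-trial session
means (6*sqrt(2/28) ~ 1.6 bpm), the measured subject-level correlation is
~0.707 — the planted analogue of the reported parieto-occipital association.
`simulate_coupled_topographies()` generates exactly this quantity at the
topography level for the inference-calibration studies, and
`simulate_hrd_measurements()` is the trial-level shortcut for power studies;
a calibration test keeps the shortcut consistent with the full
signal-synthesis path.

What the generator does *not* emulate: sleep spindles, slow oscillations and
other NREM microstructure; ocular and muscular artifacts; non-stationary
tonic EDA drifts beyond a linear trend; circadian structure in REM-period
lengths; and any dependence of arousability on sleep depth. Tests passing on
this cohort therefore demonstrate that the estimators and tests recover known
truths under realistic noise levels and the right data shapes — not that they
are robust to every pathology of real polysomnography.

## Verification problem sizes

The operating-characteristic studies run at 17 subjects with 500 Monte Carlo
permutations (scaled down from the 5000 used for reporting real analyses) and
200 replicate cohorts: family-wise error of the topography and correlation
cluster tests on null cohorts; recovery rate and cluster-mean correlation for
the planted posterior-alpha coupling; and power of the mixed-model
habituation analysis (significant Condition x Session interaction plus a
significant Bonferroni-corrected CTR T0-vs-T1 contrast). Estimator
calibration uses 100-120 epochs where a single subject's ERSP is measured,
and 1000 random hypnograms for the transition-matrix oracle equivalence.
`scripts/acceptance.R` re-runs all of these from scratch under a caller-chosen
seed.

## Known limitations

The CDA.SCR statistic is a regularized deconvolution with fixed kernel
constants, not a full continuous-decomposition optimization; absolute values
are comparable within a study but not to Ledalab outputs. The EDF layer
covers continuous 16-bit recordings with a common sampling rate — enough for
multichannel EEG exchange, not the full EDF+ annotation standard. The Markov
hypnogram model has geometric stage-bout durations, which is adequate for
transition statistics but underdisperses REM-period lengths relative to real
nights. Mixed-model denominator degrees of freedom are Satterthwaite
approximations; with 17 subjects, small-sample behaviour of the three-way
interaction F-test should be interpreted with the usual caution.
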