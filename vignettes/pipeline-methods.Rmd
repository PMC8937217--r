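---
title: "Methods: trial-aligned calcium transient analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-aligned calcium transient analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the analysis model implemented by `axonca`, the
reasoning behind its tunable parameters, what the synthetic-session
generator does and does not emulate, and the numerical conventions chosen
where a published description leaves the details open.

## The analysis model

### Task structure

A session is a sequence of go/no-go trials. Within each trial, time zero
is the trial start; the tactile stimulus (or, on catch trials, a virtual
stimulus time used for alignment) occurs at +3 s; licking during the
half-open response window [stimulus, stimulus + 1.5 s) determines the
outcome; rewarded trials have the reward delivered at the window's end.
Trials are recorded out to the end of the reward-retrieval window plus a
2 s tail (8.5 s total), so that the −2 s spontaneous window and
post-reward frames always exist, and are separated by a 4–7 s randomized
inter-trial interval. Outcomes follow signal-detection conventions: on
stimulus trials HIT/MISS, on catch trials FA/CR. In the *action* task a
HIT is a lick inside the window; in the *suppression* task the
contingency inverts — withholding licks for the full window is the HIT.

### From movie to ΔF/F

Rigid motion is estimated per frame as the integer shift maximizing the
whole-frame cross-correlation with a reference image built by averaging
frames whose drift relative to a provisional anchor (the temporal median
frame) stays below 15 px in both axes. ROI traces are mean intensities
over mask pixels; frames whose estimated shift reaches 15 px are flagged
and their samples treated as missing downstream.

The baseline F₀ of an ROI on a given trial is the centered rolling median
(default 5 trials, truncated at session edges) of the per-trial mean
fluorescence over the 60 frames (2 s) preceding stimulus onset. The
rolling median tracks slow drift and bleaching while remaining immune to
a single event-contaminated baseline; the companion noise estimate,
`baseline_sd`, pools all pre-stimulus raw samples of the ROI across
trials, which stabilizes the estimate at the cost of a slight upward bias
when spontaneous transients intrude on the baseline window (see
*Limitations*). ΔF/F = (F − F₀)/F₀ per trial; ROIs with non-positive F₀
are excluded with a logged reason.

### Transient detection

An event is a maximal contiguous run of samples with ΔF/F above the
threshold, lasting *strictly longer* than 200 ms. The threshold
implements the raw-fluorescence criterion F₀ + 2·SD in ΔF/F units:
2·`baseline_sd`/F₀(trial). "Strictly longer" is taken literally: at
30 Hz a 6-sample (200 ms) run is rejected and 7 samples (233 ms) is the
minimum event. Onset is the first suprathreshold sample, offset the first
sample back below threshold (one sample period past the run's last sample
when the trial ends while still suprathreshold), peak the maximum ΔF/F in
the run, duration the offset minus onset. Missing samples split runs at
the gap rather than bridging it — a conservative choice that can split
one physiological transient in two but never fabricates suprathreshold
time.

### Active axons, deduplication, epoch statistics

Only ROIs with at least one detected transient anywhere in the session
("active axons") enter probability analyses; amplitude and duration are
additionally conditioned on having an event in the analysed epoch, so
those statistics describe evoked transients rather than mixing in zeros.

Axonal branches and boutons of one neuron appear as separate ROIs with
nearly identical activity. Two phrasings of the published exclusion rule
circulate — trace correlation above 95%, and event coincidence in more
than 95% of trials — and they are not equivalent. The per-trial
event-agreement reading is implemented: for each ROI pair and trial,
agreement is 1 when both have an event with onsets within ±2 frames
(~67 ms) or both are silent, else 0; pairs whose mean agreement exceeds
0.95 are linked, connected components form duplicate groups, and the
member with the highest mean event peak (a proxy for the
best-signal-to-noise branch) survives. The threshold and tolerance are
arguments, so the stricter correlation reading can be approximated by
tightening them. Deduplication is skipped with a warning on single-trial
sessions, where the agreement fraction is degenerate.

The canonical epochs are spontaneous [−2, −1) s and response [0, +1) s
relative to stimulus onset, and reward [0, +1) s relative to reward
delivery; an optional split subdivides the first post-stimulus second
into stimulus [0, 0.5) and response [0.5, 1.0). The merged window is the
default because few axons respond during the stimulus half alone. The
reward epoch is anchored on the actual reward-delivery time, not a fixed
post-stimulus offset; on unrewarded trials the window is omitted, never
zero-filled, and statistics with zero eligible trials are reported as
missing rather than 0. Event probability counts a trial once however many
onsets fall in the window (Σ event-trials / Σ trials), which keeps the
statistic a probability bounded by 1.

### Behavior and pupil

d′ = z(H) − z(F) with z the standard-normal quantile; rates of exactly 0
or 1 are moved to 1/(2N) and 1 − 1/(2N) (N the relevant trial count), the
standard signal-detection correction. The correct fraction is
(HIT + CR)/(stimulus + catch), with ≥ 0.8 flagging an expert session.
Lick–activity association uses the Spearman rank correlation between
per-trial lick frequency and the fraction of ROIs with an event in the
trial, via `stats::cor.test`.

Pupil traces are split into 11 s trial windows (−4 to +7 s around trial
start) and averaged within outcome class; peak diameters are the maxima
of the average trace in the baseline [−4, 0) s (trial start), pre-tactile
[−3, 0) s and post-tactile [0, +4) s (stimulus) windows. Samples flagged
as eyelid artifacts are excluded, and a trial is dropped when more than
20% of any window is flagged — a concrete rule standing in for the
published "checked post hoc" screening.

## The synthetic-session generator

The generator's purpose is validation: it produces sessions whose every
downstream quantity is known. Per axon, trial and epoch, at most one
transient is injected with the configured probability (matching the
"probability per trial" reading of the event statistic); onsets are
uniform in the epoch window, snapped to the frame grid, and kept 0.1 s
clear of the window end so that threshold-crossing latency cannot move a
detected onset across the epoch boundary — without this margin the
recovered probability would be biased low by edge leakage rather than by
any property of the detector. Impulse trains are convolved with a
difference-of-exponentials kernel (rise 50 ms, decay 400 ms, unit peak on
the sampling grid — fast-indicator-like kinetics), scaled by the baseline
level, and overlaid with slow sinusoidal drift and white noise. Branch
ROIs share the parent's event train and amplitudes with independent
noise. Probabilities may be outcome-dependent (e.g. response HIT 0.27 vs
MISS 0.12) to emulate performance-correlated signaling.

Default conditions: ~300 trials with 40% catch trials, 30 Hz, 512×512 px,
19 ROIs, lognormal amplitudes with mean 1.0 ΔF/F and SD 0.25, baseline
level 100 with noise SD 8 and drift amplitude 2. The noise default was
chosen so that the resulting 2·SD detection threshold sits near 0.2 ΔF/F:
at that operating point virtually every injected transient is detectable
(so injected probabilities are interpretable as ground truth for
recovery) and detected durations come out in the 600–750 ms range typical
of fast indicators. The narrow amplitude spread serves the same purpose —
at SD 0.25 essentially no event falls below threshold, which is what
"high signal-to-noise" should mean in a recovery benchmark. Raw-frame
rendering (Gaussian blobs at ROI centroids under a piecewise-constant
integer drift) and the pupil model (raised-cosine dilation confined to
the 4 s post-tactile window, optional blink dropouts) follow the same
philosophy: simple, fully known, and sufficient to exercise the analysis.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: neuropil and out-of-focus
contamination, overlapping or summating transients within one epoch,
amplitude adaptation, non-rigid motion and z-drift, bleaching beyond a
slow sinusoid, correlated noise across ROIs, and any behavioral model
(outcomes are sampled from configured rates, since they are inputs to the
analysis, not its product).

## Numerical choices

- Cross-correlation is computed on mean-subtracted images in the
  frequency domain; it is circular, so shifts are unambiguous only below
  half the frame size — far above the 15 px flagging threshold at any
  realistic field of view. Ties in the correlation maximum break toward
  the zero shift, then deterministically by magnitude and sign. Exposed
  pixels after correction are filled with the frame's median. A
  zero-variance frame yields shift (0, 0) and a flag.
- The strict duration rule uses `floor(d·f + 1e-9) + 1` samples to be
  robust to floating-point representation of 200 ms at 30 Hz.
- The rolling median truncates at session edges (a 5-trial window becomes
  3 at the first trial) and skips missing per-trial baselines.
- Row order and number formatting of the epoch-statistics CSV are fixed,
  so identical seeds give byte-identical files.

## Problem sizes used in validation

The test suite validates parameter recovery at 418 ROIs × 40 trials
(epoch probabilities, with ordering checked across 20 seeded replicates),
159 ROIs × 40 trials (HIT/MISS contrast, 20 replicates), 20 duplicate
triplets plus 20 singleton axons × 40 trials (deduplication), all 841
integer shifts up to ±14 px (registration), 1,000 mixed-SNR traces
against a brute-force detection oracle, and 50 trials for pupil recovery.
These sizes keep every statistic's sampling error well inside its
acceptance band while the full suite runs in minutes on one CPU.

## Limitations

The pooled `baseline_sd` is biased upward when spontaneous transients
land in the pre-stimulus window, so the effective threshold is slightly
conservative for highly active ROIs. Overlapping transients are detected
as a single event (no deconvolution), which can shadow a reward-epoch
onset behind a long response transient on rare trials. Registration is
integer-pixel and rigid only. The per-trial event-agreement deduplication
cannot distinguish genuinely synchronized distinct axons from branches of
one axon — at 95% over 40 trials this is a negligible false-positive
source, but it is a conceptual limit of any activity-based rule.
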