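---
title: "Methods: hierarchical activity and gait-phase recognition from wearable IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical activity and gait-phase recognition from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

People with knee osteoarthritis move differently from healthy adults during
exactly the activities that matter clinically: standing up from and sitting
down on a chair, negotiating stairs, and walking. A wearable system that
recognizes *which* activity a patient is performing — and, within gait,
*which phase* (stance or swing) each instant belongs to — lets a clinician
count stair use at home or cut out the stance phase of stair descent for
biomechanical analysis without supervising the recording.

`kneehar` implements such a system as a three-level hierarchy over
windowed inertial-measurement-unit (IMU) data from four sensors
(left/right thigh and shank, 100 Hz, tri-axial accelerometer + gyroscope;
magnetometer channels are read but discarded before modelling):

* **Level 1** — activity: chair transition, stairs, walking.
* **Level 2** — direction: sit down / stand up (chair), ascending /
  descending (stairs). Walking has no direction split.
* **Level 3** — gait phase: stance / swing, separately for stair ascent,
  stair descent and walking.

Six independent convolutional classifiers, one per internal node of this
taxonomy, are arranged in a decision tree: a window first receives an
activity label; contiguous runs of one activity are handed to the routed
child, which classifies its own, finer window grid inside the span.

## Synthetic cohort

The patient recordings such a system would be trained on cannot be bundled,
so the package ships a simulator that generates labeled cohorts with the
statistical structure the classifiers rely on, and every stage is tested
against it. Per participant the default battery mirrors a realistic
laboratory session: 5 chair sit-to-stand-to-sit trials, 3 stair ascents,
3 stair descents and 3 short walks (14 trials; an 18-participant cohort
yields 252).

The signal family is deliberately simple — the simplest family that
produces the class-distinguishing structure the classifiers exploit:

* **Gait activities** (walking, stairs up/down): each channel is a sum of
  2–3 harmonics of the cycle frequency with channel- and activity-specific
  weights and phases. The right limb's channels repeat the left limb's
  waveform advanced by half a cycle (reciprocal gait); chair channels are
  bilaterally synchronized. Stance/swing contrast is injected by amplitude
  modulation: the swinging limb's shank gyroscope oscillates harder and its
  thigh accelerometer carries a DC shift. The label track records the
  *right* limb's phase (a documented convention; the taxonomy does not say
  whose phase is labeled).
* **Chair trials** are alternating stand-up/sit-down half-sine bursts
  (starting with stand-up, per the sit-to-stand-to-sit definition),
  separated by quiet gaps drawn uniformly from 0.5–1.5 s, with opposite
  signs for the two directions.

Key parameters (see `signal_params()`):

* `cycle_duration_s` — stride/burst duration; defaults 1.1 s (walking),
  1.4 s (stairs), 1.5 s (chair burst), in the range reported for older
  adults with knee pain.
* `stance_fraction` — fraction of each gait cycle in stance; defaults 0.62
  (walking) and 0.60 (stairs), typical published values.
* `separation` — a single non-negative dial scaling *between-class*
  signature differences. Activity amplitude profiles and cycle durations
  are interpolated between the across-activity mean (separation 0) and
  their own values (separation 1); the stance/swing modulation is
  proportional to it. At 0 the gait classes and phases collapse; increasing
  it cannot hurt a trained classifier, a property the tests check.
* `noise_sd` — additive Gaussian noise as a fraction of each channel's
  reference amplitude (default 0.05).
* `participant_sd` — log-normal multiplicative perturbation (sd on the log
  scale, default 0.10) of each participant's amplitudes and cycle
  durations, drawn once per participant so leave-one-out folds differ. This
  is a crude stand-in for the elevated movement variability of the target
  population.

Gait default durations cover whole numbers of cycles (e.g. 4 strides for
walking), which makes the generated stance fraction exact up to
cycle-boundary rounding regardless of the random start phase.

What the simulator does **not** emulate: soft-tissue artefact, sensor
drift and re-mounting variability, magnetometer disturbances, non-battery
activities, and the heavy-tailed idiosyncrasies of real patient movement.
Consequently, high accuracy on the synthetic cohort demonstrates that the
pipeline *recovers structure it is pointed at* — correct plumbing, no
leakage, sufficient model capacity — not that comparable accuracy would be
reached on patient data.

## Windowing and image encoding

Each level uses a fixed window slid in 10 ms increments (defaults 200,
100 and 40 ms for levels 1/2/3, i.e. 20/10/4 samples at 100 Hz — read
literally, and overridable per level because 4-sample windows are very
short). A trial of length `L` yields `floor((L - W)/S) + 1` windows: every
extra slide increment is one extra training image, which is the pipeline's
data augmentation. `suggest_window()` implements the sizing rule used to
pick these values from data: the 80th percentile of the event-duration
distribution, rounded down to a multiple of the slide.

A window becomes a 24-row image (sensors in a fixed order, accelerometer
before gyroscope, x/y/z; see `channel_names()`) by per-channel min–max
normalization to 0–255. Numerical choices, all tested:

* normalization constants come from the **training fold only**; held-out
  values beyond them clamp to 0/255 (fitting them globally would leak);
* rounding is half-away-from-zero, so encodings are bit-reproducible
  across platforms (R's default `round()` is banker's rounding);
* a zero-range channel maps to 0;
* a training window overlapping two label intervals takes the majority
  label of its samples, an exact tie going to the earlier-starting label
  (at inference, competing decisions for one span are instead resolved by
  the higher prediction probability, `resolve_overlap()`); a window with
  fewer than half its samples labeled gets `NA` and is dropped from
  training.

Because stance/swing sample counts are unbalanced, each node's training
windows are balanced by random downsampling to the minimum class count
(`balance_by_class()`), per training fold — balancing before the
participant split would let the held-out participant influence the
selection.

## The classifiers

No deep-learning framework is assumed: the package contains a compact,
fully deterministic convolutional-network engine (`R/cnn.R`) operating on
the tiny 24×W images via an im2col expansion and BLAS matrix products.
Architecture per node: two convolutional layers at level 1, three at
levels 2 and 3 (3×3 kernels, 16/32/64 filters by default, ReLU), one 2×2
max-pool after the first convolution where the feature map allows it, a
64-unit dense layer with dropout 0.3, and a softmax head. For the 4-sample
level-3 windows, kernels shrink automatically to the available width and
pooling is skipped, keeping the literal 40 ms window usable. Training is
Adam (learning rate 1e-3 by default, settable per node) on minibatches,
with a stratified 10 % validation split driving early stopping (patience
3) and the best-epoch parameters retained. All randomness — initial
weights, shuffling, dropout, splits — flows from one seed, so two
identical runs produce identical networks.

The class order within each node is fixed and documented; it is the
tie-break order wherever probabilities tie exactly, and ties are logged.

## Evaluation

Validation is leave-one-participant-out: train the six nodes on all
participants but one, test on the held-out participant, repeat for every
participant. Per node and fold a confusion matrix is accumulated; metrics
are the standard

$$\mathrm{accuracy} = \frac{TP+TN}{TP+FP+TN+FN},\qquad
  \mathrm{precision} = \frac{TP}{TP+FP},\qquad
  \mathrm{recall} = \frac{TP}{TP+FN},$$

reduced one-vs-rest per class for multiclass nodes, with macro averages.
An undefined ratio (empty denominator) is reported as `NA` with a flag,
never silently zeroed, because silent zeros bias macro averages. The
headline per-node accuracy is the mean of per-fold accuracies (the average
across participants); the pooled-confusion accuracy is reported alongside.

By default each node is evaluated on its ground-truth-routed windows, so
per-node accuracies are independent of upstream mistakes and comparable
across nodes; `routing = "predicted"` instead pushes held-out trials
through the full tree and scores every emitted decision against the
majority true label of its span, measuring the deployed system end to end.

## Problem sizes and reproducibility

The bundled `quickstart.yaml` is the configuration the package's
system-level checks run: 6 participants, a reduced battery (3 chair, 2+2
stair, 2 walking trials), separation 2.5 with noise 0.05 (a
high-separation, low-noise regime), slides of 50/20/20 ms, 8/16/32
filters, 32 dense units and at most 8 epochs — a full leave-one-out run of
all six nodes takes about 3 minutes on one CPU and recovers the taxonomy
essentially perfectly (all node accuracies ≥ 0.99 at the pinned seed). Two
runs with the same master seed produce byte-identical reports; the master
seed fans out to per-stage seeds through a documented counter scheme
(`derive_seed()`), so the randomized balancing required by the unbalanced
phase counts remains reproducible.

## Known limitations

* Trials are the unit of inference; continuous unsegmented monitoring
  (unknown trial boundaries) is out of scope.
* There is no rejection of out-of-vocabulary activities: every window is
  forced into the taxonomy.
* The reference architecture's exact hyper-parameters are not published;
  the defaults here are the package's own choices, exposed in the
  configuration rather than claimed as reproductions.
* Synthetic accuracies say nothing quantitative about patient data (see
  the simulator section); the published patient-data accuracies (85 %
  level 1, 97 %/89 % level 2, 60–67 % level 3) are properties of an
  unavailable dataset and are intentionally not asserted by any test.
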