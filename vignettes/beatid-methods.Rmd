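---
title: "Single-heartbeat ECG identification: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-heartbeat ECG identification: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatid)
```

## The method

An electrocardiogram carries a morphological signature that is stable within
a person and different between persons: the relative timing of the Q, R, S
and T landmarks of each heartbeat. **beatid** identifies a person from a
single beat using only three temporal intervals,

$$\mathrm{QT} = t_T - t_Q,\qquad \mathrm{RT} = t_T - t_R,\qquad
\mathrm{ST} = t_T - t_S,$$

each divided by one population constant $\overline{RR}$, the mean R-to-R
interval over *all* accepted training beats pooled across subjects:

$$\mathrm{QT}_n = \mathrm{QT}/\overline{RR},\quad
\mathrm{RT}_n = \mathrm{RT}/\overline{RR},\quad
\mathrm{ST}_n = \mathrm{ST}/\overline{RR}.$$

Dividing by a *shared* constant (rather than a per-subject or per-beat RR
correction such as Bazett's formula) means a deployed system stores exactly
one normalization number, and a new beat can be projected into the training
feature space without knowing whose beat it is — which is the whole point of
identification. The cost is that the normalization removes only the
population-average heart-rate scale, not each subject's rate; what remains
of the subject's rate is treated as part of their signature.

Classification is one-against-all: one soft-margin SVM per enrolled subject,
with the Gaussian kernel

$$K(x, y) = \exp\!\left(-\frac{\lVert x-y\rVert^2}{2\sigma^2}\right).$$

Note the convention: $\sigma$ is the kernel *width*. Libsvm-style interfaces
use $\gamma = 1/(2\sigma^2)$; confusing the two rescales the entire
hyper-parameter grid. A beat is assigned to the class whose binary decision
value is largest (ties go to the first class in sorted order). The
hyper-parameters $(C, \sigma)$ are selected from the grid
$\{0.01, 0.1, 1, 10, 50, 100, 150, 200\}^2$ by stratified 5-fold
cross-validation of the full one-against-all scheme, ties broken toward the
smallest $C$, then the smallest $\sigma$.

## The pipeline

1. **Low-pass filtering** (`lowpass_filter`): second-order Butterworth,
   10 Hz cut-off, applied forward and backward. Zero-phase application
   matters: a causal filter would delay the Q/S/T landmarks relative to the
   R marks and corrupt every interval. The two passes square the magnitude
   response, so the cut-off sits at −6 dB. Edges are handled by
   odd-symmetric reflection padding of eight filter time constants, which
   makes filtering commute with time reversal to 1e−9 — the property the
   test suite checks.
2. **R detection** (`detect_r_peaks`): the Pan-Tompkins chain — band-pass
   5–15 Hz, centered five-point derivative, squaring, 150 ms moving-window
   integration, dual adaptive thresholds with search-back, 200 ms refractory
   period, 360 ms T-wave slope test. All thresholds adapt multiplicatively,
   so detection is invariant to amplitude scaling. Candidate peaks are
   pruned so only the dominant integrated-energy maximum within any
   refractory window survives; without this, the Q/S slope energy creates
   side lobes that shadow the true peak. Detections are snapped to the raw
   maximum within ±25 ms.
3. **Q/S/T delineation** (`delineate`): on the derivative of the filtered
   signal, Q is the *last* sign change within 0.100 s before R; S the
   *first* negative-to-positive transition within 0.050 s after R; T the
   *last* positive-to-negative transition 0.050–0.400 s after R. A crossing
   is reported at the later sample, i.e. at the extremum sample itself. One
   subtlety: these rules exclude R itself because the R extremum is a
   trivial crossing — but the *filtered* R extremum sits a couple of
   milliseconds from the raw maximum. `delineate` therefore re-anchors each
   beat to the filtered-signal maximum within ±10 ms of the Pan-Tompkins
   mark and reports all indices on that one timeline, which makes the
   exclusion rule well-posed and the intervals self-consistent.
4. **Plausibility filtering** (`quality_filter`): accept a beat iff
   $QR \le 0.075$ s (inclusive), $0.200 < QT/RR < 0.360$ (strict), and —
   gated, on by default — $0.3 \le RR \le 2.0$ s. The first failed rule is
   recorded. The RR for both the ratio and the gate is the *preceding*
   R-to-R interval (causal, computable in streaming); the first beat of a
   record is dropped for lack of one.
5. **Fit and predict** (`beatid`, `predict.beatid`): $\overline{RR}$ and
   the normalization are recomputed from each training set alone; test
   beats are normalized with the *stored* constant. Beats failing the
   plausibility filter are refused (NA label with a reason), never
   classified.

## Evaluation protocol

Each subject's record is cut into contiguous 10 s blocks numbered from the
record start (the 120 s default gives 12). For every one of the
$\binom{12}{2} = 66$ unordered test-block pairs, a model is trained on the
first $d/10$ blocks of that plan's training order ($d$ = 10…100 s) and
tested on the two held-out blocks of every subject; training orders are
seeded random permutations, rejection-sampled so no order repeats across
plans, and train/test disjointness is asserted at run time. Reported per
duration, averaged over the 66 runs:

* argmax identification accuracy, and the averaged binary accuracy (the
  mean over classes of each binary's accept/reject accuracy — both are
  reported because the two summaries genuinely differ: a binary can reject
  its own class while argmax still ranks it first);
* FAR and FRR in percent, from the binaries' accept/reject decisions
  (`FRR = FN/(TP+FN)` over genuine beats, `FAR = FP/(FP+TN)` over
  impostors, averaged over classes) — verification semantics at beat level;
* mean beats-to-identification: per subject and repetition, test beats are
  reshuffled and classified one at a time until the first correct label or
  exhaustion (exhausted repetitions contribute the full set size and are
  reported separately); 500 repetitions by default. For a set of $n$ beats
  of which $m$ classify correctly, the expected count is
  $(n+1)/(m+1)$ — the test suite checks the simulation against this closed
  form;
* the speed-rate range: mean beats-to-identification times the extreme
  observed test RR intervals.

When a short training duration leaves a subject with fewer accepted beats
than the fold count, the cross-validation folds shrink to the smallest
class size (floor 2) for that run rather than aborting; `cv_grid_search`
called directly keeps the strict error.

Records are delineated once in full and beats assigned to blocks by their R
index. Slicing the signal first and delineating per block would lose one to
two edge beats per block (their search windows leave the block); either
reading satisfies the protocol, and block disjointness is asserted
identically.

## The synthetic generator

`generate_record` builds each beat as five Gaussian bumps (P, Q, R, S, T)
with per-subject timing offsets, tiled at R-to-R intervals drawn i.i.d.
from a truncated normal on [0.3, 2] s, plus white noise. It emulates the
properties the method relies on — stable per-subject QT/RT/ST morphology,
inter-subject timing differences, RR variability, additive noise — and
deliberately not the ones it does not use: no RR autocorrelation, no
baseline wander, no powerline interference, no pathological morphologies,
no amplitude variability between beats. Passing tests on this generator
therefore demonstrate correct mechanics and parameter recovery, not
robustness to every artifact of ambulatory recordings.

**Ground truth and pre-compensation.** The delineator analyses the 10 Hz
filtered waveform, and that filter moves the extrema of narrow overlapping
bumps by up to ~15 ms (the filtered Q/S notches migrate away from their raw
centers). Raw bump centers are therefore *pre-compensated* by a damped
fixed-point iteration until the filtered waveform's extrema land exactly on
the template offsets; those offsets are recorded as the ground truth. The
ground truth is thus the analytic landmark position of the morphology the
pipeline observes, and noise-free delineation recovers it to within a
sample or two. Templates whose morphology admits no such consistent
placement (residual > 2.5 samples) are rejected.

**Defaults** (one beat, resting adult, chosen once): QR 40 ms, RS 35 ms,
RT 270 ms, P 180 ms before R; widths 30/18/10/16/55 ms; amplitudes
0.12/−0.45/1.10/−0.80/0.45 mV; RR 1.00 ± 0.025 s; noise SD 0.02 mV
(≈20 µV, a clean resting recording). The late T keeps the flat tail of the
0.05–0.40 s T search window short — with an early T, filtered-noise ripple
in the long flat tail occasionally captures the "last" crossing, and such
beats are (correctly) discarded by the plausibility filter. With these
defaults a 10-subject, 120 s cohort yields ≈1140 accepted beats, matching
the scale of a real two-minute single-lead enrollment study.

**Separation control.** `generate_cohort` draws per-subject (QT, RT, ST)
triplets as `base + separation × sd × u`, with `u` uniform in
[−1.5, 1.5]³ and pairwise triplet distances ≥ `separation × sd`, where
`sd` is the empirical timing-noise scale measured by delineating a
reference record at the cohort's noise level (MAD-based, floored at one
sample: occasional rejected-downstream T mis-locks must not inflate the
unit). `separation = 0` collapses all subjects onto one template, so
identification can only succeed at chance — the negative control the test
suite uses. Each draw is checked against the template bounds and the
plausibility band (so generated beats pass their own filter), with bounded
retries before declaring a separation infeasible.

## Numerical choices and degenerate inputs

* Crossing convention: a sign change between consecutive derivative
  elements, reported at the later sample; an exact zero counts as a
  crossing. Deterministic at any sampling rate.
* The SVM dual is solved by libsvm (termination tolerance 1e−6 by
  default); support points with $|\alpha| <$ 1e−8 are dropped. Decision
  values agree with an independent brute-force KKT enumeration to better
  than 1e−5 on every fixture in the test suite.
* Serialized models are JSON at full double precision; a round trip
  reproduces decision values exactly.
* Empty or degenerate inputs error early with explicit messages: empty
  feature sets, single-class training data, non-positive $\overline{RR}$,
  records shorter than one block or than the 2 s the detector needs.
* Problem sizes in the tests: the study-scale checks run a 10-subject,
  120 s, 1000 Hz cohort with a reduced 4×4 grid at training durations
  {10, 30, 60} s over all 66 plans; the chance-level control runs at 10 s
  training over 11 plans (chance behaviour does not depend on training
  duration, and non-separable fits are an order of magnitude slower).
  Smaller unit fixtures use 3 subjects at 500 Hz.

## Known limitations

* The generator's beats are time-invariant within subject apart from RR
  jitter; real within-subject morphological drift (posture, respiration,
  autonomic state) is not modelled, so real-data accuracy will be lower
  than the synthetic plateau.
* The QT/RR plausibility band (0.200, 0.360) is the published rule set and
  is narrow relative to textbook QT values; with the default heart rate the
  generator's templates are chosen to sit inside it, as the reference
  subjects' delineated beats evidently did.
* FAR/FRR use the binaries' accept/reject decisions (verification
  semantics). An identification-matrix derivation would give different
  numbers; the per-class table is returned so either can be computed.
* WFDB support covers standard header + format-16/212 signal pairs, one
  lead at a time — enough to reproduce a public-database study, not a
  general-purpose reader.
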