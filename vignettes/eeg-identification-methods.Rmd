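---
title: "Identifying people from resting-state EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from resting-state EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Scalp EEG carries stable, subject-specific structure — spectral signatures
and the spatial projection of cortical sources onto the electrode array —
which makes it usable as a biometric. Resting-state protocols (eyes open,
EO, or eyes closed, EC) are the most deployable variant: no task, no
stimulus hardware, and only a short acquisition. `eegid` implements a
closed-set identification system for such recordings: given `O` enrolled
subjects and a 0.5-second multichannel segment, predict which subject
produced it, and score verification claims (FAR/FRR/EER) from the same
classifier.

The pipeline is: EDF ingestion and montage selection → per-subject Z-score
standardization → temporal train/test split → sliding-window segmentation
→ a convolutional network with a learnable channel-mixing first stage →
Rank-1 / EER evaluation.

## Preprocessing

No filtering, artifact rejection or re-referencing is applied anywhere:
the raw signal is preserved except for one affine scaling. For each
subject, the mean $\mu$ and population standard deviation $\sigma$ are
pooled over *all* of that subject's values — every channel, every
time-point, and every session included in the experiment — and each value
is mapped to $(x - \mu)/\sigma$. This stabilizes optimization without
touching the information content.

Two deliberate choices here:

* **Pooling scope.** When an experiment uses both resting sessions of a
  subject, the statistics pool both sessions; single-session experiments
  pool only that session. The configuration records which pool was used.
* **Statistics before the split.** Statistics are computed on the full
  recording before the train/test time split, matching a pipeline in
  which preprocessing precedes division. Two scalars per subject leak
  negligible information from the test span, but the strict variant is
  available (`stats_scope = "train"` in `run_experiment()`), which pools
  training intervals only.

Population (divide-by-N) rather than sample standard deviation is used;
at $N \sim 10^5$ values per subject the difference is far below any
tolerance in this package, but fixing it keeps runs bit-reproducible.

## Sliding-window augmentation

A window of `length_s` seconds advanced by `stride_s` seconds cuts a
recording of $T$ samples into
$$N = \left\lfloor \frac{T - L}{S} \right\rfloor + 1$$
segments ($L$, $S$ in samples), starting at offset 0 and discarding any
trailing remainder. `stride_s = length_s` is the non-overlapping "fixed
window"; the system's operating point is a 0.5 s window with 0.25 s stride
(sliding ratio 0.5, i.e. 50% overlap), which at 160 Hz gives `P = 80`
time-points per segment.

Windowing always happens *after* the train/test division, independently
inside each split interval, so no window straddles a boundary. With
overlapping windows this is what keeps near-duplicate segments from
leaking between train and test.

Segments are stored time-major (`P x C`), the orientation the network's
first convolution expects; class labels are dense 0-based indices assigned
by lexicographic subject-id sort, so labeling is deterministic across
platforms and file orderings.

## The network

The architecture rests on the blind-source-separation view of EEG: the
observed channel vector at each instant is modeled as a linear mixture
$X = AS$ of latent cortical sources $S$. Classical ICA estimates a
separation matrix $W$ with $Y = WX \approx S$ by optimizing an
independence criterion *outside* any classifier. Here instead $W$ is the
first network layer — a bias-free linear map on the channel axis applied
at every time-point, mapping `C` observed channels to 64 latent source
traces — and is optimized by backpropagation jointly with everything
downstream. Identity-discriminative unmixing is thus learned directly.

The full stack for a `1 x P x C` input plane:

| stage   | output            | details                                        |
|---------|-------------------|------------------------------------------------|
| mix     | `1 x P x 64`      | linear `C -> 64` on the channel axis, no bias  |
| conv1   | `32 x P/2 x 64`   | 5x3 kernel, stride (2,1), padding (2,1), ELU   |
| pool1   | `32 x P/4 x 64`   | max 2x1, stride (2,1)                          |
| conv2   | `32 x P/4 x 64`   | 3x3 kernel, stride (1,1), padding (1,1), ELU   |
| pool2   | `32 x P/4 x 32`   | max 1x2, stride (1,2)                          |
| conv3   | `32 x P/4 x 32`   | 3x3 kernel, stride (1,1), padding (1,1), ELU   |
| pool3   | `32 x P/8 x 32`   | max 2x1, stride (2,1)                          |
| flatten | `32 * P/8 * 32`   |                                                |
| FC1     | 512               | linear                                         |
| dropout | 512               | p = 0.5, between the fully connected layers    |
| FC2     | `O`               | linear                                         |
| output  | `O`               | log-softmax                                    |

Notes on points the architecture table leaves open, and how they are
resolved here:

* The temporal axis is halved three times (conv1 stride plus pools 1 and
  3), so `P` must be divisible by 8; the source axis is halved once, so
  the source count must be even. Output sizing uses floor arithmetic and
  reproduces `P/2`, `P/4`, `P/8` exactly with the stated
  kernel/stride/padding — asserted in the test suite, not assumed.
* No activation follows the fully connected layers (the convolution
  blocks alone carry ELU), and the single dropout layer sits between FC1
  and FC2.
* The loss is the mean over the batch of the cross entropy
  $-\log p_{\text{true}}$ computed from the log-softmax scores. Mean
  rather than sum reduction is the convention under which the published
  learning rate is meaningful.
* Weights initialize from the uniform fan-in scheme
  $U(-1/\sqrt{\text{fan-in}}, 1/\sqrt{\text{fan-in}})$ under a recorded
  seed; identical seeds give identical weights, and training with the
  same seed and inputs is bit-reproducible on one platform
  (cross-platform bit-identity is not promised).

For `P = 80`, `C = 14`, `O = 109` the network has 5,319,213 parameters,
dominated by the 10240-to-512 fully connected layer.

Training uses Adam at learning rate $3 \times 10^{-3}$, batch size 64,
seeded shuffling each epoch, no early stopping and no schedule; the
final-epoch weights are the model. The reference protocol trains 2000
epochs; see "Problem sizes" below for the desk-scale settings.

The layers are implemented in the package itself — dense 2-D convolution
and max-pooling as im2col/GEMM compiled kernels, the rest as BLAS-backed
matrix algebra — and the analytic gradients are verified against central
finite differences in the test suite.

## Electrode montages

Experiments run at three channel counts: the full 64-electrode 10-10 cap,
and two consumer-headset layouts — the 14-electrode EPOC layout (all 14
present in the 64-channel cap) and a 32-electrode layout modeled on the
EPOC Flex saline kit. Four Flex positions absent from the 64-channel cap
are reselected to FT7, TP7, TP8 and FT8; since the published description
stops short of the full list, the remaining 28 labels are reconstructed
from the Flex layout mapped into the cap's label set (this reconstruction
is this package's own, and is shipped as a plain JSON asset). Channel
order within a montage is the montage's declared order, making the mixing
layer's input dimensions deterministic across files.

PhysioNet-style EDF labels (`"Fc5."`) are normalized by stripping
non-alphanumerics and upper-casing. Recordings whose header rate differs
from the expected 160 Hz are flagged and, by default, excluded by the
protocol runner (`on_rate_mismatch` switches to `keep` or `error`); the
public 109-subject dataset contains a few such subjects and the reference
description does not say how they were handled.

## Protocols

* **Hold-out:** per recording, the first 48 s train and the last 12 s
  test. Both sides are windowed separately.
* **k-fold cross-validation (k = 5):** each recording is divided into
  five contiguous 12 s spans; fold *i* tests on span *i* of every
  recording (every subject, every session in the chosen set) and trains
  on the rest. Folds are temporal blocks, *not* shuffled segments:
  shuffling 50%-overlapping windows across folds would place near-copies
  of test segments in the training set. Whether the original experiments
  used blocks or shuffled segments is unstated; blocks are the only
  leak-free reading.
* **Session sets:** EO only, EC only, or the union of both sessions
  pooled into one dataset per subject (session kept as metadata).

Fold metrics aggregate as mean ± sample (n−1) standard deviation.
`verify_split()` checks by interval arithmetic that no training interval
overlaps a test interval of the same recording; combined with
post-split windowing this guarantees no test sample index ever lies
inside a training window.

## Biometric evaluation

**Rank-1** is the percentage of test segments whose top-scoring class is
the true subject; argmax ties break toward the lowest class index
(a measure-zero event for float scores, fixed for determinism).

**Verification scores.** The published evaluation reports FRR/FAR/EER but
does not define genuine/impostor trials for a closed-set classifier, so
the package adopts the standard construction available from a softmax
classifier without retraining: every test segment claims every enrolled
identity in turn, and the match score of claim (segment, k) is the
posterior probability of class k. True-identity claims are genuine, the
other `O - 1` per segment are impostors.

**EER.** Every distinct observed score is swept as an acceptance
threshold $\theta$: FAR($\theta$) = % impostor scores ≥ $\theta$
(non-increasing), FRR($\theta$) = % genuine scores < $\theta$
(non-decreasing). The EER is read off at the crossing of the two
piecewise-linear curves, interpolating between the bracketing
thresholds — grid-free and deterministic. The swept (FAR, FRR) pairs form
the DET curve (`plot_det()`).

## The synthetic cohort

Real-data runs at published scale (109 subjects, 2000 epochs) need the
PhysioNet download and GPU-class compute, so the package ships a
generator that embodies exactly the generative assumption the
architecture is built on. Each synthetic subject owns:

* `n_sources` latent oscillators with subject-specific center frequencies
  drawn uniformly from 4–30 Hz (theta-to-beta, safely under the 80 Hz
  Nyquist limit at 160 Hz), amplitudes in 0.5–1.5, plus per-source
  broadband noise (scale 0.2);
* a subject-specific mixing matrix `A` with entries
  $N(0, 1)/\sqrt{n_\text{sources}}$.

Observed channels are $X = AS$ plus white sensor noise at `noise_sd`
times the clean-signal RMS (default 0.25), scaled to microvolt range.
Identity is deliberately encoded in *both* the spectra and the mixing, so
a linear channel-unmixing stage genuinely helps — the architectural
premise is exercised, not bypassed. Across a subject's two sessions the
identity carriers (frequencies, amplitudes, `A`) are held fixed while
phases and noise are redrawn. All randomness derives from a master seed
through per-(subject, session) sub-seeds, so fixtures are reproducible
regardless of generation order.

What the generator does **not** emulate: 1/f background spectra,
non-stationarity, eye blinks and muscle artifacts, volume-conduction
correlation structure, electrode drift, or session-to-session variability
beyond phase/noise. Passing the synthetic end-to-end check therefore
demonstrates that the pipeline is implemented correctly and can recover
identity under its own generative assumptions — it does not certify
real-data accuracy.

EDF export writes per-channel physical ranges spanning the observed
signal, so 16-bit quantization error is below `range / 65534` — in
practice orders of magnitude under 0.1% of signal RMS — giving round-trip
tests a known bound.

## Problem sizes and numerical choices

Desk-scale runs (tests and `scripts/acceptance.R`) use 8 subjects, 14
channels, 60 s at 160 Hz, the 0.5 s / 0.25 s window, the 48/12 s split,
and 15 training epochs — 1528 training and 376 test segments. On this
cohort the training loss reaches zero within about ten epochs and
held-out identification is essentially perfect; 15 epochs keeps a
comfortable margin while the run stays around six minutes on one CPU
core. Property tests that train repeatedly (e.g. noise-degradation
monotonicity) shrink the network (`conv_width`, `fc_width`,
`n_sources` are configurable) and the cohort further.

Other numerical conventions, fixed once: population standard deviation in
standardization; floor arithmetic in convolution sizing; argmax ties to
the lowest index; EER by linear interpolation at the curve crossing;
window starts at offset 0 with trailing remainder discarded; labels by
lexicographic subject sort; per-fold training seeds derived as
`seed + fold - 1`.

## Known limitations

* Closed-set only: unknown subjects are rejected with an error, not
  scored (no open-set protocol, no score normalization, no fusion).
* The verification construction shares one softmax across claims, so
  genuine and impostor scores of a segment are coupled (they sum to 1
  with the other claims); this is inherent to deriving verification from
  a closed-set classifier.
* EDF support covers the plain 16-bit format with homogeneous sampling
  rates; EDF+ annotations and event channels are out of scope.
* Training is single-threaded CPU; published-scale runs (109 subjects x
  2000 epochs) are supported in code but impractical without substantial
  compute.
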