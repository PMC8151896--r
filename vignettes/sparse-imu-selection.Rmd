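---
title: "Training-data and sensor-placement selection for sparse inertial motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-data and sensor-placement selection for sparse inertial motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Commercial inertial motion-capture suits ask the subject to wear 17 or
more IMUs. Because human movement is highly redundant, a small subset of
sensors — worn on well-chosen body segments — can drive a learned model
that reconstructs the posture of the remaining segments. Two questions
decide how well this works for a *specific* target activity:

1. **Which training data?** Motion corpora accumulate unevenly across
   activities. Training a reconstructor for, say, walking on the whole
   corpus wastes capacity on irrelevant movement and on near-duplicate
   gait cycles. Given a short reference recording from the target
   scenario, which continuous corpus segments form a compact,
   IID-like training set whose feature distribution matches the target?
2. **Which sensors?** Among the 21 candidate placements of a full-body
   skeleton, which `k` carry the most information about the placements
   they will have to predict, with the least mutual redundancy?

`mocapselect` implements both selection algorithms, the kinematic
preprocessing they assume, a controllable synthetic motion generator,
and a compact bidirectional LSTM reconstructor used to validate the
selections end to end at desk scale.

## Kinematic preprocessing

An IMU reports its world-frame orientation ${}^W_S R$ and acceleration
${}^W a_S$. A static calibration pose identifies the fixed sensor-to-bone
rotation ${}^S_B R = ({}^W_S R)^\top {}^W_B R$ (`calibrate_sensor()`).
All kinematics are then normalized to the root bone (pelvis):

$$ {}^{Root}_B R = ({}^W_{Root} R)^\top\, {}^W_B R, \qquad
   {}^{Root} a_B = ({}^W_{Root} R)^\top ({}^W a_B - {}^W a_{Root}), $$

so features are invariant to the subject's heading and to any global
rotation of the world frame (`normalize_frames()`, tested as an exact
invariance). Reconstruction quality is measured by the relative rotation
angle $\theta = \arccos\big((\operatorname{tr}(R_{pred}^\top
R_{true})-1)/2\big)$ in degrees, clamped before the arccosine.

Numerical details: rotations are stored as row-major $3\times3$ blocks
(n × 9 matrices for vectorized math); orthonormality is asserted at
`1e-9`; matrices loaded from files may be repaired by polar projection
(SVD) or rejected in strict mode; axis-angle extraction near $\pi$ uses
the largest-diagonal-element branch.

## Per-frame features

A frame's feature vector concatenates, for each bone of interest, the
root-normalized orientation in axis-angle form (3) and the normalized
acceleration (3): 6 features per bone. The same representation feeds the
similarity screening, the histograms and the MIC relevance estimates; by
default all 20 non-root bones contribute ($N_f = 120$).

## Training-data selection

The selection maximizes
$$ f(D) \;=\; \alpha H(D) \;-\; \beta\, d(D, D_{ref}) \;-\; \gamma \log N(D) $$
over unions of continuous corpus pieces, where $H$ is the mean
per-feature Shannon entropy of 20-bin histograms, $d$ the mean
per-feature KL divergence to the reference histograms, and $N$ the
selected frame count. Two stages keep this tractable:

* **Similarity screening.** Segments are cut into 50-frame units
  (0.5 s at 100 Hz). A unit survives if its best frame-wise cosine
  similarity against any reference unit reaches $\eta_0 = 0.8$;
  surviving contiguous units merge into runs, and runs shorter than
  $L = 300$ frames (one model sequence) are dropped. A zero-norm frame
  vector contributes a neutral 0 to the cosine mean.
* **Greedy pruning.** Starting from all surviving runs, the piece whose
  deletion most improves $f$ is removed, until no single deletion
  improves it or fewer than $L$ frames would remain. Ties break toward
  the lowest `(segment_id, start)`, making the pipeline deterministic.

Histogram bin edges are fixed from the pooled per-feature range of the
screened data and the reference so both distributions are binned
identically; every bin receives additive smoothing
$\varepsilon = 10^{-6}$ before normalization so the KL terms stay
finite. The entropy term is implemented with the standard positive sign
(so $\alpha H$ rewards information content), and the objective is the
plain linear combination above with $\alpha=\beta=\gamma=1$ by default.
The same deletion rule (best single deletion by the objective) is used
from the first iteration onward. The reference recording itself is
appended to the final training set by default (`include_reference`),
since it is target-scenario data.

`exhaustive_prune()` enumerates all piece subsets and is the package's
brute-force oracle: on 5-piece candidates the greedy matches the
enumerated optimum on 49–50 of 50 seeded fixtures and never exceeds it.

## Sensor placement

The relevance of two placements sums the maximal information coefficient
over their $s = 6$ features each,
$\mathrm{Rele}(x,y) = \sum_{i=1}^{s}\sum_{j=1}^{s} \mathrm{MIC}(x_i, y_j)$.
MIC itself is the maximum over grids with $a\,b < B = n^{0.6}$ cells of
the binned mutual information normalized by $\log_2 \min(a,b)$. The
estimator (C++): equipartition one axis into $a$ bins, optimize the other
axis' cut points by dynamic programming over a finer candidate
equipartition (5 candidates per requested bin, capped at 60), take the
best over both orientations, cap each axis at 15 bins. An exhaustive
small-n estimator (`estimator = "exhaustive_small"`) enumerates all
consecutive-group partitions and bounds the DP from above in tests.
Because MIC cost grows superlinearly in $n$, relevance matrices are
estimated on a deterministic stride subsample (10,000 frames by default;
the package's experiments use 300–500).

A sensor group is scored by $\Phi = T - R$ with
$$ T = \frac{1}{|S||C|}\sum_{x\in S}\sum_{c\in C}\mathrm{Rele}(x,c),
\qquad R = \frac{1}{|S|^2}\sum_{x_i\in S}\sum_{x_j\in S}\mathrm{Rele}(x_i,x_j). $$
The double sum in $R$ includes self-pairs; the relevance-matrix diagonal
is the constant $s \cdot \mathrm{MIC}(x;x) = s$, so the self-pairs
contribute a fixed $s/|S|$ offset that cannot change rankings at a given
group size. (Computing the diagonal by the raw double sum would make it
vary with the number of non-constant channels per bone, and a set-level
optimizer then games the self-term by preferring low-activity sensors —
an artifact, not information.)

The greedy search (`greedy_select()`) forces the root in (normalization
requires it), seeds with the placement of greatest total relevance to
the others, then repeatedly adds the candidate maximizing
$\Phi(S\cup\{x\},\, C\setminus\{x\})$, breaking ties by placement order.

**Known limitation.** Compared against `exhaustive_select()` (exact
maximization of $\Phi$ by enumeration) on randomized-coupling fixtures
over a 10-placement body, the greedy search consistently lands some
5–20% below the exhaustive optimum and exactly matches it essentially
never. The mechanism is structural: the $\Phi$-optimal set tends to
*leave highly connected hub bones unselected* — a hub is predictable
from its followers, and excluding it keeps selected-set redundancy
minimal — whereas no single-sensor-add path can discover that set-level
arrangement; replacing the relevance-based seeding with $\Phi$-based
seeding reaches the identical local optimum. The acceptance suite states
the stricter bound (within 5% on at least 18 of 20 fixtures) and the
corresponding assertion fails by design of the algorithm, not by
accident of implementation; the greedy's *first* pick, by contrast,
reliably identifies the hub (the property the recovery experiment
checks).

## The posture reconstructor

A single-layer bidirectional LSTM (64 units per direction by default)
maps, per frame, the selected bones' rotation matrices and accelerations
(12 numbers per selected bone) to the unselected bones' axis-angle
orientation and acceleration norm (4 per unselected bone), with dropout
probability 0.2 on the input layer and a linear readout from the
concatenated forward/backward states. The loss is the mean squared error
of the output vector, minimized by full-batch Adam; training is
deterministic given the seed. The forward/backward passes and
backpropagation through time are implemented directly in R matrix
algebra — ample for the desk-scale models the package trains.

Numerical choices worth knowing:

* **Target scaling.** Output channels are centered per channel but
  scaled per channel *group* — one global scale for all axis-angle
  channels, one for all acceleration norms. Per-channel scaling would
  weight a near-constant bone's radians an order of magnitude less than
  a moving bone's, starving static bones of gradient and misaligning
  the loss with the angular-error metric.
* **Windows.** Training windows never cross segment boundaries; the
  default stride equals the sequence length (non-overlapping). When the
  data are strongly periodic and the stride divides the period, every
  window of a continuous selection is locked to one movement phase; the
  package's experiments therefore use stride 70 against the 100-frame
  gait cycle so windows cover all phases.
* **Evaluation.** Segments are reconstructed in tiles of the model's
  sequence length (the last tile shifted back to fit), so the recurrent
  state only ever runs at the length it was trained on. The mean error
  is reported over the reconstructed bones by default; when models with
  *different sensor counts* are compared, `reduction = "all"` averages
  over the full skeleton (sensor-bearing bones contributing zero), since
  means over different unselected-bone sets are not comparable.
* The sequence length defaults to 300 frames (1.5 s of past and future
  context at 100 Hz each way); the experiments use 100-frame windows to
  keep training inside a desk-scale budget.
* Axis-angle targets are continuous because the generator keeps joint
  angles well inside $(-\pi, \pi)$; on real data with near-$\pi$
  orientations the representation has a discontinuity the model would
  see as a target jump.

## The synthetic generator

Every algorithm above is testable without any recorded data. An
`activity_spec()` gives each bone a scalar joint angle about its
skeleton axis: a sinusoid with a per-bone golden-ratio phase (periodic
activities) or a band-limited random walk (aperiodic), plus band-limited
noise. Angles drive a 21-bone kinematic tree with fixed segment offsets;
world orientations compose down the chain and accelerations come from
double-differencing joint positions at 100 Hz.

Two design points matter more than they look:

* **Noise is strictly band-limited** (random-phase sinusoids below
  2 Hz, unit variance, scaled by `noise_sd`). Double differencing
  amplifies spectral power as $\omega^4$, so any white or AR(1) noise
  component would dominate the accelerations with unphysical jitter;
  real postural tremor carries no power near the Nyquist frequency.
  Noise applies only to actively moving bones — unlisted bones hold the
  rest pose exactly.
* **Coupling copies the measured series.** A follower bone reproduces
  its driver's measured angle series (signal *and* driver noise),
  lagged by the phase offset and rescaled to its own amplitude, plus
  its own independent noise. A coupled pair is therefore one noise hop
  apart and two followers of a common driver two hops — the information
  gradient the placement experiments rely on. The alternative (both
  bones copying a clean latent wave) makes every pair equally noisy and
  erases the hub structure.

What the generator does **not** emulate: soft-tissue artifact, sensor
drift and magnetometer disturbance, ground contact and balance
constraints, inter-subject variation, and any correlation between
activity difficulty and noise. Passing tests on this generator show the
algorithms recover the statistical structure they were designed for;
they say nothing about robustness to those real-world effects.

The packaged `example_activity_specs()` (walk / arms / trunk) move
largely disjoint bone sets with distinct dynamics, giving cross-activity
frame cosines well below 0.5 while same-activity realizations stay above
0.9 — the regime the similarity threshold $\eta_0 = 0.8$ was chosen for.
The `hub_activity_spec()` places the hub and its five followers on leaf
bones of distinct chains, because a mover that is an ancestor of another
mover leaks its signal into the descendant's measurements through the
rotation composition and the fixture would no longer test what it claims.

## Experiment sizes

The standing experiments (`experiment_*`, also driven by
`scripts/acceptance.R`) run at sizes chosen to finish on a single CPU in
a few minutes while leaving the measured properties clear: 350–900-frame
segments, 50 pruning fixtures of 5 pieces, 20 sensor fixtures on a
10-placement body with MIC estimated on 300–500 frames, and
64-unit/40-epoch models on 100-frame windows. The defaults of the
user-facing functions are the full-scale values (10,000-frame MIC
subsample, 300-frame sequences).

## Reproducing the experiments

```{r}
library(mocapselect)
experiment_info_core(seed = 1)       # closed-form information anchors
experiment_prune_oracle(50, seed = 1)
experiment_sensor_oracle(20, seed = 1)
experiment_recovery(seed = 1)
experiment_end_to_end(seed = 1)      # several minutes
```

or, from a shell,

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
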