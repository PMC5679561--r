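---
title: "Inverse fitting of a two-mass vocal-fold model to high-speed trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse fitting of a two-mass vocal-fold model to high-speed trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

glottofit simulates and inversely fits the classical two-mass model (2MM)
of vocal-fold vibration. Each fold is a pair of vertically stacked masses —
a larger lower mass $m_1$ and a smaller upper mass $m_2$ — connected to the
larynx wall by springs $k_1, k_2$ with dampers $r_1, r_2$, and to each
other by a coupling spring $k_c$. With $\alpha \in \{l, r\}$ for the two
folds, the state $(x_{1\alpha}, v_{1\alpha}, x_{2\alpha}, v_{2\alpha})$
evolves under linear spring/damper dynamics plus two nonlinear terms:

* **Collision forces** $I_{i\alpha}$: when a glottal section closes
  ($a_i < 0$, see below) an additional spring $c_i = 3 k_i$ pushes the
  masses of that level apart. The term is expressed directly as an
  acceleration, $I_{i\alpha} = -\Theta(-a_i)\,(c_{i\alpha}/m_{i\alpha})\,
  a_i/(2l)$, zero at the moment of contact and growing linearly with
  overlap. (Whether the mass division is part of the collision term is a
  known ambiguity of the lumped-mass literature; this package fixes $I$ as
  an acceleration, so the collision stiffness scales with $c_i/m_i$.)
* **Bernoulli driving pressure** $F_1$ on the lower masses: $P_1 = P_s
  \left[1 - \Theta(a_{\min})\,(a_{\min}/a_1)^2\right]\Theta(a_1)$ with
  $a_{\min} = \min(a_1, a_2)$, acting on the exposed surface $l\,d_1$.
  A rectangular open glottis ($a_1 = a_2$) feels no net driving pressure;
  a closed upper section exposes the lower masses to the full subglottal
  pressure; a closed lower section shields everything. This asymmetry
  between opening and closing phases is what sustains self-oscillation.

The glottal areas are reconstructed from the displacements as
$a_i = a_{0i} + l\,(x_{il} + x_{ir})$; negative values encode collision
depth. $\Theta$ is the sharp unit step by default; a tanh-smoothed variant
(`smooth_eps`) exists for experimentation but is off by default because
smoothing shifts the phonation threshold.

Seen from above (the endoscopic view), the medial edge of each fold is the
more medial of its two mass edges, clamped at the midline:
$T_{M\alpha} = \max(0, \min(x_{01} + x_{1\alpha}, x_{02} + x_{2\alpha}))$.
This is the quantity comparable with trajectories extracted from high-speed
videoendoscopy (HSV), which cannot report a negative gap.

### Units and reference parameters

Internally everything is cgs-ms (g, cm, ms); the pressure unit
g cm$^{-1}$ ms$^{-2}$ equals $10^5$ Pa, so subglottal pressures given in
cmH$_2$O convert by $98.0665 / 10^5$ (8 cmH$_2$O $\approx$ 0.00785). In
this system the classical reference set (`standard_parameters()`) is usable
verbatim: $m_1 = 0.125$ g, $m_2 = 0.025$ g, $k_1 = 0.08$, $k_2 = 0.008$,
$k_c = 0.025$ g/ms$^2$, $r_1 = r_2 = 0.02$ g/ms, rest half-gaps
$x_{01} = x_{02} = 0.0179$ cm, rest areas $a_{0i} = 2 l x_{0i}$, lower-mass
thickness $d_1 = 0.25$ cm, fold length $l = 1.4$ cm.

### Q-scaling

The inverse problem varies three quantities: per-side scaling factors
$Q_l, Q_r$ and the subglottal pressure $P_s$. $Q$ scales all stiffnesses of
its side up and the masses down,

$$k_{i\alpha} = Q_\alpha k_{i0}, \quad c_{i\alpha} = Q_\alpha c_{i0},
\quad m_{i\alpha} = m_{i0} / Q_\alpha,$$

encoding the physiological observation that a tenser fold vibrates with
less effective mass. Since the small-oscillation frequency scales as
$\sqrt{k/m} \propto Q$, $Q$ is primarily a frequency knob, while $P_s$
mostly controls amplitude; left–right differences in $Q$ express laryngeal
asymmetry, summarized by the symmetry quotient
$Q_{lr} = \max(Q_l, Q_r) / \min(Q_l, Q_r) \ge 1$.

## Numerical integration

The eight coupled ODEs are integrated with a fixed-step classical
fourth-order Runge–Kutta scheme (compiled C++ inner loop), then decimated
to the 4000 Hz output rate of HSV. The default internal step is
**0.005 ms** (200 kHz). This choice deserves a note: with sharp unit steps
the right-hand side is continuous but has discontinuous derivatives at
every contact event, so the scheme's effective order drops at events and
convergence in the step size is event-dominated and *non-monotone* — we
measured a maximum post-transient deviation from fine-step references of
about $3\times10^{-4}$ cm at 0.01 ms, $7\times10^{-5}$ cm at 0.005 ms, and
*larger* errors again at 0.0025 and 0.001 ms before eventual convergence.
0.005 ms is the coarsest step whose error against a 10× finer reference
stays below $10^{-4}$ cm, which the acceptance suite re-verifies.

Each simulation runs 500 ms and discards the first 400 ms: the model is
compared only in steady-state oscillation, on a 100 ms window of 400
samples matching the experimental recordings. Initial conditions are a
small symmetric displacement (0.01 cm on all masses), which preserves the
exact left–right symmetry of the equations when $Q_l = Q_r$ — symmetric
parameter sets therefore produce bitwise-identical left and right series.

## Preprocessing experimental trajectories

HSV yields trajectories in pixels. The metric scale is estimated from the
glottal-axis length in pixels and an assumed vibrating fold length of
1.0 cm for women and 1.6 cm for men (average membranous lengths from the
morphometry literature). Rest geometry is tied to the recording by setting
$x_{01} = x_{02}$ to the time- and side-averaged edge distance and
$a_{0i} = 2 l x_{0i}$ (`estimate_rest_geometry()`); the sides are averaged
because the model formulation shares one rest gap per level between the
folds. For *synthetic* subjects the generating geometry is known and is
carried in the subject's metadata; `fit_subject()` uses it directly, so
that recovery studies fit within the same model family that generated the
data. Re-estimating the rest gap from the time-mean of an oscillating,
closure-clipped trajectory yields a systematically different geometry and
would make exact parameter recovery ill-posed — a caveat that applies to
real recordings too, where the rest-position rule is an interpretation,
not a measurement.

## Cost functions

Three costs compare an experimental pair $T_E$ with a model pair $T_M$:

* **`gamma1` (frequency domain).** Harmonics are selected on the
  experimental signal only: every DFT bin with magnitude at least 25% of
  the dominant one, plus each selected bin's immediate neighbors (to
  tolerate slight harmonic drift); the DC bin is excluded and signals are
  mean-centered (the mean is carried by the rest geometry instead). Per
  side, the cost is $s\,\lVert |e| - |s| \rVert_2 + \lVert \arg e - \arg s
  \rVert_2$ over the selected bins, phases wrapped to $(-\pi, \pi]$. The
  balancing factor $s$ defaults to $\pi\sqrt{L}/\lVert e \rVert_2$
  averaged over sides, so that a maximal phase error and a total magnitude
  error contribute comparably. Phase terms at numerically dead bins
  (magnitude below $10^{-9}$ of the dominant) are zeroed, since the angle
  of floating-point residue carries no information.
* **`gamma2` (time domain).** The per-side Euclidean distance
  $\lVert T_{El} - T_{Ml} \rVert_2 + \lVert T_{Er} - T_{Mr} \rVert_2$.
  Because a self-oscillating model has arbitrary steady-state phase, the
  model pair is first aligned by one common circular shift maximizing the
  summed cross-correlation.
* **`gamma3` (normalized frequency domain).** `gamma1` with each side's
  magnitude vector divided by its own dominant magnitude (so only relative
  harmonic structure is compared), plus a regularization term: the
  Euclidean distance, joint over sides, of the un-normalized dominant
  magnitudes. Whether "normalized to 1" means unit-maximum or unit-norm is
  genuinely open; this package reads it as dominant-coefficient
  normalization and isolates the choice in this one function.

The final arbiter across runs is the **normalized Euclidean selection
metric** (`gamma_final`),

$$\Gamma = \tfrac12\left[\frac{\sum_i (T_{El}[i]-T_{Ml}[i])^2}
{\sum_i T_{El}[i]^2} + \frac{\sum_i (T_{Er}[i]-T_{Mr}[i])^2}
{\sum_i T_{Er}[i]^2}\right],$$

computed after the same circular alignment. $\Gamma = 0$ is a perfect fit;
a model stuck at zero, or at twice the experimental amplitude, scores
exactly 1, which anchors the scale.

## The optimization pipeline

`fit_subject()` runs three derivative-free optimizers against the three
costs — nine runs — and selects the run whose simulated trajectories
minimize $\Gamma$:

* **Initial value search.** A coarse regular grid (default steps 0.5 in
  $Q$, 5 cmH$_2$O in $P_s$ over $Q \in [0.5, 6]$, $P_s \in [5, 50]$ —
  bounds that bracket all values we have seen fitted to healthy adult
  recordings, with margin) charts the box. On its own the grid is
  insufficient: the cost basins have half-width $\approx 0.05$ in $Q$,
  because matching the fundamental within the 10 Hz spectral resolution of
  a 100 ms window requires $Q$ within a few hundredths. Two supplementary
  searches land on that sheet cheaply: a fine sweep along the symmetric
  axis ($Q_l = Q_r$, step 0.05, crossed with a halved-step $P_s$ grid),
  which must cross the frequency-matching region because the fundamental
  is monotone in the common $Q$; and an *asymmetry fan* that splits the top
  symmetric candidates into $(Qs, Q/s)$ pairs for $s$ up to 1.2 — coupled
  oscillators lock to a frequency governed mainly by the geometric mean of
  the two factors, so these splits stay on the sheet while covering
  left–right asymmetric subjects.
* **Nelder–Mead** starts from the best sweep/fan candidate (the coarse
  grid's top points can rank well while sitting in spurious modes, so they
  seed only the swarm). Standard coefficients (reflection 1, expansion 2,
  contraction 0.5, shrink 0.5), box handling by projection plus quadratic
  penalty, and initial steps scaled per dimension to the valley geometry
  (0.005, 0.005, 0.02 of the bound ranges). The simplex is rebuilt around
  the incumbent with a halved step every 100 evaluations: in the narrow
  curved frequency-matching valley a single simplex collapses and stalls,
  and periodic restarts restore progress. Restart boundaries depend only on
  the evaluation count, never the budget, so enlarging the budget extends
  the same search sequence (a larger budget can never yield a worse
  incumbent).
* **Particle swarm**: 30 particles, inertia 0.72, cognitive = social
  = 1.49, velocities clamped to half the range, positions reflected at the
  bounds; the top five initial-search candidates are injected into the
  initial swarm.
* **Bee colony**: 30 food sources, abandonment limit 20, employed /
  onlooker / scout phases, random uniform initialization — deliberately
  *without* initial-search seeding, preserving an unbiased global
  component.

All stochastic optimizers are seeded and bitwise reproducible; per-run
sub-seeds derive deterministically from the subject seed. Objective
evaluations share a trajectory cache keyed on the parameter triple rounded
to $10^{-6}$, so the three costs and the searches re-use integrations; a
diverging simulation returns a large finite penalty ($10^6$) instead of
propagating, keeping the stochastic searches alive. The default budget is
2000 objective evaluations per run; the `"fast"` profile (300) is used for
batch validation and continuous testing.

## Success criteria

A fit is rated successful when all three hold:

1. **Frequency**: the fundamental of each model trajectory deviates at
   most 5% from the corresponding experimental one — enforced on *both*
   sides (the stricter reading; enforcing it on the average would mask a
   one-sided failure). Fundamentals come from the largest non-DC DFT bin
   refined by Quinn's first estimator on the complex coefficients; on
   un-windowed 400-sample transforms this keeps single-tone errors below
   0.2 Hz, where a plain magnitude parabola is biased by up to 2.6 Hz at
   half-bin offsets.
2. **Closure**: model and experiment agree on whether the glottis closes.
   A pair closes when, in at least half the cycles, the per-cycle minimum
   of the total gap falls to at most 5% of the median per-cycle peak gap
   (boundary inclusive). The threshold operationalizes "closure as seen in
   the recording": a residual gap below 5% of the oscillation peak is not
   distinguishable from contact in pixel-quantized imaging.
3. **Amplitude**: per side, the median model per-cycle peak lies within
   the min–max band of the experimental per-cycle peaks. The model's
   steady state has nearly constant peaks, so the median is the natural
   representative against the recording's own cycle-to-cycle variation.

Cycles are delimited by positive-going crossings of the mean level
(sub-sample interpolated; crossings closer than half the expected period
are merged), which is robust to amplitude modulation where peak-picking is
not.

## The synthetic-subject generator

Real HSV recordings exhibit cycle-to-cycle period and amplitude
perturbations (jitter, shimmer) that a time-invariant 2MM cannot produce,
plus measurement noise and pixel quantization. `generate_model_subject()`
emulates exactly these: it simulates the model at known ground truth, then
applies (in order) a cycle-wise time warp — each cycle's duration scaled by
$1 + \varepsilon_k$, $\varepsilon_k \sim N(0, \text{jitter})$, implemented
as piecewise-linear warping of the time axis with cubic-spline resampling
(linear interpolation would attenuate the peaks of a 300+ Hz oscillation
sampled at 4 kHz by several percent and bias the amplitude statistics) —
then per-cycle multiplicative shimmer, additive Gaussian noise scaled to
the median per-cycle peak, clamping at zero, and optional pixel
quantization (round-half-away-from-zero, applied after the noise as in a
real imaging chain). Jitter is implemented as time-warping rather than
frequency modulation because the downstream cycle segmentation is
boundary-based. With all perturbations zero the output equals the model
trajectories sample for sample.

What the generator does **not** emulate: irregular/aperiodic vibration,
amplitude drift within a recording, segmentation artifacts, vertical
dynamics, or any vocal-tract loading. Passing recovery tests on these
synthetic subjects therefore demonstrates that the pipeline inverts the
model family under realistic periodic perturbations — not that the 2MM
captures every feature of pathological phonation.

Ground-truth draws (`draw_subject_truth()`) sample $(Q_l, Q_r, P_s)$
jointly within one of four demographic groups (young/elderly × male/female)
from ranges observed in in-vivo optimization studies; drawing the
parameters independently over the pooled ranges can combine maximal
stiffness with minimal pressure, which sits below the phonation threshold
(the generator then correctly refuses with a no-oscillation error).

## Validation problem sizes

The test suite validates parameter recovery on 10 seeded synthetic
subjects (2% noise, 0.5% jitter) at the fast 300-evaluation profile,
asserting ≤10% median relative error on both $Q$ factors, ≤25% on $P_s$,
and all three success criteria in at least 8 of 10 subjects; a noiseless
subject must be recovered to $\Gamma \le 0.05$ with $Q$ within 5%. These
sizes keep the full suite within a routine continuous-integration run
while exercising every stage of the pipeline end to end.

Two identifiability caveats surfaced during validation and are worth
knowing. First, $Q$ and $P_s$ trade off along a narrow ridge on which the
fundamental frequency is constant; with jitter and noise the data
constrain $Q$ to a fraction of a percent but $P_s$ only to several
percent, and $\Gamma$ is nearly flat along the ridge. Second, because run
selection is by $\Gamma$ alone, two near-tied runs can differ in whether
the amplitude criterion passes; for strongly asymmetric subjects
($Q_{lr} \gtrsim 1.4$) the fast budget occasionally settles on a ridge
point a few percent off in amplitude.

## Limitations

* The model is time-invariant within a run: onset, offset, and pitch
  glides are out of scope, as are vertical (inferior–superior) dynamics
  and acoustic coupling to the vocal tract.
* The rest-geometry rule (mean edge distance) is an interpretation of
  standard practice, isolated in one function.
* Inferential statistics on fitted groups (normality tests, rank tests)
  are deliberately not reimplemented; the result JSON and the group
  summary CSV are structured for standard statistics tooling.
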