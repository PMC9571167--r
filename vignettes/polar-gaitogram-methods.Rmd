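---
title: "Polar gaitogram methods: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar gaitogram methods: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpolar)
```

## The problem

Insole pressure sensors give a cheap, wearable window on gait. Event-based
asymmetry indices built on heel-strike times (such as the phase coordination
index, PCI) degrade in people with gait disorders because shuffling and
flat-foot contact corrupt event detection, and the anterior–posterior centre
of pressure is particularly inconsistent in that population. `gaitpolar`
implements an alternative built on the **medial–lateral** centre of pressure
(COPx), which remains comparatively consistent: a continuous gait phase is
entrained to the COPx waveform, the cycle is replotted in polar coordinates,
and weight-bearing asymmetry is read off as an area imbalance between two
closed curves.

## Signal model

With five force sensors per insole at signed medial–lateral coordinates
$x_i$ (right foot positive, left negative) and per-sensor forces $F_i \ge
0$, the pooled centre of pressure is

$$\mathrm{COPx} = \frac{\sum_i F_i x_i}{\sum_i F_i}\cdot
\frac{100}{x_{\mathrm{5th\,meta}}}$$

in percent of the fifth-metatarsal (outermost) coordinate. Pooling both
feet makes the sign encode the stance side: positive during right-foot
stance, negative during left-foot stance, so one stride traces a signed,
sinusoid-like oscillation. Samples whose total force falls below a floor
(default 2% of the trial's 95th-percentile total force) carry the last
valid value forward; the floor handles swing/idle segments that the
formula's denominator cannot.

## Continuous phase: the adaptive frequency oscillator

A bank of five harmonics with phases $\varphi_i$, amplitudes $\alpha_i$,
offset $\alpha_0$ and shared fundamental frequency $\omega$ is integrated
by forward Euler at the sampling interval ($dt = 1/f_s = 0.01$ s,
mirroring a real-time microcontroller implementation):

$$\dot\varphi_i = i\,\omega + k_\varphi e \cos\varphi_i,\qquad
\dot\omega = k_\omega e \cos\varphi_1,\qquad
\dot\alpha_i = k_\alpha e \sin\varphi_i,\qquad
\dot\alpha_0 = k_0 e,$$

with $\hat u = \alpha_0 + \sum_i \alpha_i\sin\varphi_i$ and $e = u - \hat
u$. When $e \equiv 0$ the adaptation laws vanish identically — this exact
fixed point is asserted in the tests. The wrapped fundamental phase
$\varphi_1 \in [0, 2\pi)$ is the continuous gait phase.

Numerical choices worth knowing:

* **Gain profiles.** `"healthy"` (0.8, 1.2, 0.6, 1.0) adapts quickly;
  `"stroke"` (0.2, 0.2, 0.4, 0.8) trades speed for robustness on less
  consistent input. Gains depend on the insole hardware and should be tuned
  per setup; both profiles are overridable.
* **Input standardisation.** The gains are calibrated for unit-amplitude
  input, while COPx is a percentage of order 100. `estimate_phase()`
  divides the input by its robust amplitude (95th percentile of |u|) and
  scales the reconstruction back, leaving the phase untouched. Without
  this, the frequency adaptation overshoots its basin.
* **Frequency floor.** $\omega$ is clipped at 0.1 rad/s because the raw
  update can transiently drive it negative.
* **Initial state.** $\alpha_i = \alpha_0 = \varphi_i = 0$, $\omega = 2\pi
  \cdot 0.9$ rad/s (a typical comfortable cadence). Entrainment takes a few
  strides at healthy gains; downstream analyses therefore drop two warm-up
  cycles by default (`warmup_cycles`).
* **Cycle spans.** A cycle ends at each downward wrap of $\varphi_1$; the
  span is the last pre-wrap value, so spans undershoot $2\pi$ by about half
  a phase step ($\approx \omega\,dt/2$) plus adaptation jitter. The
  per-cycle span statistics report this deficit explicitly.

## The polar gaitogram and its indices

Each sample maps to $(\theta, r) = (\varphi_1, |\mathrm{COPx}|)$; right
stance forms the upper closed curve, left stance the lower. Per cycle and
side, the closed-curve area is the standard polar integral $\int \tfrac12
r^2\, d\theta$ by the trapezoid rule. The published area formula carries an
extra $\theta$ inside the integrand; we treat it as a typesetting slip —
only the standard area makes the ratio interpretation ("share of
weight-bearing time") coherent — but the literal integrand is available via
`closed_area(..., literal = TRUE)`. Similarly, the published left-ratio
denominator repeats the right area; we use $A_R + A_L$, the only reading
under which the two ratios sum to 100%.

Per-cycle areas are averaged across cycles before forming

$$\mathrm{Arearatio}_{R} = \frac{A_R}{A_R + A_L} \times 100,\qquad
\mathrm{ARI} = |\mathrm{Arearatio}_R - \mathrm{Arearatio}_L|,$$

because how many strides a subject contributes should not reweight the
index (the aggregation across strides is not pinned down in the source
description; per-cycle averaging is our choice and is stated in the
report). With an ARI threshold of 10%, the per-foot decision band is $50\%
\pm 10/2 = [45\%, 55\%]$: a subject whose larger share exceeds 55% is
classified as having a gait disorder, the foot above 55% as the unaffected
(longer weight-bearing) foot and the foot below 45% as the affected one.

**Tangent angle.** The segment joining the two weight-transfer points
(COPx sign changes, located by linear interpolation of the $(\theta, r)$
pair between the bracketing samples — interpolating $r$ across the sign
change takes the chord over the V-shaped dip rather than collapsing to
zero) is tangent to both curves. The published slope formula mixes polar
coordinates ($|\mathrm{atan2}(\theta_R - \theta_L,\, r_R - r_L)|$), which
is dimensionally odd; whether it abbreviates a Cartesian slope cannot be
resolved from the text. Both are computed: `"as-printed"` evaluates the
formula literally, `"cartesian"` converts the points to the plane and takes
the segment's angle with the horizontal folded to $[0, \pi/2]$ (the
geometric reading consistent with the published figures and the
0.15–0.16 rad cutoff band; we use the midpoint 0.155 rad as the default
cutoff). Reports always name the convention and carry both values.

## Reference indices

* **PPD** uses whole-trial per-foot force sums: $2|GRF_R -
  GRF_L|/(GRF_R+GRF_L)\times 100$. Whole-trial aggregation (rather than
  per-cycle) keeps the index scale-invariant and stride-count robust.
* **Heel strikes** are detected on the heel channel at upward crossings of
  10% of the channel's robust maximum, debounced over 3 samples, with a
  0.3 s refractory window. The source defines no detector; this is
  deliberately simple and its constant latency cancels in interval-based
  indices.
* **PCI** pairs each right–left–right strike triplet into a stepping phase
  $\phi_i = 2\pi (t_{Li}-t_{Ri})/(t_{R(i+1)}-t_{Ri})$ ($\pi$ when ideally
  symmetric) and sums the percentage mean absolute deviation from $\pi$
  with the coefficient of variation. The published dispersion formula omits
  a square root, which would leave the first summand in squared radians
  while the total is a percentage; we implement the standard CV
  ($\sqrt{\mathrm{msd}}/\bar\phi \times 100$) and keep the literal no-root
  variant behind `literal_cv = TRUE`. The per-stride mean of
  $|\phi_i-\pi|$ is used (mean-of-deviations, not deviation-of-mean).

## Group statistics

Group rows are summarised with means and sample ($n-1$) SDs; display
rounding is half-away-from-zero with 1 decimal for area ratios/ARI and 2
for the rest, matching the reference tables. Group comparisons use an
exact two-sided Mann–Whitney U test: for tie-free samples the null
distribution over all $\binom{n_1+n_2}{n_1}$ labelings gives $p =
\min\{1, 2\min(P(U\le u), P(U\ge u))\}$; ties fall back to the midrank
normal approximation with tie correction. On the packaged reference table
this reproduces $p = 2/495 \approx 0.004$ for ARI and $4/495 \approx
0.008$ for PCI. The reference PPD column contains ties, so its published
exact p-value cannot be reconstructed and is not used as a check.

## The synthetic-gait generator

No raw recordings ship with the package, so every signal-level claim is
exercised on synthetic trials with known ground truth. The generator
emulates level walking:

* Per stance, total vertical force follows an M-shaped profile (loading and
  push-off peaks, mid-stance valley) whose value is 1 at the window edges;
  weight hand-overs between feet are congruent raised-cosine cross-fades
  over the double-support window (default 10% of the stride per transfer).
  This construction makes the time the pooled COPx spends positive per
  stride equal the right-foot stance share $\mathrm{duty}_R/(\mathrm{duty}_R
  + \mathrm{duty}_L)$, which is what lets the tests assert
  $\mathrm{Arearatio}_R \approx 100\,\rho/(1+\rho)$ for duty ratio $\rho$.
* Each foot's force is distributed over the five sensors by a
  piecewise-linear heel → cuboid/5th-metatarsal → 1st-metatarsal → toe
  progression whose windows are mirror-symmetric about mid-stance, and the
  default synthetic layout (20, 36, 48, 36, 20 mm) gives a time-symmetric
  lateral sweep — together these make the pooled COPx of a symmetric
  stride sinusoid-like and place the weight-transfer points at phase
  $\approx 0$ and $\pi$. Roll-over progress runs from weight acceptance,
  not first contact: a foot that steps early holds a light heel tap (8%
  peak, settling to 1.5%) until the hand-over, with an onset ramp congruent
  to a normal contact so detection latency is identical for both feet.
* `left_offset_frac` places the left heel strike as a stride fraction $q$
  (0.5 = symmetric stepping), driving $P_{\phi ABS} = 100\,|2q-1|$;
  `shuffle_prob` adds low-force heel taps before true left contacts — the
  artefact that corrupts event-based indices in practice.
* Defaults describe comfortable healthy adult gait: 1.1 s stride, equal
  duty, 1% force noise. The stroke-like template lengthens the stride to
  1.4 s, shifts stance time (duty ratio 1.4) and load (amplitude ratio
  1.3) to the unaffected right foot, delays the left step to $q = 0.58$,
  doubles the noise and adds shuffling (probability 0.15 per stride).
  Cohorts jitter these per subject (log-normal, 2–4%) from a single seed.

What the generator does **not** emulate: anterior–posterior COP dynamics,
sensor saturation and hysteresis of real force-sensing resistors,
inter-stride drift, turning or gait initiation/termination. Passing the
synthetic recovery tests therefore demonstrates the correctness of the
pipeline's computations under the stated gait model, not clinical validity
on real recordings. One consequence of compounding duty and load asymmetry
in the stroke template is that its PPD (≈ 50%) is larger than typical
clinical values (≈ 10–35%); ARI, which is amplitude-invariant during
single support, stays in a realistic range.

## Problem sizes and determinism

Property-style tests use 25–30-stride trials at 100 Hz, 10 seeds per
condition; sinusoid frequency-recovery runs 160 s per seed, which covers
the slowest entrainment at the edges of the 0.5–1.5 Hz band with the
default initial frequency. All randomness flows from named seeds, and the
end-to-end report is byte-stable across repeated runs on the same input.

## Known limitations

* The tangent-angle convention ambiguity is unresolved by design: both
  values are always reported, and thresholding applies to the Cartesian
  reading.
* Sensor coordinates must be supplied (or the synthetic defaults used);
  the package does not derive them from wearer height.
* The oscillator assumes quasi-periodic input; trials much shorter than
  ~6 strides leave too few cycles after warm-up for stable indices.
* Classification thresholds (ARI 10%, PPD 10%, tangent 0.155 rad) come
  from a 12-subject reference cohort and should be re-derived for other
  hardware or populations.
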