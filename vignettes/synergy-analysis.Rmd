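---
title: "Muscle synergy analysis of perturbed walking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis of perturbed walking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

## The model

Locomotor muscle activity is modeled as the output of a small number of
*muscle synergies*: modules that combine a fixed, non-negative muscle-weight
vector with a time-varying, non-negative activation pattern. For a gait
cycle recorded from $m = 13$ muscles and normalized in time to $n = 200$
points, the envelope matrix $V \in \mathbb{R}_{\ge 0}^{m \times n}$ is
approximated by

$$ V \approx V_R = M P, $$

where $M$ ($m \times p$) holds the time-invariant muscle weights and $P$
($p \times n$) the activation patterns; $p$ is the smallest number of
synergies that satisfactorily reconstructs the recorded signals. During
steady walking four fundamental synergies are expected, each with a single
main activation peak tied to a gait phase: weight acceptance (knee extensors
and glutei), propulsion (plantar flexors), early swing (foot dorsiflexors)
and late swing (knee flexors).

The scientific question the pipeline serves is how these synergies are
modulated when walking is perturbed: whether the same four modules persist
in the perturbed and recovery cycles, and how their *timing* (center of
activity, CoA), *duration* (full width at half maximum, FWHM) and
*similarity* to unperturbed walking (cosine similarity, CS) change.

## Pipeline stages and the choices behind them

### EMG conditioning

Raw EMG (nominally 2 kHz, already band-passed 10–500 Hz by the acquisition
device, which we do not re-apply) is high-pass filtered at 50 Hz with a
4th-order IIR Butterworth applied forward–backward (zero phase), full-wave
rectified, and low-pass filtered at 20 Hz with the same design. We read
"4th-order zero-phase" as *design order 4 per pass*, giving an effective
8th-order magnitude response after the two passes; the alternative
(designing order 2 so the cascade is effectively 4th order) is a plausible
reading but the literal one is adopted and fixed here. Forward–backward
filtering with zero initial conditions produces step-response transients at
the trace edges for signals with non-zero mean, so each channel's mean is
removed before the high-pass (which eliminates DC regardless) and the
envelope's small negative undershoots are clipped at zero.

Amplitudes are normalized per muscle *and per trial*: the minimum over the
trial's 12 consecutive cycles is subtracted and the result divided by the
trial-wide maximum. A cycle whose local maximum is below the trial maximum
therefore keeps a normalized maximum below 1 — this is intentional, since
cross-cycle amplitude changes are part of the perturbation response.

### Gait events from foot acceleration

The foot-mounted accelerometer (nominally 143 Hz) is low-pass filtered at
15 Hz (4th-order zero-phase Butterworth). Touchdown: the minimal vertical
acceleration is found for each cycle, an interval of −150 to +100 ms is
built around it, and touchdown is the maximum of the vertical acceleration
inside that interval. Candidate cycles are discovered by peak-picking
vertical minima at least 0.6 s apart (configurable) and at most a quarter of
the trace's range above its global minimum; the detection method presumes
cycles exist but states no discovery rule, so this is our own, and a flat
trace yields an empty result with a warning rather than an error.
"Characteristic maximum" is read as the in-window global maximum.

Lift-off: for each touchdown pair, the minimum of the anteroposterior
acceleration inside [td + 300 ms, td_next − 200 ms], plus a +3 ms constant
correction (the detector's validated mean offset against force plates). The
correction is a configuration value with default 0.003 s so the uncorrected
detector remains testable. Cycles too short to hold the window are skipped
with a warning, never silently reordered.

Temporal parameters per cycle: $t_{st} = lo - td$, $t_{sw} = td_{next} - lo$,
duty factor $t_{st}/(t_{st}+t_{sw})$, and cadence $2 \cdot 60/(t_{st}+t_{sw})$
steps min⁻¹. The cadence formula counts two steps per gait cycle, the
convention behind "steps per minute"; it is a documented decision of this
package. Variability is summarized by the coefficient of variation, sd/mean.

### Time normalization

Each cycle is resampled to 200 points with stance and swing each receiving
100 points, by piecewise-linear interpolation (the simplest method
consistent with the procedure, which names none). The grid is half-open:
point 1 is the touchdown sample and the next touchdown is excluded, so
consecutive cycles never share a boundary sample. The stance grid is
interpolated from samples in $[td, lo]$ and the swing grid from
$[lo, td_{next}]$; the boundary sample is shared by both phases, which is
the only way to keep each 100-point half self-contained while remaining
continuous at the phase boundary.

### Synergy extraction

Gaussian NMF: multiplicative updates minimizing the squared Frobenius error,
with factors initialized uniformly on (0, 1] under an explicit seed (the
standard choice for this algorithm; nothing in the procedure constrains it).
Updates are run pattern-first, then weights; the reconstruction error is
recorded every iteration and is non-increasing by construction. Convergence:
the relative improvement of $R^2 = 1 - SSE/SST$ (SST around the grand mean
of $V$) over the previous 20 iterations falls below 0.01%, with a hard cap
of 1000 iterations.

Robustness to initialization comes from repeating the factorization 20
times per cycle and averaging. Because NMF is defined only up to a
permutation of its components, "averaging" requires alignment first: each
repetition's synergies are matched to the first repetition's by optimal
one-to-one assignment on the cosine similarity of the muscle-weight columns
(exhaustive over permutations for $p \le 8$, greedy beyond). The aligned
factors are averaged and renormalized. The alternative reading — keeping the
best single run — is not what "averaged" says, so matching-then-averaging is
used.

Output convention: each pattern row is scaled to a maximum of 1 with the
inverse scale folded into the matching weight column, so $MP$ is unchanged;
for figure-style reporting the weights can additionally be max-normalized.

### Rank selection

For each candidate rank $1..10$ the best $R^2$ over repeated seeded runs is
computed (5 repetitions per rank by default — the 20-repetition rule belongs
to the per-cycle extraction; the repetition count of the rank sweep is a
runtime choice of this package). The selected rank is the smallest $r$ such
that an ordinary least-squares line fitted to the $R^2$ curve on ranks
$r..10$ leaves a mean squared residual below $10^{-4}$. This mirrors the
curve-flattening logic used for cluster counting (below), with a tighter
threshold appropriate to the $R^2$ scale; the threshold is exposed in the
configuration. Segments of fewer than three points are treated as exactly
linear, so the criterion always selects some rank.

### Classification

Activation patterns pooled across cycles (and participants, when available)
are max-normalized and clustered with k-means (squared Euclidean distance,
10 seeded restarts per candidate count). The cluster count is chosen from
the within-cluster-sum-of-squares curve over $k = 1..13$ (one candidate per
recorded muscle): the WSS curve is normalized by the total sum of squares —
the flatness threshold of $10^{-3}$ presumes a normalization, and dividing
by TSS makes it scale-free — and the chosen $k$ is the smallest from which
the remaining curve fits a least-squares line with MSE below $10^{-3}$.

Clusters are labeled by the circular timing of their centroids: the
assignment of the four fundamental labels to (up to four of) the centroids
minimizing total circular distance to the conventional phase centers (10%,
40%, 60%, 90% of the cycle — conventions of this package consistent with the
stance/swing placement of the four synergies, not measured values). A
"fundamental" synergy must have a single main activation peak; the rule is:
after 5-point circular moving-average smoothing, local maxima at or above
50% of the global maximum and at least 20 of 200 points apart (higher peak
wins at closer range) count as main peaks, and exactly one must remain.
Synergies failing this rule, or resembling their assigned centroid with
cosine similarity below 0.75, are labeled non-classifiable and excluded from
metric aggregation — their fraction is always reported, never silently
dropped. The 50%/20-point/0.75 constants operationalize a verbal definition
and are exposed in the configuration.

### Spatiotemporal metrics

* **CS**: $\cos(A, B) = A \cdot B / (\lVert A \rVert \lVert B \rVert)$ of
  muscle weights (length 13) and activation patterns (length 200) of each
  cycle against the matched synergy of the *reference* cycle — the first of
  the series, i.e. the cycle most remote from the perturbation.
* **FWHM**: after subtracting the pattern minimum, the count of points
  exceeding half of the min-subtracted maximum. The points need not be
  contiguous (the definition sums *all* points above the half-maximum), so
  this is a duration measure, not an interval width.
* **CoA**: the angle of the polar vector to the center of mass of the
  pattern on the circle, $\theta_i = 2\pi i/200$ with $\theta = 0$ at
  touchdown (the origin convention is ours; only the range $[0, 2\pi)$ is
  prescribed). Patterns with vanishing resultant (e.g. uniform) give an
  undefined sentinel (`NA`) with a warning.

Cross-cycle matching uses classification labels when available and
otherwise optimal cosine-similarity assignment of activation patterns
against the reference cycle.

### Statistics

The package stops at descriptive statistics: Cohen's *d* on the pooled
(n−1) standard deviation with the conventional magnitude cutoffs
(0.2/0.5/0.8), and Benjamini–Hochberg step-up adjustment for families of
post-hoc contrasts (delegated to `stats::p.adjust`). Mixed-effects modeling
and statistical parametric mapping are deliberately out of scope — they are
off-the-shelf analyses best run on the tidy tables this package exports
(`nlme::lme` and SPM tooling consume them directly).

## The synthetic-data generator

No recordings are distributed with this package, so every stage is
validated against a seeded generator with known ground truth. It emulates:

* 13 muscles × 200-point cycles, with four von Mises-type prototype
  patterns $\exp(\kappa(\cos(\theta - \mu) - 1))$ — circular, unimodal,
  max 1 — at phase centers 0.10/0.40/0.60/0.90 and concentration
  $\kappa = 6$ (FWHM ≈ 30 of 200 points, in the range typical of basic
  activation patterns). A circular kernel is required because CoA lives on
  the circle and the late-swing synergy straddles the cycle boundary.
* Muscle weights near 1 for each synergy's dominant muscles and small
  positive weights (0.02–0.10) elsewhere, scaled once so the noiseless
  baseline reconstruction has maximum exactly 1.
* 12-cycle trials — three unperturbed, the perturbed cycle, eight recovery —
  with the planted perturbation (CoA shift −0.3 rad, widening ×1.5 by
  default) decaying geometrically (ratio 0.5) over four recovery cycles,
  matching the observation that perturbation effects persist for up to four
  recovery steps.
* Additive Gaussian amplitude noise truncated at zero (default sd 0.05 of
  the maximum amplitude) so matrices stay non-negative as NMF requires.
* Raw signals: per-muscle EMG as band-limited (50 Hz–0.45·fs) unit-variance
  noise carriers amplitude-modulated by the planted envelopes at 2 kHz;
  foot acceleration at 143 Hz with a smooth impact transient at each true
  touchdown, a pronounced minimum 55 ms before it (the swing-end dip the
  touchdown detector anchors on), and an anteroposterior minimum at each
  true lift-off. Default stance/swing durations are 0.65 s/0.40 s, a
  typical older-adult cycle at 1.1 m s⁻¹.

What it does **not** emulate: biomechanical perturbation physics, real EMG
amplitude statistics or noise spectra (no SNR is documented for the
reference recordings, so noise levels are free parameters), inter-muscle
crosstalk, electrode artifacts, or inter-participant variability. Passing
tests therefore demonstrate that the *pipeline recovers what was planted
under its own model assumptions* — correctness of the algorithms, not
real-data effect sizes. Real-data quantities (reconstruction $R^2$ around
0.89, the non-classifiable fraction, table-level contrasts) depend on
recordings that are not distributed and are explicitly not reproduced.

## Problem sizes and numerical choices

Validation runs use desk-scale sizes chosen to exercise every code path:
12–30 cycles per trial, 5–20 NMF repetitions, 10 random seeds for
recovery studies. Degenerate inputs are handled explicitly rather than
silently: constant channels (amplitude normalization), constant matrices
(SST = 0), zero vectors (CS), uniform patterns (CoA), flat traces (event
detection) and too-short cycles (lift-off window) each produce a documented
error, warning or sentinel. Multiplicative updates guard denominators with
1e−12; error monotonicity is asserted to 1e−10 in tests.

## A worked example

```{r example, eval = FALSE}
library(synergait)

res <- run_pipeline(pipeline_config(seed = 5, nmf_repetitions = 10),
                    out_dir = "synergy_out")
res$rank                      # number of synergies selected on the reference cycle
aggregate(cs_patterns ~ cycle, res$metrics, mean)   # similarity dip at cycle 4
res$classification$fraction_non_classifiable
```

The similarity of the activation patterns to the reference cycle drops
sharply at the perturbed cycle and recovers over the following cycles, the
FWHM widens at the perturbed cycle, and the CoA shifts earlier — the
planted spatiotemporal perturbation response, recovered end-to-end from raw
synthetic signals.

## Known limitations

* The flatness thresholds (10⁻⁴ for rank, 10⁻³ for clusters) act on
  normalized curves; data normalized differently would need re-tuning.
* The touchdown detector's cycle-discovery heuristic assumes pronounced
  vertical minima once per cycle; heavily smoothed or low-impact gait
  (e.g. soft footwear on compliant belts) may need a different prominence
  rule.
* Component matching is exhaustive only to rank 8; the greedy fallback can
  be suboptimal for larger ranks, which do not occur in this application.
* With a single synthetic trial the descriptive contrasts have very few
  degrees of freedom; they are exported for completeness, with the
  mixed-model analysis intentionally left to dedicated tools.
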