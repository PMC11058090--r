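# synergait

Muscle synergy analysis of perturbed walking, for researchers in neuromotor
control and biomechanical signal processing who record multi-channel surface
EMG and foot-mounted accelerometry on a treadmill and want a tested,
reproducible pipeline from raw signals to spatiotemporal synergy metrics.

## What it computes

Locomotor muscle activity is modeled as a non-negative combination of a few
**muscle synergies**. For each gait cycle, the 13-muscle envelope matrix
*V* (13 × 200, time-normalized with 100 stance + 100 swing points) is
factorized with Gaussian non-negative matrix factorization:

&nbsp;&nbsp;&nbsp;&nbsp;*V* ≈ *V*<sub>R</sub> = *M P*

where *M* (13 × *p*) holds the time-invariant muscle weights, *P*
(*p* × 200) the time-dependent activation patterns, and the rank *p* is the
minimum number of synergies that satisfactorily reconstructs the signals
(chosen by a flatness criterion on the *R*² versus rank curve). Extracted
synergies are classified into the four fundamental walking synergies —
weight acceptance, propulsion, early swing, late swing — by k-means
clustering with a within-cluster-sum-of-squares elbow criterion, and
characterized per cycle by:

* **CS** — cosine similarity of weights and patterns against a reference
  (unperturbed) cycle,
* **FWHM** — number of points exceeding the half-maximum of the
  (min-subtracted) activation pattern,
* **CoA** — center of activity, the circular first-moment angle of the
  pattern over the cycle, θ ∈ [0, 2π).

Upstream stages implement the standard conditioning chain: 50 Hz zero-phase
Butterworth high-pass, full-wave rectification, 20 Hz low-pass, per-trial
amplitude normalization; gait events come from foot acceleration (touchdown
from a −150/+100 ms window around each cycle's vertical minimum, lift-off
from the anteroposterior minimum in [td+300 ms, td<sub>next</sub>−200 ms]
plus a +3 ms correction), yielding stance/swing times, cadence and duty
factor.

Because no recordings are distributed, the package ships a seeded
synthetic-data generator that plants known synergies, gait events and
perturbation responses (a −0.3 rad timing shift and ×1.5 widening at the
perturbed cycle, decaying over four recovery cycles), giving every stage a
ground truth to be validated against.

## Worked example

```r
library(synergait)

res <- run_pipeline(pipeline_config(seed = 5, nmf_repetitions = 10),
                    out_dir = "synergy_out")
res$rank
#> [1] 4
round(aggregate(cbind(cs_patterns, fwhm_points) ~ cycle, res$metrics, mean), 3)
#>    cycle cs_patterns fwhm_points
#> 1      1       1.000       30.50
#> 2      2       0.984       29.75
#> 3      3       0.982       30.25
#> 4      4       0.893       43.00
#> 5      5       0.952       36.00
#> 6      6       0.978       33.25
#> ...
res$classification$fraction_non_classifiable
#> [1] 0.02083333
```

The pipeline simulated a 12-cycle trial (3 unperturbed cycles, a
perturbation at cycle 4, 8 recovery cycles), conditioned the raw EMG,
detected gait events from the synthetic accelerometer, selected **4**
synergies on the reference cycle, and recovered the planted perturbation
response: the pattern cosine similarity dips to 0.893 at the perturbed
cycle and recovers over the following cycles, while the FWHM widens from
~30 to 43 points. All artifacts (events, temporal parameters, per-cycle
synergy sets, classification labels, metrics, descriptive contrasts) are
written as tidy delimited text under `synergy_out/`.

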