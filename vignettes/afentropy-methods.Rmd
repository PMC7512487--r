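---
title: "Methods: ranged-distance fuzzy entropy for AF detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranged-distance fuzzy entropy for AF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afentropy)
```

## The detection problem

Atrial fibrillation (AF) disorganizes atrial activation, and the ventricles
respond at short, highly irregular, serially near-uncorrelated intervals.
In the RR-interval series — the sequence of times between consecutive
heartbeats — AF therefore looks like fast, noisy data, while normal sinus
rhythm (NSR) looks like slow, smooth data with a gentle respiratory
oscillation. Entropy statistics quantify exactly this kind of
irregularity, and because they work on windows as short as 12–30 beats they
suit wearable ECG monitors, where rhythm must be decided on short, possibly
noisy strips.

This package implements such a detector, `entropy_af()`, together with the
three entropy measures it is usually compared against — sample entropy
(`sampen()`), fuzzy measure entropy (`fuzzymen()`) and the coefficient of
sample entropy (`cosen()`) — plus the preprocessing, evaluation and
synthetic-data machinery needed to use and validate them end to end.

## The detector

For an RR segment $x(1), \dots, x(N)$, form the $N - m$ templates
$X_i^m = (x(i), \dots, x(i+m-1))$. Two templates are compared with the
**ranged distance**

$$d(X_i, X_j) \;=\;
\frac{\max_k |x(i+k) - x(j+k)| \;-\; \min_k |x(i+k) - x(j+k)|}
     {\max_k |x(i+k) - x(j+k)| \;+\; \min_k |x(i+k) - x(j+k)| \;+\;
      \varepsilon},$$

which is bounded in $[0, 1)$ and — unlike the Chebyshev distance used by
the comparator measures — is invariant to a common gain applied to the
signal and to a common offset. The distance is graded by the fuzzy kernel
$\exp(-d^{\,n}/r)$ rather than a hard 0/1 threshold, which stabilizes the
statistic against small changes in the tolerance $r$.

Let $B$ and $A$ be the mean similarity degrees over all template pairs
(including $i = j$) at dimensions $m$ and $m+1$; both levels deliberately
use the same $N - m$ templates so the averaging counts match. The output is
the density-based (rather than probability-based) estimate, adjusted for
heart rate:

$$\mathrm{value} \;=\; -\ln\frac{A}{B} \;+\; \ln(2r) \;-\; w\,
\ln(\overline{RR}).$$

The $\ln(2r)$ term converts the conditional-probability form into a density
by dividing each similarity mass by the matching-region volume $(2r)^m$;
the two forms are algebraically identical up to that term, and the test
suite asserts the identity to machine precision. The heart-rate term
exploits the clinical fact that AF usually runs fast: a short
$\overline{RR}$ (in seconds) pushes the value up.

### The flexible tolerance

Rather than fixing $r$, the detector walks the grid
$r = 0.05, 0.10, 0.15, \dots$ and keeps the smallest value at which the
average match mass per template at dimension $m+1$ (the sum of fuzzy
similarity degrees, self-pair included) reaches a quota. This is the
minimum-numerator idea behind COSEn's flexible threshold: the numerator of
the entropy estimate must rest on enough matches to be statistically
stable. Whether the quota should count graded similarity mass or hard
thresholded matches is a genuinely open choice; we count similarity mass,
consistent with the measure's own kernel, and use hard counts only for the
Chebyshev/Heaviside search inside `cosen()`. If the quota is never met the
search stops at the top of the grid (1 for the ranged distance, the maximum
pairwise distance for Chebyshev) and the result carries a
`r_quota_unmet` flag instead of failing.

## Parameters, defaults and what they mean

| symbol | default | unit | role |
|---|---|---|---|
| `m` | 1 | beats | template length; 1 suits 12–30-beat windows (COSEn convention) |
| `n` | 2 | — | fuzzy weight; larger sharpens the kernel toward Heaviside |
| `r_init` | 0.05 | ranged distance | first tolerance tried |
| `r_step` | 0.05 | ranged distance | additive grid step |
| `r_max` | 1 | ranged distance | grid cap (Chebyshev: max pairwise distance) |
| `min_avg_matches` | 5 | matches/template | numerator quota ending the search |
| `w` | 1 | — | heart-rate adjustment weight |
| `epsilon` | 1e-10 | — | ranged-distance denominator guard |

Two defaults deserve comment.

**The `m = 1` degeneracy.** The ranged distance of two length-1 templates
is identically zero (its max and min coincide), so at `m = 1` the
dimension-`m` similarity `B` is exactly 1 and all discriminative
information sits in the `m+1 = 2` level. We expose `m` rather than
silently overriding it, and the discrimination tests exercise both `m = 1`
and `m = 2`.

**The weight `w` is a trained parameter.** Plainly subtracting
$\ln(\overline{RR})$ (that is, `w = 1`) is a convention, not a law; `w`
scales how much the heart-rate channel contributes relative to the
irregularity channel, and the appropriate balance depends on the data.
`tune_w()` grid-searches `w` over $[0, 2]$ in steps of 0.1, maximizing the
training AUC of the decomposition
$\mathrm{part} + w \cdot (-\ln \overline{RR})$, where the gain-invariant
part is computed once per segment. On the package's synthetic 12-beat data
the default `w = 1` under-weights heart rate (AUC $\approx 0.84$) while the
trained weight restores AUC $> 0.95$; on the 30-beat data the default is
already near-ceiling. The per-segment tables always record the `r` actually
used so runs are auditable.

**Comparator settings.** `sampen()` and `fuzzymen()` default to `m = 2` and
`r = 0.2 * sd(segment)`, the standard heart-rate-variability practice, with
a 1-ms floor on `r` so constant segments stay defined. `fuzzymen()` applies
the same weight `n` to its local (template-mean-removed) and global
(series-mean-removed) terms. `cosen()` uses `m = 1` and steps its Chebyshev
tolerance by `0.01 * sd(segment)` per grid point. Sample entropy on short
AF-like windows frequently has zero matches at the longer template length;
the value is then non-finite and flagged (`a_zero`), never coerced, and the
ROC stage drops non-finite scores with a reported count.

## Preprocessing

Beat-annotation exports are converted to RR series
(`read_beat_annotations()`), intervals above 2 s are removed
(`filter_rr()`) — a removal breaks template continuity, so windowing
restarts after the gap rather than stitching beats across it — and
episodes of a single rhythm are windowed independently
(`segment_episodes()`), so every segment is rhythm-pure. Whether windows
may straddle brief episode interruptions is not something we can settle
from first principles; restarting is the conservative choice and is what
the randomized boundary tests assert. Two task encodings are supported:
AF vs N (atrial flutter and junctional segments excluded) and AF vs
non-AF (N, AFL and J merged).

For wearable recordings, a 10-s ECG window is declared noisy when at least
2 of 5 signal-quality predicates fire (`bSQI < 0.5`, `tSQI = 0`,
`iSQI = 0`, `pSQI < 0.8`, `kSQI < 3`); a segment overlapping any noisy
window is excluded by default (`segment_noise_gate()`, `rule = "any"`),
with a majority variant available. Computing the quality indices from raw
ECG is out of scope — the package consumes their values.

## Evaluation protocol

`roc_entropy()` sweeps 101 thresholds from the minimum to the maximum score
in steps of 1% of the range, computes Se and Sp at each, anchors the curve
at (0,0) and (1,1) and integrates by trapezoid. The orientation (whether
high or low values indicate AF) is auto-detected so AUC $\ge$ 0.5 and
recorded. The exact Mann–Whitney AUC (`auc_mw()`) is exposed separately;
the two agree to within grid discretization when adjacent distinct scores
are resolved by the grid, and the test suite checks this on small
instances. Operating points come from the Youden index
(`youden_optimal()`, ties toward the smaller threshold), from
high-sensitivity / high-specificity constraints (`cutpoint_at()`, strict
`> level` on the grid, flagged when unattainable), or from a fixed
externally learned threshold (`metrics_report(operating = "fixed")`), which
is the transfer protocol for applying training-set cut-points to new data.
AUCs of two measures on the same segments are compared with a paired
two-sided DeLong test (`compare_auc()`); the choice of DeLong is ours, so
its p-values should be read as the package's convention rather than a
reproduction of any published test. No multiple-testing correction is
applied. A zero-variance difference (e.g. identical scores) is flagged
rather than producing a spurious p-value.

## The synthetic generators

The generators exist so that every pipeline stage is testable without
clinical recordings, and their defaults are the package's fixed study
conditions.

* **AF-like** (`synth_af_rr()`): iid log-normal intervals,
  mean 0.6 s, coefficient of variation 0.25. This captures the two
  signatures the detector keys on — short mean RR and high, serially
  uncorrelated variability — without modelling AV-node physiology.
* **NSR-like** (`synth_nsr_rr()`): mean 0.85 s with a 0.04 s respiratory
  sinusoid at 0.25 Hz over the cumulative beat time plus 0.03 s Gaussian
  beat noise, so sinus rhythm is regular-but-not-constant and entropies
  stay non-degenerate.
* Both clip intervals to (0.25 s, 2 s), mirroring the preprocessing bound,
  and report clip counts. A shuffled-NSR variant destroys serial structure
  while keeping the marginal distribution, as a second null.

What the synthetic data do **not** contain: ectopic beats, rhythm
transitions inside a window, annotation errors, sensor noise, atrial
flutter's organized sawtooth patterns, or the long-range nonstationarity
of day-long recordings. Passing the synthetic discrimination tests
therefore demonstrates that the implementation behaves as designed — it
does not by itself establish clinical performance, which must be assessed
on real annotated recordings (the pipeline accepts PhysioNet-style beat
annotation exports for exactly that purpose). A further honest caveat:
because the ranged distance is scale-invariant, the *normalized* shape of
the synthetic NSR series (sinusoid-to-noise ratio about 4:3) is less
regular than clinical sinus rhythm, so on these data a large share of the
detector's separation is carried by the heart-rate term; the comparator
measures, which see absolute variability, separate the classes through
their tolerance and similarity channels.

## Numerical choices and degenerate inputs

* Problem sizes: the package's own evaluation uses 500 + 500 synthetic
  segments per window length, 100-segment batches for invariance
  properties, and 200 permutation replicates for the null calibration of
  the DeLong test.
* Indexing is 1-based in all formulas above and 0-based nowhere visible to
  the user; templates are rows of `embed_vectors()`.
* The `epsilon` guard makes the ranged distance of two identical templates
  exactly 0 instead of 0/0; it perturbs other distances by at most one part
  in $10^9$ and the gain-invariance tests bound its visible effect.
* Constant segments: every distance is 0, so `sampen()` and `fuzzymen()`
  return 0 and the flexible search ends at `r_init`, giving
  `cosen() = entropy_af() = ln(2 r_init) - w ln(RRmean)`.
* Ties in the Youden scan break toward the smaller threshold; ROC
  orientation is recorded with every curve; non-finite entropy values
  propagate as flags and are dropped (with counts) only at the ROC stage.
* Reproducibility: all generators accept seeds and restore the caller's
  RNG state; `run_pipeline()` is byte-deterministic given its config.

## Known limitations

* The comparator tolerances (`0.2 * sd`) are conventions; published
  clinical comparisons do not always state theirs, so absolute comparator
  values may differ across implementations even when rankings agree.
* `fuzzymen()` uses one weight `n` for both its local and global terms;
  implementations following the original two-weight parameterization
  (`nL = 3`, `nG = 2`) will differ slightly.
* The DeLong test is asymptotic; at very small segment counts its null
  rejection rate can drift from nominal (the test suite calibrates it at
  n = 200).
* The CLI is a thin wrapper (`inst/cli/afentropy.R`); the package functions
  are the primary interface.
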