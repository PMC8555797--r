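---
title: "Methods behind actimetrics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind actimetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimetrics)
```

actimetrics analyses wrist-actigraphy recordings: movement aggregated by the
device into *activity counts* per fixed epoch (typically 15–120 s), worn for
days to weeks. This vignette is the package's own account of the statistics
it implements, the conventions it fixes where the literature is ambiguous,
and the limits of what its synthetic-data validation shows.

## The data model

An `epoch_series` stores counts on a strictly uniform grid: `start_time`,
`epoch_length`, a counts vector and an aligned logical mask. Timestamps are
implied (`timestamp(i) = start_time + (i-1)·epoch_length`) and label the
*start* of each epoch; all intervals package-wide are half-open
`[start, stop)`, which avoids double counting at boundaries. Two
consequences are worth spelling out:

* **Missing data are masked, never dropped.** A gap in a source file becomes
  a run of epochs with count 0 and mask `FALSE`. This keeps 24 h folding
  aligned for every downstream metric. Each metric documents its own mask
  policy; the common rule is "excluded from sums and counts": masked epochs
  never enter bin means, variance sums, IV difference pairs, or rest/active
  runs (a run cannot span missing data).
* **Masking is non-destructive.** `apply_mask()` only flips mask bits;
  `detect_inactivity_mask()` returns a *proposal* (`mask_spec`) rather than
  modifying the series, so automatically detected non-wear candidates can be
  inspected, edited in a spreadsheet (the spec round-trips through the
  `SUBJECT_ID,START,STOP` CSV dialect) and applied deliberately.

Timestamps are naive local time, held internally as UTC so that no
daylight-saving arithmetic is ever applied. This is deliberate: actigraphy
devices log naive clock time, and a 23- or 25-hour civil day would corrupt
the 24 h folding that nearly every metric relies on.

Readers exist for a canonical CSV dialect
(`timestamp,count[,light,marker]`, ISO-8601) and for AWD-style plaintext
(7 header lines, then one count per line). The AWD epoch-code table
{1 → 15 s, 2 → 30 s, 4 → 60 s, 8 → 120 s} follows the commonly documented
CamNtech convention; unknown codes are rejected loudly rather than guessed,
because misreading the epoch length silently rescales every rhythm
variable. Count lines with trailing event-marker characters ("123M") keep
the numeric part, with markers recorded in the series metadata.

## Daily profiles and onset/offset times

`average_daily_profile()` folds the recording at 24 h and averages valid
epochs per clock bin. The onset/offset estimator scans every bin boundary
`t` and computes the symmetric relative difference

$$d(t) = \frac{\mu_{after} - \mu_{before}}{\mu_{after} + \mu_{before}},$$

with means over cyclic windows (default 12 h, i.e. a half-day split) after
and before `t`. The onset is the boundary maximising `d`, the offset the
one minimising it. The symmetric ratio was chosen because it is bounded in
[−1, 1] and scale-free, so thresholding or comparing across subjects does
not depend on absolute count levels; no sub-bin interpolation is attempted
(the estimate's resolution is the bin width). Ties are broken toward the
earliest clock time, which makes the degenerate flat-profile case
deterministic.

## Non-parametric rhythm variables

With `p` bins per 24 h, the across-day mean $\bar x_h$ of clock bin `h`,
and `N` valid bins in total:

$$IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2},
\qquad
IV = \frac{N \sum_{i \ge 2} (x_i - x_{i-1})^2}{(N-1)\sum_i (x_i - \bar x)^2}.$$

IS is the fraction of variance explained by the average daily profile: 1
exactly for any signal that repeats every 24 h on the bin grid, and close
to 1/(number of days) for uncorrelated noise. IV is a normalized mean
squared successive difference: near 0 for a smooth circadian rhythm, about
2 for white noise, 4 for a perfectly alternating series. Both are computed
by default on 60-min bins — the classical convention of the non-parametric
literature — but any width dividing 24 h is available, and `mean_IS_IV()`
averages over a width set (default: every integer minute in 1..60 dividing
24 h, since the originating literature does not enumerate a set). For a
24 h-periodic signal sampled `m` times per day IV does not vanish exactly:
the first difference of a sampled cosine leaves the residual
$4\sin^2(\pi/m)$ (≈ 0.069 at hourly samples, ≈ 2·10⁻⁵ at 1-min epochs).
The package's validation therefore checks the analytic zero at the native
epoch resolution, where the residual is observable only in the fifth
decimal.

M10 and L5 scan all cyclic 10 h and 5 h windows of the *hourly average
profile* — not per-day windows later averaged — because that is what yields
a single onset clock time per recording; values are mean counts per
acquisition epoch. RA = (M10 − L5)/(M10 + L5). Interval-wise variants chop
the recording into consecutive non-overlapping blocks (at least 48 h when
IS is requested, since IS needs two days) and flag a trailing partial
block rather than silently dropping or silently including it.

## Rest–activity fragmentation (kRA, kAR)

Epochs with count ≤ threshold (default 0) are *rest*, others *active*. For
runs of one state, the per-duration hazard is
`rate(t) = n_end(t)/n_atrisk(t)`; the scalar transition probability is the
at-risk-weighted mean of `rate(t)`, which collapses algebraically to
(completed runs)/(total epochs spent in runs). Runs cut by the series end,
by missing data, or by a clock-window boundary are **censored**: they stay
at risk for their observed length but never count as events. This is the
standard survival-analysis convention; it is also what makes the estimator
consistent for memoryless runs — if rest-run lengths are Geometric(p), kRA
estimates exactly p. An unweighted hazard mean over durations is exposed as
a sensitivity option. Clock windows may wrap midnight; a bout spanning a
window edge is treated as censored inside the window because its
continuation is unobserved there. `transition_in_rest_span()` wires the
profile-derived offset→onset span in explicitly — never implicitly —
because silently coupling two estimators would make failures hard to
attribute.

## Sleep detection

**Epoch scorers** (Cole-Kripke, Sadeh, Scripps, Oakley) share one engine: a
sliding window centred on the epoch, a kernel of published weights, a
threshold. The constants are *not* re-derived here; they are transcribed
from the original publications into a versioned preset table
(`scoring_presets()`), so a transcription erratum is a data fix. All four
presets are defined at their native 60 s epochs and refuse other epoch
lengths with a pointer to `resample_series()` rather than rescaling weights
behind the user's back. Windows reaching past the recording edges are
zero-padded; this is documented because it biases edge epochs toward rest
by up to half a kernel width, visible in the boundary tolerances of the
package's own tests. Labels use rest = 1 / active = 0 package-wide; each
algorithm's native polarity is converted at the boundary. The Oakley preset
transcribes the Actiware-style weighting (0.04, 0.2, 1, 0.2, 0.04) with the
medium wake threshold (40); the firmware family has variants, which is
precisely why the choice is recorded in the preset rather than the code.

**Consolidated detectors** return whole rest periods. The Roenneberg-style
detector compares counts with a centred 24 h moving-average trend
(candidates: count < fraction·trend, default fraction 0.15 with 0.25 as the
common stricter variant), closes gaps shorter than 15 min, and discards
periods under 30 min. The Crespo-style detector log-transforms counts,
separates the rest/activity modes of the (bimodal) distribution with Otsu's
minimum-intra-class-variance threshold, then applies morphological closing
and opening sized by expected wake/sleep bouts. One design choice needs
flagging: Otsu's criterion returns a cut for *any* non-constant
distribution, so a recording with a single activity regime would otherwise
grow rest periods out of noise. The detector therefore requires the
between-class variance fraction (Otsu's η) to exceed 0.8 before accepting
bimodality; below that, the recording is judged single-regime and scored
all-active (or all-rest when essentially all counts are zero). Labels and
the period list are kept mutually consistent after consolidation.

**Sleep regularity.** The concordance profile is, per clock bin, the
fraction of consecutive day pairs in the same state; the index is
SRI = 200·mean(concordance) − 100, anchored at 100 (identical days), −100
(complemented days) and 0 (independent fair-coin states). The
multiplicative variant (product of concordances instead of the mean) is
available behind `method = "product"` but is never the default: only the
average-based definition satisfies the anchor cases while remaining a
per-bin average, matching the index as defined in the sleep-regularity
literature. Sleep midpoints are averaged on the 24 h circle, so 23:00 and
01:00 give 00:00, not noon.

## Advanced signal analyses

**Cosinor.** $Y(t) = M + A\cos(2\pi t/T + \phi)$ fitted by linear least
squares on cos/sin regressors; $A = \sqrt{\beta_1^2+\beta_2^2}$,
$\phi = \mathrm{atan2}(-\beta_2, \beta_1) \in (-\pi, \pi]$, so the curve
peaks at $t = -\phi/\omega$. The sign convention is stated because cosinor
software disagrees on it. Standard errors come from linear-model theory
(delta method for A and φ); when the fitted amplitude is numerically zero
the acrophase is reported as 0 by convention. Free-period fits scan a
candidate grid (default 23–25 h) and keep the minimal residual variance;
the grid is explicit because the profile of residual variance in T is
non-convex.

**MF-DFA.** Profile integration, segmentation of size n taken forward *and*
backward (standard multifractal practice, so both ends of the recording
contribute), polynomial detrending (default order 1), and
$F_q(n) = \{\mathrm{mean}(RMS^q)\}^{1/q}$ with the logarithmic-mean variant
at q = 0. h(q) is the log–log slope over the scale range (default 8 to
N/4, 12 log-spaced sizes; at least 4 sizes are required for a slope worth
reporting). The mask is not honoured here — detrended fluctuations are
meaningless across stitched gaps — so the function warns instead.

**Functional representation.** Daily profiles can be converted to smooth
functions by Fourier expansion (inherently 24 h-periodic), least-squares
B-splines, or a Nadaraya–Watson smoother with a circular Gaussian kernel.
The kernel wraps distances on the 24 h circle so midnight is not an
artificial boundary; B-splines do not wrap, which is acceptable for
anchored profiles and kept simple deliberately.

**LIDS.** Inactivity during sleep is obtained by the bounded inversion
LIDS(t) = 100/(count(t)+1) ∈ (0, 100], smoothed with a 30-min moving
average; candidate sleep bouts are rest periods of 3–12 h, and a cosine is
fitted per bout with the period searched on a grid over 30–180 min (1-min
steps), reporting period, amplitude, phase and the fit–signal correlation.
These constants follow the originating LIDS methodology and are all
exposed as parameters.

**SSA.** Embedding with window L (2 ≤ L ≤ N/2; two days is a sensible
default for circadian work), eigendecomposition of the L×L lag-covariance
matrix $XX^T$ (numerically equivalent to the SVD of the trajectory matrix
and much cheaper for L ≪ K), and diagonal averaging implemented as an
FFT-based convolution of $u_k$ with $X^T u_k$ — this avoids ever forming
an elementary matrix, reconstructs any component in O(N log N), and keeps
full-decomposition completeness exact even for zero singular values.
Partial variances are $\lambda_k/\sum\lambda$. Grouping is the user's
decision: `suggest_groups()` proposes connected components of the
|w-correlation| > 0.3 graph, and the w-correlation matrix itself is always
available, but nothing is grouped silently.

## Synthetic data: what the validation does and does not show

The generators define the package's study conditions, not tunable fixtures:

* `synth_sine` / `synth_square` — 24 h-periodic signals (defaults: 7 days,
  1-min epochs, mesor 100, amplitude 100) for the analytic identities
  IS = 1 and IV ≈ 0.
* `synth_noise` — i.i.d. Gaussian counts (mean 50, sd 10, clipped at zero)
  for the IS ≈ 1/days and IV ≈ 2 expectations.
* `synth_geometric_binary` — alternating rest/active runs with geometric
  lengths, the memoryless regime in which kRA = p exactly.
* `synth_composite` — mesor + circadian cosine (peak 15:00), optional
  ultradian cosine, truncated-Gaussian count noise (the noise family is a
  package choice; nothing in the underlying model prescribes one), nightly
  rest 23:00–07:00, optional naps and no-wear gaps, with ground-truth
  annotations returned alongside. The annotations are guaranteed consistent
  with the emitted counts (no-wear gaps are all-zero).

All randomness flows from a single seed per generator call, so every
fixture regenerates byte-for-byte. Passing these checks demonstrates
*estimator correctness* under known regimes — it does not demonstrate
clinical validity on real wrist data, where counts are autocorrelated,
non-stationary across days, and device-dependent. The epoch-scorer
presets in particular were validated by their original authors against
polysomnography on specific devices; this package verifies only that the
published arithmetic is implemented exactly (against brute-force
sliding-window oracles).

Problem sizes used by the package's own test suite are part of its design:
7-day × 1-min recordings for the periodic identities, 10⁵ epochs for the
geometric transition checks, series of length 4096 with 50 replicates for
the DFA exponents, 200 simulations for cosinor interval coverage, and
N = 10⁴ with L = 2880 for the SSA decomposition. They were chosen as the
smallest sizes at which each estimator's sampling error is comfortably
below the assertion tolerances.

## Numerical choices and degenerate inputs

* Zero-variance series make IS/IV undefined → explicit errors, not NaN.
* All-zero profiles make onset/offset and RA undefined → errors.
* Binarization uses strict `count > threshold`, so threshold 0 separates
  "no activity" from "any activity"; rest detection mirrors it with
  `count ≤ threshold`.
* Resampling masks a coarse bin if *any* constituent epoch is masked:
  partially observed bins would bias count sums downward.
* Bins with no valid epochs are excluded from profile sums; IV difference
  pairs spanning a masked bin are excluded.
* Which.max/which.min-style scans break ties toward the earliest clock
  time, making flat-signal behaviour deterministic.
* Epoch-length arithmetic tolerates 1e-9 relative error before declaring a
  width "not a multiple".

## Known limitations

Binary vendor formats are out of scope (the canonical CSV dialect is the
interchange format); timestamps are naive local time by design; DFA and
SSA require contiguous signals and only warn about masks; no
raw-acceleration-to-count conversion is provided; consolidated-detector
parameters (trend fraction, bout and gap lengths, the η = 0.8 bimodality
bar) are sensible defaults for adult wrist actigraphy, not universal
constants, and are all exposed for tuning.
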