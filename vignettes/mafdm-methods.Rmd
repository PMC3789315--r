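---
title: "The modified amplitude fractal dimension method: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified amplitude fractal dimension method: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafdm)
```

## The problem

The fractal dimension of a time-series graph, between 1 (a smooth line)
and 2 (an area-filling curve), is a widely used complexity measure for
biomedical signals: EEG, accelerometry, acoustics.  Established
estimators disagree about what to do with the signal's amplitude.
Amplitude-only ("mono-dimensional", Higuchi-principle) estimators sum
the amplitude differential per decimated step and are invariant to
amplitude scaling; box-counting estimators make the amplitude-to-time
ratio integer with a ceiling function.  On signals whose per-step
amplitude change sits just below the sampling interval, the two
families give *opposite* answers — near 2 and near 1 on the same
window — because `ceil(x)` pins small ratios at one box while the raw
ratio keeps shrinking with decimation.  Both also assign zero length to
a locally constant signal, although a flat stretch plainly has extent
in time.

The estimator implemented here works in a genuinely two-dimensional,
dimensionless space.  The signal is first normalised to unit amplitude
and unit time (a pure unit-stripping step, never a rescaling), then its
amplitude is multiplied by a single dial `m`, and curve length is
measured as a Euclidean hypotenuse per decimated step.  The multiplier
interpolates continuously between the two worlds: `m -> 0` flattens
every signal to a line (dimension 1), `m -> Inf` recovers the
amplitude-only dimension exactly.  Because the dimension of the
*modified* signal depends on `m`, `m` becomes a design parameter that
can be optimised so that two signal classes are maximally separated in
dimension — the package's reason for existing.

## The estimator

For a dimensionless series `y` sampled at frequency `f0`, the relative
length of one segment at decimation level `n` is

    R_i = (f0 / n) * sqrt(m^2 (y_{i+n} - y_i)^2 + (n / f0)^2),

a hypotenuse normalised to its own coarse time base, hence never below
1.  Over a window of `w` intervals starting at sample `j`, the `n`
decimation phases are averaged with fractional boundary weights:
interior segments `i = j .. j+w-n` count fully, the `n - 1` partial
segments reaching beyond each window edge count with weights
`(n-l)/n`, and the total is divided by the number of phases `n`.  On a
constant window every level returns exactly `w / n`, which is what
makes the flat-line dimension exactly 1 instead of undefined.  The
dimension of the window is the ordinary least-squares gradient of
`log R` against `log(f0 / n)` over the levels, reported together with
the intercept and the signed fit correlation `r` as a quality check.
A sliding evaluation with step one sample assigns each estimate to the
window centre `j + floor(w/2)`.

Levels must be log-equidistant (`1, 2, 4, 8` or `1, 3, 9`, never
`1, 2, 3, 4, 5`), otherwise the regression is weighted towards the low
frequencies.  The default `{1, 2, 4}` mirrors the three frequencies
`f`, `f/2`, `f/4` used throughout the comparison analyses; `{1, 3, 9}`
is the natural choice for strictly alternating signals, whose
even-level decimation is degenerate.

### Numerical and edge choices

* **Generalised phase divisor.**  The windowed sum is divided by `n`
  (the number of phases).  The `n = 2` and `n = 4` special cases fix
  this unambiguously; a printed `(4)^-1` in one generalised line is a
  typo carried by the source material.
* **Boundary weight range.**  The fractional weights run `l = 1 ..
  n-1`; the `l = n` term has weight zero and is never fetched.
* **Edge policy.**  `full_context` (default) requires `max(levels)-1`
  samples of context on each side of the window and reproduces the
  boundary-corrected sums exactly.  `truncate` uses only samples inside
  the window: the missing fractional terms are dropped and the
  remaining weights renormalised, i.e. the value is `(w/n)` times the
  weighted mean of the available step lengths.  Under full context the
  two formulations are algebraically identical, and a constant window
  still yields exactly `w/n` at every level, so flat-line exactness is
  preserved at the series edges.  Whole-signal estimates (the accuracy
  benchmark) use `truncate` with `w = length - 1`, since no context
  beyond the signal exists.
* **No clamping.**  Estimates outside `[1, 2]` are reported as-is with
  their fit correlation; out-of-range values are a diagnostic (the
  comparison estimators produce them by construction on threshold
  signals), not an error.
* **Degenerate windows.**  A non-positive windowed sum (possible for
  the amplitude-only and box-counting estimators on locally constant
  signals) yields `NaN` flagged `zero_length`/`degenerate` rather than
  an error, so sliding series stay aligned with their time axis.
* **Unweighted regression.**  The log-log fit is plain OLS; nothing in
  the method calls for level weighting.

The window width trades time resolution against estimate noise; the
estimate itself is insensitive to `w` at fixed sampling frequency
(tested: mean estimate drift below 0.05 between `w = 100` and
`w = 1000` on a dimension-1.5 Knopp signal at 1 kHz).  `w >= 4 *
max(levels)` is enforced so the coarsest level still sees at least four
intervals.

## The triangular-wave closed form

For a zig-zag wave alternating between 0 and `h` every sample,
decimation to an odd level `n` replaces `n` zig-zag segments by one
diagonal, and the two-point gradient has a closed form (implemented in
`closed_form_dimension()`) that depends on `m` and `h` only through the
product `m h`.  Its limits are exactly 1 (`m -> 0`) and 2
(`m -> Inf`); every finite multiplier lies strictly between.  This is
the package's central oracle: sampled zig-zag windows must reproduce it
to 1e-10 across eight decades of `m`, which pins down the boundary
weights, the phase divisor and the regression in one stroke.  The
asymptote contract is checked numerically at `m = 1e-9` and `1e9` with
tolerance 1e-10 — a floating-point-verifiable statement, unlike a
symbolic limit.  Note that between its two corner scales
(`m h f0 ~ 1` and `~ n`) the spectrum's gradient carries a `1/log(n)`
factor: larger `n` *widens* the sigmoid transition while preserving
the asymptotes.

## Benchmark generators

Four continuous nowhere-differentiable families with known theoretical
dimension serve as ground truth (`cndf_signal()`):

* **Knopp**: `K(t) = sum a^k <<b^k t>>` with `a = b^D / 4`; defaults
  `b = 2`, 50 terms.  Valid for `D` in `[1, 2]` at `b = 2`
  (`0.5 <= a <= 1`, `ab >= 1`).
* **Weierstrass cosine**: `W(t) = sum gamma^{-kH} cos(2 pi gamma^k t)`,
  defaults `gamma = 5`, 51 terms (`k = 0..50`), `D = 2 - H`.  A
  trailing index typo in the printed series definition is resolved to
  this standard form, the one whose graph dimension is `2 - H`.
* **Weierstrass–Mandelbrot**:
  `Wm(t) = sum (1 - cos(b^k t)) / b^{Hk}` over `k = -50..50`, default
  `b = 1.5`.  The negative-`k` tail is bounded by `(1-cos x) <= x^2/2`
  and negligible at double precision.
* **Fractional Brownian motion**: exact-covariance synthesis of
  fractional Gaussian noise by Davies–Harte circulant embedding
  (Hosking recursion as a guarded fallback), cumulated with `B(0) = 0`
  and scaled so one unit of time has unit variance.  Only the
  `tau^{2H}` increment-variance law and rank recovery are asserted;
  this deliberately sidesteps the wavelet synthesis of the original
  workflow, whose particular spectral shortcuts are irrelevant to the
  benchmark.

The default sampling grid is endpoint-inclusive, `t = 0, 1/fs, ...,
duration` (`fs * duration + 1` samples) — the `0:1/fs:T` idiom of the
Matlab environment the original analyses ran in.  "One second at
1 kHz" therefore means 1001 samples here; the benchmark results move
by well under a tenth of a percentage point between the inclusive and
exclusive conventions.

`benchmark_accuracy()` estimates each curve with a single whole-signal
window (the open choice between one window and averaged sliding
windows is resolved to the single window and documented here), and
replicates the stochastic fBm family over ten seeds per dimension,
averaging the estimates.  Behaviour reproduced by the test suite:
maximum Weierstrass error of 2.48% of the theoretical dimension over
`D = 1.2 .. 1.8` at `m = 1`; clear overestimation of Knopp dimensions
near `D = 1`; systematically higher estimates at coarser sampling
frequencies; perfect Spearman rank recovery across the fBm dimension
grid.  (At `D = 1.9` the Knopp estimate is essentially unbiased here
rather than underestimated; the interior bias at the top of the range
did not reproduce and is not asserted.)

## Multiplier optimisation

`m_spectrum()` evaluates the mean sliding dimension of labelled
segments over a log-spaced multiplier grid — by default `1e-4` to
`1e4` at 9 points per decade, wide enough to bracket optima observed
in practice (roughly `1e-3` to a few units) with margin.  The same
multiplier is applied to every signal at each grid point, because
dimensions of modified signals are only comparable at equal `m`, and
the window width is carried inside the spectrum object so the final
analysis necessarily runs under the configuration the optimum was
determined for.  Segment aggregation uses the mean (not the median) of
the windowed estimates.

Three criteria pick the optimal multiplier:

1. **Range** (`optimise_range()`): maximise
   `D^max(m) - D^min(m)`.  The difference is kept signed: the two
   curves can intersect at large `m` (a low-activity segment can
   out-dimension an event segment in the amplitude-only limit), and a
   sign change is exactly the information the analyst needs.  Grid
   ties break towards smaller `m`, where the filter effect is
   stronger.
2. **Max vs average** (`optimise_max_vs_avg()`): maximise
   `D^max(m) - D^avg(m)`, the criterion for a rare event that barely
   influences the whole-signal average.
3. **Ratio** (`optimise_ratio()`): maximise
   `(D^max - 1) / (D^avg - 1)`.  The ratio typically grows as `m`
   shrinks and plateaus at small `m`; the optimum is placed at the
   *onset* of that plateau, operationalised as the smallest grid
   multiplier reaching 98% of the grid maximum (the 2% plateau
   tolerance is this package's convention; the source analyses name
   only "the beginning of the asymptotic segment").  Grid points where
   `D^avg - 1 <= 1e-6` are masked to keep the ratio finite, and the
   masking is reported.

Where more than two classes yield pairwise optima, `mean_log_m()`
combines them as a geometric mean — a documented convention, not an
asserted property.

A practical by-product: at a small optimal `m` the sliding dimension of
quiet signal stretches is far less noisy than at `m = 1` (the
"filter effect"); the test suite asserts the standard-deviation drop on
a burst-in-noise fixture.

## What the synthetic fixtures do and do not show

`generate_fixture()` builds seeded baseline-plus-events series: a flat
or low-noise baseline, with embedded exact zig-zag bursts (whose
windowed dimension obeys the closed form), Gaussian amplitude bursts,
or scaled CNDF stretches, together with ground-truth segment roles.
The defaults (2000-sample low-noise baseline, `sd = 0.02`, one
200-sample unit-amplitude burst at 100 samples per unit time in the
test fixture) emulate the *structure* of real case-study recordings —
rare high-amplitude events over quiet backgrounds.

These fixtures are idealisations.  Real EEG, accelerometer and
acoustic recordings have coloured noise floors, drifting baselines,
quantised amplitudes, and event morphology far richer than a zig-zag
burst.  Passing tests therefore demonstrate that the estimator and
optimiser are *correct implementations with the claimed analytic
behaviour*, not that any particular `m` or dimension threshold will
transfer to a given recording; published case-study optima rest on
recordings that are not redistributable, and their printed numbers are
deliberately not asserted anywhere in this package.  The workflow —
spectrum, criterion, re-analysis at the optimum — is what is
reproduced and tested.

## Problem sizes used by the test suite

Deterministic oracle checks run on waves of tens to hundreds of
samples; benchmark sweeps use one-second signals at 1 kHz; the fBm
scaling law uses ten seeds of 2^14 increments; optimiser tests use
2000-sample fixtures with 9-point-per-decade grids over two to four
decades.  These sizes were chosen so the full statistical behaviour is
visible while the suite stays comfortably interactive.

## Known limitations

* Single-channel only; batch over files rather than multi-channel
  containers.  No EDF/BDF or WAV readers: inputs are plain CSV/TSV.
* No confidence intervals on the windowed dimension; the fit
  correlation `r` is the only per-window quality measure.
* No multifractal/Rényi spectra, no detrended-fluctuation or R/S Hurst
  estimation; the amplitude-only and box-counting estimators are
  included for comparison, not as recommended tools.
* The box-counting comparator implements the ceiling box count per
  decimated step only; the sign-ambiguous amplitude-update rule of its
  original formulation is documented as not implemented.
* Automatic event detection is out of scope: segments are supplied by
  the analyst.
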