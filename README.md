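# mafdm

Robust fractal-dimension estimation for dimensionless time series with
an amplitude multiplier, plus the multiplier-spectrum optimisation that
maximises the dimension separation between signal classes.

## The problem and who this is for

Fractal dimensions (`1 <= D_H <= 2` for a time-series graph) are used
to classify and segment biomedical signals — sleep stages from EEG,
activity episodes from accelerometry, impact events from acoustics.
Standard estimators disagree systematically: amplitude-only estimators
in the Higuchi tradition are invariant to amplitude scaling, while
Euclidean and box-counting estimators are not, and on near-threshold
signals (per-step amplitude change just below the sampling interval)
the two families return *opposite* dimensions, near 2 versus near 1,
on the same window.

This package implements the modified amplitude fractal dimension
method (MAFDM) for analysts who want the dimension of a *designed*
signal rather than an arbitrary convention: the signal is normalised
to unit amplitude and unit time (dimensionless, no hidden prescaling),
its amplitude is scaled by a single multiplier `m`, and curve length is
measured per decimated step as the Euclidean hypotenuse

    R_i = (f0 / n) * sqrt(m^2 (y_{i+n} - y_i)^2 + (n / f0)^2),

summed over a window with fractional boundary weights, averaged over
the `n` decimation phases, and regressed as `log R` on `log(f0 / n)`
over log-equidistant levels `n` (e.g. `{1, 2, 4}`):

    log R_{j,w,n} = D_Hm * log(f0 / n) + I.

The gradient `D_Hm` is the dimension of the modified signal.  It runs
from 1 as `m -> 0` (any signal flattens to a line) to the
amplitude-only (Higuchi) dimension as `m -> Inf`, so `m` is a tunable
dial — and the package's optimiser chooses it to maximally separate
the dimensions of two signal classes (range `D^max - D^min`,
max-vs-average, or the `(D^max - 1)/(D^avg - 1)` ratio with a
plateau-onset rule).  A welcome side effect of small optimal
multipliers is a strong noise filter on the sliding dimension series.

Included besides the estimator and optimiser:

* the mono-dimensional (Higuchi-principle) and multiresolution
  box-counting (MRBC) comparison estimators, sharing the same windows;
* an exact closed form for triangular (zig-zag) waves — the test
  oracle — with its `m`-spectrum and analytic asymptotes 1 and 2;
* generators for four continuous nowhere-differentiable benchmark
  families with known dimension (Knopp, Weierstrass cosine,
  Weierstrass–Mandelbrot, fractional Brownian motion via Davies–Harte
  circulant embedding) and an accuracy benchmark over them;
* seeded synthetic fixtures (baseline + embedded events) and a
  command-line interface.

## Worked example

A 20-second low-noise recording (100 samples per unit time) contains a
2-second high-amplitude noisy burst.  Where is the burst best
separated from the baseline?

```r
library(mafdm)

fx <- generate_fixture(fixture_spec(
  baseline = list(kind = "low_noise", length = 2000, noise_sd = 0.02),
  events = list(list(kind = "amplitude_burst", start = 1401,
                     length = 200, amplitude = 1,
                     role = "max_event", label = "burst")),
  f0 = 100, seed = 11))

cfg <- estimator_config(levels = c(1, 2, 4), w = 100)
sp  <- m_spectrum(fx$ts, fx$segments, cfg, m_log_grid(1e-4, 1e2, 3))
res <- optimise_range(sp, "baseline", "burst")
res
#> <mafdm_opt> criterion = range, m_opt = 0.1 (curves intersect:
#>   objective changes sign over the grid)

i <- match(res$m_opt, sp$m_grid)
sp$curves[i, c("burst", "baseline")]
#>    burst baseline
#> 1.889    1.044
max(res$objective_curve$value)
#> [1] 0.845
```

At the optimal multiplier `m = 0.1` the burst sits at a mean dimension
of 1.89 against a baseline of 1.04 — a separation of 0.85, far wider
than at `m = 1`, and the note reports that the two spectrum curves
intersect at large `m`: in the amplitude-only limit the baseline would
actually *out-dimension* the burst, which is why optimising `m`
matters.  Re-running `sliding_dimension()` at `m = 0.1` also shows a
much quieter baseline dimension trace than at `m = 1` (the filter
effect).

Benchmark sanity check — a Weierstrass cosine with theoretical
dimension 1.5, estimated with one whole-signal window at `m = 1`:

```r
whole_signal_dimension(weierstrass_cosine(H = 0.5), m = 1)
#> <fd_estimate> D_Hm = 1.52639, I = 0.7609, r = 0.999985 [ok]
```

## Command line

```sh
inst/cli/mafdm cndf --family weierstrass --dim 1.5 --out w.csv
inst/cli/mafdm compute --input w.csv --m 1 --window 500 --out dhm.csv
inst/cli/mafdm optimise --input fx.csv --window 100 \
    --segments segments.json --criterion range --out opt.json
```

Subcommands: `compute`, `compare`, `spectrum`, `optimise`, `cndf`,
`benchmark`, `triangular-spectrum`, `fixture`.  Logs go to standard
error, results to files, each with its effective configuration as `#`
header comments.

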