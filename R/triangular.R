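# Exact closed form for the symmetric triangular (zig-zag) wave: the one
# waveform whose modified-amplitude dimension can be written down
# analytically, used throughout the test suite as an independent oracle
# for the numerical estimator.

#' Generate a sampled triangular (zig-zag) wave
#'
#' Values alternate `0, h, 0, h, ...` at spacing `1/f0`: the steepest
#' waveform a sampled series can hold, whose amplitude-only dimension is
#' 2 and whose modified-amplitude dimension spans the full `(1, 2)` range
#' as the multiplier is varied.
#'
#' @param h Peak amplitude (positive; unity default).
#' @param f0 Sampling frequency.
#' @param num_points Number of samples, `>= 2`.
#' @return A [mafdm_ts()].
#' @examples
#' generate_triangular_wave(1, 1, 5)$values  # 0 1 0 1 0
#' @export
generate_triangular_wave <- function(h = 1, f0 = 1, num_points) {
  stopifnot(h > 0, f0 > 0, num_points >= 2)
  mafdm_ts(rep_len(c(0, h), num_points), f0 = f0, label = "triangular")
}

check_triangular_args <- function(h, f0, m, n) {
  if (!(n >= 3 && n %% 2 == 1))
    stop("the coarse level n must be an odd integer >= 3 (even decimation ",
         "collapses the alternation), got n = ", n)
  stopifnot(h > 0, f0 > 0, all(m > 0))
}

#' Closed-form dimension of the amplitude-scaled triangular wave
#'
#' For a zig-zag wave of amplitude `h` sampled at `f0`, decimating to an
#' odd coarse level `n` replaces `n` zig-zag segments by a single
#' diagonal.  The two-point log-log gradient is then exact:
#' \deqn{D_{Hm} = \frac{\log\!\big(f_0 n \sqrt{(mh)^2 + (1/f_0)^2}\big)
#'   - \log\!\big((f_0/n) \sqrt{(mh)^2 + (n/f_0)^2}\big)}{\log n}.}
#' The value lies strictly inside `(1, 2)` for any finite positive `m`,
#' tends to 1 as `m -> 0` (the wave flattens to a line) and to 2 as
#' `m -> Inf` (the wave fills an area); it depends on `m` and `h` only
#' through the product `m h`.
#'
#' @param h Peak amplitude.
#' @param f0 Sampling frequency.
#' @param m Amplitude multiplier (vectorised).
#' @param n Odd integer `>= 3`: the coarse decimation level.
#' @return The dimension(s), same length as `m`.
#' @examples
#' closed_form_dimension(h = 1, f0 = 1, m = 1, n = 3)   # 1.26762
#' closed_form_dimension(h = 1, f0 = 1, m = 1e9, n = 3) # 2
#' @export
closed_form_dimension <- function(h = 1, f0 = 1, m = 1, n = 3) {
  check_triangular_args(h, f0, m, n)
  mh2 <- (m * h)^2
  (log(f0 * n * sqrt(mh2 + (1 / f0)^2)) -
     log((f0 / n) * sqrt(mh2 + (n / f0)^2))) / log(n)
}

#' Analytic asymptotes of the triangular m-spectrum
#'
#' The limits of [closed_form_dimension()] as the multiplier tends to 0
#' and to infinity: 1 (a straight line) and 2 (a filled area).  Every
#' finite positive multiplier yields a dimension strictly between them.
#'
#' @return Named numeric vector `c(low = 1, high = 2)`.
#' @export
triangular_asymptotes <- function() c(low = 1, high = 2)

#' Closed-form m-spectrum of the triangular wave
#'
#' [closed_form_dimension()] evaluated over a grid of multipliers: a
#' non-decreasing sigmoid in `log m` running from 1 to 2, which steepens
#' with `n` and shifts by one decade in `m` per decade in `h` (only the
#' product `m h` matters).
#'
#' @inheritParams closed_form_dimension
#' @param m_grid Increasing vector of positive multipliers (log-spaced
#'   recommended, see [m_log_grid()]).
#' @return A data frame with columns `m` and `D`.
#' @export
closed_form_spectrum <- function(h = 1, f0 = 1, n = 3, m_grid) {
  stopifnot(all(m_grid > 0), !is.unsorted(m_grid, strictly = TRUE))
  data.frame(m = m_grid, D = closed_form_dimension(h, f0, m_grid, n))
}

#' Log-spaced amplitude-multiplier grid
#'
#' The default optimisation grid: `10^-4` to `10^4` with 9 points per
#' decade, wide enough to bracket the optimal multiplier of typical
#' dimensionless biomedical signals with margin.
#'
#' @param lo,hi Grid end points (positive).
#' @param per_decade Points per decade.
#' @return Increasing numeric vector including both end points' decades.
#' @export
m_log_grid <- function(lo = 1e-4, hi = 1e4, per_decade = 9) {
  stopifnot(lo > 0, hi > lo, per_decade >= 1)
  10^seq(log10(lo), log10(hi), by = 1 / per_decade)
}
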