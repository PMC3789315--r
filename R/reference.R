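# Comparison estimators: the mono-dimensional (Higuchi-principle)
# estimator, which sums the amplitude differential only, and
# multiresolution box counting (MRBC), which makes the amplitude-to-time
# ratio integer with a ceiling function.  Both share the MAFDM windowed
# phase-averaging scheme so that all three methods are compared on
# identical windows.

# Scalar windowed, phase-averaged sum of a per-step quantity; mirrors
# windowed_relative_length() for an arbitrary step kind.
windowed_step_sum <- function(values, f0, j, w, n, edge_policy, kind) {
  N <- length(values)
  if (n > w) stop("level n = ", n, " exceeds window width w = ", w)
  S <- step_lengths(values, n, f0, m = 1, kind = kind)
  if (edge_policy == "full_context") {
    miss_left <- max(0L, n - j)
    miss_right <- max(0L, j + w + n - 1L - N)
    if (miss_left > 0L || miss_right > 0L)
      stop(sprintf(paste0("insufficient context at j = %d, w = %d, n = %d: ",
                          "missing %d sample(s) left, %d right"),
                   j, w, n, miss_left, miss_right))
    sum(edge_kernel(n, w) * S[(j - n + 1L):(j + w - 1L)]) / n
  } else {
    if (j < 1L || j + w > N)
      stop("window [", j, ", ", j + w, "] outside the signal")
    (w / n) * mean(S[j:(j + w - n)])
  }
}

#' Mono-dimensional (amplitude-only) fractal dimension of a window
#'
#' Runs the MAFDM pipeline with the Euclidean segment length replaced by
#' the bare amplitude differential `|y_{i+n} - y_i|`, i.e. the exact
#' `m -> Inf` limit of the modified-amplitude estimator (the constant
#' multiplier cancels in the log-log gradient).  The same fractional
#' boundary weights and phase divisor are used, so the two estimators are
#' directly comparable window by window.
#'
#' A constant decimated signal has zero summed amplitude differential at
#' that level; the estimate is then `NaN` flagged `"zero_length"` — the
#' characteristic pathology of amplitude-only estimators, which assign no
#' length to a flat stretch of signal even though it has extent in time.
#'
#' @param ts A [mafdm_ts()].
#' @param j 1-based window start sample.
#' @param w Window width in intervals.
#' @param levels Decimation levels as in [estimator_config()].
#' @param edge_policy `"full_context"` or `"truncate"`.
#' @return An `fd_estimate` (unclamped: values above 2 are reported
#'   as-is).
#' @examples
#' ramp <- mafdm_ts(seq(0, 1, by = 0.01), f0 = 100)
#' mono_dimensional_dimension(ramp, j = 4, w = 80)$D_Hm  # 1
#' @export
mono_dimensional_dimension <- function(ts, j, w, levels = c(1L, 2L, 4L),
                                       edge_policy = "full_context") {
  stopifnot(inherits(ts, "mafdm_ts"))
  cfg <- estimator_config(levels = levels, w = w, edge_policy = edge_policy)
  S <- vapply(cfg$levels, function(n)
    windowed_step_sum(ts$values, ts$f0, as.integer(j), cfg$w, n,
                      cfg$edge_policy, "mono"), numeric(1L))
  est <- fit_dimension(list(n = cfg$levels, R = S), ts$f0)
  if (est$flag == "degenerate") est$flag <- "zero_length"
  est
}

#' MRBC box count for one decimated step
#'
#' The number of boxes needed to cover the amplitude change `h` between
#' samples `i` and `i + n` of the series decimated to `f0/n`:
#' `N = ceil(|h| / (n/f0))`.  `N` is zero only when the two samples are
#' equal, and any amplitude change smaller than the coarse time step
#' still yields a full box — the two properties that drive MRBC and
#' amplitude-only estimates apart on near-threshold signals.  (The
#' follow-up amplitude-update rule of the original MRBC formulation is
#' sign-ambiguous and not needed for box counting; it is intentionally
#' not implemented.)
#'
#' @inheritParams relative_length_at_level
#' @return A list with elements `n` (level) and `N` (box count,
#'   non-negative integer).
#' @examples
#' ts <- mafdm_ts(c(0, 0.92, 0), f0 = 1)
#' mrbc_boxes(ts, i = 1, n = 1)$N  # ceil(0.92) = 1
#' @export
mrbc_boxes <- function(ts, i, n) {
  stopifnot(inherits(ts, "mafdm_ts"))
  i <- as.integer(i); n <- as.integer(n)
  if (i < 1L || i + n > length(ts$values))
    stop("index out of range: need i + n <= ", length(ts$values))
  h <- ts$values[i + n] - ts$values[i]
  list(n = n, N = as.integer(ceiling(abs(h) / (n / ts$f0))))
}

#' MRBC fractal dimension of a window
#'
#' Sums [mrbc_boxes()] counts over the window at each decimation level
#' (phases averaged with the same boundary scheme as the MAFDM, for
#' comparability) and takes the gradient of `log N` against
#' `log(f0/n)`.  Estimates below 1 are reported unclamped: the ceiling
#' function pins the per-step count at 1 whenever `|h|` is below the
#' coarse time step, which flattens the log-log line and can push the
#' gradient under 1 on low-amplitude signals.
#'
#' @inheritParams mono_dimensional_dimension
#' @return An `fd_estimate`; `NaN` flagged `"zero_length"` if the box
#'   count at any level is zero (flat decimated window).
#' @export
mrbc_dimension <- function(ts, j, w, levels = c(1L, 2L, 4L),
                           edge_policy = "full_context") {
  stopifnot(inherits(ts, "mafdm_ts"))
  cfg <- estimator_config(levels = levels, w = w, edge_policy = edge_policy)
  S <- vapply(cfg$levels, function(n)
    windowed_step_sum(ts$values, ts$f0, as.integer(j), cfg$w, n,
                      cfg$edge_policy, "boxes"), numeric(1L))
  est <- fit_dimension(list(n = cfg$levels, R = S), ts$f0)
  if (est$flag == "degenerate") est$flag <- "zero_length"
  est
}
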