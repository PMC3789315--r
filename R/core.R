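# Core MAFDM machinery: per-step relative lengths, boundary-corrected
# windowed sums at each decimation level, and the log-log gradient D_Hm.

# Per-step quantity at level n for every admissible start index i
# (i = 1 .. N - n).  kind selects the estimator family:
#   "euclid" : R_i = (f0/n) * sqrt(m^2 (y_{i+n}-y_i)^2 + (n/f0)^2)  (MAFDM)
#   "mono"   : R_i = (f0/n) * |y_{i+n}-y_i|        (amplitude-only; the
#              constant multiplier cancels in the log-log gradient)
#   "boxes"  : N_i = ceil(|y_{i+n}-y_i| / (n/f0))  (MRBC box count)
step_lengths <- function(values, n, f0, m = 1, kind = "euclid") {
  N <- length(values)
  if (n >= N) stop("level n = ", n, " needs more than ", n, " samples")
  dy <- values[(1L + n):N] - values[1L:(N - n)]
  switch(kind,
    euclid = (f0 / n) * sqrt(m^2 * dy^2 + (n / f0)^2),
    mono   = (f0 / n) * abs(dy),
    boxes  = ceiling(abs(dy) / (n / f0)),
    stop("unknown step kind: ", kind))
}

# Fractional phase weights of the windowed sum: weight for R_{j-l} and
# R_{j+w-n+l} is (n-l)/n, l = 1..n-1 (the l = n term has weight zero and
# is never fetched); interior terms i = j..j+w-n have weight 1.  Ordered
# by ascending R index j-n+1 .. j+w-1.
edge_kernel <- function(n, w) {
  if (n == 1L) rep(1, w)
  else c(seq_len(n - 1L) / n, rep(1, w - n + 1L), rev(seq_len(n - 1L)) / n)
}

#' Relative length of one Euclidean segment at a decimation level
#'
#' The Euclidean distance between samples `i` and `i + n` of the
#' amplitude-scaled signal, normalised to the coarse time base `n / f0`:
#' `R_i = (f0/n) * sqrt(m^2 (y_{i+n} - y_i)^2 + (n/f0)^2)`.  Being a
#' hypotenuse over its own time base, `R_i >= 1` always, which is what
#' keeps the method well defined on locally constant signals.
#'
#' @param ts A [mafdm_ts()].
#' @param i 1-based start index; requires `i + n <= length(ts)`.
#' @param n Decimation level (positive integer).
#' @param m Positive amplitude multiplier.
#' @return The relative length, a scalar `>= 1`.
#' @examples
#' ts <- mafdm_ts(c(0, 1, 0, 1), f0 = 1)
#' relative_length_at_level(ts, i = 1, n = 1, m = 1)  # sqrt(2)
#' @export
relative_length_at_level <- function(ts, i, n, m = 1) {
  stopifnot(inherits(ts, "mafdm_ts"))
  if (!is.numeric(m) || m <= 0) stop("'m' must be positive")
  n <- as.integer(n); i <- as.integer(i)
  if (i < 1L || i + n > length(ts$values))
    stop("index out of range: need 1 <= i and i + n <= ", length(ts$values),
         ", got i = ", i, ", n = ", n)
  dy <- ts$values[i + n] - ts$values[i]
  (ts$f0 / n) * sqrt(m^2 * dy^2 + (n / ts$f0)^2)
}

#' Boundary-corrected windowed relative length at one level
#'
#' Sums the relative lengths over a window of `w` intervals starting at
#' sample `j`, averaging the `n` decimation phases.  Interior segments
#' (`i = j .. j+w-n`) enter with weight 1; the partial segments that the
#' coarse phases would otherwise lose at the window edges enter with
#' fractional weights `(n-l)/n` from `n - 1` samples of context on each
#' side; the total is divided by the number of phases `n`.  On a constant
#' signal every level returns exactly `w / n`.
#'
#' Under `edge_policy = "truncate"` only samples inside `[j, j + w]` are
#' used: the fractional boundary terms are dropped and the remaining
#' weights renormalised, so the value is `(w/n)` times the mean interior
#' relative length (still exactly `w / n` on a constant signal).
#'
#' @inheritParams relative_length_at_level
#' @param j 1-based start sample of the window.
#' @param w Window width in intervals.
#' @param edge_policy `"full_context"` or `"truncate"`.
#' @return The windowed relative length, a positive scalar.
#' @export
windowed_relative_length <- function(ts, j, w, n, m = 1,
                                     edge_policy = "full_context") {
  stopifnot(inherits(ts, "mafdm_ts"))
  j <- as.integer(j); w <- as.integer(w); n <- as.integer(n)
  N <- length(ts$values)
  if (n > w) stop("level n = ", n, " exceeds window width w = ", w)
  if (edge_policy == "full_context") {
    miss_left <- max(0L, n - j)
    miss_right <- max(0L, j + w + n - 1L - N)
    if (miss_left > 0L || miss_right > 0L)
      stop(sprintf(paste0("insufficient context for full_context at j = %d, ",
                          "w = %d, n = %d: missing %d sample(s) on the left ",
                          "and %d on the right"),
                   j, w, n, miss_left, miss_right))
    R <- step_lengths(ts$values, n, ts$f0, m, "euclid")
    sum(edge_kernel(n, w) * R[(j - n + 1L):(j + w - 1L)]) / n
  } else if (edge_policy == "truncate") {
    if (j < 1L || j + w > N)
      stop("window [", j, ", ", j + w, "] outside the signal")
    R <- step_lengths(ts$values, n, ts$f0, m, "euclid")
    (w / n) * mean(R[j:(j + w - n)])
  } else stop("unknown edge_policy: ", edge_policy)
}

#' Fit the fractal dimension from windowed relative lengths
#'
#' Ordinary least squares of `log R` on `log(f0 / n)` over the levels:
#' the gradient is the dimension `D_Hm`, together with the intercept `I`
#' and the signed Pearson correlation `r` of the fit (the quality-of-fit
#' check of the method).  The base of the logarithm does not affect the
#' gradient; natural logarithms are used.
#'
#' Estimates are never clamped to `[1, 2]`: out-of-range gradients are a
#' diagnostic in their own right (amplitude-only estimators can exceed 2
#' and box counting can drop below 1 on near-threshold signals).  A
#' non-positive windowed length (the zero-amplitude pathology of
#' amplitude-only estimators) yields an `NaN` estimate flagged
#' `"degenerate"` rather than an error, so sliding series stay aligned.
#'
#' @param points A data frame (or list) with components `n` (levels) and
#'   `R` (windowed relative lengths), at least two distinct levels.
#' @param f0 Sampling frequency of the underlying series.
#' @return An object of class `fd_estimate`: list with `D_Hm`,
#'   `intercept`, `r`, `levels_used`, `flag` (`"ok"`, `"degenerate"` or
#'   `"low_quality"`).
#' @examples
#' fit_dimension(list(n = c(1, 2, 4), R = c(100, 50, 25)), f0 = 1)$D_Hm  # 1
#' @export
fit_dimension <- function(points, f0) {
  n <- as.numeric(points$n)
  R <- as.numeric(points$R)
  if (length(n) < 2L || length(unique(n)) < 2L)
    stop("at least two distinct levels are required for the log-log fit")
  if (length(R) != length(n)) stop("'n' and 'R' must have equal length")
  if (any(!is.finite(R)) || any(R <= 0))
    return(structure(list(D_Hm = NaN, intercept = NaN, r = NaN,
                          levels_used = n, flag = "degenerate"),
                     class = "fd_estimate"))
  lx <- log(f0 / n)
  ly <- log(R)
  cx <- lx - mean(lx)
  slope <- sum(cx * ly) / sum(cx^2)
  intercept <- mean(ly) - slope * mean(lx)
  sy <- sum((ly - mean(ly))^2)
  r <- if (sy == 0) NA_real_ else sum(cx * ly) / sqrt(sum(cx^2) * sy)
  structure(list(D_Hm = slope, intercept = intercept, r = r,
                 levels_used = n, flag = "ok"),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> D_Hm = %.6g, I = %.4g, r = %.6g [%s]\n",
              x$D_Hm, x$intercept, x$r, x$flag))
  invisible(x)
}

#' Fractal dimension of one window
#'
#' Composes [windowed_relative_length()] over the configured levels and
#' [fit_dimension()] into a single windowed estimate.  If the squared fit
#' correlation falls below `qc_min_correlation^2` the estimate is flagged
#' `"low_quality"` but still returned.
#'
#' @param ts A [mafdm_ts()].
#' @param j 1-based start sample of the window.
#' @param config An [estimator_config()].
#' @return An `fd_estimate`.
#' @examples
#' ts <- mafdm_ts(rep(c(0, 1), 20), f0 = 1)
#' window_dimension(ts, j = 4, estimator_config(levels = c(1, 3), w = 12))
#' @export
window_dimension <- function(ts, j, config) {
  stopifnot(inherits(config, "mafdm_config"))
  R <- vapply(config$levels, function(n)
    windowed_relative_length(ts, j, config$w, n, config$m,
                             config$edge_policy), numeric(1L))
  est <- fit_dimension(list(n = config$levels, R = R), ts$f0)
  if (est$flag == "ok" && config$qc_min_correlation > 0 &&
      (!is.finite(est$r) || est$r^2 < config$qc_min_correlation^2))
    est$flag <- "low_quality"
  est
}

#' Whole-signal fractal dimension
#'
#' One estimate over all intervals of the series (`w = length - 1`) with
#' the truncate edge policy, as used by the accuracy benchmark.
#'
#' @param ts A [mafdm_ts()].
#' @param m Amplitude multiplier.
#' @param levels Decimation levels.
#' @return An `fd_estimate`.
#' @export
whole_signal_dimension <- function(ts, m = 1, levels = c(1L, 2L, 4L)) {
  w <- length(ts$values) - 1L
  cfg <- estimator_config(m = m, levels = levels, w = w,
                          edge_policy = "truncate")
  window_dimension(ts, 1L, cfg)
}

# Windowed sums at every valid start j in one vectorised pass.
# Returns list(j = starts, R = matrix windows x levels).
rolling_windowed_sums <- function(values, f0, m, config, kind = "euclid") {
  N <- length(values)
  w <- config$w
  nmax <- max(config$levels)
  if (config$edge_policy == "full_context") {
    j <- seq.int(nmax, N - w - nmax + 1L)
  } else {
    j <- seq.int(1L, N - w)
  }
  if (length(j) < 1L || j[length(j)] < j[1L])
    stop("signal of ", N, " samples is shorter than one window (w = ", w,
         if (config$edge_policy == "full_context")
           paste0(" plus ", nmax - 1L, " context samples per side") else "",
         ")")
  Rmat <- matrix(NA_real_, nrow = length(j), ncol = length(config$levels))
  for (k in seq_along(config$levels)) {
    n <- config$levels[k]
    R <- step_lengths(values, n, f0, m, kind)
    if (config$edge_policy == "full_context") {
      kern <- edge_kernel(n, w)
      # filter(..., sides = 1): out[t] = sum_{u} kern[u] * R[t - K + u],
      # K = kernel length; window start j corresponds to t = j + w - 1.
      conv <- stats::filter(R, rev(kern), method = "convolution", sides = 1)
      Rmat[, k] <- as.numeric(conv)[j + w - 1L] / n
    } else {
      width <- w - n + 1L
      conv <- stats::filter(R, rep(1, width), method = "convolution",
                            sides = 1)
      Rmat[, k] <- (w / n) * as.numeric(conv)[j + w - n] / width
    }
  }
  list(j = j, R = Rmat)
}

#' Sliding-window fractal dimension series
#'
#' Evaluates [window_dimension()] at every valid window start with a step
#' of one sample and assigns each estimate to the window's centre sample
#' `j + floor(w/2)`.  Computed in a single vectorised pass (rolling
#' weighted sums per level, then a closed-form least-squares gradient
#' across levels per window); identical to calling [window_dimension()]
#' window by window.
#'
#' @param ts A [mafdm_ts()].
#' @param config An [estimator_config()].
#' @param method `"mafdm"` (default) for the Euclidean relative-length
#'   estimator; `"mono"` or `"mrbc"` run the comparison estimators of
#'   [mono_dimensional_dimension()] / [mrbc_dimension()] over the same
#'   windows (the multiplier in `config` is then ignored).
#' @return An object of class `fd_series`: a data frame with columns
#'   `center_index`, `center_time`, `D_Hm`, `intercept`, `r`, `flag`,
#'   with the config attached as attribute `"config"`.
#' @examples
#' ts <- mafdm_ts(rep(0.5, 300), f0 = 100)
#' fd <- sliding_dimension(ts, estimator_config(w = 100))
#' all(abs(fd$D_Hm - 1) < 1e-9)
#' @export
sliding_dimension <- function(ts, config,
                              method = c("mafdm", "mono", "mrbc")) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "mafdm_ts"), inherits(config, "mafdm_config"))
  kind <- c(mafdm = "euclid", mono = "mono", mrbc = "boxes")[[method]]
  rs <- rolling_windowed_sums(ts$values, ts$f0, config$m, config, kind)
  out <- fit_dimension_rows(rs$R, config$levels, ts$f0,
                            config$qc_min_correlation)
  if (method != "mafdm")
    out$flag[out$flag == "degenerate"] <- "zero_length"
  center <- rs$j + config$w %/% 2L
  res <- data.frame(center_index = center,
                    center_time = (center - 1L) / ts$f0,
                    D_Hm = out$D_Hm, intercept = out$intercept, r = out$r,
                    flag = out$flag, stringsAsFactors = FALSE)
  attr(res, "config") <- config
  attr(res, "start_index") <- rs$j
  class(res) <- c("fd_series", "data.frame")
  res
}

# Row-wise log-log OLS across levels for a matrix of windowed sums.
fit_dimension_rows <- function(Rmat, levels, f0, qc_min_correlation = 0) {
  lx <- log(f0 / levels)
  cx <- lx - mean(lx)
  sxx <- sum(cx^2)
  bad <- rowSums(!is.finite(Rmat) | Rmat <= 0) > 0L
  LY <- log(pmax(Rmat, .Machine$double.xmin))
  slope <- as.numeric(LY %*% cx) / sxx
  my <- rowMeans(LY)
  intercept <- my - slope * mean(lx)
  sy <- rowSums((LY - my)^2)
  r <- ifelse(sy > 0, as.numeric(LY %*% cx) / sqrt(sxx * sy), NA_real_)
  flag <- rep("ok", nrow(Rmat))
  if (qc_min_correlation > 0)
    flag[is.na(r) | r^2 < qc_min_correlation^2] <- "low_quality"
  slope[bad] <- NaN; intercept[bad] <- NaN; r[bad] <- NaN
  flag[bad] <- "degenerate"
  list(D_Hm = slope, intercept = intercept, r = r, flag = flag)
}

#' @export
print.fd_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<fd_series> %d windows, m = %g, w = %d, levels = {%s}\n",
              nrow(x), cfg$m, cfg$w, paste(cfg$levels, collapse = ",")))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  invisible(x)
}
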