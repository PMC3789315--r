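#' Configuration of a MAFDM run
#'
#' Bundles everything that determines a dimension estimate: the amplitude
#' multiplier `m`, the decimation levels `n` (simulated sampling
#' frequencies `f0/n`), the window width `w` in sampling intervals, the
#' edge policy for the boundary-corrected windowed sums, and an optional
#' quality threshold on the log-log fit correlation.
#'
#' Levels must start at 1 and be log-equidistant (constant ratio, e.g.
#' `1, 2, 4, 8` or `1, 3, 9`), never arithmetic like `1, 2, 3, 4, 5`,
#' which would weight the fit towards the lower frequencies.  The window
#' must span at least four coarse intervals at the coarsest level
#' (`w >= 4 * max(levels)`).
#'
#' @param m Positive amplitude multiplier applied to the dimensionless
#'   amplitude before measuring Euclidean segment lengths.  `m -> 0`
#'   flattens the signal towards a line (dimension 1); `m -> Inf`
#'   recovers the mono-dimensional (Higuchi) dimension of the original
#'   signal.
#' @param levels Strictly increasing positive integers, first equal to 1,
#'   constant ratio.
#' @param w Window width in sampling intervals (a window spans `w + 1`
#'   samples), integer `>= 4 * max(levels)`.
#' @param edge_policy `"full_context"` uses the fractional boundary terms
#'   reaching `max(levels) - 1` samples beyond each window edge;
#'   `"truncate"` uses only samples inside the window and renormalises
#'   the phase weights.
#' @param qc_min_correlation Threshold in `[0, 1]`; estimates whose
#'   squared fit correlation falls below its square are flagged
#'   `"low_quality"` but still returned.  Default 0 (report-only).
#'
#' @return An object of class `mafdm_config`.
#' @examples
#' estimator_config(m = 1, levels = c(1, 2, 4), w = 100)
#' @export
estimator_config <- function(m = 1, levels = c(1L, 2L, 4L), w = 100L,
                             edge_policy = c("full_context", "truncate"),
                             qc_min_correlation = 0) {
  edge_policy <- match.arg(edge_policy)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("'m' must be a single positive finite number")
  levels <- as.numeric(levels)
  if (length(levels) < 2L) stop("at least 2 decimation levels are required")
  if (any(levels != round(levels)) || any(levels < 1))
    stop("levels must be positive integers")
  if (levels[1L] != 1) stop("the first level must be 1 (the original f0)")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  ratios <- levels[-1L] / levels[-length(levels)]
  if (max(ratios) - min(ratios) > 1e-9 * max(ratios))
    stop("levels must be log-equidistant (constant ratio, e.g. 1,2,4,8 ",
         "or 1,3,9), not arithmetic")
  w <- as.integer(w)
  if (w < 4L * max(levels))
    stop("window width w = ", w, " must be >= 4 * max(levels) = ",
         4L * max(levels))
  if (qc_min_correlation < 0 || qc_min_correlation > 1)
    stop("'qc_min_correlation' must lie in [0, 1]")
  structure(list(m = m, levels = as.integer(levels), w = w,
                 edge_policy = edge_policy,
                 qc_min_correlation = qc_min_correlation),
            class = "mafdm_config")
}

#' @export
print.mafdm_config <- function(x, ...) {
  cat(sprintf("<mafdm_config> m = %g, levels = {%s}, w = %d, edge = %s\n",
              x$m, paste(x$levels, collapse = ","), x$w, x$edge_policy))
  invisible(x)
}
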