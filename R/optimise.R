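# Amplitude-multiplier optimisation: compute the m-dependent dimension
# spectra of labelled signal segments and select the multiplier that
# best separates the segment classes, by one of three criteria
# (max - min range, max - average, or the (max-1)/(avg-1) ratio with a
# plateau-onset rule).

#' Define labelled signal segments
#'
#' Validates a segment table for [m_spectrum()].  Indices are 1-based and
#' half-open: `start` inclusive, `end` exclusive.
#'
#' @param label Character labels, unique.
#' @param start,end Integer sample indices, `end > start`.
#' @param role One of `"min_event"`, `"max_event"`, `"whole_signal"`,
#'   `"rare_event"` per segment.
#' @param signal Index into the signal list (default 1).
#' @return A data frame with the validated columns.
#' @export
segment_spec <- function(label, start, end,
                         role = "max_event", signal = 1L) {
  df <- data.frame(label = as.character(label), start = as.integer(start),
                   end = as.integer(end), role = as.character(role),
                   signal = as.integer(signal), stringsAsFactors = FALSE)
  if (anyDuplicated(df$label)) stop("segment labels must be unique")
  if (any(df$end <= df$start)) stop("segment end must exceed start")
  ok_roles <- c("min_event", "max_event", "whole_signal", "rare_event")
  bad <- setdiff(df$role, ok_roles)
  if (length(bad)) stop("unknown segment role(s): ",
                        paste(bad, collapse = ", "))
  df
}

#' m-spectrum of segment mean dimensions
#'
#' For every multiplier on the grid, runs [sliding_dimension()] over each
#' signal and averages the windowed estimates whose centre falls inside
#' each segment (`whole_signal` segments average over the entire series).
#' The same multiplier is applied to every signal at each grid point —
#' dimensions of modified signals are only comparable at equal `m` — and
#' the same window width is carried inside the result so the final
#' analysis is guaranteed to run under the configuration the optimum was
#' determined for.
#'
#' Degenerate (flagged) window estimates are excluded from the means and
#' counted in the `excluded` matrix; a segment with zero valid windows at
#' any grid point is an error.
#'
#' @param ts_list A [mafdm_ts()] or list of them.
#' @param segments A [segment_spec()] table.
#' @param base_config An [estimator_config()]; its `m` is ignored.
#' @param m_grid Increasing positive multipliers, see [m_log_grid()].
#' @return An object of class `m_spectrum`: list with `m_grid`, `curves`
#'   (matrix, one column per segment label), `segments`, `config`,
#'   `excluded`.
#' @export
m_spectrum <- function(ts_list, segments, base_config,
                       m_grid = m_log_grid()) {
  if (inherits(ts_list, "mafdm_ts")) ts_list <- list(ts_list)
  stopifnot(all(vapply(ts_list, inherits, logical(1), "mafdm_ts")),
            inherits(base_config, "mafdm_config"),
            all(m_grid > 0), !is.unsorted(m_grid, strictly = TRUE))
  if (max(segments$signal) > length(ts_list))
    stop("segment refers to signal ", max(segments$signal),
         " but only ", length(ts_list), " signal(s) given")
  curves <- matrix(NA_real_, nrow = length(m_grid),
                   ncol = nrow(segments),
                   dimnames = list(NULL, segments$label))
  excluded <- curves
  for (gi in seq_along(m_grid)) {
    cfg <- estimator_config(m = m_grid[gi], levels = base_config$levels,
                            w = base_config$w,
                            edge_policy = base_config$edge_policy,
                            qc_min_correlation =
                              base_config$qc_min_correlation)
    fd_by_signal <- lapply(ts_list, sliding_dimension, config = cfg)
    for (si in seq_len(nrow(segments))) {
      fd <- fd_by_signal[[segments$signal[si]]]
      inside <- if (segments$role[si] == "whole_signal") {
        rep(TRUE, nrow(fd))
      } else {
        fd$center_index >= segments$start[si] &
          fd$center_index < segments$end[si]
      }
      valid <- inside & fd$flag != "degenerate" & is.finite(fd$D_Hm)
      if (!any(valid))
        stop("segment '", segments$label[si], "' has no valid window at ",
             "m = ", m_grid[gi])
      curves[gi, si] <- mean(fd$D_Hm[valid])
      excluded[gi, si] <- sum(inside) - sum(valid)
    }
  }
  structure(list(m_grid = m_grid, curves = curves, segments = segments,
                 config = base_config, excluded = excluded),
            class = "m_spectrum")
}

#' @export
print.m_spectrum <- function(x, ...) {
  cat(sprintf("<m_spectrum> %d grid points in [%g, %g], segments: %s\n",
              length(x$m_grid), min(x$m_grid), max(x$m_grid),
              paste(colnames(x$curves), collapse = ", ")))
  invisible(x)
}

#' Tidy view of an m-spectrum
#'
#' @param x An `m_spectrum`.
#' @param ... Unused.
#' @return A long data frame with columns `m`, `label`, `mean_D`.
#' @export
as.data.frame.m_spectrum <- function(x, ...) {
  data.frame(m = rep(x$m_grid, ncol(x$curves)),
             label = rep(colnames(x$curves), each = length(x$m_grid)),
             mean_D = as.vector(x$curves), stringsAsFactors = FALSE)
}

spectrum_curve <- function(spectrum, label) {
  if (!label %in% colnames(spectrum$curves))
    stop("no segment labelled '", label, "' in the spectrum")
  spectrum$curves[, label]
}

whole_signal_label <- function(spectrum) {
  lab <- spectrum$segments$label[spectrum$segments$role == "whole_signal"]
  if (length(lab) < 1L)
    stop("this criterion needs a segment with role 'whole_signal'")
  lab[1L]
}

opt_result <- function(criterion, m_opt, m_grid, objective, notes = "") {
  structure(list(criterion = criterion, m_opt = m_opt,
                 objective_curve = data.frame(m = m_grid,
                                              value = objective),
                 notes = notes),
            class = "mafdm_opt")
}

#' @export
print.mafdm_opt <- function(x, ...) {
  cat(sprintf("<mafdm_opt> criterion = %s, m_opt = %g%s\n", x$criterion,
              x$m_opt, if (nzchar(x$notes)) paste0(" (", x$notes, ")")
              else ""))
  invisible(x)
}

#' Optimal multiplier by the max - min range criterion
#'
#' The objective is the signed difference between the designated maximal
#' and minimal segment curves, `Delta D_Hm(m) = D^max(m) - D^min(m)`;
#' the optimum is the grid multiplier maximising it, ties broken towards
#' smaller `m` (the smaller the multiplier, the stronger the filter
#' effect).  The difference is kept signed because the two curves can
#' intersect: beyond the crossing the nominal "maximal" segment actually
#' has the lower dimension, which the result's `notes` report.
#'
#' @param spectrum An [m_spectrum()].
#' @param min_label,max_label Segment labels to separate.
#' @return A `mafdm_opt` with the objective curve and `m_opt`.
#' @export
optimise_range <- function(spectrum, min_label, max_label) {
  objective <- spectrum_curve(spectrum, max_label) -
    spectrum_curve(spectrum, min_label)
  if (all(objective == 0))
    stop("segments indistinguishable: the range objective is ",
         "identically zero")
  i <- which.max(objective)
  notes <- if (any(objective < 0))
    "curves intersect: objective changes sign over the grid" else ""
  opt_result("range", spectrum$m_grid[i], spectrum$m_grid,
             unname(objective), notes)
}

#' Optimal multiplier by the max - average criterion
#'
#' Objective `D^max(m) - D^avg(m)`, where the average curve is the
#' whole-signal segment mean: the criterion for a rare event embedded in
#' a long signal whose dimension it barely influences.
#'
#' @param spectrum An [m_spectrum()].
#' @param max_label Label of the rare-event segment.
#' @param avg_label Label of the average curve; defaults to the segment
#'   with role `"whole_signal"`.
#' @return A `mafdm_opt`.
#' @export
optimise_max_vs_avg <- function(spectrum, max_label, avg_label = NULL) {
  if (is.null(avg_label)) avg_label <- whole_signal_label(spectrum)
  objective <- spectrum_curve(spectrum, max_label) -
    spectrum_curve(spectrum, avg_label)
  if (all(objective == 0))
    stop("segments indistinguishable: the max-vs-average objective is ",
         "identically zero")
  i <- which.max(objective)
  opt_result("max_vs_avg", spectrum$m_grid[i], spectrum$m_grid,
             unname(objective))
}

#' Optimal multiplier by the dimension-ratio criterion
#'
#' Objective `(D^max(m) - 1) / (D^avg(m) - 1)`, which suppresses the
#' average dimension and accentuates the event.  The ratio typically
#' increases as `m` decreases and finally plateaus at small `m`; the
#' optimum is placed at the onset of that plateau: the smallest grid
#' multiplier whose ratio reaches `(1 - plateau_tolerance)` times the
#' grid maximum.  Grid points where `D^avg(m) - 1 <= 1e-6` would let the
#' ratio blow up; they are masked and reported in `notes`.
#'
#' @inheritParams optimise_max_vs_avg
#' @param plateau_tolerance Relative tolerance defining the plateau
#'   onset, default 0.02.
#' @return A `mafdm_opt`; masked grid points carry `NA` in the objective
#'   curve.
#' @export
optimise_ratio <- function(spectrum, max_label, avg_label = NULL,
                           plateau_tolerance = 0.02) {
  if (is.null(avg_label)) avg_label <- whole_signal_label(spectrum)
  dmax <- spectrum_curve(spectrum, max_label)
  davg <- spectrum_curve(spectrum, avg_label)
  ok <- (davg - 1) > 1e-6
  if (!any(ok))
    stop("the average dimension never exceeds 1 + 1e-6: the ratio ",
         "criterion is undefined on this grid")
  ratio <- ifelse(ok, (dmax - 1) / (davg - 1), NA_real_)
  plateau <- max(ratio, na.rm = TRUE)
  hit <- which(!is.na(ratio) &
                 ratio >= (1 - plateau_tolerance) * plateau)
  i <- hit[1L]
  notes <- if (all(ok)) "" else
    sprintf("%d grid point(s) masked where D_avg - 1 <= 1e-6",
            sum(!ok))
  opt_result("ratio", spectrum$m_grid[i], spectrum$m_grid,
             unname(ratio), notes)
}

#' Combine pairwise optimal multipliers
#'
#' When more than two signal classes are compared, pairwise range optima
#' can be combined into a single multiplier as their mean in log space
#' (the natural scale of the m-grid).  A convention, not an assertion of
#' the method.
#'
#' @param m_values Positive multipliers (e.g. pairwise `m_opt` values).
#' @return Their geometric mean.
#' @export
mean_log_m <- function(m_values) {
  stopifnot(all(m_values > 0))
  exp(mean(log(m_values)))
}
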