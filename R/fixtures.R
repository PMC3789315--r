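# Synthetic event-embedded fixtures: a baseline with embedded bursts and
# ground-truth segment labels, emulating the structure of case-study
# recordings (long quiet stretches punctuated by short high-complexity
# events) for exercising the optimisation workflow end to end.

#' Specify a synthetic fixture
#'
#' @param baseline List: `kind` (`"flat"` or `"low_noise"`), `length`
#'   (samples), `noise_sd` (for `"low_noise"`), `level` (offset,
#'   default 0).
#' @param events List of event lists: `kind` (`"alternating"`, `"cndf"`
#'   or `"amplitude_burst"`), `start` (1-based sample), `length`
#'   (samples), `amplitude`, optional `role` (default `"max_event"`),
#'   optional `params` (for `"cndf"`: `family`, `target_D`).
#' @param f0 Sampling frequency of the fixture.
#' @param seed Integer seed; identical specs give identical series.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(baseline = list(kind = "flat", length = 1000L,
                                         noise_sd = 0, level = 0),
                         events = list(), f0 = 1, seed = 1) {
  baseline$kind <- match.arg(baseline$kind, c("flat", "low_noise"))
  if (is.null(baseline$noise_sd)) baseline$noise_sd <- 0
  if (is.null(baseline$level)) baseline$level <- 0
  stopifnot(baseline$length >= 2, f0 > 0)
  for (ev in events) {
    stopifnot(!is.null(ev$kind), !is.null(ev$start), !is.null(ev$length),
              !is.null(ev$amplitude))
    if (ev$start < 1 || ev$start + ev$length - 1 > baseline$length)
      stop("event [", ev$start, ", ", ev$start + ev$length - 1,
           "] outside the baseline of length ", baseline$length)
  }
  if (length(events) > 1L) {
    iv <- t(vapply(events, function(e)
      c(e$start, e$start + e$length - 1), numeric(2L)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      stop("events overlap")
  }
  structure(list(baseline = baseline, events = events, f0 = f0,
                 seed = as.integer(seed)), class = "fixture_spec")
}

#' Generate a synthetic event-embedded fixture
#'
#' Builds the baseline (constant or low-amplitude Gaussian noise),
#' replaces the event stretches with the requested waveforms, and
#' returns both the series and ground-truth segments: one `max_event`
#' (or as specified) segment per event, the longest event-free stretch
#' as `min_event` baseline, and the full series as `whole_signal`.
#'
#' Event kinds: `"alternating"` writes an exact zig-zag `0, A, 0, A, ...`
#' (so burst windows obey the triangular-wave closed form),
#' `"amplitude_burst"` writes Gaussian noise with standard deviation `A`,
#' `"cndf"` writes a CNDF stretch scaled by `A`
#' (`params = list(family=, target_D=)`).
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `ts` (a [mafdm_ts()]) and `segments`
#'   (a [segment_spec()] table).
#' @examples
#' fx <- generate_fixture(fixture_spec(
#'   baseline = list(kind = "flat", length = 400),
#'   events = list(list(kind = "alternating", start = 201, length = 100,
#'                      amplitude = 1))))
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$baseline$length
  values <- with_seed(spec$seed, {
    y <- if (spec$baseline$kind == "flat") rep(spec$baseline$level, n)
         else spec$baseline$level +
           stats::rnorm(n, 0, spec$baseline$noise_sd)
    for (ev in spec$events) {
      idx <- seq.int(ev$start, ev$start + ev$length - 1L)
      y[idx] <- switch(ev$kind,
        alternating = rep_len(c(0, ev$amplitude), ev$length),
        amplitude_burst = stats::rnorm(ev$length, 0, ev$amplitude),
        cndf = {
          p <- ev$params
          seg <- cndf_signal(p$family, p$target_D, fs = spec$f0,
                             duration = ev$length / spec$f0,
                             seed = spec$seed)
          ev$amplitude * seg$values[seq_len(ev$length)]
        },
        stop("unknown event kind: ", ev$kind))
    }
    y
  })
  ts <- mafdm_ts(values, f0 = spec$f0, label = "fixture")
  segs <- list()
  for (k in seq_along(spec$events)) {
    ev <- spec$events[[k]]
    segs[[k]] <- segment_spec(
      label = if (!is.null(ev$label)) ev$label else paste0("event_", k),
      start = ev$start, end = ev$start + ev$length,
      role = if (!is.null(ev$role)) ev$role else "max_event")
  }
  # longest event-free stretch is the baseline reference segment
  covered <- rep(FALSE, n)
  for (ev in spec$events)
    covered[seq.int(ev$start, ev$start + ev$length - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  free <- which(!r$values)
  if (length(free)) {
    j <- free[which.max(r$lengths[free])]
    segs[[length(segs) + 1L]] <- segment_spec("baseline", starts[j],
                                              ends[j] + 1L,
                                              role = "min_event")
  }
  segs[[length(segs) + 1L]] <- segment_spec("whole", 1L, n + 1L,
                                            role = "whole_signal")
  list(ts = ts, segments = do.call(rbind, segs))
}
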