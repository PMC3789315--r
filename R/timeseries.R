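#' Construct a dimensionless time series
#'
#' The universal input object of the package: an ordered vector of
#' dimensionless amplitude values sampled at a constant, dimensionless
#' sampling frequency `f0` (samples per unit time, so the time step is
#' `1/f0`).  All estimators in the package operate on this type; unit
#' handling happens once, in [normalise()].
#'
#' @param values Numeric vector of dimensionless amplitudes, length >= 2,
#'   all finite.
#' @param f0 Positive dimensionless sampling frequency.
#' @param label Optional free-text label carried through to outputs.
#'
#' @return An object of class `mafdm_ts`: a list with elements `values`,
#'   `f0` and `label`.
#' @examples
#' ts <- mafdm_ts(sin(seq(0, 2 * pi, length.out = 100)), f0 = 100)
#' ts
#' @export
mafdm_ts <- function(values, f0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 samples, got ", length(values))
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite value at sample index ", bad[1L])
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("'f0' must be a single positive finite number")
  structure(list(values = values, f0 = as.numeric(f0),
                 label = as.character(label)[1L]),
            class = "mafdm_ts")
}

#' @export
print.mafdm_ts <- function(x, ...) {
  cat(sprintf("<mafdm_ts> %d samples, f0 = %g (dt = %g)%s\n",
              length(x$values), x$f0, 1 / x$f0,
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' @export
length.mafdm_ts <- function(x) length(x$values)

#' Normalise a recorded signal to unit amplitude and unit time
#'
#' Divides raw sample values by a chosen unit amplitude and rescales the
#' sampling rate by the chosen unit time, turning a recorded signal
#' (e.g. mV sampled in seconds) into the dimensionless series all
#' estimators expect.  The defaults divide by 1, i.e. take the numbers as
#' already dimensionless: the normalisation exists only to strip units,
#' never to prescale the amplitude (prescaling is what the amplitude
#' multiplier `m` of the estimator is for, and it must be applied
#' identically to every signal that is compared).
#'
#' @param raw_values Numeric vector of recorded samples (with units).
#' @param unit_amplitude Positive scalar: the amplitude that maps to 1.
#' @param unit_time Positive scalar: the time span that maps to 1.
#' @param sampling_rate Positive scalar: samples per `unit_time^-1`
#'   (e.g. Hz when `unit_time` is in seconds).
#' @param label Optional label for the resulting series.
#'
#' @return A [mafdm_ts()] with `values = raw_values / unit_amplitude` and
#'   `f0 = sampling_rate * unit_time`.
#' @examples
#' normalise(c(1, 2, 3), sampling_rate = 100)           # identity, f0 = 100
#' normalise(c(10, 20), unit_amplitude = 10, sampling_rate = 1)
#' @export
normalise <- function(raw_values, unit_amplitude = 1, unit_time = 1,
                      sampling_rate = 1, label = "") {
  if (length(raw_values) == 0L) stop("empty input signal")
  stopifnot(unit_amplitude > 0, unit_time > 0, sampling_rate > 0)
  bad <- which(!is.finite(as.numeric(raw_values)))
  if (length(bad))
    stop("non-finite raw value at sample index ", bad[1L])
  mafdm_ts(as.numeric(raw_values) / unit_amplitude,
           f0 = sampling_rate * unit_time, label = label)
}

#' Read a time series from a delimited text file
#'
#' Accepts either a single value column together with an explicit `f0`,
#' or a time column plus a value column, in which case `f0` is inferred
#' from the median time spacing.  Sampling must be uniform: the maximum
#' relative deviation of the spacing from its median is checked against
#' `tolerance`.
#'
#' @param path Path to a CSV/TSV file.
#' @param value_col Name or index of the value column (default: last
#'   column, or the only column).
#' @param time_col Name or index of the time column, or `NULL` when `f0`
#'   is given.
#' @param f0 Sampling frequency; required when no time column is given.
#' @param sep Field separator; `","` default, use `"\t"` for TSV.
#' @param header Does the file have a header line?
#' @param tolerance Relative tolerance on spacing uniformity.
#' @param label Label for the series; defaults to the file name.
#'
#' @return A [mafdm_ts()].
#' @export
load_timeseries <- function(path, value_col = NULL, time_col = NULL,
                            f0 = NULL, sep = ",", header = TRUE,
                            tolerance = 1e-6, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = header,
                          comment.char = "#", stringsAsFactors = FALSE)
  pick <- function(col) {
    if (is.numeric(col)) df[[col]] else {
      if (!col %in% names(df)) stop("column '", col, "' not in file")
      df[[col]]
    }
  }
  if (is.null(time_col) && is.null(f0) && ncol(df) >= 2L &&
      all(c("t", "y") %in% names(df))) {
    time_col <- "t"; value_col <- "y"
  }
  if (is.null(value_col)) {
    if (ncol(df) == 1L) value_col <- 1L
    else if (!is.null(time_col)) value_col <- setdiff(seq_len(ncol(df)),
      if (is.numeric(time_col)) time_col else match(time_col, names(df)))[1L]
    else value_col <- ncol(df)
  }
  y <- as.numeric(pick(value_col))
  if (anyNA(y)) stop("missing value at row ", which(is.na(y))[1L])
  if (!is.null(time_col)) {
    t <- as.numeric(pick(time_col))
    if (anyNA(t)) stop("missing time stamp at row ", which(is.na(t))[1L])
    dt <- diff(t)
    med <- stats::median(dt)
    if (med <= 0) stop("time column is not strictly increasing")
    dev <- max(abs(dt - med)) / med
    if (dev > tolerance)
      stop(sprintf(paste0("non-uniform sampling: max relative spacing ",
                          "deviation %.3g exceeds tolerance %.3g"),
                   dev, tolerance))
    f0 <- 1 / med
  } else if (is.null(f0)) {
    stop("no time column given: the sampling frequency 'f0' is required")
  }
  mafdm_ts(y, f0 = f0, label = label)
}

#' Write a time series to CSV at full double precision
#'
#' Values are written with 17 significant digits so that a
#' load -> write -> load round trip reproduces them bit-identically.
#'
#' @param ts A [mafdm_ts()].
#' @param path Output file path.
#' @param time_col Write an explicit time column `t` as well?
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, time_col = TRUE) {
  stopifnot(inherits(ts, "mafdm_ts"))
  n <- length(ts$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mafdm_ts f0=%.17g n=%d label=%s",
                     ts$f0, n, ts$label), con)
  if (time_col) {
    writeLines("t,y", con)
    writeLines(sprintf("%.17g,%.17g", (seq_len(n) - 1) / ts$f0, ts$values),
               con)
  } else {
    writeLines("y", con)
    writeLines(sprintf("%.17g", ts$values), con)
  }
  invisible(path)
}
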