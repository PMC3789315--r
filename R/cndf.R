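# Continuous nowhere-differentiable benchmark functions with known
# theoretical dimension: Knopp, Weierstrass cosine,
# Weierstrass-Mandelbrot, and fractional Brownian motion.  These are the
# ground truth for the estimator accuracy benchmark.

default_t_grid <- function(t_grid, fs, duration) {
  if (!is.null(t_grid)) {
    t_grid <- as.numeric(t_grid)
    stopifnot(length(t_grid) >= 2, !is.unsorted(t_grid, strictly = TRUE))
    dt <- diff(t_grid)
    list(t = t_grid, f0 = 1 / stats::median(dt))
  } else {
    # endpoint-inclusive grid 0, 1/fs, ..., duration (the Matlab
    # t = 0:1/fs:T idiom): fs*duration + 1 samples
    n <- round(fs * duration) + 1L
    list(t = (seq_len(n) - 1) / fs, f0 = fs)
  }
}

# distance from x to the nearest integer (triangular wave of period 1)
tri_wave <- function(x) abs(x - floor(x + 0.5))

#' Knopp (Takagi-type) function with prescribed dimension
#'
#' `K(t) = sum_{k=1}^{k_max} a^k <<b^k t>>`, where `<<x>>` is the
#' distance from `x` to the nearest integer and `a = b^D / 4` is derived
#' from the requested Minkowski-Bouligand dimension `D` (which equals the
#' Hausdorff dimension for this strictly self-similar family).  Validity
#' requires `0.5 <= a <= 1`, `b > 1` and `ab >= 1`; with the default
#' `b = 2` this admits exactly `D` in `[1, 2]`.
#'
#' @param t_grid Optional explicit time grid in `[0, 1]`; by default
#'   `duration` seconds at `fs` samples per unit time.
#' @param target_D Requested dimension.
#' @param b Frequency ratio of consecutive terms (`> 1`), default 2.
#' @param k_max Truncation order of the series, default 50.
#' @param fs,duration Sampling grid when `t_grid` is `NULL`.
#' @return A [mafdm_ts()].
#' @examples
#' k <- knopp(target_D = 1.5, fs = 100, duration = 1)
#' @export
knopp <- function(t_grid = NULL, target_D, b = 2, k_max = 50,
                  fs = 1000, duration = 1) {
  a <- b^target_D / 4
  if (b <= 1) stop("constraint violated: b > 1 (b = ", b, ")")
  if (a < 0.5 || a > 1)
    stop(sprintf(paste0("constraint violated: 0.5 <= a <= 1 with ",
                        "a = b^D/4 = %.4g (target_D = %g, b = %g)"),
                 a, target_D, b))
  if (a * b < 1)
    stop(sprintf("constraint violated: ab >= 1 (ab = %.4g)", a * b))
  g <- default_t_grid(t_grid, fs, duration)
  y <- numeric(length(g$t))
  for (k in seq_len(k_max)) y <- y + a^k * tri_wave(b^k * g$t)
  mafdm_ts(y, f0 = g$f0, label = sprintf("knopp D=%g", target_D))
}

#' Weierstrass cosine function with prescribed Hurst exponent
#'
#' `W(t) = sum_{k=0}^{k_max} gamma^{-kH} cos(2 pi gamma^k t)` with
#' `gamma > 1` and Hurst exponent `H` in `(0, 1)`; its graph has
#' dimension `D_H = 2 - H`.
#'
#' @inheritParams knopp
#' @param H Hurst exponent in `(0, 1)` (`H = 2 - D`).
#' @param gamma Frequency ratio (`> 1`), default 5.
#' @return A [mafdm_ts()].
#' @examples
#' w <- weierstrass_cosine(H = 0.5, fs = 1000, duration = 1)
#' @export
weierstrass_cosine <- function(t_grid = NULL, H, gamma = 5, k_max = 50,
                               fs = 1000, duration = 1) {
  if (gamma <= 1) stop("'gamma' must exceed 1")
  if (H <= 0 || H >= 1) stop("Hurst exponent H must lie in (0, 1), got ", H)
  g <- default_t_grid(t_grid, fs, duration)
  y <- numeric(length(g$t))
  for (k in 0:k_max) y <- y + gamma^(-k * H) * cos(2 * pi * gamma^k * g$t)
  mafdm_ts(y, f0 = g$f0, label = sprintf("weierstrass H=%g", H))
}

#' Weierstrass-Mandelbrot function with prescribed Hurst exponent
#'
#' `Wm(t) = sum_{k=-k_range}^{k_range} (1 - cos(b^k t)) / b^{Hk}` with
#' `b > 1` and `H` in `(0, 1)`; dimension `D_H = 2 - H`.  The symmetric
#' truncation at `|k| = k_range` leaves a negative-`k` tail bounded by
#' `(1 - cos x) <= x^2 / 2`, negligible at double precision for the
#' default `b = 1.5`, `k_range = 50`.
#'
#' @inheritParams weierstrass_cosine
#' @param b Frequency ratio (`> 1`), default 1.5.
#' @param k_range Symmetric truncation order, default 50.
#' @return A [mafdm_ts()].
#' @export
weierstrass_mandelbrot <- function(t_grid = NULL, H, b = 1.5, k_range = 50,
                                   fs = 1000, duration = 1) {
  if (b <= 1) stop("'b' must exceed 1")
  if (H <= 0 || H >= 1) stop("Hurst exponent H must lie in (0, 1), got ", H)
  g <- default_t_grid(t_grid, fs, duration)
  y <- numeric(length(g$t))
  for (k in -k_range:k_range) y <- y + (1 - cos(b^k * g$t)) / b^(H * k)
  mafdm_ts(y, f0 = g$f0, label = sprintf("weierstrass-mandelbrot H=%g", H))
}

#' Fractional Brownian motion by circulant embedding
#'
#' Exact-covariance synthesis of a fractional Brownian motion path with
#' Hurst exponent `H` (graph dimension `2 - H`): fractional Gaussian
#' noise is drawn via Davies-Harte circulant embedding of the increment
#' covariance and cumulated, with `B(0) = 0`.  Should the embedding ever
#' fail to be positive semi-definite, the generator falls back to the
#' (slower, equally exact) Hosking recursion with a message.  Increments
#' are scaled so that one unit of time has unit variance,
#' i.e. `E[(B(t+tau) - B(t))^2] = tau^{2H}` in series time.
#'
#' @param H Hurst exponent in `(0, 1)`.
#' @param num_points Number of samples (`>= 16`), including `B(0)`.
#' @param seed Integer seed; identical seeds give identical paths.  The
#'   global RNG state is left untouched.
#' @param fs Sampling frequency; defaults to `num_points - 1` samples per
#'   unit time so the path spans one unit of time.
#' @return A [mafdm_ts()].
#' @examples
#' b <- fractional_brownian(H = 0.5, num_points = 256, seed = 1)
#' b$values[1] == 0
#' @export
fractional_brownian <- function(H, num_points, seed,
                                fs = num_points - 1) {
  if (H <= 0 || H >= 1) stop("Hurst exponent H must lie in (0, 1), got ", H)
  if (num_points < 16) stop("'num_points' must be >= 16")
  n <- num_points - 1L
  inc <- with_seed(seed, {
    x <- fgn_davies_harte(H, n)
    if (is.null(x)) {
      message("circulant embedding not positive semi-definite; ",
              "falling back to Hosking recursion")
      x <- fgn_hosking(H, n)
    }
    x
  })
  inc <- inc * (1 / fs)^H   # unit-time self-affine scaling
  mafdm_ts(c(0, cumsum(inc)), f0 = fs, label = sprintf("fbm H=%g", H))
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Autocovariance of fractional Gaussian noise at lag k (unit variance).
fgn_acov <- function(H, k) {
  k <- abs(k)
  0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

# Davies-Harte sampler: n fGn values, or NULL if the embedding fails.
fgn_davies_harte <- function(H, n) {
  m <- 2L * n
  circ <- fgn_acov(H, c(0:n, (n - 1):1))
  lambda <- Re(stats::fft(circ))
  if (any(lambda < -1e-12 * max(lambda))) return(NULL)
  lambda <- pmax(lambda, 0)
  w <- complex(length.out = m)
  u <- stats::rnorm(m)
  half <- n  # m/2
  w[1] <- sqrt(lambda[1]) * u[1]
  w[half + 1] <- sqrt(lambda[half + 1]) * u[2]
  idx <- seq_len(half - 1L)
  re <- u[2L + idx]
  im <- u[2L + half - 1L + idx]
  w[1L + idx] <- sqrt(lambda[1L + idx] / 2) * complex(real = re,
                                                      imaginary = im)
  w[m + 1L - idx] <- Conj(w[1L + idx])
  Re(stats::fft(w))[seq_len(n)] / sqrt(m)
}

# Hosking (Durbin-Levinson) recursion: exact but O(n^2); fallback only.
fgn_hosking <- function(H, n) {
  g <- fgn_acov(H, 0:n)
  x <- numeric(n)
  phi <- numeric(0)
  v <- g[1]
  x[1] <- stats::rnorm(1) * sqrt(v)
  for (t in seq_len(n - 1)) {
    if (t == 1) {
      phi <- g[2] / g[1]
    } else {
      a <- (g[t + 1] - sum(phi * g[t:2])) / v
      phi <- c(phi - a * rev(phi), a)
    }
    v <- v * (1 - phi[length(phi)]^2)
    x[t + 1] <- sum(phi * x[t:1]) + stats::rnorm(1) * sqrt(v)
  }
  x
}

#' Generate a CNDF benchmark signal from a spec
#'
#' Dispatcher over the four families used by [benchmark_accuracy()].
#'
#' @param family One of `"knopp"`, `"weierstrass"`,
#'   `"weierstrass_mandelbrot"`, `"fbm"`.
#' @param target_D Theoretical dimension in `(1, 2)` (for Knopp, `[1, 2]`);
#'   the Hurst families use `H = 2 - target_D`.
#' @param fs,duration Sampling grid.
#' @param b_or_gamma Family frequency ratio; defaults `b = 2` (knopp),
#'   `gamma = 5` (weierstrass), `b = 1.5` (weierstrass_mandelbrot).
#' @param k_max Truncation order (deterministic families), default 50.
#' @param seed Seed (fbm only).
#' @return A [mafdm_ts()].
#' @export
cndf_signal <- function(family = c("knopp", "weierstrass",
                                   "weierstrass_mandelbrot", "fbm"),
                        target_D, fs = 1000, duration = 1,
                        b_or_gamma = NULL, k_max = 50, seed = 1) {
  family <- match.arg(family)
  switch(family,
    knopp = knopp(target_D = target_D,
                  b = if (is.null(b_or_gamma)) 2 else b_or_gamma,
                  k_max = k_max, fs = fs, duration = duration),
    weierstrass = weierstrass_cosine(H = 2 - target_D,
                  gamma = if (is.null(b_or_gamma)) 5 else b_or_gamma,
                  k_max = k_max, fs = fs, duration = duration),
    weierstrass_mandelbrot = weierstrass_mandelbrot(H = 2 - target_D,
                  b = if (is.null(b_or_gamma)) 1.5 else b_or_gamma,
                  k_range = k_max, fs = fs, duration = duration),
    fbm = fractional_brownian(H = 2 - target_D,
                  num_points = round(fs * duration) + 1L, seed = seed,
                  fs = fs))
}

#' Estimator accuracy benchmark on CNDF signals
#'
#' Generates each family at each requested theoretical dimension,
#' estimates the dimension with one whole-signal window, and tabulates
#' estimate and error.  The stochastic fBm family is replicated over
#' `n_fbm` seeds per dimension and the estimates averaged; the
#' deterministic families use a single curve each.  Degenerate estimates
#' are recorded as `NA`, never dropped silently.
#'
#' @param families Character vector of [cndf_signal()] families.
#' @param target_D_list Theoretical dimensions to test.
#' @param estimator `"mafdm"` (with multiplier `m`), `"mono"`, `"mrbc"`,
#'   or any function taking a [mafdm_ts()] and returning an
#'   `fd_estimate`.
#' @param fs,duration Sampling grid per curve.
#' @param m Amplitude multiplier for the MAFDM estimator, default 1.
#' @param levels Decimation levels, default `{1, 2, 4}`.
#' @param k_max Truncation order of the deterministic families.
#' @param n_fbm Number of seeded fBm replicates per dimension.
#' @param seed Base seed for the fBm replicates.
#' @return A data frame with columns `family`, `target_D`, `estimated_D`,
#'   `error` (= estimated - theoretical).
#' @export
benchmark_accuracy <- function(families = c("knopp", "weierstrass",
                                            "weierstrass_mandelbrot",
                                            "fbm"),
                               target_D_list = seq(1.1, 1.9, by = 0.1),
                               estimator = "mafdm", fs = 1000,
                               duration = 1, m = 1,
                               levels = c(1L, 2L, 4L), k_max = 50,
                               n_fbm = 10, seed = 1) {
  est_fun <- if (is.function(estimator)) estimator else {
    est_name <- match.arg(estimator, c("mafdm", "mono", "mrbc"))
    function(ts) {
      w <- length(ts$values) - 1L
      switch(est_name,
        mafdm = whole_signal_dimension(ts, m = m, levels = levels),
        mono = mono_dimensional_dimension(ts, 1L, w, levels, "truncate"),
        mrbc = mrbc_dimension(ts, 1L, w, levels, "truncate"))
    }
  }
  rows <- list()
  for (fam in families) {
    for (D in target_D_list) {
      est <- if (fam == "fbm") {
        vals <- vapply(seq_len(n_fbm), function(i) {
          ts <- cndf_signal("fbm", D, fs, duration, seed = seed + i - 1L)
          e <- est_fun(ts)
          if (e$flag %in% c("degenerate", "zero_length")) NA_real_
          else e$D_Hm
        }, numeric(1L))
        mean(vals, na.rm = TRUE)
      } else {
        ts <- cndf_signal(fam, D, fs, duration, k_max = k_max)
        e <- est_fun(ts)
        if (e$flag %in% c("degenerate", "zero_length")) NA_real_
        else e$D_Hm
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, target_D = D, estimated_D = est, error = est - D,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
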