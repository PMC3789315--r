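# Shared generators for the test suite.  Everything is built in code at
# test time; seeds are fixed so runs are reproducible.

# Random-walk test signal: rough, non-constant everywhere.
random_walk_ts <- function(n = 200, f0 = 50, seed = 1, scale = 1) {
  set.seed(seed)
  mafdm_ts(scale * cumsum(stats::rnorm(n)), f0 = f0)
}

# Zig-zag with per-step amplitude ratio |dy| * f0 = ratio.
zigzag_ts <- function(ratio, n = 200, f0 = 1) {
  mafdm_ts(rep_len(c(0, ratio / f0), n), f0 = f0)
}

# Direct evaluation of the two-point triangular log-log gradient,
# written out independently of closed_form_dimension().
triangular_gradient_direct <- function(h, f0, m, n) {
  R1 <- f0 * n * sqrt((m * h)^2 + (1 / f0)^2)
  Rn <- (f0 / n) * sqrt((m * h)^2 + (n / f0)^2)
  (log(R1) - log(Rn)) / (log(f0) - log(f0 / n))
}

# The Case-1-style fixture: long low-noise baseline with one short
# high-amplitude noisy burst.
case1_fixture <- function(seed = 11) {
  generate_fixture(fixture_spec(
    baseline = list(kind = "low_noise", length = 2000, noise_sd = 0.02),
    events = list(list(kind = "amplitude_burst", start = 1401,
                       length = 200, amplitude = 1,
                       role = "max_event", label = "burst")),
    f0 = 100, seed = seed))
}
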