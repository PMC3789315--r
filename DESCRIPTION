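Package: mafdm
Title: Modified Amplitude Fractal Dimension Method for Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust multi-scale estimation of the fractal dimension of
    dimensionless time series whose amplitude is scaled by a multiplier m
    (the modified amplitude fractal dimension method, MAFDM).  Computes
    boundary-corrected windowed relative curve lengths at log-equidistant
    decimation levels and derives the dimension D_Hm from the log-log
    gradient, per window and as a sliding series.  Includes the
    mono-dimensional (Higuchi-principle) and multiresolution box-counting
    (MRBC) comparison estimators, an exact closed form for triangular
    waves with its m-spectrum and asymptotes, generators for four
    continuous nowhere-differentiable benchmark functions (Knopp,
    Weierstrass cosine, Weierstrass-Mandelbrot, fractional Brownian
    motion) with known theoretical dimension, an accuracy benchmark, and
    amplitude-multiplier spectrum optimisation that maximises the
    separation of fractal dimensions between signal classes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
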