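`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic fixtures used across test files
tiny_city <- function(n = 9, peak = 100) make_fixture_city(n, peak)

tiny_params <- function(n = 9, sigma = 2, ...) {
  dispersion_params(n = n, sigma = sigma, ...)
}

# random positive raster pair (concentration, population) under the caller's seed
random_grid_case <- function(side = sample(2:6, 1)) {
  list(conc = matrix(runif(side^2, 0.1, 10), side),
       pop  = matrix(runif(side^2, 0, 5), side))
}

# scalar, loop-based evaluation of the Gaussian field (+ optional decay):
# the independent oracle for the vectorized implementation
scalar_field_oracle <- function(source, params) {
  n <- params$n
  out <- matrix(NA_real_, n, n)
  denom <- if (params$normalization == "cells") n^2 else n
  for (yi in 0:(n - 1)) for (xi in 0:(n - 1)) {
    v <- source$emission_rate / (denom * params$wind_speed * params$boundary_height) *
      exp(-((xi - source$x0)^2 / (2 * params$sigma^2) +
            (yi - source$y0)^2 / (2 * params$sigma^2)))
    if (params$decay_rate > 0) {
      d <- sqrt((xi - source$x0)^2 + (yi - source$y0)^2) * params$cell_length
      v <- v * exp(-params$decay_rate * d / params$wind_speed)
    }
    out[yi + 1, xi + 1] <- v
  }
  out
}

# scalar oracle for the population-weighted mean
scalar_pwm_oracle <- function(conc, pop) {
  num <- 0; den <- 0
  for (i in seq_along(conc)) {
    num <- num + pop[i] * conc[i]
    den <- den + pop[i]
  }
  num / den
}
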