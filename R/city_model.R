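#' Build the synthetic segregated city
#'
#' Constructs a deterministic two-group population on an `n` x `n` grid that
#' emulates a segregated urban area: total density peaks at the city center
#' and decays linearly with radial distance (a cone,
#' `T(r) = peak * max(0, 1 - r / r_max)` with `r_max = n / sqrt(2)` so the
#' cone just covers the grid corners), while the share of group alpha rises
#' linearly from 0 at the west edge to 1 at the east edge
#' (`f(x) = x / (n - 1)`). The mirror symmetry of the share about the central
#' column makes the two group totals exactly equal.
#'
#' Grid convention: cell coordinates are 0-based, `x` is the column index
#' (west to east), `y` the row index (south to north); matrices are stored
#' as `values[y + 1, x + 1]`.
#'
#' @param n Grid side length in cells (>= 3).
#' @param center_peak_density Person count per cell at the city center
#'   (> 0). All disparity metrics are invariant to this scale.
#' @return An object of class `"population_grid"`: list with `n` x `n`
#'   matrices `pop_alpha` and `pop_beta`, the side length `n`, and the
#'   continuous center coordinate `center` (`(n-1)/2` in both axes).
#' @examples
#' city <- build_city(n = 9)
#' sum(city$pop_alpha) == sum(city$pop_beta)
#' @export
build_city <- function(n = 200, center_peak_density = 100) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 || n != round(n))
    stop_validation("'n' must be a single integer >= 3")
  check_scalar(center_peak_density, "center_peak_density")
  if (center_peak_density <= 0)
    stop_validation("'center_peak_density' must be positive")
  n <- as.integer(n)
  ax <- 0:(n - 1)
  ctr <- (n - 1) / 2
  r <- sqrt(outer((ax - ctr)^2, (ax - ctr)^2, "+"))  # [y+1, x+1]
  total <- center_peak_density * pmax(0, 1 - r / (n / sqrt(2)))
  frac_alpha <- matrix(rep(ax / (n - 1), each = n), n, n)
  out <- list(
    pop_alpha = total * frac_alpha,
    pop_beta  = total * (1 - frac_alpha),
    n = n,
    center = c(x = ctr, y = ctr)
  )
  class(out) <- "population_grid"
  out
}

#' Point emission source
#'
#' @param x0,y0 Source cell coordinates (0-based, continuous positions
#'   allowed, e.g. along a relocation trajectory).
#' @param emission_rate Emission rate, conventionally g/s (>= 0).
#' @return Object of class `"emission_source"`.
#' @export
emission_source <- function(x0, y0, emission_rate) {
  check_scalar(x0, "x0"); check_scalar(y0, "y0")
  check_scalar(emission_rate, "emission_rate")
  if (emission_rate < 0) stop_validation("'emission_rate' must be >= 0")
  structure(list(x0 = x0, y0 = y0, emission_rate = emission_rate),
            class = "emission_source")
}

#' Dispersion and domain parameters
#'
#' Parameters of the illustrative dispersion model. The concentration field
#' is a radially symmetric two-dimensional Gaussian centered at the source,
#' scaled by `E / (n * u * H)`; an optional first-order loss
#' `exp(-k d / u)` attenuates it with distance, emulating a shorter-lived
#' reactive pollutant.
#'
#' @param n Grid side length in cells (default 200).
#' @param wind_speed Average wind speed `u` in m/s (default 5).
#' @param boundary_height Average boundary-layer height `H` in m
#'   (default 100).
#' @param sigma Plume spread (standard deviation, equal in x and y) in cell
#'   units; default 40 cells, i.e. 20% of the default domain — wide enough
#'   that both demographic groups are measurably exposed, narrow enough that
#'   a disparity exists.
#' @param decay_rate First-order rate constant `k` in 1/s (default 0 =
#'   conserved pollutant). See [default_decay_rate()] for a value that
#'   competes substantially with dilution over the domain.
#' @param cell_length Physical cell size in m (default 100); only used to
#'   convert cell distances to meters in the decay term.
#' @param normalization Either `"side"` (default) — the dilution prefactor
#'   divides by the grid side length `n` — or `"cells"`, dividing by the
#'   total cell count `n^2`. The two differ only by a constant factor, which
#'   cancels out of every relative quantity.
#' @return Object of class `"dispersion_params"`.
#' @export
dispersion_params <- function(n = 200, wind_speed = 5, boundary_height = 100,
                              sigma = 40, decay_rate = 0, cell_length = 100,
                              normalization = c("side", "cells")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 || n != round(n))
    stop_validation("'n' must be a single integer >= 3")
  check_scalar(wind_speed, "wind_speed")
  check_scalar(boundary_height, "boundary_height")
  check_scalar(sigma, "sigma")
  check_scalar(decay_rate, "decay_rate")
  check_scalar(cell_length, "cell_length")
  if (wind_speed <= 0) stop_validation("'wind_speed' must be positive")
  if (boundary_height <= 0) stop_validation("'boundary_height' must be positive")
  if (sigma <= 0) stop_validation("'sigma' must be positive")
  if (decay_rate < 0) stop_validation("'decay_rate' must be >= 0")
  if (cell_length <= 0) stop_validation("'cell_length' must be positive")
  structure(list(n = as.integer(n), wind_speed = wind_speed,
                 boundary_height = boundary_height, sigma = sigma,
                 decay_rate = decay_rate, cell_length = cell_length,
                 normalization = normalization),
            class = "dispersion_params")
}

#' Default first-order decay rate
#'
#' `k = u / (50 * cell_length)`: an e-folding distance of 50 cells (a
#' quarter of the default domain), so the loss process competes
#' substantially with dilution over the grid.
#'
#' @param params A [dispersion_params] object.
#' @return Decay rate in 1/s.
#' @export
default_decay_rate <- function(params) {
  stopifnot(inherits(params, "dispersion_params"))
  params$wind_speed / (50 * params$cell_length)
}

#' Gaussian concentration field from a point source
#'
#' Evaluates the illustrative dispersion form on every grid cell:
#' \deqn{C(x, y) = \frac{E}{n u H}
#'   \exp\!\left(-\frac{(x-x_0)^2}{2\sigma^2}-\frac{(y-y_0)^2}{2\sigma^2}\right),}
#' a radially symmetric Gaussian centered at the source, linear in the
#' emission rate. With the default parameters (E = 10 g/s, n = 200,
#' u = 5 m/s, H = 100 m) the peak concentration at the source cell is
#' `10 / (200 * 5 * 100) = 1e-4`.
#'
#' @param source An [emission_source]; must lie inside the grid.
#' @param params A [dispersion_params].
#' @return Object of class `"concentration_field"`: list with the `n` x `n`
#'   matrix `values` (indexed `[y + 1, x + 1]`), plus `source` and `params`.
#' @export
gaussian_concentration <- function(source, params) {
  stopifnot(inherits(params, "dispersion_params"))
  if (!inherits(source, "emission_source"))
    stop_validation("'source' must be an emission_source")
  n <- params$n
  if (source$x0 < 0 || source$x0 > n - 1 || source$y0 < 0 || source$y0 > n - 1)
    stop_validation(sprintf("source (%g, %g) lies outside the %d x %d grid",
                            source$x0, source$y0, n, n))
  ax <- 0:(n - 1)
  d2 <- outer((ax - source$y0)^2, (ax - source$x0)^2, "+")  # [y+1, x+1]
  denom <- if (params$normalization == "cells") as.numeric(n)^2 else as.numeric(n)
  peak <- source$emission_rate /
    (denom * params$wind_speed * params$boundary_height)
  structure(list(values = peak * exp(-d2 / (2 * params$sigma^2)),
                 source = source, params = params),
            class = "concentration_field")
}

#' Apply first-order decay to a concentration field
#'
#' Multiplies each cell by `exp(-k d / u)` where `d` is the Euclidean
#' distance from the source in meters (cell distance times `cell_length`).
#' With `k = 0` the field is returned unchanged; the source cell is always
#' unchanged. Cell values can only decrease, so the field maximum stays at
#' the source.
#'
#' @param conc A [concentration_field].
#' @param source The [emission_source] the field was computed from; defaults
#'   to the one stored in `conc`.
#' @param params A [dispersion_params] supplying `decay_rate`, `wind_speed`
#'   and `cell_length`; defaults to the one stored in `conc`.
#' @return A `"concentration_field"` with attenuated values.
#' @export
apply_first_order_decay <- function(conc, source = conc$source,
                                    params = conc$params) {
  if (!inherits(conc, "concentration_field"))
    stop_validation("'conc' must be a concentration_field")
  stopifnot(inherits(params, "dispersion_params"))
  k <- params$decay_rate
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop_validation("'decay_rate' must be a single finite number >= 0")
  if (k == 0) return(conc)
  n <- params$n
  ax <- 0:(n - 1)
  d <- sqrt(outer((ax - source$y0)^2, (ax - source$x0)^2, "+")) *
    params$cell_length
  out <- conc
  out$values <- conc$values * exp(-k * d / params$wind_speed)
  out
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("Synthetic two-group city: %d x %d grid\n", x$n, x$n))
  cat(sprintf("  group alpha total: %.6g persons (east-leaning)\n", sum(x$pop_alpha)))
  cat(sprintf("  group beta  total: %.6g persons (west-leaning)\n", sum(x$pop_beta)))
  invisible(x)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("Concentration field on %d x %d grid\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  source at (%.6g, %.6g), E = %.6g\n",
              x$source$x0, x$source$y0, x$source$emission_rate))
  cat(sprintf("  peak %.6g, mean %.6g\n", max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
plot.population_grid <- function(x, which = c("total", "alpha", "beta"), ...) {
  which <- match.arg(which)
  m <- switch(which, total = x$pop_alpha + x$pop_beta,
              alpha = x$pop_alpha, beta = x$pop_beta)
  # image() draws rows along the x axis; transpose so x = west-east
  graphics::image(0:(x$n - 1), 0:(x$n - 1), t(m),
                  xlab = "x (west - east)", ylab = "y (south - north)",
                  main = paste("Population density:", which),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' @export
plot.concentration_field <- function(x, ...) {
  n <- nrow(x$values)
  graphics::image(0:(n - 1), 0:(n - 1), t(x$values),
                  xlab = "x (west - east)", ylab = "y (south - north)",
                  main = "Concentration field",
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE), ...)
  graphics::points(x$source$x0, x$source$y0, pch = 16)
  invisible(x)
}
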