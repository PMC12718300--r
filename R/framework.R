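#' Population-weighted mean exposure
#'
#' Averages a gridded concentration field over people rather than area:
#' each cell's concentration is weighted by the number of residents of the
#' group in that cell, \deqn{PWM = \sum_i P_i C_i / \sum_i P_i.}
#' This is the exposure metric underlying all disparity components.
#'
#' @param conc A [concentration_field] or a numeric matrix/vector of per-cell
#'   concentrations.
#' @param pop Numeric matrix/vector of per-cell person counts for one group,
#'   with the same shape as `conc`.
#' @return A single concentration value, bounded by the range of `conc` over
#'   populated cells.
#' @examples
#' population_weighted_mean(c(2, 6), c(1, 3))  # 5
#' @export
population_weighted_mean <- function(conc, pop) {
  cv <- field_values(conc)
  if (!is.numeric(cv) || !is.numeric(pop))
    stop_validation("'conc' and 'pop' must be numeric")
  if (!identical(dim(cv), dim(pop)) || length(cv) != length(pop))
    stop_shape(sprintf("shape mismatch: conc is %s, pop is %s",
                       paste(dim(cv) %||% length(cv), collapse = "x"),
                       paste(dim(pop) %||% length(pop), collapse = "x")))
  if (anyNA(cv) || any(!is.finite(cv)) || anyNA(pop) || any(!is.finite(pop)))
    stop_validation("'conc' and 'pop' must be finite")
  if (any(pop < 0))
    stop_validation("'pop' must be nonnegative")
  total <- sum(pop)
  if (total <= 0)
    stop_domain("total population is zero; population-weighted mean undefined")
  sum(pop * cv) / total
}

#' Absolute disparity in exposure
#'
#' The difference, in concentration units, between a group's
#' population-weighted mean exposure and the total population's. Positive
#' values indicate an over-exposed (overburdened) group, negative values an
#' under-exposed one.
#'
#' @param pwm_group,pwm_total Population-weighted mean exposures (both
#'   finite and nonnegative).
#' @return `pwm_group - pwm_total`, in concentration units.
#' @export
absolute_disparity <- function(pwm_group, pwm_total) {
  check_scalar(pwm_group, "pwm_group"); check_scalar(pwm_total, "pwm_total")
  if (pwm_group < 0 || pwm_total < 0)
    stop_validation("population-weighted means must be nonnegative")
  pwm_group - pwm_total
}

#' Relative disparity in exposure
#'
#' The absolute disparity expressed as a fraction of the total population's
#' mean exposure, in decimal form (0.2 means the group's exposure is 20%
#' above the population average). It measures spatial bias in pollution
#' relative to where a group lives, and is independent of the emission
#' magnitude. May be negative for under-exposed groups.
#'
#' @inheritParams absolute_disparity
#' @return `(pwm_group - pwm_total) / pwm_total`, dimensionless.
#' @export
relative_disparity <- function(pwm_group, pwm_total) {
  check_scalar(pwm_group, "pwm_group"); check_scalar(pwm_total, "pwm_total")
  if (pwm_group < 0 || pwm_total < 0)
    stop_validation("population-weighted means must be nonnegative")
  if (pwm_total == 0)
    stop_domain("relative disparity undefined when total exposure is zero")
  (pwm_group - pwm_total) / pwm_total
}

#' Population-average exposure factor
#'
#' Exposure per unit emission rate: the total population's mean exposure
#' divided by the emission rate. An intake-fraction analogue, it measures a
#' source's potential to expose the population, driven by proximity and
#' dispersion, independently of how much is emitted.
#'
#' @param pwm_total Total-population mean exposure (concentration units).
#' @param emissions Emission rate (mass/time, must be positive).
#' @return Concentration per unit emission rate.
#' @export
exposure_factor <- function(pwm_total, emissions) {
  check_scalar(pwm_total, "pwm_total"); check_scalar(emissions, "emissions")
  if (emissions <= 0)
    stop_domain("exposure factor undefined for emissions <= 0")
  pwm_total / emissions
}

#' Decompose a group's exposure disparity into its three drivers
#'
#' Absolute exposure disparity factors exactly as the product of three
#' independently controllable components,
#' \deqn{D_A = E \times \bar{XF} \times D_R,}
#' where \eqn{E} is the emission rate, \eqn{\bar{XF}} the population-average
#' exposure factor, and \eqn{D_R} the relative disparity (decimal form).
#' The identity is algebraic: \eqn{E\,(PWM_T/E)\,((PWM_g - PWM_T)/PWM_T) =
#' PWM_g - PWM_T}.
#'
#' @param conc A [concentration_field] or per-cell concentration matrix.
#' @param pop_group,pop_total Per-cell person counts for the group of
#'   interest and for the whole population (same shape as `conc`).
#' @param emissions Emission rate that produced `conc` (must be positive;
#'   at exactly zero emissions the exposure factor is a 0/0 form and the
#'   decomposition is undefined).
#' @param group_label Name attached to the group (e.g. `"alpha"`).
#' @return An object of class `"disparity_decomposition"`: a list with
#'   elements `group_label`, `emissions`, `exposure_factor`,
#'   `relative_disparity`, `absolute_disparity`, `pwm_group`, `pwm_total`.
#' @seealso [change_decomposition()] for baseline-vs-policy comparison.
#' @examples
#' conc <- matrix(c(1, 2, 3, 4), 2)
#' pop  <- matrix(c(4, 3, 2, 1), 2)
#' grp  <- matrix(c(0, 1, 1, 2), 2)
#' d <- decompose_disparity(conc, grp, pop, emissions = 10)
#' d$emissions * d$exposure_factor * d$relative_disparity  # equals d$absolute_disparity
#' @export
decompose_disparity <- function(conc, pop_group, pop_total, emissions,
                                group_label = "group") {
  pwm_g <- population_weighted_mean(conc, pop_group)
  pwm_t <- population_weighted_mean(conc, pop_total)
  out <- list(
    group_label        = as.character(group_label),
    emissions          = check_scalar(emissions, "emissions"),
    exposure_factor    = exposure_factor(pwm_t, emissions),
    relative_disparity = relative_disparity(pwm_g, pwm_t),
    absolute_disparity = absolute_disparity(pwm_g, pwm_t),
    pwm_group          = pwm_g,
    pwm_total          = pwm_t
  )
  class(out) <- "disparity_decomposition"
  out
}

#' Signed percent change between two values
#'
#' `100 * (value_end - value_start) / value_start`. The sign follows the
#' arithmetic: a move from 0.1 to 0.12 is +20%. No magnitude convention is
#' applied; callers wanting "percent of the starting magnitude" should take
#' `abs()` themselves.
#'
#' @param value_start,value_end Numeric scalars (or equal-length vectors);
#'   `value_start` must be nonzero.
#' @return Percent change(s).
#' @examples
#' percent_change(0.1, 0.12)  # 20
#' @export
percent_change <- function(value_start, value_end) {
  if (!is.numeric(value_start) || !is.numeric(value_end) ||
      any(!is.finite(value_start)) || any(!is.finite(value_end)))
    stop_validation("'value_start' and 'value_end' must be finite numeric")
  if (any(value_start == 0))
    stop_domain("percent change undefined from a zero starting value")
  100 * (value_end - value_start) / value_start
}

#' Decompose the change between a baseline and a policy state
#'
#' Expresses a policy's effect as fractional changes of the four framework
#' components. Because the components multiply, the fractional changes obey
#' \deqn{(1+\Delta E)(1+\Delta \bar{XF})(1+\Delta D_R) = 1+\Delta D_A,}
#' which is how modelled or observed policy outcomes are attributed to
#' emission magnitude, source placement, and spatial bias.
#'
#' @param baseline,policy [decompose_disparity()] records for the same group.
#' @return An object of class `"change_decomposition"`: list with
#'   `group_label` and the four fractional changes `frac_change_E`,
#'   `frac_change_XF`, `frac_change_DR`, `frac_change_DA` (dimensionless,
#'   e.g. -0.5 for a halving).
#' @export
change_decomposition <- function(baseline, policy) {
  if (!inherits(baseline, "disparity_decomposition") ||
      !inherits(policy, "disparity_decomposition"))
    stop_validation("'baseline' and 'policy' must be disparity_decomposition objects")
  if (!identical(baseline$group_label, policy$group_label))
    stop_validation(sprintf("group mismatch: baseline is '%s', policy is '%s'",
                            baseline$group_label, policy$group_label))
  comp <- c(E = "emissions", XF = "exposure_factor",
            DR = "relative_disparity", DA = "absolute_disparity")
  for (nm in comp) {
    if (baseline[[nm]] == 0)
      stop_domain(sprintf("baseline component '%s' is zero; fractional change undefined", nm))
  }
  fc <- function(nm) (policy[[nm]] - baseline[[nm]]) / baseline[[nm]]
  out <- list(
    group_label    = baseline$group_label,
    frac_change_E  = fc("emissions"),
    frac_change_XF = fc("exposure_factor"),
    frac_change_DR = fc("relative_disparity"),
    frac_change_DA = fc("absolute_disparity")
  )
  class(out) <- "change_decomposition"
  out
}

# extract raw values from a concentration_field or pass a matrix through
field_values <- function(conc) {
  if (inherits(conc, "concentration_field")) conc$values else conc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.disparity_decomposition <- function(x, ...) {
  cat("Exposure disparity decomposition - group:", x$group_label, "\n")
  cat(sprintf("  emissions (E):            %.6g\n", x$emissions))
  cat(sprintf("  exposure factor (XF-bar): %.6g\n", x$exposure_factor))
  cat(sprintf("  relative disparity (D_R): %.6g  (%.4g%%)\n",
              x$relative_disparity, 100 * x$relative_disparity))
  cat(sprintf("  absolute disparity (D_A): %.6g\n", x$absolute_disparity))
  cat(sprintf("  PWM group / total:        %.6g / %.6g\n", x$pwm_group, x$pwm_total))
  invisible(x)
}

#' @export
print.change_decomposition <- function(x, ...) {
  cat("Component changes (policy vs baseline) - group:", x$group_label, "\n")
  cat(sprintf("  E:      %+.4g%%\n", 100 * x$frac_change_E))
  cat(sprintf("  XF-bar: %+.4g%%\n", 100 * x$frac_change_XF))
  cat(sprintf("  D_R:    %+.4g%%\n", 100 * x$frac_change_DR))
  cat(sprintf("  D_A:    %+.4g%%\n", 100 * x$frac_change_DA))
  invisible(x)
}
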