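SCENARIO_KINDS <- c("reduce_E", "reduce_E_XF", "reduce_E_XF_DR")

#' Find the demographic-equity longitude
#'
#' The source x-position at which group alpha's relative disparity is zero,
#' holding the y-position fixed: west of it the field favors group beta,
#' east of it group alpha. Found by root-finding on `D_R(x)`; for the
#' default city, whose demographic gradient is mirror-symmetric, this is the
#' central column `(n - 1) / 2`.
#'
#' @param city A [build_city()] population grid.
#' @param params A [dispersion_params] with matching `n`.
#' @param y Source y-position at which to search.
#' @param tol Convergence tolerance on the x-position (cells).
#' @return The equity x-coordinate (continuous, 0-based cells).
#' @export
find_equity_longitude <- function(city, params, y = city$center[["y"]],
                                  tol = 1e-9) {
  stopifnot(inherits(city, "population_grid"), inherits(params, "dispersion_params"))
  if (params$n != city$n)
    stop_shape("'city' and 'params' disagree on grid size")
  pop_total <- city$pop_alpha + city$pop_beta
  dr_at <- function(x) {
    fld <- gaussian_concentration(emission_source(x, y, 1), params)
    if (params$decay_rate > 0) fld <- apply_first_order_decay(fld)
    relative_disparity(population_weighted_mean(fld, city$pop_alpha),
                       population_weighted_mean(fld, pop_total))
  }
  lo <- 0; hi <- city$n - 1
  if (dr_at(lo) * dr_at(hi) > 0)
    stop_domain("relative disparity does not change sign across the grid; no equity longitude")
  stats::uniroot(dr_at, c(lo, hi), tol = tol)$root
}

#' Define an emission-reduction scenario
#'
#' Builds the source trajectory for one of three policy archetypes, all
#' sharing the same linear emission schedule (`E_t = E0 * (1 - t/T)`, ending
#' one increment above zero):
#' \describe{
#'   \item{`reduce_E`}{Emissions fall in place; the source never moves, so
#'     the spatial pattern — and with it the exposure factor and the
#'     relative disparity — is frozen.}
#'   \item{`reduce_E_XF`}{The source additionally moves due north,
#'     perpendicular to the west-east demographic gradient, toward the
#'     sparsely populated periphery: average exposure per unit emission
#'     falls, but the east-west spatial bias (relative disparity) is
#'     maintained.}
#'   \item{`reduce_E_XF_DR`}{Phase 1 (first half of the steps): the source
#'     moves along an arc away from the overburdened group and the dense
#'     center — its x-position declines linearly to the equity longitude
#'     while its radial distance from the city center grows linearly to
#'     `0.325 * n` cells — so the exposure factor and the relative disparity
#'     both fall monotonically, the latter reaching zero at the end of the
#'     phase. Phase 2: from there the source continues radially away from
#'     the center (due north along the equity longitude, where relative
#'     disparity stays zero by symmetry) out to the periphery.}
#' }
#'
#' @param kind One of `"reduce_E"`, `"reduce_E_XF"`, `"reduce_E_XF_DR"`.
#' @param city A [build_city()] population grid.
#' @param params A [dispersion_params] with matching `n`.
#' @param n_steps Number of model steps `T` (default 1000).
#' @param initial_emissions Starting emission rate `E0` in g/s (default 10).
#' @param source_start Numeric `c(x, y)` start position; default
#'   `(floor(0.75 n), floor(0.5 n))` — inside the overburdened group's
#'   territory, east of center.
#' @param edge_margin Cells kept between moving trajectories and the grid
#'   edge (default `n / 20`).
#' @param phase1_steps For `reduce_E_XF_DR`: steps to spend reaching the
#'   equity longitude (default `floor(n_steps / 2)`, so relative disparity
#'   reaches zero at the trajectory midpoint).
#' @param phase1_radius_end For `reduce_E_XF_DR`: radial distance from the
#'   city center at the end of phase 1, in cells (default
#'   `max(0.325 * n, starting radius)`).
#' @return Object of class `"scenario_spec"`: list with `kind`, `n_steps`,
#'   `initial_emissions`, `source_start`, and the `n_steps` x 2 `trajectory`
#'   matrix of per-step source positions.
#' @export
make_scenario <- function(kind, city, params, n_steps = 1000,
                          initial_emissions = 10, source_start = NULL,
                          edge_margin = NULL, phase1_steps = NULL,
                          phase1_radius_end = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% SCENARIO_KINDS)
    stop_validation(sprintf("unknown scenario kind '%s'; expected one of %s",
                            paste(kind, collapse = ","),
                            paste(SCENARIO_KINDS, collapse = ", ")))
  stopifnot(inherits(city, "population_grid"), inherits(params, "dispersion_params"))
  if (params$n != city$n)
    stop_shape("'city' and 'params' disagree on grid size")
  n <- city$n
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2 ||
      n_steps != round(n_steps))
    stop_validation("'n_steps' must be a single integer >= 2")
  n_steps <- as.integer(n_steps)
  check_scalar(initial_emissions, "initial_emissions")
  if (initial_emissions <= 0) stop_validation("'initial_emissions' must be positive")
  if (is.null(source_start)) source_start <- c(floor(0.75 * n), floor(0.5 * n))
  if (!is.numeric(source_start) || length(source_start) != 2L ||
      any(!is.finite(source_start)))
    stop_validation("'source_start' must be numeric c(x, y)")
  x0 <- source_start[[1]]; y0 <- source_start[[2]]
  if (x0 < 0 || x0 > n - 1 || y0 < 0 || y0 > n - 1)
    stop_validation(sprintf("source_start (%g, %g) lies outside the %d x %d grid",
                            x0, y0, n, n))
  edge_margin <- edge_margin %||% (n / 20)
  y_end <- n - 1 - edge_margin
  steps <- seq_len(n_steps) - 1L

  traj <- switch(
    kind,
    reduce_E = cbind(x = rep(x0, n_steps), y = rep(y0, n_steps)),
    reduce_E_XF = {
      if (y_end <= y0)
        stop_validation("northward trajectory needs y_end above source_start; reduce 'edge_margin' or lower the start")
      cbind(x = rep(x0, n_steps),
            y = y0 + (y_end - y0) * steps / (n_steps - 1))
    },
    reduce_E_XF_DR = {
      cx <- city$center[["x"]]; cy <- city$center[["y"]]
      x_eq <- find_equity_longitude(city, params, y = y0)
      t1 <- phase1_steps %||% floor(n_steps / 2)
      if (t1 < 1 || t1 > n_steps - 1)
        stop_validation("'phase1_steps' must be in [1, n_steps - 1]")
      r0 <- sqrt((x0 - cx)^2 + (y0 - cy)^2)
      r1 <- phase1_radius_end %||% max(0.325 * n, r0)
      if (r1 < r0) stop_validation("'phase1_radius_end' must be >= the starting radius")
      sgn <- if (y0 >= cy) 1 else -1
      s1 <- pmin(steps, t1) / t1
      x <- x0 + (x_eq - x0) * s1
      rr <- r0 + (r1 - r0) * s1
      y <- cy + sgn * sqrt(pmax(0, rr^2 - (x - cx)^2))
      # phase 2: radially outward along the equity longitude
      p2 <- steps > t1
      if (any(p2)) {
        y1 <- y[t1 + 1L]
        y_out <- if (sgn >= 0) max(y_end, y1) else min(n - 1 - y_end, y1)
        s2 <- (steps[p2] - t1) / (n_steps - 1L - t1)
        y[p2] <- y1 + (y_out - y1) * s2
      }
      cbind(x = x, y = y)
    }
  )
  if (any(traj < 0) || any(traj > n - 1))
    stop_validation("scenario trajectory leaves the grid; adjust margins or start position")
  structure(list(kind = kind, n_steps = n_steps,
                 initial_emissions = initial_emissions,
                 source_start = c(x = x0, y = y0), trajectory = traj),
            class = "scenario_spec")
}

#' Run an emission-reduction scenario
#'
#' Steps the emission rate linearly from `E0` down to `E0 / T` (one
#' increment above zero, where the per-unit exposure factor would become a
#' 0/0 form), recomputing the Gaussian concentration field at each step's
#' source position (with first-order decay when `params$decay_rate > 0`) and
#' recording the full disparity decomposition for group alpha, group beta,
#' and the total population. Entirely deterministic: identical inputs give
#' bitwise-identical results.
#'
#' @param city A [build_city()] population grid.
#' @param spec A [make_scenario()] specification.
#' @param params A [dispersion_params] with matching `n`.
#' @return Object of class `"scenario_result"`: list with
#'   \describe{
#'     \item{records}{data frame with one row per step and group, columns
#'       `step` (0-based), `group`, `E`, `XF_bar`, `D_R`, `D_A`,
#'       `PWM_group`, `PWM_total`.}
#'     \item{emission_fraction_reduced}{per-step fraction `t / T` in
#'       `[0, 1)`.}
#'     \item{spec, params}{the inputs.}
#'   }
#' @seealso [summarize_at_fraction()], [emission_reduction_at_zero_disparity()],
#'   [compare_scenarios()], [write_result_csv()].
#' @export
run_scenario <- function(city, spec, params) {
  stopifnot(inherits(city, "population_grid"),
            inherits(spec, "scenario_spec"),
            inherits(params, "dispersion_params"))
  if (params$n != city$n)
    stop_shape("'city' and 'params' disagree on grid size")
  n_steps <- spec$n_steps
  e0 <- spec$initial_emissions
  pops <- list(alpha = city$pop_alpha, beta = city$pop_beta,
               total = city$pop_alpha + city$pop_beta)
  pop_sums <- vapply(pops, sum, numeric(1))
  if (any(pop_sums <= 0)) stop_domain("each population group must have positive total")
  n_grp <- length(pops)
  n_rec <- n_steps * n_grp
  rec <- list(step = integer(n_rec), group = character(n_rec),
              E = numeric(n_rec), XF_bar = numeric(n_rec),
              D_R = numeric(n_rec), D_A = numeric(n_rec),
              PWM_group = numeric(n_rec), PWM_total = numeric(n_rec))
  for (t in seq_len(n_steps) - 1L) {
    e_t <- e0 * (1 - t / n_steps)
    src <- emission_source(spec$trajectory[t + 1L, 1L],
                           spec$trajectory[t + 1L, 2L], e_t)
    fld <- gaussian_concentration(src, params)
    if (params$decay_rate > 0) fld <- apply_first_order_decay(fld)
    cv <- fld$values
    pwm <- vapply(seq_len(n_grp),
                  function(g) sum(pops[[g]] * cv) / pop_sums[[g]], numeric(1))
    pwm_t <- pwm[[n_grp]]
    idx <- t * n_grp + seq_len(n_grp)
    rec$step[idx] <- t
    rec$group[idx] <- names(pops)
    rec$E[idx] <- e_t
    rec$XF_bar[idx] <- pwm_t / e_t
    rec$D_R[idx] <- (pwm - pwm_t) / pwm_t
    rec$D_A[idx] <- pwm - pwm_t
    rec$PWM_group[idx] <- pwm
    rec$PWM_total[idx] <- pwm_t
  }
  structure(list(records = as.data.frame(rec, stringsAsFactors = FALSE),
                 emission_fraction_reduced = (seq_len(n_steps) - 1L) / n_steps,
                 spec = spec, params = params),
            class = "scenario_result")
}

# records for one group, ordered by step
group_records <- function(result, group_label) {
  stopifnot(inherits(result, "scenario_result"))
  r <- result$records[result$records$group == group_label, , drop = FALSE]
  if (nrow(r) == 0L)
    stop_validation(sprintf("unknown group '%s'; result has groups: %s",
                            group_label,
                            paste(unique(result$records$group), collapse = ", ")))
  r[order(r$step), , drop = FALSE]
}

#' Component changes at a given emission-reduction fraction
#'
#' Percent change of each framework component between the scenario start and
#' the first step at which at least `fraction` of emissions has been cut
#' (e.g. the 50% midpoint). Changes are signed percent changes of the
#' decimal components; the emission change is `-100 * fraction` by
#' construction of the linear schedule.
#'
#' @param result A [run_scenario()] result.
#' @param fraction Target emission-reduction fraction in (0, 1].
#' @param groups Groups to report (default alpha and beta; the total
#'   population has zero disparity by definition, so its relative-disparity
#'   change is undefined).
#' @return Data frame with columns `group`, `pct_change_E`, `pct_change_XF`,
#'   `pct_change_DR`, `pct_change_DA`.
#' @export
summarize_at_fraction <- function(result, fraction,
                                  groups = c("alpha", "beta")) {
  stopifnot(inherits(result, "scenario_result"))
  check_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction > 1)
    stop_validation("'fraction' must be in (0, 1]")
  hit <- which(result$emission_fraction_reduced >= fraction)
  if (length(hit) == 0L)
    stop_domain(sprintf("fraction %g exceeds the maximum reached (%g)",
                        fraction, max(result$emission_fraction_reduced)))
  at <- hit[1L] - 1L  # 0-based step
  out <- lapply(groups, function(g) {
    r <- group_records(result, g)
    i0 <- which(r$step == 0L); i1 <- which(r$step == at)
    data.frame(group = g,
               pct_change_E  = percent_change(r$E[i0], r$E[i1]),
               pct_change_XF = percent_change(r$XF_bar[i0], r$XF_bar[i1]),
               pct_change_DR = percent_change(r$D_R[i0], r$D_R[i1]),
               pct_change_DA = percent_change(r$D_A[i0], r$D_A[i1]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Emission reduction needed to eliminate a group's absolute disparity
#'
#' The smallest emission-reduction fraction at which the group's absolute
#' disparity has genuinely vanished, or 1.0 if that only happens because
#' emissions themselves go to zero. Because the linear schedule drives
#' `D_A = E * XF_bar * D_R` toward zero at the end of every scenario
#' regardless of spatial pattern, the test is applied to the disparity per
#' remaining unit of emissions: the first step with
#' `|D_A(t)| * E0 / E_t <= tolerance`. This detects a zero of
#' `XF_bar * D_R` — true elimination of the spatial bias — and is immune to
#' the shrinking-emissions envelope.
#'
#' @param result A [run_scenario()] result.
#' @param group_label Group to assess (default `"alpha"`).
#' @param tolerance Absolute-disparity tolerance in concentration units;
#'   default `1e-3 * |D_A|` at the scenario start.
#' @return Emission-reduction fraction in `[0, 1]`.
#' @export
emission_reduction_at_zero_disparity <- function(result, group_label = "alpha",
                                                 tolerance = NULL) {
  r <- group_records(result, group_label)
  da <- r$D_A; e <- r$E; e0 <- e[1L]
  tolerance <- tolerance %||% (1e-3 * abs(da[1L]))
  check_scalar(tolerance, "tolerance")
  hit <- which(abs(da) * (e0 / e) <= tolerance)
  if (length(hit) == 0L) return(1.0)
  result$emission_fraction_reduced[hit[1L]]
}

#' Compare how fast two scenarios eliminate disparity
#'
#' The percent saving in required emission reduction of scenario `result_b`
#' relative to scenario `result_a`: `100 * (r_a - r_b) / r_a`, where each
#' `r` is the scenario's [emission_reduction_at_zero_disparity()]. Positive
#' values mean scenario b eliminates the group's absolute disparity with
#' less emission reduction.
#'
#' @param result_a,result_b [run_scenario()] results on the same city and
#'   parameters.
#' @param group_label Group to compare (default `"alpha"`).
#' @param tolerance Passed to [emission_reduction_at_zero_disparity()].
#' @return Percent saving (may be negative if b is slower).
#' @export
compare_scenarios <- function(result_a, result_b, group_label = "alpha",
                              tolerance = NULL) {
  stopifnot(inherits(result_a, "scenario_result"),
            inherits(result_b, "scenario_result"))
  r_a <- emission_reduction_at_zero_disparity(result_a, group_label, tolerance)
  r_b <- emission_reduction_at_zero_disparity(result_b, group_label, tolerance)
  100 * (r_a - r_b) / r_a
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Emission-reduction scenario:", x$kind, "\n")
  cat(sprintf("  %d steps, E0 = %g g/s (linear to E0/T)\n",
              x$n_steps, x$initial_emissions))
  cat(sprintf("  source: (%.6g, %.6g) -> (%.6g, %.6g)\n",
              x$trajectory[1, 1], x$trajectory[1, 2],
              x$trajectory[x$n_steps, 1], x$trajectory[x$n_steps, 2]))
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  a0 <- group_records(x, "alpha")
  cat("Scenario result:", x$spec$kind, "-", x$spec$n_steps, "steps\n")
  cat(sprintf("  group alpha D_A: %.6g (start) -> %.6g (final)\n",
              a0$D_A[1L], a0$D_A[nrow(a0)]))
  cat(sprintf("  group alpha D_R: %.4g%% (start) -> %.4g%% (final)\n",
              100 * a0$D_R[1L], 100 * a0$D_R[nrow(a0)]))
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, fraction = 0.5, ...) {
  out <- list(kind = object$spec$kind,
              n_steps = object$spec$n_steps,
              at_fraction = fraction,
              changes = summarize_at_fraction(object, fraction),
              elimination = vapply(c(alpha = "alpha", beta = "beta"),
                                   function(g) emission_reduction_at_zero_disparity(object, g),
                                   numeric(1)))
  class(out) <- "summary.scenario_result"
  out
}

#' @export
print.summary.scenario_result <- function(x, ...) {
  cat("Scenario", x$kind, "-", x$n_steps, "steps\n")
  cat(sprintf("Component changes at %g%% emission reduction:\n", 100 * x$at_fraction))
  print(x$changes, row.names = FALSE, digits = 4)
  cat("Emission reduction eliminating absolute disparity:\n")
  for (g in names(x$elimination))
    cat(sprintf("  %s: %s\n", g,
                if (x$elimination[[g]] >= 1) "only at full elimination of emissions"
                else sprintf("%.1f%%", 100 * x$elimination[[g]])))
  invisible(x)
}

#' @export
as.data.frame.scenario_result <- function(x, ...) x$records

#' Plot a scenario result
#'
#' `type = "disparity"` draws group alpha's absolute disparity against the
#' emission-reduction fraction; `type = "components"` draws the percent
#' change of each framework component at `fraction` as a bar chart.
#'
#' @param x A [run_scenario()] result.
#' @param type `"disparity"` or `"components"`.
#' @param group_label Group to plot.
#' @param fraction Emission-reduction fraction for `type = "components"`.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.scenario_result <- function(x, type = c("disparity", "components"),
                                 group_label = "alpha", fraction = 0.5, ...) {
  type <- match.arg(type)
  if (type == "disparity") {
    r <- group_records(x, group_label)
    graphics::plot(100 * x$emission_fraction_reduced, r$D_A, type = "l",
                   xlab = "Emissions reduced (%)",
                   ylab = sprintf("Absolute disparity D_A (%s)", group_label),
                   main = x$spec$kind, ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    ch <- summarize_at_fraction(x, fraction, groups = group_label)
    vals <- unlist(ch[1, c("pct_change_E", "pct_change_XF",
                           "pct_change_DR", "pct_change_DA")])
    graphics::barplot(vals, names.arg = c("E", "XF-bar", "D_R", "D_A"),
                      ylab = sprintf("Percent change at %g%% emission cut",
                                     100 * fraction),
                      main = x$spec$kind, ...)
    graphics::abline(h = 0)
  }
  invisible(x)
}
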