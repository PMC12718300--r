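# all scenario tests run on a small fixture city; the full-size configuration
# is exercised in test-acceptance.R
fixture_setup <- function(n = 9, sigma = 2, n_steps = 40, decay = FALSE) {
  city <- tiny_city(n)
  params <- tiny_params(n = n, sigma = sigma)
  if (decay)
    params <- tiny_params(n = n, sigma = sigma,
                          decay_rate = default_decay_rate(params))
  list(city = city, params = params, n_steps = n_steps)
}

test_that("scenario trajectories implement their archetypes", {
  fx <- fixture_setup()
  s1 <- make_scenario("reduce_E", fx$city, fx$params, n_steps = fx$n_steps)
  expect_true(all(s1$trajectory[, 1] == s1$trajectory[1, 1]))
  expect_true(all(s1$trajectory[, 2] == s1$trajectory[1, 2]))

  s2 <- make_scenario("reduce_E_XF", fx$city, fx$params, n_steps = fx$n_steps)
  expect_true(all(s2$trajectory[, 1] == s2$trajectory[1, 1]))  # x frozen
  expect_true(all(diff(s2$trajectory[, 2]) > 0))               # y strictly north

  s3 <- make_scenario("reduce_E_XF_DR", fx$city, fx$params, n_steps = fx$n_steps)
  expect_true(all(diff(s3$trajectory[, 1]) <= 1e-12))  # x monotone west
  # radial distance from the center never shrinks
  rad <- sqrt((s3$trajectory[, 1] - fx$city$center[["x"]])^2 +
              (s3$trajectory[, 2] - fx$city$center[["y"]])^2)
  expect_true(all(diff(rad) >= -1e-9))
  # all positions inside the grid
  expect_true(all(s3$trajectory >= 0 & s3$trajectory <= fx$city$n - 1))

  expect_error(make_scenario("reduce_nothing", fx$city, fx$params),
               class = "airdisp_validation_error")
  expect_error(make_scenario("reduce_E", fx$city, fx$params,
                             source_start = c(99, 0)),
               class = "airdisp_validation_error")
})

test_that("the equity longitude of the symmetric city is the central column", {
  fx <- fixture_setup(n = 15, sigma = 3)
  x_eq <- find_equity_longitude(fx$city, fx$params, y = 7)
  expect_equal(x_eq, (fx$city$n - 1) / 2, tolerance = 1e-6)
  # relative disparity at the equity longitude is zero to tolerance
  fld <- gaussian_concentration(emission_source(x_eq, 7, 1), fx$params)
  dr <- relative_disparity(
    population_weighted_mean(fld, fx$city$pop_alpha),
    population_weighted_mean(fld, fx$city$pop_alpha + fx$city$pop_beta))
  expect_lt(abs(dr), 1e-3)
})

test_that("emissions decline linearly and stop one increment above zero", {
  fx <- fixture_setup()
  spec <- make_scenario("reduce_E", fx$city, fx$params, n_steps = fx$n_steps,
                        initial_emissions = 10)
  res <- run_scenario(fx$city, spec, fx$params)
  e <- res$records$E[res$records$group == "alpha"]
  expect_equal(e, 10 * (1 - (0:(fx$n_steps - 1)) / fx$n_steps))
  expect_true(all(diff(e) < 0))
  expect_equal(min(e), 10 / fx$n_steps)  # epsilon endpoint, never exactly zero
  expect_equal(res$emission_fraction_reduced,
               (0:(fx$n_steps - 1)) / fx$n_steps)
})

test_that("reduce_E freezes the spatial pattern: constant D_R, D_A proportional to E", {
  fx <- fixture_setup()
  spec <- make_scenario("reduce_E", fx$city, fx$params, n_steps = fx$n_steps)
  res <- run_scenario(fx$city, spec, fx$params)
  a <- res$records[res$records$group == "alpha", ]
  expect_lt(max(a$D_R) - min(a$D_R), 1e-10)
  f <- res$emission_fraction_reduced
  expect_equal(a$D_A, (1 - f) * a$D_A[1], tolerance = 1e-6)
  # D_A at the step nearest 50% reduction is half the initial value
  at50 <- which(f >= 0.5)[1]
  expect_equal(a$D_A[at50], 0.5 * a$D_A[1], tolerance = 0.01)
})

test_that("identical inputs give identical results, and all records satisfy the identity", {
  fx <- fixture_setup()
  spec <- make_scenario("reduce_E_XF_DR", fx$city, fx$params, n_steps = fx$n_steps)
  r1 <- run_scenario(fx$city, spec, fx$params)
  r2 <- run_scenario(fx$city, spec, fx$params)
  expect_identical(r1$records, r2$records)
  with(r1$records, expect_equal(E * XF_bar * D_R, D_A, tolerance = 1e-12))
  # the two complementary groups have share-weighted disparities summing to zero
  a <- r1$records[r1$records$group == "alpha", ]
  b <- r1$records[r1$records$group == "beta", ]
  share <- sum(fx$city$pop_alpha) / sum(fx$city$pop_alpha + fx$city$pop_beta)
  expect_equal(share * a$D_A + (1 - share) * b$D_A, rep(0, fx$n_steps),
               tolerance = 1e-15)
})

test_that("component changes at the 50% point follow each archetype", {
  fx <- fixture_setup()
  runs <- lapply(c("reduce_E", "reduce_E_XF", "reduce_E_XF_DR"), function(kind) {
    run_scenario(fx$city,
                 make_scenario(kind, fx$city, fx$params, n_steps = fx$n_steps),
                 fx$params)
  })
  ch <- lapply(runs, summarize_at_fraction, fraction = 0.5, groups = "alpha")
  # the linear schedule pins the emission change at -100 * fraction
  for (x in ch) expect_equal(x$pct_change_E, -50)
  # scenario 1: pattern frozen
  expect_equal(ch[[1]]$pct_change_XF, 0, tolerance = 1e-8)
  expect_equal(ch[[1]]$pct_change_DR, 0, tolerance = 1e-8)
  expect_equal(ch[[1]]$pct_change_DA, -50, tolerance = 1e-6)
  # scenario 2: exposure factor falls, relative disparity does not fall
  expect_lt(ch[[2]]$pct_change_XF, 0)
  expect_gt(ch[[2]]$pct_change_DR, -5)
  # scenario 3: all three fall; the disparity reduction beats 50%
  expect_lt(ch[[3]]$pct_change_XF, 0)
  expect_lt(ch[[3]]$pct_change_DR, -99)
  expect_gt(abs(ch[[3]]$pct_change_DA), 50)
  # a fraction beyond the final step is a domain error
  expect_error(summarize_at_fraction(runs[[1]], 0.9999),
               class = "airdisp_domain_error")
})

test_that("only the scenario that reduces relative disparity eliminates D_A early", {
  for (decay in c(FALSE, TRUE)) {
    fx <- fixture_setup(decay = decay)
    runs <- lapply(c("reduce_E", "reduce_E_XF", "reduce_E_XF_DR"), function(kind) {
      run_scenario(fx$city,
                   make_scenario(kind, fx$city, fx$params, n_steps = fx$n_steps),
                   fx$params)
    })
    elim <- vapply(runs, emission_reduction_at_zero_disparity, numeric(1))
    expect_equal(elim[1], 1.0)
    expect_equal(elim[2], 1.0)
    expect_lt(elim[3], 1.0)
    # disparity ordering holds at every step: s3 <= s2 <= s1
    da <- vapply(runs, function(r) r$records$D_A[r$records$group == "alpha"],
                 numeric(fx$n_steps))
    expect_true(all(da[, 3] <= da[, 2] + 1e-15))
    expect_true(all(da[, 2] <= da[, 1] + 1e-15))
  }
})

test_that("scenario comparison reports the saving in required emission reduction", {
  fx <- fixture_setup()
  runs <- lapply(c("reduce_E", "reduce_E_XF", "reduce_E_XF_DR"), function(kind) {
    run_scenario(fx$city,
                 make_scenario(kind, fx$city, fx$params, n_steps = fx$n_steps),
                 fx$params)
  })
  expect_equal(compare_scenarios(runs[[1]], runs[[1]]), 0)
  expect_equal(compare_scenarios(runs[[1]], runs[[2]]), 0)
  saving <- compare_scenarios(runs[[1]], runs[[3]])
  expect_gt(saving, 0)
  expect_lt(saving, 100)
  expect_error(emission_reduction_at_zero_disparity(runs[[1]], "gamma"),
               class = "airdisp_validation_error")
})

test_that("final disparity is bounded by the emission scaling when D_R does not rise", {
  fx <- fixture_setup()
  for (kind in c("reduce_E", "reduce_E_XF_DR")) {
    res <- run_scenario(fx$city,
                        make_scenario(kind, fx$city, fx$params, n_steps = fx$n_steps),
                        fx$params)
    a <- res$records[res$records$group == "alpha", ]
    expect_lte(a$D_A[fx$n_steps],
               a$D_A[1] * a$E[fx$n_steps] / a$E[1] + 1e-12)
  }
})
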