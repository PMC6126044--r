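test_that("feed carbohydrate concentration sums monomer-equivalent fractions", {
  sw <- switchgrass_composition()
  expect_equal(feed_carbohydrate_concentration(sw, 30), 17.3,
    tolerance = 0.05 / 17.3)
  zero <- feedstock_composition(0, 0, 0, cod_per_gram = 1.22)
  expect_identical(feed_carbohydrate_concentration(zero, 30), 0)
  half <- feedstock_composition(0.5, 0, 0)
  expect_equal(feed_carbohydrate_concentration(half, 10), 5.0)
  expect_error(feed_carbohydrate_concentration(sw, -1),
    class = "thermodigest_domain_error")
  expect_error(feedstock_composition(0.8, 0.3, 0.2),
    class = "thermodigest_invalid_composition")
})

test_that("FCS is the solubilized share and rejects inconsistent masses", {
  expect_equal(compute_fcs(17.3, 17.3), 0)
  expect_equal(compute_fcs(17.3, 0), 1)
  expect_equal(compute_fcs(17.3, 5.0), (17.3 - 5) / 17.3)
  expect_equal(round(compute_fcs(17.3, 5.0), 3), 0.711)
  expect_error(compute_fcs(0, 1), class = "thermodigest_domain_error")
  expect_error(compute_fcs(10, 11),
    class = "thermodigest_measurement_inconsistency")
  # round trip: residual implied by an FCS maps back to the same FCS
  fcs <- c(0, 0.25, 0.711, 1)
  expect_equal(compute_fcs(17.3, 17.3 * (1 - fcs)), fcs)
})

test_that("steady-state points follow C = C0(1-FCS), r = C0 FCS / RT", {
  pts <- steady_state_points(
    tibble::tibble(rt_days = 10, fcs_total = 0.654), c0 = 17.3)
  expect_equal(pts$c_unutilized, 17.3 * 0.346)
  expect_equal(pts$rate, 17.3 * 0.654 / 10)
  expect_equal(round(pts$c_unutilized, 2), 5.99)
  expect_equal(round(pts$rate, 3), 1.131)

  corner <- steady_state_points(
    tibble::tibble(rt_days = c(20, 5), fcs_total = c(0, 1)), c0 = 17.3)
  expect_equal(corner$c_unutilized, c(17.3, 0))
  expect_equal(corner$rate, c(0, 17.3 / 5))

  expect_error(
    steady_state_points(tibble::tibble(rt_days = 0, fcs_total = 0.5), 17.3),
    class = "thermodigest_domain_error")
})

test_that("rate-law fit matches the closed-form OLS oracle on printed means", {
  pts <- steady_state_points(printed_obs(), c0 = 17.3)
  fit <- fit_recalcitrant_first_order(pts, c0 = 17.3)

  o <- ols_oracle(pts$c_unutilized, pts$rate)
  expect_equal(fit$k, o$slope, tolerance = 1e-12)
  expect_equal(fit$f_r, -o$intercept / (o$slope * 17.3), tolerance = 1e-12)

  # the four published means reproduce the published fit inside its own SE
  expect_lt(abs(fit$k - 0.717), 0.068)
  expect_lt(abs(fit$f_r - 0.247), 0.036)
  expect_gt(fit$r_squared, 0.9)

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "k"], fit$k)
  expect_equal(glance(fit)$nobs, 4L)
})

test_that("noiseless model-generated points are recovered to machine precision", {
  c0 <- 17.3
  k <- 0.5
  f_r <- 0.25
  C <- c(4.8, 6.1, 7.4, 9.0, 12.0)
  pts <- tibble::tibble(c_unutilized = C, rate = k * (C - c0 * f_r))
  fit <- fit_recalcitrant_first_order(pts, c0)
  expect_equal(fit$k, k, tolerance = 1e-10)
  expect_equal(fit$f_r, f_r, tolerance = 1e-10)
})

test_that("degenerate or non-physical kinetic inputs are rejected", {
  expect_error(
    fit_recalcitrant_first_order(
      tibble::tibble(c_unutilized = c(5, 5, 5), rate = c(1, 2, 3)), 17.3),
    class = "thermodigest_fit_error")
  expect_error(
    fit_recalcitrant_first_order(
      tibble::tibble(c_unutilized = c(5, 6), rate = c(1, 2)), 17.3),
    class = "thermodigest_fit_error")
  decreasing <- tibble::tibble(
    c_unutilized = c(4, 6, 8), rate = c(3, 2, 1))
  expect_error(fit_recalcitrant_first_order(decreasing, 17.3),
    class = "thermodigest_nonphysical_fit")
})

test_that("delta-method f_r standard error tracks the sampling spread", {
  c0 <- 17.3
  k <- 0.717
  f_r <- 0.247
  C <- seq(4.5, 9, length.out = 8)
  set.seed(42)
  ests <- replicate(200, {
    pts <- tibble::tibble(
      c_unutilized = C,
      rate = k * (C - c0 * f_r) * (1 + rnorm(8, 0, 0.03)))
    fit <- fit_recalcitrant_first_order(pts, c0)
    c(fit$f_r, fit$f_r_se)
  })
  empirical_sd <- sd(ests[1, ])
  mean_se <- mean(ests[2, ])
  expect_gt(mean_se / empirical_sd, 0.6)
  expect_lt(mean_se / empirical_sd, 1.6)
})

test_that("steady-state FCS prediction obeys its closed form and limits", {
  fit <- list(k = 0.717, f_r = 0.247)
  expect_equal(predict_steady_state_fcs(fit, 20), 0.704, tolerance = 5e-4)
  expect_equal(predict_steady_state_fcs(fit, 1e9), 1 - 0.247,
    tolerance = 1e-6)
  expect_lt(predict_steady_state_fcs(fit, 1e-9), 1e-8)

  rts <- c(0.5, 1, 2, 5, 10, 20, 50, 200)
  fcs <- predict_steady_state_fcs(fit, rts)
  expect_true(all(diff(fcs) > 0))
  expect_true(all(fcs < 1 - fit$f_r))
  # increasing in k as well
  expect_true(all(predict_steady_state_fcs(list(k = 1.0, f_r = 0.247), rts) >
    fcs))
  expect_error(predict_steady_state_fcs(fit, 0),
    class = "thermodigest_domain_error")
})

test_that("fit and prediction round-trip through model-generated points", {
  k <- 0.6
  f_r <- 0.3
  c0 <- 17.3
  rts <- c(3.3, 5, 8, 12, 20, 40)
  fcs <- predict_steady_state_fcs(list(k = k, f_r = f_r), rts)
  fit <- tibble::tibble(rt_days = rts, fcs_total = fcs) |>
    steady_state_points(c0) |>
    fit_recalcitrant_first_order(c0)
  expect_equal(fit$k, k, tolerance = 1e-9)
  expect_equal(predict_steady_state_fcs(fit, rts), fcs, tolerance = 1e-9)
})

test_that("glucan-xylan regression recovers exact and noisy lines", {
  exact <- tibble::tibble(
    fcs_glucan = c(0, 0.5, 1),
    fcs_xylan = 0.826 * c(0, 0.5, 1) + 0.114)
  r <- glucan_xylan_regression(exact)
  expect_equal(r$slope, 0.826, tolerance = 1e-12)
  expect_equal(r$intercept, 0.114, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)

  set.seed(7)
  g <- runif(100, 0.3, 0.9)
  noisy <- tibble::tibble(
    fcs_glucan = g, fcs_xylan = 0.8 * g + 0.1 + rnorm(100, 0, 0.01))
  rn <- glucan_xylan_regression(noisy)
  expect_lt(abs(rn$slope - 0.8), 3 * rn$slope_se)
  expect_lt(abs(rn$intercept - 0.1), 3 * rn$intercept_se)

  expect_error(glucan_xylan_regression(
    tibble::tibble(fcs_glucan = c(0.5, 0.5, 0.5), fcs_xylan = c(1, 2, 3))),
    class = "thermodigest_fit_error")
})
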