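test_that("reactor config validates the feeding-protocol invariants", {
  expect_error(reactor_config(rt_days = 20, k = 0.7, f_r = 0.25,
    feeds_per_rt = 10, replaced_fraction = 0.2),
    class = "thermodigest_config_error")
  expect_error(reactor_config(rt_days = 20, k = 0.7, f_r = 0.25,
    replaced_fraction = 1.2), class = "thermodigest_config_error")
  expect_error(reactor_config(rt_days = -1, k = 0.7, f_r = 0.25),
    class = "thermodigest_config_error")
  expect_error(reactor_config(rt_days = 20, k = 0.7, f_r = 1.0),
    class = "thermodigest_config_error")
  cfg <- reactor_config(rt_days = 20, k = 0.7, f_r = 0.25,
    feeds_per_rt = 20, replaced_fraction = 0.05)
  expect_equal(cfg$c0, feed_carbohydrate_concentration(
    cfg$feed_composition, 30))
})

test_that("every feed event conserves mass exactly", {
  cfg <- reactor_config(rt_days = 10, k = 0.717, f_r = 0.247)
  sim <- simulate_reactor(cfg, 6)
  pool_before <- sim$c_accessible + sim$c_recalcitrant
  pool_after <- sim$a_post + sim$r_post
  imbalance <- abs((pool_after - pool_before) -
    (sim$feed_in - sim$removed_mass))
  expect_lt(max(imbalance / pool_before), 1e-9)
})

test_that("the recalcitrant pool settles at C0 * f_r", {
  cfg <- reactor_config(rt_days = 10, k = 0.717, f_r = 0.247)
  sim <- simulate_reactor(cfg, 5)
  final_r <- dplyr::last(sim$c_recalcitrant)
  expect_equal(final_r, cfg$c0 * 0.247, tolerance = 0.01)
})

test_that("kinetic limits: no reaction means no solubilization, fast reaction full", {
  dead <- simulate_reactor(
    reactor_config(rt_days = 10, k = 0, f_r = 0.2), 12)
  expect_lt(dplyr::last(dead$fcs), 1e-4)

  fast <- simulate_reactor(
    reactor_config(rt_days = 10, k = 50, f_r = 0), 5)
  expect_gt(dplyr::last(fast$fcs), 0.999)
})

test_that("simulations are bit-reproducible under a seed", {
  cfg <- reactor_config(rt_days = 10, k = 0.717, f_r = 0.247,
    noise_cv = 0.01, seed = 99)
  s1 <- simulate_reactor(cfg, 5)
  s2 <- simulate_reactor(cfg, 5)
  expect_identical(s1$fcs_measured, s2$fcs_measured)
  cfg2 <- reactor_config(rt_days = 10, k = 0.717, f_r = 0.247,
    noise_cv = 0.01, seed = 100)
  expect_false(identical(simulate_reactor(cfg2, 5)$fcs_measured,
    s1$fcs_measured))
})

test_that("cycle-mean FCS at RT 20 matches the continuous closed form", {
  cfg <- reactor_config(rt_days = 20, k = 0.717, f_r = 0.247)
  s <- steady_state_summary(simulate_reactor(cfg, 10))
  closed <- predict_steady_state_fcs(list(k = 0.717, f_r = 0.247), 20)
  expect_equal(s$fcs_cycle_mean, closed, tolerance = 0.01 / closed)
  # and the sampled (pre-feed) value matches the discrete closed form
  expect_equal(s$fcs_sampled_mean,
    discrete_sampled_fcs(0.717, 0.247, cfg$c0, 20), tolerance = 1e-9)
})

test_that("dataset generation needs three distinct residence times", {
  cfgs <- list(
    reactor_config(rt_days = 10, k = 0.7, f_r = 0.25),
    reactor_config(rt_days = 10, k = 0.7, f_r = 0.25))
  expect_error(generate_steady_state_dataset(cfgs),
    class = "thermodigest_domain_error")
})

test_that("noiseless dataset round-trips the rate constant within 2%", {
  cfgs <- lapply(c(20, 10, 5, 3.3), function(rt) {
    reactor_config(rt_days = rt, k = 0.717, f_r = 0.247)
  })
  ds <- generate_steady_state_dataset(cfgs)
  truth <- attr(ds, "truth")
  fit <- ds |>
    steady_state_points(truth$c0) |>
    fit_recalcitrant_first_order(truth$c0)
  expect_lt(abs(fit$k - truth$k) / truth$k, 0.02)
})

test_that("discrete sampling biases f_r down by a known, bounded amount", {
  # fitting nominal steady-state formulas to pre-feed samples from
  # 10-feeds-per-RT operation underestimates f_r; the bias is a property
  # of the protocol, pinned here against the closed-form oracle
  c0 <- 17.271
  rts <- c(3.3, 4, 5, 7, 10, 13, 16, 20)
  est <- discrete_fit_estimand(0.717, 0.247, c0, rts)
  expect_lt(est$f_r, 0.247)
  expect_lt(abs(est$f_r - 0.247), 0.04)
  expect_gt(abs(est$f_r - 0.247), 0.02)
  expect_lt(abs(est$k - 0.717) / 0.717, 0.03)
})

test_that("noisy replicates recover the protocol's estimand", {
  # 1% multiplicative measurement noise, 8 RT levels, 200 seeded replicates
  k_true <- 0.717
  f_r_true <- 0.247
  rts <- c(3.3, 4, 5, 7, 10, 13, 16, 20)
  c0 <- feed_carbohydrate_concentration(switchgrass_composition(), 30)
  estimand <- discrete_fit_estimand(k_true, f_r_true, c0, rts)

  errs <- vapply(1:200, function(rep) {
    cfgs <- lapply(seq_along(rts), function(i) {
      reactor_config(rt_days = rts[i], k = k_true, f_r = f_r_true,
        noise_cv = 0.01, seed = rep * 100 + i)
    })
    ds <- generate_steady_state_dataset(cfgs)
    fit <- ds |>
      steady_state_points(c0) |>
      fit_recalcitrant_first_order(c0)
    c(abs(fit$k - k_true) / k_true, abs(fit$f_r - estimand$f_r))
  }, numeric(2))

  expect_lte(median(errs[1, ]), 0.05)
  expect_lte(median(errs[2, ]), 0.02)
})
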