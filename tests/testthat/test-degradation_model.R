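test_that("area_fraction follows the isotropic shrinkage law", {
  p <- degradation_params(0.1, 0.1, 0.0019115)
  expect_identical(area_fraction(0, p), 1.0)
  # complete degradation where 1 - 2kt/0.1 hits zero
  tc <- 0.1 / (2 * 0.0019115)
  expect_equal(tc, 26.15747, tolerance = 1e-5)
  expect_equal(t_complete(p), tc)
  expect_identical(area_fraction(tc * 1.01, p), 0)
  # loss at 1 month forced by construction
  k75 <- k_from_loss_at_1M(7.5)
  expect_equal(area_fraction(1, degradation_params(0.1, 0.1, k75)), 0.925)
  # non-increasing in t and k, exactly 0 beyond t_complete
  ts <- seq(0, 40, by = 0.5)
  f <- area_fraction(ts, p)
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f[ts >= tc] == 0))
})

test_that("k_from_loss_at_1M matches closed form and a numeric root-finder", {
  expect_identical(k_from_loss_at_1M(0), 0)
  expect_equal(k_from_loss_at_1M(5, 0.1), 0.1 * (1 - sqrt(0.95)) / 2)
  expect_equal(k_from_loss_at_1M(5, 0.1), 0.001266, tolerance = 1e-3)
  expect_equal(k_from_loss_at_1M(100, 0.1), 0.05)
  expect_error(k_from_loss_at_1M(120), "loss")
  # rectangular case against uniroot run independently here
  w <- 0.2; h <- 0.1; loss <- 12
  k <- k_from_loss_at_1M(loss, w, h)
  oracle <- uniroot(function(kk) (1 - 2 * kk / w) * (1 - 2 * kk / h) -
                      (1 - loss / 100), c(0, 0.05), tol = 1e-13)$root
  expect_equal(k, oracle, tolerance = 1e-9)
  # round trip: loss -> k -> loss recovers k to 1e-10 (square case)
  for (loss in c(1, 5, 7.5, 10, 40, 80)) {
    k <- k_from_loss_at_1M(loss, 0.1)
    p <- degradation_params(0.1, 0.1, k)
    k2 <- k_from_loss_at_1M(100 * (1 - area_fraction(1, p)), 0.1)
    expect_equal(k, k2, tolerance = 1e-10)
  }
})

test_that("t50 and t_complete obey the square closed form and a grid oracle", {
  # square: t50 / t_complete = 1 - 1/sqrt(2) for any parameterization
  for (k in c(0.001, 0.0019115, 0.01)) {
    p <- degradation_params(0.1, 0.1, k)
    expect_equal(t50(p) / t_complete(p), 1 - 1 / sqrt(2), tolerance = 1e-9)
  }
  # rectangular: t50 by bisection vs dense grid evaluation
  p <- degradation_params(w = 0.2, h = 0.1, k = 0.0025)
  expect_equal(t_complete(p), 20)
  ts <- seq(0, 20, by = 1e-4)
  grid_t50 <- ts[which.min(abs(area_fraction(ts, p) - 0.5))]
  expect_equal(t50(p), grid_t50, tolerance = 1e-3)
  p0 <- degradation_params(0.1, 0.1, 0)
  expect_warning(tc0 <- t_complete(p0), "infinite")
  expect_identical(tc0, Inf)
})

test_that("scenario curves start at 1, order by loss, and hit closed-form endpoints", {
  curves <- simulate_scenarios(times = c(0, 1, 5, 10, 15, 19, 25))
  expect_length(curves, 3)
  for (cv in curves) {
    expect_identical(cv$fractions[1], 1.0)
    expect_true(all(diff(cv$fractions) <= 1e-12))
    expect_true(all(cv$fractions >= 0 & cv$fractions <= 1))
  }
  at5 <- vapply(curves, function(cv) cv$fractions[cv$times == 5], numeric(1))
  expect_true(at5[1] > at5[2] && at5[2] > at5[3])
  # the 10% curve completes at 1 / (1 - sqrt(0.9)) months
  p10 <- degradation_params(0.1, 0.1, k_from_loss_at_1M(10))
  expect_equal(t_complete(p10), 1 / (1 - sqrt(0.9)), tolerance = 1e-9)
  expect_equal(t_complete(p10), 19.4868, tolerance = 1e-4)
})

test_that("fit_T recovers the programmed period", {
  ts <- c(1, 6, 12, 18)
  obs <- data.frame(time = ts, fraction = pmax(0, 1 - ts / 20)^2)
  fit <- fit_T(obs)
  expect_equal(fit$T_fit, 20, tolerance = 5e-4)
  expect_lt(fit$residual_ss, 1e-10)
  expect_equal(fit$t50, fit$T_fit * (1 - 1 / sqrt(2)), tolerance = 1e-9)
  # noisy recovery: median over 100 replicates within +-1.5 months of 23.5
  set.seed(7)
  T_hat <- replicate(100, {
    y <- pmax(0, 1 - ts / 23.5)^2 + rnorm(4, 0, 0.03)
    fit_T(data.frame(time = ts, fraction = y))$T_fit
  })
  expect_lt(abs(median(T_hat) - 23.5), 1.5)
  expect_error(fit_T(data.frame(time = c(6, 6), fraction = c(0.5, 0.5))),
               "distinct times")
  expect_error(fit_T(data.frame(time = ts, fraction = rep(0, 4))),
               "unidentifiable")
})

test_that("best_scenario picks the closest loss", {
  expect_equal(as.numeric(best_scenario(23.5)), 7.5)
  # reference exactly a scenario curve returns that scenario
  for (loss in c(5, 10)) {
    Tl <- t_complete(degradation_params(0.1, 0.1, k_from_loss_at_1M(loss)))
    expect_equal(as.numeric(best_scenario(Tl)), loss)
  }
  ssq <- attr(best_scenario(23.5), "sums_of_squares")
  expect_length(ssq, 3)
  expect_true(ssq[["7.5"]] < ssq[["5"]] && ssq[["7.5"]] < ssq[["10"]])
})
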