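# Maximum-entropy reweighting: Kish ratio, dual solver, theta tuning,
# cross-validation.

test_that("the Kish ratio matches closed forms", {
  expect_equal(kish_ratio(rep(1, 10)), 1.0)
  expect_equal(kish_ratio(rep(0.25, 8)), 1.0)  # normalization-invariant
  expect_equal(kish_ratio(c(1, rep(0, 9))), 0.1)
  expect_equal(kish_ratio(c(0.5, 0.25, 0.25)), 1 / (3 * 0.375))
  expect_error(kish_ratio(c(-1, 2)), "non-negative")
  expect_error(kish_ratio(c(0, 0)), "zero")
})

test_that("a two-frame hard constraint solves exactly", {
  obs <- observable_table(matrix(c(0, 1), 2, 1), targets = 0.75,
                          uncertainties = 0.1)
  fit <- maxent_fit(obs, theta = 1e-10)
  expect_equal(fit$weights, c(0.25, 0.75), tolerance = 1e-6)
  expect_lt(fit$rmse_fit, 1e-6)
})

test_that("targets at the prior means leave the weights uniform", {
  fx <- fx_reweight()
  obs <- fx$obs
  obs$targets[] <- colMeans(obs$values)
  fit <- maxent_fit(obs, restraints = fx$restr, theta = 1e-8)
  expect_equal(fit$kish, 1.0, tolerance = 1e-6)
  expect_lt(max(abs(fit$lambda)), 1e-4)
  expect_equal(fit$weights, rep(1 / 200, 200), tolerance = 1e-6)
})

test_that("noiseless Gibbs-form truth weights are recovered exactly", {
  fx <- fx_reweight()
  fit <- maxent_fit(fx$obs, restraints = fx$restr, holdout = fx$held,
                    theta = 1e-8)
  cosine <- sum(fit$weights * fx$wtruth) /
    sqrt(sum(fit$weights^2) * sum(fx$wtruth^2))
  expect_gt(cosine, 0.95)
  expect_equal(fit$kish, kish_ratio(fx$wtruth), tolerance = 1e-3)
  # weights stay a probability vector
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  # reweighting improves held-out prediction over uniform weights
  expect_lt(fit$rmse_cv, observable_rmse(fx$obs, rep(1, 200), fx$held))
})

test_that("the Kish ratio is monotone in theta and tunable to 0.101", {
  fx <- fx_reweight()
  thetas <- c(1e-2, 1e2, 1e6, 1e10)
  kish <- vapply(thetas, function(th)
    maxent_fit(fx$obs, restraints = fx$restr, theta = th)$kish, numeric(1))
  expect_true(all(diff(kish) >= -1e-9))
  tuned <- tune_theta(fx$obs, restraints = fx$restr, target_kish = 0.101,
                      holdout = fx$held)
  expect_lt(abs(tuned$result$kish - 0.101), 0.005)
  # a target below the hard-constraint Kish floor is diagnosed
  expect_error(tune_theta(fx$obs, restraints = fx$restr, target_kish = 0.01),
               "unreachable")
})

test_that("solutions are minimum-relative-entropy among feasible weights", {
  # brute force on a 4-frame, 1-observable problem: among weight vectors
  # matching the restraint, the maxent solution has the smallest KL to the
  # uniform prior
  vals <- matrix(c(0, 1, 2, 3), 4, 1)
  obs <- observable_table(vals, targets = 1.8, uncertainties = 0.05)
  fit <- maxent_fit(obs, theta = 1e-10)
  expect_equal(sum(fit$weights * vals), 1.8, tolerance = 1e-6)
  kl_fit <- sum(fit$weights * log(fit$weights * 4))
  # enumerate the feasible set directly: with weights (w1, w2, w3, w4),
  # normalization and the restraint leave a 2-parameter family
  set.seed(77)
  checked <- 0
  for (i in 1:500) {
    w1 <- runif(1, 0, 0.4)
    w2 <- runif(1, 0, 0.6)
    w4 <- -0.2 + 2 * w1 + w2
    w3 <- 1.2 - 3 * w1 - 2 * w2
    w <- c(w1, w2, w3, w4)
    if (any(w <= 0)) next
    expect_equal(sum(w * vals), 1.8, tolerance = 1e-12)
    kl <- sum(w * log(w * 4))
    expect_gte(kl, kl_fit - 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("observable RMSE matches hand computation", {
  vals <- matrix(c(1, 3, 2, 4, 0, 2), 2, 3)
  obs <- observable_table(vals, targets = c(2, 3, 0), uncertainties = rep(1, 3))
  w <- c(0.5, 0.5)
  mu <- colMeans(vals)
  expect_equal(observable_rmse(obs, w), sqrt(mean((mu - c(2, 3, 0))^2)))
  expect_equal(observable_rmse(obs, w, subset = 1), 0)
  # all residuals equal to c give RMSE |c|
  obs2 <- observable_table(vals, targets = mu + 0.5, uncertainties = rep(1, 3))
  expect_equal(observable_rmse(obs2, w), 0.5)
})
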