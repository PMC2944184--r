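# shared small fixture
bt3 <- as_branching_times(c(2, 1))

test_that("pure-birth closed form agrees with 1-D numeric maximisation", {
  fit <- fit_model(bt3, "pure_birth")
  expect_equal(fit$params$lambda, 0.2, tolerance = 1e-12)   # (n-2)/sum(i g_i)
  expect_equal(fit$AIC, 2 - 2 * fit$lnL)
  lnl <- function(lam, bt) {
    n <- bt$n
    sum(log((2:(n - 1)) * lam)) - lam * sum((2:n) * bt$intervals)
  }
  for (r in 1:10) {
    bt <- branching_times(simulate_yule(sample(5:50, 1), seed = 300 + r))
    opt <- optimize(lnl, c(1e-6, 50), bt = bt, maximum = TRUE, tol = 1e-10)
    expect_equal(fit_model(bt, "pure_birth")$params$lambda, opt$maximum,
                 tolerance = 1e-6)
  }
})

test_that("rate-variable models nest the rate-constant ones", {
  for (r in 1:5) {
    bt <- branching_times(simulate_yule(30, seed = 400 + r))
    pb <- fit_model(bt, "pure_birth")
    expect_gte(fit_model(bt, "yule2rate")$lnL, pb$lnL - 1e-9)
    expect_gte(fit_model(bt, "birth_death")$lnL, pb$lnL - 1e-9)
    expect_gte(fit_model(bt, "DDX")$lnL, pb$lnL - 1e-9)
    expect_gte(fit_model(bt, "DDL")$lnL, pb$lnL - 1e-6)
  }
  # DDL at essentially infinite carrying capacity is pure birth
  bt <- branching_times(simulate_yule(40, seed = 77))
  s <- divtempo:::bt_sums(bt)
  pb <- fit_model(bt, "pure_birth")
  expect_equal(divtempo:::ddl_profile_z(log(1e8 - bt$n), s), pb$lnL,
               tolerance = 1e-4)
  # a two-rate likelihood constrained to lambda1 = lambda2 is pure birth
  lam <- pb$params$lambda
  n <- bt$n
  constrained <- lfactorial(n - 1) + (n - 2) * log(lam) -
    lam * sum((2:n) * bt$intervals)
  expect_equal(constrained, pb$lnL, tolerance = 1e-9)
})

test_that("birth-death fit matches the established implementation", {
  for (s in 1:3) {
    phy <- simulate_birth_death(35, lambda = 1, mu = 0.5, seed = 500 + s)
    mine <- fit_model(branching_times(phy), "birth_death")
    ref <- suppressWarnings(ape::birthdeath(phy))
    expect_equal(mine$lnL, -ref$dev / 2, tolerance = 1e-3)
    expect_equal(unname(mine$params$r), unname(ref$para["b-d"]),
                 tolerance = 1e-2)
  }
})

test_that("a strong rate shift is detected and comparison conventions hold", {
  set.seed(88)
  bt <- as_branching_times(two_rate_times(200, 0.5, 0.1, shift_at = 100))
  fits <- fit_all_models(bt)
  expect_gt(fits$yule2rate$lnL - fits$pure_birth$lnL, 10)
  cmp <- compare_models(fits, critical_delta = 4)
  expect_equal(cmp$selected, "yule2rate")
  # boundary: delta exactly at the critical value retains rate-constant
  mk <- function(m, lnL, k) divtempo:::new_model_fit(m, list(), lnL, k)
  flat <- list(pure_birth = mk("pure_birth", -10, 1L),
               birth_death = mk("birth_death", -10, 2L),
               DDX = mk("DDX", -9, 2L), DDL = mk("DDL", -9.5, 2L),
               yule2rate = mk("yule2rate", -9.2, 3L))
  delta <- flat$pure_birth$AIC - flat$DDX$AIC
  expect_equal(compare_models(flat, critical_delta = delta)$selected,
               "pure_birth")
  expect_equal(compare_models(flat,
                              critical_delta = delta - 1e-9)$selected, "DDX")
  # extra parameters with no lnL gain keep the rate-constant model
  expect_equal(compare_models(flat, critical_delta = 0)$selected,
               "pure_birth")
  expect_error(compare_models(flat[1:4]), "missing")
})

test_that("delta-AIC calibration returns the right quantile edge cases", {
  cal <- calibrate_delta_critical(15, reps = 100, alpha = 0.05, seed = 19)
  expect_length(cal$deltas, 100)
  expect_equal(cal$critical, sort(cal$deltas)[95])
  expect_equal(mean(cal$deltas > cal$critical), 0.05)
  cal1 <- calibrate_delta_critical(15, reps = 100, alpha = 1, seed = 19)
  expect_equal(cal1$critical, min(cal1$deltas))
  # reproducible given the seed
  cal2 <- calibrate_delta_critical(15, reps = 100, alpha = 0.05, seed = 19)
  expect_identical(cal$deltas, cal2$deltas)
})

test_that("pure-birth rate is recovered from simulated trees", {
  set.seed(21)
  lam_hat <- replicate(100, fit_model(branching_times(
    simulate_yule(60, lambda = 0.2)), "pure_birth")$params$lambda)
  expect_lt(abs(mean(lam_hat) - 0.2) / 0.2, 0.08)
})
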