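test_that("Yule simulator is seeded, ultrametric and has the analytic 2-tip depth", {
  expect_identical(write_chronogram(simulate_yule(20, seed = 4)),
                   write_chronogram(simulate_yule(20, seed = 4)))
  for (s in 1:5)
    expect_silent(validate_chronogram(simulate_yule(sample(2:80, 1),
                                                    seed = 900 + s)))
  # E[root age] for n = 2 is E[Exp(2 lambda)] = 0.5 at lambda = 1
  set.seed(123)
  roots <- replicate(10000, branching_times(simulate_yule(2))$root_age)
  expect_equal(mean(roots), 0.5, tolerance = 0.02)
  expect_error(simulate_yule(1), "n_tips")
})

test_that("birth-death reduces to Yule at mu = 0 and extinction inflates gamma", {
  set.seed(77)
  g_yule <- replicate(1000,
    gamma_statistic(branching_times(simulate_yule(15)))$gamma)
  g_bd0 <- replicate(1000,
    gamma_statistic(branching_times(simulate_birth_death(15, 1, 0)))$gamma)
  expect_gt(suppressWarnings(ks.test(g_yule, g_bd0)$p.value), 0.01)
  # heavy extinction pulls nodes toward the present: mean gamma rises
  g_bd9 <- replicate(600,
    gamma_statistic(branching_times(simulate_birth_death(20, 1, 0.9)))$gamma)
  g_y20 <- replicate(600,
    gamma_statistic(branching_times(simulate_yule(20)))$gamma)
  expect_gt(mean(g_bd9), mean(g_y20))
  for (s in 1:3)
    expect_silent(validate_chronogram(
      simulate_birth_death(12, 1, 0.5, seed = 40 + s)))
  expect_error(simulate_birth_death(10, 1, 1.2), "mu")
})

test_that("incomplete sampling keeps a subset of times and biases gamma negative", {
  tr <- simulate_yule(50, seed = 8)
  expect_identical(sample_incomplete(tr, 50), tr)
  sub <- sample_incomplete(tr, 20, seed = 1)
  bt_all <- branching_times(tr)$times
  expect_true(all(vapply(branching_times(sub)$times, function(t)
    any(abs(bt_all - t) < 1e-9), logical(1L))))
  expect_length(branching_times(sample_incomplete(tr, 2, seed = 2))$times, 1L)
  set.seed(55)
  g_pruned <- replicate(1000, gamma_statistic(branching_times(
    sample_incomplete(simulate_yule(60), 30)))$gamma)
  g_complete <- replicate(1000,
    gamma_statistic(branching_times(simulate_yule(30)))$gamma)
  expect_lt(mean(g_pruned), mean(g_complete))
  expect_error(sample_incomplete(tr, 1), "n_keep")
})

test_that("Mk1 character simulation respects rate limits", {
  tr <- simulate_yule(40, seed = 6)
  expect_true(all(simulate_mk1_states(tr, q = 0, root_state = 1L) == 1L))
  expect_true(all(simulate_mk1_states(tr, q = 0, root_state = 0L) == 0L))
  # stationary limit: huge q makes tips coin flips
  big <- simulate_yule(1000, seed = 13)
  st <- simulate_mk1_states(big, q = 50, root_state = 1L, seed = 14)
  expect_gt(mean(st), 0.44)
  expect_lt(mean(st), 0.56)
  # low rate on a deep tree: most tips keep the root state
  deep <- simulate_yule(500, seed = 15)
  deep$edge.length <- deep$edge.length *
    (16 / branching_times(deep)$root_age)
  st2 <- simulate_mk1_states(deep, q = 0.007, root_state = 1L, seed = 16)
  expect_gt(mean(st2), 0.5)
  expect_error(simulate_mk1_states(tr, q = -1), "q")
})

test_that("tip-state tables round-trip through TSV", {
  tr <- simulate_yule(12, seed = 21)
  st <- simulate_mk1_states(tr, q = 0.3, seed = 22)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tip_states(st, f)
  expect_identical(read_tip_states(f), st)
})
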