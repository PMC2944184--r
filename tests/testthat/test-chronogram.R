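test_that("parsing computes node ages and enforces ultrametricity", {
  tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  ages <- chronogram_ages(tr)
  expect_equal(max(ages), 2)
  expect_error(read_chronogram(text = "((A:1,B:2):1,C:2);"),
               "not ultrametric.*B")
  expect_error(read_chronogram(text = "((A:1,B:1),C:2);"),
               "branch length")
  expect_error(read_chronogram(text = "not a tree"), "parse|malformed")
})

test_that("write/parse round-trip preserves node ages to 1e-9", {
  tr <- simulate_yule(90, seed = 11)
  back <- read_chronogram(text = write_chronogram(tr))
  expect_lt(max(abs(sort(chronogram_ages(back)) - sort(chronogram_ages(tr)))),
            1e-9)
  # polytomies survive the round trip
  poly <- read_chronogram(text = "((A:1,B:1,C:1):1,D:2);")
  expect_false(ape::is.binary.phylo(poly))
  poly2 <- read_chronogram(text = write_chronogram(poly))
  expect_equal(poly2$Nnode, poly$Nnode)
})

test_that("branching times and intervals follow the LTT bookkeeping", {
  bt <- branching_times(read_chronogram(text = "((A:1,B:1):1,C:2);"))
  expect_equal(bt$times, c(2, 1))
  expect_equal(unname(bt$intervals), c(1, 1))
  two <- branching_times(read_chronogram(text = "(A:5,B:5);"))
  expect_equal(two$times, 5)
  expect_equal(unname(two$intervals), 5)
  # conservation: intervals always sum to the root age
  for (s in 1:5) {
    bt <- branching_times(simulate_yule(sample(5:60, 1), seed = 100 + s))
    expect_equal(sum(bt$intervals), bt$root_age)
    expect_length(bt$times, bt$n - 1L)
  }
  # polytomies resolve to zero-length intervals, flagged
  btp <- branching_times(read_chronogram(text = "((A:1,B:1,C:1):1,D:2);"))
  expect_true(btp$polytomies_resolved)
  expect_true(any(btp$intervals == 0))
  expect_equal(sum(btp$intervals), 2)
})

test_that("pruning keeps retained node ages and yields nested times", {
  tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
  pr <- prune_chronogram(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(branching_times(pr)$times, 2)
  expect_error(prune_chronogram(tr, "A"), "at least 2")
  expect_error(prune_chronogram(tr, c("A", "Z")), "unknown")
  big <- simulate_yule(40, seed = 5)
  keep <- big$tip.label[1:15]
  sub <- prune_chronogram(big, keep)
  expect_true(all(vapply(branching_times(sub)$times, function(t)
    any(abs(branching_times(big)$times - t) < 1e-9), logical(1L))))
})

test_that("calibration rescaling is linear and leaves gamma invariant", {
  tr <- simulate_yule(30, seed = 9)
  g0 <- gamma_statistic(branching_times(tr))$gamma
  cal <- scale_to_calibration(tr, "t1", "t2", age = 7.5)
  mrca <- ape::getMRCA(cal, c("t1", "t2"))
  expect_equal(chronogram_ages(cal)[mrca], 7.5, tolerance = 1e-12)
  expect_equal(gamma_statistic(branching_times(cal))$gamma, g0,
               tolerance = 1e-9)
  # calibrating to the current age is the identity
  age_now <- chronogram_ages(tr)[ape::getMRCA(tr, c("t1", "t2"))]
  same <- scale_to_calibration(tr, "t1", "t2", age = age_now)
  expect_equal(same$edge.length, tr$edge.length, tolerance = 1e-12)
  expect_error(scale_to_calibration(tr, "t1", "t1", 5), "differ")
})
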