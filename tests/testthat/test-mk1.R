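test_that("two-tip likelihoods match the degenerate chain by hand", {
  tr <- read_chronogram(text = "(A:1,B:1);")
  expect_equal(mk1_loglik(tr, c(A = 1, B = 1), q = 0), -log(2))
  expect_equal(mk1_loglik(tr, c(A = 1, B = 0), q = 0), -Inf)
  # stationary limit: each branch forgets the root, L -> 1/4
  long <- read_chronogram(text = "(A:500,B:500);")
  expect_equal(mk1_loglik(long, c(A = 1, B = 1), q = 1), -log(4),
               tolerance = 1e-6)
  expect_error(mk1_loglik(tr, c(A = 1), q = 1), "missing state")
  expect_error(mk1_loglik(tr, c(A = 1, B = 1), q = -1), "q")
})

test_that("pruning likelihood equals exhaustive enumeration to 1e-9", {
  for (r in 1:30) {
    n <- sample(4:8, 1)
    phy <- simulate_yule(n, seed = 800 + r)
    q <- runif(1, 0, 2)
    states <- simulate_mk1_states(phy, q = max(q, 0.2), seed = 850 + r)
    expect_equal(mk1_loglik(phy, states, q),
                 mk1_enum_oracle(phy, states, q), tolerance = 1e-9)
  }
})

test_that("marginal reconstructions equal enumeration and respect symmetry", {
  for (r in 1:10) {
    n <- sample(4:6, 1)
    phy <- simulate_yule(n, seed = 860 + r)
    states <- simulate_mk1_states(phy, q = 0.5, seed = 870 + r)
    if (length(unique(states)) == 1L) next
    q <- 0.4
    rec <- marginal_states(phy, states, q = q)
    oracle <- mk1_enum_oracle(phy, states, q, marginals = TRUE)
    expect_equal(unname(as.matrix(rec$node_probs[, c("p0", "p1")])),
                 oracle$probs, tolerance = 1e-9)
    expect_equal(rowSums(rec$node_probs[, c("p0", "p1")]),
                 rep(1, phy$Nnode), tolerance = 1e-12)
  }
  # a symmetric 2-tip tree with discordant tips: root exactly 50:50
  tr <- read_chronogram(text = "(A:2,B:2);")
  rec <- marginal_states(tr, c(A = 1, B = 0), q = 0.3)
  expect_equal(rec$node_probs$p1, 0.5, tolerance = 1e-12)
  # q = 0 with uniform tips: certainty everywhere
  tr4 <- simulate_yule(6, seed = 881)
  st1 <- setNames(rep(1L, 6), tr4$tip.label)
  rec1 <- marginal_states(tr4, st1, q = 0)
  expect_true(all(rec1$node_probs$p1 == 1))
})

test_that("rate estimation matches a brute-force grid and handles boundaries", {
  phy <- simulate_yule(10, seed = 91)
  states <- simulate_mk1_states(phy, q = 0.4, seed = 92)
  fit <- fit_mk1(phy, states)
  grid <- exp(seq(log(1e-4), log(10), length.out = 10000))
  lls <- vapply(grid, function(q) mk1_loglik(phy, states, q), numeric(1))
  expect_equal(fit$q_hat, grid[which.max(lls)], tolerance = 1e-3)
  expect_gte(fit$lnL, max(lls) - 1e-8)
  # monomorphic data: q = 0 boundary, flagged not errored
  mono <- fit_mk1(phy, setNames(rep(1L, 10), phy$tip.label))
  expect_true(mono$boundary)
  expect_equal(mono$q_hat, 0)
  expect_equal(mono$lnL, -log(2))
})

test_that("marginals depend on the tip-to-state map, not vector order", {
  phy <- simulate_yule(8, seed = 95)
  states <- simulate_mk1_states(phy, q = 0.5, seed = 96)
  rec <- marginal_states(phy, states, q = 0.3)
  set.seed(1)
  states2 <- states[sample(names(states))]   # same map, shuffled storage
  rec2 <- marginal_states(phy, states2, q = 0.3)
  expect_equal(rec2$node_probs$p1, rec$node_probs$p1, tolerance = 1e-12)
})

test_that("focal-root search returns the oldest confident node", {
  phy <- simulate_yule(12, seed = 97)
  st1 <- setNames(rep(1L, 12), phy$tip.label)
  rec <- marginal_states(phy, st1, q = 0)
  root_hit <- find_focal_root(phy, rec, focal_state = 1L, threshold = 0.95)
  expect_true(root_hit$found)
  expect_equal(root_hit$node, 13L)          # the ape root number
  expect_equal(root_hit$probability, 1)
  expect_setequal(root_hit$tips, phy$tip.label)
  # nothing qualifies: explicit miss with the best candidate reported
  miss <- find_focal_root(phy, rec, focal_state = 0L, threshold = 0.95)
  expect_false(miss$found)
  expect_true(miss$probability < 0.95)
  expect_error(find_focal_root(phy, rec, 1L, threshold = 1.5), "threshold")
})
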