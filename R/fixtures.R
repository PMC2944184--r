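#' Deterministic test fixtures
#'
#' Regenerates the package's canned fixture set from a seed: tiny trees
#' with hand-checkable statistics plus a seeded batch at the scale of the
#' motivating study (a 122-tip pure-birth tree randomly pruned to 90 tips,
#' root rescaled to 16.2 time units).
#'
#' Components:
#' \describe{
#'   \item{gamma3}{the 3-tip tree `((A:1,B:1):1,C:2);` whose gamma is
#'     -0.34641 by direct arithmetic.}
#'   \item{harmonic}{trees with intervals `g_k = 1/k` for
#'     `n` in 5, 10, 50; their gamma is exactly 0 (the partial sums hit
#'     the pure-birth expectation identically).}
#'   \item{study_complete / study_pruned}{the 122-tip Yule tree and its
#'     90-tip random pruning.}
#'   \item{mk1}{small (4-8 tip) Yule trees with simulated Mk1 tip states,
#'     sized so brute-force enumeration over internal states is feasible.}
#'   \item{expected}{a table of statistic, value, provenance for the
#'     hand-checkable quantities above.}
#' }
#'
#' @param seed master seed (default 1).
#' @param dir optional directory; when given, Newick and TSV files are
#'   written there.
#' @return a list with the components above (class `fixture_set`).
#' @export
make_fixtures <- function(seed = 1L, dir = NULL) {
  gamma3 <- read_chronogram(text = "((A:1,B:1):1,C:2);")

  harmonic <- lapply(c(5L, 10L, 50L), function(n) {
    g <- 1 / (2:n)                       # g_k = 1/k => gamma = 0 exactly
    times <- rev(cumsum(rev(g)))         # t_k = sum_{j>k} g_j + g_{k+1}...
    as_branching_times(times)
  })
  names(harmonic) <- paste0("n", c(5, 10, 50))

  study_complete <- simulate_yule(122L, lambda = 1,
                                  seed = derive_seed(seed, 301L))
  study_complete$edge.length <- study_complete$edge.length *
    (16.2 / branching_times(study_complete)$root_age)
  study_pruned <- sample_incomplete(study_complete, 90L,
                                    seed = derive_seed(seed, 302L))

  mk1 <- lapply(1:4, function(j) {
    n <- 4L + j                          # 5..8 tips
    phy <- simulate_yule(n, lambda = 1, seed = derive_seed(seed, 310L + j))
    states <- simulate_mk1_states(phy, q = 0.3, root_state = 1L,
                                  seed = derive_seed(seed, 320L + j))
    list(tree = phy, states = states)
  })

  expected <- data.frame(
    statistic = c("gamma3_gamma", "harmonic_n10_gamma",
                  "study_pruned_n_branching_times",
                  "study_complete_root_age"),
    value = c(gamma_statistic(branching_times(gamma3))$gamma,
              gamma_statistic(harmonic$n10)$gamma,
              length(branching_times(study_pruned)$times),
              branching_times(study_complete)$root_age),
    oracle = c("direct formula arithmetic (T = 5, S_2 = 2)",
               "algebraic identity: harmonic intervals give gamma = 0",
               "n - 1 for a binary 90-tip tree",
               "rescaled to 16.2 by construction"))

  out <- structure(list(gamma3 = gamma3, harmonic = harmonic,
                        study_complete = study_complete,
                        study_pruned = study_pruned, mk1 = mk1,
                        expected = expected, seed = seed),
                   class = "fixture_set")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_chronogram(gamma3, file.path(dir, "gamma3.nwk"))
    write_chronogram(study_complete, file.path(dir, "study_complete_122.nwk"))
    write_chronogram(study_pruned, file.path(dir, "study_pruned_90.nwk"))
    for (j in seq_along(mk1)) {
      write_chronogram(mk1[[j]]$tree,
                       file.path(dir, sprintf("mk1_tree_%d.nwk", j)))
      write_tip_states(mk1[[j]]$states,
                       file.path(dir, sprintf("mk1_states_%d.tsv", j)))
    }
    utils::write.table(expected, file.path(dir, "expected_values.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
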