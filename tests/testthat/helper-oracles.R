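# Independent oracles used across the suite. Deliberately written as
# plodding loops over the LTT sweep / state enumerations so they share no
# code path with the package implementations they check.

# gamma recomputed by sweeping the lineage-through-time step function of a
# tree: rebuild each g_k as the duration during which exactly k lineages
# exist, then evaluate the formula term by term.
gamma_ltt_oracle <- function(phy) {
  ages <- sort(as.numeric(ape::branching.times(phy)), decreasing = TRUE)
  n <- length(ages) + 1L
  g <- numeric(n)
  for (k in 2:n) {
    upper <- ages[k - 1L]
    lower <- if (k == n) 0 else ages[k]
    g[k] <- upper - lower
  }
  T_tot <- 0
  for (k in 2:n) T_tot <- T_tot + k * g[k]
  S <- numeric(n)
  acc <- 0
  for (i in 2:n) { acc <- acc + i * g[i]; S[i] <- acc }
  num <- mean(S[2:(n - 1L)]) - T_tot / 2
  num / (T_tot * sqrt(1 / (12 * (n - 2))))
}

# Mk1 tree likelihood by exhaustive enumeration over all internal-state
# assignments (feasible to ~8 tips). Returns the log joint sum; marginals
# optionally as the per-node share of the total.
mk1_enum_oracle <- function(phy, states, q, marginals = FALSE) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label)
  n_int <- phy$Nnode
  states <- states[phy$tip.label]
  p_same <- function(t) (1 + exp(-2 * q * t)) / 2
  total <- 0
  node_tot <- matrix(0, n_int, 2L)
  for (code in 0:(2^n_int - 1L)) {
    assign <- as.integer(intToBits(code))[seq_len(n_int)]
    full <- c(as.integer(states), assign)   # indexed by ape node number
    lik <- 0.5                               # equal root prior
    for (e in seq_len(nrow(phy$edge))) {
      a <- full[phy$edge[e, 1L]]
      b <- full[phy$edge[e, 2L]]
      ps <- p_same(phy$edge.length[e])
      lik <- lik * if (a == b) ps else 1 - ps
    }
    total <- total + lik
    if (marginals)
      for (v in seq_len(n_int))
        node_tot[v, assign[v] + 1L] <- node_tot[v, assign[v] + 1L] + lik
  }
  if (marginals) list(lnL = log(total), probs = node_tot / total)
  else log(total)
}

# one-step "tree route" truncation: collapse the most recent branching
# event by dropping one tip of its cherry, so the two daughter lineages
# merge into one lineage running to the present
collapse_most_recent <- function(phy) {
  ages <- divtempo::chronogram_ages(phy)
  n <- length(phy$tip.label)
  internal <- (n + 1L):(2L * n - 1L)
  v <- internal[which.min(ages[internal])]
  tip <- phy$edge[phy$edge[, 1L] == v, 2L][1L]
  stopifnot(tip <= n)   # youngest internal node of an ultrametric tree is a cherry
  ape::drop.tip(phy, phy$tip.label[tip])
}

# interval draws for a two-rate pure-birth process: rate lambda1 while
# fewer than `shift_at` lineages exist, lambda2 after
two_rate_times <- function(n, lambda1, lambda2, shift_at) {
  k <- 2:n
  rates <- ifelse(k <= shift_at, lambda1, lambda2)
  g <- stats::rexp(n - 1L, rate = k * rates)
  rev(cumsum(rev(g)))
}
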