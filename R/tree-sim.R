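#' @title Synthetic chronogram and character simulators
#' @description Seeded generators for pure-birth and birth-death
#'   chronograms conditioned on tip count, random incomplete taxon
#'   sampling, and binary characters evolved under the symmetric two-state
#'   (Mk1) Markov process. These drive every null distribution and
#'   calibration in the package.
#' @name tree_sim
NULL

# Deterministic per-replicate seed stream: an LCG-style map of the master
# seed kept strictly below 2^31 so set.seed() always accepts it. Adding
# streams never perturbs earlier ones.
derive_seed <- function(master, k) {
  as.integer((((master %% 2147483647) * 48271) %% 2147483647 +
                (k * 1013904223) %% 2147483647) %% 2147483647)
}

# Assemble a phylo from interval durations g_2..g_n and the uniform split
# choices; event creating k+1 lineages happens after interval g_k.
build_yule_tree <- function(intervals, picks) {
  n <- length(intervals) + 1L
  root <- n + 1L
  parent_of <- integer(2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  event_time <- cumsum(intervals)          # s_2..s_n; s_n = total depth T
  act_parent <- c(root, root)
  act_ptime <- c(0, 0)
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      v <- n + k                           # internal node created at event k
      i <- picks[k - 1L]
      s <- event_time[k - 1L]
      parent_of[v] <- act_parent[i]
      node_time[v] <- s
      act_parent[i] <- v
      act_ptime[i] <- s
      act_parent[k + 1L] <- v
      act_ptime[k + 1L] <- s
    }
  }
  T_tot <- event_time[n - 1L]
  parent_of[1:n] <- act_parent
  node_time[1:n] <- T_tot
  children <- c(1:n, if (n > 2L) (n + 2L):(2L * n - 1L))
  phy <- structure(list(
    edge = cbind(parent_of[children], children, deparse.level = 0),
    edge.length = node_time[children] - node_time[parent_of[children]],
    tip.label = paste0("t", 1:n),
    Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a pure-birth (Yule) chronogram with a fixed tip count
#'
#' Grows the tree forward in time: while `i` lineages exist the next
#' speciation waits an exponential time with rate `i * lambda`, and a
#' uniformly chosen lineage splits. After the `n`-th lineage appears the
#' final interval to the present is drawn as the `Exp(n * lambda)` waiting
#' time to the (unobserved) next speciation — the construction under which
#' the gamma statistic of complete trees is exactly standard normal.
#' Uniform split choice yields the Yule topology distribution.
#'
#' @param n_tips number of tips (`>= 2`).
#' @param lambda per-lineage speciation rate (`> 0`). Gamma-based nulls are
#'   invariant to this choice (gamma is time-scale free).
#' @param seed optional integer seed; identical seeds give identical trees.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @examples
#' phy <- simulate_yule(10, seed = 1)
#' gamma_statistic(branching_times(phy))
#' @export
simulate_yule <- function(n_tips, lambda = 1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be >= 2")
  if (lambda <= 0) stop("lambda must be > 0")
  if (!is.null(seed)) set.seed(seed)
  intervals <- stats::rexp(n_tips - 1L, rate = (2:n_tips) * lambda)
  picks <- if (n_tips > 2L)
    1L + floor(stats::runif(n_tips - 2L) * (2:(n_tips - 1L)))
  else integer(0)
  build_yule_tree(intervals, as.integer(picks))
}

#' Simulate a birth-death chronogram conditioned on the surviving tip count
#'
#' Forward simulation with per-lineage speciation rate `lambda` and
#' extinction rate `mu`, stopped the first time the standing lineage count
#' reaches `n_tips`; the final interval to the present is the exponential
#' waiting time to the next (unobserved) event. Replicates in which the
#' clade dies out entirely are discarded and redrawn. The returned tree is
#' the reconstructed tree of the survivors (extinct lineages pruned), which
#' is ultrametric. At `mu = 0` the process is exactly the fixed-n Yule
#' construction of [simulate_yule()].
#'
#' @inheritParams simulate_yule
#' @param mu per-lineage extinction rate, `0 <= mu < lambda` (relative
#'   extinction capped at 0.9 so rejection sampling stays practical).
#' @param max_tries retry budget for total-extinction rejections.
#' @return an ultrametric `phylo` with `n_tips` tips.
#' @export
simulate_birth_death <- function(n_tips, lambda = 1, mu = 0, seed = NULL,
                                 max_tries = 10000L) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be >= 2")
  if (lambda <= 0) stop("lambda must be > 0")
  if (mu < 0 || mu >= lambda) stop("need 0 <= mu < lambda")
  if (mu / lambda > 0.9) stop("relative extinction mu/lambda capped at 0.9")
  if (!is.null(seed)) set.seed(seed)
  rate <- lambda + mu
  p_birth <- lambda / rate
  for (try in seq_len(max_tries)) {
    cap <- 4L * n_tips + 8L
    par_key <- integer(cap); birth <- numeric(cap); endt <- numeric(cap)
    fate <- integer(cap)                  # 0 pending, 1 split, 2 dead, 3 alive
    par_key[1:2] <- 0L; birth[1:2] <- 0
    nkey <- 2L
    alive <- c(1L, 2L)
    t <- 0
    repeat {
      k <- length(alive)
      if (k == n_tips) {                  # stop: extend survivors to present
        t <- t + stats::rexp(1L, n_tips * rate)
        endt[alive] <- t; fate[alive] <- 3L
        break
      }
      t <- t + stats::rexp(1L, k * rate)
      i <- alive[sample.int(k, 1L)]
      if (stats::runif(1L) < p_birth) {
        if (nkey + 2L > cap) {
          cap <- cap * 2L
          length(par_key) <- cap; length(birth) <- cap
          length(endt) <- cap; length(fate) <- cap
          par_key[is.na(par_key)] <- 0L
        }
        endt[i] <- t; fate[i] <- 1L
        par_key[nkey + 1:2] <- i; birth[nkey + 1:2] <- t
        alive <- c(alive[alive != i], nkey + 1L, nkey + 2L)
        nkey <- nkey + 2L
      } else {
        endt[i] <- t; fate[i] <- 2L
        alive <- alive[alive != i]
        if (!length(alive)) break         # total extinction: retry
      }
    }
    if (length(alive)) break
    if (try == max_tries) stop("birth-death simulation failed to survive")
  }
  keys <- seq_len(nkey)
  fate <- fate[keys]
  tip_keys <- keys[fate != 1L]
  split_keys <- keys[fate == 1L]
  n_all <- length(tip_keys)
  node_of <- integer(nkey)
  node_of[tip_keys] <- seq_len(n_all)
  node_of[split_keys] <- n_all + 1L + seq_along(split_keys)
  root <- n_all + 1L
  pk <- par_key[keys]
  parent_node <- integer(nkey)
  parent_node[pk == 0L] <- root
  parent_node[pk > 0L] <- node_of[pk[pk > 0L]]
  phy <- structure(list(
    edge = cbind(parent_node, node_of[keys], deparse.level = 0),
    edge.length = endt[keys] - birth[keys],
    tip.label = ifelse(fate[tip_keys] == 3L,
                       paste0("t", seq_len(n_all)),
                       paste0("x", seq_len(n_all))),
    Nnode = length(split_keys) + 1L), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  survivors <- phy$tip.label[startsWith(phy$tip.label, "t")]
  if (length(survivors) < n_all) phy <- ape::keep.tip(phy, survivors)
  phy
}

#' Randomly prune a chronogram to emulate incomplete taxon sampling
#'
#' Retains a uniformly random subset of `n_keep` tips (the MCCR test's
#' model of missing taxa: uniformly random, not clade-biased).
#'
#' @inheritParams simulate_yule
#' @param phy a chronogram.
#' @param n_keep number of tips to retain, `2 <= n_keep <= n`.
#' @return the pruned chronogram.
#' @export
sample_incomplete <- function(phy, n_keep, seed = NULL) {
  n <- length(phy$tip.label)
  n_keep <- as.integer(n_keep)
  if (is.na(n_keep) || n_keep < 2L || n_keep > n)
    stop("n_keep must be in [2, n_tips]")
  if (n_keep == n) return(phy)
  if (!is.null(seed)) set.seed(seed)
  prune_chronogram(phy, phy$tip.label[sample.int(n, n_keep)])
}

#' Evolve a binary character along a chronogram under the Mk1 model
#'
#' Root-to-tip simulation of the symmetric two-state Markov chain with
#' flip rate `q`: along a branch of length `t` the probability of ending
#' in the other state is `(1 - exp(-2 q t)) / 2`.
#'
#' @inheritParams simulate_yule
#' @param phy a chronogram.
#' @param q symmetric transition rate per unit time (`>= 0`).
#' @param root_state state at the root, 0 or 1.
#' @return named integer vector of tip states (names = tip labels).
#' @export
simulate_mk1_states <- function(phy, q, root_state = 1L, seed = NULL) {
  if (q < 0) stop("q must be >= 0")
  if (!root_state %in% c(0L, 1L)) stop("root_state must be 0 or 1")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::reorder.phylo(phy, "cladewise")   # parents precede children
  n <- length(phy$tip.label)
  state <- integer(2L * n - 1L)
  state[n + 1L] <- as.integer(root_state)
  p_flip <- (1 - exp(-2 * q * phy$edge.length)) / 2
  flip <- stats::runif(nrow(phy$edge)) < p_flip
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2L]
    state[child] <- if (flip[e]) 1L - state[phy$edge[e, 1L]]
                    else state[phy$edge[e, 1L]]
  }
  stats::setNames(state[seq_len(n)], phy$tip.label)
}

#' Read / write a two-column tip-state table
#'
#' Plain TSV with header `tip<TAB>state`, states coded 0/1 (in the
#' motivating biogeographic application 1 = Central America, 0 = South
#' America / Greater Antilles).
#'
#' @param file path to the TSV.
#' @return named integer vector of states.
#' @export
read_tip_states <- function(file) {
  df <- utils::read.delim(file, header = TRUE,
                          colClasses = c("character", "integer"))
  if (!identical(names(df)[1:2], c("tip", "state")))
    stop("expected header: tip<TAB>state")
  if (!all(df$state %in% 0:1)) stop("states must be 0/1")
  if (anyDuplicated(df$tip)) stop("duplicate tip in state table")
  stats::setNames(as.integer(df$state), df$tip)
}

#' @rdname read_tip_states
#' @param states named 0/1 vector (names = tip labels).
#' @export
write_tip_states <- function(states, file) {
  utils::write.table(
    data.frame(tip = names(states), state = as.integer(states)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
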