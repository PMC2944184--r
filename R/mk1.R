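#' @title Symmetric two-state (Mk1) ancestral reconstruction
#' @description The one-parameter Markov model for a binary character
#'   (here: occupancy of a focal area, 1 = focal, 0 = elsewhere). With a
#'   single symmetric flip rate `q`, the transition probabilities along a
#'   branch of length `t` are `P(stay) = (1 + exp(-2 q t)) / 2` and
#'   `P(flip) = (1 - exp(-2 q t)) / 2`. Tree likelihoods use the standard
#'   post-order pruning recursion with per-node rescaling; the root is
#'   combined with the equal prior (1/2, 1/2), which is also the
#'   stationary distribution of the symmetric chain.
#' @name mk1_ancestral
NULL

check_states <- function(phy, states) {
  if (is.null(names(states))) stop("states must be a named vector")
  miss <- setdiff(phy$tip.label, names(states))
  if (length(miss)) stop("missing state for tip: ", miss[1L])
  states <- states[phy$tip.label]
  if (!all(states %in% 0:1)) stop("states must be coded 0/1")
  as.integer(states)
}

#' Mk1 log-likelihood of tip states on a chronogram
#'
#' @param phy a chronogram (`phylo`).
#' @param states named 0/1 vector covering every tip.
#' @param q symmetric transition rate (`>= 0`).
#' @return the log-likelihood (may be `-Inf` for `q = 0` with discordant
#'   tips).
#' @examples
#' phy <- read_chronogram(text = "(A:1,B:1);")
#' mk1_loglik(phy, c(A = 1, B = 1), q = 0)  # -log(2)
#' @export
mk1_loglik <- function(phy, states, q) {
  if (q < 0) stop("q must be >= 0")
  states <- check_states(phy, states)
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  m <- max(po$edge)
  L <- matrix(0, m, 2L)
  L[cbind(seq_len(n), states + 1L)] <- 1
  L[(n + 1L):m, ] <- 1
  logscale <- 0
  same <- (1 + exp(-2 * q * po$edge.length)) / 2
  parent <- po$edge[, 1L]; child <- po$edge[, 2L]
  last_edge_of <- !duplicated(parent, fromLast = TRUE)
  for (e in seq_along(parent)) {
    cl <- L[child[e], ]
    L[parent[e], 1L] <- L[parent[e], 1L] *
      (same[e] * cl[1L] + (1 - same[e]) * cl[2L])
    L[parent[e], 2L] <- L[parent[e], 2L] *
      ((1 - same[e]) * cl[1L] + same[e] * cl[2L])
    if (last_edge_of[e]) {                 # node complete: rescale
      sc <- max(L[parent[e], ])
      if (sc > 0 && sc < 1e-50) {
        L[parent[e], ] <- L[parent[e], ] / sc
        logscale <- logscale + log(sc)
      }
    }
  }
  root <- n + 1L
  lik <- 0.5 * L[root, 1L] + 0.5 * L[root, 2L]
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

#' Maximum-likelihood estimate of the Mk1 rate
#'
#' One-dimensional bounded optimisation of [mk1_loglik()] over `log q`
#' with bracket `[1e-8, 10]` per unit time. If every tip carries the same
#' state the optimum is the `q = 0` boundary (no change needed anywhere);
#' this is returned with a flag rather than an error.
#'
#' @inheritParams mk1_loglik
#' @param q_min,q_max search bracket for `q` (per unit branch length).
#' @return list of class `mk1_fit`: `q_hat`, `lnL`, `boundary` (TRUE when
#'   the monomorphic boundary was returned).
#' @export
fit_mk1 <- function(phy, states, q_min = 1e-8, q_max = 10) {
  st <- check_states(phy, states)
  if (length(unique(st)) == 1L)
    return(structure(list(q_hat = 0, lnL = -log(2), boundary = TRUE),
                     class = "mk1_fit"))
  opt <- stats::optimize(function(lq) mk1_loglik(phy, states, exp(lq)),
                         interval = log(c(q_min, q_max)), maximum = TRUE,
                         tol = 1e-10)
  structure(list(q_hat = exp(opt$maximum), lnL = opt$objective,
                 boundary = FALSE),
            class = "mk1_fit")
}

#' @export
print.mk1_fit <- function(x, ...) {
  cat(sprintf("Mk1 fit: q_hat = %.6g per unit time, lnL = %.4f%s\n",
              x$q_hat, x$lnL,
              if (x$boundary) " (monomorphic boundary)" else ""))
  invisible(x)
}

#' Marginal ancestral-state probabilities under Mk1
#'
#' The standard two-pass algorithm: a post-order (pruning) pass collects
#' the conditional likelihood of the subtree below every node, a pre-order
#' pass propagates the likelihood of everything above it, and the marginal
#' probability of each state at a node is the normalised product of the
#' two with the equal root prior. These are the per-node "pie diagram"
#' probabilities.
#'
#' @inheritParams mk1_loglik
#' @param q transition rate; if `NULL` (default) the ML rate from
#'   [fit_mk1()] is used.
#' @return an object of class `ancestral_reconstruction`: list with
#'   `q` (rate used), `q_source` (`"ml"` or `"fixed"`), `lnL`, `boundary`
#'   and `node_probs`, a data frame with one row per internal node
#'   (`node` = ape node number, `age`, `p0`, `p1`).
#' @export
marginal_states <- function(phy, states, q = NULL) {
  st <- check_states(phy, states)
  q_source <- if (is.null(q)) "ml" else "fixed"
  boundary <- FALSE
  if (is.null(q)) {
    fit <- fit_mk1(phy, states)
    q <- fit$q_hat
    boundary <- fit$boundary
  }
  if (q < 0) stop("q must be >= 0")
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  m <- max(po$edge)
  parent <- po$edge[, 1L]; child <- po$edge[, 2L]
  same <- (1 + exp(-2 * q * po$edge.length)) / 2
  # post-order pass: per-node scaled partials and per-edge messages
  L <- matrix(0, m, 2L)
  L[cbind(seq_len(n), st + 1L)] <- 1
  L[(n + 1L):m, ] <- 1
  msg <- matrix(0, length(parent), 2L)     # message child -> parent
  for (e in seq_along(parent)) {
    cl <- L[child[e], ]
    msg[e, 1L] <- same[e] * cl[1L] + (1 - same[e]) * cl[2L]
    msg[e, 2L] <- (1 - same[e]) * cl[1L] + same[e] * cl[2L]
    L[parent[e], ] <- L[parent[e], ] * msg[e, ]
    sc <- max(L[parent[e], ])
    if (sc > 0) L[parent[e], ] <- L[parent[e], ] / sc
  }
  root <- n + 1L
  # pre-order pass: G[v, s] is the (scaled) likelihood of data outside the
  # subtree of v given state s at v, seeded with the equal root prior
  G <- matrix(0, m, 2L)
  G[root, ] <- c(0.5, 0.5)
  for (e in rev(seq_along(parent))) {
    p <- parent[e]; v <- child[e]
    # everything at p except the message from v
    other <- G[p, ] * L[p, ] / pmax(msg[e, ], .Machine$double.xmin)
    if (any(msg[e, ] <= .Machine$double.xmin)) {
      # recompute without division when a message underflows
      sib <- which(parent == p & child != v)
      other <- G[p, ]
      for (e2 in sib) other <- other * msg[e2, ]
    }
    G[v, 1L] <- same[e] * other[1L] + (1 - same[e]) * other[2L]
    G[v, 2L] <- (1 - same[e]) * other[1L] + same[e] * other[2L]
    sc <- max(G[v, ])
    if (sc > 0) G[v, ] <- G[v, ] / sc
  }
  internal <- (n + 1L):m
  joint <- G[internal, , drop = FALSE] * L[internal, , drop = FALSE]
  tot <- rowSums(joint)
  if (any(tot <= 0)) stop("zero likelihood: q = 0 with discordant tips?")
  probs <- joint / tot
  ages <- chronogram_ages(phy)
  structure(list(
    q = q, q_source = q_source, boundary = boundary,
    lnL = mk1_loglik(phy, states, q),
    node_probs = data.frame(node = internal, age = ages[internal],
                            p0 = probs[, 1L], p1 = probs[, 2L])),
    class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("Mk1 marginal reconstruction: q = %.6g (%s), lnL = %.4f\n",
              x$q, x$q_source, x$lnL))
  cat(sprintf("  %d internal nodes; root P(state 1) = %.4f\n",
              nrow(x$node_probs),
              x$node_probs$p1[which.max(x$node_probs$age)]))
  invisible(x)
}

#' Find the focal root: the oldest confidently-focal internal node
#'
#' Scans the marginal reconstruction for internal nodes whose probability
#' of the focal state exceeds `threshold` and returns the most basal
#' (oldest) of them — the node from which diversification within the focal
#' area is measured downstream. If no node qualifies, the best candidate
#' is reported with `found = FALSE`.
#'
#' @param phy the chronogram the reconstruction was computed on.
#' @param recon an `ancestral_reconstruction` from [marginal_states()].
#' @param focal_state 0 or 1 (default 1).
#' @param threshold probability threshold in (0, 1), default 0.95.
#' @return list with `found`, `node`, `age`, `probability`, and `tips`
#'   (labels of the node's descendant tips).
#' @export
find_focal_root <- function(phy, recon, focal_state = 1L, threshold = 0.95) {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  np <- recon$node_probs
  p <- if (focal_state == 1L) np$p1 else np$p0
  ok <- which(p > threshold)
  pick <- function(idx) {
    j <- idx[order(-np$age[idx], np$node[idx])][1L]
    node <- np$node[j]
    tips <- ape::extract.clade(phy, node)$tip.label
    list(node = node, age = np$age[j], probability = p[j], tips = tips)
  }
  if (length(ok)) c(found = TRUE, pick(ok))
  else c(found = FALSE, pick(which.max(p)))
}
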