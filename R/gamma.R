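#' Lineage-through-time curve
#'
#' The step function of reconstructed lineage count against age: one knot
#' per branching time (ties keep their multiplicity), starting at
#' `(root_age, 2)` and ending at `(0, n)`.
#'
#' @param bt a [branching_times()] object.
#' @return a data frame with columns `age` and `lineages`.
#' @export
ltt_curve <- function(bt) {
  stopifnot(inherits(bt, "branching_times"))
  n <- bt$n
  data.frame(age = c(bt$times, 0), lineages = c(2:n, n))
}

#' The Pybus-Harvey gamma statistic
#'
#' Summarises whether branching times are concentrated toward the root
#' (gamma < 0, a slowdown) or toward the present (gamma > 0) relative to
#' the constant-rate pure-birth expectation. With internode intervals
#' `g_k` (k = 2..n), total weighted length `T = sum(k * g_k)` and partial
#' sums `S_i = sum_{k<=i} k * g_k`,
#' `gamma = (mean(S_2..S_{n-1}) - T/2) / (T * sqrt(1 / (12 (n - 2))))`.
#' Under a complete-sampling pure-birth process gamma is standard normal,
#' which is the basis of the one-tailed constant-rates test
#' ([cr_test()]).
#'
#' Gamma is invariant to a global rescaling of the time axis. Zero
#' intervals (resolved polytomies, tied ages) are valid limits of the
#' formula and are used as-is.
#'
#' @param bt a [branching_times()] object (or a `phylo`, converted via
#'   [branching_times()]). Needs `n >= 3`.
#' @param alpha one-tailed significance level for the accompanying
#'   constant-rates test (default 0.05).
#' @return an object of class `gamma_result`: list with `gamma`, `n`,
#'   `p_one_tailed` (lower-tail standard-normal probability), `alpha`,
#'   `critical_value` and `reject`.
#' @examples
#' g <- gamma_statistic(as_branching_times(c(2, 1)))
#' g$gamma  # -0.34641
#' @export
gamma_statistic <- function(bt, alpha = 0.05) {
  if (inherits(bt, "phylo")) bt <- branching_times(bt)
  stopifnot(inherits(bt, "branching_times"))
  n <- bt$n
  if (n < 3L) stop("gamma is undefined for fewer than 3 tips")
  kg <- (2:n) * bt$intervals           # k * g_k, k = 2..n
  T_tot <- sum(kg)
  if (T_tot <= 0) stop("degenerate tree: all internode intervals are zero")
  S <- cumsum(kg)                      # S_i for i = 2..n
  num <- mean(S[seq_len(n - 2L)]) - T_tot / 2
  gamma <- num / (T_tot * sqrt(1 / (12 * (n - 2))))
  cr_test(structure(list(gamma = gamma, n = n,
                         p_one_tailed = stats::pnorm(gamma)),
                    class = "gamma_result"),
          alpha = alpha)
}

#' One-tailed constant-rates (CR) test
#'
#' Compares an observed gamma with the lower tail of the standard normal:
#' the null (constant-rate pure birth, complete sampling) is rejected when
#' `gamma` falls strictly below the lower-tail critical value at `alpha`
#' (e.g. -1.645 at alpha = 0.05). Only the slowdown direction is tested;
#' positive gamma values are reported but never rejected.
#'
#' @param g a `gamma_result` (from [gamma_statistic()]).
#' @param alpha one-tailed significance level in (0, 1).
#' @return the updated `gamma_result` with `alpha`, `critical_value` and
#'   `reject` fields set.
#' @export
cr_test <- function(g, alpha = 0.05) {
  stopifnot(inherits(g, "gamma_result"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  g$alpha <- alpha
  g$critical_value <- stats::qnorm(alpha)
  g$reject <- g$gamma < g$critical_value
  g
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma = %.5f (n = %d tips), one-tailed P = %.4f\n",
              x$gamma, x$n, x$p_one_tailed))
  cat(sprintf("CR test at alpha = %g (critical %.4f): %s\n",
              x$alpha, x$critical_value,
              if (x$reject) "reject constant rates (slowdown)"
              else "no deviation from constant rates"))
  invisible(x)
}
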