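#' Read and validate an ultrametric chronogram
#'
#' Parses a Newick tree (from a file or a literal string) into an
#' [ape::phylo] object and checks that it is a valid chronogram: branch
#' lengths present on all non-root edges, unique non-empty tip labels, and
#' root-to-tip path lengths equal within a relative tolerance (ages carried
#' by external programs are often rounded).
#'
#' Node ages are measured backward from the present: every tip sits at age
#' 0 and the root at `root_age`. Polytomies are accepted; functions that
#' need a binary tree resolve them into zero-length bifurcations (see
#' [branching_times()]).
#'
#' @param file path to a Newick file (exactly one of `file`/`text`).
#' @param text a Newick string.
#' @param tol relative ultrametricity tolerance, as a fraction of the root
#'   age. Default `1e-6`.
#' @return an object of class `phylo`, validated as a chronogram.
#' @examples
#' tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
#' chronogram_ages(tr)
#' @export
read_chronogram <- function(file = NULL, text = NULL, tol = 1e-6) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `file` or `text`")
  phy <- suppressWarnings(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text))
  if (is.null(phy)) stop("malformed Newick: could not parse input")
  validate_chronogram(phy, tol = tol)
  phy
}

#' Write a chronogram to Newick
#'
#' Branch lengths are written with enough digits that re-parsing reproduces
#' all node ages to better than 1e-9. Polytomies are preserved.
#'
#' @param phy a chronogram (`phylo`).
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_chronogram <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Validate chronogram invariants
#'
#' Checks tip-label uniqueness, presence of branch lengths, non-negative
#' edges and ultrametricity (relative to root age). Errors name the first
#' offending tip so malformed inputs are easy to trace.
#'
#' @inheritParams write_chronogram
#' @param tol relative ultrametricity tolerance.
#' @return `phy`, invisibly.
#' @export
validate_chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a `phylo` object")
  if (is.null(phy$edge.length)) stop("format error: tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("format error: missing branch length")
  if (any(phy$edge.length < 0)) stop("format error: negative branch length")
  lab <- phy$tip.label
  if (any(!nzchar(lab))) stop("empty tip label")
  if (anyDuplicated(lab)) stop("duplicate tip label: ", lab[duplicated(lab)][1L])
  depth <- ape::node.depth.edgelength(phy)
  n <- length(lab)
  ref <- stats::median(depth[seq_len(n)])   # consensus depth; names the odd tip out
  if (ref <= 0) stop("tree has zero depth")
  off <- abs(depth[seq_len(n)] - ref) / ref
  if (any(off > tol)) {
    worst <- which.max(off)
    stop(sprintf(
      "not ultrametric: tip '%s' at depth %.9g vs root age %.9g (rel. dev. %.3g)",
      lab[worst], depth[worst], ref, off[worst]))
  }
  invisible(phy)
}

#' Node ages of a chronogram
#'
#' @inheritParams write_chronogram
#' @return numeric vector of ages (time before present) indexed by node
#'   number (tips `1..n`, then internal nodes); tip ages are forced to
#'   exactly 0 and internal ages never below 0.
#' @export
chronogram_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  n <- length(phy$tip.label)
  root_age <- max(depth[seq_len(n)])
  age <- root_age - depth
  age[seq_len(n)] <- 0
  pmax(age, 0)
}

#' Extract branching times and internode intervals
#'
#' The sufficient statistic for all diversification computations: the ages
#' of the internal nodes sorted from the root downward, and the derived
#' internode intervals `g_k` (the duration during which exactly `k`
#' reconstructed lineages exist, `k = 2..n`). Polytomies are resolved into
#' zero-length bifurcations first, so tied ages and zero intervals are
#' legitimate values.
#'
#' @inheritParams write_chronogram
#' @return an object of class `branching_times`: a list with `n` (tip
#'   count), `times` (length `n - 1`, descending; `times[1]` is the root
#'   age), `intervals` (named `g2..gn`), `root_age`, and
#'   `polytomies_resolved` (flag).
#' @examples
#' bt <- branching_times(read_chronogram(text = "((A:1,B:1):1,C:2);"))
#' bt$times      # 2 1
#' bt$intervals  # g2 = 1, g3 = 1
#' @export
branching_times <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a `phylo` object")
  n <- length(phy$tip.label)
  if (n < 2) stop("need at least 2 tips")
  resolved <- FALSE
  if (!ape::is.binary.phylo(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
    resolved <- TRUE
  }
  age <- chronogram_ages(phy)
  times <- sort(age[(n + 1L):(2L * n - 1L)], decreasing = TRUE,
                method = "radix")
  as_branching_times(times, polytomies_resolved = resolved)
}

#' Build a `branching_times` object from a vector of node ages
#'
#' Used wherever the tree itself is not needed (node truncation, two-rate
#' simulations specified by their interval draws).
#'
#' @param times numeric vector of internal-node ages; sorted descending
#'   internally. An `n`-tip binary chronogram has `n - 1` of them.
#' @param polytomies_resolved flag carried through to output metadata.
#' @return a `branching_times` object (see [branching_times()]).
#' @export
as_branching_times <- function(times, polytomies_resolved = FALSE) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("need at least one branching time")
  if (anyNA(times) || any(times < 0)) stop("branching times must be >= 0 and finite")
  times <- sort(times, decreasing = TRUE, method = "radix")
  n <- length(times) + 1L
  # g_k = t_{k-1} - t_k for k = 2..n-1, g_n = t_{n-1}
  intervals <- c(-diff(times), times[n - 1L])
  names(intervals) <- paste0("g", 2:n)
  structure(
    list(n = n, times = times, intervals = intervals,
         root_age = times[1L], polytomies_resolved = polytomies_resolved),
    class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: n = %d tips, root age = %.6g\n", x$n, x$root_age))
  cat("  times: ", paste(signif(utils::head(x$times, 8), 6), collapse = " "),
      if (length(x$times) > 8) "..." else "", "\n")
  if (isTRUE(x$polytomies_resolved))
    cat("  (polytomies resolved to zero-length bifurcations)\n")
  invisible(x)
}

#' Rescale a chronogram to a fixed calibration age
#'
#' Multiplies every branch length by `age / current MRCA age` so that the
#' most recent common ancestor of two calibration tips sits at the required
#' age. This is a linear rescaling of the whole time axis only (no rate
#' smoothing); relative node ages, and hence the gamma statistic, are
#' unchanged.
#'
#' @inheritParams write_chronogram
#' @param tip_a,tip_b labels of the two tips whose MRCA is calibrated.
#' @param age fixed age (time units before present) for that MRCA; `> 0`.
#' @return the rescaled chronogram.
#' @export
scale_to_calibration <- function(phy, tip_a, tip_b, age) {
  if (!is.numeric(age) || age <= 0) stop("calibration age must be > 0")
  idx <- match(c(tip_a, tip_b), phy$tip.label)
  if (anyNA(idx)) stop("calibration tip not in tree: ",
                       c(tip_a, tip_b)[which(is.na(idx))[1L]])
  if (idx[1L] == idx[2L]) stop("calibration tips must differ")
  mrca <- ape::getMRCA(phy, idx)
  cur <- chronogram_ages(phy)[mrca]
  if (cur <= 0) stop("calibration MRCA has age 0")
  phy$edge.length <- phy$edge.length * (age / cur)
  phy
}

#' Prune a chronogram to a subset of tips
#'
#' Returns the induced subtree on `keep`: degree-2 nodes are suppressed,
#' retained node ages are unchanged, and the result is ultrametric with
#' root age equal to the age of the most recent common ancestor of `keep`.
#'
#' @inheritParams write_chronogram
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned chronogram.
#' @export
prune_chronogram <- function(phy, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  missing <- setdiff(keep, phy$tip.label)
  if (length(missing)) stop("unknown tip label: ", missing[1L])
  ape::keep.tip(phy, keep)
}
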