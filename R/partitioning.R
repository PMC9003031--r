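#' Adaptive equipartition of one axis
#'
#' Divides the sorted values of one axis into at most `b` nonempty bins of
#' near-equal size.  Ties are atomic: a cut is only placed after the tie
#' group whose end is closest to each ideal boundary `i * n / b` (earlier
#' boundary preferred on a distance tie).  When ties force merging, fewer
#' than `b` bins are returned.
#'
#' @param values Numeric vector (length `n >= b`).
#' @param b Target bin count, at least 1.
#' @param axis Axis label to attach to the returned partition.
#' @param quiet Suppress the warning emitted when `b` exceeds the number of
#'   distinct tie groups (the maximal feasible partition is returned).
#' @return An [axis_partition()].
#' @examples
#' equipartition(c(1, 1, 2, 2, 2, 3), 3, "x")$cuts   # sizes (2, 3, 1)
#' @export
equipartition <- function(values, b, axis = c("x", "y", "z"), quiet = FALSE) {
  axis <- match.arg(axis)
  n <- length(values)
  b <- as.integer(b)
  if (b < 1L) stop("b must be >= 1", call. = FALSE)
  if (n < b && !quiet)
    warning("fewer points than requested bins", call. = FALSE)
  ends <- which(diff(sort(values)) != 0)
  cuts <- equipartition_cuts(ends, n, b)
  if (length(cuts) + 1L < b && !quiet)
    warning(sprintf("ties allow only %d of %d requested bins",
                    length(cuts) + 1L, b), call. = FALSE)
  axis_partition(cuts, n, axis)
}

# Greedy cut placement over precomputed tie-group ends (rank positions).
equipartition_cuts <- function(tie_ends, n, b) {
  if (b <= 1L || !length(tie_ends)) return(integer(0))
  cuts <- integer(b - 1L)
  nc <- 0L
  prev <- 0L
  for (i in seq_len(b - 1L)) {
    cand <- tie_ends[tie_ends > prev]
    if (!length(cand)) break
    pick <- cand[which.min(abs(cand - i * n / b))]
    nc <- nc + 1L
    cuts[nc] <- pick
    prev <- pick
  }
  cuts[seq_len(nc)]
}

#' Clump sequence of a target axis under two fixed partitions
#'
#' Walks the target axis in sorted order and merges maximal runs of
#' consecutive points that share one fixed-cell label (the (i,j) cell of the
#' two fixed partitions).  Tie groups on the target axis are atomic: a run
#' boundary falling inside a tie group is suppressed (the clumps are merged
#' and the merged clump carries no single label).  Clump boundaries are the
#' preferred candidate cut positions when the dynamic program must coarsen
#' its search.
#'
#' @param sample A [tri_sample()].
#' @param target_axis Axis being partitioned (`"x"`, `"y"` or `"z"`).
#' @param fixedA,fixedB [axis_partition()]s on the two other axes.
#' @return An object of class `clump_seq`: list with `ends` (end position of
#'   each clump in target-sorted order, last equals `n`), `labels` (shared
#'   fixed-cell label per clump, `NA` for merged mixed clumps), `sizes`, `n`.
#' @export
make_clumps <- function(sample, target_axis, fixedA, fixedB) {
  target_axis <- match.arg(target_axis, axis_names)
  other <- setdiff(axis_names, target_axis)
  if (!setequal(c(fixedA$axis, fixedB$axis), other))
    stop("fixed partitions must be on the two non-target axes", call. = FALSE)
  ord <- order(axis_values(sample, target_axis))
  ba <- bin_assign(axis_values(sample, fixedA$axis), fixedA)[ord]
  bb <- bin_assign(axis_values(sample, fixedB$axis), fixedB)[ord]
  lab <- (ba - 1L) * fixedB$bins + bb
  tie_ends <- axis_cache(axis_values(sample, target_axis))$tie_ends
  clumps_from_labels(lab, tie_ends, sample$n)
}

clumps_from_labels <- function(lab, tie_ends, n) {
  r <- rle(as.integer(lab))
  ends <- cumsum(r$lengths)
  labels <- r$values
  # suppress run boundaries that fall inside a tie group
  allowed <- c(tie_ends, n)
  keep <- ends %in% allowed
  keep[length(keep)] <- TRUE
  if (!all(keep)) {
    grp <- cumsum(c(TRUE, keep[-length(keep)]))   # merge run into next on drop
    pieces <- split(seq_along(ends), grp)         # grp is nondecreasing
    ends <- vapply(pieces, function(i) max(ends[i]), integer(1))
    labels <- vapply(pieces, function(i) {
      v <- unique(labels[i]); if (length(v) == 1L) v else NA_integer_
    }, integer(1))
    names(ends) <- names(labels) <- NULL
  }
  structure(list(ends = as.integer(ends), labels = labels,
                 sizes = diff(c(0L, as.integer(ends))), n = as.integer(n)),
            class = "clump_seq")
}

#' Coarsen a clump sequence to a candidate budget
#'
#' If the clump count already fits the budget the sequence is returned
#' unchanged.  Otherwise the points are equipartitioned into at most
#' `budget` groups whose boundaries are snapped to the nearest clump
#' boundary, so no clump is ever split.  This bounds the cost of the
#' dynamic program (the `c^2` factor of the coefficient's time complexity).
#'
#' @param clumps A `clump_seq` from [make_clumps()].
#' @param budget Maximum number of groups, at least 2.
#' @return A `clump_seq` with at most `budget` clumps whose boundaries are a
#'   subset of the input boundaries.
#' @export
superclumps <- function(clumps, budget) {
  stopifnot(inherits(clumps, "clump_seq"), budget >= 2)
  m <- length(clumps$ends)
  if (m <= budget) return(clumps)
  n <- clumps$n
  inner <- clumps$ends[-m]
  targets <- seq_len(budget - 1L) * n / budget
  pick <- vapply(targets, function(t) inner[which.min(abs(inner - t))], integer(1))
  ends <- unique(sort(c(pick, n)))
  idx <- findInterval(clumps$ends - 1L, ends) + 1L
  labels <- vapply(split(clumps$labels, idx), function(v) {
    u <- unique(v); if (length(u) == 1L) u else NA_integer_
  }, integer(1))
  names(labels) <- NULL
  structure(list(ends = ends, labels = labels,
                 sizes = diff(c(0L, ends)), n = n),
            class = "clump_seq")
}

# Fixed-pair mutual information K (bits): the part of the trivariate MI that
# does not depend on the target partition.
fixed_pair_mi <- function(binsA, binsB, nA, nB, n) {
  tab <- tabulate((binsA - 1L) * nB + binsB, nbins = nA * nB)
  p <- tab / n
  pm <- matrix(p, nrow = nA, byrow = TRUE)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log2(pm[nz] / outer(pa, pb)[nz]))
}

#' Optimize one axis partition by dynamic programming
#'
#' With the two other axes' partitions fixed, the trivariate mutual
#' information decomposes into a constant `K` (the fixed-pair MI) plus a sum
#' of independent per-bin terms over the target partition.  This additivity
#' admits an exact dynamic program over a candidate cut-position set: the
#' returned value for each bin count `k` is the maximum of the objective
#' over all partitions with cuts in the candidate set.
#'
#' Candidate cuts are all tie-respecting boundaries when they fit the budget
#' `chat`; beyond that, clump boundaries ([make_clumps()]) are used, and
#' beyond that, superclump boundaries ([superclumps()]).  Positions in
#' `extra_cuts` (e.g. the incumbent equipartition of the axis) are always
#' included, so enlarging the candidate set never decreases the optimum.
#'
#' @param sample A [tri_sample()].
#' @param target_axis Axis to repartition.
#' @param fixedA,fixedB Fixed [axis_partition()]s on the other two axes.
#' @param kmax Largest bin count to solve for (at least 2).
#' @param chat Candidate budget (superclump cap), at least 2.
#' @param extra_cuts Integer cut positions forced into the candidate set.
#' @return Object of class `axis_optima`: list with `k` (feasible bin
#'   counts, `2..k_feasible`), `best_I` (bits, one per `k`), `partitions`
#'   (list of [axis_partition()]), and attributes `K` (fixed-pair MI) and
#'   `candidates` (cut positions used).
#' @export
optimize_axis <- function(sample, target_axis, fixedA, fixedB, kmax, chat,
                          extra_cuts = integer(0)) {
  target_axis <- match.arg(target_axis, axis_names)
  stopifnot(kmax >= 2, chat >= 2)
  ord <- order(axis_values(sample, target_axis))
  ba <- bin_assign(axis_values(sample, fixedA$axis), fixedA)
  bb <- bin_assign(axis_values(sample, fixedB$axis), fixedB)
  tie_ends <- axis_cache(axis_values(sample, target_axis))$tie_ends
  core <- dp_core(ba[ord], bb[ord], fixedA$bins, fixedB$bins, tie_ends,
                  sample$n, chat, kmax, extra_cuts)
  kfeas <- length(core$g)
  ks <- if (kfeas >= 2) 2:kfeas else integer(0)
  structure(list(
    k = ks,
    best_I = core$g[ks] + core$K,
    partitions = lapply(ks, function(k)
      axis_partition(core$cuts[[k]], sample$n, target_axis))
  ), class = "axis_optima", K = core$K, candidates = core$cand)
}

# Shared DP driver over pre-sorted fixed-cell labels.  baS/bbS are the
# fixed-partition bins of each point in target-sorted order.
dp_core <- function(baS, bbS, nA, nB, tie_ends, n, chat, kmax,
                    extra_cuts = integer(0)) {
  if (length(tie_ends) + 1L <= chat) {
    cand <- tie_ends
  } else {
    lab <- (baS - 1L) * nB + bbS
    cl <- clumps_from_labels(lab, tie_ends, n)
    if (length(cl$ends) > chat) cl <- superclumps(cl, chat)
    cand <- cl$ends[-length(cl$ends)]
  }
  if (length(extra_cuts)) {
    extra <- intersect(as.integer(extra_cuts), tie_ends)
    if (length(extra)) cand <- sort(unique(c(cand, extra)))
  }
  cand <- as.integer(cand)
  res <- axis_dp_cpp(baS, bbS, nA, nB, cand,
                     as.integer(min(kmax, length(cand) + 1L)))
  K <- fixed_pair_mi(baS, bbS, nA, nB, n)
  list(g = res$g, cuts = res$cuts, K = K, cand = cand)
}

#' Quadratic-optimization pass on the y axis
#'
#' The second dynamic-partition step: with the x-axis equipartition `R` and
#' the retained z-axis partition `P_l` fixed, the y axis is re-optimized by
#' the same dynamic program.  The incumbent y equipartition cuts are always
#' part of the candidate set, so the returned value never falls below the
#' value achieved before optimization.
#'
#' @param sample A [tri_sample()].
#' @param R x-axis [axis_partition()] (equipartition).
#' @param P_l Retained z-axis [axis_partition()].
#' @param chat Candidate budget for the dynamic program.
#' @param y Target y-axis bin count.
#' @return A list with `k` (the bin count actually achieved, `y` when
#'   feasible), `best_I` (bits) and `partition`.
#' @export
quadratic_approx_mi <- function(sample, R, P_l, chat, y) {
  inc <- equipartition(axis_values(sample, "y"), y, "y", quiet = TRUE)
  opt <- optimize_axis(sample, "y", R, P_l, kmax = y, chat = chat,
                       extra_cuts = inc$cuts)
  if (!length(opt$k)) return(NULL)
  i <- which(opt$k == y)
  if (!length(i)) i <- length(opt$k)      # maximal feasible bin count
  list(k = opt$k[i], best_I = opt$best_I[i], partition = opt$partitions[[i]])
}
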