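#' Exhaustive single-axis optimum (reference oracle)
#'
#' Enumerates every subset of `k - 1` cuts among the tie-respecting
#' boundaries of the target axis, evaluating the trivariate mutual
#' information of each induced grid directly with [trivariate_mi()].  This
#' is a brute-force certification path, deliberately independent of the
#' dynamic program in [optimize_axis()]; a combinatorial guard refuses
#' inputs with more than `max_boundaries` candidate boundaries.
#'
#' @inheritParams optimize_axis
#' @param k Exact bin count for the target axis.
#' @param max_boundaries Guard on the number of tie-respecting boundaries.
#' @return List with `best_I` (bits), `best_partition`, and `enumerated`
#'   (number of candidate partitions examined).
#' @export
exhaustive_axis <- function(sample, target_axis, fixedA, fixedB, k,
                            max_boundaries = 20L) {
  target_axis <- match.arg(target_axis, axis_names)
  stopifnot(k >= 1)
  vals <- axis_values(sample, target_axis)
  bounds <- axis_cache(vals)$tie_ends
  if (length(bounds) > max_boundaries)
    stop(sprintf("refusing exhaustive search over %d boundaries (guard %d)",
                 length(bounds), max_boundaries), call. = FALSE)
  if (k - 1L > length(bounds))
    stop("not enough tie-respecting boundaries for k bins", call. = FALSE)
  sets <- if (k == 1L) list(integer(0)) else
    lapply(utils::combn(seq_along(bounds), k - 1L, simplify = FALSE),
           function(ix) bounds[ix])
  best <- -Inf; best_part <- NULL
  for (cuts in sets) {
    pt <- axis_partition(cuts, sample$n, target_axis)
    ps <- list(pt, fixedA, fixedB)
    names(ps) <- c(target_axis, fixedA$axis, fixedB$axis)
    I <- trivariate_mi(count_cube(sample, ps$x, ps$y, ps$z))
    if (I > best) { best <- I; best_part <- pt }
  }
  list(best_I = best, best_partition = best_part, enumerated = length(sets))
}

#' Exhaustive cubic-grid optimum (reference oracle)
#'
#' Enumerates all tie-respecting partitions of all three axes with
#' `x * y * z <= B` and every dimension at least 2, and returns the exact
#' maximum of the normalized entries.  Guarded to tiny inputs
#' (`n <= 12`, `B <= 16` by default); any approximation computed by the
#' package must be bounded above by this value.
#'
#' @param sample A [tri_sample()].
#' @param B Grid budget.
#' @param max_n,max_B Guards on problem size.
#' @return List with `best_value` (normalized), `best_I` (bits),
#'   `best_dims`, `best_partitions`, and `enumerated`.
#' @export
exhaustive_grid <- function(sample, B, max_n = 12L, max_B = 16L) {
  if (sample$n > max_n || B > max_B)
    stop(sprintf("refusing exhaustive grid search (n = %d > %d or B = %d > %d)",
                 sample$n, max_n, B, max_B), call. = FALSE)
  caches <- sample_caches(sample)
  part_sets <- function(axis, bins) {
    bounds <- caches[[axis]]$tie_ends
    if (bins - 1L > length(bounds)) return(list())
    sets <- if (bins == 1L) list(integer(0)) else
      lapply(utils::combn(seq_along(bounds), bins - 1L, simplify = FALSE),
             function(ix) bounds[ix])
    lapply(sets, axis_partition, n = sample$n, axis = axis)
  }
  best <- -Inf; best_I <- NA_real_; best_dims <- NULL; best_parts <- NULL
  enumerated <- 0L
  xmax <- B %/% 4L
  if (xmax < 2L) stop("B too small for any admissible grid", call. = FALSE)
  for (x in 2:xmax) for (y in 2:max(2L, B %/% (2L * x))) {
    zmax <- B %/% (x * y)
    if (zmax < 2L) next
    for (z in 2:zmax) {
      psx <- part_sets("x", x); psy <- part_sets("y", y); psz <- part_sets("z", z)
      for (px in psx) for (py in psy) for (pz in psz) {
        enumerated <- enumerated + 1L
        I <- trivariate_mi(count_cube(sample, px, py, pz))
        v <- I / log2(min(x, y, z))
        if (v > best) {
          best <- v; best_I <- I; best_dims <- c(x = x, y = y, z = z)
          best_parts <- list(x = px, y = py, z = pz)
        }
      }
    }
  }
  list(best_value = best, best_I = best_I, best_dims = best_dims,
       best_partitions = best_parts, enumerated = enumerated)
}
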