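#' Shannon entropy of a probability vector
#'
#' @param masses Nonnegative numeric vector summing to 1 (within 1e-8).
#'   The convention 0 * log 0 = 0 applies.
#' @return Entropy in bits (base-2 logarithm), nonnegative.
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # 1 bit
#' @export
shannon_entropy <- function(masses) {
  masses <- as.numeric(masses)
  if (any(masses < 0))
    stop("probability masses must be nonnegative", call. = FALSE)
  if (abs(sum(masses) - 1) > 1e-8)
    stop("probability masses must sum to 1", call. = FALSE)
  p <- masses[masses > 0]
  -sum(p * log2(p))
}

#' Axis partition in rank space
#'
#' An ordered division of one axis's sorted sample into consecutive bins.
#' `cuts` are end-exclusive boundary positions in the sorted order: a cut at
#' position p separates the p-th and (p+1)-th smallest values.  Constructors
#' in this package only place cuts at tie-group ends, so tied values are
#' never split across bins.
#'
#' @param cuts Strictly increasing integer positions in `1..(n-1)` (may be
#'   empty for a single bin).
#' @param n Sample size the partition refers to.
#' @param axis Which axis the partition belongs to (`"x"`, `"y"` or `"z"`).
#' @return An object of class `axis_partition` with elements `axis`, `cuts`,
#'   `bins` and `n`.
#' @export
axis_partition <- function(cuts, n, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  cuts <- as.integer(cuts)
  if (length(cuts)) {
    if (is.unsorted(cuts, strictly = TRUE))
      stop("cuts must be strictly increasing", call. = FALSE)
    if (cuts[1] < 1L || cuts[length(cuts)] >= n)
      stop("cuts must lie in 1..(n-1)", call. = FALSE)
  }
  structure(list(axis = axis, cuts = cuts, bins = length(cuts) + 1L,
                 n = as.integer(n)),
            class = "axis_partition")
}

#' @export
print.axis_partition <- function(x, ...) {
  cat(sprintf("<axis_partition> axis %s, %d bins, n = %d\n",
              x$axis, x$bins, x$n))
  invisible(x)
}

# Bin index of each point given its rank position; cuts never split ties,
# so the ties.method = "first" ranking is immaterial to the result.
bin_of_pos <- function(pos, cuts) {
  if (!length(cuts)) return(rep(1L, length(pos)))
  findInterval(pos - 1L, cuts) + 1L
}

bin_assign <- function(values, partition) {
  pos <- rank(values, ties.method = "first")
  bin_of_pos(as.integer(pos), partition$cuts)
}

#' Cell counts of a cubic grid
#'
#' Counts how many points fall into each cell of the cubic grid induced by
#' three axis partitions.  The counts array is the basis of every empirical
#' probability used by the coefficients: probabilities are plain cell
#' frequencies (no pseudocounts).
#'
#' @param sample A [tri_sample()].
#' @param px,py,pz [axis_partition()]s for the x, y and z axes.
#' @return Integer array of dimension `bins(px) x bins(py) x bins(pz)`
#'   summing to `sample$n`.
#' @examples
#' d <- tri_sample(1:8, rep(1:2, 4), rep(1:2, each = 4), min_n = 8)
#' ct <- count_cube(d, equipartition(d$x, 2, "x"),
#'                     equipartition(d$y, 2, "y"),
#'                     equipartition(d$z, 2, "z"))
#' sum(ct) == d$n
#' @export
count_cube <- function(sample, px, py, pz) {
  stopifnot(inherits(sample, "tri_sample"))
  for (p in list(px, py, pz))
    if (!inherits(p, "axis_partition") || p$n != sample$n)
      stop("partition does not match the sample size", call. = FALSE)
  if (anyDuplicated(c(px$axis, py$axis, pz$axis)))
    stop("partitions must be on distinct axes", call. = FALSE)
  bx <- bin_assign(axis_values(sample, px$axis), px)
  by <- bin_assign(axis_values(sample, py$axis), py)
  bz <- bin_assign(axis_values(sample, pz$axis), pz)
  dims <- c(px$bins, py$bins, pz$bins)
  idx <- (bx - 1L) * dims[2] * dims[3] + (by - 1L) * dims[3] + bz
  counts <- tabulate(idx, nbins = prod(dims))     # x-major, z fastest
  aperm(array(as.integer(counts), dim = dims[c(3, 2, 1)]), c(3, 2, 1))
}

tri_mi_entropy <- function(p) {
  H <- function(m) { m <- m[m > 0]; -sum(m * log2(m)) }
  Hx <- H(apply(p, 1, sum)); Hy <- H(apply(p, 2, sum)); Hz <- H(apply(p, 3, sum))
  Hxy <- H(apply(p, c(1, 2), sum)); Hxz <- H(apply(p, c(1, 3), sum))
  Hyz <- H(apply(p, c(2, 3), sum))
  Hxyz <- H(p)
  Hx + Hy + Hz - Hxy - Hxz - Hyz + Hxyz
}

tri_mi_plugin <- function(p) {
  px <- apply(p, 1, sum); py <- apply(p, 2, sum); pz <- apply(p, 3, sum)
  pxy <- apply(p, c(1, 2), sum); pxz <- apply(p, c(1, 3), sum)
  pyz <- apply(p, c(2, 3), sum)
  d <- dim(p)
  total <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    pe <- p[i, j, k]
    if (pe > 0)
      total <- total + pe * log2(pxy[i, j] * pxz[i, k] * pyz[j, k] /
                                 (px[i] * py[j] * pz[k] * pe))
  }
  total
}

#' Trivariate mutual information of a count cube
#'
#' Computes the interaction information
#' `I(X;Y;Z) = H(X)+H(Y)+H(Z)-H(X,Y)-H(X,Z)-H(Y,Z)+H(X,Y,Z)` from empirical
#' cell frequencies.  The value may be negative (e.g. XOR-type
#' distributions); no clamping happens here, so the sign is preserved for
#' diagnostics.  Two algebraically equivalent forms are available: the
#' entropy sum above, and the direct plug-in sum over cells
#' `sum p(x,y,z) log2[ p(x,y)p(x,z)p(y,z) / (p(x)p(y)p(z)p(x,y,z)) ]`.
#'
#' @param cube Nonnegative integer array of counts with three dimensions
#'   (as from [count_cube()]), total at least 1.
#' @param form `"entropy"` (default) or `"plugin"`; both agree to within
#'   1e-9 and exist so that tests can certify the identity.
#' @return Mutual information in bits.
#' @examples
#' xor <- array(0, c(2, 2, 2))
#' xor[1, 1, 1] <- xor[1, 2, 2] <- xor[2, 1, 2] <- xor[2, 2, 1] <- 1
#' trivariate_mi(xor)   # -1: pure three-way (XOR) interaction
#' @export
trivariate_mi <- function(cube, form = c("entropy", "plugin")) {
  form <- match.arg(form)
  if (length(dim(cube)) != 3L)
    stop("cube must be a 3-dimensional array", call. = FALSE)
  tot <- sum(cube)
  if (tot < 1) stop("empty cube", call. = FALSE)
  if (any(cube < 0)) stop("counts must be nonnegative", call. = FALSE)
  p <- cube / tot
  if (form == "entropy") tri_mi_entropy(p) else tri_mi_plugin(p)
}

#' Normalize a characteristic-matrix entry
#'
#' Divides a trivariate mutual information value by `log2 min(x, y, z)`, the
#' bound implied by pairwise-MI dominance: `I(X;Y;Z) <= I` of any pair
#' `<= log2` of the smaller bin count, so the result never exceeds 1.
#' Negative inputs pass through unclamped; clamping happens at score level.
#'
#' @param I Mutual information in bits.
#' @param x,y,z Grid dimensions, each at least 2.
#' @return `I / log2(min(x, y, z))`.
#' @export
normalize_entry <- function(I, x, y, z) {
  if (min(x, y, z) < 2)
    stop("all grid dimensions must be >= 2", call. = FALSE)
  I / log2(min(x, y, z))
}
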