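#' Construct a trivariate sample
#'
#' Bundles three parallel real-valued columns of equal length `n` into the
#' basic data object scored by the trivariate information coefficients.
#'
#' @param x,y,z Numeric vectors of equal length; all values must be finite.
#' @param min_n Minimum sample size accepted (coefficient computation needs
#'   at least 8 points, the smallest admissible 2x2x2 grid).
#' @return An object of class `tri_sample`: a list with elements `x`, `y`,
#'   `z` and `n`.
#' @examples
#' r <- runif(50)
#' d <- tri_sample(r, r^2, r^3)
#' d$n
#' @export
tri_sample <- function(x, y, z, min_n = 8L) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have equal length", call. = FALSE)
  if (n < min_n)
    stop(sprintf("sample too small: n = %d < %d", n, min_n), call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("all values must be finite", call. = FALSE)
  structure(list(x = x, y = y, z = z, n = n), class = "tri_sample")
}

#' @export
print.tri_sample <- function(x, ...) {
  cat(sprintf("<tri_sample> n = %d\n", x$n))
  invisible(x)
}

axis_names <- c("x", "y", "z")

axis_values <- function(sample, axis) {
  axis <- match.arg(axis, axis_names)
  sample[[axis]]
}

# Per-axis rank-space cache: sorted positions and tie-group end positions.
# All partitioning happens in rank space; tied values are atomic.
axis_cache <- function(values) {
  n <- length(values)
  pos <- rank(values, ties.method = "first")
  vs <- sort(values)
  ends <- which(diff(vs) != 0)           # allowed cut positions, excluding n
  list(pos = as.integer(pos), tie_ends = as.integer(ends), n = n)
}

sample_caches <- function(sample) {
  lapply(sample[axis_names], axis_cache)
}
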