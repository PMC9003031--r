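# Shared fixture builders; everything is generated in code under fixed seeds.

# Random count cube with the given dimensions and total mass n.
rand_cube <- function(dims, n) {
  cells <- prod(dims)
  counts <- tabulate(sample.int(cells, n, replace = TRUE), nbins = cells)
  array(as.integer(counts), dim = dims)
}

# Random small trivariate sample; `ties` draws from a small integer support
# so that all three axes carry tied values.
rand_tri <- function(n, ties = FALSE) {
  if (ties) {
    tri_sample(sample(4, n, TRUE) + 0, sample(5, n, TRUE) + 0,
               sample(3, n, TRUE) + 0, min_n = 1L)
  } else {
    tri_sample(runif(n), runif(n), runif(n), min_n = 1L)
  }
}

# Independent tally of a cubic grid: explicit per-point loop over rank
# positions, written without count_cube's vectorized indexing.
tally_cube <- function(sample, px, py, pz) {
  bin_one <- function(values, cuts) {
    pos <- rank(values, ties.method = "first")
    vapply(pos, function(p) sum(cuts < p) + 1L, integer(1))
  }
  bx <- bin_one(sample$x, px$cuts)
  by <- bin_one(sample$y, py$cuts)
  bz <- bin_one(sample$z, pz$cuts)
  out <- array(0L, dim = c(px$bins, py$bins, pz$bins))
  for (i in seq_len(sample$n))
    out[bx[i], by[i], bz[i]] <- out[bx[i], by[i], bz[i]] + 1L
  out
}
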