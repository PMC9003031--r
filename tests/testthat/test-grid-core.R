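test_that("shannon_entropy handles basic masses and rejects bad input", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1.0)
  expect_equal(shannon_entropy(c(1, 0)), 0.0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2.0)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(shannon_entropy(c(0.4, 0.4)), "sum to 1")
})

test_that("count_cube places points in the expected cells", {
  # 8 points at the corners of the unit cube: each 2x2x2 cell holds 1 point
  corners <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  d <- tri_sample(corners$x, corners$y, corners$z)
  ct <- count_cube(d, equipartition(d$x, 2, "x"), equipartition(d$y, 2, "y"),
                   equipartition(d$z, 2, "z"))
  expect_equal(as.vector(ct), rep(1L, 8))

  # n = 12 fixture with assorted ranks matches an independent per-point tally
  set.seed(401)
  d12 <- tri_sample(sample(12), c(rep(1, 5), rep(2, 4), rep(3, 3))[sample(12)],
                    runif(12))
  px <- equipartition(d12$x, 3, "x"); py <- equipartition(d12$y, 2, "y")
  pz <- equipartition(d12$z, 2, "z")
  ct12 <- count_cube(d12, px, py, pz)
  expect_identical(ct12, tally_cube(d12, px, py, pz))
  expect_equal(sum(ct12), 12L)

  # size-mismatched partition is rejected; duplicate axes are rejected
  other <- equipartition(runif(20), 2, "x")
  expect_error(count_cube(d12, other, py, pz), "sample size")
  expect_error(count_cube(d12, px, px, pz), "distinct axes")
})

test_that("a fully tied axis collapses to a single usable bin", {
  d <- tri_sample(rep(1, 8), 1:8, 8:1)
  expect_warning(p <- equipartition(d$x, 2, "x"), "ties")
  expect_equal(p$bins, 1L)
})

test_that("trivariate_mi matches hand-derived values and can be negative", {
  unif <- array(1L, dim = c(2, 2, 2))
  expect_equal(trivariate_mi(unif), 0.0)

  diag2 <- array(0L, dim = c(2, 2, 2))
  diag2[1, 1, 1] <- 1L; diag2[2, 2, 2] <- 1L
  expect_equal(trivariate_mi(diag2), 1.0)

  # XOR distribution: pairwise independent, pure three-way interaction
  xor <- array(0L, dim = c(2, 2, 2))
  xor[1, 1, 1] <- xor[1, 2, 2] <- xor[2, 1, 2] <- xor[2, 2, 1] <- 1L
  expect_equal(trivariate_mi(xor), -1.0)
  expect_equal(trivariate_mi(xor, form = "plugin"), -1.0)

  expect_error(trivariate_mi(array(0L, dim = c(2, 2, 2))), "empty")
})

test_that("entropy-sum and plug-in forms agree on random cubes", {
  set.seed(42)
  for (i in 1:200) {
    dims <- sample(2:5, 3, replace = TRUE)
    cube <- rand_cube(dims, sample(10:100, 1))
    if (sum(cube) == 0) next
    e1 <- trivariate_mi(cube, "entropy")
    e2 <- trivariate_mi(cube, "plugin")
    expect_lt(abs(e1 - e2), 1e-9)
    # normalized entries never exceed 1 (pairwise-MI dominance)
    expect_lte(normalize_entry(e1, dims[1], dims[2], dims[3]), 1 + 1e-12)
  }
})

test_that("joint entropies dominate marginals on every cube", {
  set.seed(99)
  H <- function(m) { m <- m[m > 0]; -sum(m * log2(m)) }
  for (i in 1:50) {
    p <- rand_cube(sample(2:4, 3, TRUE), 60)
    p <- p / sum(p)
    joint3 <- H(p)
    pair <- c(H(apply(p, c(1, 2), sum)), H(apply(p, c(1, 3), sum)),
              H(apply(p, c(2, 3), sum)))
    single <- c(H(apply(p, 1, sum)), H(apply(p, 2, sum)), H(apply(p, 3, sum)))
    expect_gte(joint3 + 1e-12, max(pair))
    expect_gte(max(pair) + 1e-12, max(single))
  }
})

test_that("count_cube is invariant under strictly increasing transforms", {
  set.seed(7)
  d <- rand_tri(30)
  parts <- list(equipartition(d$x, 3, "x"), equipartition(d$y, 4, "y"),
                equipartition(d$z, 2, "z"))
  ct <- count_cube(d, parts[[1]], parts[[2]], parts[[3]])
  d2 <- tri_sample(exp(d$x), atan(d$y) * 3 + 1, d$z^3 + d$z)
  parts2 <- list(equipartition(d2$x, 3, "x"), equipartition(d2$y, 4, "y"),
                 equipartition(d2$z, 2, "z"))
  expect_identical(ct, count_cube(d2, parts2[[1]], parts2[[2]], parts2[[3]]))
})

test_that("normalize_entry applies the log-min denominator", {
  expect_equal(normalize_entry(1.0, 2, 2, 2), 1.0)
  expect_equal(normalize_entry(0, 5, 7, 2), 0)
  expect_equal(normalize_entry(2.0, 4, 4, 8), 1.0)
  expect_equal(normalize_entry(-1.0, 2, 2, 2), -1.0)  # sign passes through
  expect_error(normalize_entry(1.0, 1, 2, 2), ">= 2")
})
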