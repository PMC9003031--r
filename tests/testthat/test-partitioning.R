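test_that("equipartition balances bins and respects ties", {
  expect_equal(equipartition(c(1, 2, 3, 4, 5, 6), 3, "x")$cuts, c(2L, 4L))
  expect_warning(p <- equipartition(c(1, 1, 1, 1), 2, "x"), "ties")
  expect_equal(p$bins, 1L)
  # ties pull the greedy cut to the nearest tie-group end: sizes (2, 3, 1)
  p2 <- equipartition(c(1, 1, 2, 2, 2, 3), 3, "x")
  expect_equal(diff(c(0, p2$cuts, 6)), c(2, 3, 1))
})

test_that("make_clumps run-length encodes fixed-cell labels", {
  # labels along z order: (1,1,2,2,2,1,3,3,1,1) -> 5 clumps (2,3,1,2,2)
  d <- tri_sample(c(1, 2, 6, 7, 8, 3, 9, 10, 4, 5), runif(10), 1:10,
                  min_n = 8L)
  px <- axis_partition(c(5L, 8L), 10L, "x")
  py <- axis_partition(integer(0), 10L, "y")
  cl <- make_clumps(d, "z", px, py)
  expect_equal(cl$sizes, c(2L, 3L, 1L, 2L, 2L))
  expect_equal(cl$labels, c(1L, 2L, 1L, 3L, 1L))
  expect_equal(sum(cl$sizes), 10L)

  # one fixed cell -> one clump; alternating labels -> n clumps
  d1 <- tri_sample(rep(1, 9), rep(1, 9), 1:9)
  expect_warning(p1 <- equipartition(d1$x, 2, "x"), "ties")
  cl1 <- make_clumps(d1, "z", p1, equipartition(d1$y, 1, "y"))
  expect_equal(length(cl1$ends), 1L)
  d2 <- tri_sample(rep(c(1, 2), 5), runif(10), 1:10)
  cl2 <- make_clumps(d2, "z", equipartition(d2$x, 2, "x"),
                     equipartition(d2$y, 1, "y", quiet = TRUE))
  expect_equal(length(cl2$ends), 10L)
})

test_that("superclumps coarsens without splitting any clump", {
  lab <- rep(1:3, times = c(2, 4, 3))
  cl <- qotic:::clumps_from_labels(lab, 1:8, 9L)
  expect_identical(superclumps(cl, 10), cl)      # within budget: unchanged

  lab7 <- c(1, 2, 3, 3, 3, 3, 4, 5, 6, 7)       # sizes (1,1,4,1,1,1,1)
  cl7 <- qotic:::clumps_from_labels(lab7, 1:9, 10L)
  expect_equal(length(cl7$ends), 7L)
  sc <- superclumps(cl7, 4)
  expect_lte(length(sc$ends), 4L)
  expect_true(all(sc$ends %in% cl7$ends))        # boundaries snapped
  expect_equal(sum(sc$sizes), 10L)
})

test_that("the per-bin decomposition reproduces trivariate MI", {
  set.seed(11)
  for (i in 1:20) {
    d <- rand_tri(12, ties = i %% 2 == 0)
    fa <- equipartition(d$x, 2, "x", quiet = TRUE)
    fb <- equipartition(d$y, 3, "y", quiet = TRUE)
    if (fa$bins < 2 || fb$bins < 2) next
    opt <- optimize_axis(d, "z", fa, fb, kmax = 4, chat = d$n)
    for (j in seq_along(opt$k)) {
      direct <- trivariate_mi(count_cube(d, fa, fb, opt$partitions[[j]]))
      expect_lt(abs(opt$best_I[j] - direct), 1e-9)
    }
  }
})

test_that("the dynamic program equals brute-force search at full budget", {
  set.seed(23)
  checked <- 0L
  for (i in 1:60) {
    n <- sample(9:14, 1)
    d <- rand_tri(n, ties = i %% 3 == 0)
    fa <- equipartition(d$x, sample(2:4, 1), "x", quiet = TRUE)
    fb <- equipartition(d$y, sample(2:4, 1), "y", quiet = TRUE)
    if (fa$bins < 2 || fb$bins < 2) next
    opt <- optimize_axis(d, "z", fa, fb, kmax = 4, chat = n)
    for (j in seq_along(opt$k)) {
      ex <- exhaustive_axis(d, "z", fa, fb, opt$k[j])
      expect_equal(opt$best_I[j], ex$best_I, tolerance = 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 50L)
})

test_that("enlarging the candidate set never decreases the optimum", {
  set.seed(31)
  for (i in 1:10) {
    d <- rand_tri(40)
    fa <- equipartition(d$x, 3, "x"); fb <- equipartition(d$y, 3, "y")
    small <- optimize_axis(d, "z", fa, fb, kmax = 4, chat = 6)
    full <- optimize_axis(d, "z", fa, fb, kmax = 4, chat = d$n)
    ks <- intersect(small$k, full$k)
    for (k in ks) {
      expect_gte(full$best_I[match(k, full$k)],
                 small$best_I[match(k, small$k)] - 1e-12)
    }
  }
})

test_that("returned partitions never split tied values", {
  set.seed(37)
  for (i in 1:15) {
    d <- rand_tri(25, ties = TRUE)
    fa <- equipartition(d$x, 2, "x", quiet = TRUE)
    fb <- equipartition(d$y, 2, "y", quiet = TRUE)
    if (fa$bins < 2 || fb$bins < 2) next
    opt <- optimize_axis(d, "z", fa, fb, kmax = 3, chat = d$n)
    allowed <- qotic:::axis_cache(d$z)$tie_ends
    for (p in opt$partitions)
      expect_true(all(p$cuts %in% allowed))
  }
})

test_that("the quadratic pass never falls below the incumbent", {
  set.seed(43)
  for (i in 1:10) {
    d <- rand_tri(60)
    R <- equipartition(d$x, 3, "x")
    Q <- equipartition(d$y, 3, "y")
    Pl <- equipartition(d$z, 2, "z")
    incumbent <- trivariate_mi(count_cube(d, R, Q, Pl))
    qa <- quadratic_approx_mi(d, R, Pl, chat = 20, y = 3)
    expect_gte(qa$best_I, incumbent - 1e-12)
  }
})
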