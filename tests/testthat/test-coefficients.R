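test_that("per-entry dominance holds: estic >= qotic >= single_opt", {
  set.seed(53)
  for (i in 1:4) {
    d <- generate_relationship(sample(12, 1), "table1", n = 80, r2 = 0.6,
                               seed = i)
    cms <- lapply(c(estic = "estic", qotic = "qotic", single = "single_opt"),
                  function(m) characteristic_matrix(d, method = m))
    key <- function(cm) paste(cm$x, cm$y, cm$z)
    common <- Reduce(intersect, lapply(cms, key))
    at <- function(cm) cm$value[match(common, key(cm))]
    expect_true(all(at(cms$estic) >= at(cms$qotic) - 1e-12))
    expect_true(all(at(cms$qotic) >= at(cms$single) - 1e-12))
    scores <- vapply(c("estic", "qotic", "single_opt"), function(m)
      tic_score(d, m)$score, numeric(1))
    expect_true(scores[1] >= scores[2] && scores[2] >= scores[3])
  }
})

test_that("noiseless monotone triples saturate at 1", {
  r <- seq_len(100) / 100
  expect_equal(tic_score(tri_sample(r, r, r), "qotic")$score, 1, tolerance = 1e-6)
  # any strictly monotone pair of transforms gives the same ranks
  set.seed(59)
  r <- runif(150)
  s <- tic_score(tri_sample(r, exp(3 * r), log(r + 0.2)), "qotic")
  expect_equal(s$score, 1, tolerance = 1e-6)
  for (m in c("estic", "single_opt", "teic"))
    expect_equal(tic_score(tri_sample(r, exp(3 * r), log(r + 0.2)), m)$score,
                 1, tolerance = 1e-6)
})

test_that("scores are exactly invariant to monotone rescaling and row order", {
  set.seed(61)
  d <- generate_relationship(5, "table1", n = 120, r2 = 0.5, seed = 3)
  base <- tic_score(d, "qotic")
  warped <- tri_sample(exp(d$x), atan(d$y) * 2 + 5, d$z^3 + d$z)
  expect_identical(tic_score(warped, "qotic")$score, base$score)
  perm <- sample(d$n)
  shuffled <- tri_sample(d$x[perm], d$y[perm], d$z[perm])
  expect_identical(tic_score(shuffled, "qotic")$score, base$score)
})

test_that("scores are clamped at zero but keep the raw maximum", {
  # three-way XOR structure drives the interaction information negative
  set.seed(67)
  a <- rep(0:1, each = 32); b <- rep(0:1, times = 32)
  cbit <- xor(a == 1, b == 1) * 1
  jit <- function(v) v + runif(64) * 0.5
  s <- tic_score(tri_sample(jit(a), jit(b), jit(cbit)), "single_opt")
  expect_gte(s$score, 0)
  expect_gte(s$score, s$raw_max)
})

test_that("too-small samples are rejected with an explicit error", {
  d <- tri_sample(runif(10), runif(10), runif(10))
  expect_error(tic_score(d, "qotic"), "sample too small")
  expect_error(characteristic_matrix(d), "sample too small")
})

test_that("every characteristic-matrix key respects the grid budget", {
  set.seed(71)
  d <- rand_tri(100)
  for (m in c("qotic", "teic")) {
    cm <- characteristic_matrix(d, method = m)
    B <- attr(cm, "B")
    expect_true(all(cm$x * cm$y * cm$z <= B))
    expect_true(all(cm$x >= 2 & cm$y >= 2 & cm$z >= 2))
    expect_true(all(cm$value <= 1 + 1e-9))
  }
})

test_that("symmetrized scoring takes the best of the three axis rotations", {
  set.seed(73)
  g <- floor(4 * runif(200))
  d <- tri_sample(runif(200), g + 0, g + 0)
  plain <- tic_score(d, "qotic")$score
  sym <- tic_score(d, "qotic", symmetrize = TRUE)$score
  expect_gte(sym, plain - 1e-12)
  rot <- tic_score(tri_sample(d$y, d$z, d$x), "qotic")$score
  expect_gte(sym, rot - 1e-12)
})
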