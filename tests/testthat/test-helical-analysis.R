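# Distributions, state calls and bound-vs-unbound alteration analysis.

constSeries <- function(values, label = "TA", region = "yre") {
  m <- matrix(values, ncol = 1)
  z <- m * 0
  StepParameterSeries(m, z, z, z, z, z, label, region)
}

test_that("normalized distributions integrate to one", {
  s <- constSeries(rep(1.0, 50))
  h <- normalizedDistribution(s, "shift", 1, binWidth = 0.1)
  expect_equal(sum(h$density) * 0.1, 1)
  expect_equal(sum(h$density > 0), 1L)
  expect_equal(h$density[h$density > 0], 1 / 0.1)

  s2 <- constSeries(rep(c(-1, 1), each = 100))
  h2 <- normalizedDistribution(s2, "shift", 1, binWidth = 0.1)
  occ <- h2$density[h2$density > 0]
  expect_length(occ, 2L)
  expect_equal(occ[1], occ[2])
  expect_equal(sum(h2$density) * 0.1, 1)
})

test_that("histogram mean tracks the generator mean for Gaussian draws", {
  set.seed(123)
  mu <- 0.7; sigma <- 1.0; n <- 10000
  s <- constSeries(rnorm(n, mu, sigma))
  h <- normalizedDistribution(s, "shift", 1, binWidth = 0.1)
  histMean <- sum(h$center * h$density) * 0.1
  expect_lt(abs(histMean - mu), 3 * sigma / sqrt(n) + 0.01)
})

test_that("absent cells are excluded and all-absent steps error", {
  m <- matrix(c(1, NA, 1, NA), ncol = 2)
  z <- m * 0
  s <- StepParameterSeries(m, z, z, z, z, z, c("TA", "AC"), c("yre", "+1"))
  h <- normalizedDistribution(s, "shift", 1, binWidth = 0.1)
  expect_equal(sum(h$density) * 0.1, 1)
  allNA <- StepParameterSeries(matrix(NA_real_, 2, 1), matrix(0, 2, 1),
                               matrix(0, 2, 1), matrix(0, 2, 1),
                               matrix(0, 2, 1), matrix(0, 2, 1), "TA", "yre")
  expect_error(normalizedDistribution(allNA, "shift", 1), "absent")
})

test_that("state calls follow the sign of the dominant population", {
  expect_equal(classifyState(constSeries(rep(1, 40)), "shift", 1,
                             neutralBand = 0.3)$state, "positive")
  expect_equal(classifyState(constSeries(rep(1, 40)), "shift", 1)$fraction, 1)
  expect_equal(classifyState(constSeries(rep(-1, 40)), "shift", 1)$state,
               "negative")
  expect_equal(classifyState(constSeries(rep(0.1, 40)), "shift", 1)$state,
               "neutral")
  # exact tie is called neutral
  tie <- classifyState(constSeries(c(-1, 1)), "shift", 1)
  expect_equal(tie$state, "neutral")
  expect_equal(sum(tie$fractions), 1)
})

test_that("a 60/40 mixture is called for the majority sign at counting accuracy", {
  gh <- genHelicalSeries(frames = 2000, mixtureMeans = c(1.2, -1.2),
                        mixtureSds = c(0.25, 0.25),
                        mixtureWeights = c(0.6, 0.4),
                        displacement = 0, seed = 19)
  cl <- classifyState(gh$unbound, "shift", 3)
  expect_equal(cl$state, "positive")
  expect_lt(abs(cl$fraction - 0.6), 3 * sqrt(0.6 * 0.4 / 2000) + 0.01)
  expect_equal(sum(cl$fractions), 1)
})

test_that("state calls are invariant to frame permutation", {
  set.seed(5)
  v <- rnorm(500, 0.4, 0.5)
  a <- classifyState(constSeries(v), "shift", 1)
  b <- classifyState(constSeries(sample(v)), "shift", 1)
  expect_identical(a, b)
})

test_that("identical series score zero alteration everywhere", {
  gh <- genHelicalSeries(frames = 200, displacement = 0, seed = 3)
  cmp <- compareBoundUnbound(gh$bound, gh$bound, "shift")
  expect_true(all(cmp$perStep$score == 0))
  expect_equal(cmp$reach5, 0L)
  expect_equal(cmp$reach3, 0L)
})

test_that("disjoint supports reach the KS upper bound of one", {
  m1 <- matrix(rep(c(-2, 1), c(50, 50)), ncol = 1)
  m2 <- matrix(rep(c(5, 8), c(50, 50)), ncol = 1)
  z <- m1 * 0
  b <- StepParameterSeries(m1, z, z, z, z, z, "TA", "yre")
  u <- StepParameterSeries(m2, z, z, z, z, z, "TA", "yre")
  expect_equal(compareBoundUnbound(b, u, "shift")$perStep$score, 1)
})

test_that("a planted 5'-only displacement is recovered as reach 4/0", {
  gh <- genHelicalSeries(frames = 2000, displacement = 1.0,
                         reach5 = 4L, reach3 = 0L, seed = 7)
  cmp <- compareBoundUnbound(gh$bound, gh$unbound, "shift")
  expect_equal(cmp$reach5, 4L)
  expect_equal(cmp$reach3, 0L)
  expect_identical(cmp$perStep$altered, gh$truth$altered)
})

test_that("flagged reach grows with the planted displacement", {
  reaches <- vapply(c(0.15, 0.5, 1.5), function(d) {
    gh <- genHelicalSeries(frames = 1200, displacement = d,
                           reach5 = 4L, reach3 = 4L, seed = 11)
    compareBoundUnbound(gh$bound, gh$unbound, "shift")$reach5
  }, integer(1))
  expect_true(all(diff(reaches) >= 0))
  expect_equal(reaches[3], 4L)
})

test_that("label mismatch between series is an error", {
  a <- constSeries(rnorm(10), "TA", "yre")
  b <- constSeries(rnorm(10), "AC", "yre")
  expect_error(compareBoundUnbound(a, b), "share step labels")
})

test_that("equilibration discard is a pure slice", {
  gh <- genHelicalSeries(frames = 100, seed = 2)
  cut <- discardEquilibration(gh$bound, fraction = 0.25)
  expect_equal(nFrames(cut), 75L)
  expect_equal(paramMatrix(cut, "shift"),
               paramMatrix(gh$bound, "shift")[26:100, ])
  g <- genStructureEnsemble("ACGT", nFrames = 10,
                            paramNoise = rep(0.05, 6), seed = 4)
  e <- discardEquilibration(g$ensemble, nDrop = 4)
  expect_equal(nFrames(e), 6L)
  expect_equal(frameCoords(e, 1), frameCoords(g$ensemble, 5))
})
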