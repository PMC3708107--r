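test_that("threshold filter removes only sub-threshold pairs", {
  P <- matrix(0, 10, 10)
  P[1, 6] <- P[6, 1] <- 0.005
  P[2, 8] <- P[8, 2] <- 0.5
  expect_equal(thresholdFilter(P, 0), P)
  F <- thresholdFilter(P, 0.01)
  expect_equal(F[1, 6], 0)
  expect_equal(F[2, 8], 0.5)
  expect_true(all(rowSums(F) <= rowSums(P)))
  B <- foldGlobal("GGGGAAAACCCC")
  expect_s4_class(thresholdFilter(B, 0.01), "BasePairMatrix")
})

test_that("self-containedness separates enclosed from straddling stems", {
  # designed matrix: a strong stem entirely inside [11, 30] and one
  # straddling the boundary at 30
  n <- 40
  P <- matrix(0, n, n)
  for (k in 0:3) P[12 + k, 28 - k] <- P[28 - k, 12 + k] <- 0.9
  for (k in 0:3) P[25 + k, 38 - k] <- P[38 - k, 25 + k] <- 0.9
  Z <- matrix(0, n, n)
  expect_true(selfContained(P, Z, c(1, n), alpha = 1)) # full seq always
  expect_true(selfContained(P, Z, c(11, 30), alpha = 0.99))
  # both ensembles structured: the straddling stem fails the test
  # (an all-zero ensemble would pass trivially, 0 >= alpha * 0)
  expect_false(selfContained(P, P, c(24, 31), alpha = 1))
  # agreement with direct sums on random matrices, plus monotonicity in
  # alpha: admissible at alpha stays admissible at any smaller alpha
  set.seed(301)
  for (t in 1:20) {
    A <- randomBppLike(30); B <- randomBppLike(30)
    k <- sample(1:20, 1); l <- k + sample(5:9, 1)
    a <- runif(1, 0.2, 2)
    got <- selfContained(A, B, c(k, l), a)
    expect_equal(got, oracleSelfContained(A, B, k, l, a))
    if (got) expect_true(selfContained(A, B, c(k, l), a * runif(1)))
  }
})

test_that("MN tables reproduce direct interval sums", {
  Z <- matrix(0, 12, 12)
  mnZ <- mnTables(Z)
  expect_true(all(mnZ$M == 0) && all(mnZ$N == 0))
  set.seed(302)
  P <- randomBppLike(25)
  mn <- mnTables(P)
  pi <- rowSums(P)
  # recursion structure and full-interval limit
  for (i in 2:24) {
    expect_equal(mn$M[i, 1] + mn$N[i, 25], pi[i], tolerance = 1e-12)
    k <- sample(1:(i - 1), 1)
    expect_equal(mn$M[i, k], sum(P[k:(i - 1), i]), tolerance = 1e-12)
    l <- sample(i:25, 1)
    expect_equal(mn$N[i, l],
                 if (l == i) 0 else sum(P[i, (i + 1):l]),
                 tolerance = 1e-12)
  }
})

test_that("restricted measures equal naive recomputation", {
  set.seed(303)
  P1 <- randomBppLike(30); P2 <- randomBppLike(30)
  for (t in 1:15) {
    k <- sample(1:20, 1); l <- k + sample(5:9, 1)
    for (basis in c("pi", "xi", "P")) {
      expect_equal(restrictedMeasure(P1, P2, c(k, l), "d", basis),
                   oracleRestricted(P1, P2, k, l, "d", basis),
                   tolerance = 1e-10)
      want <- oracleRestricted(P1, P2, k, l, "r", basis)
      if (!is.na(want))
        expect_equal(restrictedMeasure(P1, P2, c(k, l), "r", basis),
                     want, tolerance = 1e-10)
    }
  }
  # full interval equals the global measure
  n <- nrow(P1)
  expect_equal(restrictedMeasure(P1, P2, c(1, n), "d", "P"),
               euclidDistance(P1, P2), tolerance = 1e-12)
  expect_equal(restrictedMeasure(P1, P2, c(1, n), "d", "pi"),
               euclidDistance(rowSums(P1), rowSums(P2)),
               tolerance = 1e-12)
  expect_equal(restrictedMeasure(P1, P1, c(3, 20), "d", "pi"), 0)
  Z <- matrix(0, 30, 30)
  expect_error(restrictedMeasure(Z, Z, c(2, 10), "r", "pi"),
               "undefined correlation")
})

test_that("interval optimization equals exhaustive search", {
  set.seed(304)
  for (t in 1:6) {
    n <- sample(50:90, 1)
    minLen <- sample(c(8L, 15L, 30L), 1)
    P1 <- randomBppLike(n, 0.08); P2 <- randomBppLike(n, 0.08)
    for (basis in c("pi", "xi", "P")) for (meas in c("d", "r")) {
      got <- optimizeInterval(P1, P2, meas, basis, minLen = minLen)
      want <- oracleOptimize(P1, P2, meas, basis, minLen = minLen)
      expect_false(is.null(want))
      expect_equal(got$interval, c(want$k, want$l))
      expect_equal(got$score, want$score, tolerance = 1e-10)
    }
  }
})

test_that("optimizer ties, symmetry and degenerate cases are stable", {
  # all-zero ensembles: every interval scores 0; smallest (k, l) wins
  Z <- matrix(0, 70, 70)
  got <- optimizeInterval(Z, Z, "d", "pi", minLen = 50)
  expect_equal(got$interval, c(1L, 50L))
  expect_equal(got$score, 0)
  # correlation is undefined everywhere on empty ensembles
  gr <- optimizeInterval(Z, Z, "r", "pi", minLen = 50)
  expect_false(gr$found)
  expect_true(is.na(gr$score))
  # d_max is invariant under wild-type/mutant relabeling
  set.seed(305)
  P1 <- randomBppLike(80, 0.06); P2 <- randomBppLike(80, 0.06)
  a <- optimizeInterval(P1, P2, "d", "pi", minLen = 20)
  b <- optimizeInterval(P2, P1, "d", "pi", minLen = 20)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  expect_equal(a$interval, b$interval)
  expect_error(optimizeInterval(P1, P2, "d", "pi", minLen = 100),
               "below the minimal")
})
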