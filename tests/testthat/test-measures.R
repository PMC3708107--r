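test_that("pairing profiles do the single-pair bookkeeping", {
  P <- matrix(0, 8, 8)
  pr0 <- pairingProfiles(P)
  expect_true(all(pr0$pi == 0) && all(pr0$xiUnpaired == 1))
  P[2, 7] <- P[7, 2] <- 0.4
  pr <- pairingProfiles(P)
  expect_equal(pr$pi[2], 0.4)
  expect_equal(pr$pi[7], 0.4)
  expect_equal(pr$xiDown[2], 0.4)
  expect_equal(pr$xiUp[7], 0.4)
  expect_equal(pr$xiUp[2], 0)
})

test_that("profiles satisfy their identities and match enumeration", {
  set.seed(201)
  for (t in 1:5) {
    s <- randomSeqChar(sample(8:12, 1), 0.6)
    B <- foldGlobal(s)
    pr <- pairingProfiles(B)
    expect_equal(pr$pi, pr$xiUp + pr$xiDown, tolerance = 1e-12)
    expect_equal(pr$xiUp + pr$xiDown + pr$xiUnpaired,
                 rep(1, seqLength(B)), tolerance = 1e-12)
    expect_equal(pr$pi, rowSums(oracleBpp(s)), tolerance = 1e-9)
  }
})

test_that("Euclidean distance counts each unordered pair once", {
  set.seed(202)
  A <- randomBppLike(30); expect_equal(euclidDistance(A, A), 0)
  B <- A
  B[4, 20] <- B[4, 20] + 1 # one asymmetric-entry bump, upper triangle
  expect_equal(euclidDistance(A, B), 1)
  # naive double-loop oracle
  A <- randomBppLike(60); B <- randomBppLike(60)
  naive <- 0
  for (i in 1:59) for (j in (i + 1):60) naive <- naive + (A[i, j] - B[i, j])^2
  expect_equal(euclidDistance(A, B), sqrt(naive), tolerance = 1e-12)
  expect_error(euclidDistance(A, randomBppLike(10)), "shape mismatch")
})

test_that("Pearson correlation matches the textbook formula", {
  set.seed(203)
  A <- randomBppLike(40)
  expect_equal(pearsonCorrelation(A, A), 1)
  expect_equal(pearsonCorrelation(A, 0.7 - A), -1)
  B <- randomBppLike(40)
  a <- A[upper.tri(A)]; b <- B[upper.tri(B)]
  m <- length(a)
  want <- (m * sum(a * b) - sum(a) * sum(b)) /
    sqrt((m * sum(a^2) - sum(a)^2) * (m * sum(b^2) - sum(b)^2))
  expect_equal(pearsonCorrelation(A, B), want, tolerance = 1e-12)
  Z <- matrix(0, 40, 40)
  expect_error(pearsonCorrelation(Z, Z), "undefined correlation")
  # covariance identity ties the two measures to the same sums
  expect_equal(euclidDistance(A, B)^2,
               sum(a^2) + sum(b^2) - 2 * sum(a * b), tolerance = 1e-12)
})

test_that("ensemble distance matches explicit structure-space summation", {
  set.seed(204)
  for (t in 1:8) {
    n <- sample(7:12, 1)
    s <- randomSeqChar(n, runif(1, 0.4, 0.7))
    res <- strsplit(s, "")[[1]]
    pos <- sample(n, 1)
    alt <- sample(setdiff(c("A", "C", "G", "U"), res[pos]), 1)
    s2 <- s; substr(s2, pos, pos) <- alt
    expect_equal(ensembleDistance(s, s2), oracleDelta(s, s2),
                 tolerance = 1e-8)
  }
  expect_equal(ensembleDistance("GGGAAACCC", "GGGAAACCC"), 0,
               tolerance = 1e-9)
  expect_error(ensembleDistance("ACGU", "ACGUA"), "equal length")
  expect_error(ensembleDistance("ACGU", "ACGA", energyModel("thermo")),
               "builtin")
})
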