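test_that("span-limited profiles equal masked summation", {
  set.seed(401)
  P <- randomBppLike(40)
  h <- 5L
  want <- vapply(1:40, function(i) {
    js <- which(abs(seq_len(40) - i) <= h)
    sum(P[i, js])
  }, 0)
  expect_equal(spanLimitedProfile(P, h), want, tolerance = 1e-12)
  expect_equal(spanLimitedProfile(P, 40L), rowSums(P), tolerance = 1e-12)
  expect_equal(spanLimitedProfile(P, 1000L), rowSums(P), tolerance = 1e-12)
})

test_that("d# sliding recursion equals from-scratch summation", {
  set.seed(402)
  P1 <- randomBppLike(120, 0.06); P2 <- randomBppLike(120, 0.06)
  hP <- 9L; hD <- 30L
  prof <- dSharpProfile(P1, P2, hP, hD)
  d1 <- spanLimitedProfile(P1, hD); d2 <- spanLimitedProfile(P2, hD)
  want <- vapply(prof$k, function(k)
    sqrt(sum((d1[k:(k + hP - 1)] - d2[k:(k + hP - 1)])^2)), 0)
  expect_lt(max(abs(prof$d - want)), 1e-10)
  expect_equal(prof$kStar, prof$k[which.max(prof$d)])
  # identical ensembles scan flat at zero
  expect_true(all(dSharpProfile(P1, P1, hP, hD)$d == 0))
  # restricting to a substitution keeps the stated start range
  pr <- dSharpProfile(P1, P2, hP, hD, snpPos = 60)
  expect_equal(range(pr$k), c(60 - hD, 60 + hD))
  expect_error(dSharpProfile(P1, P2, 50L, 30L), "hPrime")
})

test_that("d# ties resolve to the smallest start", {
  # two identical bumps produce equal-scoring windows
  n <- 60L
  P1 <- matrix(0, n, n); P2 <- matrix(0, n, n)
  P2[10, 20] <- P2[20, 10] <- 0.5
  P2[40, 50] <- P2[50, 40] <- 0.5
  pr <- dSharpProfile(P1, P2, hPrime = 3L, hDPrime = 15L)
  expect_equal(max(pr$d[pr$k > 30]), max(pr$d[pr$k <= 30]))
  expect_true(pr$kStar <= 30)
})

test_that("peak-anchored re-optimization equals brute force", {
  set.seed(403)
  for (t in 1:10) {
    n <- sample(80:150, 1)
    P1 <- randomBppLike(n, 0.07); P2 <- randomBppLike(n, 0.07)
    kStar <- sample(seq_len(n - 5), 1)
    hP <- 6L; hD <- 25L
    got <- reoptimizeAtPeak(P1, P2, kStar, hP, hD, pThr = 0.01)
    want <- oracleReopt(P1, P2, kStar, hP, hD, pThr = 0.01)
    expect_equal(got$interval[1], kStar)
    expect_equal(got$interval, c(want$k, want$l))
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
  Z <- matrix(0, 50, 50)
  expect_equal(reoptimizeAtPeak(Z, Z, 10)$score, 0)
})

test_that("anchoring at the peak can only restrict the exact optimum", {
  set.seed(404)
  for (t in 1:8) {
    s <- randomSeqChar(80, 0.55)
    res <- strsplit(s, "")[[1]]
    pos <- sample(20:60, 1)
    alt <- sample(setdiff(c("A", "C", "G", "U"), res[pos]), 1)
    s2 <- s; substr(s2, pos, pos) <- alt
    S1 <- bppMatrix(foldScanning(s, 40L, 25L))
    S2 <- bppMatrix(foldScanning(s2, 40L, 25L))
    prof <- dSharpProfile(S1, S2, 6L, 25L, snpPos = pos)
    re <- reoptimizeAtPeak(S1, S2, prof$kStar, 6L, 25L)
    free <- optimizeInterval(S1, S2, "d", "pi", minLen = 2,
                             selfContain = FALSE)
    expect_lte(re$score, free$score + 1e-12)
  }
})

test_that("d# reduces to the global profile distance in the small limit", {
  set.seed(405)
  s <- randomSeqChar(18, 0.6)
  s2 <- s; substr(s2, 9, 9) <- if (substr(s, 9, 9) == "A") "G" else "A"
  G1 <- bppMatrix(foldGlobal(s)); G2 <- bppMatrix(foldGlobal(s2))
  hD <- 18L # >= n: no span is excluded
  pr <- dSharpProfile(G1, G2, hPrime = 18L, hDPrime = 18L)
  expect_length(pr$d, 1)
  expect_equal(pr$d, euclidDistance(rowSums(G1), rowSums(G2)),
               tolerance = 1e-10)
})
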