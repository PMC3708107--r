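test_that("substitutions are validated and applied exactly", {
  expect_equal(residues(applySubstitutions("GGGAAACCC",
                                           substitutionSet(5, "A", "G"))),
               "GGGAGACCC")
  # identical ref/alt rejected at construction
  expect_error(substitutionSet(1, "A", "A"), "identical")
  # reference mismatch names position and both alleles
  expect_error(applySubstitutions("ACGU", substitutionSet(2, "G", "C")),
               "position 2: expected G, found C")
  expect_error(applySubstitutions("ACGU", substitutionSet(9, "A", "C")),
               "beyond sequence length")
  # multiple simultaneous substitutions, order-independent input
  mut <- applySubstitutions("AAAAAA", substitutionSet(c(5, 2),
                                                      c("A", "A"),
                                                      c("G", "C")))
  expect_equal(residues(mut), "ACAAGA")
})

test_that("sequence construction normalizes DNA and checks the alphabet", {
  expect_equal(residues(suppressMessages(rnaSequence("acgt"))), "ACGU")
  expect_error(rnaSequence("ACGX"), "outside")
  expect_error(rnaSequence(""), "nonempty")
  s <- rnaSequence("GGAUCC", id = "x")
  expect_equal(seqLength(s), 6L)
  expect_equal(seqId(s), "x")
})

test_that("builtin global fold matches exhaustive enumeration", {
  set.seed(101)
  for (t in 1:15) {
    n <- sample(6:12, 1)
    s <- randomSeqChar(n, runif(1, 0.3, 0.7))
    P <- bppMatrix(foldGlobal(s))
    expect_lt(max(abs(P - oracleBpp(s))), 1e-9)
  }
})

test_that("sequences without an admissible structure fold to zero", {
  expect_true(all(bppMatrix(foldGlobal("ACGUA")) == 0))
  # A/C alphabet cannot pair at all
  expect_true(all(bppMatrix(foldGlobal(strrep("AC", 20))) == 0))
})

test_that("global fold conserves per-position probability", {
  set.seed(102)
  for (gc in c(0.3, 0.5, 0.8)) {
    P <- bppMatrix(foldGlobal(randomSeqChar(50, gc)))
    expect_true(all(rowSums(P) <= 1 + 1e-9))
    expect_equal(P, t(P))
  }
})

test_that("scanning fold equals the direct window-average", {
  set.seed(103)
  s <- randomSeqChar(30, 0.6)
  W <- 12L; L <- 8L; n <- 30L
  S <- bppMatrix(foldScanning(s, W, L))
  acc <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (a in 1:(n - W + 1)) {
    Pw <- bppMatrix(foldGlobal(substr(s, a, a + W - 1)))
    idx <- a:(a + W - 1)
    acc[idx, idx] <- acc[idx, idx] + Pw
    cnt[idx, idx] <- cnt[idx, idx] + 1
  }
  M <- ifelse(cnt > 0, acc / cnt, 0)
  M[abs(row(M) - col(M)) > L] <- 0
  expect_lt(max(abs(S - M)), 1e-9)
})

test_that("scanning fold of a short sequence is a span-capped global fold", {
  set.seed(104)
  s <- randomSeqChar(35, 0.5)
  S <- bppMatrix(foldScanning(s, W = 60L, L = 10L))
  G <- bppMatrix(foldGlobal(s))
  G[abs(row(G) - col(G)) > 10] <- 0
  expect_equal(S, G, tolerance = 1e-12)
  expect_error(foldScanning(s, W = 20L, L = 30L), "must not exceed")
})

test_that("thermodynamic engine produces valid matrices", {
  set.seed(105)
  s <- randomSeqChar(60, 0.55)
  G <- foldGlobal(s, energyModel("thermo"))
  expect_s4_class(G, "BasePairMatrix")
  expect_equal(foldEngine(G), "thermo")
  expect_true(all(rowSums(bppMatrix(G)) <= 1 + 1e-9))
  S <- foldScanning(s, W = 40L, L = 30L, model = energyModel("thermo"))
  expect_equal(backendTag(S), "scanning")
  expect_true(all(bppMatrix(S)[abs(row(bppMatrix(S)) -
                                   col(bppMatrix(S))) > 30] == 0))
})

test_that("a missing thermodynamic engine is a clear error", {
  withr::local_envvar(PATH = "")
  expect_error(foldGlobal("GGGAAACCC", energyModel("thermo")),
               "ViennaRNA")
})

test_that("FASTA input selects records and converts DNA", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a first", "GGGAAACCC", ">b second", "ACGTACGT"), fa)
  seqs <- suppressMessages(readRnaFasta(fa))
  expect_length(seqs, 2)
  expect_equal(residues(seqs[[2]]), "ACGUACGU")
  one <- suppressMessages(readRnaFasta(fa, id = "b"))
  expect_length(one, 1)
  expect_equal(seqId(one[[1]]), "b")
  expect_error(readRnaFasta(fa, id = "zz"), "no FASTA record")
})
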