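# Independent oracles: exhaustive structure enumeration for small n,
# naive measure recomputation, and brute-force interval search.  These
# deliberately avoid the package's recursion code paths.

oraclePairable <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

oraclePairEnergy <- function(a, b, pe = c(GC = -3, AU = -2, GU = -1)) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) pe[["GC"]]
  else if (key %in% c("AU", "UA")) pe[["AU"]]
  else if (key %in% c("GU", "UG")) pe[["GU"]]
  else stop("not pairable")
}

# all secondary structures (lists of pairs) on res[i..j], hairpins >= minh
oracleStructures <- function(res, minh = 3L) {
  n <- length(res)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j) # i unpaired
    kset <- if (j >= i + minh + 1L) (i + minh + 1L):j else integer(0)
    for (k in kset) {
      if (!oraclePairable(res[i], res[k])) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (s1 in left) for (s2 in right)
        out <- c(out, list(rbind(c(i, k), s1, s2)))
    }
    assign(key, out, envir = memo)
    out
  }
  rec(1L, n)
}

# Boltzmann distribution over enumerated structures
oracleEnsemble <- function(seq, minh = 3L, rt = 1) {
  res <- strsplit(toupper(seq), "")[[1]]
  structs <- oracleStructures(res, minh)
  E <- vapply(structs, function(s) {
    if (nrow(s) == 0) return(0)
    sum(vapply(seq_len(nrow(s)), function(r)
      oraclePairEnergy(res[s[r, 1]], res[s[r, 2]]), 0))
  }, 0)
  w <- exp(-E / rt)
  list(structs = structs, w = w, Z = sum(w), p = w / sum(w))
}

# pair probability matrix from the enumeration
oracleBpp <- function(seq, minh = 3L) {
  ens <- oracleEnsemble(seq, minh)
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (t in seq_along(ens$structs)) {
    s <- ens$structs[[t]]
    if (nrow(s) == 0) next
    P[s] <- P[s] + ens$p[t]
  }
  P + t(P)
}

structureKey <- function(s) {
  if (nrow(s) == 0) return("")
  o <- order(s[, 1])
  paste(s[o, 1], s[o, 2], sep = ":", collapse = ",")
}

# ensemble distance by explicit summation over the union of structures
oracleDelta <- function(seq1, seq2, minh = 3L) {
  e1 <- oracleEnsemble(seq1, minh)
  e2 <- oracleEnsemble(seq2, minh)
  k1 <- vapply(e1$structs, structureKey, "")
  k2 <- vapply(e2$structs, structureKey, "")
  keys <- union(k1, k2)
  p1 <- setNames(rep(0, length(keys)), keys)
  p2 <- p1
  p1[k1] <- e1$p
  p2[k2] <- e2$p
  sqrt(sum((p1 - p2)^2))
}

# direct (loop-based) restricted measure from scratch
oracleRestricted <- function(P1, P2, k, l, measure = "d", basis = "pi") {
  idx <- k:l
  if (basis == "P") {
    a <- P1[idx, idx][upper.tri(P1[idx, idx, drop = FALSE])]
    b <- P2[idx, idx][upper.tri(P2[idx, idx, drop = FALSE])]
  } else {
    restr <- function(P) {
      up <- vapply(idx, function(i)
        if (i == k) 0 else sum(P[i, k:(i - 1)]), 0)
      dn <- vapply(idx, function(i)
        if (i == l) 0 else sum(P[i, (i + 1):l]), 0)
      if (basis == "pi") up + dn else c(up, dn)
    }
    a <- restr(P1)
    b <- restr(P2)
  }
  if (measure == "d") sqrt(sum((a - b)^2))
  else if (sd(a) == 0 || sd(b) == 0) NA_real_
  else cor(a, b)
}

oracleSelfContained <- function(P1, P2, k, l, alpha = 1) {
  chk <- function(P) {
    idx <- k:l
    win <- sum(P[idx, idx][upper.tri(P[idx, idx, drop = FALSE])])
    cross <- sum(P[idx, -idx, drop = FALSE])
    win >= alpha * cross
  }
  chk(P1) || chk(P2)
}

# exhaustive search over all admissible intervals with independent
# per-interval recomputation.  Row cumulative sums give the restricted
# marginals; the expected number of pairs inside [k,l] uses the
# double-counting identity W_in = sum_i pi_i[k,l] / 2 (P symmetric).
oracleOptimize <- function(P1, P2, measure = "d", basis = "pi",
                           minLen = 50L, alpha = 1, pThr = 0.01,
                           selfContain = TRUE) {
  P1[P1 < pThr] <- 0
  P2[P2 < pThr] <- 0
  n <- nrow(P1)
  C1 <- cbind(0, t(apply(P1, 1, cumsum))) # C[i, t+1] = sum_{j<=t} P[i,j]
  C2 <- cbind(0, t(apply(P2, 1, cumsum)))
  cpi1 <- c(0, cumsum(C1[, n + 1]))
  cpi2 <- c(0, cumsum(C2[, n + 1]))
  best <- NULL
  for (k in seq_len(n - minLen + 1L)) {
    for (l in seq(k + minLen - 1L, n)) {
      idx <- k:l
      a <- C1[idx, l + 1] - C1[idx, k]  # pi_i[k,l], wild type
      b <- C2[idx, l + 1] - C2[idx, k]
      if (selfContain) {
        win1 <- sum(a) / 2
        win2 <- sum(b) / 2
        ok1 <- win1 >= alpha * ((cpi1[l + 1] - cpi1[k]) - 2 * win1)
        ok2 <- win2 >= alpha * ((cpi2[l + 1] - cpi2[k]) - 2 * win2)
        if (!ok1 && !ok2) next
      }
      if (basis == "xi") {
        a <- c(C1[cbind(idx, idx)] - C1[idx, k],
               C1[idx, l + 1] - C1[cbind(idx, idx + 1L)])
        b <- c(C2[cbind(idx, idx)] - C2[idx, k],
               C2[idx, l + 1] - C2[cbind(idx, idx + 1L)])
      } else if (basis == "P") {
        a <- P1[idx, idx][upper.tri(P1[idx, idx, drop = FALSE])]
        b <- P2[idx, idx][upper.tri(P2[idx, idx, drop = FALSE])]
      }
      if (measure == "d") {
        sc <- sqrt(sum((a - b)^2))
      } else {
        if (sd(a) == 0 || sd(b) == 0) next
        sc <- cor(a, b)
      }
      better <- if (is.null(best)) TRUE
                else if (measure == "d") sc > best$score
                else sc < best$score
      if (better) best <- list(k = k, l = l, score = sc)
    }
  }
  best
}

# brute force for the peak-anchored re-optimization: maximal restricted
# profile distance over ends l in (kStar, min(n, kStar + hD + hP)]
oracleReopt <- function(P1, P2, kStar, hPrime = 20L, hDPrime = 120L,
                        pThr = 0.01) {
  P1[P1 < pThr] <- 0
  P2[P2 < pThr] <- 0
  n <- nrow(P1)
  C1 <- cbind(0, t(apply(P1, 1, cumsum)))
  C2 <- cbind(0, t(apply(P2, 1, cumsum)))
  best <- NULL
  lMax <- min(n, kStar + hDPrime + hPrime)
  if (kStar + 1 > lMax) return(NULL)
  for (l in (kStar + 1):lMax) {
    idx <- kStar:l
    a <- C1[idx, l + 1] - C1[idx, kStar]
    b <- C2[idx, l + 1] - C2[idx, kStar]
    sc <- sqrt(sum((a - b)^2))
    if (is.null(best) || sc > best$score)
      best <- list(k = kStar, l = l, score = sc)
  }
  best
}

# random symmetric "probability-like" matrix with controlled sparsity;
# rows are rescaled so that total pairing probabilities stay below 1
randomBppLike <- function(n, density = 0.05) {
  M <- matrix(0, n, n)
  up <- which(upper.tri(M) & (col(M) - row(M)) >= 4)
  pick <- sample(up, max(1, round(density * length(up))))
  M[pick] <- runif(length(pick))
  M <- M + t(M)
  rs <- rowSums(M)
  scale <- max(rs, 1)
  M / scale
}

randomSeqChar <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "U"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}
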