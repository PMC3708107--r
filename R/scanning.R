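#' Span-limited pairing profile
#'
#' \code{piHat[i] = sum over j with |j - i| <= hSpan of P[i, j]}: the
#' positional pairing probability counting only pairs of limited span.
#' Equals the plain profile when the matrix is already span-capped at or
#' below \code{hSpan}.
#'
#' @param P a [BasePairMatrix-class] or matrix
#' @param hSpan maximal pair span
#' @return numeric vector
#' @export
spanLimitedProfile <- function(P, hSpan = 120L) {
  M <- asProbMatrix(P)
  n <- nrow(M)
  cum <- cbind(0, t(apply(M, 1, cumsum)))
  i <- seq_len(n)
  lo <- pmax(0L, i - hSpan - 1L)
  hi <- pmin(n, i + hSpan)
  cum[cbind(i, hi + 1L)] - cum[cbind(i, lo + 1L)]
}

#' Scanning dissimilarity profile d#
#'
#' The screening score: for each window start k,
#' \eqn{d^\#(k)^2 = \sum_{i=k}^{k+h'-1} (\hat\pi_i - \hat\pi^*_i)^2},
#' where \eqn{\hat\pi} are span-limited pairing profiles with maximal
#' pair span \code{hDPrime}.  Computed with the sliding-window recursion
#' \eqn{d^\#(k+1)^2 = d^\#(k)^2 - \Delta_k + \Delta_{k+h'}}.  The
#' integration window covers \code{hPrime} positions, [k, k + h' - 1].
#' When \code{snpPos} is given the scan is restricted to starts within
#' \code{hDPrime} of the substitution; profile differences vanish far
#' from it.
#'
#' @param P,Pstar wild-type and mutant matrices (same backend)
#' @param hPrime integration window length (default 20)
#' @param hDPrime maximal base pair span (default 120)
#' @param snpPos optional substitution position restricting the scan range
#' @return list with positions k, scores d, and the peak kStar (class
#'   \code{ScanProfile}); ties resolve to the smallest k
#' @export
dSharpProfile <- function(P, Pstar, hPrime = 20L, hDPrime = 120L,
                          snpPos = NULL) {
  stopifnot(hPrime >= 1, hPrime <= hDPrime)
  M1 <- asProbMatrix(P); M2 <- asProbMatrix(Pstar)
  n <- nrow(M1)
  if (n < hPrime) stop("sequence shorter than the integration window")
  d1 <- spanLimitedProfile(M1, hDPrime)
  d2 <- spanLimitedProfile(M2, hDPrime)
  delta2 <- (d1 - d2)^2
  kMax <- n - hPrime + 1L
  if (is.null(snpPos)) {
    ks <- seq_len(kMax)
  } else {
    stopifnot(snpPos >= 1, snpPos <= n)
    ks <- max(1L, snpPos - hDPrime):min(kMax, snpPos + hDPrime)
  }
  # sliding recursion over the scanned range
  d2acc <- numeric(length(ks))
  d2acc[1] <- sum(delta2[ks[1]:(ks[1] + hPrime - 1L)])
  if (length(ks) > 1) {
    for (t in 2:length(ks)) {
      k <- ks[t]
      d2acc[t] <- d2acc[t - 1] - delta2[k - 1L] + delta2[k + hPrime - 1L]
    }
  }
  d <- sqrt(pmax(0, d2acc))
  structure(list(k = ks, d = d, kStar = ks[which.max(d)],
                 hPrime = hPrime, hDPrime = hDPrime),
            class = "ScanProfile")
}

#' Exact re-optimization anchored at the scan peak
#'
#' Given the peak position k* of a [dSharpProfile()], computes the exact
#' restricted distance \eqn{d_{[k^*, l]}} on the pairing profiles and
#' maximizes it over ends l in (k*, min(n, k* + h'' + h')].  The end cap
#' keeps the exact search within the span the scanning fold could see.
#' Matrices are threshold-filtered first.
#'
#' @param P,Pstar wild-type and mutant matrices (scanning backend)
#' @param kStar anchored interval start
#' @param hPrime,hDPrime scan parameters (defaults 20, 120)
#' @param pThr noise filter threshold
#' @return an \code{IntervalScore} whose interval starts at kStar
#' @export
reoptimizeAtPeak <- function(P, Pstar, kStar, hPrime = 20L,
                             hDPrime = 120L, pThr = 0.01) {
  M1 <- thresholdFilter(asProbMatrix(P), pThr)
  M2 <- thresholdFilter(asProbMatrix(Pstar), pThr)
  n <- nrow(M1)
  stopifnot(kStar >= 1, kStar <= n)
  lMax <- min(n, kStar + hDPrime + hPrime)
  res <- .cppOptimizeInterval(M1, M2, basis = 0L, measure = 0L,
                              minLen = 2L, alpha = 1, selfContain = FALSE,
                              fixedK = as.integer(kStar),
                              lMax = as.integer(lMax))
  if (!res$found) {
    return(structure(list(interval = c(kStar, kStar), score = 0,
                          measure = "d", basis = "pi", found = FALSE),
                     class = "IntervalScore"))
  }
  structure(list(interval = c(res$k, res$l), score = res$score,
                 measure = "d", basis = "pi", found = TRUE),
            class = "IntervalScore")
}
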