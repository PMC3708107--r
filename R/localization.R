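#' Discard base pairs below a probability threshold
#'
#' Noise filter: entries with probability strictly below \code{pThr} are
#' set to 0; the filter is applied before interval optimization and
#' before the self-containedness sums.
#'
#' @param P a [BasePairMatrix-class] or matrix
#' @param pThr threshold probability in [0, 1)
#' @return object of the same kind as \code{P}
#' @export
thresholdFilter <- function(P, pThr = 0.01) {
  stopifnot(pThr >= 0, pThr < 1)
  if (is(P, "BasePairMatrix")) {
    M <- P@probs
    M[M < pThr] <- 0
    methods::initialize(P, probs = M)
  } else {
    P[P < pThr] <- 0
    P
  }
}

#' Self-containedness of a sequence interval
#'
#' An interval is self-contained when the expected number of base pairs
#' lying entirely inside it is at least \code{alpha} times the expected
#' number of positions inside pairing with partners outside, for the
#' wild-type or for the mutant ensemble.  The full sequence is always
#' self-contained (nothing can cross its boundary).
#'
#' @param P,Pstar wild-type and mutant matrices
#' @param interval integer c(k, l), 1-based inclusive
#' @param alpha threshold factor, default 1
#' @return logical
#' @export
selfContained <- function(P, Pstar, interval, alpha = 1) {
  M1 <- asProbMatrix(P); M2 <- asProbMatrix(Pstar)
  k <- interval[1]; l <- interval[2]
  stopifnot(k >= 1, l <= nrow(M1), k <= l)
  ok <- function(M) {
    idx <- k:l
    win <- sum(M[idx, idx][upper.tri(M[idx, idx, drop = FALSE])])
    tot <- sum(M[idx, ])
    win >= alpha * (tot - 2 * win)
  }
  ok(M1) || ok(M2)
}

#' Interval pairing tables M and N
#'
#' \code{M[i, k]} is the probability that position i pairs with a partner
#' in [k, i-1]; \code{N[i, l]} that it pairs in [i+1, l].  They satisfy
#' \code{M[i,k] = M[i,k+1] + P[k,i]} and \code{N[i,l] = N[i,l-1] + P[i,l]}
#' and give the interval-restricted pairing probability
#' \code{pi_i[k,l] = M[i,k] + N[i,l]} in constant time per evaluation.
#'
#' @param P a [BasePairMatrix-class] or matrix
#' @return list with matrices M and N (class \code{MNTables})
#' @export
mnTables <- function(P) {
  M0 <- asProbMatrix(P)
  n <- nrow(M0)
  cum <- cbind(0, t(apply(M0, 1, cumsum))) # cum[i, t+1] = sum_{j<=t} P[i,j]
  R <- function(i, t) cum[cbind(i, t + 1)]
  ii <- rep(seq_len(n), each = n)
  kk <- rep(seq_len(n), times = n)
  M <- matrix(0, n, n)
  use <- kk <= ii
  M[cbind(ii[use], kk[use])] <-
    R(ii[use], ii[use] - 1L) - R(ii[use], kk[use] - 1L)
  N <- matrix(0, n, n)
  use <- kk >= ii
  N[cbind(ii[use], kk[use])] <- R(ii[use], kk[use]) - R(ii[use], ii[use])
  structure(list(M = M, N = N, n = n), class = "MNTables")
}

restrictedProfiles <- function(P, interval, mn = NULL, basis = "pi") {
  M0 <- asProbMatrix(P)
  if (is.null(mn)) mn <- mnTables(M0)
  k <- interval[1]; l <- interval[2]
  idx <- k:l
  up <- mn$M[cbind(idx, rep(k, length(idx)))]   # pairs into [k, i-1]
  down <- mn$N[cbind(idx, rep(l, length(idx)))]
  if (basis == "pi") up + down else c(up, down)
}

#' Interval-restricted (dis)similarity
#'
#' Computes the Euclidean distance or Pearson correlation between
#' wild-type and mutant restricted to the interval [k, l]: profile bases
#' use the restricted marginals \code{pi_i[k,l]} (or the upstream /
#' downstream split), the matrix basis uses pairs with both ends inside.
#'
#' @param P,Pstar wild-type and mutant matrices
#' @param interval integer c(k, l)
#' @param measure "d" (Euclidean) or "r" (Pearson)
#' @param basis "pi", "xi" or "P"
#' @param mn,mnStar optional precomputed [mnTables()] for the two inputs
#' @return the restricted score
#' @export
restrictedMeasure <- function(P, Pstar, interval,
                              measure = c("d", "r"),
                              basis = c("pi", "xi", "P"),
                              mn = NULL, mnStar = NULL) {
  measure <- match.arg(measure)
  basis <- match.arg(basis)
  M1 <- asProbMatrix(P); M2 <- asProbMatrix(Pstar)
  k <- interval[1]; l <- interval[2]
  stopifnot(k >= 1, l <= nrow(M1), k <= l)
  if (basis == "P") {
    idx <- k:l
    a <- M1[idx, idx, drop = FALSE]; a <- a[upper.tri(a)]
    b <- M2[idx, idx, drop = FALSE]; b <- b[upper.tri(b)]
  } else {
    a <- restrictedProfiles(M1, interval, mn, basis)
    b <- restrictedProfiles(M2, interval, mnStar, basis)
  }
  if (measure == "d") {
    sqrt(sum((a - b)^2))
  } else {
    if (length(a) < 2 || sd(a) == 0 || sd(b) == 0)
      stop("undefined correlation on interval [", k, ",", l,
           "]: constant restriction")
    min(1, max(-1, cor(a, b)))
  }
}

#' Find the interval of maximal structural change
#'
#' Scans all intervals of length at least \code{minLen} that pass the
#' self-containedness test and returns the one maximizing the restricted
#' Euclidean distance (measure "d") or minimizing the restricted Pearson
#' correlation (measure "r").  Both matrices are threshold-filtered
#' first.  Ties resolve to the smallest start, then smallest end.  If no
#' interval can be scored (possible only for "r" when every admissible
#' restriction is constant), the full sequence is reported with score NA.
#'
#' @param P,Pstar wild-type and mutant matrices
#' @param measure "d" or "r"
#' @param basis "pi", "xi" or "P"
#' @param minLen minimal interval length (default 50)
#' @param alpha self-containedness factor (default 1)
#' @param pThr noise filter threshold (default 0.01)
#' @param selfContain apply the self-containedness filter (default TRUE)
#' @return list with interval, score, measure, basis, found (class
#'   \code{IntervalScore})
#' @export
optimizeInterval <- function(P, Pstar, measure = c("d", "r"),
                             basis = c("pi", "xi", "P"),
                             minLen = 50L, alpha = 1, pThr = 0.01,
                             selfContain = TRUE) {
  measure <- match.arg(measure)
  basis <- match.arg(basis)
  M1 <- thresholdFilter(asProbMatrix(P), pThr)
  M2 <- thresholdFilter(asProbMatrix(Pstar), pThr)
  n <- nrow(M1)
  if (n < minLen)
    stop("sequence length ", n, " is below the minimal interval length ",
         minLen)
  res <- .cppOptimizeInterval(M1, M2,
                              basis = match(basis, c("pi", "xi", "P")) - 1L,
                              measure = match(measure, c("d", "r")) - 1L,
                              minLen = as.integer(minLen), alpha = alpha,
                              selfContain = selfContain,
                              fixedK = 0L, lMax = 0L)
  if (!res$found) {
    return(structure(list(interval = c(1L, n), score = NA_real_,
                          measure = measure, basis = basis, found = FALSE),
                     class = "IntervalScore"))
  }
  structure(list(interval = c(res$k, res$l), score = res$score,
                 measure = measure, basis = basis, found = TRUE),
            class = "IntervalScore")
}

#' @export
print.IntervalScore <- function(x, ...) {
  cat(sprintf("IntervalScore: %s on %s basis, [%d, %d], score %.6g\n",
              x$measure, x$basis, x$interval[1], x$interval[2], x$score))
  invisible(x)
}
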