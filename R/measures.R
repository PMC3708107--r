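#' Position-wise pairing profiles
#'
#' Marginals of the base pair probability matrix: the probability that
#' position i is paired at all (\code{pi}), paired with a partner
#' upstream (\code{xiUp}) or downstream (\code{xiDown}), or unpaired
#' (\code{xiUnpaired}).  By construction \code{pi = xiUp + xiDown} and
#' \code{xiUp + xiDown + xiUnpaired = 1}.
#'
#' @param P a [BasePairMatrix-class] or symmetric probability matrix
#' @return list with components pi, xiUp, xiDown, xiUnpaired
#' @export
pairingProfiles <- function(P) {
  M <- asProbMatrix(P)
  xiUp <- rowSums(M * lower.tri(M))   # partner j < i
  xiDown <- rowSums(M * upper.tri(M)) # partner j > i
  pi <- xiUp + xiDown
  structure(list(pi = pi, xiUp = xiUp, xiDown = xiDown,
                 xiUnpaired = pmax(0, 1 - pi)),
            class = "PairingProfiles")
}

asProbMatrix <- function(P) {
  if (is(P, "BasePairMatrix")) P@probs
  else if (is.matrix(P)) P
  else stop("expected a BasePairMatrix or matrix")
}

#' Flatten a profile (or matrix) to the comparison vector of a basis
#'
#' \code{"pi"} uses the total pairing probabilities; \code{"xi"}
#' concatenates the upstream and downstream components (the unpaired
#' component is redundant and excluded); \code{"P"} uses each unordered
#' pair once.
#'
#' @param P matrix or [BasePairMatrix-class]
#' @param basis "pi", "xi" or "P"
#' @return numeric vector
#' @export
profileVector <- function(P, basis = c("pi", "xi", "P")) {
  basis <- match.arg(basis)
  M <- asProbMatrix(P)
  if (basis == "P") return(M[upper.tri(M)])
  pr <- pairingProfiles(M)
  if (basis == "pi") pr$pi else c(pr$xiUp, pr$xiDown)
}

comparisonVectors <- function(A, B, what = "input") {
  a <- if (is(A, "BasePairMatrix") || is.matrix(A)) {
    M <- asProbMatrix(A); M[upper.tri(M)]
  } else as.numeric(A)
  b <- if (is(B, "BasePairMatrix") || is.matrix(B)) {
    M <- asProbMatrix(B); M[upper.tri(M)]
  } else as.numeric(B)
  if (length(a) != length(b))
    stop("shape mismatch between the two ", what, "s")
  list(a = a, b = b)
}

#' Euclidean distance between probability collections
#'
#' For matrices each unordered pair is summed once; vectors are compared
#' entry-wise.
#'
#' @param A,B equal-shape matrices ([BasePairMatrix-class] accepted) or
#'   numeric vectors
#' @return nonnegative distance
#' @export
euclidDistance <- function(A, B) {
  v <- comparisonVectors(A, B)
  sqrt(sum((v$a - v$b)^2))
}

#' Pearson correlation between probability collections
#'
#' @inheritParams euclidDistance
#' @return correlation in [-1, 1]; an error if both inputs are constant
#' @export
pearsonCorrelation <- function(A, B) {
  v <- comparisonVectors(A, B)
  if (sd(v$a) == 0 && sd(v$b) == 0)
    stop("undefined correlation: both inputs are constant")
  if (sd(v$a) == 0 || sd(v$b) == 0)
    stop("undefined correlation: an input is constant")
  min(1, max(-1, cor(v$a, v$b)))
}

#' Ensemble distance between two structure distributions
#'
#' Euclidean distance \eqn{\delta} between the Boltzmann distributions of
#' secondary structures of two equal-length sequences,
#' \eqn{\delta^2 = \sum_\psi (p_x(\psi) - p_{x^*}(\psi))^2}, computed from
#' partition functions: the squared-probability sums are partition
#' functions evaluated with the thermal energy halved, and the cross term
#' is a partition function over structures formable by both sequences
#' with pair energies averaged between them.  Builtin model only.
#'
#' @param x,xstar equal-length sequences
#' @param model a builtin [EnergyModel-class]
#' @return nonnegative distance \eqn{\delta}
#' @export
ensembleDistance <- function(x, xstar, model = energyModel()) {
  x <- rnaSequence(x); xstar <- rnaSequence(xstar)
  if (seqLength(x) != seqLength(xstar))
    stop("sequences must have equal length")
  if (model@mode != "builtin")
    stop("ensemble distance is implemented for the builtin model")
  w1 <- pairWeightMatrix(x, model)
  w2 <- pairWeightMatrix(xstar, model)
  .cppEnsembleDistance(w1, w2, model@minHairpin,
                       (gcFraction(x) + gcFraction(xstar)) / 2)
}
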