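#' Simulate a null sample of substitution scores
#'
#' Draws random sequences, applies one random substitution at the stated
#' position, and scores each variant through the same path the pipeline
#' uses: global folding with exact interval optimization for "dmax" and
#' "rmin", scanning folding with the d# screen ("dsharp") and its exact
#' peak re-optimization ("dmaxScan").  Several measures can be collected
#' from the same draws.
#'
#' @param nSamples number of draws
#' @param length sequence length
#' @param gcRange G+C content range; each draw samples a target uniformly
#'   within it (a single value fixes it)
#' @param position substitution position
#' @param measures subset of c("dmax", "rmin", "dsharp", "dmaxScan")
#' @param config a [rnasnpConfig()]
#' @return data.frame with one row per draw: gc, alt and one column per
#'   measure ("rmin" is NA where undefined)
#' @export
nullSample <- function(nSamples, length = 400L, gcRange = c(0.5, 0.6),
                       position = 200L,
                       measures = c("dmax", "rmin"),
                       config = rnasnpConfig()) {
  stopifnot(nSamples >= 1, position >= 1, position <= length)
  measures <- match.arg(measures,
                        c("dmax", "rmin", "dsharp", "dmaxScan"),
                        several.ok = TRUE)
  needGlobal <- any(measures %in% c("dmax", "rmin"))
  needScan <- any(measures %in% c("dsharp", "dmaxScan"))
  if (length(gcRange) == 1) gcRange <- rep(gcRange, 2)
  model <- config$model
  # draw all variants first, then score (lets the thermodynamic engine
  # fold wild-type/mutant pairs in batches)
  gc <- runif(nSamples, gcRange[1], gcRange[2])
  wt <- lapply(gc, function(g) randomSequence(length, g))
  ref <- vapply(wt, function(s) substr(residues(s), position, position), "")
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "U"), r), 1), "")
  mut <- lapply(seq_len(nSamples), function(s)
    applySubstitutions(wt[[s]], substitutionSet(position, ref[s], alt[s])))
  out <- data.frame(gc = gc, alt = alt, stringsAsFactors = FALSE)
  for (m in measures) out[[m]] <- NA_real_

  scoreGlobal <- function(s, Pw, Pm) {
    if ("dmax" %in% measures)
      out$dmax[s] <<- optimizeInterval(Pw, Pm, "d", "pi",
                                       minLen = config$minLen,
                                       alpha = config$alpha,
                                       pThr = config$pThr)$score
    if ("rmin" %in% measures)
      out$rmin[s] <<- optimizeInterval(Pw, Pm, "r", "pi",
                                       minLen = config$minLen,
                                       alpha = config$alpha,
                                       pThr = config$pThr)$score
  }
  scoreScan <- function(s, Sw, Sm) {
    prof <- dSharpProfile(Sw, Sm, config$hPrime, config$hDPrime,
                          snpPos = position)
    if ("dsharp" %in% measures)
      out$dsharp[s] <<- max(prof$d)
    if ("dmaxScan" %in% measures)
      out$dmaxScan[s] <<- reoptimizeAtPeak(Sw, Sm, prof$kStar,
                                           config$hPrime, config$hDPrime,
                                           config$pThr)$score
  }

  if (model@mode == "thermo") {
    # interleave wt/mut so each pair lands in the same chunk
    pairSeqs <- vector("list", 2L * nSamples)
    pairSeqs[2 * seq_len(nSamples) - 1L] <- wt
    pairSeqs[2 * seq_len(nSamples)] <- mut
    if (needGlobal) {
      hold <- new.env(parent = emptyenv())
      thermoFoldBatch(pairSeqs, "global", chunkSize = 100L,
                      consume = function(i, P) {
                        s <- (i + 1L) %/% 2L
                        if (i %% 2L == 1L) assign("wt", P, envir = hold)
                        else scoreGlobal(s, get("wt", envir = hold), P)
                        NULL
                      })
    }
    if (needScan) {
      hold <- new.env(parent = emptyenv())
      thermoFoldBatch(pairSeqs, "scanning", W = config$W, L = config$L,
                      chunkSize = 100L,
                      consume = function(i, P) {
                        s <- (i + 1L) %/% 2L
                        if (i %% 2L == 1L) assign("wt", P, envir = hold)
                        else scoreScan(s, get("wt", envir = hold), P)
                        NULL
                      })
    }
  } else {
    for (s in seq_len(nSamples)) {
      if (needGlobal)
        scoreGlobal(s, foldGlobal(wt[[s]], model),
                    foldGlobal(mut[[s]], model))
      if (needScan)
        scoreScan(s, foldScanning(wt[[s]], config$W, config$L, model),
                  foldScanning(mut[[s]], config$W, config$L, model))
    }
  }
  out
}

#' Gumbel fit of transformed distance scores
#'
#' Distances enter the fit through \eqn{x = 1 - \log d}; exact zeros
#' (no structural change, P value 1 by convention) are excluded.
#' Maximum-likelihood estimation via the profile likelihood in the scale
#' parameter.
#'
#' @param d distance scores
#' @return named numeric c(mu, sigma)
#' @export
fitGumbel <- function(d) {
  x <- 1 - log(d[is.finite(d) & d > 0])
  if (length(x) < 10) stop("too few positive distances to fit")
  if (sd(x) == 0) stop("degenerate sample: all transformed values equal")
  xbar <- mean(x)
  # ML scale solves sigma = mean(x) - sum(x w)/sum(w), w = exp(-x/sigma)
  f <- function(s) {
    w <- exp(-(x - xbar) / s)
    s - xbar + sum(x * w) / sum(w)
  }
  s0 <- sd(x) * sqrt(6) / pi
  lo <- s0 / 10; hi <- s0 * 10
  while (f(lo) > 0 && lo > s0 * 1e-4) lo <- lo / 2
  while (f(hi) < 0 && hi < s0 * 1e4) hi <- hi * 2
  sigma <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  mu <- -sigma * log(mean(exp(-(x - xbar) / sigma))) + xbar
  c(mu = mu, sigma = sigma)
}

#' Beta fit of transformed correlation scores
#'
#' Correlations enter through \eqn{y = (r + 1)/2}; values are shrunk
#' infinitesimally into (0, 1) where they touch the boundary.  Maximum
#' likelihood via \code{MASS::fitdistr}.
#'
#' @param r correlation scores in [-1, 1]
#' @return named numeric c(a, b)
#' @export
fitBeta <- function(r) {
  r <- r[is.finite(r)]
  if (any(r < -1 - 1e-9 | r > 1 + 1e-9))
    stop("correlations outside [-1, 1]")
  y <- (pmin(1, pmax(-1, r)) + 1) / 2
  n <- length(y)
  if (n < 10) stop("too few correlations to fit")
  y <- (y * (n - 1) + 0.5) / n # keep strictly inside (0, 1)
  m <- mean(y); v <- var(y)
  if (v <= 0) stop("degenerate sample: all transformed values equal")
  k <- m * (1 - m) / v - 1
  start <- list(shape1 = max(m * k, 1e-2), shape2 = max((1 - m) * k, 1e-2))
  fit <- suppressWarnings(
    MASS::fitdistr(y, "beta", start = start,
                   lower = c(1e-6, 1e-6), method = "L-BFGS-B"))
  c(a = unname(fit$estimate["shape1"]), b = unname(fit$estimate["shape2"]))
}

pgumbel <- function(q, mu, sigma) exp(-exp(-(q - mu) / sigma))

#' Fitted-distribution P value of an observed score
#'
#' For distances, the upper-tail probability
#' \eqn{P = F_{Gumbel}(1 - \log d; \mu, \sigma)} (the transform is
#' decreasing in d, so the Gumbel CDF of the transform gives the upper
#' tail of d); nonpositive distances get P = 1 by convention.  For
#' correlations, \eqn{P = F_{beta}((r + 1)/2; a, b)}.
#'
#' @param score observed score(s)
#' @param family "gumbel" or "beta"
#' @param p1,p2 fitted parameters (mu, sigma) or (a, b)
#' @return P value(s) in [0, 1]
#' @export
fittedPValue <- function(score, family = c("gumbel", "beta"), p1, p2) {
  family <- match.arg(family)
  if (family == "gumbel") {
    ifelse(score <= 0, 1, pgumbel(1 - log(score), p1, p2))
  } else {
    pbeta((pmin(1, pmax(-1, score)) + 1) / 2, p1, p2)
  }
}

#' Rank-based empirical P value within a sample
#'
#' For distances the fraction of sample scores at least as large; for
#' correlations the fraction at most as small.
#'
#' @param score score(s) to evaluate
#' @param sample reference sample of null scores
#' @param tail "upper" for distances, "lower" for correlations
#' @return empirical P value(s)
#' @export
rankPValue <- function(score, sample, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (tail == "upper")
    vapply(score, function(s) sum(sample >= s) / n, 0)
  else
    vapply(score, function(s) sum(sample <= s) / n, 0)
}

#' Kolmogorov-Smirnov check of a fitted null distribution
#'
#' Reports the KS statistic of the transformed sample against the fitted
#' distribution.  Deviations beyond the threshold yield a warning status
#' (not a failure): fitted tails are known to deviate for the largest
#' discrepancies, where rank-based P values are unreliable anyway.
#'
#' @param sample raw scores (distances or correlations)
#' @param family "gumbel" or "beta"
#' @param p1,p2 fitted parameters
#' @param warnAt warning threshold on the KS statistic
#' @return list(statistic, p.value, status)
#' @export
ksCheck <- function(sample, family = c("gumbel", "beta"), p1, p2,
                    warnAt = 0.05) {
  family <- match.arg(family)
  x <- if (family == "gumbel") {
    1 - log(sample[is.finite(sample) & sample > 0])
  } else {
    (pmin(1, pmax(-1, sample[is.finite(sample)])) + 1) / 2
  }
  kt <- suppressWarnings(if (family == "gumbel") {
    ks.test(x, pgumbel, mu = p1, sigma = p2)
  } else {
    ks.test(x, pbeta, shape1 = p1, shape2 = p2)
  })
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       status = if (unname(kt$statistic) > warnAt) "warn" else "pass")
}

measureFamily <- function(measure) {
  if (measure %in% c("dmax", "dsharp", "dmaxScan")) "gumbel" else "beta"
}

measureTail <- function(measure) {
  if (measureFamily(measure) == "gumbel") "upper" else "lower"
}

#' Assemble a background table from null score samples
#'
#' Fits the measure's distribution family to each supplied score sample
#' and records it under its grid cell.  Useful when null draws are
#' produced elsewhere (e.g. shared between measures).
#'
#' @param measure one of "dmax", "rmin", "dsharp", "dmaxScan"
#' @param engine folding engine the samples used
#' @param grid data.frame with columns length, gc, pos (pos is the
#'   mirrored relative substitution position in (0, 0.5], see
#'   [pValue()])
#' @param scores list of numeric score vectors, one per grid row
#' @return a [BackgroundTable-class]
#' @export
backgroundTableFromScores <- function(measure, engine, grid, scores) {
  measure <- match.arg(measure, c("dmax", "rmin", "dsharp", "dmaxScan"))
  stopifnot(nrow(grid) == length(scores))
  fam <- measureFamily(measure)
  fits <- lapply(scores, function(s)
    if (fam == "gumbel") fitGumbel(s) else fitBeta(s))
  cells <- data.frame(length = as.integer(grid$length), gc = grid$gc,
                      pos = grid$pos, family = fam,
                      p1 = vapply(fits, `[`, 0, 1L),
                      p2 = vapply(fits, `[`, 0, 2L),
                      n = vapply(scores, function(s) sum(is.finite(s)), 0L))
  new("BackgroundTable", measure = measure, engine = engine,
      cells = cells,
      meta = list(created = format(Sys.time(), "%Y-%m-%d")))
}

#' Build a background table of fitted null distributions
#'
#' For every grid cell (length, GC bin, mirrored relative substitution
#' position) a null sample is simulated with [nullSample()] and the
#' appropriate family fitted (Gumbel for distances, beta for
#' correlations).  Null distributions are invariant under sequence
#' reversal for i.i.d. random sequences, so positions are binned by
#' their mirrored relative position min(p, n - p + 1)/n in (0, 0.5].
#'
#' @param measure one of "dmax", "rmin", "dsharp", "dmaxScan"
#' @param lengths sequence length grid
#' @param gcBins G+C bin centers (draws sample GC within +- 0.05)
#' @param posBins mirrored relative substitution positions in (0, 0.5];
#'   default one central bin
#' @param nSamples draws per cell (minimum 200 enforced by default)
#' @param minSamples smallest admissible nSamples
#' @param config a [rnasnpConfig()]
#' @return a [BackgroundTable-class]
#' @export
buildBackgroundTable <- function(measure, lengths = 400L,
                                 gcBins = 0.5, posBins = 0.5,
                                 nSamples = 200L, minSamples = 200L,
                                 config = rnasnpConfig()) {
  measure <- match.arg(measure, c("dmax", "rmin", "dsharp", "dmaxScan"))
  if (nSamples < minSamples)
    stop("nSamples must be at least ", minSamples)
  grid <- expand.grid(length = as.integer(lengths), gc = gcBins,
                      pos = posBins, KEEP.OUT.ATTRS = FALSE)
  scores <- lapply(seq_len(nrow(grid)), function(i) {
    len <- grid$length[i]
    gc <- grid$gc[i]
    pos <- max(1L, min(len, as.integer(round(grid$pos[i] * len))))
    nullSample(nSamples, length = len,
               gcRange = c(gc - 0.05, gc + 0.05), position = pos,
               measures = measure, config = config)[[measure]]
  })
  tab <- backgroundTableFromScores(measure, config$model@mode, grid, scores)
  tab@meta$nSamples <- nSamples
  tab
}

#' Empirical P value of an observed score from a background table
#'
#' Nearest-cell lookup: the query length, G+C fraction (clamped to
#' [0.2, 0.8]) and mirrored relative substitution position
#' min(p, n - p + 1)/n select the closest fitted cell; the fitted
#' distribution converts the score to its tail probability.
#'
#' @param score observed score
#' @param table a [BackgroundTable-class]
#' @param length folded window length
#' @param gc G+C fraction of the folded window
#' @param position substitution position within the folded window
#' @return P value in [0, 1]
#' @export
pValue <- function(score, table, length, gc, position) {
  if (!is(table, "BackgroundTable"))
    stop("no background table available: generate one with ",
         "buildBackgroundTable() first")
  cl <- table@cells
  gc <- min(0.8, max(0.2, gc))
  relPos <- min(position, length - position + 1) / length
  d <- abs(cl$length - length) / max(cl$length) +
    abs(cl$gc - gc) + abs(cl$pos - relPos)
  cell <- cl[which.min(d), ]
  fittedPValue(score, cell$family, cell$p1, cell$p2)
}

#' Serialize a background table to JSON
#' @param table a [BackgroundTable-class]
#' @param path output file
#' @export
writeBackgroundTable <- function(table, path) {
  jsonlite::write_json(
    list(measure = table@measure, engine = table@engine,
         cells = table@cells, meta = table@meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a background table from JSON
#' @param path file written by [writeBackgroundTable()]
#' @return a [BackgroundTable-class]
#' @export
readBackgroundTable <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("BackgroundTable", measure = x$measure, engine = x$engine,
      cells = as.data.frame(x$cells), meta = as.list(x$meta))
}
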