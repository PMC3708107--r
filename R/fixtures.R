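#' Designed hairpin fixture
#'
#' Embeds one strong GC-rich complementary stem with a short loop in a
#' random low-GC context and labels substitutions that break a stem pair
#' (disruptive: the 5' arm base is replaced so it cannot pair with its
#' designed partner) and substitutions in the loop that leave every
#' designed pair intact (neutral).
#'
#' @param stemLen stem length in pairs (>= 4)
#' @param loopLen loop length (>= minimal hairpin size)
#' @param contextLen total random context added around the hairpin
#' @param gcContext G+C content of the context
#' @return list with seq ([RnaSequence-class]), stem5/stem3/loop
#'   coordinate ranges, and disruptive/neutral [substitutionSet()] lists
#' @export
makeHairpinFixture <- function(stemLen = 15L, loopLen = 5L,
                               contextLen = 360L, gcContext = 0.35) {
  stopifnot(stemLen >= 4, loopLen >= 3)
  # aperiodic GC-rich stem: interspersed AU pairs pin the register
  # (a pure GC stem could slide between near-isoenergetic registers)
  stem5 <- sample(c("G", "C", "A", "U"), stemLen, replace = TRUE,
                  prob = c(0.35, 0.35, 0.15, 0.15))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  stem3 <- rev(unname(comp[stem5]))
  loop <- rep("A", loopLen) # unpairable among themselves
  left <- max(0L, as.integer(round(contextLen / 2)))
  right <- contextLen - left
  ctx <- function(k) if (k == 0) character(0) else
    strsplit(residues(randomSequence(k, gcContext)), "")[[1]]
  res <- c(ctx(left), stem5, loop, stem3, ctx(right))
  s5 <- left + 1L
  s5e <- left + stemLen
  lp <- s5e + 1L
  lpe <- s5e + loopLen
  s3 <- lpe + 1L
  s3e <- lpe + stemLen
  seq <- rnaSequence(paste(res, collapse = ""), "hairpin_fixture")
  # disruptive: swap a 5'-arm base for one that cannot pair its partner
  noPair <- c(G = "C", C = "A", A = "C", U = "C")
  disruptive <- lapply(seq(2L, stemLen - 1L), function(k) {
    pos <- s5 + k - 1L
    ref <- res[pos]
    substitutionSet(pos, ref, noPair[[ref]])
  })
  # neutral: loop A -> C leaves every designed pair intact
  neutral <- lapply(seq_len(loopLen), function(k) {
    pos <- lp + k - 1L
    substitutionSet(pos, "A", "C")
  })
  list(seq = seq, stem5 = c(s5, s5e), loop = c(lp, lpe),
       stem3 = c(s3, s3e), pairs = cbind(s5:s5e, rev(s3:s3e)),
       disruptive = disruptive, neutral = neutral)
}

#' Rank correlation study of the local (dis)similarity measures
#'
#' Random sequences receive all three substitutions at a central
#' position; every variant is scored with the local measures (distance
#' and correlation on the matrix, profile and up/downstream bases) and
#' the ensemble distance, scores are ranked, and Spearman correlations
#' across measures returned — a compact way to see which measures carry
#' the same ranking information.
#'
#' @param nSeqs number of sequences
#' @param length sequence length
#' @param gcRange G+C content range to sample
#' @param position substitution position (default: center)
#' @param config a [rnasnpConfig()]
#' @return Spearman correlation matrix across measures
#' @export
measureCorrelationStudy <- function(nSeqs = 100L, length = 200L,
                                    gcRange = c(0.2, 0.8),
                                    position = NULL,
                                    config = rnasnpConfig()) {
  stopifnot(nSeqs >= 10)
  if (is.null(position)) position <- as.integer(round(length / 2))
  measures <- c("dmax_P", "dmax_pi", "dmax_xi",
                "rmin_P", "rmin_pi", "rmin_xi", "delta")
  scores <- matrix(NA_real_, nSeqs * 3L, length(measures),
                   dimnames = list(NULL, measures))
  row <- 0L
  for (s in seq_len(nSeqs)) {
    gc <- runif(1, gcRange[1], gcRange[2])
    wt <- randomSequence(length, gc)
    Pw <- foldGlobal(wt, config$model)
    ref <- substr(residues(wt), position, position)
    for (alt in setdiff(c("A", "C", "G", "U"), ref)) {
      row <- row + 1L
      mut <- applySubstitutions(wt, substitutionSet(position, ref, alt))
      Pm <- foldGlobal(mut, config$model)
      for (basis in c("P", "pi", "xi")) {
        od <- optimizeInterval(Pw, Pm, "d", basis,
                               minLen = min(config$minLen, length),
                               alpha = config$alpha, pThr = config$pThr)
        orr <- optimizeInterval(Pw, Pm, "r", basis,
                                minLen = min(config$minLen, length),
                                alpha = config$alpha, pThr = config$pThr)
        scores[row, paste0("dmax_", basis)] <- od$score
        scores[row, paste0("rmin_", basis)] <- orr$score
      }
      scores[row, "delta"] <- ensembleDistance(wt, mut, config$model)
    }
  }
  cor(scores, method = "spearman", use = "pairwise.complete.obs")
}

#' Fit-quality study: fitted versus rank-based P values
#'
#' Builds a null sample for one measure, fits its distribution family,
#' computes fitted and rank-based P values, and returns their Pearson
#' correlation -- the fit-quality statistic reported for each measure and
#' folding route.  With \code{holdout = TRUE} the fit uses one half of
#' the sample and both P value kinds are evaluated on the other half;
#' with \code{holdout = FALSE} fit and evaluation use the full sample.
#'
#' @param measure "dmax", "rmin", "dsharp" or "dmaxScan"
#' @param nSeqs null sample size (>= 100)
#' @param length,gcRange,position null sample settings
#' @param holdout evaluate on a held-out half
#' @param config a [rnasnpConfig()]
#' @return list with rho, fit parameters, and the score sample
#' @export
fitQualityStudy <- function(measure = "dmax", nSeqs = 500L,
                            length = 400L, gcRange = c(0.5, 0.6),
                            position = 200L, holdout = TRUE,
                            config = rnasnpConfig()) {
  stopifnot(nSeqs >= 100)
  smp <- nullSample(nSeqs, length = length, gcRange = gcRange,
                    position = position, measures = measure,
                    config = config)[[measure]]
  fam <- measureFamily(measure)
  tail <- measureTail(measure)
  if (holdout) {
    half <- seq_len(floor(nSeqs / 2))
    fitSmp <- smp[half]
    evalSmp <- smp[-half]
  } else {
    fitSmp <- evalSmp <- smp
  }
  par <- if (fam == "gumbel") fitGumbel(fitSmp) else fitBeta(fitSmp)
  keep <- if (fam == "gumbel") evalSmp > 0 else is.finite(evalSmp)
  evalSmp <- evalSmp[keep]
  fitted <- fittedPValue(evalSmp, fam, par[1], par[2])
  ranked <- rankPValue(evalSmp, evalSmp, tail)
  list(rho = cor(fitted, ranked), par = par, sample = smp,
       fitted = fitted, ranked = ranked)
}
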