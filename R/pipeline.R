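#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline.  The folding window
#' half-width \code{winsizeFold} (mode 1) must lie between 200 and 800 in
#' multiples of 50; \code{W}/\code{L} are the scanning window and span
#' cap; \code{hPrime}/\code{hDPrime} the screening integration window and
#' span; \code{alpha} the self-containedness factor; \code{pThr} the
#' noise filter; \code{minLen} the minimal interval length of the exact
#' search; \code{t1}/\code{t2} the two screening thresholds of mode 3.
#'
#' @param winsizeFold half-width of the mode-1 folding window (default 200)
#' @param W,L scanning fold window size and span cap (defaults 200, 120)
#' @param hPrime,hDPrime d# integration window and span (defaults 20, 120)
#' @param alpha self-containedness threshold factor (default 1)
#' @param pThr base pair probability noise filter (default 0.01)
#' @param minLen minimal interval length of the exact search (default 50)
#' @param t1,t2 mode-3 stage thresholds (defaults 0.4, 0.1)
#' @param model an [EnergyModel-class]
#' @return a list of validated parameters (class \code{rnasnpConfig})
#' @export
rnasnpConfig <- function(winsizeFold = 200L, W = 200L, L = 120L,
                         hPrime = 20L, hDPrime = 120L, alpha = 1,
                         pThr = 0.01, minLen = 50L, t1 = 0.4, t2 = 0.1,
                         model = energyModel()) {
  winsizeFold <- as.integer(winsizeFold)
  if (winsizeFold < 200L || winsizeFold > 800L || winsizeFold %% 50L != 0L)
    stop("winsizeFold must lie between 200 and 800 in multiples of 50")
  if (L > W) stop("span cap L must not exceed window size W")
  if (hPrime < 1L || hPrime > hDPrime)
    stop("hPrime must be positive and at most hDPrime")
  stopifnot(alpha >= 0, pThr >= 0, pThr < 1, minLen >= 1,
            t1 > 0, t1 <= 1, t2 > 0, t2 <= 1)
  structure(list(winsizeFold = winsizeFold, W = as.integer(W),
                 L = as.integer(L), hPrime = as.integer(hPrime),
                 hDPrime = as.integer(hDPrime), alpha = alpha,
                 pThr = pThr, minLen = as.integer(minLen),
                 t1 = t1, t2 = t2, model = model),
            class = "rnasnpConfig")
}

#' Parse variant specifications
#'
#' One variant per element/line; a variant is one or more comma-joined
#' tokens of the form RefPosAlt (e.g. \code{"G201C"}; simultaneous
#' substitutions \code{"A51G,A54C,U57C"}).  DNA alleles are accepted.
#'
#' @param text character vector of variant lines
#' @return list of [substitutionSet()] objects
#' @export
parseVariants <- function(text) {
  text <- trimws(unlist(strsplit(text, "\n", fixed = TRUE)))
  text <- text[nzchar(text)]
  lapply(text, function(line) {
    toks <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
    m <- regmatches(toks, regexec("^([ACGUTacgut])([0-9]+)([ACGUTacgut])$",
                                  toks))
    bad <- vapply(m, length, 0L) != 4L
    if (any(bad))
      stop("malformed variant token '", toks[bad][1],
           "': expected RefPosAlt, e.g. G201C")
    substitutionSet(pos = vapply(m, function(x) as.integer(x[3]), 0L),
                    ref = vapply(m, function(x) x[2], ""),
                    alt = vapply(m, function(x) x[4], ""))
  })
}

#' Format a variant, optionally in HGVS-like nomenclature
#'
#' Without annotation, tokens are plain \code{RefPosAlt}.  With
#' \code{noncoding = TRUE}, n.-numbering relative to the transcription
#' start is used.  With CDS offsets, c.-numbering is used: positions
#' before \code{cdsStart} get a \code{-} prefix counting backwards from
#' the start codon, positions after \code{cdsEnd} a \code{*} prefix.
#' HGVS-style output uses the DNA alphabet (U shown as T).
#'
#' @param snps a [substitutionSet()]
#' @param cdsStart,cdsEnd 1-based positions of the first and last CDS
#'   nucleotide (both or neither)
#' @param noncoding use n.-numbering
#' @return single formatted string
#' @export
formatVariant <- function(snps, cdsStart = NULL, cdsEnd = NULL,
                          noncoding = FALSE) {
  if (is.null(cdsStart) != is.null(cdsEnd))
    stop("cdsStart and cdsEnd must be given together")
  if (!is.null(cdsStart) && cdsEnd < cdsStart)
    stop("inconsistent CDS offsets: cdsEnd < cdsStart")
  if (is.null(cdsStart) && !noncoding)
    return(paste0(snps$ref, snps$pos, snps$alt, collapse = ","))
  dna <- function(x) chartr("U", "T", x)
  num <- if (noncoding) {
    as.character(snps$pos)
  } else {
    vapply(snps$pos, function(p) {
      if (p < cdsStart) paste0("-", cdsStart - p)
      else if (p > cdsEnd) paste0("*", p - cdsEnd)
      else as.character(p - cdsStart + 1L)
    }, "")
  }
  prefix <- if (noncoding) "n." else "c."
  toks <- paste0(num, dna(snps$ref), ">", dna(snps$alt))
  if (length(toks) == 1) paste0(prefix, toks)
  else paste0(prefix, "[", paste(toks, collapse = ";"), "]")
}

# window around the (mean) substitution position, clipped at the ends
# (one-sided rather than re-centered; the P-value lookup uses the
# actual folded length)
foldingWindow <- function(n, snps, half) {
  center <- as.integer(round(mean(snps$pos)))
  c(max(1L, center - half), min(n, center + half))
}

resultRow <- function(variant, mode, measure, win, ival, score, pval) {
  data.frame(variant = variant, mode = mode, measure = measure,
             window_start = win[1], window_end = win[2],
             interval_start = ival[1], interval_end = ival[2],
             score = score, pvalue = pval, stringsAsFactors = FALSE)
}

lookupP <- function(tables, measure, score, len, gc, pos) {
  tab <- tables[[measure]]
  if (is.null(tab)) return(NA_real_)
  if (is.na(score)) return(1)
  pValue(score, tab, len, gc, pos)
}

#' Mode 1: exact local analysis of a variant
#'
#' Extracts a window of +-\code{winsizeFold} around the substitution
#' (clipped at the sequence ends), folds wild-type and mutant windows
#' globally, optimizes the interval-restricted distance and correlation
#' on the pairing profiles, and attaches P values from the supplied
#' background tables ("dmax", "rmin").  A variant with no structural
#' change scores 0 with P value 1.
#'
#' @param seq input sequence
#' @param snps a [substitutionSet()] (one variant, possibly several
#'   simultaneous substitutions)
#' @param config a [rnasnpConfig()]
#' @param tables named list of [BackgroundTable-class] objects (names
#'   "dmax", "rmin"); missing tables yield NA P values
#' @return data.frame of results, one row per measure, intervals in
#'   full-sequence coordinates
#' @export
runMode1 <- function(seq, snps, config = rnasnpConfig(), tables = list()) {
  seq <- rnaSequence(seq)
  n <- seqLength(seq)
  win <- foldingWindow(n, snps, config$winsizeFold)
  if (any(snps$pos < win[1] | snps$pos > win[2]))
    stop("substitutions too far apart: not all fall into one folding window")
  wtWin <- rnaSequence(substr(residues(seq), win[1], win[2]), seqId(seq))
  local <- substitutionSet(snps$pos - win[1] + 1L, snps$ref, snps$alt)
  mutWin <- applySubstitutions(wtWin, local)
  Pw <- foldGlobal(wtWin, config$model)
  Pm <- foldGlobal(mutWin, config$model)
  len <- seqLength(wtWin)
  gc <- gcFraction(wtWin)
  posInWin <- as.integer(round(mean(local$pos)))
  variant <- formatVariant(snps)
  out <- list()
  for (measure in c("d", "r")) {
    key <- if (measure == "d") "dmax" else "rmin"
    opt <- optimizeInterval(Pw, Pm, measure, "pi",
                            minLen = min(config$minLen, len),
                            alpha = config$alpha, pThr = config$pThr)
    score <- opt$score
    pv <- if (is.na(score) || (measure == "d" && score <= 0)) 1
          else lookupP(tables, key, score, len, gc, posInWin)
    out[[key]] <- resultRow(variant, 1L, key, win,
                            opt$interval + win[1] - 1L, score, pv)
  }
  do.call(rbind, out)
}

#' Mode 2: scanning analysis of a variant on a long sequence
#'
#' Folds the full sequence with the scanning method (window \code{W},
#' span cap \code{L}), locates the d# peak near the substitution, and
#' re-estimates the exact profile distance anchored at the peak.  The P
#' value comes from the "dmaxScan" table.
#'
#' @inheritParams runMode1
#' @param tables named list with element "dmaxScan"
#' @return one-row data.frame
#' @export
runMode2 <- function(seq, snps, config = rnasnpConfig(), tables = list()) {
  seq <- rnaSequence(seq)
  n <- seqLength(seq)
  mut <- applySubstitutions(seq, snps)
  Sw <- foldScanning(seq, config$W, config$L, config$model)
  Sm <- foldScanning(mut, config$W, config$L, config$model)
  pos <- as.integer(round(mean(snps$pos)))
  prof <- dSharpProfile(Sw, Sm, config$hPrime, config$hDPrime, snpPos = pos)
  opt <- reoptimizeAtPeak(Sw, Sm, prof$kStar, config$hPrime,
                          config$hDPrime, config$pThr)
  score <- opt$score
  pv <- if (is.na(score) || score <= 0) 1
        else lookupP(tables, "dmaxScan", score, n, gcFraction(seq), pos)
  resultRow(formatVariant(snps), 2L, "dmaxScan", c(1L, n),
            opt$interval, score, pv)
}

#' Mode 3: exhaustive two-stage screening of all substitutions
#'
#' Stage 1 scores all 3n substitutions with the scanning d# measure
#' against the "dsharp" table; candidates with P below \code{t1} are
#' re-scored through the mode-1 path (global refold of the variant
#' window, exact d_max) and reported when the refined P is below
#' \code{t2}.  Reported intervals are merged into screening regions with
#' the count of distinct variants supporting each.
#'
#' @param seq input sequence
#' @param config a [rnasnpConfig()]
#' @param tables named list with elements "dsharp" and "dmax"; each
#'   stage is calibrated against the table built with its own folding
#'   route
#' @param stage2Config configuration for the global-refold stage
#'   (defaults to \code{config}; the stages may use different engines)
#' @param verbose report progress
#' @return list with elements \code{results} (per-variant data.frame:
#'   variant, pos, alt, dsharp, p_stage1, dmax, p_stage2, flagged,
#'   interval bounds) and \code{regions} (merged flagged intervals with
#'   variant counts)
#' @export
runMode3 <- function(seq, config = rnasnpConfig(), tables = list(),
                     stage2Config = config, verbose = FALSE) {
  seq <- rnaSequence(seq)
  n <- seqLength(seq)
  res <- strsplit(residues(seq), "")[[1]]
  Sw <- foldScanning(seq, config$W, config$L, config$model)
  gcAll <- gcFraction(seq)

  # all 3n variants
  pos <- rep(seq_len(n), each = 3L)
  alt <- unlist(lapply(res, function(r) setdiff(c("A", "C", "G", "U"), r)))
  nv <- length(pos)
  ref <- res[pos]

  # stage 1: d# of every variant against the scanning fold
  dsharpOf <- function(v, Sm) {
    max(dSharpProfile(Sw, Sm, config$hPrime, config$hDPrime,
                      snpPos = pos[v])$d)
  }
  muts <- lapply(seq_len(nv), function(v)
    applySubstitutions(seq, substitutionSet(pos[v], ref[v], alt[v])))
  ds <- if (config$model@mode == "thermo") {
    unlist(thermoFoldBatch(muts, "scanning", W = config$W, L = config$L,
                           chunkSize = 60L, consume = dsharpOf))
  } else {
    vapply(seq_len(nv), function(v) {
      if (verbose && v %% 300L == 0L)
        message("stage 1: variant ", v, "/", nv)
      dsharpOf(v, foldScanning(muts[[v]], config$W, config$L,
                               config$model))
    }, 0)
  }
  p1 <- vapply(seq_len(nv), function(v) {
    if (ds[v] <= 0) 1 else lookupP(tables, "dsharp", ds[v], n, gcAll, pos[v])
  }, 0)

  results <- data.frame(
    variant = paste0(ref, pos, alt), pos = pos, alt = alt,
    dsharp = ds, p_stage1 = p1, dmax = NA_real_, p_stage2 = NA_real_,
    flagged = FALSE, interval_start = NA_integer_,
    interval_end = NA_integer_, stringsAsFactors = FALSE)

  # stage 2: exact re-scoring of stage-1 candidates
  wtWindowCache <- new.env(parent = emptyenv())
  cand <- which(!is.na(p1) & p1 < config$t1)
  for (v in cand) {
    snps <- substitutionSet(pos[v], ref[v], alt[v])
    m1 <- mode1Cached(seq, snps, stage2Config, tables, wtWindowCache)
    d <- m1[m1$measure == "dmax", ]
    results$dmax[v] <- d$score
    results$p_stage2[v] <- d$pvalue
    results$flagged[v] <- !is.na(d$pvalue) && d$pvalue < config$t2
    results$interval_start[v] <- d$interval_start
    results$interval_end[v] <- d$interval_end
  }
  list(results = results,
       regions = screeningRegions(results[results$flagged, , drop = FALSE]))
}

# mode-1 scoring with the wild-type window fold cached by window bounds
# (mode 3 re-scores many variants that share a folding window); shares
# the code path with runMode1 via the same optimizer settings
mode1Cached <- function(seq, snps, config, tables, cache) {
  n <- seqLength(seq)
  win <- foldingWindow(n, snps, config$winsizeFold)
  key <- paste(win, collapse = ":")
  wtWin <- rnaSequence(substr(residues(seq), win[1], win[2]), seqId(seq))
  Pw <- get0(key, envir = cache)
  if (is.null(Pw)) {
    Pw <- foldGlobal(wtWin, config$model)
    assign(key, Pw, envir = cache)
  }
  local <- substitutionSet(snps$pos - win[1] + 1L, snps$ref, snps$alt)
  mutWin <- applySubstitutions(wtWin, local)
  Pm <- foldGlobal(mutWin, config$model)
  len <- seqLength(wtWin)
  opt <- optimizeInterval(Pw, Pm, "d", "pi",
                          minLen = min(config$minLen, len),
                          alpha = config$alpha, pThr = config$pThr)
  score <- opt$score
  pv <- if (is.na(score) || score <= 0) 1
        else lookupP(tables, "dmax", score, len, gcFraction(wtWin),
                     as.integer(round(mean(local$pos))))
  resultRow(formatVariant(snps), 3L, "dmax", win,
            opt$interval + win[1] - 1L, score, pv)
}

#' Merge flagged variant intervals into screening regions
#'
#' Overlapping reported intervals are merged into maximal regions; each
#' region carries the number of distinct variants whose interval
#' overlaps it.
#'
#' @param flagged data.frame with interval_start/interval_end columns
#' @return data.frame with region_start, region_end, count
#' @export
screeningRegions <- function(flagged) {
  flagged <- flagged[!is.na(flagged$interval_start), , drop = FALSE]
  if (nrow(flagged) == 0)
    return(data.frame(region_start = integer(0), region_end = integer(0),
                      count = integer(0)))
  ir <- IRanges::IRanges(start = flagged$interval_start,
                         end = flagged$interval_end)
  merged <- IRanges::reduce(ir)
  data.frame(region_start = IRanges::start(merged),
             region_end = IRanges::end(merged),
             count = IRanges::countOverlaps(merged, ir))
}

#' Write pipeline results as TSV
#' @param results data.frame from a run mode
#' @param path output file
#' @export
writeResultsTsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
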