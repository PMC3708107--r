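#' Folding energy model
#'
#' The builtin model scores a secondary structure by the sum of its base
#' pair energies, in RT units: by default e(GC) = -3, e(AU) = -2,
#' e(GU) = -1, with hairpin loops of at least 3 unpaired bases.  It is the
#' simplest model with a nontrivial Boltzmann ensemble, chosen so that all
#' derived quantities can be verified against exhaustive structure
#' enumeration.  \code{mode = "thermo"} selects the ViennaRNA
#' nearest-neighbour engine (RNAfold / RNAplfold must be on the PATH).
#'
#' @param mode "builtin" or "thermo"
#' @param pairEnergies named numeric, energies of GC, AU and GU pairs in
#'   RT units (used by the builtin mode only)
#' @param minHairpin minimal number of unpaired bases in a hairpin loop
#' @param rt thermal energy unit
#' @return an [EnergyModel-class]
#' @export
energyModel <- function(mode = c("builtin", "thermo"),
                        pairEnergies = c(GC = -3, AU = -2, GU = -1),
                        minHairpin = 3L, rt = 1) {
  mode <- match.arg(mode)
  new("EnergyModel", mode = mode, pairEnergies = pairEnergies,
      minHairpin = as.integer(minHairpin), rt = rt)
}

# integer codes A=1, C=2, G=3, U=4
encodeResidues <- function(seq) {
  match(strsplit(residues(rnaSequence(seq)), "")[[1]],
        c("A", "C", "G", "U"))
}

#' Pairwise Boltzmann weight matrix under the builtin model
#'
#' Entry (i, j) is exp(-e(pair)/RT) when residues i and j can form a
#' canonical (GC, AU, GU) pair, and 0 otherwise.  Span and hairpin
#' constraints are enforced by the folding recursions, not here.
#'
#' @param seq sequence
#' @param model an [EnergyModel-class]
#' @return numeric matrix of pair weights
#' @keywords internal
pairWeightMatrix <- function(seq, model = energyModel()) {
  pe <- model@pairEnergies
  w <- matrix(0, 4, 4)
  w[3, 2] <- w[2, 3] <- exp(-pe[["GC"]] / model@rt)
  w[1, 4] <- w[4, 1] <- exp(-pe[["AU"]] / model@rt)
  w[3, 4] <- w[4, 3] <- exp(-pe[["GU"]] / model@rt)
  codes <- encodeResidues(seq)
  w[codes, codes, drop = FALSE]
}

#' Global partition-function fold
#'
#' Computes the base pair probability matrix of the full-length Boltzmann
#' ensemble: with the builtin model via exact McCaskill inside/outside
#' recursions, with the thermodynamic model via \command{RNAfold -p}.
#'
#' @param seq sequence ([RnaSequence-class] or character)
#' @param model an [EnergyModel-class]
#' @return a [BasePairMatrix-class] with backend tag "global"
#' @examples
#' foldGlobal("GGGGAAAACCCC")
#' @export
foldGlobal <- function(seq, model = energyModel()) {
  seq <- rnaSequence(seq)
  if (model@mode == "thermo") {
    P <- thermoFoldBatch(list(seq), type = "global")[[1]]
    return(new("BasePairMatrix", probs = P, backend = "global",
               engine = "thermo", spanCap = NA_integer_))
  }
  pw <- pairWeightMatrix(seq, model)
  P <- .cppFoldGlobal(pw, model@minHairpin, gcFraction(seq))
  new("BasePairMatrix", probs = P, backend = "global",
      engine = "builtin", spanCap = NA_integer_)
}

#' Scanning (window-averaged) partition-function fold
#'
#' Pair probabilities are averaged over all sequence windows of length
#' \code{W} that contain the pair, and pairs with span greater than
#' \code{L} are excluded, as in scanning folds of long sequences.  At the
#' sequence ends the window set is truncated (only fully contained
#' windows are used); for sequences shorter than \code{W} the single
#' window is the whole sequence, so the result equals a span-capped
#' global fold.
#'
#' @param seq sequence
#' @param W window size (default 200)
#' @param L maximal base pair span (default 120); must satisfy L <= W
#' @param model an [EnergyModel-class]
#' @return a [BasePairMatrix-class] with backend tag "scanning"
#' @export
foldScanning <- function(seq, W = 200L, L = 120L, model = energyModel()) {
  seq <- rnaSequence(seq)
  W <- as.integer(W); L <- as.integer(L)
  if (L > W) stop("maximal pair span L must not exceed window size W")
  if (model@mode == "thermo") {
    P <- thermoFoldBatch(list(seq), type = "scanning", W = W, L = L)[[1]]
    return(new("BasePairMatrix", probs = P, backend = "scanning",
               engine = "thermo", spanCap = L))
  }
  pw <- pairWeightMatrix(seq, model)
  P <- .cppFoldScanning(pw, model@minHairpin, W, L, gcFraction(seq))
  new("BasePairMatrix", probs = P, backend = "scanning",
      engine = "builtin", spanCap = L)
}

# ---- thermodynamic engine (ViennaRNA command line programs) ----------

viennaBinary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path))
    stop("thermodynamic backend requires '", name,
         "' (ViennaRNA) on the PATH; install ViennaRNA or use the ",
         "builtin model")
  path
}

# Fold a batch of sequences with one engine invocation per chunk
# (multi-FASTA input amortizes process startup when many mutants are
# scored).  Returns a list of symmetric probability matrices, or, when
# `consume` is given, applies it to each matrix in order and returns
# its results (keeps memory flat for large screens).
thermoFoldBatch <- function(seqs, type = c("global", "scanning"),
                            W = 200L, L = 120L, cutoff = 1e-6,
                            chunkSize = 100L, consume = NULL) {
  type <- match.arg(type)
  bin <- viennaBinary(if (type == "global") "RNAfold" else "RNAplfold")
  out <- vector("list", length(seqs))
  for (chunk in split(seq_along(seqs),
                      ceiling(seq_along(seqs) / chunkSize))) {
    dir <- tempfile("vrna")
    dir.create(dir)
    ids <- sprintf("q%06d", seq_along(chunk))
    fa <- file.path(dir, "batch.fa")
    writeLines(unlist(lapply(seq_along(chunk), function(i)
      c(paste0(">", ids[i]), residues(rnaSequence(seqs[[chunk[i]]]))))), fa)
    owd <- setwd(dir)
    args <- if (type == "global") {
      c("-p", "--noPS", sprintf("--bppmThreshold=%g", cutoff))
    } else {
      c("-W", W, "-L", L, sprintf("--cutoff=%g", cutoff))
    }
    status <- system2(bin, args, stdout = FALSE, stderr = FALSE,
                      stdin = fa)
    setwd(owd)
    if (status != 0) {
      unlink(dir, recursive = TRUE)
      stop(basename(bin), " failed with status ", status)
    }
    for (i in seq_along(chunk)) {
      n <- seqLength(rnaSequence(seqs[[chunk[i]]]))
      P <- readDotplot(file.path(dir, paste0(ids[i], "_dp.ps")), n)
      out[[chunk[i]]] <- if (is.null(consume)) P else consume(chunk[i], P)
    }
    unlink(dir, recursive = TRUE)
  }
  out
}

# parse 'i j sqrt(p) ubox' records from a ViennaRNA dot plot file
readDotplot <- function(path, n) {
  if (!file.exists(path)) stop("missing dot plot file ", path)
  lines <- readLines(path, warn = FALSE)
  ub <- lines[endsWith(lines, " ubox") & !startsWith(lines, "%")]
  P <- matrix(0, n, n)
  if (length(ub)) {
    f <- scan(text = ub, what = list(integer(), integer(), numeric(),
                                     character()), quiet = TRUE)
    p <- f[[3]]^2
    P[cbind(f[[1]], f[[2]])] <- p
    P[cbind(f[[2]], f[[1]])] <- p
  }
  P
}
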