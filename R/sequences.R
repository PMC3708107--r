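#' Construct an RNA sequence
#'
#' Accepts RNA or DNA input; \code{T} is silently mapped to \code{U} (a
#' message is emitted once per session) and lower case is raised.
#'
#' @param residues character string (or \pkg{Biostrings} XString) of
#'   residues over A, C, G, U/T
#' @param id sequence identifier
#' @return an [RnaSequence-class] object
#' @examples
#' rnaSequence("GGGAAACCC", id = "hairpin")
#' @export
rnaSequence <- function(residues, id = "seq") {
  if (is(residues, "RnaSequence")) return(residues)
  if (is(residues, "XString") || is(residues, "XStringSet"))
    residues <- as.character(residues)[1]
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(residues)
  if (grepl("T", res, fixed = TRUE)) {
    noteDnaInput()
    res <- chartr("T", "U", res)
  }
  new("RnaSequence", id = as.character(id), residues = res)
}

.rnasnipEnv <- new.env(parent = emptyenv())

noteDnaInput <- function() {
  if (is.null(.rnasnipEnv$dnaNoted)) {
    message("DNA input detected: T mapped to U")
    .rnasnipEnv$dnaNoted <- TRUE
  }
  invisible(NULL)
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record files are allowed; DNA is converted to RNA.
#'
#' @param path FASTA file
#' @param id optional record identifier to select (first word of header);
#'   default: all records
#' @return a list of [RnaSequence-class] objects
#' @export
readRnaFasta <- function(path, id = NULL) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (!is.null(id)) {
    keep <- ids %in% id
    if (!any(keep)) stop("no FASTA record with id '", id, "'")
    set <- set[keep]
    ids <- ids[keep]
  }
  mapply(function(s, i) rnaSequence(s, i), as.character(set), ids,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Define a set of simultaneous substitutions
#'
#' @param pos 1-based positions
#' @param ref reference alleles
#' @param alt substituted alleles (each must differ from its ref)
#' @return a data.frame with columns pos, ref, alt (class
#'   \code{SubstitutionSet})
#' @examples
#' substitutionSet(5, "A", "G")
#' @export
substitutionSet <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- chartr("T", "U", toupper(as.character(ref)))
  alt <- chartr("T", "U", toupper(as.character(alt)))
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  if (length(pos) == 0) stop("empty substitution set")
  if (anyDuplicated(pos)) stop("substitution positions must be unique")
  if (any(pos < 1L)) stop("substitution positions must be positive")
  bad <- !ref %in% c("A", "C", "G", "U") | !alt %in% c("A", "C", "G", "U")
  if (any(bad)) stop("alleles must be A, C, G or U/T")
  same <- ref == alt
  if (any(same))
    stop("substitution at position ", pos[same][1],
         " has identical reference and alternative allele")
  out <- data.frame(pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SubstitutionSet", "data.frame")
  out
}

#' Apply substitutions to a sequence
#'
#' Each reference allele is checked against the sequence; a mismatch is an
#' error naming the position and both alleles.
#'
#' @param seq an [RnaSequence-class] (or character coercible to one)
#' @param snps a [substitutionSet()]
#' @return the mutant [RnaSequence-class]
#' @examples
#' applySubstitutions(rnaSequence("GGGAAACCC"), substitutionSet(5, "A", "G"))
#' @export
applySubstitutions <- function(seq, snps) {
  seq <- rnaSequence(seq)
  res <- strsplit(residues(seq), "")[[1]]
  if (any(snps$pos > length(res)))
    stop("substitution position ", max(snps$pos),
         " beyond sequence length ", length(res))
  found <- res[snps$pos]
  bad <- found != snps$ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "reference allele mismatch at position %d: expected %s, found %s",
      snps$pos[i], snps$ref[i], found[i]))
  }
  res[snps$pos] <- snps$alt
  new("RnaSequence", id = paste0(seqId(seq), "_mut"),
      residues = paste(res, collapse = ""))
}

#' Generate a random RNA sequence with a target G+C content
#'
#' Residues are drawn i.i.d. with Pr(G) = Pr(C) = gc/2 and
#' Pr(A) = Pr(U) = (1 - gc)/2, using the R random number generator (set a
#' seed for reproducibility).
#'
#' @param length sequence length
#' @param gc target G+C fraction in (0, 1)
#' @param id identifier
#' @return an [RnaSequence-class]
#' @export
randomSequence <- function(length, gc = 0.5, id = "random") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  res <- sample(c("G", "C", "A", "U"), length, replace = TRUE,
                prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  new("RnaSequence", id = id, residues = paste(res, collapse = ""))
}

#' G+C fraction of a sequence
#' @param seq an [RnaSequence-class] or character
#' @return fraction of G and C residues
#' @export
gcFraction <- function(seq) {
  seq <- rnaSequence(seq)
  res <- strsplit(residues(seq), "")[[1]]
  mean(res %in% c("G", "C"))
}
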