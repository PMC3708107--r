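#' @rdname BasePairMatrix-class
#' @param x object
#' @export
setGeneric("bppMatrix", function(x) standardGeneric("bppMatrix"))

#' @rdname BasePairMatrix-class
#' @export
setGeneric("backendTag", function(x) standardGeneric("backendTag"))

#' @rdname BasePairMatrix-class
#' @export
setGeneric("foldEngine", function(x) standardGeneric("foldEngine"))

#' @rdname BasePairMatrix-class
#' @export
setGeneric("spanCap", function(x) standardGeneric("spanCap"))

#' @rdname RnaSequence-class
#' @param x object
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname RnaSequence-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname RnaSequence-class
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @describeIn BasePairMatrix-class probability matrix accessor
setMethod("bppMatrix", "BasePairMatrix", function(x) x@probs)

#' @describeIn BasePairMatrix-class backend tag ("global"/"scanning")
setMethod("backendTag", "BasePairMatrix", function(x) x@backend)

#' @describeIn BasePairMatrix-class folding engine ("builtin"/"thermo")
setMethod("foldEngine", "BasePairMatrix", function(x) x@engine)

#' @describeIn BasePairMatrix-class maximal pair span (NA if none)
setMethod("spanCap", "BasePairMatrix", function(x) x@spanCap)

#' @describeIn BasePairMatrix-class sequence length
setMethod("seqLength", "BasePairMatrix", function(x) nrow(x@probs))

#' @describeIn RnaSequence-class sequence length
setMethod("seqLength", "RnaSequence", function(x) nchar(x@residues))

#' @describeIn RnaSequence-class residue string accessor
setMethod("residues", "RnaSequence", function(x) x@residues)

#' @describeIn RnaSequence-class identifier accessor
setMethod("seqId", "RnaSequence", function(x) x@id)

setMethod("show", "RnaSequence", function(object) {
  n <- seqLength(object)
  head <- substr(object@residues, 1, 40)
  cat(sprintf("RnaSequence '%s': %d nt\n  %s%s\n", object@id, n, head,
              if (n > 40) "..." else ""))
})

setMethod("show", "BasePairMatrix", function(object) {
  cat(sprintf(
    "BasePairMatrix: %d nt, %s fold (%s engine), span cap %s\n  %d pairs with probability > 0.01\n",
    seqLength(object), object@backend, object@engine,
    ifelse(is.na(object@spanCap), "none", object@spanCap),
    sum(object@probs[upper.tri(object@probs)] > 0.01)))
})

setMethod("show", "EnergyModel", function(object) {
  pe <- object@pairEnergies
  cat(sprintf(
    "EnergyModel (%s): e(GC)=%g, e(AU)=%g, e(GU)=%g RT; min hairpin %d\n",
    object@mode, pe[["GC"]], pe[["AU"]], pe[["GU"]], object@minHairpin))
})

setMethod("show", "BackgroundTable", function(object) {
  cat(sprintf(
    "BackgroundTable for %s (%s engine): %d cell(s)\n",
    object@measure, object@engine, nrow(object@cells)))
  cat(sprintf("  lengths: %s | GC bins: %s | position bins: %s\n",
              paste(unique(object@cells$length), collapse = ","),
              paste(unique(object@cells$gc), collapse = ","),
              paste(unique(object@cells$pos), collapse = ",")))
})
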