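#' RnaSequence: a validated RNA sequence
#'
#' Residues are normalized to the \code{A,C,G,U} alphabet (input \code{T}
#' is mapped to \code{U}, lower case is raised).
#'
#' @slot id single character identifier
#' @slot residues single character string over \code{A,C,G,U}
#' @export
setClass("RnaSequence",
  representation(id = "character", residues = "character"),
  validity = function(object) {
    if (length(object@id) != 1L) return("id must be a single string")
    if (length(object@residues) != 1L || !nzchar(object@residues))
      return("residues must be a nonempty string")
    if (grepl("[^ACGU]", object@residues))
      return("residues contain characters outside {A,C,G,U}")
    TRUE
  }
)

#' BasePairMatrix: equilibrium base pair probabilities
#'
#' Symmetric matrix of probabilities that positions i and j are paired in
#' the Boltzmann ensemble; the diagonal is zero.  \code{backend} records
#' whether the probabilities come from a global or a window-averaged
#' scanning fold, \code{engine} which folding engine produced them, and
#' \code{spanCap} the maximal pair span (NA when unrestricted).
#'
#' @slot probs numeric matrix of pair probabilities
#' @slot backend "global" or "scanning"
#' @slot engine "builtin" or "thermo"
#' @slot spanCap integer maximal base pair span, NA if none
#' @export
setClass("BasePairMatrix",
  representation(probs = "matrix", backend = "character",
                 engine = "character", spanCap = "integer"),
  validity = function(object) {
    P <- object@probs
    if (nrow(P) != ncol(P)) return("probability matrix must be square")
    if (any(P < -1e-12) || any(P > 1 + 1e-12))
      return("pair probabilities must lie in [0, 1]")
    if (max(abs(P - t(P))) > 1e-9)
      return("probability matrix must be symmetric")
    # probability conservation holds per ensemble, i.e. for global
    # folds; window-averaged (scanning) probabilities mix ensembles
    # with pair-dependent weights and may exceed it slightly
    if (object@backend == "global" && any(rowSums(P) > 1 + 1e-9))
      return("per-position pairing probabilities must not exceed 1")
    if (!object@backend %in% c("global", "scanning"))
      return("backend must be 'global' or 'scanning'")
    if (!object@engine %in% c("builtin", "thermo"))
      return("engine must be 'builtin' or 'thermo'")
    if (!is.na(object@spanCap)) {
      n <- nrow(P)
      if (n > 1) {
        span <- abs(row(P) - col(P))
        if (any(P[span > object@spanCap] > 0))
          return("entries beyond the span cap must be zero")
      }
    }
    TRUE
  }
)

#' EnergyModel: folding energy model specification
#'
#' The builtin model assigns each admissible base pair a single energy (in
#' RT units) and scores a structure by the sum of its pair energies; it
#' admits an exact enumeration oracle.  The thermodynamic mode delegates
#' folding to the ViennaRNA programs (nearest-neighbour parameters).
#'
#' @slot mode "builtin" or "thermo"
#' @slot pairEnergies named numeric: energies of GC, AU, GU pairs (RT units)
#' @slot minHairpin integer, minimal hairpin loop size
#' @slot rt numeric, thermal energy unit for the builtin model
#' @export
setClass("EnergyModel",
  representation(mode = "character", pairEnergies = "numeric",
                 minHairpin = "integer", rt = "numeric"),
  validity = function(object) {
    if (!object@mode %in% c("builtin", "thermo"))
      return("mode must be 'builtin' or 'thermo'")
    pe <- object@pairEnergies
    if (!all(c("GC", "AU", "GU") %in% names(pe)))
      return("pairEnergies must name GC, AU and GU")
    if (any(pe >= 0)) return("pair energies must be negative")
    if (object@minHairpin < 3L) return("minimal hairpin size must be >= 3")
    if (object@rt <= 0) return("rt must be positive")
    TRUE
  }
)

#' BackgroundTable: fitted null score distributions
#'
#' One fitted distribution per grid cell (sequence length bin, GC bin,
#' relative substitution position bin) for one score and folding route.
#' Distances use a Gumbel fit of \eqn{1 - \log d}; correlations use a beta
#' fit of \eqn{(r + 1)/2}.
#'
#' @slot measure score identity ("dmax", "rmin", "dsharp", "dmaxScan")
#' @slot engine folding engine the null sample used
#' @slot cells data.frame: length, gc, pos, family, p1, p2, n
#' @slot meta list of generation metadata (seed, sample sizes, ...)
#' @export
setClass("BackgroundTable",
  representation(measure = "character", engine = "character",
                 cells = "data.frame", meta = "list"),
  validity = function(object) {
    cl <- object@cells
    need <- c("length", "gc", "pos", "family", "p1", "p2", "n")
    if (!all(need %in% names(cl)))
      return(paste("cells must have columns:", paste(need, collapse = ", ")))
    if (nrow(cl) == 0) return("table has no fitted cells")
    if (any(!cl$family %in% c("gumbel", "beta")))
      return("family must be 'gumbel' or 'beta'")
    if (any(cl$family == "gumbel" & cl$p2 <= 0))
      return("Gumbel scale must be positive")
    if (any(cl$family == "beta" & (cl$p1 <= 0 | cl$p2 <= 0)))
      return("beta shapes must be positive")
    TRUE
  }
)
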