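#' Accessors for rnavae classes
#'
#' @param x an rnavae object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname accessors
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))
#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname accessors
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))

#' @rdname accessors
#' @export
setMethod("residues", "RnaSequence", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("seqId", "RnaSequence", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("seqLength", "RnaSequence", function(x) nchar(x@residues))
#' @rdname accessors
#' @export
setMethod("seqLength", "SecondaryStructure", function(x) as.integer(x@L))
#' @rdname accessors
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("nPairs", "SecondaryStructure", function(x) nrow(x@pairs))
#' @rdname accessors
#' @export
setMethod("probValues", "PairProbabilityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("channel", "PairProbabilityMatrix", function(x) x@channel)

setMethod("show", "RnaSequence", function(object) {
  L <- nchar(object@residues)
  preview <- if (L > 60L) paste0(substr(object@residues, 1L, 57L), "...")
             else object@residues
  cat(sprintf("RnaSequence '%s' (%d nt)\n  %s\n", object@id, L, preview))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: L=%d, %d base pair(s)%s\n",
      object@L, nrow(object@pairs),
      if (hasCrossing(object)) ", pseudoknotted" else ""))
  if (object@L <= 120L) cat(" ", writeDotBracket(object), "\n")
})

setMethod("show", "PairProbabilityMatrix", function(object) {
  cat(sprintf("PairProbabilityMatrix (%s): L=%d, max off-diagonal %.3f\n",
      object@channel, nrow(object@values), max(object@values)))
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: K=%d structures, L=%d (seed %s)\n",
      length(object@structures), object@structures[[1L]]@L,
      ifelse(is.na(object@seed), "unset", object@seed)))
})

setMethod("show", "TvaeModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "TvaeModel: d_model=%d, %d+%d layers, %d heads, d_latent=%d\n",
    "  input width D=%d, S_max=%d, growth_rate=%g, %s parameters, step %d\n"),
    cfg$d_model, cfg$n_encoder_layers, cfg$n_decoder_layers, cfg$n_heads,
    cfg$d_latent, cfg$d_input, cfg$S_max, cfg$growth_rate,
    format(parameterCount(object), big.mark = ","), object@step))
})
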