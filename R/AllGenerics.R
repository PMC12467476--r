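#' Extract the null-model summary from an analyzer result
#' @param x an analyzer result object.
#' @return a [NullSummary-class] or `NULL` when no null was computed.
#' @export
setGeneric("nullSummary", function(x) standardGeneric("nullSummary"))

#' Significance call of a result ("high", "low" or "none")
#' @param x an analyzer result or [NullSummary-class].
#' @return a character scalar, `NA` when no null was computed.
#' @export
setGeneric("significanceCall", function(x) standardGeneric("significanceCall"))

#' z-score of the observed statistic against its null
#' @param x an analyzer result or [NullSummary-class].
#' @return numeric scalar (`NA` when undefined or absent).
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' Primary bias residue of each region
#' @param x a [BiasRegions-class] object.
#' @return character vector of primary (first-signature) residues.
#' @export
setGeneric("primaryBias", function(x) standardGeneric("primaryBias"))

#' Curly-brace bias signature strings
#' @param x a [BiasRegions-class] object.
#' @return character vector like `"{Q,N}"`.
#' @export
setGeneric("biasSignature", function(x) standardGeneric("biasSignature"))
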