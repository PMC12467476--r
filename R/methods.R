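## Accessors, subsetting, coercion and show methods.

#' @describeIn nullSummary for NullSummary itself (identity).
#' @export
setMethod("nullSummary", "NullSummary", function(x) x)

#' @describeIn significanceCall call stored in a NullSummary.
#' @export
setMethod("significanceCall", "NullSummary", function(x) x@call)

#' @describeIn zScore z stored in a NullSummary.
#' @export
setMethod("zScore", "NullSummary", function(x) x@z)

.nullOrNA <- function(null, what) {
  if (is.null(null)) {
    if (what == "call") NA_character_ else NA_real_
  } else slot(null, if (what == "call") "call" else "z")
}

for (cls in c("BlockinessResult", "HomopeptideProfile",
              "RepetitivenessResult", "BandAssessment")) {
  setMethod("nullSummary", cls, function(x) x@null)
  setMethod("significanceCall", cls, function(x) .nullOrNA(x@null, "call"))
  setMethod("zScore", cls, function(x) .nullOrNA(x@null, "z"))
}

#' @describeIn primaryBias first signature residue per region.
#' @export
setMethod("primaryBias", "BiasRegions", function(x)
  vapply(x@signature, `[`, character(1L), 1L))

#' @describeIn biasSignature curly-brace-delimited signatures.
#' @export
setMethod("biasSignature", "BiasRegions", function(x)
  vapply(x@signature, function(s) paste0("{", paste(s, collapse = ","), "}"),
         character(1L)))

#' @export
setMethod("length", "BiasRegions", function(x) length(x@start))

#' @export
setMethod("[", "BiasRegions", function(x, i, j, ..., drop = TRUE) {
  new("BiasRegions", seqId = x@seqId[i], start = x@start[i], end = x@end[i],
      signature = x@signature[i], pValue = x@pValue[i], k = x@k[i],
      w = x@w[i], paramsId = x@paramsId[i])
})

#' Coerce BiasRegions to a data.frame
#' @param x a [BiasRegions-class] object.
#' @param ... ignored.
#' @return data.frame with columns seq_id, start, end, signature, k, w,
#'   p_value, params_id.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.BiasRegions <- function(x, ...) {
  data.frame(seq_id = x@seqId, start = x@start, end = x@end,
             signature = biasSignature(x), k = x@k, w = x@w,
             p_value = x@pValue, params_id = x@paramsId,
             stringsAsFactors = FALSE)
}
setMethod("as.data.frame", "BiasRegions",
          function(x, ...) as.data.frame.BiasRegions(x, ...))

setMethod("show", "BiasRegions", function(object) {
  cat("BiasRegions with", length(object), "region(s)\n")
  if (length(object))
    print(head(as.data.frame(object), 10L))
  if (length(object) > 10L) cat("...", length(object) - 10L, "more\n")
})

setMethod("show", "NullSummary", function(object) {
  cat(sprintf(
    "NullSummary: observed %.6g vs null %.6g +/- %.6g (n = %d)\n",
    object@observed, object@nullMean, object@nullSd, object@nSamples))
  cat(sprintf("  z = %s, p_high = %.4g, p_low = %.4g, call = %s%s\n",
              ifelse(object@defined, sprintf("%.3f", object@z), "undefined"),
              object@pHigh, object@pLow, object@call,
              if (!object@defined) " [degenerate null]" else ""))
})

setMethod("show", "BlockinessResult", function(object) {
  if (is.na(object@B)) {
    cat("BlockinessResult [", object@seqId, "]: B undefined",
        "(single residue type)\n")
    return(invisible(NULL))
  }
  cat(sprintf("BlockinessResult [%s]: B = %.4f\n", object@seqId, object@B))
  if (length(object@contributing))
    cat("  contributing residues:",
        paste(object@contributing, collapse = ", "), "\n")
  if (!is.null(object@null)) show(object@null)
})

setMethod("show", "HomopeptideProfile", function(object) {
  cat(sprintf("HomopeptideProfile [%s]: %d run(s), hpep = %d\n",
              object@seqId, object@runCount, object@hpep))
  if (object@runCount)
    cat(" ", paste(sprintf("%s@%d-%d", object@runs$residue,
                           object@runs$start, object@runs$end),
                   collapse = "; "), "\n")
  if (!is.null(object@null)) show(object@null)
})

setMethod("show", "IntervalCensus", function(object) {
  cat(sprintf(
    "IntervalCensus: %d interval type(s), total %d (deltaMax %d, minOcc %d)\n",
    object@N, object@total, object@deltaMax, object@minOcc))
})

setMethod("show", "RepetitivenessResult", function(object) {
  cat(sprintf(
    "RepetitivenessResult [%s]: IE = %.4f bits (same %.4f, diff %.4f)\n",
    object@seqId, object@IE, object@IESame, object@IEDiff))
  if (!is.null(object@null)) show(object@null)
})

setMethod("show", "BandAssessment", function(object) {
  cat(sprintf(
    "BandAssessment [%s] group {%s}: %d bands on span %d-%d, DPB = %.3f\n",
    object@seqId, object@groupKey, length(object@bands),
    object@spanStart, object@spanEnd, object@dpb))
  if (length(object@excisedGaps))
    cat("  excised gap index(es):",
        paste(object@excisedGaps, collapse = ","), "\n")
  if (!is.na(object@role)) cat("  role:", object@role, "\n")
  if (!is.null(object@null)) show(object@null)
})
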