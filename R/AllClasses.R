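## S4 containers shared across the analyzers.

#' NullSummary: an observed statistic against a permutation/random null
#'
#' Produced by [summarizeNull()]. Holds the observed value, the null moments,
#' the z-score (NA when the null is degenerate, i.e. sd = 0), add-one
#' empirical p-values for both directions, and the significance call.
#'
#' @slot observed observed value of the statistic.
#' @slot nullMean,nullSd mean and standard deviation of the null sample.
#' @slot z `(observed - nullMean)/nullSd`; `NA` when `nullSd == 0`.
#' @slot pHigh,pLow one-sided empirical p-values with the add-one
#'   (pseudo-count) convention, `(1 + #\{null >= obs\})/(n + 1)` and the
#'   `<=` analogue; both in (0, 1].
#' @slot nSamples number of null samples.
#' @slot alpha significance level used for the call.
#' @slot call `"high"`, `"low"` or `"none"`.
#' @slot defined `FALSE` when the null sd is zero (z undefined).
#' @exportClass NullSummary
setClass("NullSummary", representation(
  observed = "numeric", nullMean = "numeric", nullSd = "numeric",
  z = "numeric", pHigh = "numeric", pLow = "numeric",
  nSamples = "integer", alpha = "numeric", call = "character",
  defined = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@call) != 1L || !object@call %in% c("high", "low", "none"))
      msg <- c(msg, "call must be one of 'high', 'low', 'none'")
    if (object@pHigh <= 0 || object@pHigh > 1 ||
        object@pLow <= 0 || object@pLow > 1)
      msg <- c(msg, "empirical p-values must lie in (0, 1]")
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (length(msg)) msg else TRUE
  })

setClassUnion("NullSummaryOrNULL", members = c("NullSummary", "NULL"))

#' BiasRegions: compositionally biased regions from the scanner
#'
#' A parallel-slot container (one element per region) for scanner hits:
#' 1-based inclusive coordinates, ordered bias signature (primary residue
#' first), the binomial p-value, the signature-residue count `k` and window
#' width `w`.
#'
#' @slot seqId parent sequence identifier per region.
#' @slot start,end 1-based inclusive coordinates.
#' @slot signature list of character vectors; residues in order of bias
#'   precedence, primary first.
#' @slot pValue binomial tail p-value of the region.
#' @slot k total count of signature residues inside the region.
#' @slot w region width (`end - start + 1`).
#' @slot paramsId label of the generating parameter triad (may be `""`).
#' @exportClass BiasRegions
setClass("BiasRegions", representation(
  seqId = "character", start = "integer", end = "integer",
  signature = "list", pValue = "numeric", k = "integer", w = "integer",
  paramsId = "character"),
  validity = function(object) {
    n <- length(object@start)
    lens <- c(length(object@seqId), length(object@end),
              length(object@signature), length(object@pValue),
              length(object@k), length(object@w), length(object@paramsId))
    if (any(lens != n)) return("slot lengths differ")
    if (n == 0L) return(TRUE)
    msg <- character()
    if (any(object@start < 1L)) msg <- c(msg, "start must be >= 1")
    if (any(object@end < object@start)) msg <- c(msg, "end must be >= start")
    if (any(object@w != object@end - object@start + 1L))
      msg <- c(msg, "w must equal end - start + 1")
    if (any(object@pValue < 0 | object@pValue > 1))
      msg <- c(msg, "pValue must lie in [0, 1]")
    if (any(vapply(object@signature, length, 1L) < 1L))
      msg <- c(msg, "signatures must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' BlockinessResult: residue segregation score B with optional null
#'
#' @slot seqId sequence identifier.
#' @slot B overall blockiness score; `NA` when undefined (single residue
#'   type).
#' @slot perResidue named numeric of residue-specific B values (types with
#'   at least 2 occurrences).
#' @slot contributing residues with `perResidue > B`.
#' @slot null a [NullSummary-class] over scrambled sequences, or `NULL`.
#' @exportClass BlockinessResult
setClass("BlockinessResult", representation(
  seqId = "character", B = "numeric", perResidue = "numeric",
  contributing = "character", null = "NullSummaryOrNULL"))

#' HomopeptideProfile: maximal same-residue runs and hpep content
#'
#' @slot seqId sequence identifier.
#' @slot runs data.frame with columns residue, start, end, length; maximal
#'   runs of length >= the configured minimum (default 3). X runs are never
#'   reported.
#' @slot hpep total residues inside runs.
#' @slot byResidue named integer of per-type run-residue totals.
#' @slot runCount number of runs.
#' @slot null a [NullSummary-class] over scrambled sequences, or `NULL`.
#' @exportClass HomopeptideProfile
setClass("HomopeptideProfile", representation(
  seqId = "character", runs = "data.frame", hpep = "integer",
  byResidue = "integer", runCount = "integer", null = "NullSummaryOrNULL"),
  validity = function(object) {
    if (object@hpep != sum(object@runs$length))
      return("hpep must equal the sum of run lengths")
    TRUE
  })

#' IntervalCensus: counts of residue interval types (x, z, delta)
#'
#' An interval type is an ordered residue pair (x, z) separated by `delta`
#' residues strictly in between (adjacent residues have delta = 0). All
#' ordered position pairs with delta <= `deltaMax` contribute, restricted to
#' residue types whose sequence-wide count is >= `minOcc`; X never
#' participates.
#'
#' @slot counts data.frame with columns x, z, delta, count.
#' @slot total sum of counts.
#' @slot N number of distinct interval types present.
#' @slot deltaMax,minOcc the census parameters.
#' @exportClass IntervalCensus
setClass("IntervalCensus", representation(
  counts = "data.frame", total = "integer", N = "integer",
  deltaMax = "integer", minOcc = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@total != sum(object@counts$count))
      msg <- c(msg, "total must equal sum of counts")
    if (object@N != nrow(object@counts))
      msg <- c(msg, "N must equal the number of census rows")
    if (length(msg)) msg else TRUE
  })

#' RepetitivenessResult: interval entropy with scrambled-null assessment
#'
#' @slot seqId sequence identifier.
#' @slot IE interval entropy in bits; 0 (flagged) for an empty census.
#' @slot IESame,IEDiff entropies of the same-residue (x == z) and
#'   different-residue (x != z) sub-censuses, renormalized within each
#'   subset; `NA` when the subset is empty.
#' @slot census the observed [IntervalCensus-class].
#' @slot null a [NullSummary-class] on IE, or `NULL`. Slots `nullSame` and
#'   `nullDiff` carry the same assessment of the subset entropies.
#' @slot nullSame,nullDiff NullSummary on IESame / IEDiff, or `NULL`.
#' @slot topByFreq,topByP data.frames (x, z, delta, count, p) of up to ten
#'   significant interval types sorted by decreasing frequency and by
#'   ascending empirical p, respectively.
#' @exportClass RepetitivenessResult
setClass("RepetitivenessResult", representation(
  seqId = "character", IE = "numeric", IESame = "numeric", IEDiff = "numeric",
  census = "IntervalCensus", null = "NullSummaryOrNULL",
  nullSame = "NullSummaryOrNULL", nullDiff = "NullSummaryOrNULL",
  topByFreq = "data.frame", topByP = "data.frame"))

#' BandAssessment: a same-bias band set scored for evenness
#'
#' @slot seqId sequence identifier.
#' @slot groupKey primary residue, or "primary,secondary" for multi-residue
#'   band groups.
#' @slot bands the member [BiasRegions-class], sorted by start, pairwise
#'   non-overlapping, at least 2 of them.
#' @slot spanStart,spanEnd first band's start and last band's end.
#' @slot dpb distance to perfect banding: the sum over the 2k sorted band
#'   endpoints of absolute deviations from the evenly spaced endpoint grid
#'   over the span.
#' @slot null [NullSummary-class] of dpb against random endpoint sets on the
#'   same span; call "low" means significantly even, "high" significantly
#'   uneven.
#' @slot excisedGaps indices (into the pre-excision gap list) of inter-band
#'   gaps removed as MAD outliers before assessment.
#' @slot role one of "max_bands", "min_z", "max_z" once assigned by
#'   [reportBandSets()], else `NA`.
#' @exportClass BandAssessment
setClass("BandAssessment", representation(
  seqId = "character", groupKey = "character", bands = "BiasRegions",
  spanStart = "integer", spanEnd = "integer", dpb = "numeric",
  null = "NullSummaryOrNULL", excisedGaps = "integer", role = "character"))
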