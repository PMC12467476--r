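## Repetitiveness as residue interval entropy (IE): Shannon entropy (bits)
## over interval types (x, z, delta), delta = residues strictly between an
## x occurrence and a later z occurrence, capped at deltaMax.

#' Census of residue interval types
#'
#' Counts every ordered position pair (i, j), i < j, with
#' `delta = j - i - 1 <= deltaMax`, as an occurrence of the interval type
#' (residue at i, residue at j, delta). Only residue types whose
#' sequence-wide count is at least `minOcc` (default 3) participate, and X
#' never does; X positions still contribute to delta when they lie between
#' a pair. Note the strictly-between convention: adjacent residues have
#' delta = 0.
#'
#' @param x a single sequence (L >= 2).
#' @param deltaMax maximum delta (default 100).
#' @param minOcc minimum sequence-wide residue-type count (default 3).
#' @return an [IntervalCensus-class] (possibly empty).
#' @examples
#' intervalCensus("ABABAB", minOcc = 3)  # 9 types, total 15
#' @export
intervalCensus <- function(x, deltaMax = 100, minOcc = 3) {
  s <- .asSequence(x)
  codes <- .residueCodes(s$residues)
  if (length(codes) < 2L) stop("interval census needs L >= 2")
  cen <- cpp_census(codes - 1L, as.integer(deltaMax), as.integer(minOcc))
  counts <- data.frame(x = AA20[cen$x + 1L], z = AA20[cen$z + 1L],
                       delta = cen$delta, count = cen$count,
                       stringsAsFactors = FALSE)
  new("IntervalCensus", counts = counts,
      total = as.integer(sum(counts$count)), N = nrow(counts),
      deltaMax = as.integer(deltaMax), minOcc = as.integer(minOcc))
}

.entropyBits <- function(counts) {
  if (!length(counts) || sum(counts) == 0L) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Interval entropy of a census
#'
#' `IE = sum over the N interval types of -p_i log2 p_i` with
#' `p_i = count_i / total`. The same-residue (x == z) and
#' different-residue (x != z) components are entropies of the sub-censuses
#' with probabilities renormalized within each subset (`NA` for an empty
#' subset). An empty census gives IE = 0 with attribute `empty = TRUE`.
#'
#' @param census an [IntervalCensus-class].
#' @return named numeric `c(IE =, IESame =, IEDiff =)`; attribute `empty`.
#' @export
intervalEntropy <- function(census) {
  stopifnot(is(census, "IntervalCensus"))
  cc <- census@counts
  if (nrow(cc) == 0L) {
    out <- c(IE = 0, IESame = NA_real_, IEDiff = NA_real_)
    attr(out, "empty") <- TRUE
    return(out)
  }
  same <- cc$x == cc$z
  out <- c(IE = .entropyBits(cc$count),
           IESame = .entropyBits(cc$count[same]),
           IEDiff = .entropyBits(cc$count[!same]))
  attr(out, "empty") <- FALSE
  out
}

#' Assess repetitiveness against scrambled nulls
#'
#' Computes IE for the observed sequence and for `nSamples`
#' composition-preserving scrambles. Repetitive sequences concentrate their
#' interval mass on few types, giving a lower IE than their scrambles: a
#' negative z and call "low" mean significantly repetitive, "high"
#' significantly un-repetitive. The same- and different-residue subset
#' entropies are assessed against the same scrambles (slots `nullSame`,
#' `nullDiff`), which shows which component carries a repetitive signal.
#' Each observed interval type also receives a one-sided (enrichment)
#' add-one empirical p-value from its count across the scrambles;
#' significant types are reported twice, sorted by decreasing observed
#' count (`topByFreq`) and by ascending p (`topByP`), both truncated to
#' ten.
#'
#' @param x a single sequence (L >= 2).
#' @param nSamples number of scrambles.
#' @param alpha significance level.
#' @param deltaMax,minOcc census parameters (see [intervalCensus()]).
#' @return a [RepetitivenessResult-class]. An empty census yields a flagged
#'   result with no null and call left unset.
#' @export
assessRepetitiveness <- function(x, nSamples = 1000, alpha = 0.05,
                                 deltaMax = 100, minOcc = 3) {
  s <- .asSequence(x)
  codes <- .residueCodes(s$residues)
  if (length(codes) < 2L) stop("interval census needs L >= 2")
  census <- intervalCensus(s$residues, deltaMax, minOcc)
  ie <- intervalEntropy(census)
  emptyTop <- data.frame(x = character(), z = character(),
                         delta = integer(), count = integer(),
                         p = numeric(), stringsAsFactors = FALSE)
  if (census@N == 0L)
    return(new("RepetitivenessResult", seqId = s$id, IE = 0,
               IESame = NA_real_, IEDiff = NA_real_, census = census,
               null = NULL, nullSame = NULL, nullDiff = NULL,
               topByFreq = emptyTop, topByP = emptyTop))
  sim <- cpp_assess_ie(codes - 1L, as.integer(nSamples),
                       as.integer(deltaMax), as.integer(minOcc))
  null <- summarizeNull(ie[["IE"]], sim$ie_null[, 1L], alpha)
  nullSame <- if (!is.na(ie[["IESame"]]) && !anyNA(sim$ie_null[, 2L]))
    summarizeNull(ie[["IESame"]], sim$ie_null[, 2L], alpha) else NULL
  nullDiff <- if (!is.na(ie[["IEDiff"]]) && !anyNA(sim$ie_null[, 3L]))
    summarizeNull(ie[["IEDiff"]], sim$ie_null[, 3L], alpha) else NULL
  typeP <- (1 + sim$exceed) / (nSamples + 1)
  cc <- census@counts
  cc$p <- typeP
  sig <- cc[cc$p < alpha, , drop = FALSE]
  topByFreq <- head(sig[order(-sig$count, sig$p, sig$x, sig$z, sig$delta),
                        , drop = FALSE], 10L)
  topByP <- head(sig[order(sig$p, -sig$count, sig$x, sig$z, sig$delta),
                     , drop = FALSE], 10L)
  rownames(topByFreq) <- rownames(topByP) <- NULL
  new("RepetitivenessResult", seqId = s$id, IE = ie[["IE"]],
      IESame = ie[["IESame"]], IEDiff = ie[["IEDiff"]], census = census,
      null = null, nullSame = nullSame, nullDiff = nullDiff,
      topByFreq = topByFreq, topByP = topByP)
}

#' Tabulate repetitiveness results
#' @param results list of [RepetitivenessResult-class] objects.
#' @return data.frame: seq_id, IE, IE_same, IE_diff, z, p_low, p_high,
#'   call, top_by_freq, top_by_p (`x-delta-z:count:p` lists).
#' @export
repetitivenessTable <- function(results) {
  fmt <- function(df) paste(sprintf("%s-%d-%s:%d:%.4g", df$x, df$delta,
                                    df$z, df$count, df$p), collapse = ";")
  do.call(rbind, lapply(results, function(r) data.frame(
    seq_id = r@seqId, IE = r@IE, IE_same = r@IESame, IE_diff = r@IEDiff,
    z = if (is.null(r@null)) NA_real_ else r@null@z,
    p_low = if (is.null(r@null)) NA_real_ else r@null@pLow,
    p_high = if (is.null(r@null)) NA_real_ else r@null@pHigh,
    call = if (is.null(r@null)) NA_character_ else r@null@call,
    top_by_freq = fmt(r@topByFreq), top_by_p = fmt(r@topByP),
    stringsAsFactors = FALSE)))
}
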