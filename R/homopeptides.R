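## Homopeptides: maximal same-residue runs (>= 3 by default) and total
## homopeptide content (hpep) against scrambled nulls.

#' Enumerate homopeptides (maximal same-residue runs)
#'
#' A homopeptide is a run of identical residues of at least `minLen`
#' (default 3). Runs are maximal (not extendable in either direction); X
#' runs are never reported. `hpep` is the total number of residues inside
#' runs — the homopeptide content mass — with per-residue totals and the
#' run count reported alongside.
#'
#' @param x a single sequence.
#' @param minLen minimum run length (default 3).
#' @return a [HomopeptideProfile-class] (without null assessment).
#' @examples
#' findHomopeptides("AAABBCCCC")  # runs A@1-3 and C@6-9, hpep = 7
#' @export
findHomopeptides <- function(x, minLen = 3) {
  s <- .asSequence(x)
  ch <- strsplit(s$residues, "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= minLen & r$values != "X"
  runs <- data.frame(residue = r$values[keep], start = starts[keep],
                     end = ends[keep], length = r$lengths[keep],
                     stringsAsFactors = FALSE)
  byRes <- vapply(split(runs$length, factor(runs$residue, levels = AA20)),
                  sum, 1L)
  new("HomopeptideProfile", seqId = s$id, runs = runs,
      hpep = as.integer(sum(runs$length)), byResidue = as.integer(byRes),
      runCount = nrow(runs), null = NULL)
}

#' Assess homopeptide content against scrambled nulls
#'
#' Tests the total hpep of the observed sequence against `nSamples`
#' composition-preserving scrambles; "high" means significant enrichment,
#' "low" significant lack. Degenerate nulls (e.g. a homopolymer, where
#' every scramble is identical) yield an undefined z and call "none".
#'
#' @param x a single sequence (L >= 3).
#' @param nSamples number of scrambles.
#' @param alpha significance level.
#' @param minLen minimum run length.
#' @return a [HomopeptideProfile-class] with the null slot filled.
#' @export
assessHomopeptides <- function(x, nSamples = 1000, alpha = 0.05,
                               minLen = 3) {
  prof <- findHomopeptides(x, minLen)
  codes <- .residueCodes(.asSequence(x)$residues)
  if (length(codes) < 3L) stop("hpep assessment needs L >= 3")
  nullH <- cpp_hpep_null(codes - 1L, as.integer(nSamples),
                         as.integer(minLen))
  prof@null <- summarizeNull(prof@hpep, as.numeric(nullH), alpha)
  prof
}

#' Tabulate homopeptide profiles
#' @param results list of [HomopeptideProfile-class] objects.
#' @return data.frame: seq_id, hpep, run_count, z, p_high, p_low, call,
#'   runs (residue:start-end;...), then per-residue totals.
#' @export
homopeptideTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    per <- setNames(as.list(r@byResidue), paste0("hpep_", AA20))
    cbind(data.frame(
      seq_id = r@seqId, hpep = r@hpep, run_count = r@runCount,
      z = if (is.null(r@null)) NA_real_ else r@null@z,
      p_high = if (is.null(r@null)) NA_real_ else r@null@pHigh,
      p_low = if (is.null(r@null)) NA_real_ else r@null@pLow,
      call = if (is.null(r@null)) NA_character_ else r@null@call,
      runs = paste(sprintf("%s:%d-%d", r@runs$residue, r@runs$start,
                           r@runs$end), collapse = ";"),
      stringsAsFactors = FALSE), as.data.frame(per))
  }))
}
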