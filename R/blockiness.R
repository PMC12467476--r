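## Residue segregation ("blockiness"): B = sum of nearest-different-type
## distances over sum of nearest-same-type distances.

.blockinessFromCore <- function(seqId, core) {
  if (!core$defined)
    return(new("BlockinessResult", seqId = seqId, B = NA_real_,
               perResidue = setNames(numeric(), character()),
               contributing = character(), null = NULL))
  B <- core$num / core$den
  ok <- core$den_a > 0 & core$counts >= 2L
  perResidue <- setNames((core$num_a / core$den_a)[ok], AA20[ok])
  new("BlockinessResult", seqId = seqId, B = B, perResidue = perResidue,
      contributing = names(perResidue)[perResidue > B], null = NULL)
}

#' Blockiness score B of a sequence
#'
#' For every position i, `dmin_diff(i)` is the distance (in residues,
#' adjacent = 1) to the nearest residue of a different type and
#' `dmin_same(i)` the distance to the nearest residue of the same type;
#' `B = sum(dmin_diff) / sum(dmin_same)`. Positions whose residue type
#' occurs only once lack a same-type partner and are dropped from both
#' sums, keeping the ratio balanced. X positions are excluded from both
#' sums but count as a (different) 21st type for their neighbours'
#' `dmin_diff`. Residue-specific scores `B_a` restrict both sums to
#' positions holding residue a (types with >= 2 occurrences); residues with
#' `B_a > B` are reported as contributing to the segregation tendency. For
#' a homopolymer no different-type residue exists and B is flagged
#' undefined (`NA`), not an error.
#'
#' @param x a single sequence.
#' @return a [BlockinessResult-class] (without null assessment).
#' @examples
#' blockinessScore("ABABABAB")@B   # 0.5: perfect alternation
#' blockinessScore("AAAABBBB")@B   # 2.5: full segregation
#' @export
blockinessScore <- function(x) {
  s <- .asSequence(x)
  codes <- .residueCodes(s$residues)
  if (length(codes) < 2L) stop("blockiness needs L >= 2")
  .blockinessFromCore(s$id, cpp_blockiness(codes - 1L))
}

#' Assess blockiness against scrambled-sequence nulls
#'
#' Computes B for the observed sequence and for `nSamples`
#' composition-preserving scrambles; a "high" call means significantly
#' blocky, "low" significantly un-blocky. Contributing residues are
#' computed on the observed sequence only. Uses the current RNG state.
#'
#' @param x a single sequence.
#' @param nSamples number of scrambles (default 1000).
#' @param alpha significance level.
#' @return a [BlockinessResult-class] with the null slot filled.
#' @export
assessBlockiness <- function(x, nSamples = 1000, alpha = 0.05) {
  res <- blockinessScore(x)
  if (is.na(res@B)) return(res)
  codes <- .residueCodes(.asSequence(x)$residues)
  nullB <- cpp_blockiness_null(codes - 1L, as.integer(nSamples))
  res@null <- summarizeNull(res@B, nullB, alpha)
  res
}

#' Tabulate blockiness results
#' @param results list of [BlockinessResult-class] objects.
#' @return data.frame: seq_id, B, z, p_high, p_low, call, contributing,
#'   then one B_a column per standard residue.
#' @export
blockinessTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    ba <- setNames(rep(NA_real_, 20L), paste0("B_", AA20))
    ba[paste0("B_", names(r@perResidue))] <- r@perResidue
    cbind(data.frame(
      seq_id = r@seqId, B = r@B,
      z = if (is.null(r@null)) NA_real_ else r@null@z,
      p_high = if (is.null(r@null)) NA_real_ else r@null@pHigh,
      p_low = if (is.null(r@null)) NA_real_ else r@null@pLow,
      call = if (is.null(r@null)) NA_character_ else r@null@call,
      contributing = paste(r@contributing, collapse = ","),
      stringsAsFactors = FALSE), as.data.frame(as.list(ba)))
  }))
}
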