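## Compositional banding: detection of same-bias band sets with
## small-window scans, distance to perfect banding (DPB), MAD-based gap
## excision, and random-endpoint nulls.

#' Default small-window parameter grid for band detection
#'
#' Twelve triads in the small-window regime: m in \{3, 5\}, M in \{10, 20\},
#' t in \{1e-2, 1e-3, 1e-4\}.
#'
#' @return data.frame with columns m, M, t (12 rows).
#' @export
defaultBandGrid <- function() {
  g <- expand.grid(m = c(3L, 5L), M = c(10L, 20L),
                   t = c(1e-2, 1e-3, 1e-4))
  data.frame(m = g$m, M = g$M, t = g$t)
}

.bandGroupKey <- function(regions) {
  vapply(regions@signature, function(s)
    if (length(s) == 1L) s[1L] else paste(s[1:2], collapse = ","),
    character(1L))
}

#' Collect candidate band sets per bias group
#'
#' Pools small-window scanner hits, segregates them by primary residue (or
#' by the (primary, secondary) pair for multiple-residue regions), and
#' within each group greedily selects a maximal pairwise non-overlapping
#' band list in ascending p-value order. Groups with fewer than 2 bands are
#' dropped.
#'
#' @param x sequences.
#' @param grid small-window scanner grid (default [defaultBandGrid()]).
#' @param background background mode or table (see
#'   [backgroundFrequencies()]).
#' @return named list of [BiasRegions-class] band lists (sorted by start);
#'   names are `"<seqId>|<groupKey>"`.
#' @export
collectBands <- function(x, grid = defaultBandGrid(),
                         background = "dataset") {
  if (any(grid$m < 3L) || any(grid$M > 20L))
    stop("band detection requires a small-window grid (m >= 3, M <= 20)")
  pooled <- scanBiasGrid(x, grid, background = background,
                         smallWindow = TRUE)
  pooled <- .dedupeRegions(pooled)
  if (length(pooled) == 0L) return(list())
  key <- paste(pooled@seqId, .bandGroupKey(pooled), sep = "|")
  out <- list()
  for (kk in unique(key)) {
    grp <- pooled[key == kk]
    ord <- .selectionOrder(grp)
    sel <- integer()
    for (i in ord) {
      if (!any(grp@start[i] <= grp@end[sel] & grp@end[i] >= grp@start[sel]))
        sel <- c(sel, i)
    }
    if (length(sel) >= 2L)
      out[[kk]] <- grp[sel[order(grp@start[sel])]]
  }
  out
}

.dpbEndpoints <- function(endp) {
  n <- length(endp)
  perfect <- endp[1L] + (0:(n - 1L)) * (endp[n] - endp[1L]) / (n - 1L)
  sum(abs(endp - perfect))
}

#' Distance to perfect banding (DPB)
#'
#' The 2k band endpoints are compared to 2k perfectly even endpoints
#' redistributed over the same overall span (first band start to last band
#' end): `perfect_j = s + (j - 1)(e - s)/(2k - 1)`. DPB is the sum of
#' absolute deviations of each original endpoint from its perfect
#' counterpart; it is 0 iff the endpoints already sit on the even grid, and
#' is invariant under translation of the whole band set.
#'
#' @param bands a [BiasRegions-class] of k >= 2 sorted, pairwise
#'   non-overlapping bands on one sequence.
#' @return the DPB value (numeric >= 0).
#' @export
perfectBandingDistance <- function(bands) {
  k <- length(bands)
  if (k < 2L) stop("a band set needs at least 2 bands")
  if (is.unsorted(bands@start) || any(bands@start[-1L] <= bands@end[-k]))
    stop("bands must be sorted by start and pairwise non-overlapping")
  .dpbEndpoints(as.numeric(rbind(bands@start, bands@end)))
}

## Modified z-scores of inter-band gaps (0.6745 consistency constant).
## MAD = 0 (all gaps equal except outliers) maps deviations to +/-Inf so
## that a single wildly long gap among otherwise equal gaps is still caught.
.gapModifiedZ <- function(gaps) {
  med <- stats::median(gaps)
  madv <- stats::median(abs(gaps - med))
  if (madv > 0) return(0.6745 * (gaps - med) / madv)
  ifelse(gaps > med, Inf, ifelse(gaps < med, -Inf, 0))
}

.assessOneBandSet <- function(bands, seqId, groupKey, excised,
                              nSamples, alpha) {
  k <- length(bands)
  s <- bands@start[1L]; e <- bands@end[k]
  if (e <= s) stop("degenerate band span (e <= s)")
  endp <- as.numeric(rbind(bands@start, bands@end))
  observed <- .dpbEndpoints(endp)
  n2 <- 2L * k
  perfect <- s + (0:(n2 - 1L)) * (e - s) / (n2 - 1L)
  inner <- matrix(runif(nSamples * (n2 - 2L), min = s, max = e),
                  nrow = nSamples)
  inner <- matrix(inner[order(row(inner), inner)], nrow = nSamples,
                  byrow = TRUE)
  E <- cbind(s, inner, e)
  nullDpb <- rowSums(abs(sweep(E, 2L, perfect)))
  new("BandAssessment", seqId = seqId, groupKey = groupKey, bands = bands,
      spanStart = as.integer(s), spanEnd = as.integer(e), dpb = observed,
      null = summarizeNull(observed, nullDpb, alpha),
      excisedGaps = as.integer(excised), role = NA_character_)
}

#' Assess a band set against a random-endpoint null
#'
#' For sets of at least 4 bands, inter-band gaps
#' (`start[i+1] - end[i]`) are first screened with the modified z-score
#' (MAD) outlier rule: gaps scoring >= 3.5 are excised, splitting the set;
#' every resulting sub-set with >= 2 bands is then assessed, the largest
#' first. Each assessment compares the observed DPB to DPB values of
#' `nSamples` random endpoint sets on the same span: the two outermost
#' endpoints stay pinned at the span ends and the 2k - 2 interior endpoints
#' are drawn uniformly, so the span itself is held fixed. A "low" call
#' means significantly even banding; "high" means significantly uneven.
#'
#' @param bands a [BiasRegions-class] of k >= 2 sorted non-overlapping
#'   bands.
#' @param nSamples number of random endpoint sets (default 1000).
#' @param alpha significance level.
#' @param groupKey optional group label; derived from the first band's
#'   signature when omitted.
#' @return list of [BandAssessment-class], largest sub-set first.
#' @export
assessBandSet <- function(bands, nSamples = 1000, alpha = 0.05,
                          groupKey = NULL) {
  k <- length(bands)
  if (k < 2L) stop("a band set needs at least 2 bands")
  seqId <- bands@seqId[1L]
  if (is.null(groupKey)) groupKey <- .bandGroupKey(bands)[1L]
  pieces <- list(list(idx = seq_len(k), excised = integer()))
  if (k >= 4L) {
    gaps <- bands@start[-1L] - bands@end[-k]
    mz <- .gapModifiedZ(gaps)
    out <- which(mz >= 3.5)
    if (length(out)) {
      grpIdx <- cumsum(c(1L, as.integer(seq_len(k - 1L) %in% out)))
      pieces <- lapply(split(seq_len(k), grpIdx), function(ii)
        list(idx = ii, excised = out))
      pieces <- Filter(function(p) length(p$idx) >= 2L, pieces)
      if (!length(pieces)) return(list())
    }
  }
  res <- lapply(pieces, function(p)
    .assessOneBandSet(bands[p$idx], seqId, groupKey, p$excised,
                      nSamples, alpha))
  res[order(-vapply(res, function(a) length(a@bands), 1L))]
}

#' Select the reported band sets per primary bias
#'
#' For each primary bias residue, three (possibly coinciding) assessed sets
#' are reported: (a) the set with the highest band number, ties broken by
#' the smallest empirical p-value; (b) the set with the lowest z-score;
#' (c) the set with the highest z-score.
#'
#' @param assessments list of [BandAssessment-class] objects (one
#'   sequence).
#' @return list of role-assigned [BandAssessment-class] objects (up to 3
#'   per primary bias, in role order max_bands, min_z, max_z).
#' @export
reportBandSets <- function(assessments) {
  if (!length(assessments)) return(list())
  prim <- vapply(assessments, function(a)
    strsplit(a@groupKey, ",", fixed = TRUE)[[1L]][1L], character(1L))
  out <- list()
  for (p in unique(prim)) {
    cand <- assessments[prim == p]
    ks <- vapply(cand, function(a) length(a@bands), 1L)
    pmin_ <- vapply(cand, function(a)
      min(a@null@pLow, a@null@pHigh), 1)
    zs <- vapply(cand, function(a)
      if (is.null(a@null)) NA_real_ else a@null@z, 1)
    pick <- function(a, role) { a@role <- role; a }
    out <- c(out, list(
      pick(cand[[order(-ks, pmin_)[1L]]], "max_bands"),
      pick(cand[[order(zs)[1L]]], "min_z"),
      pick(cand[[order(-zs)[1L]]], "max_z")))
  }
  out
}

#' End-to-end banding assessment of sequences
#'
#' Runs [collectBands()], [assessBandSet()] on every group, and
#' [reportBandSets()] per sequence.
#'
#' @param x sequences.
#' @param grid small-window grid (default [defaultBandGrid()]).
#' @param background background mode or table.
#' @param nSamples,alpha null-model settings.
#' @return named list (by sequence id) of lists of role-assigned
#'   [BandAssessment-class] objects (empty where no band set was found).
#' @export
assessBanding <- function(x, grid = defaultBandGrid(),
                          background = "dataset", nSamples = 1000,
                          alpha = 0.05) {
  seqs <- .asSequenceSet(x)
  groups <- collectBands(seqs, grid, background)
  out <- setNames(rep(list(list()), length(seqs)), names(seqs))
  if (!length(groups)) return(out)
  bySeq <- split(groups, vapply(strsplit(names(groups), "|", fixed = TRUE),
                                `[`, character(1L), 1L))
  for (id in names(bySeq)) {
    ass <- unlist(lapply(bySeq[[id]], assessBandSet, nSamples = nSamples,
                         alpha = alpha), recursive = FALSE,
                  use.names = FALSE)
    out[[id]] <- reportBandSets(ass)
  }
  out
}

#' Tabulate band assessments
#'
#' @param assessments list of [BandAssessment-class] objects (e.g. one
#'   element of [assessBanding()] output, or all of them flattened).
#' @return data.frame with one row per assessment: seq_id, group_key, role,
#'   bands (semicolon-joined start-end pairs), k, dpb, z, p_low, p_high,
#'   call, excised_gaps.
#' @export
bandReportTable <- function(assessments) {
  if (!length(assessments))
    return(data.frame(seq_id = character(), group_key = character(),
                      role = character(), bands = character(),
                      k = integer(), dpb = numeric(), z = numeric(),
                      p_low = numeric(), p_high = numeric(),
                      call = character(), excised_gaps = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(assessments, function(a) {
    data.frame(
      seq_id = a@seqId, group_key = a@groupKey, role = a@role,
      bands = paste(sprintf("%d-%d", a@bands@start, a@bands@end),
                    collapse = ";"),
      k = length(a@bands), dpb = a@dpb,
      z = if (is.null(a@null)) NA_real_ else a@null@z,
      p_low = if (is.null(a@null)) NA_real_ else a@null@pLow,
      p_high = if (is.null(a@null)) NA_real_ else a@null@pHigh,
      call = if (is.null(a@null)) NA_character_ else a@null@call,
      excised_gaps = paste(a@excisedGaps, collapse = ","),
      stringsAsFactors = FALSE)
  }))
}
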