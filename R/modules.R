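## Reduction of pooled scanner output to optimized compositional modules
## (CModules) and boundary sets by p-value-ordered greedy de-selection.

#' Default twelve-triad parameter grid for module derivation
#'
#' Twelve (m, M, t) scanner triads covering a range of target region lengths
#' and stringencies: m in \{15, 25, 50\}, M = 500, t in
#' \{1e-3, 1e-5, 1e-7, 1e-9\}. The grid is a configurable default; any
#' twelve-row data.frame with columns m, M, t can be supplied instead.
#'
#' @return data.frame with columns m, M, t (12 rows).
#' @export
defaultModuleGrid <- function() {
  g <- expand.grid(m = c(15L, 25L, 50L), t = c(1e-3, 1e-5, 1e-7, 1e-9))
  data.frame(m = g$m, M = 500L, t = g$t)
}

## order regions for greedy selection: ascending p, ties by longer width,
## then smaller start (deterministic, independent of input order)
.selectionOrder <- function(regions) {
  order(regions@pValue, -regions@w, regions@start, regions@seqId,
        primaryBias(regions))
}

## drop byte-identical duplicates arising from different parameter triads
.dedupeRegions <- function(regions) {
  key <- paste(regions@seqId, regions@start, regions@end,
               biasSignature(regions), regions@pValue, sep = "|")
  regions[!duplicated(key)]
}

.greedyDeselect <- function(pooled, deselects) {
  if (length(pooled) == 0L) return(pooled)
  pooled <- .dedupeRegions(pooled)
  ord <- .selectionOrder(pooled)
  seqId <- pooled@seqId[ord]; start <- pooled@start[ord]
  end <- pooled@end[ord]; prim <- primaryBias(pooled)[ord]
  alive <- rep(TRUE, length(ord))
  accepted <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    accepted[i] <- TRUE
    later <- which(alive & !accepted)
    later <- later[later > i & seqId[later] == seqId[i] &
                     prim[later] == prim[i]]
    if (length(later))
      alive[later[deselects(start[i], end[i], start[later], end[later])]] <-
        FALSE
  }
  res <- pooled[ord[accepted]]
  res[order(res@seqId, res@start, res@pValue)]
}

#' Derive optimized compositional modules (CModules)
#'
#' Pooled scanner hits are sorted on increasing p-value (ties broken by
#' longer region, then smaller start) and greedily accepted; each
#' acceptance de-selects every remaining region with the same primary
#' residue on the same sequence whose overlap with the accepted region
#' covers at least `overlapFraction` of that remaining region's own length.
#' De-selection proceeds until no regions remain to assess; survivors are
#' the modules.
#'
#' @param pooled a [BiasRegions-class] pool, typically from
#'   [scanBiasGrid()] over [defaultModuleGrid()].
#' @param overlapFraction minimum fraction of the candidate's extent that
#'   must be covered for de-selection (default 0.5).
#' @return a [BiasRegions-class] of modules, sorted by sequence and start.
#' @export
deriveModules <- function(pooled, overlapFraction = 0.5) {
  stopifnot(is(pooled, "BiasRegions"))
  .greedyDeselect(pooled, function(s, e, ss, ee) {
    inter <- pmin(e, ee) - pmax(s, ss) + 1L
    inter / (ee - ss + 1) >= overlapFraction
  })
}

#' Derive boundary sets
#'
#' Same greedy loop as [deriveModules()], but a candidate is de-selected
#' only when both of its endpoints lie within `margin` residues of the
#' accepted region's endpoints (and the primary residue matches). Because
#' this criterion removes a subset of what the overlap criterion removes,
#' the boundary-set list is at least as large as the module list on the
#' same pool.
#'
#' @param pooled a [BiasRegions-class] pool.
#' @param margin endpoint margin in residues (default 5).
#' @return a [BiasRegions-class] of retained boundary sets.
#' @export
deriveBoundarySets <- function(pooled, margin = 5) {
  stopifnot(is(pooled, "BiasRegions"))
  .greedyDeselect(pooled, function(s, e, ss, ee)
    abs(ss - s) <= margin & abs(ee - e) <= margin)
}
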