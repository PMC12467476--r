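## Compositional-bias scanner: binomial probability minimization over
## sliding windows, with hill-climbing boundary refinement, same-primary
## merging, and greedy multiple-residue signature extension.

#' Upper binomial tail probability P(X >= k)
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param p success probability, in (0, 1).
#' @return P(X >= k) for X ~ Binomial(n, p).
#' @examples
#' binomialTail(3, 3, 0.25)   # 0.25^3
#' @export
binomialTail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly in (0, 1)")
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Background amino-acid composition
#'
#' The binomial model needs a per-residue background frequency `p_a > 0`.
#' `"dataset"` (the default) estimates frequencies from the supplied
#' sequence set with add-one smoothing over the 20 standard residues, so
#' every frequency is strictly positive and no external table is needed;
#' `"uniform"` uses 1/20 everywhere; a named numeric vector supplies a user
#' table (renormalized, all entries must be positive).
#'
#' @param seqs sequence set (named character vector or `AAStringSet`).
#' @param mode `"dataset"`, `"uniform"`, or a named numeric vector over the
#'   20 standard residues.
#' @return named numeric vector of length 20 summing to 1.
#' @export
backgroundFrequencies <- function(seqs, mode = "dataset") {
  if (is.numeric(mode)) {
    if (is.null(names(mode)) || !all(AA20 %in% names(mode)))
      stop("a user background table must name all 20 standard residues")
    p <- mode[AA20]
    if (any(p <= 0)) stop("background frequencies must all be positive")
    return(p / sum(p))
  }
  mode <- match.arg(mode, c("dataset", "uniform"))
  if (mode == "uniform")
    return(setNames(rep(1 / 20, 20L), AA20))
  seqs <- .asSequenceSet(seqs)
  ch <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  counts <- table(factor(ch, levels = AA20))  # drops X
  p <- (as.numeric(counts) + 1) / (sum(counts) + 20)
  setNames(p, AA20)
}

.checkScanParams <- function(m, M, t, smallWindow) {
  if (m < 3L) stop("minimum window size m must be >= 3")
  if (M < m) stop("maximum window size M must be >= m")
  if (!smallWindow && m < 15L)
    stop("m < 15 requires small-window mode (smallWindow = TRUE)")
  if (smallWindow && M > 20L)
    stop("small-window mode requires M <= 20")
  if (t <= 0 || t >= 1) stop("threshold t must lie strictly in (0, 1)")
  invisible(TRUE)
}

## prefix-count matrix: (L+1) x 20, CS[i+1, a] = count of residue a in 1..i
.prefixCounts <- function(codes, L) {
  CS <- matrix(0L, nrow = L + 1L, ncol = 20L, dimnames = list(NULL, AA20))
  for (a in seq_len(20L)) {
    ind <- codes == a
    if (any(ind)) CS[, a] <- c(0L, cumsum(ind))
  }
  CS
}

## lean scalar binomial tail for the hot loops (inputs pre-validated)
.btail <- function(k, n, p) {
  if (k <= 0L) 1 else stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

## Hill-climb one region boundary pair to a local p minimum: repeatedly try
## moving each boundary by +/-1 and take the move that most lowers p.
.hillClimb <- function(cs, s, e, pS, m, Wmax, L) {
  p <- .btail(cs[e + 1L] - cs[s], e - s + 1L, pS)
  dmv <- c(-1L, 1L, 0L, 0L)
  emv <- c(0L, 0L, -1L, 1L)
  repeat {
    bs <- s; be <- e; bp <- p
    for (mv in 1:4) {
      s2 <- s + dmv[mv]
      e2 <- e + emv[mv]
      w2 <- e2 - s2 + 1L
      if (s2 < 1L || e2 > L || w2 < m || w2 > Wmax) next
      p2 <- .btail(cs[e2 + 1L] - cs[s2], w2, pS)
      if (p2 < bp) { bp <- p2; bs <- s2; be <- e2 }
    }
    if (bp >= p) break
    s <- bs; e <- be; p <- bp
  }
  list(s = s, e = e, p = p)
}

## Re-minimize a region for a given signature S (composite success class
## p_S = sum of member frequencies, k = total member count).
.minimizeRegion <- function(CS, bg, S, s, e, m, Wmax, L) {
  pS <- sum(bg[S])
  if (pS >= 1) return(NULL)
  cs <- if (length(S) == 1L) CS[, S] else rowSums(CS[, S, drop = FALSE])
  res <- .hillClimb(cs, s, e, pS, m, Wmax, L)
  res$S <- S
  res
}

## Greedy multiple-residue signature extension. Candidate residues must be
## enriched in the current window under the same count pre-filter the seeds
## honour (count >= p_b * w + 2); they are tried most-common-first, adding
## one re-minimizes the boundaries for the composite success class, and the
## extension is kept iff the p-value strictly decreases and the primary
## residue keeps the top count. Signature order = order of addition.
.extendSignature <- function(CS, bg, reg, m, Wmax, L) {
  repeat {
    w <- reg$e - reg$s + 1L
    wc <- CS[reg$e + 1L, ] - CS[reg$s, ]
    cand <- setdiff(AA20[wc >= bg[AA20] * w + 2], reg$S)
    if (!length(cand)) break
    cand <- cand[order(-wc[cand], cand)]
    improved <- FALSE
    for (b in cand) {
      S2 <- c(reg$S, b)
      res <- .minimizeRegion(CS, bg, S2, reg$s, reg$e, m, Wmax, L)
      if (is.null(res) || res$p >= reg$p) next
      cw <- CS[res$e + 1L, S2] - CS[res$s, S2]
      if (any(cw[-1L] > cw[1L])) next
      reg <- res
      improved <- TRUE
      break
    }
    if (!improved) break
  }
  reg
}

## Greedy signature chain evaluated at a fixed window (no boundary moves):
## returns the lowest-p chain prefix. This complements the re-minimizing
## extension, which can wander away from windows where a composite
## signature is optimal.
.chainAtWindow <- function(CS, bg, a, s, e) {
  w <- e - s + 1L
  wc <- CS[e + 1L, ] - CS[s, ]
  S <- a
  p <- .btail(wc[[a]], w, bg[[a]])
  best <- list(S = S, s = s, e = e, p = p)
  repeat {
    cand <- setdiff(AA20[wc >= bg[AA20] * w + 2], S)
    if (!length(cand)) break
    cand <- cand[order(-wc[cand], cand)]
    added <- FALSE
    for (b in cand) {
      S2 <- c(S, b)
      pS2 <- sum(bg[S2])
      if (pS2 >= 1) next
      p2 <- .btail(sum(wc[S2]), w, pS2)
      if (p2 >= p) next
      if (any(wc[S2[-1L]] > wc[[a]])) next
      S <- S2; p <- p2; added <- TRUE
      if (p < best$p) best <- list(S = S, s = s, e = e, p = p)
      break
    }
    if (!added) break
  }
  best
}

## Merge overlapping same-primary regions (union of spans, re-minimize from
## the union, re-extend) until no same-primary overlap remains. The union
## is re-minimized under each parent's signature and under the primary
## alone, keeping whichever lands lowest; the width cap is relaxed to the
## union width so that merged runs longer than M survive as single regions.
.mergeSamePrimary <- function(regs, CS, bg, m, Wcap, L) {
  repeat {
    if (length(regs) < 2L) return(regs)
    ord <- order(vapply(regs, `[[`, 1L, "s"))
    regs <- regs[ord]
    merged <- FALSE
    for (i in seq_len(length(regs) - 1L)) {
      if (regs[[i + 1L]]$s <= regs[[i]]$e) {
        s <- min(regs[[i]]$s, regs[[i + 1L]]$s)
        e <- max(regs[[i]]$e, regs[[i + 1L]]$e)
        Wmax <- max(Wcap, e - s + 1L)
        sigs <- unique(list(regs[[i]]$S, regs[[i + 1L]]$S,
                            regs[[i]]$S[1L]))
        tries <- lapply(sigs, function(S)
          .minimizeRegion(CS, bg, S, s, e, m, Wmax, L))
        tries <- lapply(Filter(Negate(is.null), tries), function(r)
          .extendSignature(CS, bg, r, m, Wmax, L))
        ## a union that re-minimizes worse than a parent must not replace
        ## it: the better parent then absorbs the overlap instead
        tries <- c(tries, regs[i], regs[i + 1L])
        res <- tries[[which.min(vapply(tries, `[[`, 1, "p"))]]
        regs <- c(regs[-c(i, i + 1L)], list(res))
        merged <- TRUE
        break
      }
    }
    if (!merged) return(regs)
  }
}

.scanOneSequence <- function(seqId, residues, m, M, t, bg, paramsId = "") {
  codes <- .residueCodes(residues)
  L <- length(codes)
  empty <- new("BiasRegions", seqId = character(), start = integer(),
               end = integer(), signature = list(), pValue = numeric(),
               k = integer(), w = integer(), paramsId = character())
  if (L < m) return(empty)
  Wcap <- min(M, L)
  CS <- .prefixCounts(codes, L)
  totals <- CS[L + 1L, ]
  ## window sizes: exhaustive when the range is small, else doubling from m
  sizes <- if (Wcap - m <= 30L) seq.int(m, Wcap) else
    unique(pmin.int(c(m * 2^(0:ceiling(log2(Wcap / m))), Wcap), Wcap))
  byPrimary <- list()
  for (a in AA20[totals >= pmax(1, ceiling(m * bg[AA20]))]) {
    cs <- CS[, a]
    seeds <- NULL
    for (w in sizes) {
      ks <- cs[(w + 1L):(L + 1L)] - cs[1L:(L - w + 1L)]
      keep <- which(ks >= bg[[a]] * w + 2)  # count pre-filter before tails
      if (!length(keep)) next
      pv <- stats::pbinom(ks[keep] - 1, w, bg[[a]], lower.tail = FALSE)
      ## seeds pass a relaxed threshold: a window can fail t on its own
      ## yet anchor a multiple-residue signature that passes it, so only
      ## the final regions are filtered at t
      sel <- which(pv <= max(t, 0.1))
      if (length(sel) > 60L) sel <- sel[order(pv[sel])[1:60]]
      if (length(sel))
        seeds <- rbind(seeds, cbind(keep[sel], keep[sel] + w - 1L, pv[sel]))
    }
    if (is.null(seeds)) next
    seeds <- seeds[order(seeds[, 3L]), , drop = FALSE]
    if (nrow(seeds) > 400L) seeds <- seeds[1:400, , drop = FALSE]
    regs <- list()
    addReg <- function(res) {
      dup <- any(vapply(regs, function(r)
        r$s == res$s && r$e == res$e &&
          identical(r$S, res$S), logical(1L)))
      if (!dup) regs[[length(regs) + 1L]] <<- res
    }
    for (i in seq_len(nrow(seeds))) {
      s0 <- as.integer(seeds[i, 1L]); e0 <- as.integer(seeds[i, 2L])
      ## a multiple-residue signature may only reveal itself at the seed
      ## window (another enriched residue sharing it), so the fixed-window
      ## greedy chain is evaluated for every seed, even those whose span
      ## is already covered by an accepted region
      ch0 <- .chainAtWindow(CS, bg, a, s0, e0)
      if (length(ch0$S) > 1L) {
        covered <- any(vapply(regs, function(r)
          identical(r$S, ch0$S) && r$s <= e0 && r$e >= s0 &&
            r$p <= ch0$p, logical(1L)))
        if (!covered) addReg(.extendSignature(
          CS, bg, .minimizeRegion(CS, bg, ch0$S, s0, e0, m, Wcap, L),
          m, Wcap, L))
      }
      contained <- any(vapply(regs, function(r)
        r$s <= s0 && e0 <= r$e, logical(1L)))
      if (contained) next
      res <- .hillClimb(cs, s0, e0, bg[[a]], m, Wcap, L)
      res$S <- a
      addReg(res)
      seed0 <- list(S = a, s = s0, e = e0, p = seeds[i, 3L])
      ext0 <- .extendSignature(CS, bg, seed0, m, Wcap, L)
      if (length(ext0$S) > 1L) addReg(ext0)
    }
    regs <- .mergeSamePrimary(regs, CS, bg, m, Wcap, L)
    regs <- lapply(regs, function(r) {
      Wmax <- max(Wcap, r$e - r$s + 1L)
      .extendSignature(CS, bg, r, m, Wmax, L)
    })
    regs <- .mergeSamePrimary(regs, CS, bg, m, Wcap, L)
    regs <- Filter(function(r) r$p <= t, regs)
    if (length(regs)) byPrimary[[a]] <- regs
  }
  regs <- unlist(byPrimary, recursive = FALSE, use.names = FALSE)
  if (!length(regs)) return(empty)
  ## bias precedence: the primary residue is the most dominant member of
  ## the signature in the final window, so members are ordered by their
  ## final counts (stable for ties, preserving order of addition).
  ## Reordering can expose new same-primary overlaps, so reorder and
  ## merge alternate until stable.
  reorder <- function(r) {
    if (length(r$S) > 1L) {
      cw <- CS[r$e + 1L, r$S] - CS[r$s, r$S]
      r$S <- r$S[order(-cw)]
    }
    r
  }
  keyOf <- function(rs) sort(vapply(rs, function(r)
    paste(r$s, r$e, paste(r$S, collapse = ",")), ""))
  for (iter in 1:5) {
    regs <- lapply(regs, reorder)
    regs <- regs[!duplicated(vapply(regs, function(r)
      paste(r$s, r$e, paste(r$S, collapse = ",")), ""))]
    before <- keyOf(regs)
    prim <- vapply(regs, function(r) r$S[1L], "")
    regs <- unlist(lapply(unique(prim), function(a)
      .mergeSamePrimary(regs[prim == a], CS, bg, m, Wcap, L)),
      recursive = FALSE, use.names = FALSE)
    regs <- lapply(regs, reorder)
    if (identical(keyOf(regs), before)) break
  }
  regs <- Filter(function(r) r$p <= t, regs)
  if (!length(regs)) return(empty)
  starts <- vapply(regs, `[[`, 1L, "s")
  ends <- vapply(regs, `[[`, 1L, "e")
  sigs <- lapply(regs, `[[`, "S")
  ks <- vapply(seq_along(regs), function(i) {
    S <- sigs[[i]]
    sum(CS[ends[i] + 1L, S] - CS[starts[i], S])
  }, 1L)
  ord <- order(starts, vapply(sigs, `[`, character(1L), 1L))
  new("BiasRegions", seqId = rep(seqId, length(regs))[ord],
      start = starts[ord], end = ends[ord], signature = sigs[ord],
      pValue = vapply(regs, `[[`, 1, "p")[ord], k = as.integer(ks[ord]),
      w = as.integer(ends - starts + 1L)[ord],
      paramsId = rep(paramsId, length(regs)))
}

#' Scan sequences for compositionally biased regions
#'
#' Finds single- and multiple-residue biased regions by binomial probability
#' minimization: for each candidate residue, windows of increasing size are
#' slid along the sequence, windows whose binomial tail p-value passes the
#' threshold seed a hill-climbing boundary refinement, overlapping hits with
#' the same primary residue are merged and re-minimized, and signatures are
#' greedily extended with further enriched residues whenever that strictly
#' lowers the p-value. Each returned region is labelled with its ordered
#' bias signature (primary residue first) and binomial p-value, and is
#' locally p-minimal: no single-residue boundary move lowers its p-value.
#'
#' @param x sequences (named character vector, `AAStringSet`, or a single
#'   string).
#' @param m minimum window size (>= 3; values below 15 require
#'   `smallWindow = TRUE`).
#' @param M maximum seed window size (<= 20 in small-window mode). Regions
#'   produced by merging overlapping same-primary hits may exceed `M`.
#' @param t binomial p-value threshold, in (0, 1).
#' @param background `"dataset"`, `"uniform"`, or a named frequency vector;
#'   see [backgroundFrequencies()]. `"dataset"` uses the composition of `x`
#'   itself.
#' @param smallWindow logical; enables the small-window parameter regime
#'   (m down to 3, M capped at 20) used for band detection.
#' @param paramsId label stored with each region (defaults to
#'   `"m<m>_M<M>_t<t>"`).
#' @return a [BiasRegions-class] object sorted by sequence and start.
#' @examples
#' scanBias(c(q = strrep("Q", 10)), m = 5, M = 20, t = 1e-3,
#'          background = "uniform", smallWindow = TRUE)
#' @export
scanBias <- function(x, m = 15, M = 500, t = 1e-3, background = "dataset",
                     smallWindow = FALSE, paramsId = NULL) {
  m <- as.integer(m); M <- as.integer(M)
  .checkScanParams(m, M, t, smallWindow)
  seqs <- .asSequenceSet(x)
  bg <- backgroundFrequencies(seqs, background)
  if (is.null(paramsId)) paramsId <- sprintf("m%d_M%d_t%g", m, M, t)
  out <- lapply(names(seqs), function(id)
    .scanOneSequence(id, seqs[[id]], m, M, t, bg, paramsId))
  .bindRegions(out)
}

#' Scan sequences over a parameter grid
#'
#' Runs [scanBias()] once per grid row and pools the hits (byte-identical
#' regions arising from different triads are deduplicated downstream by the
#' module/boundary derivation).
#'
#' @param x sequences.
#' @param grid data.frame with columns `m`, `M`, `t` (one scanner triad per
#'   row), e.g. [defaultModuleGrid()] or [defaultBandGrid()].
#' @param background background mode or table shared across triads.
#' @param smallWindow logical, as in [scanBias()].
#' @return pooled [BiasRegions-class].
#' @export
scanBiasGrid <- function(x, grid, background = "dataset",
                         smallWindow = FALSE) {
  stopifnot(is.data.frame(grid), all(c("m", "M", "t") %in% names(grid)))
  seqs <- .asSequenceSet(x)
  bg <- backgroundFrequencies(seqs, background)
  ## triads sharing (m, M) differ only in the final p-value filter, so the
  ## scan runs once per window pair at the loosest t and is re-filtered
  key <- paste(grid$m, grid$M)
  out <- list()
  for (kk in unique(key)) {
    rows <- which(key == kk)
    tmax <- max(grid$t[rows])
    base <- scanBias(seqs, m = grid$m[rows[1L]], M = grid$M[rows[1L]],
                     t = tmax, background = bg, smallWindow = smallWindow)
    for (i in rows) {
      sub <- base[base@pValue <= grid$t[i]]
      sub@paramsId <- rep(sprintf("m%d_M%d_t%g", grid$m[i], grid$M[i],
                                  grid$t[i]), length(sub))
      out[[length(out) + 1L]] <- sub
    }
  }
  .bindRegions(out)
}

.bindRegions <- function(lst) {
  lst <- Filter(function(r) length(r) > 0L, lst)
  if (!length(lst))
    return(new("BiasRegions", seqId = character(), start = integer(),
               end = integer(), signature = list(), pValue = numeric(),
               k = integer(), w = integer(), paramsId = character()))
  new("BiasRegions",
      seqId = unlist(lapply(lst, slot, "seqId")),
      start = unlist(lapply(lst, slot, "start")),
      end = unlist(lapply(lst, slot, "end")),
      signature = unlist(lapply(lst, slot, "signature"), recursive = FALSE),
      pValue = unlist(lapply(lst, slot, "pValue")),
      k = unlist(lapply(lst, slot, "k")),
      w = unlist(lapply(lst, slot, "w")),
      paramsId = unlist(lapply(lst, slot, "paramsId")))
}
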