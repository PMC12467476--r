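## Independent brute-force oracles used to freeze expected values. These
## deliberately share no code with the package internals.

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

## term-by-term binomial upper tail, summed in plain double arithmetic
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 1))
}

## position-by-position blockiness (nearest same/different distances)
oracleBlockiness <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  counts <- table(ch)
  num <- 0; den <- 0; used <- FALSE
  for (i in seq_len(L)) {
    if (ch[i] == "X") next
    if (counts[[ch[i]]] < 2L) next
    same <- Inf; diff <- Inf
    for (j in seq_len(L)) {
      if (j == i) next
      d <- abs(i - j)
      if (ch[j] == ch[i]) same <- min(same, d) else diff <- min(diff, d)
    }
    if (!is.finite(same) || !is.finite(diff)) next
    num <- num + diff; den <- den + same
    used <- TRUE
  }
  if (!used || den == 0) return(NA_real_)
  num / den
}

## exhaustive O(L^2) interval census -> named count vector "x|z|delta"
oracleCensus <- function(s, deltaMax = 100, minOcc = 3) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  tab <- table(ch)
  ok <- setdiff(names(tab)[tab >= minOcc], "X")
  counts <- new.env()
  for (i in seq_along(ch)) {
    if (!(ch[i] %in% ok)) next
    jmax <- min(length(ch), i + deltaMax + 1L)
    for (j in seq.int(i + 1L, length.out = max(0L, jmax - i))) {
      if (!(ch[j] %in% ok)) next
      key <- paste(ch[i], ch[j], j - i - 1L, sep = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  unlist(as.list(counts))
}

oracleEntropyBits <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

## independent re-implementation of p-ordered greedy de-selection
## (quadratic pairwise loop; deselects = function(kept_row, cand_row))
oracleDeselect <- function(df, deselects) {
  df <- df[!duplicated(df[c("seq_id", "start", "end", "sig", "p")]), ]
  df <- df[order(df$p, -(df$end - df$start + 1L), df$start, df$seq_id,
                 df$prim), ]
  keep <- logical(nrow(df))
  dead <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (dead[i]) next
    keep[i] <- TRUE
    if (i == nrow(df)) break
    for (j in seq.int(i + 1L, nrow(df))) {
      if (dead[j] || keep[j]) next
      if (df$seq_id[j] != df$seq_id[i] || df$prim[j] != df$prim[i]) next
      if (deselects(df[i, ], df[j, ])) dead[j] <- TRUE
    }
  }
  df[keep, ]
}

## random region pool for de-selection oracle tests
randomRegionPool <- function(n, Lseq = 300, minW = 20, maxW = 80,
                             residues = c("Q", "N", "S")) {
  w <- sample(minW:maxW, n, replace = TRUE)
  start <- vapply(w, function(wi) sample.int(Lseq - wi + 1L, 1L), 1L)
  prim <- sample(residues, n, replace = TRUE)
  data.frame(seq_id = "s", start = start, end = start + w - 1L,
             prim = prim, sig = prim, p = 10^-runif(n, 3, 12),
             stringsAsFactors = FALSE)
}

## convert a pool data.frame to a BiasRegions object
poolToRegions <- function(df) {
  new("BiasRegions", seqId = df$seq_id, start = as.integer(df$start),
      end = as.integer(df$end), signature = as.list(df$prim),
      pValue = df$p, k = as.integer(df$end - df$start + 1L),
      w = as.integer(df$end - df$start + 1L),
      paramsId = rep("", nrow(df)))
}

## DPB by direct transcription of the definition, from explicit endpoints
oracleDpb <- function(endpoints) {
  n <- length(endpoints)
  s <- endpoints[1L]; e <- endpoints[n]
  perfect <- s + (seq_len(n) - 1L) * (e - s) / (n - 1L)
  sum(abs(endpoints - perfect))
}

## simple BiasRegions constructor for band fixtures
makeBands <- function(starts, ends, residue = "Q", seqId = "s") {
  k <- length(starts)
  new("BiasRegions", seqId = rep(seqId, k), start = as.integer(starts),
      end = as.integer(ends), signature = rep(list(residue), k),
      pValue = rep(1e-6, k), k = as.integer(ends - starts + 1L),
      w = as.integer(ends - starts + 1L), paramsId = rep("", k))
}

## fixed-window greedy-chain scan oracle: per primary residue, the minimum
## p over all windows of the greedy signature chain evaluated at that
## window (single-residue minima tracked separately)
oracleScanBest <- function(s, m, M, t, bg) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  chain <- setNames(rep(Inf, 20L), AA20_TEST)
  single <- setNames(rep(Inf, 20L), AA20_TEST)
  singleWin <- chainWin <- setNames(vector("list", 20L), AA20_TEST)
  for (i in 1:L) for (j in i:L) {
    w <- j - i + 1L
    if (w < m || w > min(M, L)) next
    wc <- table(factor(ch[i:j], levels = AA20_TEST))
    for (a in AA20_TEST[wc > 0]) {
      S <- a
      p <- oracleBinomTail(wc[[a]], w, bg[[a]])
      if (p < single[a]) { single[a] <- p; singleWin[[a]] <- c(i, j) }
      if (p < chain[a]) { chain[a] <- p; chainWin[[a]] <- c(i, j) }
      repeat {
        cand <- setdiff(AA20_TEST[wc >= bg[AA20_TEST] * w + 2], S)
        if (!length(cand)) break
        cand <- cand[order(-wc[cand], cand)]
        added <- FALSE
        for (b in cand) {
          S2 <- c(S, b)
          pS2 <- sum(bg[S2])
          if (pS2 >= 1) next
          p2 <- oracleBinomTail(sum(wc[S2]), w, pS2)
          if (p2 < p && !any(wc[S2[-1L]] > wc[[a]])) {
            S <- S2; p <- p2; added <- TRUE
            if (p < chain[a]) { chain[a] <- p; chainWin[[a]] <- c(i, j) }
            break
          }
        }
        if (!added) break
      }
    }
  }
  list(chain = chain, single = single, chainWin = chainWin,
       singleWin = singleWin)
}

## best scanner p per primary residue, optionally single-residue only
scanBestByPrimary <- function(regions, singleOnly = FALSE) {
  best <- setNames(rep(Inf, 20L), AA20_TEST)
  if (length(regions)) for (q in seq_len(length(regions))) {
    if (singleOnly && length(regions@signature[[q]]) > 1L) next
    pr <- regions@signature[[q]][1L]
    best[pr] <- min(best[pr], regions@pValue[q])
  }
  best
}
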