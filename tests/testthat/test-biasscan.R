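test_that("binomialTail matches term-by-term summation", {
  expect_equal(binomialTail(0, 10, 0.3), 1)
  expect_equal(binomialTail(3, 3, 0.25), 0.25^3)
  set.seed(5)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.95)
    expect_equal(binomialTail(k, n, p), oracleBinomTail(k, n, p),
                 tolerance = 1e-12)
  }
  expect_error(binomialTail(5, 3, 0.1), "k")
  expect_error(binomialTail(1, 3, 0), "p")
})

test_that("background composition modes are valid distributions", {
  seqs <- c(a = "QQQQN", b = "MKV")
  for (mode in list("dataset", "uniform")) {
    bg <- backgroundFrequencies(seqs, mode)
    expect_equal(sum(bg), 1, tolerance = 1e-9)
    expect_true(all(bg > 0))
    expect_identical(names(bg), cbpatterns:::AA20)
  }
  ## dataset mode is add-one smoothed: absent residues keep p > 0
  bg <- backgroundFrequencies(seqs, "dataset")
  expect_gt(bg[["W"]], 0)
  expect_gt(bg[["Q"]], bg[["W"]])
  ## user table is renormalized
  user <- setNames(rep(2, 20), cbpatterns:::AA20)
  expect_equal(unname(backgroundFrequencies(seqs, user)), rep(0.05, 20))
})

test_that("a forced homopolymer window is found with its exact tail p", {
  res <- scanBias(c(q = strrep("Q", 10)), m = 5, M = 20, t = 1e-3,
                  background = "uniform", smallWindow = TRUE)
  expect_identical(length(res), 1L)
  expect_identical(res@start, 1L)
  expect_identical(res@end, 10L)
  expect_identical(biasSignature(res), "{Q}")
  expect_equal(res@pValue, 0.05^10, tolerance = 1e-9)
})

test_that("sequences shorter than m yield an empty result, not an error", {
  res <- scanBias(c(s = "MKV"), m = 15, M = 500, t = 1e-3,
                  background = "uniform")
  expect_identical(length(res), 0L)
})

test_that("uniform-random sequences rarely pass a tight threshold", {
  set.seed(11)
  hits <- vapply(1:50, function(i) {
    s <- paste(sample(AA20_TEST, 200, replace = TRUE), collapse = "")
    length(scanBias(setNames(s, "r"), m = 15, M = 500, t = 1e-9,
                    background = "uniform"))
  }, 1L)
  expect_gte(mean(hits == 0L), 0.98)
})

test_that("two adjacent single-residue runs fuse into the lower-p composite", {
  res <- scanBias(c(s = "QQQQQNNNNN"), m = 5, M = 20, t = 0.05,
                  background = "uniform", smallWindow = TRUE)
  df <- as.data.frame(res)
  qbest <- df[df$signature %in% c("{Q,N}", "{Q}"), ]
  expect_true("{Q,N}" %in% df$signature)
  ## composite beats the two pure halves: p = 0.1^10 < 0.05^5
  expect_equal(min(df$p_value), 0.1^10, tolerance = 1e-9)
})

test_that("scan output satisfies the region invariants", {
  set.seed(13)
  for (rep_ in 1:8) {
    s <- paste(sample(c("Q", "Q", "N", AA20_TEST), 150, replace = TRUE),
               collapse = "")
    t <- 1e-3
    res <- scanBias(setNames(s, "s"), m = 15, M = 100, t = t,
                    background = "uniform")
    if (!length(res)) next
    expect_true(all(res@pValue <= t))
    expect_true(all(res@w >= 15L))
    expect_true(all(res@end - res@start + 1L == res@w))
    prim <- primaryBias(res)
    ## primary residue count >= any other signature member count
    for (q in seq_len(length(res))) {
      ch <- strsplit(substr(s, res@start[q], res@end[q]), "")[[1]]
      cnt <- table(factor(ch, levels = AA20_TEST))
      S <- res@signature[[q]]
      expect_true(all(cnt[S[1]] >= cnt[S]))
      expect_identical(res@k[q], as.integer(sum(cnt[S])))
    }
    ## no same-primary overlaps survive
    for (a in unique(prim)) {
      sub <- res[prim == a]
      if (length(sub) < 2) next
      o <- order(sub@start)
      expect_true(all(sub@start[o][-1] > sub@end[o][-length(o)]))
    }
    ## local p-minimality: no +/-1 boundary move lowers the p-value
    bg <- backgroundFrequencies(setNames(s, "s"), "uniform")
    for (q in seq_len(length(res))) {
      S <- res@signature[[q]]
      pS <- sum(bg[S])
      kIn <- function(i, j) {
        ch <- strsplit(substr(s, i, j), "")[[1]]
        sum(ch %in% S)
      }
      p0 <- binomialTail(kIn(res@start[q], res@end[q]), res@w[q], pS)
      for (mv in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        i <- res@start[q] + mv[1]; j <- res@end[q] + mv[2]
        if (i < 1 || j > nchar(s) || j - i + 1 < 15 ||
            j - i + 1 > max(100, res@w[q])) next
        expect_gte(binomialTail(kIn(i, j), j - i + 1, pS), p0)
      }
    }
  }
})

test_that("the scanner is deterministic and monotone in t", {
  set.seed(17)
  s <- setNames(paste(sample(c("S", "S", AA20_TEST), 200, replace = TRUE),
                      collapse = ""), "s")
  r1 <- scanBias(s, m = 15, M = 200, t = 1e-3, background = "uniform")
  r2 <- scanBias(s, m = 15, M = 200, t = 1e-3, background = "uniform")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  ## lowering t never adds regions
  r3 <- scanBias(s, m = 15, M = 200, t = 1e-6, background = "uniform")
  expect_lte(length(r3), length(r1))
  if (length(r3)) expect_true(all(r3@pValue <= 1e-6))
})

test_that("parameter validation mirrors the small-window regime", {
  s <- c(s = strrep("QA", 30))
  expect_error(scanBias(s, m = 5, M = 100, t = 1e-3), "small-window")
  expect_error(scanBias(s, m = 3, M = 30, t = 1e-3, smallWindow = TRUE),
               "M <= 20")
  expect_error(scanBias(s, m = 2, M = 20, t = 1e-3, smallWindow = TRUE),
               "m")
  expect_error(scanBias(s, m = 15, M = 10, t = 1e-3), "M")
  expect_error(scanBias(s, m = 15, M = 100, t = 0), "t")
})
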