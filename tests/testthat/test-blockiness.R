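test_that("B matches hand-derived values on alternation and segregation", {
  ## perfect alternation: every dmin_diff = 1, every dmin_same = 2
  expect_equal(blockinessScore("ARARARAR")@B, 0.5)
  ## full segregation: sum(dmin_diff) = 20, sum(dmin_same) = 8
  expect_equal(blockinessScore("AAAARRRR")@B, 2.5)
  ## homopolymer: no different-type residue exists -> flagged undefined
  expect_true(is.na(blockinessScore("AAAA")@B))
})

test_that("B agrees with the position-by-position oracle", {
  set.seed(37)
  for (i in 1:30) {
    s <- paste(sample(AA20_TEST[1:sample(c(2, 4, 8), 1)],
                      sample(10:60, 1), replace = TRUE), collapse = "")
    expect_equal(blockinessScore(s)@B, oracleBlockiness(s),
                 tolerance = 1e-12, label = s)
  }
})

test_that("B is invariant under reversal and residue renaming", {
  set.seed(41)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "D", "E"), 40, replace = TRUE),
               collapse = "")
    b <- blockinessScore(s)@B
    rev_ <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(blockinessScore(rev_)@B, b, tolerance = 1e-12)
    ren <- chartr("ACDE", "WYVH", s)
    expect_equal(blockinessScore(ren)@B, b, tolerance = 1e-12)
    expect_gt(b, 0)
  }
})

test_that("full segregation maximizes B over all two-type arrangements", {
  ## exhaustive over all arrangements for small compositions
  for (comp in list(c(3, 3), c(4, 2), c(4, 4), c(5, 3))) {
    ch <- rep(c("A", "R"), comp)
    L <- length(ch)
    perms <- unique(combn(L, comp[1], simplify = FALSE))
    best <- -Inf
    for (idx in perms) {
      arr <- rep("R", L); arr[idx] <- "A"
      best <- max(best, oracleBlockiness(paste(arr, collapse = "")))
    }
    seg <- blockinessScore(paste(rep(c("A", "R"), comp), collapse = ""))@B
    expect_equal(seg, best, tolerance = 1e-12)
  }
})

test_that("X positions are skipped but act as a different type", {
  ## X is excluded from the sums yet provides dmin_diff for neighbours
  b <- blockinessScore("AAXXAA")
  expect_false(is.na(b@B))
  oracle <- oracleBlockiness("AAXXAA")
  expect_equal(b@B, oracle, tolerance = 1e-12)
})

test_that("contributing residues are exactly those with B_a above B", {
  res <- blockinessScore("AAAARRRRWYWYWY")
  expect_setequal(res@contributing,
                  names(res@perResidue)[res@perResidue > res@B])
  expect_true(all(c("A", "R") %in% res@contributing))
  expect_false(any(c("W", "Y") %in% res@contributing))
})

test_that("scrambled nulls separate blocky from dispersed arrangements", {
  set.seed(43)
  blocky <- assessBlockiness(strrep("QQQQQQQQAAAAAAAA", 6), nSamples = 500)
  expect_identical(blocky@null@call, "high")
  dispersed <- assessBlockiness(strrep("QA", 48), nSamples = 500)
  expect_identical(dispersed@null@call, "low")
  expect_gt(blocky@null@z, 0)
  expect_lt(dispersed@null@z, 0)
})
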