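## De-selection examples traced by hand against the selection rules.

regionsFromSpecs <- function(...) {
  specs <- list(...)
  poolToRegions(data.frame(
    seq_id = "s",
    start = vapply(specs, `[[`, 1, "start"),
    end = vapply(specs, `[[`, 1, "end"),
    prim = vapply(specs, `[[`, "", "prim"),
    sig = vapply(specs, `[[`, "", "prim"),
    p = vapply(specs, `[[`, 1, "p"), stringsAsFactors = FALSE))
}

test_that("module de-selection removes nested same-primary regions", {
  pool <- regionsFromSpecs(
    list(start = 1, end = 50, prim = "Q", p = 1e-9),
    list(start = 10, end = 40, prim = "Q", p = 1e-4))
  mod <- deriveModules(pool)
  expect_identical(length(mod), 1L)
  expect_identical(c(mod@start, mod@end), c(1L, 50L))

  ## different primary residues never de-select each other
  pool <- regionsFromSpecs(
    list(start = 1, end = 50, prim = "Q", p = 1e-9),
    list(start = 10, end = 40, prim = "N", p = 1e-4))
  expect_identical(length(deriveModules(pool)), 2L)

  ## disjoint same-primary regions both survive
  pool <- regionsFromSpecs(
    list(start = 1, end = 20, prim = "Q", p = 1e-9),
    list(start = 100, end = 120, prim = "Q", p = 1e-4))
  expect_identical(length(deriveModules(pool)), 2L)

  ## the overlap fraction is measured against the candidate's own extent
  pool <- regionsFromSpecs(
    list(start = 1, end = 50, prim = "Q", p = 1e-9),    # accepted first
    list(start = 41, end = 140, prim = "Q", p = 1e-4))  # 10/100 overlap
  expect_identical(length(deriveModules(pool)), 2L)
})

test_that("boundary-set de-selection uses the 5-residue endpoint margin", {
  pool <- regionsFromSpecs(
    list(start = 1, end = 50, prim = "Q", p = 1e-9),
    list(start = 3, end = 52, prim = "Q", p = 1e-7),
    list(start = 10, end = 40, prim = "Q", p = 1e-4))
  bs <- deriveBoundarySets(pool)
  df <- as.data.frame(bs)
  expect_identical(nrow(df), 2L)
  expect_setequal(df$start, c(1L, 10L))

  ## single region: nothing to de-select
  one <- regionsFromSpecs(list(start = 5, end = 60, prim = "S", p = 1e-5))
  expect_identical(length(deriveBoundarySets(one)), 1L)
})

test_that("selection never alters coordinates and ignores input order", {
  set.seed(23)
  for (i in 1:20) {
    df <- randomRegionPool(30)
    pool <- poolToRegions(df)
    mod <- deriveModules(pool)
    keyIn <- paste(df$start, df$end, df$prim)
    keyOut <- paste(mod@start, mod@end, primaryBias(mod))
    expect_true(all(keyOut %in% keyIn))
    perm <- sample(nrow(df))
    mod2 <- deriveModules(poolToRegions(df[perm, ]))
    expect_identical(as.data.frame(mod), as.data.frame(mod2))
    bs <- deriveBoundarySets(pool)
    bs2 <- deriveBoundarySets(poolToRegions(df[perm, ]))
    expect_identical(as.data.frame(bs), as.data.frame(bs2))
  }
})

test_that("greedy selection matches an independent re-implementation", {
  set.seed(29)
  for (i in 1:200) {
    df <- randomRegionPool(sample(2:50, 1))
    pool <- poolToRegions(df)

    oModules <- oracleDeselect(df, function(kept, cand) {
      inter <- min(kept$end, cand$end) - max(kept$start, cand$start) + 1
      inter / (cand$end - cand$start + 1) >= 0.5
    })
    mod <- as.data.frame(deriveModules(pool))
    expect_identical(nrow(mod), nrow(oModules))
    expect_setequal(paste(mod$start, mod$end),
                    paste(oModules$start, oModules$end))

    oBounds <- oracleDeselect(df, function(kept, cand)
      abs(cand$start - kept$start) <= 5 && abs(cand$end - kept$end) <= 5)
    bs <- as.data.frame(deriveBoundarySets(pool))
    expect_identical(nrow(bs), nrow(oBounds))
    expect_setequal(paste(bs$start, bs$end),
                    paste(oBounds$start, oBounds$end))

    ## boundary sets are never fewer than modules on the same pool
    expect_gte(nrow(bs), nrow(mod))
  }
})
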