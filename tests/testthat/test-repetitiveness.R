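test_that("the interval census enumerates all capped ordered pairs", {
  cen <- intervalCensus("ARARAR")
  expect_identical(cen@total, 15L)  # choose(6, 2), all within the cap
  expect_identical(cen@N, 9L)
  df <- cen@counts
  key <- setNames(df$count, paste(df$x, df$z, df$delta))
  expect_identical(key[["A R 0"]], 3L)
  expect_identical(key[["R A 0"]], 2L)
  expect_identical(key[["A A 1"]], 2L)
  expect_identical(key[["R R 1"]], 2L)
  expect_identical(key[["A R 2"]], 2L)
  expect_identical(key[["R A 2"]], 1L)
  expect_identical(key[["A A 3"]], 1L)
  expect_identical(key[["R R 3"]], 1L)
  expect_identical(key[["A R 4"]], 1L)

  ## the abundance filter empties the census when no type reaches 3
  expect_identical(intervalCensus("AAR")@N, 0L)

  ## homopolymer: only same-residue types, counts L-1-delta
  cen <- intervalCensus("AAAAAA")
  expect_identical(cen@counts$count, c(5L, 4L, 3L, 2L, 1L))
  expect_identical(cen@counts$delta, 0:4)
  expect_identical(cen@total, 15L)
})

test_that("census counts match exhaustive enumeration up to L = 300", {
  set.seed(53)
  cases <- list(
    paste(sample(AA20_TEST, 300, TRUE), collapse = ""),
    strrep("PAQGS", 60),
    paste(sample(c("Q", "Q", "N", "A"), 250, TRUE), collapse = ""),
    paste(c(sample(AA20_TEST[1:6], 150, TRUE), rep("X", 10),
            sample(AA20_TEST[1:6], 140, TRUE)), collapse = ""))
  for (s in cases) {
    cen <- intervalCensus(s)
    ref <- oracleCensus(s)
    got <- setNames(cen@counts$count,
                    paste(cen@counts$x, cen@counts$z, cen@counts$delta,
                          sep = "|"))
    expect_identical(length(ref), length(got))
    expect_identical(sort(names(ref)), sort(names(got)))
    expect_identical(unname(ref[names(got)]), unname(got))
  }
})

test_that("interval entropy follows the Shannon formula in bits", {
  cen <- intervalCensus("ARARAR")
  ie <- intervalEntropy(cen)
  expect_equal(ie[["IE"]],
               oracleEntropyBits(c(3, 2, 2, 2, 2, 1, 1, 1, 1)),
               tolerance = 1e-9)
  expect_equal(ie[["IE"]], 3.0566, tolerance = 1e-4)

  ## one interval type -> zero entropy
  one <- intervalCensus("AAAR")  # only (A,A,0) x2 ... A count 3
  expect_identical(one@N, 2L)
  solo <- new("IntervalCensus",
              counts = data.frame(x = "A", z = "A", delta = 0L,
                                  count = 7L),
              total = 7L, N = 1L, deltaMax = 100L, minOcc = 3L)
  expect_equal(intervalEntropy(solo)[["IE"]], 0)

  ## k equiprobable types -> log2 k
  k <- 8L
  eq <- new("IntervalCensus",
            counts = data.frame(x = rep("A", k), z = rep("C", k),
                                delta = 0:(k - 1L), count = rep(4L, k)),
            total = 4L * k, N = k, deltaMax = 100L, minOcc = 3L)
  expect_equal(intervalEntropy(eq)[["IE"]], log2(k))

  ## empty census: IE = 0, flagged
  emp <- intervalEntropy(intervalCensus("AAR"))
  expect_identical(emp[["IE"]], 0)
  expect_true(attr(emp, "empty"))
})

test_that("IE bounds, renaming invariance, and total conservation hold", {
  set.seed(59)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "D", "E"), 80, TRUE), collapse = "")
    cen <- intervalCensus(s)
    ie <- intervalEntropy(cen)
    expect_gte(ie[["IE"]], 0)
    expect_lte(ie[["IE"]], log2(cen@N) + 1e-9)
    ren <- chartr("ACDE", "WYVH", s)
    expect_equal(intervalEntropy(intervalCensus(ren))[["IE"]], ie[["IE"]],
                 tolerance = 1e-12)
    ## with L <= deltaMax + 1 and every type abundant, the census total
    ## depends only on composition, so scrambling conserves it
    sc <- scrambleSequence(setNames(s, "s"))
    expect_identical(intervalCensus(sc)@total, cen@total)
  }
})

test_that("tandem repeats score repetitive; scrambles do not", {
  set.seed(61)
  rep_ <- assessRepetitiveness(strrep("PAQGS", 40), nSamples = 1000)
  expect_identical(rep_@null@call, "low")
  expect_lt(rep_@null@z, -5)
  ## a perfect repeat is below at least 99% of its scrambles
  expect_lte(rep_@null@pLow, 0.01)

  ## top lists hold significant types, correctly ordered and capped
  expect_lte(nrow(rep_@topByFreq), 10L)
  expect_lte(nrow(rep_@topByP), 10L)
  expect_true(all(rep_@topByFreq$p < 0.05))
  expect_true(!is.unsorted(-rep_@topByFreq$count))
  expect_true(!is.unsorted(rep_@topByP$p))
})

test_that("degenerate inputs produce flagged results, not errors", {
  res <- assessRepetitiveness("ACDEF", nSamples = 100)
  expect_identical(res@census@N, 0L)
  expect_null(res@null)
  expect_identical(res@IE, 0)
})
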