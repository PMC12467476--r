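test_that("DPB reproduces the worked three-band example", {
  bands <- makeBands(c(1, 31, 61), c(10, 40, 70))
  expect_equal(perfectBandingDistance(bands), 14.4, tolerance = 1e-9)
  expect_equal(oracleDpb(c(1, 10, 31, 40, 61, 70)), 14.4, tolerance = 1e-9)
})

test_that("DPB is zero on the even grid and invariant under translation
          and reflection", {
  ## endpoints exactly on the even grid: 2k = 4 points over span 1..31
  bands <- makeBands(c(1, 21), c(11, 31))
  expect_equal(perfectBandingDistance(bands), 0)

  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    starts <- sort(sample(seq(1, 500, by = 25), k))
    ends <- starts + sample(3:10, k, replace = TRUE)
    d0 <- perfectBandingDistance(makeBands(starts, ends))
    expect_gte(d0, 0)
    ## translation
    expect_equal(perfectBandingDistance(makeBands(starts + 37, ends + 37)),
                 d0, tolerance = 1e-9)
    ## reflection within the span
    s <- starts[1]; e <- ends[k]
    rs <- sort(s + e - ends); re <- sort(s + e - starts)
    expect_equal(perfectBandingDistance(makeBands(rs, re)), d0,
                 tolerance = 1e-9)
  }
  expect_error(perfectBandingDistance(makeBands(1, 10)), "2 bands")
})

test_that("band collection segregates by bias and needs two patches", {
  ## two forced Q windows across an X gap
  g <- collectBands(c(b = "QQQQXXXXXXQQQQ"),
                    grid = data.frame(m = 3L, M = 20L, t = 0.05),
                    background = "dataset")
  expect_identical(names(g), "b|Q")
  df <- as.data.frame(g[[1]])
  expect_identical(df$start, c(1L, 11L))
  expect_identical(df$end, c(4L, 14L))

  ## a single run is not banding
  g <- collectBands(c(b = strrep("Q", 8)), background = "uniform")
  expect_identical(length(g), 0L)

  ## the alternating-band toy yields one group with one band per patch
  set.seed(3)
  toy <- makeToySequence("alternating_bands")
  g <- collectBands(toy$sequence, background = "dataset")
  expect_true("toy_alternating_bands|Q" %in% names(g))
  bands <- g[["toy_alternating_bands|Q"]]
  expect_identical(length(bands), length(toy$truth$start))
  expect_true(all(abs(bands@start - toy$truth$start) <= 1))
})

test_that("gap outliers are excised by the modified z-score rule", {
  ## four bands, one inter-band gap ten times the others
  bands <- makeBands(c(1, 21, 41, 161), c(10, 30, 50, 170))
  set.seed(5)
  res <- assessBandSet(bands, nSamples = 200)
  expect_identical(length(res[[1]]@bands), 3L)
  expect_identical(res[[1]]@excisedGaps, 3L)
  expect_identical(res[[1]]@bands@start, c(1L, 21L, 41L))

  ## two bands: excision is never attempted
  two <- makeBands(c(1, 161), c(10, 170))
  set.seed(5)
  res <- assessBandSet(two, nSamples = 200)
  expect_identical(length(res), 1L)
  expect_identical(res[[1]]@excisedGaps, integer(0))
  expect_identical(length(res[[1]]@bands), 2L)
})

test_that("a perfectly even band set is called significantly even", {
  bands <- makeBands(c(1, 31, 61), c(16, 46, 76))
  expect_equal(perfectBandingDistance(bands), 0)
  set.seed(7)
  res <- assessBandSet(bands, nSamples = 1000)[[1]]
  expect_identical(res@null@call, "low")
  expect_equal(res@null@pLow, 1 / 1001)
  ## null DPB values are non-negative: mean must be positive
  expect_gt(res@null@nullMean, 0)
})

test_that("role selection picks max-band, min-z and max-z sets", {
  set.seed(9)
  a1 <- assessBandSet(makeBands(c(1, 31, 61, 91), c(16, 46, 76, 106)),
                      nSamples = 200)[[1]]    # 4 even bands, low z
  a2 <- assessBandSet(makeBands(c(1, 5, 95), c(3, 8, 100)),
                      nSamples = 200)[[1]]    # 3 uneven bands, high z
  roles <- reportBandSets(list(a1, a2))
  expect_identical(length(roles), 3L)
  expect_identical(vapply(roles, function(x) x@role, ""),
                   c("max_bands", "min_z", "max_z"))
  expect_identical(length(roles[[1]]@bands), 4L)
  expect_lt(roles[[2]]@null@z, roles[[3]]@null@z)
  ## a single assessed set fills all three roles
  solo <- reportBandSets(list(a1))
  expect_identical(length(solo), 3L)
  expect_true(all(vapply(solo, function(x) length(x@bands), 1L) == 4L))
})
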