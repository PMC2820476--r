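test_that("duplication distance matches the worked small cases", {
  expect_equal(dupDistance("abcd", "bbccd"), 2)
  expect_equal(dupDistance("abcd", "dab"), 2)
  expect_equal(dupDistance("abc", "abc"), 1)
  expect_equal(dupDistance("abc", ""), 0)
  err <- tryCatch(dupDistance("ab", "abz"), error = identity)
  expect_true(isUndefinedDistance(err))
})

test_that("duplication-deletion distance prices deleted runs correctly", {
  ## one op spanning abcde and retaining a, c, e: 3 + 5*1 + 1 + 1
  m <- costModel(3, 1, phi = c(0, 1))
  expect_equal(dupDistance("abcde", "ace", m, "dupdel"), 10)
  expect_equal(dupDistance("abcd", "bd", unitCosts(), "dupdel"), 2)
  expect_equal(dupDistance("abc", "", unitCosts(), "dupdel"), 0)
})

test_that("duplication-inversion distance uses inverted copies when cheaper", {
  expect_equal(dupDistance("+a +b +c", "-c -b -a", unitCosts(), "dupinv"), 1)
  expect_equal(dupDistance("+a", "-a +a", unitCosts(), "dupinv"), 2)
  ## forward copy when the inversion gains nothing
  m <- costModel(1, 0.5, 1, 0.5)
  expect_equal(dupDistance("+a +b", "+a +b", m, "dupinv"), 2)
})

test_that("inversion-deletion and substring-inversion variants combine correctly", {
  m <- costModel(1, 0, 1, 0, phi = c(0, 0))
  expect_equal(dupDistance("+a +b +c +d", "-d -b", m, "dupinvdel"), 1)
  expect_equal(dupDistance("+a", "", unitCosts(), "dupinvdel"), 0)

  ## single op with an internal inverted span, Phi prohibitive
  ms <- costModel(1, 0, phi = c(1000, 1000),
                  theta = function(l) ifelse(l > 0, 0.5, 0)) |>
    suppressWarnings()
  expect_equal(dupDistance("+a +b +c +d +e +f", "+a +b -e -d -c +f",
                           ms, "dupsubinv"), 1.5)

  ## forcing the identity inversion collapses to duplication-deletion
  mInf <- costModel(2, 1, phi = c(1, 1),
                    theta = function(l) ifelse(l > 0, 1e9, 0)) |>
    suppressWarnings()
  mPlain <- costModel(2, 1, phi = c(1, 1))
  set.seed(31)
  for (k in seq_len(20)) {
    x <- randomSignedString(4, letters[1:2])
    y <- randomSignedString(sample(1:5, 1L), letters[1:2])
    expect_equal(distanceOrInf(x, y, mInf, "dupsubinv"),
                 distanceOrInf(x, y, mPlain, "dupdel"))
  }
})

test_that("deletion variants only pay for deletions they use", {
  ## when y needs no inversion and Theta is prohibitive, the inversion
  ## branch never fires: dupinvdel equals dupdel
  m <- costModel(1, 0, 11, 0, phi = "unit")
  set.seed(17)
  for (k in seq_len(25)) {
    x <- randomSignedString(4, letters[1:2])
    y <- randomSignedString(sample(0:5, 1L), letters[1:2])
    expect_equal(distanceOrInf(x, y, m, "dupinvdel"),
                 distanceOrInf(x, y, m, "dupdel"))
  }
})

test_that("traceback replays to the target at the DP cost for every variant", {
  set.seed(23)
  models <- list(unitCosts(), affineCosts())
  for (k in seq_len(30)) {
    p <- randomSignedPair(maxX = 4L, maxY = 5L)
    for (v in c("dup", "dupdel", "dupinv", "dupinvdel", "dupsubinv"))
      for (m in models) {
        d <- tryCatch(dupDistance(p$x, p$y, m, v),
                      undefinedDistanceError = function(e) NULL)
        if (is.null(d)) next
        sc <- dupTraceback(p$x, p$y, m, v)
        r <- replayScenario(p$x, sc, m)
        if (v %in% c("dup", "dupdel"))   # sign-free: symbols reproduced
          expect_equal(symbols(r$target), symbols(p$y))
        else
          expect_true(r$target == p$y)
        expect_equal(r$cost, d, tolerance = 1e-9)
        expect_equal(totalCost(sc), d, tolerance = 1e-9)
      }
  }
})

test_that("traceback is deterministic and canonical on the worked examples", {
  sc <- dupTraceback("abcd", "bbccd")
  expect_equal(length(scenarioOps(sc)), 2L)
  expect_equal(scenarioOps(sc)[[1]]@sourceSpan, c(2L, 4L))
  sc2 <- dupTraceback("abcd", "bbccd")
  expect_identical(writeScenarioJSON(sc, signedString("abcd")),
                   writeScenarioJSON(sc2, signedString("abcd")))

  single <- dupTraceback("abc", "b")
  expect_equal(length(scenarioOps(single)), 1L)
  expect_equal(scenarioOps(single)[[1]]@sourceSpan, c(2L, 2L))

  inv <- dupTraceback("+a +b +c", "-c -b -a", variant = "dupinv")
  expect_equal(length(scenarioOps(inv)), 1L)
  expect_equal(scenarioOps(inv)[[1]]@kind, "DUPINV")
})

test_that("unit-cost bounds and concatenation subadditivity hold", {
  set.seed(41)
  for (k in seq_len(100)) {
    x <- randomSignedString(sample(2:4, 1L), letters[1:3])
    y1 <- randomSignedString(sample(1:4, 1L), symbols(x))
    y2 <- randomSignedString(sample(1:4, 1L), symbols(x))
    d1 <- dupDistance(x, y1); d2 <- dupDistance(x, y2)
    d12 <- dupDistance(x, c(y1, y2))
    expect_lte(d12, d1 + d2)
    expect_gte(d1, ceiling(length(y1) / length(x)))
    expect_lte(d1, length(y1))
  }
})
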