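test_that("partition-enumeration oracle solves tiny instances exactly", {
  ## bbccd is not a substring of abcd, so one op is impossible; two suffice
  expect_equal(oracleDistance("abcd", "bbccd"), 2)
  expect_equal(oracleDistance("ab", ""), 0)
  expect_equal(oracleDistance("+a +b +c", "-c -b -a", variant = "dupinv"), 1)
  ## undefined targets come back infinite
  expect_equal(oracleDistance("ab", "az"), Inf)
})

test_that("oracle distance is invariant under alphabet relabelling", {
  relabel <- function(s, map) {
    sym <- map[symbols(s)]
    names(sym) <- NULL
    do.call(c, lapply(seq_along(sym), function(i)
      signedString(paste0(ifelse(signs(s)[i] == 1, "+", "-"), sym[i]))))
  }
  set.seed(9)
  maps <- list(c(a = "b", b = "c", c = "a"), c(a = "c", b = "a", c = "b"))
  for (k in seq_len(20)) {
    p <- randomSignedPair(maxX = 3L, maxY = 4L)
    if (!length(p$y)) next
    for (map in maps) for (v in c("dup", "dupinv")) {
      d0 <- oracleDistance(p$x, p$y, variant = v)
      d1 <- oracleDistance(relabel(p$x, map), relabel(p$y, map), variant = v)
      expect_equal(d0, d1)
    }
  }
})

test_that("canonicalizeScenario performs the deletion-absorbing surgeries", {
  x <- signedString("abc")
  mkScen <- function(...) new("DupScenario", ops = list(...), totalCost = 0)

  ## internal deletion is fused into the generating op
  s1 <- canonicalizeScenario(x, mkScen(dupOp("DUP", c(1, 3), 1),
                                       dupOp("DEL", deleteSpan = c(2, 2))))
  expect_equal(length(scenarioOps(s1)), 1L)
  expect_equal(scenarioOps(s1)[[1]]@kind, "DUPDEL")
  expect_true(replayScenario(x, s1)$target == signedString("ac"))

  ## deleted prefix: never generate it
  s2 <- canonicalizeScenario(x, mkScen(dupOp("DUP", c(1, 3), 1),
                                       dupOp("DEL", deleteSpan = c(1, 1))))
  expect_equal(scenarioOps(s2)[[1]]@kind, "DUP")
  expect_equal(scenarioOps(s2)[[1]]@sourceSpan, c(2L, 3L))

  ## an op deleted in full is dropped
  s3 <- canonicalizeScenario(x, mkScen(dupOp("DUP", c(1, 2), 1),
                                       dupOp("DUP", c(3, 3), 3),
                                       dupOp("DEL", deleteSpan = c(3, 3))))
  expect_equal(length(scenarioOps(s3)), 1L)
  expect_true(replayScenario(x, s3)$target == signedString("ab"))
})

test_that("canonicalization preserves the product and never raises the cost", {
  set.seed(77)
  model <- costModel(2, 1, 3, 1, phi = c(1, 1))
  for (k in seq_len(60)) {
    x <- randomSignedString(sample(2:4, 1L), letters[1:2], signFlipProb = 0.3)
    sim <- randomScenario(x, sample(1:3, 1L), "dupinvdel", model)
    ops <- scenarioOps(sim$scenario)
    ## sprinkle free-standing deletions between the fused ops
    z <- replayScenario(x, sim$scenario, model)$target
    if (length(z) > 1L) {
      s <- sample(length(z) - 1L, 1L)
      t <- min(length(z), s + sample(0:1, 1L))
      ops[[length(ops) + 1L]] <- dupOp("DEL", deleteSpan = c(s, t))
    }
    scen <- new("DupScenario", ops = ops, totalCost = 0)
    before <- replayScenario(x, scen, model)
    canon <- canonicalizeScenario(x, scen, model)
    expect_true(all(vapply(scenarioOps(canon),
                           function(o) o@kind != "DEL", logical(1))))
    after <- replayScenario(x, canon, model)
    expect_true(after$target == before$target)
    expect_lte(after$cost, before$cost + 1e-9)
  }
})

test_that("bounded interleaved search reproduces fused-op minima", {
  m <- costModel(2, 1, phi = c(1, 1))
  for (pair in list(c("abc", "ac"), c("ab", "abab"), c("abc", "cab"),
                    c("aba", "aa"))) {
    fused <- oracleDistance(pair[1], pair[2], m, "dupdel")
    inter <- oracleDistance(pair[1], pair[2], m, "dupdel",
                            interleaved = TRUE, budget = 2L)
    expect_equal(inter, fused)
  }
})
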