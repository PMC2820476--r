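test_that("classifyPair reproduces the positional relations", {
  expect_equal(classifyPair(c(1, 3), c(2, 4)), "alternating")
  expect_equal(classifyPair(c(2, 3), c(1, 4)), "inside_S_in_T")
  expect_equal(classifyPair(c(1, 4), c(2, 3)), "inside_T_in_S")
  expect_equal(classifyPair(c(1, 2), c(3, 4)), "disjoint_ordered")
  ## multi-element overlap without a 2-2 alternating labelling
  expect_equal(classifyPair(c(1, 3, 5), c(2, 4)), "overlapping")
  expect_error(classifyPair(c(1, 2), c(2, 3)), "disjoint")
  expect_error(classifyPair(c(1, 2), c(3, 4), host = signedString("ab")),
               "exceed")
})

test_that("classifyPair agrees with a direct scan for alternating index pairs", {
  ## independent definition: S, T overlap iff some (s, s') and (t, t')
  ## alternate; brute-force over all pairs of pairs
  bruteOverlap <- function(S, T) {
    for (a in seq_along(S)) for (a2 in seq_along(S)) for (b in seq_along(T))
      for (b2 in seq_along(T))
        if (a < a2 && b < b2) {
          s <- S[a]; s2 <- S[a2]; t <- T[b]; t2 <- T[b2]
          if ((s < t && t < s2 && s2 < t2) || (t < s && s < t2 && t2 < s2))
            return(TRUE)
        }
    FALSE
  }
  set.seed(5)
  for (k in seq_len(300)) {
    host <- sample(12, sample(4:10, 1L))
    cut <- sample(length(host) - 1L, 1L)
    S <- sort(host[seq_len(cut)])
    T <- sort(host[(cut + 1L):length(host)])
    rel <- classifyPair(S, T)
    expect_equal(rel %in% c("alternating", "overlapping"), bruteOverlap(S, T),
                 info = sprintf("S=%s T=%s", toString(S), toString(T)))
  }
})

test_that("applyOperation implements the six operation kinds", {
  x <- signedString("abcd")
  z0 <- applyOperation(emptySignedString(), x, dupOp("DUP", c(2, 4), 1))
  expect_equal(as.character(z0), "bcd")
  z1 <- applyOperation(z0, x, dupOp("DUP", c(2, 3), 2))
  expect_equal(as.character(z1), "bbccd")

  expect_true(applyOperation(signedString("+a +b +c"), x,
                             dupOp("DEL", deleteSpan = c(2, 2))) ==
                signedString("+a +c"))

  xs <- signedString("+a +b +c +d +e")
  dd <- dupOp("DUPDEL", c(1, 5), 1,
              retainedSegments = rbind(c(1, 1), c(3, 3), c(5, 5)))
  expect_true(applyOperation(emptySignedString(), xs, dd) ==
                signedString("+a +c +e"))

  di <- dupOp("DUPINV", c(1, 3), 1)
  expect_true(applyOperation(emptySignedString(), xs, di) ==
                signedString("-c -b -a"))

  did <- dupOp("DUPINVDEL", c(1, 3), 1,
               retainedSegments = rbind(c(1, 1), c(3, 3)))
  expect_true(applyOperation(emptySignedString(), xs, did) ==
                signedString("-c -a"))

  xf <- signedString("+a +b +c +d +e +f")
  ds <- dupOp("DUPSUBINV", c(1, 6), 1, invertedSpan = c(3, 5))
  expect_true(applyOperation(emptySignedString(), xf, ds) ==
                signedString("+a +b -e -d -c +f"))

  expect_error(applyOperation(emptySignedString(), x,
                              dupOp("DEL", deleteSpan = c(1, 1))), "empty")
  expect_error(applyOperation(emptySignedString(), x, dupOp("DUP", c(2, 9), 1)),
               "range")
})

test_that("operationCost follows the affine formulas", {
  unit <- unitCosts()
  expect_equal(operationCost(dupOp("DUP", c(1, 3), 1), unit), 1)
  expect_equal(operationCost(dupOp("DUPINV", c(1, 4), 1),
                             costModel(1, 0, 2, 1)), 6)
  ## spanning 1..5 keeping a, c, e: Delta1 + 5*Delta2 + Phi(1) + Phi(1)
  m <- costModel(3, 1, phi = c(0, 1))
  op <- dupOp("DUPDEL", c(1, 5), 1,
              retainedSegments = rbind(c(1, 1), c(3, 3), c(5, 5)))
  expect_equal(operationCost(op, m), 10)
  ## a DUPDEL with no gaps prices exactly like the plain DUP
  for (model in list(unit, m)) {
    full <- dupOp("DUPDEL", c(2, 4), 1, retainedSegments = rbind(c(2, 4)))
    expect_equal(operationCost(full, model),
                 operationCost(dupOp("DUP", c(2, 4), 1), model))
  }
  expect_equal(operationCost(dupOp("DEL", deleteSpan = c(2, 4)), m), 3)
})

test_that("operations are canonical: no deleted prefixes or suffixes", {
  expect_error(dupOp("DUPDEL", c(1, 5), 1,
                     retainedSegments = rbind(c(2, 3), c(5, 5))),
               "flush")
  expect_error(dupOp("DUPDEL", c(1, 5), 1,
                     retainedSegments = rbind(c(1, 3), c(3, 5))),
               "disjoint")
})

test_that("replayScenario folds operations and reports generated positions", {
  x <- signedString("abcd")
  twoOp <- new("DupScenario",
              ops = list(dupOp("DUP", c(2, 4), 1), dupOp("DUP", c(2, 3), 2)),
              totalCost = 2)
  r <- replayScenario(x, twoOp)
  expect_equal(as.character(r$target), "bbccd")
  expect_equal(r$cost, 2)
  expect_equal(r$generated, list(c(1L, 4L, 5L), c(2L, 3L)))

  rootLast <- new("DupScenario",
              ops = list(dupOp("DUP", c(4, 4), 1), dupOp("DUP", c(1, 2), 2)),
              totalCost = 2)
  expect_equal(as.character(replayScenario(x, rootLast)$target), "dab")

  empty <- new("DupScenario", ops = list(), totalCost = 0)
  r0 <- replayScenario(x, empty)
  expect_equal(length(r0$target), 0L)
  expect_equal(r0$cost, 0)

  ## the source is never modified
  before <- as.character(x)
  invisible(replayScenario(x, twoOp))
  expect_equal(as.character(x), before)

  bad <- new("DupScenario", ops = list(dupOp("DUP", c(2, 4), 5)),
             totalCost = 1)
  expect_error(replayScenario(x, bad), "operation 1")
})
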