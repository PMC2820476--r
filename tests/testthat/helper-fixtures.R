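## Shared fixtures: string enumerators, the exhaustive sweep cache, and a
## distance wrapper that maps the undefined-distance condition to Inf so
## DP values can be compared with the oracle's Inf.

distanceOrInf <- function(x, y, model = unitCosts(), variant = "dup") {
  tryCatch(dupDistance(x, y, model, variant),
           undefinedDistanceError = function(e) Inf)
}

## all plain strings over `alphabet` with lengths in `lengths`
allStrings <- function(alphabet, lengths) {
  unlist(lapply(lengths, function(n) {
    if (n == 0L) return("")
    apply(do.call(expand.grid,
                  c(rep(list(alphabet), n), stringsAsFactors = FALSE)),
          1L, paste, collapse = "")
  }), use.names = FALSE)
}

## canonical representatives under alphabet relabelling: strings whose
## distinct symbols first appear in alphabet order (every (x, y) pair can
## be relabelled so that x is canonical, and all distances are invariant
## under relabelling)
canonicalStrings <- function(alphabet, lengths) {
  strs <- allStrings(alphabet, lengths)
  ok <- vapply(strsplit(strs, ""), function(s) {
    first <- unique(s)
    identical(first, alphabet[seq_along(first)])
  }, logical(1))
  strs[ok]
}

## affine non-unit cost configuration used throughout acceptance testing
affineCosts <- function()
  costModel(dupOpen = 3, dupExt = 1, invOpen = 4, invExt = 2,
            phi = c(1, 1), theta = c(1, 2))

## random signed pair generator (sizes per the small-instance guards)
randomSignedPair <- function(maxX = 4L, maxY = 4L, alphabet = letters[1:3],
                             signFlipProb = 0.4) {
  list(x = randomSignedString(sample(seq_len(maxX), 1L), alphabet,
                              signFlipProb),
       y = randomSignedString(sample(0:maxY, 1L), alphabet, signFlipProb))
}

## ---------------------------------------------------------------------
## Exhaustive sweep cache: DP and oracle values for every canonical source
## (|x| <= 4 over {a,b,c}) against every target (|y| <= 5 over {a,b,c}),
## five variants, unit and affine cost models.  Computed lazily once per
## test run and shared across test files.
## ---------------------------------------------------------------------
.sweepEnv <- new.env(parent = emptyenv())

getExhaustiveSweep <- function() {
  if (!is.null(.sweepEnv$res)) return(.sweepEnv$res)
  xs <- canonicalStrings(c("a", "b", "c"), 1:4)
  ys <- allStrings(c("a", "b", "c"), 0:5)
  variants <- c("dup", "dupdel", "dupinv", "dupinvdel", "dupsubinv")
  models <- list(unit = unitCosts(), affine = affineCosts())
  res <- list(xs = xs, ys = ys)
  for (mn in names(models)) {
    model <- models[[mn]]
    dp <- list(); orc <- list()
    for (v in variants) {
      dpM <- matrix(NA_real_, length(xs), length(ys))
      orM <- matrix(NA_real_, length(xs), length(ys))
      for (xi in seq_along(xs)) {
        x <- signedString(xs[xi], format = "plain")
        solver <- oracleSolver(x, model, v)
        for (yi in seq_along(ys)) {
          y <- signedString(ys[yi], format = "plain")
          dpM[xi, yi] <- distanceOrInf(x, y, model, v)
          orM[xi, yi] <- solver(y)
        }
      }
      dp[[v]] <- dpM; orc[[v]] <- orM
    }
    res[[mn]] <- list(dp = dp, oracle = orc)
  }
  .sweepEnv$res <- res
  res
}
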