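#' Duplication distances between a source and a target string
#'
#' `dupDistance()` computes the minimum total cost of a sequence of
#' operations that builds the target `y` from an initially empty string by
#' copying material from the immutable source `x`.  The operation set is
#' chosen by `variant`:
#'
#' \describe{
#'   \item{`"dup"`}{duplicate operations only (signs ignored); with unit
#'     costs this is the classical duplication distance.}
#'   \item{`"dupdel"`}{fused duplicate-delete operations: internal runs of
#'     the copied substring may be deleted before pasting, paying
#'     `Phi(run length)` per run (deleted characters still pay the
#'     per-character affine term).  Signs ignored.}
#'   \item{`"dupinv"`}{duplicate and duplicate-invert operations on signed
#'     strings.}
#'   \item{`"dupinvdel"`}{duplicate-delete and duplicate-invert-delete.}
#'   \item{`"dupsubinv"`}{duplicate-delete where any single substring of
#'     the source span may first be inverted in place, paying `Theta(l)`.}
#' }
#'
#' The distance is undefined (an error of class `undefinedDistanceError`)
#' when some character of `y` cannot be generated from `x` under the
#' variant's matching rule.
#'
#' @param x,y source and target: [SignedString-class] objects or strings
#'   accepted by [signedString()].
#' @param model a [CostModel-class]; defaults to unit costs.
#' @param variant one of `"dup"`, `"dupdel"`, `"dupinv"`, `"dupinvdel"`,
#'   `"dupsubinv"`.
#' @param details if TRUE, return a list with the cost and the number of
#'   memoized states evaluated (for complexity diagnostics).
#' @return the minimum cost (or a list when `details = TRUE`).
#' @examples
#' dupDistance("abcd", "bbccd")                       # 2
#' dupDistance("abcde", "ace", costModel(3, 1, phi = c(0, 1)),
#'             variant = "dupdel")                    # 10
#' dupDistance("+a +b +c", "-c -b -a", variant = "dupinv")  # 1
#' @seealso [dupTraceback()] for the optimal scenario, [oracleDistance()]
#'   for the brute-force reference on tiny instances.
#' @export
dupDistance <- function(x, y, model = unitCosts(),
                        variant = c("dup", "dupdel", "dupinv", "dupinvdel",
                                    "dupsubinv"),
                        details = FALSE) {
  variant <- match.arg(variant)
  x <- signedString(x); y <- signedString(y)
  sol <- dpSolve(x, y, model, variant)
  if (!details) return(sol$value)
  st <- sol$stateCount()
  list(cost = sol$value, freeStates = st$free, chainStates = st$chain,
       channels = length(sol$channels))
}

#' @rdname dupDistance
#' @export
duplicationDistance <- function(x, y, model = unitCosts(), details = FALSE)
  dupDistance(x, y, model, "dup", details)

#' @rdname dupDistance
#' @export
duplicationDeletionDistance <- function(x, y, model = unitCosts(),
                                        details = FALSE)
  dupDistance(x, y, model, "dupdel", details)

#' @rdname dupDistance
#' @export
duplicationInversionDistance <- function(x, y, model = unitCosts(),
                                         details = FALSE)
  dupDistance(x, y, model, "dupinv", details)

#' @rdname dupDistance
#' @export
duplicationInversionDeletionDistance <- function(x, y, model = unitCosts(),
                                                 details = FALSE)
  dupDistance(x, y, model, "dupinvdel", details)

#' @rdname dupDistance
#' @export
duplicationSubinvDeletionDistance <- function(x, y, model = unitCosts(),
                                              details = FALSE)
  dupDistance(x, y, model, "dupsubinv", details)

#' Optimal scenario by traceback
#'
#' Reconstructs one minimum-cost sequence of operations achieving
#' [dupDistance()].  Ties are broken deterministically (terminate the
#' current operation rather than extend it; then smallest split position;
#' then smallest source index), so repeated runs give identical scenarios.
#' Operations are emitted outermost-first: replaying them with
#' [replayScenario()] reproduces `y` at the DP cost -- exactly for the
#' signed variants, and up to orientation for the sign-free variants
#' (`"dup"`, `"dupdel"`), where copied characters keep the source's signs
#' while matching is on symbols alone.
#'
#' @inheritParams dupDistance
#' @return a [DupScenario-class].
#' @examples
#' sc <- dupTraceback("abcd", "bbccd")
#' replayScenario(signedString("abcd"), sc)$target
#' @export
dupTraceback <- function(x, y, model = unitCosts(),
                         variant = c("dup", "dupdel", "dupinv", "dupinvdel",
                                     "dupsubinv")) {
  variant <- match.arg(variant)
  x <- signedString(x); y <- signedString(y)
  sol <- dpSolve(x, y, model, variant)
  assembleScenario(sol$traceback(), sol$channels, variant, model)
}

#' Replay a scenario
#'
#' Folds the operations of a scenario over the empty string against the
#' source `x`, validating each step, and sums the operation costs.  When
#' the scenario contains no DEL operation, the positions in the final
#' target generated by each operation are also returned; by the
#' non-overlapping property these position sets are pairwise
#' non-overlapping subsequences of the result.
#'
#' @param x the source [SignedString-class].
#' @param scenario a [DupScenario-class] (its stored `totalCost` is not
#'   consulted; costs are recomputed).
#' @param model a [CostModel-class] used to price the operations.
#' @return list with `target` (SignedString), `cost` (number), and
#'   `generated` (list of integer position vectors, or NULL if any DEL
#'   operation is present).
#' @export
replayScenario <- function(x, scenario, model = unitCosts()) {
  x <- signedString(x)
  z <- emptySignedString()
  origin <- integer(0)
  cost <- 0
  hasDel <- FALSE
  for (k in seq_along(scenario@ops)) {
    op <- scenario@ops[[k]]
    res <- tryCatch(applyOperation(z, x, op), error = function(e)
      stop(sprintf("operation %d (%s) failed during replay: %s",
                   k, op@kind, conditionMessage(e)), call. = FALSE))
    if (op@kind == "DEL") {
      hasDel <- TRUE
      origin <- origin[-(op@deleteSpan[1]:op@deleteSpan[2])]
    } else {
      p <- op@insertPos
      ins <- length(res) - length(z)
      origin <- append(origin, rep(k, ins), after = p - 1L)
    }
    z <- res
    cost <- cost + operationCost(op, model)
  }
  generated <- if (hasDel) NULL
  else lapply(seq_along(scenario@ops), function(k) which(origin == k))
  list(target = z, cost = cost, generated = generated)
}

#' @export
setMethod("show", "DupScenario", function(object) {
  cat(sprintf("DupScenario: %d op(s), total cost %g\n",
              length(object@ops), object@totalCost))
  for (op in object@ops) show(op)
})

#' @rdname DupScenario-class
#' @export
setMethod("scenarioOps", "DupScenario", function(x) x@ops)

#' @rdname DupScenario-class
#' @export
setMethod("totalCost", "DupScenario", function(x) x@totalCost)
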