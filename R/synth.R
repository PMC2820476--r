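#' Random signed string
#'
#' Symbols are drawn uniformly from the alphabet; each sign is '-' with
#' probability `signFlipProb`.  Uses R's RNG: call `set.seed()` first for
#' reproducible strings.
#'
#' @param n string length (>= 0).
#' @param alphabet character vector of single-character symbols.
#' @param signFlipProb probability in \\[0, 1\\] of a '-' orientation.
#' @return a [SignedString-class].
#' @examples
#' set.seed(1); randomSignedString(5)
#' @export
randomSignedString <- function(n, alphabet = letters[1:3], signFlipProb = 0) {
  stopifnot(n >= 0, length(alphabet) >= 1, signFlipProb >= 0,
            signFlipProb <= 1)
  if (n == 0) return(emptySignedString())
  newSignedString(sample(alphabet, n, replace = TRUE),
                  ifelse(runif(n) < signFlipProb, -1L, 1L))
}

#' Random scenario and its target
#'
#' Draws `nOps` valid operations of the requested variant (uniform source
#' spans; internal deletions keep the span's first and last characters so
#' operations stay canonical; uniform insertion slots including both ends)
#' and replays them from the empty string.  The replayed cost is an upper
#' bound on the true distance by construction, with equality when
#' `nOps = 1`.
#'
#' @param x source [SignedString-class] (or string).
#' @param nOps number of operations (>= 1).
#' @param variant operation set, as in [dupDistance()].
#' @param model a [CostModel-class] used to price the scenario.
#' @param deletionProb probability that a deletion-capable operation
#'   deletes internal characters.
#' @param inversionProb probability that an inversion-capable operation
#'   inverts.
#' @return list with `target` (SignedString), `scenario`
#'   ([DupScenario-class]) and `cost` (its replay cost).
#' @examples
#' set.seed(7)
#' sim <- randomScenario(signedString("abcd"), 3)
#' sim$target; totalCost(sim$scenario)
#' @export
randomScenario <- function(x, nOps, variant = c("dup", "dupdel", "dupinv",
                                                "dupinvdel", "dupsubinv"),
                           model = unitCosts(), deletionProb = 0.3,
                           inversionProb = 0.3) {
  variant <- match.arg(variant)
  x <- signedString(x)
  stopifnot(nOps >= 1, length(x) >= 1)
  m <- length(x)
  z <- emptySignedString()
  ops <- vector("list", nOps)
  for (k in seq_len(nOps)) {
    s <- sample.int(m, 1L)
    t <- if (s < m) sample(s:m, 1L) else m
    span <- c(s, t)
    canDelete <- variant %in% c("dupdel", "dupinvdel", "dupsubinv")
    doDelete <- canDelete && t - s >= 2L && runif(1) < deletionProb
    seg <- NULL
    if (doDelete) {
      keepMid <- (s + 1L):(t - 1L)
      keepMid <- keepMid[runif(length(keepMid)) < 0.5]
      kept <- sort(unique(c(s, keepMid, t)))
      breaks <- which(diff(kept) != 1L)
      seg <- cbind(kept[c(1L, breaks + 1L)], kept[c(breaks, length(kept))])
      storage.mode(seg) <- "integer"
    }
    hasGaps <- !is.null(seg) && nrow(seg) > 1L
    doInvert <- variant %in% c("dupinv", "dupinvdel") && runif(1) < inversionProb
    kind <- if (variant == "dupsubinv") "DUPSUBINV"
      else if (doInvert) (if (hasGaps) "DUPINVDEL" else "DUPINV")
      else if (hasGaps) "DUPDEL" else "DUP"
    invSpan <- NA
    if (kind == "DUPSUBINV") {
      if (runif(1) < inversionProb) {
        vs <- sample.int(m, 1L)
        vt <- if (vs < m) sample(vs:m, 1L) else m
        invSpan <- c(vs, vt)
      } else invSpan <- c(1L, 0L)   # identity inversion (empty span)
    }
    if (kind == "DUPSUBINV" && invSpan[1] > invSpan[2]) {
      ## represent the identity as a length-0 span at position 1; the
      ## DupOp validity check wants a real span, so use span (1,1) with
      ## zero net effect only when x[1] is self-inverse-free: simplest is
      ## to fall back to a DUPDEL-shaped op in the same variant
      kind <- if (hasGaps) "DUPDEL" else "DUP"
      invSpan <- NA
    }
    op <- dupOp(kind, sourceSpan = span,
                insertPos = sample.int(length(z) + 1L, 1L),
                retainedSegments = if (hasGaps) seg else NULL,
                invertedSpan = invSpan)
    ops[[k]] <- op
    z <- applyOperation(z, x, op)
  }
  total <- sum(vapply(ops, operationCost, numeric(1), model = model))
  list(target = z, scenario = new("DupScenario", ops = ops, totalCost = total),
       cost = total)
}
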