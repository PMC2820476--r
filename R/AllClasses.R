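#' @import methods
NULL

#' SignedString: a sequence of oriented characters
#'
#' A signed string of length m over an alphabet Sigma is an element of
#' ({+, -} x Sigma)^m.  Every string handled by this package is a
#' `SignedString`; plain (unsigned) input is lifted to all-'+' orientation.
#' Inverting a signed string reverses the character order and flips every
#' sign.
#'
#' @slot symbol character vector of single-character symbols.
#' @slot sign integer vector of +1/-1 orientations, same length as `symbol`.
#'
#' @seealso [signedString()], [invert()], [readSignedString()]
#' @export
setClass("SignedString",
  representation(symbol = "character", sign = "integer"),
  prototype(symbol = character(0), sign = integer(0)))

setValidity("SignedString", function(object) {
  if (length(object@symbol) != length(object@sign))
    return("symbol and sign must have equal length")
  if (length(object@symbol) && any(is.na(object@symbol) | nchar(object@symbol) != 1L))
    return("symbols must be single non-NA characters")
  if (length(object@sign) && !all(object@sign %in% c(-1L, 1L)))
    return("signs must be +1 or -1")
  TRUE
})

#' CostModel: operation costs for the duplication distance family
#'
#' Duplicate operations have affine cost Delta1 + l * Delta2 in the copied
#' length l; duplicate-invert operations cost Theta1 + l * Theta2.  Deleting
#' a run of length g (inside a fused duplicate-delete) costs Phi(g), which
#' must be non-decreasing and subadditive (triangle inequality).  In the
#' substring-inversion variant, inverting an in-place span of length l in
#' the source costs ThetaSub(l), non-negative and non-decreasing with
#' ThetaSub(0) = 0.
#'
#' @slot dupOpen,dupExt non-negative affine duplication costs (Delta1, Delta2).
#' @slot invOpen,invExt non-negative affine inverted-duplication costs
#'   (Theta1, Theta2).
#' @slot delCost function(length) -> cost for a deleted run (Phi).
#' @slot subinvCost function(length) -> cost of an in-place substring
#'   inversion (Theta), with `subinvCost(0) == 0`.
#'
#' @seealso [costModel()], [unitCosts()]
#' @export
setClass("CostModel",
  representation(dupOpen = "numeric", dupExt = "numeric",
                 invOpen = "numeric", invExt = "numeric",
                 delCost = "function", subinvCost = "function"))

setValidity("CostModel", function(object) {
  par <- c(object@dupOpen, object@dupExt, object@invOpen, object@invExt)
  if (length(par) != 4L || any(is.na(par)) || any(par < 0))
    return("affine cost parameters must be single non-negative numbers")
  ## shape checks on the callables: exact validation is only possible for
  ## the affine constructors, so arbitrary functions are spot-checked.
  g <- vapply(1:16, object@delCost, numeric(1))
  if (any(g < 0)) return("delCost must be non-negative")
  if (any(diff(g) < -1e-9)) return("delCost must be non-decreasing")
  for (a in 1:8) for (b in 1:8)
    if (g[a + b] > g[a] + g[b] + 1e-9)
      return("delCost must be subadditive (triangle inequality)")
  th <- vapply(0:16, object@subinvCost, numeric(1))
  if (th[1] != 0) return("subinvCost(0) must be 0")
  if (any(th < 0) || any(diff(th) < -1e-9))
    return("subinvCost must be non-negative and non-decreasing")
  TRUE
})

#' DupOp: a single replayable operation
#'
#' Tagged union of the six operation kinds: `"DUP"` (duplicate a source
#' substring), `"DEL"` (delete a substring of the intermediate target),
#' `"DUPDEL"` (duplicate with internal runs deleted before pasting),
#' `"DUPINV"` (duplicate and invert), `"DUPINVDEL"` (duplicate, invert,
#' delete internal runs), and `"DUPSUBINV"` (duplicate with an in-place
#' substring inversion of the source span, then internal deletions).
#'
#' Spans are 1-based inclusive.  `retainedSegments` is a k x 2 matrix of
#' ordered disjoint spans whose first span starts at `sourceSpan[1]` and
#' last span ends at `sourceSpan[2]` (the canonical form: deletions at the
#' copied span's ends are expressed by shrinking the span itself).  For
#' `"DUPSUBINV"`, segment coordinates refer to the source *after* its
#' `invertedSpan` has been inverted in place.
#'
#' @slot kind one of DUP, DEL, DUPDEL, DUPINV, DUPINVDEL, DUPSUBINV.
#' @slot sourceSpan integer(2) span into the source x (NA for DEL).
#' @slot retainedSegments integer k x 2 matrix (zero rows when unused).
#' @slot invertedSpan integer(2) in-place inverted span (DUPSUBINV only;
#'   NA elsewhere).
#' @slot insertPos 1-based insertion position into the intermediate target,
#'   in 1..(length(z)+1) (NA for DEL).
#' @slot deleteSpan integer(2) span into the intermediate target (DEL only).
#' @export
setClass("DupOp",
  representation(kind = "character", sourceSpan = "integer",
                 retainedSegments = "matrix", invertedSpan = "integer",
                 insertPos = "integer", deleteSpan = "integer"))

setValidity("DupOp", function(object) {
  kinds <- c("DUP", "DEL", "DUPDEL", "DUPINV", "DUPINVDEL", "DUPSUBINV")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  seg <- object@retainedSegments
  if (!is.integer(seg) || ncol(seg) != 2L)
    return("retainedSegments must be an integer k x 2 matrix")
  if (object@kind == "DEL") {
    d <- object@deleteSpan
    if (length(d) != 2L || any(is.na(d)) || d[1] > d[2] || d[1] < 1L)
      return("DEL needs a valid deleteSpan")
    return(TRUE)
  }
  s <- object@sourceSpan
  if (length(s) != 2L || any(is.na(s)) || s[1] > s[2] || s[1] < 1L)
    return("sourceSpan must be a valid 1-based inclusive span")
  if (length(object@insertPos) != 1L || is.na(object@insertPos) ||
      object@insertPos < 1L)
    return("insertPos must be a positive position")
  if (nrow(seg)) {
    if (seg[1, 1] != s[1] || seg[nrow(seg), 2] != s[2])
      return("retained segments must start/end flush with sourceSpan (canonical form)")
    if (any(seg[, 1] > seg[, 2]))
      return("retained segments must have start <= end")
    if (nrow(seg) > 1L && any(seg[-1L, 1] <= seg[-nrow(seg), 2]))
      return("retained segments must be ordered and disjoint")
  }
  if (object@kind == "DUPSUBINV") {
    v <- object@invertedSpan
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2] || v[1] < 1L)
      return("DUPSUBINV needs a valid invertedSpan")
  }
  TRUE
})

#' DupScenario: an ordered list of operations with its total cost
#'
#' The product of [dupTraceback()] and input to [replayScenario()]:
#' replaying `ops` from the empty string against the source must reproduce
#' the target, and the summed operation costs must equal `totalCost`.
#'
#' @slot ops list of [DupOp-class] objects, applied left to right.
#' @slot totalCost non-negative number.
#' @export
setClass("DupScenario",
  representation(ops = "list", totalCost = "numeric"))

setValidity("DupScenario", function(object) {
  if (!all(vapply(object@ops, is, logical(1), "DupOp")))
    return("ops must all be DupOp objects")
  if (length(object@totalCost) != 1L || is.na(object@totalCost) ||
      object@totalCost < 0)
    return("totalCost must be a single non-negative number")
  TRUE
})

#' DupGrammar: the context-free grammar G_x of a source string
#'
#' For a fixed source x, G_x has one nontrivial production
#' S -> x_i S x_{i+1} S ... S x_j S for every span 1 <= i <= j <= |x|
#' (the restricted form, with no leading S), plus the trivial production
#' S -> epsilon; hence |x|(|x|+1)/2 + 1 rules in total.  The language of
#' G_x is exactly the set of strings buildable from x by duplicate
#' operations, and the minimum number of nontrivial productions in a parse
#' of y equals the unit-cost duplication distance d(x, y).
#'
#' @slot source the source [SignedString-class].
#' @slot rules integer matrix with columns i, j; one row per nontrivial
#'   production, ordered by i then j.
#' @export
setClass("DupGrammar",
  representation(source = "SignedString", rules = "matrix"))

#' DupParseTree: a derivation of y under G_x
#'
#' Each node applies one nontrivial production S -> x_i S x_{i+1} S ... x_j S
#' (`span = c(i, j)`); `children` holds one subtree per S slot (the slot
#' after each copied character, the last one deriving the suffix), with
#' `NULL` standing for the trivial production S -> epsilon.  `positions`
#' records the 1-based positions in the final target generated by this
#' node's own production.  The empty tree (target = empty string) has
#' `span = NA`.
#'
#' @slot span integer(2) source span copied by the root production (NA for
#'   the epsilon tree).
#' @slot children list of `DupParseTree` or NULL, one per S slot.
#' @slot positions integer positions in y generated by the root production.
#' @export
setClass("DupParseTree",
  representation(span = "integer", children = "list", positions = "integer"))
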