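#' Emit the duplication grammar G_x
#'
#' For a source x of length m, G_x has one nontrivial production
#' `S -> x_i S x_{i+1} S ... x_j S` per span 1 <= i <= j <= m (restricted
#' form: no leading S, so the first character of any derived string is
#' produced by the first rule applied) plus the trivial `S -> epsilon`,
#' giving m(m+1)/2 + 1 rules.  Its language is exactly the set of strings
#' buildable from x by duplicate operations.
#'
#' @param x source string (coerced via [signedString()]); must be
#'   nonempty.
#' @return a [DupGrammar-class].
#' @examples
#' g <- dupGrammar("ab")
#' ruleCount(g)       # 4
#' formatRules(g)
#' @export
dupGrammar <- function(x) {
  x <- signedString(x)
  if (!length(x)) stop("the grammar is defined for a nonempty source")
  m <- length(x)
  rules <- do.call(rbind, lapply(seq_len(m), function(i)
    cbind(i, i:m)))
  storage.mode(rules) <- "integer"
  colnames(rules) <- c("i", "j")
  new("DupGrammar", source = x, rules = rules)
}

#' @rdname DupGrammar-class
#' @export
setMethod("ruleCount", "DupGrammar", function(x) nrow(x@rules) + 1L)

#' @rdname DupGrammar-class
#' @export
setMethod("formatRules", "DupGrammar", function(x) {
  sym <- symbols(x@source)
  body <- apply(x@rules, 1L, function(r)
    paste(c(rbind(sym[r[1]:r[2]], "S")), collapse = " "))
  c(paste("S ->", body), "S -> ε")
})

#' @export
setMethod("show", "DupGrammar", function(object) {
  cat(sprintf("DupGrammar over source '%s': %d rules\n",
              as.character(object@source), ruleCount(object)))
})

#' Minimum-production parse of a target under G_x
#'
#' Finds a parse tree of `y` under the restricted grammar of [dupGrammar()]
#' with the minimum number of nontrivial productions; that count equals
#' the unit-cost duplication distance d(x, y).  The parse reuses the
#' distance recurrence's traceback (the recurrence *is* the parse: the
#' subtree below the first production's slot between x_i and x_{i+1}
#' derives y_{2,j-1}) rather than a generic chart parser.
#'
#' @param x,y source and target (coerced via [signedString()]).
#' @return a [DupParseTree-class]; the epsilon tree for empty `y`.
#' @examples
#' tr <- minProductionParse("abcd", "bbccd")
#' nontrivialProductions(tr)  # 2
#' @export
minProductionParse <- function(x, y) {
  x <- signedString(x); y <- signedString(y)
  sol <- dpSolve(x, y, costModel(1, 0), "dup")
  records <- sol$traceback()
  if (!length(records))
    return(new("DupParseTree", span = NA_integer_, children = list(),
               positions = integer(0)))
  mins <- vapply(records, function(r) min(r$pos), numeric(1))
  build <- function(lo, hi) {
    if (lo > hi) return(NULL)
    k <- which(mins == lo)
    stopifnot(length(k) == 1L)
    rec <- records[[k]]
    pos <- rec$pos
    kids <- vector("list", length(pos))
    for (r in seq_along(pos)) {
      from <- pos[r] + 1L
      to <- if (r < length(pos)) pos[r + 1L] - 1L else hi
      kids[[r]] <- build(from, to)
    }
    new("DupParseTree", span = c(min(rec$src), max(rec$src)),
        children = kids, positions = as.integer(pos))
  }
  build(1L, length(y))
}

#' @rdname nontrivialProductions
#' @export
setMethod("nontrivialProductions", "DupParseTree", function(x) {
  if (anyNA(x@span)) return(0L)
  1L + sum(vapply(x@children, function(ch)
    if (is.null(ch)) 0L else nontrivialProductions(ch), integer(1)))
})

#' @export
setMethod("show", "DupParseTree", function(object) {
  render <- function(node, indent) {
    if (is.null(node) || anyNA(node@span)) {
      cat(strrep("  ", indent), "S -> ε\n", sep = "")
      return(invisible(NULL))
    }
    cat(strrep("  ", indent),
        sprintf("S -> x[%d..%d] (y positions %s)\n", node@span[1],
                node@span[2], paste(node@positions, collapse = ",")),
        sep = "")
    for (ch in node@children)
      if (!is.null(ch)) render(ch, indent + 1L)
  }
  cat(sprintf("DupParseTree: %d nontrivial production(s)\n",
              nontrivialProductions(object)))
  render(object, 0L)
})

#' Convert a parse tree to a duplication scenario
#'
#' Each nontrivial production becomes one unit-cost DUP operation; parents
#' are emitted before the subtrees filling their slots (outermost-first),
#' so the scenario replays to exactly the parsed string with cost equal to
#' the nontrivial-production count.
#'
#' @param tree a [DupParseTree-class].
#' @param model a [CostModel-class] used to price the DUP operations.
#' @return a [DupScenario-class].
#' @export
parseTreeToScenario <- function(tree, model = costModel(1, 0)) {
  records <- list()
  walk <- function(node) {
    if (is.null(node) || anyNA(node@span)) return(invisible(NULL))
    records[[length(records) + 1L]] <<-
      list(span = node@span, pos = node@positions)
    for (ch in node@children) walk(ch)
  }
  walk(tree)
  if (!length(records))
    return(new("DupScenario", ops = list(), totalCost = 0))
  records <- records[order(vapply(records, function(r) min(r$pos), numeric(1)))]
  placed <- integer(0)
  ops <- list(); total <- 0
  for (rec in records) {
    op <- dupOp("DUP", sourceSpan = rec$span,
                insertPos = sum(placed < min(rec$pos)) + 1L)
    placed <- c(placed, rec$pos)
    total <- total + operationCost(op, model)
    ops[[length(ops) + 1L]] <- op
  }
  new("DupScenario", ops = ops, totalCost = total)
}
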