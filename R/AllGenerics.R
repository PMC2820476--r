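#' Invert a signed string
#'
#' The inverse of x = x_1 ... x_m is -x_m ... -x_1: character order is
#' reversed and every sign is flipped.  Inversion is an involution.
#'
#' @param x a [SignedString-class].
#' @return a [SignedString-class].
#' @examples
#' invert(signedString("+b -c -a +d"))  # (-d +a +c -b)
#' @export
setGeneric("invert", function(x) standardGeneric("invert"))

#' @rdname SignedString-class
#' @param x a SignedString.
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))

#' @rdname SignedString-class
#' @export
setGeneric("signs", function(x) standardGeneric("signs"))

#' @rdname DupScenario-class
#' @param x a DupScenario.
#' @export
setGeneric("scenarioOps", function(x) standardGeneric("scenarioOps"))

#' @rdname DupScenario-class
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))

#' @rdname DupGrammar-class
#' @param x a DupGrammar.
#' @export
setGeneric("ruleCount", function(x) standardGeneric("ruleCount"))

#' @rdname DupGrammar-class
#' @export
setGeneric("formatRules", function(x) standardGeneric("formatRules"))

#' Count nontrivial productions in a parse tree
#'
#' The number of non-epsilon productions in a [DupParseTree-class]; for a
#' minimum parse this equals the unit-cost duplication distance.
#'
#' @param x a [DupParseTree-class].
#' @return integer count.
#' @export
setGeneric("nontrivialProductions",
           function(x) standardGeneric("nontrivialProductions"))
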