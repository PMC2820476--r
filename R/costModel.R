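#' Build a cost model
#'
#' @param dupOpen,dupExt affine duplicate cost Delta1 + l * Delta2.
#' @param invOpen,invExt affine duplicate-invert cost Theta1 + l * Theta2.
#' @param phi deletion cost Phi: `"unit"` (1 per deleted run), a numeric
#'   pair `c(phi0, phi1)` for the affine form phi0 + phi1 * l (validated
#'   exactly: both non-negative makes Phi non-decreasing and subadditive),
#'   or an arbitrary function of the run length (spot-checked on lengths
#'   1..16, with a warning that validation is only partial).
#' @param theta in-place substring-inversion cost Theta(l) for the
#'   substring-inversion variant: `"zero"`, a numeric pair `c(theta0,
#'   theta1)` meaning theta0 + theta1 * l for l >= 1 (and 0 at l = 0), or
#'   a function.
#' @return a [CostModel-class].
#' @examples
#' unitCosts()
#' costModel(dupOpen = 3, dupExt = 1, phi = c(0, 1))
#' @export
costModel <- function(dupOpen = 1, dupExt = 0, invOpen = dupOpen,
                      invExt = dupExt, phi = "unit", theta = "zero") {
  delCost <- makeLengthCost(phi, kind = "phi")
  subinvCost <- makeLengthCost(theta, kind = "theta")
  new("CostModel", dupOpen = as.numeric(dupOpen), dupExt = as.numeric(dupExt),
      invOpen = as.numeric(invOpen), invExt = as.numeric(invExt),
      delCost = delCost, subinvCost = subinvCost)
}

makeLengthCost <- function(spec, kind) {
  if (is.function(spec)) {
    warning(sprintf("arbitrary %s cost function: shape only spot-checked on small lengths",
                    kind), call. = FALSE)
    return(spec)
  }
  if (identical(spec, "unit"))
    return(function(l) as.numeric(l > 0))
  if (identical(spec, "zero"))
    return(function(l) 0)
  if (is.numeric(spec) && length(spec) == 2L) {
    if (any(spec < 0)) stop(kind, " affine parameters must be non-negative")
    a <- spec[1]; b <- spec[2]
    return(function(l) ifelse(l > 0, a + b * l, 0))
  }
  stop("cannot interpret ", kind, " cost specification")
}

#' Unit operation costs
#'
#' Delta1 = Theta1 = 1, Delta2 = Theta2 = 0, Phi = 1 per delete, Theta = 0:
#' every operation costs 1 and the distances count operations, as in the
#' basic duplication-distance definition.
#' @return a [CostModel-class].
#' @export
unitCosts <- function() costModel(1, 0, 1, 0, phi = "unit", theta = "zero")

#' @export
setMethod("show", "CostModel", function(object) {
  cat(sprintf(paste0("CostModel: dup %g + l*%g, inv %g + l*%g, ",
                     "Phi(1..3) = %s, Theta(1..3) = %s\n"),
              object@dupOpen, object@dupExt, object@invOpen, object@invExt,
              paste(vapply(1:3, object@delCost, numeric(1)), collapse = ","),
              paste(vapply(1:3, object@subinvCost, numeric(1)), collapse = ",")))
})

#' @rdname CostModel-class
#' @param x a CostModel.
#' @export
dupOpen <- function(x) x@dupOpen
#' @rdname CostModel-class
#' @export
dupExt <- function(x) x@dupExt
#' @rdname CostModel-class
#' @export
invOpen <- function(x) x@invOpen
#' @rdname CostModel-class
#' @export
invExt <- function(x) x@invExt
#' @rdname CostModel-class
#' @export
delCost <- function(x) x@delCost
#' @rdname CostModel-class
#' @export
subinvCost <- function(x) x@subinvCost
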