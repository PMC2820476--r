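#' Construct an operation
#'
#' @param kind one of `"DUP"`, `"DEL"`, `"DUPDEL"`, `"DUPINV"`,
#'   `"DUPINVDEL"`, `"DUPSUBINV"`.
#' @param sourceSpan integer(2), 1-based inclusive span into the source x
#'   (all kinds but DEL).
#' @param insertPos 1-based position p: the copied material is pasted
#'   before the current p-th character of the intermediate target, so
#'   p ranges over 1..(length(z)+1).
#' @param retainedSegments k x 2 matrix of retained spans (DUPDEL,
#'   DUPINVDEL, DUPSUBINV); defaults to the whole `sourceSpan`.
#' @param invertedSpan integer(2) in-place inverted span of the source
#'   (DUPSUBINV only).
#' @param deleteSpan integer(2) span deleted from the intermediate target
#'   (DEL only).
#' @return a [DupOp-class].
#' @examples
#' dupOp("DUP", sourceSpan = c(2, 4), insertPos = 1)
#' @export
dupOp <- function(kind, sourceSpan = NA, insertPos = NA,
                  retainedSegments = NULL, invertedSpan = NA,
                  deleteSpan = NA) {
  if (is.null(retainedSegments)) {
    retainedSegments <-
      if (kind %in% c("DUPDEL", "DUPINVDEL", "DUPSUBINV") &&
          !anyNA(sourceSpan))
        matrix(as.integer(sourceSpan), 1L, 2L)
      else matrix(integer(0), 0L, 2L)
  }
  storage.mode(retainedSegments) <- "integer"
  new("DupOp", kind = kind, sourceSpan = as.integer(sourceSpan),
      retainedSegments = retainedSegments,
      invertedSpan = as.integer(invertedSpan),
      insertPos = as.integer(insertPos), deleteSpan = as.integer(deleteSpan))
}

#' @export
setMethod("show", "DupOp", function(object) {
  if (object@kind == "DEL") {
    cat(sprintf("DEL z[%d..%d]\n", object@deleteSpan[1], object@deleteSpan[2]))
    return(invisible(NULL))
  }
  seg <- object@retainedSegments
  segtxt <- if (nrow(seg) > 1L)
    paste0(" keep {", paste(sprintf("%d..%d", seg[, 1], seg[, 2]),
                            collapse = ", "), "}")
  else ""
  inv <- if (object@kind == "DUPSUBINV")
    sprintf(" inv[%d..%d]", object@invertedSpan[1], object@invertedSpan[2])
  else ""
  cat(sprintf("%s x[%d..%d]%s%s -> pos %d\n", object@kind,
              object@sourceSpan[1], object@sourceSpan[2], inv, segtxt,
              object@insertPos))
})

## gap run lengths between consecutive retained segments
segmentGaps <- function(seg) {
  if (nrow(seg) < 2L) return(integer(0))
  seg[-1L, 1] - seg[-nrow(seg), 2] - 1L
}

## the signed string an operation pastes into the target
opInsertString <- function(x, op) {
  seg <- op@retainedSegments
  takeSegments <- function(s) {
    idx <- unlist(lapply(seq_len(nrow(seg)), function(r) seg[r, 1]:seg[r, 2]))
    s[idx]
  }
  switch(op@kind,
    DUP = x[op@sourceSpan[1]:op@sourceSpan[2]],
    DUPDEL = takeSegments(x),
    DUPINV = invert(x[op@sourceSpan[1]:op@sourceSpan[2]]),
    DUPINVDEL = invert(takeSegments(x)),
    DUPSUBINV = takeSegments(subInvert(x, op@invertedSpan[1],
                                       op@invertedSpan[2])),
    stop("no insert string for kind ", op@kind))
}

#' Apply one operation to an intermediate target
#'
#' Replays `op` against the current intermediate target `z`, copying from
#' the immutable source `x`.  DUP pastes x[s..t] at position p; DEL removes
#' z[s..t]; DUPDEL pastes the concatenation of retained segments; DUPINV
#' pastes the inverse of x[s..t]; DUPINVDEL pastes the inverse of the
#' retained subsequence; DUPSUBINV inverts `invertedSpan` of x in place and
#' pastes the retained segments of the result.
#'
#' @param z intermediate target [SignedString-class].
#' @param x source [SignedString-class] (never modified).
#' @param op a [DupOp-class].
#' @return the new intermediate target.
#' @examples
#' x <- signedString("abcd")
#' applyOperation(emptySignedString(), x, dupOp("DUP", c(2, 4), 1))
#' @export
applyOperation <- function(z, x, op) {
  validObject(op)
  if (op@kind == "DEL") {
    s <- op@deleteSpan[1]; t <- op@deleteSpan[2]
    if (length(z) == 0L) stop("DEL on empty target")
    if (s < 1L || t > length(z)) stop("deleteSpan out of range")
    return(z[setdiff(seq_len(length(z)), s:t)])
  }
  if (op@sourceSpan[2] > length(x)) stop("sourceSpan out of range")
  p <- op@insertPos
  if (p < 1L || p > length(z) + 1L) stop("insertPos out of range")
  ins <- opInsertString(x, op)
  n <- length(z)
  c(z[seq_len(p - 1L)], ins, if (p <= n) z[p:n] else emptySignedString())
}

#' Cost of one operation
#'
#' DUP costs Delta1 + l * Delta2 for span length l; DEL costs Phi(l);
#' DUPDEL costs Delta1 + l * Delta2 plus Phi of every deleted internal run
#' (deleted characters still pay Delta2: the affine term spans the whole
#' copied substring); DUPINV and DUPINVDEL are the Theta analogues;
#' DUPSUBINV costs Delta1 + l * Delta2 + Theta(|invertedSpan|) plus the
#' run deletions.
#'
#' @param op a [DupOp-class].
#' @param model a [CostModel-class].
#' @return a non-negative number.
#' @export
operationCost <- function(op, model = unitCosts()) {
  if (op@kind == "DEL")
    return(model@delCost(op@deleteSpan[2] - op@deleteSpan[1] + 1L))
  l <- op@sourceSpan[2] - op@sourceSpan[1] + 1L
  gaps <- segmentGaps(op@retainedSegments)
  gapCost <- if (length(gaps)) sum(vapply(gaps, model@delCost, numeric(1))) else 0
  switch(op@kind,
    DUP = model@dupOpen + l * model@dupExt,
    DUPDEL = model@dupOpen + l * model@dupExt + gapCost,
    DUPINV = model@invOpen + l * model@invExt,
    DUPINVDEL = model@invOpen + l * model@invExt + gapCost,
    DUPSUBINV = model@dupOpen + l * model@dupExt + gapCost +
      model@subinvCost(max(0L, op@invertedSpan[2] - op@invertedSpan[1] + 1L)))
}

#' Classify the positional relation of two subsequences
#'
#' Subsequences S and T of a common host (given as strictly increasing
#' index vectors with disjoint index sets) are *alternating* when
#' s < t < s' < t' (or with roles swapped) for the two-element case;
#' *overlapping* when some pair of S indices and some pair of T indices
#' alternate; *inside* when one subsequence lies entirely between two
#' successive indices of the other; and *disjoint_ordered* when their
#' ranges do not intersect.
#'
#' @param S,T strictly increasing integer index vectors, disjoint sets.
#' @param host optional [SignedString-class] for bounds checking.
#' @return one of `"alternating"`, `"overlapping"`, `"inside_S_in_T"`,
#'   `"inside_T_in_S"`, `"disjoint_ordered"`.
#' @examples
#' classifyPair(c(1, 3), c(2, 4))  # alternating
#' classifyPair(c(2, 3), c(1, 4))  # inside_S_in_T
#' @export
classifyPair <- function(S, T, host = NULL) {
  S <- as.integer(S); T <- as.integer(T)
  if (!length(S) || !length(T)) stop("subsequences must be nonempty")
  if (is.unsorted(S, strictly = TRUE) || is.unsorted(T, strictly = TRUE))
    stop("subsequence indices must be strictly increasing")
  if (length(intersect(S, T)))
    stop("subsequences must use disjoint index sets")
  if (!is.null(host) && max(S, T) > length(host))
    stop("indices exceed host length")
  if (max(S) < min(T) || max(T) < min(S)) return("disjoint_ordered")
  insideOneGap <- function(A, B) {
    ## is all of A strictly between two successive elements of B?
    k <- findInterval(min(A), B)
    k >= 1L && k < length(B) && max(A) < B[k + 1L]
  }
  if (insideOneGap(S, T)) return("inside_S_in_T")
  if (insideOneGap(T, S)) return("inside_T_in_S")
  if (length(S) == 2L && length(T) == 2L &&
      (all(order(c(S, T)) == c(1L, 3L, 2L, 4L)) ||
       all(order(c(T, S)) == c(1L, 3L, 2L, 4L))))
    return("alternating")
  "overlapping"
}

## TRUE when the family of index vectors is pairwise non-overlapping
## (the non-overlapping property for position sets of distinct ops)
nonOverlappingFamily <- function(parts) {
  k <- length(parts)
  if (k < 2L) return(TRUE)
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    rel <- classifyPair(parts[[a]], parts[[b]])
    if (rel %in% c("alternating", "overlapping")) return(FALSE)
  }
  TRUE
}
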