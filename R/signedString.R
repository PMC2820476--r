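#' Construct a signed string
#'
#' Accepts either plain text (`"abcd"`, lifted to all-'+' orientation) or
#' whitespace-separated signed tokens (`"+a -b c"`; a bare symbol means
#' '+').  A character vector of single tokens is also accepted.
#'
#' @param x character scalar (plain or token text) or character vector of
#'   tokens; alternatively a SignedString (returned unchanged).
#' @param format `"auto"` (tokens if any whitespace or sign prefix is
#'   present, else plain), `"tokens"`, or `"plain"`.
#' @return a [SignedString-class].
#' @examples
#' signedString("abcd")
#' signedString("+b -c -a +d")
#' @export
signedString <- function(x, format = c("auto", "tokens", "plain")) {
  format <- match.arg(format)
  if (is(x, "SignedString")) return(x)
  if (!is.character(x)) stop("signedString() expects character input")
  if (length(x) == 1L && format != "tokens" &&
      (format == "plain" || !grepl("[[:space:]+-]", x))) {
    sym <- strsplit(x, "", fixed = TRUE)[[1]]
    return(newSignedString(sym, rep(1L, length(sym))))
  }
  toks <- if (length(x) == 1L) strsplit(trimws(x), "[[:space:]]+")[[1]] else x
  toks <- toks[nzchar(toks)]
  sgn <- rep(1L, length(toks))
  sym <- character(length(toks))
  for (k in seq_along(toks)) {
    t <- toks[k]
    first <- substr(t, 1L, 1L)
    if (first %in% c("+", "-")) {
      sgn[k] <- if (first == "-") -1L else 1L
      t <- substr(t, 2L, nchar(toks[k]))
    }
    if (nchar(t) != 1L)
      stop(sprintf("malformed signed token '%s' at position %d (need a single symbol)",
                   toks[k], k))
    sym[k] <- t
  }
  newSignedString(sym, sgn)
}

## internal fast constructor (skips parsing, keeps validity)
newSignedString <- function(symbol, sign) {
  new("SignedString", symbol = as.character(symbol), sign = as.integer(sign))
}

#' The empty signed string
#' @return a zero-length [SignedString-class].
#' @export
emptySignedString <- function() newSignedString(character(0), integer(0))

#' @rdname SignedString-class
#' @export
setMethod("symbols", "SignedString", function(x) x@symbol)

#' @rdname SignedString-class
#' @export
setMethod("signs", "SignedString", function(x) x@sign)

#' @describeIn SignedString-class number of characters.
#' @export
setMethod("length", "SignedString", function(x) length(x@symbol))

#' @describeIn SignedString-class extract a sub-signed-string (1-based,
#'   any index vector; contiguous indices give a substring).
#' @param i index vector.
#' @export
setMethod("[", "SignedString", function(x, i) {
  newSignedString(x@symbol[i], x@sign[i])
})

#' @describeIn SignedString-class render as signed-token text (or plain
#'   text if every sign is '+').
#' @export
setMethod("as.character", "SignedString", function(x) {
  if (!length(x)) return("")
  if (all(x@sign == 1L)) return(paste(x@symbol, collapse = ""))
  paste0(ifelse(x@sign == 1L, "+", "-"), x@symbol, collapse = " ")
})

#' @export
setMethod("show", "SignedString", function(object) {
  cat(sprintf("SignedString of length %d: %s\n", length(object),
              if (length(object)) as.character(object) else "(empty)"))
})

#' @rdname invert
#' @export
setMethod("invert", "SignedString", function(x) {
  n <- length(x)
  if (!n) return(x)
  newSignedString(rev(x@symbol), -rev(x@sign))
})

#' Concatenate signed strings
#' @param x,... SignedString objects.
#' @return a [SignedString-class].
#' @export
setMethod("c", "SignedString", function(x, ...) {
  parts <- c(list(x), list(...))
  newSignedString(unlist(lapply(parts, symbols)),
                  unlist(lapply(parts, signs)))
})

#' Signed-string equality
#' @param e1,e2 SignedString objects.
#' @export
setMethod("==", signature("SignedString", "SignedString"), function(e1, e2) {
  length(e1) == length(e2) && all(e1@symbol == e2@symbol) &&
    all(e1@sign == e2@sign)
})

#' Invert a span of x in place
#'
#' Returns x with the substring x[s..t] replaced by its inverse, i.e. the
#' string x^{s,t} used by the substring-inversion distance variant.
#'
#' @param x a [SignedString-class].
#' @param s,t 1-based inclusive span bounds; `s > t` (or both NA) returns
#'   x unchanged (the identity variant x^{0,0} = x).
#' @return a [SignedString-class] of the same length.
#' @export
subInvert <- function(x, s, t) {
  if (is.na(s) || is.na(t) || s > t) return(x)
  stopifnot(s >= 1L, t <= length(x))
  sym <- x@symbol; sgn <- x@sign
  idx <- s:t
  sym[idx] <- rev(sym[idx])
  sgn[idx] <- -rev(sgn[idx])
  newSignedString(sym, sgn)
}

## signed tokens as a character vector ("+a", "-b", ...): the engine's
## working representation and the memoization key material
signedTokens <- function(x) {
  if (!length(x)) return(character(0))
  paste0(ifelse(x@sign == 1L, "+", "-"), x@symbol)
}

#' Read a signed string from a file or literal
#'
#' @param x a file path or a literal string.
#' @param format `"tokens"` (whitespace-separated `+a -b` tokens),
#'   `"plain"` (`ab` means `+a +b`), or `"fasta"` (first record, or the
#'   record named by `id`).
#' @param id optional FASTA record name.
#' @return a [SignedString-class].
#' @export
readSignedString <- function(x, format = c("tokens", "plain", "fasta"),
                             id = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- readLines(x, warn = FALSE)
    starts <- grep("^>", lines)
    if (!length(starts)) stop("no FASTA records in ", x)
    names <- sub("^>\\s*(\\S+).*$", "\\1", lines[starts])
    pick <- if (is.null(id)) 1L else match(id, names)
    if (is.na(pick)) stop("FASTA record '", id, "' not found in ", x)
    end <- if (pick < length(starts)) starts[pick + 1L] - 1L else length(lines)
    seq <- paste(lines[(starts[pick] + 1L):end], collapse = "")
    return(signedString(gsub("[[:space:]]", "", seq), format = "plain"))
  }
  text <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = " ")
          else x
  signedString(text, format = if (format == "plain") "plain" else "tokens")
}

## condition raised when a target character cannot be generated from x
undefinedDistance <- function(msg) {
  stop(structure(class = c("undefinedDistanceError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Test whether a condition is an undefined-distance error
#' @param e a condition object.
#' @return logical.
#' @export
isUndefinedDistance <- function(e) inherits(e, "undefinedDistanceError")
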