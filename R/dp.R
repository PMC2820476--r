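## ---------------------------------------------------------------------
## The shared interval dynamic program behind all five distances.
##
## Every variant is expressed as a set of "channels".  A channel is a
## signed string c (the source read in some orientation, possibly with an
## in-place inverted span) together with affine costs (open, ext), a flag
## saying whether the copy may skip source characters (paying Phi per
## skipped run), and a terminal surcharge (the Theta(l) substring-inversion
## fee, levied exactly once per operation when it terminates).
##
##   * dup          : { x with (Delta1, Delta2), contiguous }
##   * dupdel       : { x with (Delta1, Delta2), jumps }
##   * dupinv       : { x with Delta, contiguous } + { invert(x) with Theta,
##                     contiguous }  -- a chain along invert(x) is
##                     exactly the reverse chain -x_i, -x_{i-1}, ...
##   * dupinvdel    : same two channels, with jumps
##   * dupsubinv    : { x^{s,t} with Delta and terminal Theta(t-s+1),
##                     jumps } over all spans s <= t, plus the identity
##
## State space: FREE intervals [lo, hi] of y (d(x, y_{lo,hi})) and chain
## states (channel, i, lo, hi) = the restricted distance where y_lo is
## generated by channel character i of the current operation.
##
##   free(lo, hi)      = min over channels c, i matching y_lo of ch(c,i,lo,hi)
##   ch(c, i, lo, hi)  = min( open + ext + term + free(lo+1, hi),          # case 1
##                            min over k > i, j > lo matching c_k of
##                              (k-i) ext + Phi(k-i-1) + free(lo+1, j-1)
##                                + ch(c, k, j, hi) )                      # case 2
##
## with k restricted to i+1 when the channel forbids jumps.
## ---------------------------------------------------------------------

DP_EPS <- 1e-9

dpVariants <- c("dup", "dupdel", "dupinv", "dupinvdel", "dupsubinv")

## build the channel list for a variant
dpChannels <- function(x, model, variant) {
  m <- length(x)
  mk <- function(seqs, open, ext, jumps, term, signMatters, type, invSpan)
    list(tok = signedTokens(seqs), sym = symbols(seqs), open = open,
         ext = ext, jumps = jumps, term = term, signMatters = signMatters,
         type = type, invSpan = invSpan, m = length(seqs))
  D1 <- model@dupOpen; D2 <- model@dupExt
  T1 <- model@invOpen; T2 <- model@invExt
  switch(variant,
    dup = list(mk(x, D1, D2, FALSE, 0, FALSE, "F", NA)),
    dupdel = list(mk(x, D1, D2, TRUE, 0, FALSE, "F", NA)),
    dupinv = list(mk(x, D1, D2, FALSE, 0, TRUE, "F", NA),
                  mk(invert(x), T1, T2, FALSE, 0, TRUE, "R", NA)),
    dupinvdel = list(mk(x, D1, D2, TRUE, 0, TRUE, "F", NA),
                     mk(invert(x), T1, T2, TRUE, 0, TRUE, "R", NA)),
    dupsubinv = {
      chans <- list(mk(x, D1, D2, TRUE, 0, TRUE, "V", NA))
      for (s in seq_len(m)) for (t in s:m)
        chans[[length(chans) + 1L]] <-
          mk(subInvert(x, s, t), D1, D2, TRUE,
             model@subinvCost(t - s + 1L), TRUE, "V", c(s, t))
      chans
    },
    stop("unknown variant ", variant))
}

## memoized solver; returns an environment exposing value, traceback and
## state counters (kept internal; public wrappers live in distances.R)
dpSolve <- function(x, y, model, variant) {
  channels <- dpChannels(x, model, variant)
  n <- length(y)
  ytok <- signedTokens(y); ysym <- symbols(y)
  nc <- length(channels)

  ## matchY[[c]][[k]]: y positions matching channel c character k;
  ## matchX[[c]][[q]]: channel c characters matching y position q
  matchX <- vector("list", nc)
  matchY <- vector("list", nc)
  for (ci in seq_len(nc)) {
    ch <- channels[[ci]]
    hit <- if (ch$signMatters) outer(ch$tok, ytok, "==")
           else outer(ch$sym, ysym, "==")
    matchY[[ci]] <- lapply(seq_len(ch$m), function(k) which(hit[k, ]))
    matchX[[ci]] <- lapply(seq_len(max(n, 1L)),
                           function(q) if (q <= n) which(hit[, q]) else integer(0))
  }
  if (n > 0L) {
    covered <- Reduce(`|`, lapply(seq_len(nc), function(ci)
      vapply(seq_len(n), function(q) length(matchX[[ci]][[q]]) > 0L, logical(1))))
    if (!all(covered))
      undefinedDistance(sprintf(
        "target character %s at position %d cannot be generated from the source under variant '%s'",
        ytok[which(!covered)[1]], which(!covered)[1], variant))
  }

  ## Phi on skipped-run lengths, with Phi(0) = 0
  maxGap <- max(vapply(channels, `[[`, integer(1), "m"))
  gapPhi <- c(0, vapply(seq_len(max(maxGap - 1L, 1L)), model@delCost, numeric(1)))

  freeMemo <- matrix(NA_real_, n + 2L, n + 2L)   # [lo, hi+1]
  chainMemo <- lapply(channels, function(ch)
    array(NA_real_, dim = c(ch$m, max(n, 1L), max(n, 1L))))
  freeStates <- 0L; chainStates <- 0L
  depth <- 0L
  maxDepth <- getOption("dupdist.maxDepth", 5000L)

  free <- function(lo, hi) {
    if (lo > hi) return(0)
    v <- freeMemo[lo, hi + 1L]
    if (!is.na(v)) return(v)
    depth <<- depth + 1L
    if (depth > maxDepth)
      stop("recursion depth limit exceeded (see option 'dupdist.maxDepth')")
    best <- Inf
    for (ci in seq_len(nc))
      for (i in matchX[[ci]][[lo]]) {
        cand <- chain(ci, i, lo, hi)
        if (cand < best - DP_EPS) best <- cand
      }
    depth <<- depth - 1L
    freeMemo[lo, hi + 1L] <<- best
    freeStates <<- freeStates + 1L
    best
  }

  chain <- function(ci, i, lo, hi) {
    v <- chainMemo[[ci]][i, lo, hi]
    if (!is.na(v)) return(v)
    depth <<- depth + 1L
    if (depth > maxDepth)
      stop("recursion depth limit exceeded (see option 'dupdist.maxDepth')")
    ch <- channels[[ci]]
    best <- ch$open + ch$ext + ch$term + free(lo + 1L, hi)     # case 1
    ks <- if (ch$jumps) seq_len(ch$m - i) + i
          else if (i < ch$m) i + 1L else integer(0)
    for (k in ks) {
      step <- (k - i) * ch$ext + gapPhi[k - i]
      ## any case-2 candidate is at least step + (terminal cost of the
      ## continued chain), so k cannot improve once that exceeds best
      if (step + ch$open + ch$ext + ch$term > best + DP_EPS) next
      js <- matchY[[ci]][[k]]
      js <- js[js > lo & js <= hi]
      for (j in js) {
        cand <- step + free(lo + 1L, j - 1L) + chain(ci, k, j, hi)
        if (cand < best - DP_EPS) best <- cand
      }
    }
    depth <<- depth - 1L
    chainMemo[[ci]][i, lo, hi] <<- best
    chainStates <<- chainStates + 1L
    best
  }

  value <- free(1L, n)

  ## ---- traceback -----------------------------------------------------
  ## Re-derives the argmin decisions from the memo tables with the fixed
  ## tie-break: case 1 before case 2, then smallest j, then smallest k,
  ## then smallest i, then channel order.  Emits one record per operation
  ## with the channel character indices used and the absolute y positions
  ## generated.
  traceback <- function() {
    ops <- list()
    traceFree <- function(lo, hi) {
      if (lo > hi) return(invisible(NULL))
      target <- free(lo, hi)
      for (ci in seq_len(nc))
        for (i in matchX[[ci]][[lo]])
          if (chain(ci, i, lo, hi) < target + DP_EPS)
            return(traceChain(ci, i, lo, hi, integer(0), integer(0)))
      stop("traceback failed to reproduce the DP value (internal error)")
    }
    traceChain <- function(ci, i, lo, hi, srcAcc, posAcc) {
      ch <- channels[[ci]]
      target <- chain(ci, i, lo, hi)
      srcAcc <- c(srcAcc, i); posAcc <- c(posAcc, lo)
      ## case 1 preferred
      if (ch$open + ch$ext + ch$term + free(lo + 1L, hi) < target + DP_EPS) {
        ops[[length(ops) + 1L]] <<- list(channel = ci, src = srcAcc,
                                         pos = posAcc)
        return(traceFree(lo + 1L, hi))
      }
      ks <- if (ch$jumps) seq_len(ch$m - i) + i else i + 1L
      ## smallest j first, then smallest k
      bestJ <- Inf; bestK <- NA_integer_
      for (k in ks) {
        step <- (k - i) * ch$ext + gapPhi[k - i]
        js <- matchY[[ci]][[k]]
        js <- js[js > lo & js <= hi & js < bestJ]
        for (j in sort(js))
          if (step + free(lo + 1L, j - 1L) + chain(ci, k, j, hi) <
              target + DP_EPS) {
            bestJ <- j; bestK <- k
            break
          }
      }
      if (!is.finite(bestJ))
        stop("traceback failed in chain state (internal error)")
      traceFree(lo + 1L, bestJ - 1L)
      traceChain(ci, bestK, bestJ, hi, srcAcc, posAcc)
    }
    traceFree(1L, n)
    ops
  }

  list(value = value, traceback = traceback, channels = channels,
       stateCount = function() list(free = freeStates, chain = chainStates))
}

## convert one traceback record into a DupOp (without insertPos, which is
## assigned during scenario assembly)
traceRecordToOp <- function(rec, channels, variant) {
  ch <- channels[[rec$channel]]
  src <- rec$src                      # ascending channel coordinates
  segsOf <- function(idx) {
    breaks <- which(diff(idx) != 1L)
    starts <- idx[c(1L, breaks + 1L)]
    ends <- idx[c(breaks, length(idx))]
    cbind(starts, ends)
  }
  if (ch$type == "R") {
    ## channel runs over invert(x): map back to x coordinates
    xIdx <- sort(ch$m - src + 1L)
    seg <- segsOf(xIdx)
    kind <- if (nrow(seg) == 1L) "DUPINV" else "DUPINVDEL"
    return(dupOp(kind, sourceSpan = c(min(xIdx), max(xIdx)), insertPos = 1L,
                 retainedSegments = if (kind == "DUPINVDEL") seg else NULL))
  }
  seg <- segsOf(src)
  span <- c(min(src), max(src))
  if (ch$type == "V" && !all(is.na(ch$invSpan)))
    return(dupOp("DUPSUBINV", sourceSpan = span, insertPos = 1L,
                 retainedSegments = seg, invertedSpan = ch$invSpan))
  kind <- if (nrow(seg) == 1L) "DUP" else "DUPDEL"
  dupOp(kind, sourceSpan = span, insertPos = 1L,
        retainedSegments = if (kind == "DUPDEL") seg else NULL)
}

## order ops outermost-first (ascending minimum generated position; the
## non-overlapping property guarantees no earlier op ever sits strictly
## inside a later op's span) and compute the 1-based insertion position
## of each op at its turn
assembleScenario <- function(records, channels, variant, model) {
  if (!length(records)) return(new("DupScenario", ops = list(), totalCost = 0))
  records <- records[order(vapply(records, function(r) min(r$pos), numeric(1)))]
  placed <- integer(0)
  ops <- vector("list", length(records))
  total <- 0
  for (k in seq_along(records)) {
    rec <- records[[k]]
    op <- traceRecordToOp(rec, channels, variant)
    op@insertPos <- sum(placed < min(rec$pos)) + 1L
    placed <- c(placed, rec$pos)
    total <- total + operationCost(op, model)
    ops[[k]] <- op
  }
  new("DupScenario", ops = ops, totalCost = total)
}
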