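## ---------------------------------------------------------------------
## Brute-force ground truth on tiny instances.
##
## Primary strategy: every sequence of (fused) operations partitions the
## positions of y into parts, one per operation; each part must read as a
## string one operation can paste (an admissible insert-string), and the
## parts must be pairwise non-overlapping (the non-overlapping property).
## Conversely any such partition is realizable: order the parts by their
## smallest position and paste each as a contiguous block.  The minimum
## cost is therefore the minimum, over all pairwise-non-overlapping set
## partitions of 1..|y|, of the summed minimum realization costs of the
## parts -- a search that is independent of operation order and of the
## interval recurrences it validates.
## ---------------------------------------------------------------------

ORACLE_MAX_Y <- 7L
ORACLE_MAX_X <- 5L

## cache of pairwise-non-overlapping set partitions of 1..n
partitionCache <- new.env(parent = emptyenv())

## fast pairwise non-overlap test on two sorted integer vectors
partsNonOverlapping <- function(A, B) {
  if (A[length(A)] < B[1] || B[length(B)] < A[1]) return(TRUE)
  inGap <- function(a, b) {
    k <- findInterval(a[1], b)
    k >= 1L && k < length(b) && a[length(a)] < b[k + 1L]
  }
  inGap(A, B) || inGap(B, A)
}

## all set partitions of 1..n (restricted-growth enumeration) whose parts
## are pairwise non-overlapping, as lists of sorted index vectors
nonOverlappingPartitions <- function(n) {
  key <- as.character(n)
  if (!is.null(partitionCache[[key]])) return(partitionCache[[key]])
  out <- list()
  recurse <- function(q, assign, nparts) {
    if (q > n) {
      parts <- split(seq_len(n), assign)
      k <- length(parts)
      if (k > 1L)
        for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
          if (!partsNonOverlapping(parts[[a]], parts[[b]])) return(invisible())
      out[[length(out) + 1L]] <<- unname(parts)
      return(invisible())
    }
    for (g in seq_len(nparts + 1L)) {
      assign[q] <- g
      recurse(q + 1L, assign, max(nparts, g))
    }
  }
  if (n > 0L) recurse(1L, integer(n), 0L) else out <- list(list())
  partitionCache[[key]] <- out
  out
}

## minimum cost at which one operation of the configured variant can paste
## exactly the signed string w; Inf when inadmissible.  Shares the channel
## description of the variant but performs its own embedding search.
realizationCost <- function(wtok, wsym, channels, gapPhi) {
  best <- Inf
  lw <- length(wtok)
  for (ch in channels) {
    target <- if (ch$signMatters) ch$tok else ch$sym
    w <- if (ch$signMatters) wtok else wsym
    ## h(q, i): min extension cost to emit w[q..lw] after emitting w[q-1]
    ## from channel position i
    memo <- matrix(NA_real_, lw + 1L, ch$m)
    h <- function(q, i) {
      if (q > lw) return(0)
      v <- memo[q, i]
      if (!is.na(v)) return(v)
      ks <- if (ch$jumps) which(target == w[q]) else i + 1L
      ks <- ks[ks > i & ks <= ch$m & target[ks] == w[q]]
      b <- Inf
      for (k in ks) {
        cand <- (k - i) * ch$ext + gapPhi[k - i] + h(q + 1L, k)
        if (cand < b) b <- cand
      }
      memo[q, i] <<- b
      b
    }
    starts <- which(target == w[1])
    for (i in starts) {
      cand <- ch$open + ch$ext + ch$term + h(2L, i)
      if (cand < best) best <- cand
    }
  }
  best
}

#' Reusable oracle for one source string
#'
#' Builds the admissibility machinery for `x` once and returns a function
#' computing the exact brute-force distance to any small target, so that
#' sweeps over many targets share the per-part memo.
#'
#' @inheritParams oracleDistance
#' @return function(y) -> numeric cost (Inf when no character of y is
#'   generatable, i.e. the distance is undefined).
#' @export
oracleSolver <- function(x, model = unitCosts(),
                         variant = c("dup", "dupdel", "dupinv", "dupinvdel",
                                     "dupsubinv")) {
  variant <- match.arg(variant)
  x <- signedString(x)
  stopifnot(length(x) <= ORACLE_MAX_X)
  channels <- dpChannels(x, model, variant)
  maxM <- max(vapply(channels, `[[`, integer(1), "m"))
  gapPhi <- c(0, vapply(seq_len(max(maxM - 1L, 1L)), model@delCost, numeric(1)))
  memo <- new.env(parent = emptyenv())
  function(y) {
    y <- signedString(y)
    n <- length(y)
    stopifnot(n <= ORACLE_MAX_Y)
    if (!n) return(0)
    ytok <- signedTokens(y); ysym <- symbols(y)
    partCost <- function(idx) {
      key <- paste(ytok[idx], collapse = " ")
      v <- memo[[key]]
      if (is.null(v)) {
        v <- realizationCost(ytok[idx], ysym[idx], channels, gapPhi)
        memo[[key]] <- v
      }
      v
    }
    best <- Inf
    for (parts in nonOverlappingPartitions(n)) {
      tot <- 0
      for (p in parts) {
        tot <- tot + partCost(p)
        if (tot >= best) break
      }
      if (tot < best) best <- tot
    }
    best
  }
}

#' Exact brute-force distance on a tiny instance
#'
#' Enumerates all realizable partitions of the target's positions (see the
#' package vignette) and returns the exact minimum cost for the variant's
#' operation set -- the reference value the dynamic programs are tested
#' against.  Guarded to |y| <= 7 and |x| <= 5.
#'
#' With `interleaved = TRUE` the search instead runs a bounded uniform-cost
#' search over intermediate strings in which duplications and *free-standing
#' deletions* interleave arbitrarily (the unfused operation model);
#' intermediate strings longer than |y| + `budget` are not explored.
#' Returns NA (inconclusive, never a wrong number) if the cost cap
#' `costCap` is exhausted before the target is reached.
#'
#' @param x,y source and target (coerced via [signedString()]).
#' @param model a [CostModel-class].
#' @param variant operation set, as in [dupDistance()].
#' @param interleaved use the unfused duplicate + delete search
#'   (variants `"dupdel"` and `"dupinvdel"` only).
#' @param budget surplus intermediate length allowed in the interleaved
#'   search.
#' @param costCap cost ceiling for the interleaved search; defaults to the
#'   cost of the character-by-character build plus one.
#' @return numeric cost; Inf when undefined; NA when inconclusive.
#' @examples
#' oracleDistance("abcd", "bbccd")  # 2
#' @export
oracleDistance <- function(x, y, model = unitCosts(),
                           variant = c("dup", "dupdel", "dupinv",
                                       "dupinvdel", "dupsubinv"),
                           interleaved = FALSE, budget = 2L, costCap = NULL) {
  variant <- match.arg(variant)
  if (interleaved)
    return(interleavedOracle(x, y, model, variant, budget, costCap))
  oracleSolver(x, model, variant)(y)
}

## bounded uniform-cost (Dijkstra) search over intermediate token strings,
## with plain duplicate inserts, duplicate-invert inserts (dupinvdel only)
## and free-standing deletions as moves
interleavedOracle <- function(x, y, model, variant, budget = 2L,
                              costCap = NULL) {
  stopifnot(variant %in% c("dupdel", "dupinvdel"))
  x <- signedString(x); y <- signedString(y)
  if (variant == "dupdel") {
    ## sign-free model: orientations play no role, so search unsigned
    x <- newSignedString(symbols(x), rep(1L, length(x)))
    y <- newSignedString(symbols(y), rep(1L, length(y)))
  }
  stopifnot(length(x) <= ORACLE_MAX_X, length(y) <= ORACLE_MAX_Y)
  m <- length(x)
  sgnMatters <- variant == "dupinvdel"
  keyOf <- function(s) paste(c("#", signedTokens(s)), collapse = " ")
  goal <- keyOf(y)
  cap <- length(y) + budget

  ## candidate insert blocks: all substrings of x (cost Delta1 + l Delta2)
  ## and, for the inversion variant, of invert(x) (cost Theta1 + l Theta2)
  blocks <- list()
  for (s in seq_len(m)) for (t in s:m) {
    blocks[[length(blocks) + 1L]] <-
      list(str = x[s:t], cost = model@dupOpen + (t - s + 1L) * model@dupExt)
    if (sgnMatters)
      blocks[[length(blocks) + 1L]] <-
        list(str = invert(x[s:t]),
             cost = model@invOpen + (t - s + 1L) * model@invExt)
  }
  if (is.null(costCap)) {
    per <- max(model@dupOpen + model@dupExt,
               if (sgnMatters) model@invOpen + model@invExt else 0)
    costCap <- length(y) * per + 1
  }

  ## binary min-heap on (cost, state-key); states decoded lazily
  hCost <- numeric(0); hKey <- character(0)
  push <- function(cost, key) {
    hCost[length(hCost) + 1L] <<- cost
    hKey[length(hKey) + 1L] <<- key
    i <- length(hCost)
    while (i > 1L) {
      p <- i %/% 2L
      if (hCost[p] <= hCost[i]) break
      hCost[c(p, i)] <<- hCost[c(i, p)]; hKey[c(p, i)] <<- hKey[c(i, p)]
      i <- p
    }
  }
  pop <- function() {
    top <- list(cost = hCost[1L], key = hKey[1L])
    last <- length(hCost)
    hCost[1L] <<- hCost[last]; hKey[1L] <<- hKey[last]
    hCost <<- hCost[-last]; hKey <<- hKey[-last]
    i <- 1L; sz <- length(hCost)
    repeat {
      l <- 2L * i; r <- l + 1L; sm <- i
      if (l <= sz && hCost[l] < hCost[sm]) sm <- l
      if (r <= sz && hCost[r] < hCost[sm]) sm <- r
      if (sm == i) break
      hCost[c(sm, i)] <<- hCost[c(i, sm)]; hKey[c(sm, i)] <<- hKey[c(i, sm)]
      i <- sm
    }
    top
  }

  settled <- new.env(parent = emptyenv())
  bestSeen <- new.env(parent = emptyenv())
  strings <- new.env(parent = emptyenv())
  startKey <- keyOf(emptySignedString())
  strings[[startKey]] <- emptySignedString()
  bestSeen[[startKey]] <- 0
  push(0, startKey)
  while (length(hCost)) {
    cur <- pop()
    if (!is.null(settled[[cur$key]])) next
    settled[[cur$key]] <- TRUE
    if (cur$key == goal) return(cur$cost)
    if (cur$cost > costCap) break
    z <- strings[[cur$key]]
    nz <- length(z)
    moves <- list()
    if (nz < cap)
      for (b in blocks) if (nz + length(b$str) <= cap)
        for (p in seq_len(nz + 1L)) {
          idx <- seq_len(p - 1L)
          nxt <- c(z[idx], b$str, if (p <= nz) z[p:nz] else emptySignedString())
          moves[[length(moves) + 1L]] <- list(s = nxt, c = b$cost)
        }
    if (nz > 0L)
      for (s in seq_len(nz)) for (t in s:nz)
        moves[[length(moves) + 1L]] <-
          list(s = z[setdiff(seq_len(nz), s:t)],
               c = model@delCost(t - s + 1L))
    for (mv in moves) {
      k <- keyOf(mv$s)
      nc <- cur$cost + mv$c
      if (nc > costCap) next
      old <- bestSeen[[k]]
      if (is.null(old) || nc < old) {
        bestSeen[[k]] <- nc
        strings[[k]] <- mv$s
        push(nc, k)
      }
    }
  }
  NA_real_
}

#' Canonicalize an interleaved scenario
#'
#' Transforms a scenario containing free-standing DEL operations into one
#' using only fused operations, producing the same final string at no
#' greater cost (given the cost model's non-decreasing, subadditive
#' deletion cost).  Each DEL is absorbed by the operations that generated
#' the deleted characters: operations wholly deleted are dropped; deleted
#' prefixes/suffixes shrink the copied span (those characters are never
#' generated); a deleted internal run -- which can affect at most one
#' operation -- becomes an internal deletion gap of that operation.
#'
#' @param x the source [SignedString-class].
#' @param scenario a [DupScenario-class] that replays successfully.
#' @param model a [CostModel-class] used to recost the result.
#' @return a [DupScenario-class] with no DEL operations.
#' @export
canonicalizeScenario <- function(x, scenario, model = unitCosts()) {
  x <- signedString(x)
  ops <- scenario@ops
  repeat {
    kinds <- vapply(ops, function(o) o@kind, character(1))
    di <- which(kinds == "DEL")[1]
    if (is.na(di)) break
    prefix <- ops[seq_len(di - 1L)]
    ## replay the prefix, labelling every character (creator op, offset)
    z <- emptySignedString()
    lab <- matrix(integer(0), 0L, 2L)          # columns: op index, offset
    before <- vector("list", length(prefix))   # labels before each insert
    for (k in seq_along(prefix)) {
      before[[k]] <- lab
      op <- prefix[[k]]
      ins <- opInsertString(x, op)
      p <- op@insertPos
      newLab <- cbind(rep(k, length(ins)), seq_len(length(ins)))
      lab <- rbind(lab[seq_len(p - 1L), , drop = FALSE], newLab,
                   if (p <= nrow(lab)) lab[p:nrow(lab), , drop = FALSE])
      z <- applyOperation(z, x, op)
    }
    del <- ops[[di]]@deleteSpan
    if (del[2] > nrow(lab)) stop("scenario does not replay (DEL out of range)")
    R <- lab[del[1]:del[2], , drop = FALSE]
    removedOffsets <- split(R[, 2], R[, 1])
    newPrefix <- list()
    keep <- rep(TRUE, nrow(lab)); keep[del[1]:del[2]] <- FALSE
    survives <- function(labmat) {
      ## which labelled chars survive the deletion surgery
      !(paste(labmat[, 1], labmat[, 2]) %in% paste(R[, 1], R[, 2]))
    }
    for (k in seq_along(prefix)) {
      op <- prefix[[k]]
      drop <- removedOffsets[[as.character(k)]]
      op2 <- if (is.null(drop)) op else shrinkOp(op, drop, x)
      if (is.null(op2)) next
      bl <- before[[k]]
      newP <- if (nrow(bl)) sum(survives(bl)[seq_len(op@insertPos - 1L)]) + 1L
              else 1L
      op2@insertPos <- as.integer(newP)
      newPrefix[[length(newPrefix) + 1L]] <- op2
    }
    ops <- c(newPrefix, ops[seq_along(ops) > di])
  }
  total <- if (length(ops))
    sum(vapply(ops, operationCost, numeric(1), model = model)) else 0
  new("DupScenario", ops = ops, totalCost = total)
}

## remove the given insert-string offsets from an operation, re-deriving
## the canonical span/segments; NULL when nothing remains
shrinkOp <- function(op, offsets, x) {
  seg <- op@retainedSegments
  idx <- if (nrow(seg))
    unlist(lapply(seq_len(nrow(seg)), function(r) seg[r, 1]:seg[r, 2]))
  else op@sourceSpan[1]:op@sourceSpan[2]
  inverted <- op@kind %in% c("DUPINV", "DUPINVDEL")
  ## offset o of the pasted string corresponds to source index idx[o]
  ## (forward kinds) or rev(idx)[o] (inverted kinds)
  ord <- if (inverted) rev(idx) else idx
  remain <- sort(ord[-offsets])
  if (!length(remain)) return(NULL)
  breaks <- which(diff(remain) != 1L)
  segs <- cbind(remain[c(1L, breaks + 1L)], remain[c(breaks, length(remain))])
  storage.mode(segs) <- "integer"
  contiguous <- nrow(segs) == 1L
  kind <- if (op@kind %in% c("DUP", "DUPDEL"))
    (if (contiguous) "DUP" else "DUPDEL")
  else if (inverted) (if (contiguous) "DUPINV" else "DUPINVDEL")
  else "DUPSUBINV"
  dupOp(kind, sourceSpan = c(remain[1], remain[length(remain)]),
        insertPos = op@insertPos,
        retainedSegments = if (kind %in% c("DUPDEL", "DUPINVDEL", "DUPSUBINV"))
          segs else NULL,
        invertedSpan = if (kind == "DUPSUBINV") op@invertedSpan else NA)
}
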