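#' Write a scenario as JSON
#'
#' Schema: `{"source": str, "ops": [{"kind": str, "source_span": [s,t],
#' "retained_segments": [[i,j],...], "inverted_span": [s,t]|null,
#' "insert_pos": p, "delete_span": [s,t]|null}], "total_cost": cost}`.
#' All spans are 1-based inclusive.  Costs are written as exact integers
#' when integral, else as decimals with 9 significant digits.
#'
#' @param scenario a [DupScenario-class].
#' @param source the source [SignedString-class] the scenario copies from.
#' @param path file path, or NULL to return the JSON text.
#' @return the JSON text, invisibly when written to a file.
#' @export
writeScenarioJSON <- function(scenario, source, path = NULL) {
  source <- signedString(source)
  opJSON <- function(op) {
    if (op@kind == "DEL")
      return(list(kind = "DEL", source_span = NULL, retained_segments = NULL,
                  inverted_span = NULL, insert_pos = NULL,
                  delete_span = as.integer(op@deleteSpan)))
    seg <- op@retainedSegments
    list(kind = op@kind,
         source_span = as.integer(op@sourceSpan),
         retained_segments = if (nrow(seg))
           lapply(seq_len(nrow(seg)), function(r) as.integer(seg[r, ]))
         else list(),
         inverted_span = if (op@kind == "DUPSUBINV")
           as.integer(op@invertedSpan) else NULL,
         insert_pos = as.integer(op@insertPos),
         delete_span = NULL)
  }
  tc <- scenario@totalCost
  obj <- list(source = as.character(source),
              ops = lapply(scenario@ops, opJSON),
              total_cost = if (abs(tc - round(tc)) < 1e-9) as.integer(round(tc))
                           else signif(tc, 9))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a scenario from JSON
#'
#' @param path file path or JSON text (as written by [writeScenarioJSON()]).
#' @return list with `source` ([SignedString-class]) and `scenario`
#'   ([DupScenario-class]).
#' @export
readScenarioJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ops <- lapply(obj$ops, function(o) {
    if (o$kind == "DEL")
      return(dupOp("DEL", deleteSpan = unlist(o$delete_span)))
    seg <- if (length(o$retained_segments))
      do.call(rbind, lapply(o$retained_segments, function(s)
        as.integer(unlist(s))))
    else NULL
    dupOp(o$kind, sourceSpan = unlist(o$source_span),
          insertPos = o$insert_pos, retainedSegments = seg,
          invertedSpan = if (is.null(o$inverted_span)) NA
                         else unlist(o$inverted_span))
  })
  list(source = signedString(obj$source),
       scenario = new("DupScenario", ops = ops,
                      totalCost = as.numeric(obj$total_cost)))
}
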