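#' Map collapsed tags to transcripts by exact match
#'
#' Ungapped exact matching on both strands. Positions are the 0-based
#' leftmost transcript coordinate of the alignment; multi-mapping tags are
#' reported at every locus.
#'
#' @param lib a [tag_library()] or data.frame with `tag` and `count`.
#' @param transcripts a [transcript_set()].
#' @param strands which strands to search.
#' @return data.frame with `tag`, `count`, `transcript_id`, `strand`, `pos`.
#' @export
map_tags <- function(lib, transcripts, strands = c("+", "-")) {
  if (inherits(lib, "tag_library")) {
    tags <- names(lib$tags)
    counts <- as.integer(lib$tags)
  } else {
    tags <- lib$tag
    counts <- lib$count
  }
  tx_int <- lapply(unclass(transcripts), seq_to_int)
  out <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    q_fwd <- seq_to_int(tags[i])
    q_rev <- seq_to_int(revcomp(tags[i]))
    rows <- list()
    for (tx in names(tx_int)) {
      s <- tx_int[[tx]]
      if (length(s) < length(q_fwd)) next
      if ("+" %in% strands) {
        hits <- which(mismatch_scan_cpp(s, q_fwd) == 0L) - 1L
        if (length(hits)) {
          rows[[length(rows) + 1L]] <- data.frame(
            tag = tags[i], count = counts[i], transcript_id = tx,
            strand = "+", pos = hits)
        }
      }
      if ("-" %in% strands) {
        hits <- which(mismatch_scan_cpp(s, q_rev) == 0L) - 1L
        if (length(hits)) {
          rows[[length(rows) + 1L]] <- data.frame(
            tag = tags[i], count = counts[i], transcript_id = tx,
            strand = "-", pos = hits)
        }
      }
    }
    if (length(rows)) out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(tag = character(0), count = integer(0),
                      transcript_id = character(0), strand = character(0),
                      pos = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
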