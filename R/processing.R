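#' Collapse raw reads into a tag library
#'
#' Each unique sequence gets one entry carrying its read count; the library
#' size is the number of input reads.
#'
#' @param reads character vector of read sequences.
#' @param sample_id sample label.
#' @param length_range keep only tags whose length falls in this closed
#'   range (nt); reads outside it still count toward the library size.
#' @return a [tag_library()].
#' @export
collapse_reads <- function(reads, sample_id = "sample",
                           length_range = c(16L, 30L)) {
  if (!length(reads)) {
    return(tag_library(setNames(integer(0), character(0)), sample_id,
                       library_size = 0L))
  }
  reads <- as_rna(reads)
  tab <- table(reads)
  tags <- setNames(as.integer(tab), names(tab))
  keep <- nchar(names(tags)) >= length_range[1] &
    nchar(names(tags)) <= length_range[2]
  tag_library(tags[keep], sample_id, library_size = length(reads))
}

#' Remove tags matching a blocklist
#'
#' Drops every tag with a perfect full-length match inside any blocklist
#' sequence (rRNA, tRNA, snRNA, snoRNA, repeat collections supplied as
#' FASTA), on either strand. The library size is left unchanged so RPTM
#' normalization keeps using sequencing depth.
#'
#' @param lib a [tag_library()].
#' @param blocklists a [transcript_set()] or list of them; may be empty.
#' @param max_mm allowed substitutions for a blocklist match (default 0,
#'   exact containment).
#' @return the filtered [tag_library()].
#' @export
filter_blocklist <- function(lib, blocklists, max_mm = 0L) {
  if (is.null(blocklists)) return(lib)
  if (inherits(blocklists, "transcript_set")) blocklists <- list(blocklists)
  block <- unlist(lapply(blocklists, function(b) as.character(unclass(b))))
  if (!length(block) || !length(lib$tags)) return(lib)
  block_int <- lapply(block, seq_to_int)
  hit <- vapply(names(lib$tags), function(tag) {
    q_fwd <- seq_to_int(tag)
    q_rev <- seq_to_int(revcomp(tag))
    for (b in block_int) {
      if (length(b) < length(q_fwd)) next
      if (any(mismatch_scan_cpp(b, q_fwd) <= max_mm)) return(TRUE)
      if (any(mismatch_scan_cpp(b, q_rev) <= max_mm)) return(TRUE)
    }
    FALSE
  }, logical(1))
  lib$tags <- lib$tags[!hit]
  lib
}

#' Read-length histogram of a tag library
#'
#' @param lib a [tag_library()].
#' @return data.frame with `length`, `reads` and `unique_tags`, one row per
#'   observed length.
#' @export
length_histogram <- function(lib) {
  if (!length(lib$tags)) {
    return(data.frame(length = integer(0), reads = integer(0),
                      unique_tags = integer(0)))
  }
  len <- nchar(names(lib$tags))
  reads <- tapply(lib$tags, len, sum)
  uniq <- tapply(lib$tags, len, length)
  data.frame(length = as.integer(names(reads)),
             reads = as.integer(reads),
             unique_tags = as.integer(uniq), row.names = NULL)
}

#' Reads-per-ten-million normalization
#'
#' @param raw raw read count(s).
#' @param library_size total qualified reads of the library.
#' @return `raw * 1e7 / library_size`.
#' @export
normalize_rptm <- function(raw, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  raw * 1e7 / library_size
}

#' RPTM expression matrix from raw counts
#'
#' @param counts miRNA x sample matrix of raw counts.
#' @param library_sizes per-sample total qualified reads.
#' @return matrix of RPTM values, same dimensions as `counts`.
#' @export
rptm_matrix <- function(counts, library_sizes) {
  if (ncol(counts) != length(library_sizes)) {
    stop("one library size per sample column is required")
  }
  sweep(counts, 2, library_sizes, function(x, ls) normalize_rptm(x, ls))
}
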