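#' Construct a transcript set
#'
#' A transcript set is a named character vector of sequences in the internal
#' RNA alphabet, with the input alphabet remembered so FASTA output can be
#' written back in the original alphabet.
#'
#' @param seqs named character vector of sequences (A/C/G/T/U/N).
#' @param input_alphabet `"rna"` or `"dna"`; how the sequences were supplied.
#' @return an object of class `transcript_set`.
#' @export
transcript_set <- function(seqs, input_alphabet = c("rna", "dna")) {
  input_alphabet <- match.arg(input_alphabet)
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    stop("every transcript needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id: ", ids[duplicated(ids)][1])
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for transcript: ", ids[nchar(seqs) == 0][1])
  }
  out <- as_rna(seqs)
  names(out) <- ids
  attr(out, "input_alphabet") <- input_alphabet
  class(out) <- "transcript_set"
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set with", length(x), "sequences (",
      sum(nchar(x)), "nt total )\n")
  invisible(x)
}

#' Read a FASTA file into a transcript set
#'
#' Ids are taken up to the first whitespace. T is converted to U on read; a
#' file containing T (and no U) is remembered as DNA so [write_fasta()] can
#' restore the original alphabet.
#'
#' @param path FASTA file.
#' @return a [transcript_set()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id in ", path, ": ", ids[duplicated(ids)][1])
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence in ", path, " for id: ", ids[nchar(seqs) == 0][1])
  }
  alph <- if (any(grepl("T", seqs, fixed = TRUE)) &&
              !any(grepl("U", seqs, fixed = TRUE))) "dna" else "rna"
  names(seqs) <- ids
  transcript_set(seqs, input_alphabet = alph)
}

#' Write a transcript set to FASTA
#'
#' Sequences read from a DNA file are written back as DNA (U converted to T).
#'
#' @param x a [transcript_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- unclass(x)
  if (identical(attr(x, "input_alphabet"), "dna")) {
    seqs <- chartr("U", "T", seqs)
  }
  ss <- Biostrings::BStringSet(setNames(as.character(seqs), names(x)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a collapsed tag library
#'
#' @param tags named integer vector: unique tag sequence -> read count.
#' @param sample_id sample label.
#' @param library_size total qualified reads; defaults to `sum(tags)`. Kept
#'   fixed through filtering so RPTM normalization uses sequencing depth.
#' @return an object of class `tag_library`.
#' @export
tag_library <- function(tags, sample_id = "sample", library_size = NULL) {
  if (length(tags)) {
    if (is.null(names(tags)) || any(names(tags) == "")) {
      stop("tags must be a named vector (sequence -> count)")
    }
    if (any(tags <= 0) || any(tags != round(tags))) {
      stop("tag counts must be positive integers")
    }
    seqs <- as_rna(names(tags))
    cnt <- tapply(as.integer(tags), seqs, sum)  # merge duplicates after T->U
    tags <- setNames(as.integer(cnt), names(cnt))
  } else {
    tags <- setNames(integer(0), character(0))
  }
  structure(
    list(sample_id = sample_id,
         tags = tags,
         library_size = if (is.null(library_size)) sum(tags) else library_size,
         normalized = FALSE),
    class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library", x$sample_id, ":", length(x$tags), "unique tags,",
      "library size", x$library_size, "\n")
  invisible(x)
}

#' Read a collapsed small-RNA tag library
#'
#' Two on-disk formats are supported: `fasta_count`, a FASTA file whose
#' headers end in `_<count>` or `x<count>`, and `tsv`, two tab-separated
#' columns `sequence<TAB>count` without header.
#'
#' @param path input file.
#' @param format `"fasta_count"` or `"tsv"`.
#' @param sample_id sample label (defaults to the file name).
#' @return a [tag_library()].
#' @export
read_tag_library <- function(path, format = c("fasta_count", "tsv"),
                             sample_id = NULL) {
  format <- match.arg(format)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "fasta_count") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    m <- regmatches(ids, regexec("(?:_|x)([0-9]+)$", ids))
    bad <- vapply(m, length, integer(1)) < 2
    if (any(bad)) {
      stop("header without a trailing _<count> or x<count>: ", ids[bad][1])
    }
    counts <- as.integer(vapply(m, `[`, character(1), 2))
    if (any(counts <= 0)) {
      stop("non-positive count in header: ", ids[counts <= 0][1])
    }
    tl <- tag_library(setNames(counts, toupper(as.character(ss))),
                      sample_id = sample_id)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(parts, length, integer(1))
    if (any(nf != 2)) {
      stop("line ", which(nf != 2)[1], ": expected sequence<TAB>count")
    }
    cnt_chr <- vapply(parts, `[`, character(1), 2)
    counts <- suppressWarnings(as.numeric(cnt_chr))
    bad <- is.na(counts) | counts <= 0 | counts != round(counts)
    if (any(bad)) {
      stop("line ", which(bad)[1], ": count must be a positive integer, got '",
           cnt_chr[bad][1], "'")
    }
    tl <- tag_library(setNames(as.integer(counts),
                               vapply(parts, `[`, character(1), 1)),
                      sample_id = sample_id)
  }
  tl
}

#' Write a collapsed tag library
#'
#' @param lib a [tag_library()].
#' @param path output file.
#' @param format `"fasta_count"` (headers `tagN_<count>`) or `"tsv"`.
#' @param expand if `TRUE` and `format = "fasta_count"`, write one FASTA
#'   record per read instead of collapsed tags.
#' @return `path`, invisibly.
#' @export
write_tag_library <- function(lib, path, format = c("fasta_count", "tsv"),
                              expand = FALSE) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(paste(names(lib$tags), lib$tags, sep = "\t"), path)
  } else if (expand) {
    reads <- rep(names(lib$tags), lib$tags)
    writeLines(paste0(">read", seq_along(reads), "\n", reads), path)
  } else {
    writeLines(paste0(">tag", seq_along(lib$tags), "_", lib$tags, "\n",
                      names(lib$tags)), path)
  }
  invisible(path)
}

#' Write annotated loci as GFF3
#'
#' Internal coordinates are 0-based half-open; the GFF3 output is 1-based
#' inclusive. Columns beyond `transcript_id`, `start`, `end`, `strand`,
#' `type` (and an optional `ID`) are written as attributes, so scores such as
#' `p_value`, `phase_score` or `mismatches` travel with each locus.
#'
#' @param loci data.frame with at least `transcript_id`, `start`, `end`
#'   (0-based half-open), `strand`, and `type` (one of `pre_miRNA`, `TAS3`,
#'   `phasiRNA_locus`, `target_site`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  if (is.null(loci) || nrow(loci) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    if (any(loci$start > loci$end)) {
      stop("locus with start > end: row ", which(loci$start > loci$end)[1])
    }
    gr <- GenomicRanges::GRanges(
      seqnames = loci$transcript_id,
      ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
      strand = if ("strand" %in% names(loci)) loci$strand else "*")
    gr$source <- "srnaphase"
    gr$type <- loci$type
    extra <- setdiff(names(loci),
                     c("transcript_id", "start", "end", "strand", "type"))
    for (col in extra) {
      S4Vectors::mcols(gr)[[col]] <- loci[[col]]
    }
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
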