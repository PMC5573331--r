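RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases and converts T to U. Characters outside `A C G U N` raise an
#' error.
#'
#' @param x character vector of sequences.
#' @return character vector in the RNA alphabet.
#' @export
as_rna <- function(x) {
  x <- chartr("acgutnT", "ACGUUNU", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside the A/C/G/T/U/N alphabet: ",
         substr(x[bad][1], 1, 40))
  }
  x
}

#' Reverse complement (RNA alphabet)
#'
#' @param x character vector of RNA sequences.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# integer encoding used by the C++ kernels: A=1 C=2 G=3 U=4, N=0
seq_to_int <- function(s) {
  m <- match(strsplit(s, "")[[1]], RNA_BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

int_to_seq <- function(v) {
  paste(c("N", RNA_BASES)[v + 1L], collapse = "")
}

wc_complement <- function(base) chartr("ACGU", "UGCA", base)

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

substr0 <- function(s, start, end) {
  # 0-based half-open substring
  substr(s, start + 1L, end)
}
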