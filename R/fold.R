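#' Fold an RNA sequence
#'
#' The internal backend is a maximum base-pair (Nussinov-style) fold over
#' nested structures with a minimum hairpin loop of 3 nt, scored with a
#' simple non-Turner energy model: -3 kcal/mol per G:C pair, -2 per A:U and
#' -1 per G:U wobble. The `-40` kcal/mol precursor threshold of
#' [run_config()] is calibrated for this model. If the ViennaRNA `RNAfold`
#' binary is on the PATH it can be selected as an external backend with
#' thermodynamic energies; no functionality depends on it.
#'
#' @param sequence RNA (or DNA) string, length >= 10.
#' @param backend `"nussinov"` (internal, default) or `"rnafold"`.
#' @param min_loop minimum unpaired nucleotides in a hairpin loop.
#' @return list with `structure` (dot-bracket), `energy` (kcal/mol),
#'   `partner` (0-based pairing partner per position, -1 if unpaired) and
#'   `n_pairs`.
#' @export
fold <- function(sequence, backend = c("nussinov", "rnafold"), min_loop = 3L) {
  backend <- match.arg(backend)
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n < 10) stop("fold() needs a sequence of at least 10 nt")
  if (backend == "rnafold") {
    return(fold_rnafold(sequence))
  }
  partner <- nussinov_partner(seq_to_int(sequence), as.integer(min_loop))
  n_pairs <- sum(partner >= 0) / 2
  if (n_pairs < 3) {
    return(list(structure = strrep(".", n), energy = 0,
                partner = rep(-1L, n), n_pairs = 0L))
  }
  structure_chr <- rep(".", n)
  idx <- which(partner >= 0)
  structure_chr[idx[idx - 1 < partner[idx]]] <- "("
  structure_chr[idx[idx - 1 > partner[idx]]] <- ")"
  list(structure = paste(structure_chr, collapse = ""),
       energy = pair_energy(sequence, partner),
       partner = partner,
       n_pairs = as.integer(n_pairs))
}

# simple additive energy over pairs: GC -3, AU -2, GU -1 kcal/mol
pair_energy <- function(sequence, partner) {
  b <- strsplit(sequence, "")[[1]]
  i <- which(partner >= 0 & seq_along(partner) - 1L < partner)
  if (!length(i)) return(0)
  a1 <- b[i]
  a2 <- b[partner[i] + 1L]
  pr <- paste0(pmin(a1, a2), pmax(a1, a2))
  sum(c(CG = -3, AU = -2, GU = -1)[pr], na.rm = TRUE)
}

fold_rnafold <- function(sequence) {
  bin <- Sys.which("RNAfold")
  if (bin == "") stop("RNAfold binary not found on PATH")
  out <- system2(bin, args = "--noPS", input = sequence, stdout = TRUE)
  line <- out[2]
  db <- sub("\\s.*$", "", line)
  energy <- as.numeric(gsub("[() ]", "", sub("^[.()]+\\s*", "", line)))
  partner <- dotbracket_partner(db)
  list(structure = db, energy = energy, partner = partner,
       n_pairs = as.integer(sum(partner >= 0) / 2))
}

#' Pairing partners of a dot-bracket string
#'
#' @param db dot-bracket structure.
#' @return integer vector of 0-based partners, -1 for unpaired.
#' @export
dotbracket_partner <- function(db) {
  chars <- strsplit(db, "")[[1]]
  partner <- rep(-1L, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  partner
}

# number of paired positions among 0-based positions [start, end)
paired_in_region <- function(partner, start, end) {
  idx <- seq.int(start + 1L, end)  # 1-based indices of the region
  sum(partner[idx] >= 0L)
}
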