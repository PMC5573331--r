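#' Build degradome 5'-end profiles
#'
#' Each degradome tag's exact (sense) matches increment the count at the
#' tag's 5' position on every matching transcript; multi-mapping tags count
#' at every locus.
#'
#' @param tags a [tag_library()] of 5'-anchored degradome fragments.
#' @param transcripts a [transcript_set()].
#' @return named list of per-transcript integer vectors (one count per
#'   position), class `degradome_profile`.
#' @export
build_profile <- function(tags, transcripts) {
  prof <- lapply(unclass(transcripts), function(s) integer(nchar(s)))
  hits <- map_tags(tags, transcripts, strands = "+")
  for (r in seq_len(nrow(hits))) {
    tx <- hits$transcript_id[r]
    prof[[tx]][hits$pos[r] + 1L] <- prof[[tx]][hits$pos[r] + 1L] +
      hits$count[r]
  }
  class(prof) <- "degradome_profile"
  prof
}

#' Find complementary target sites of a small RNA
#'
#' Scores reverse-complementarity of the small RNA against the transcript
#' over every ungapped alignment. Non-Watson-Crick, non-wobble oppositions
#' count 1 mismatch; G:U wobbles count 0.5 (rounded down on the total) by
#' default, or 1 with `gu_penalty = 1`. The cleavage position is the
#' transcript position opposite small-RNA position 10 (canonical slicing
#' between positions 10 and 11).
#'
#' @param small_rna named single sequence (19-24 nt) or plain string.
#' @param transcript transcript sequence.
#' @param max_mm maximum (wobble-discounted) mismatches to report.
#' @param gu_penalty mismatch weight of a G:U wobble (0.5 or 1).
#' @param transcript_id,small_rna_id labels for the output.
#' @return data.frame of sites: `small_rna_id`, `transcript_id`, `start`,
#'   `end` (0-based half-open), `mismatches`, `gu_pairs`, `cleavage_pos`,
#'   sorted by mismatches.
#' @export
find_sites <- function(small_rna, transcript, max_mm = 4L, gu_penalty = 0.5,
                       transcript_id = "tx", small_rna_id = NULL) {
  if (is.null(small_rna_id)) {
    small_rna_id <- if (!is.null(names(small_rna))) names(small_rna)[1] else "sRNA"
  }
  q <- as_rna(as.character(small_rna)[1])
  L <- nchar(q)
  s_int <- seq_to_int(as_rna(transcript))
  if (length(s_int) < L) {
    return(empty_sites())
  }
  sc <- site_scan_cpp(s_int, seq_to_int(q))
  eff <- floor(sc[, 1] + gu_penalty * sc[, 2])
  hit <- which(eff <= max_mm)
  if (!length(hit)) return(empty_sites())
  o <- hit - 1L
  out <- data.frame(
    small_rna_id = small_rna_id, transcript_id = transcript_id,
    start = o, end = o + L,
    mismatches = eff[hit], raw_mismatches = sc[hit, 1],
    gu_pairs = sc[hit, 2],
    cleavage_pos = o + L - 10L)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

empty_sites <- function() {
  data.frame(small_rna_id = character(0), transcript_id = character(0),
             start = integer(0), end = integer(0), mismatches = numeric(0),
             raw_mismatches = integer(0), gu_pairs = integer(0),
             cleavage_pos = integer(0))
}

#' Count valid degradome reads at a target site
#'
#' Valid reads are degradome 5' ends at the transcript positions opposite
#' small-RNA positions 9, 10 and 11 (canonical slicer position with 1-nt
#' tolerance). The count at the exact canonical position (opposite position
#' 10) is reported separately.
#'
#' @param site one-row site data.frame from [find_sites()].
#' @param profile a `degradome_profile` (see [build_profile()]).
#' @param positions small-RNA positions whose opposite transcript positions
#'   count as valid (default 9:11).
#' @return list with `valid_reads`, `reads_at_10`, `total_site_reads`.
#' @export
classify_valid_reads <- function(site, profile, positions = 9:11) {
  v <- profile[[site$transcript_id]]
  L <- site$end - site$start
  opp <- site$start + L - positions          # 0-based transcript positions
  opp <- opp[opp >= 0 & opp < length(v)]
  at10 <- site$start + L - 10L
  list(valid_reads = sum(v[opp + 1L]),
       reads_at_10 = if (at10 >= 0 && at10 < length(v)) v[at10 + 1L] else 0L,
       total_site_reads = sum(v[seq.int(site$start + 1L,
                                        min(site$end, length(v)))]))
}

#' Validate predicted target sites
#'
#' Applies the retention rules: for conserved miRNA families, sites with
#' fewer than 4 mismatches are kept as predictions; sites with 4-5
#' mismatches are kept only when the family has no retained site with fewer
#' mismatches. For novel miRNAs, a site needs fewer than 4 mismatches and
#' at least one valid degradome read.
#'
#' @param sites data.frame of sites from [find_sites()] (rbind over small
#'   RNAs/transcripts).
#' @param profiles a `degradome_profile`, used to attach valid-read counts.
#' @param conserved_families named character vector mapping
#'   `small_rna_id -> family` for conserved small RNAs; ids absent from it
#'   are treated as novel.
#' @param min_valid_novel valid reads required for novel-miRNA sites.
#' @return the retained sites with `valid_reads`, `reads_at_10`, `family`,
#'   `category` and the admitting `rule`.
#' @export
validate_targets <- function(sites, profiles, conserved_families = NULL,
                             min_valid_novel = 1L) {
  if (!nrow(sites)) {
    out <- sites
    out$valid_reads <- integer(0)
    out$rule <- character(0)
    return(out)
  }
  vr <- t(vapply(seq_len(nrow(sites)), function(r) {
    cv <- classify_valid_reads(sites[r, ], profiles)
    c(cv$valid_reads, cv$reads_at_10)
  }, numeric(2)))
  sites$valid_reads <- vr[, 1]
  sites$reads_at_10 <- vr[, 2]
  fam <- if (is.null(conserved_families)) {
    rep(NA_character_, nrow(sites))
  } else {
    conserved_families[sites$small_rna_id]
  }
  sites$family <- unname(fam)
  sites$category <- ifelse(is.na(sites$family), "novel", "conserved")
  keep <- rep(FALSE, nrow(sites))
  rule <- rep(NA_character_, nrow(sites))
  cons <- sites$category == "conserved"
  lt4 <- sites$mismatches < 4
  keep[cons & lt4] <- TRUE
  rule[cons & lt4] <- "conserved_lt4"
  # family fallback: 4-5 mm only when the family has no lower-mismatch site
  fb <- cons & !lt4 & sites$mismatches <= 5
  if (any(fb)) {
    fam_min <- tapply(sites$mismatches[cons], sites$family[cons], min)
    ok <- fb & sites$mismatches == fam_min[sites$family]
    # a 4-mm site blocks the family's 5-mm sites too, but nothing below 4
    ok <- ok & !(sites$family %in% names(fam_min)[fam_min < 4])
    keep[ok] <- TRUE
    rule[ok] <- "conserved_fallback_4_5"
  }
  nov <- sites$category == "novel" & lt4 & sites$valid_reads >= min_valid_novel
  keep[nov] <- TRUE
  rule[nov] <- "novel_valid"
  out <- sites[keep, , drop = FALSE]
  out$rule <- rule[keep]
  rownames(out) <- NULL
  out
}

#' Per-position t-plot table of a transcript
#'
#' @param profile a `degradome_profile`.
#' @param transcript_id transcript to extract.
#' @param sites optional sites on the transcript; their cleavage positions
#'   become markers.
#' @return list with `data` (1-based `position`, `reads`; zero positions
#'   omitted) and `markers` (cleavage positions of the supplied sites).
#' @export
tplot_data <- function(profile, transcript_id, sites = NULL) {
  v <- profile[[transcript_id]]
  nz <- which(v > 0)
  markers <- if (!is.null(sites) && nrow(sites)) {
    s <- sites[sites$transcript_id == transcript_id, , drop = FALSE]
    data.frame(small_rna_id = s$small_rna_id,
               position = s$cleavage_pos + 1L)
  } else {
    data.frame(small_rna_id = character(0), position = integer(0))
  }
  list(data = data.frame(position = nz, reads = v[nz]), markers = markers)
}

#' Detect TAS3 loci from dual miR390 sites around tasiARF homologs
#'
#' A TAS3 locus is reported when a transcript carries a tasiARF homolog
#' (at most `tasi_max_mm` substitutions against a reference tasiARF) with
#' miR390 complementary sites both 5' and 3' of the match (each at most
#' `mir390_max_mm` mismatches). The phase register between the 3' site's
#' cleavage position and the tasiARF start is reported modulo the phase
#' length; 0 means the tasiARF sits in register with miR390-guided cleavage.
#'
#' @param tasiarf_refs named character vector of reference tasiARF 21-mers
#'   (e.g. Arabidopsis/rice), see `system.file("extdata",
#'   "tasiarf_reference.fa", package = "srnaphase")`.
#' @param mir390 miR390 mature sequence.
#' @param transcripts a [transcript_set()].
#' @param cfg a [run_config()].
#' @param tasi_max_mm max substitutions for the tasiARF homolog (default 3).
#' @param mir390_max_mm max mismatches for each miR390 site (default 5).
#' @return data.frame with one row per locus: tasiARF span, both miR390
#'   site spans, the 3' cleavage position and `register`.
#' @export
find_tas3 <- function(tasiarf_refs, mir390, transcripts, cfg = run_config(),
                      tasi_max_mm = 3L, mir390_max_mm = 5L) {
  tasi_hits <- find_homolog_loci(tasiarf_refs, transcripts,
                                 max_mm = tasi_max_mm)
  tasi_hits <- tasi_hits[tasi_hits$strand == "+", , drop = FALSE]
  if (!nrow(tasi_hits)) return(empty_tas3())
  seqs <- unclass(transcripts)
  out <- list()
  for (tx in unique(tasi_hits$transcript_id)) {
    sites <- find_sites(mir390, seqs[[tx]], max_mm = mir390_max_mm,
                        transcript_id = tx, small_rna_id = "miR390")
    if (!nrow(sites)) next
    th <- tasi_hits[tasi_hits$transcript_id == tx, , drop = FALSE]
    # merge overlapping/adjacent tasiARF hits into one tasiRNA region
    th <- th[order(th$start), , drop = FALSE]
    grp <- cumsum(c(1, diff(th$start) > 42))
    for (g in unique(grp)) {
      blk <- th[grp == g, , drop = FALSE]
      t_start <- min(blk$start)
      t_end <- max(blk$end)
      five <- sites[sites$end <= t_start, , drop = FALSE]
      three <- sites[sites$start >= t_end, , drop = FALSE]
      if (!nrow(five) || !nrow(three)) next
      five <- five[which.min(five$mismatches), ]
      three <- three[which.min(three$mismatches), ]
      register <- (three$cleavage_pos - t_start) %% cfg$phase_len
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, tasi_start = t_start, tasi_end = t_end,
        n_tasiarf = nrow(blk),
        five_start = five$start, five_end = five$end,
        five_mismatches = five$mismatches,
        three_start = three$start, three_end = three$end,
        three_mismatches = three$mismatches,
        cleavage_pos = three$cleavage_pos,
        register = register)
    }
  }
  if (!length(out)) return(empty_tas3())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_tas3 <- function() {
  data.frame(transcript_id = character(0), tasi_start = integer(0),
             tasi_end = integer(0), n_tasiarf = integer(0),
             five_start = integer(0), five_end = integer(0),
             five_mismatches = numeric(0), three_start = integer(0),
             three_end = integer(0), three_mismatches = numeric(0),
             cleavage_pos = integer(0), register = integer(0))
}
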