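#' Find homologs of known mature miRNAs on transcripts
#'
#' Ungapped substitution-only search of every known mature sequence against
#' every transcript, on both strands, keeping hits with at most `max_mm`
#' mismatches (no indels). Antisense hits are kept and flagged by strand.
#'
#' @param known named character vector (or [transcript_set()]) of known
#'   mature miRNA sequences, typically 19-25 nt.
#' @param transcripts a [transcript_set()].
#' @param max_mm maximum substitutions (default 2).
#' @return data.frame with `mirna_id`, `transcript_id`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`.
#' @export
find_homolog_loci <- function(known, transcripts, max_mm = 2L) {
  known <- setNames(as_rna(as.character(unclass(known))),
                    names(unclass(known)))
  tx_int <- lapply(unclass(transcripts), seq_to_int)
  out <- list()
  for (q in names(known)) {
    L <- nchar(known[[q]])
    q_fwd <- seq_to_int(known[[q]])
    q_rev <- seq_to_int(revcomp(known[[q]]))
    for (tx in names(tx_int)) {
      s <- tx_int[[tx]]
      if (length(s) < L) next
      for (str in c("+", "-")) {
        mm <- mismatch_scan_cpp(s, if (str == "+") q_fwd else q_rev)
        hit <- which(mm <= max_mm)
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            mirna_id = q, transcript_id = tx,
            start = hit - 1L, end = hit - 1L + L,
            strand = str, mismatches = mm[hit])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract the flanked candidate window around a matched locus
#'
#' @param transcript transcript sequence (character).
#' @param span 0-based half-open interval of the matched locus.
#' @param flank nt of flank on each side (truncated at transcript ends).
#' @return list with `start`, `end` (window, 0-based half-open), `sequence`,
#'   `left_truncated`, `right_truncated` and `mature_offset` (locus start
#'   relative to the window).
#' @export
extract_flanks <- function(transcript, span, flank = 150L) {
  len <- nchar(transcript)
  if (span[1] < 0 || span[2] > len || span[1] >= span[2]) {
    stop("span must lie within the transcript")
  }
  start <- max(0L, span[1] - flank)
  end <- min(len, span[2] + flank)
  list(start = start, end = end,
       sequence = substr0(transcript, start, end),
       left_truncated = span[1] - flank < 0,
       right_truncated = span[2] + flank > len,
       mature_offset = span[1] - start)
}

#' Build a hairpin candidate from a folded window
#'
#' @param transcript_id transcript the window came from.
#' @param window_start 0-based start of the window on the transcript.
#' @param sequence window sequence.
#' @param fold_result result of [fold()] on `sequence`.
#' @param mature_span 0-based half-open mature interval within the window.
#' @return list of class `hairpin_candidate` carrying the structure, energy
#'   and `paired_in_mature`.
#' @export
hairpin_candidate <- function(transcript_id, window_start, sequence,
                              fold_result, mature_span) {
  if (!is.null(mature_span)) {
    w <- mature_span[2] - mature_span[1]
    if (mature_span[1] < 0 || mature_span[2] > nchar(sequence) ||
        w < 20 || w > 24) {
      stop("mature_span must be a 20-24 nt interval inside the window")
    }
  }
  structure(
    list(transcript_id = transcript_id,
         window_start = window_start,
         sequence = sequence,
         structure = fold_result$structure,
         energy = fold_result$energy,
         partner = fold_result$partner,
         mature_span = mature_span,
         paired_in_mature = if (is.null(mature_span)) NA_integer_ else
           paired_in_region(fold_result$partner, mature_span[1], mature_span[2]),
         verdicts = list()),
    class = "hairpin_candidate")
}

#' Putative-precursor structure filter
#'
#' Passes a candidate iff at least `min_paired` nucleotides of its mature
#' region are paired and the folding energy is strictly smaller than
#' `max_energy` kcal/mol. Both sub-verdicts are recorded.
#'
#' @param candidate a [hairpin_candidate()].
#' @param min_paired minimum paired mature nucleotides (default 18).
#' @param max_energy energy threshold, strict inequality (default -40).
#' @return the candidate with `verdicts$hairpin`, `verdicts$paired_ok`,
#'   `verdicts$energy_ok` set.
#' @export
hairpin_filter <- function(candidate, min_paired = 18L, max_energy = -40) {
  if (is.null(candidate$mature_span)) {
    stop("hairpin_filter needs a candidate with mature_span set")
  }
  paired_ok <- candidate$paired_in_mature >= min_paired
  energy_ok <- candidate$energy < max_energy
  candidate$verdicts$paired_ok <- paired_ok
  candidate$verdicts$energy_ok <- energy_ok
  candidate$verdicts$hairpin <- paired_ok && energy_ok
  candidate
}

# mismatch / asymmetric-bulge / longest-run accounting of the mature region
# against its pairing partner arm. The partner arm is the dominant duplex:
# the longest chain of paired mature positions with strictly decreasing
# partners (stray long-range pairs into the flanks are treated as
# unpaired). Mature positions unpaired (or off-chain) between two chain
# positions count as mismatches when the partner side skips nucleotides
# too, and as bulged/asymmetric otherwise. All three bounds are taken
# within the mature miRNA, so partner-side-only gaps and dangling
# unpaired mature ends are not counted.
mircheck_counts <- function(partner, mature_span) {
  idx <- seq.int(mature_span[1] + 1L, mature_span[2])  # 1-based
  p <- partner[idx]
  paired <- which(p >= 0L)
  if (length(paired) < 2) {
    return(list(mismatches = length(idx), asym = 0L,
                max_run = length(idx)))
  }
  # longest strictly-decreasing-partner subsequence (O(n^2), n <= 24)
  np <- length(paired)
  best <- rep(1L, np)
  prev <- rep(0L, np)
  for (t in seq_len(np)) {
    for (u in seq_len(t - 1L)) {
      if (p[paired[u]] > p[paired[t]] && best[u] + 1L > best[t]) {
        best[t] <- best[u] + 1L
        prev[t] <- u
      }
    }
  }
  t <- which.max(best)
  chain <- integer(0)
  while (t > 0L) {
    chain <- c(paired[t], chain)
    t <- prev[t]
  }
  mm <- 0L; asym <- 0L; max_run <- 0L
  for (t in seq_len(length(chain) - 1L)) {
    a <- chain[t]; b <- chain[t + 1L]
    gm <- b - a - 1L
    gp <- p[a] - p[b] - 1L
    mm <- mm + min(gm, gp)
    asym <- asym + max(0L, gm - gp)
    max_run <- max(max_run, min(gm, gp))
  }
  list(mismatches = mm, asym = asym, max_run = max_run)
}

#' MIRcheck-style duplex filter
#'
#' Over the mature region versus its pairing partner, counts mismatches
#' (unpaired positions opposite unpaired partner nucleotides), bulged or
#' asymmetrically unpaired nucleotides, and the longest run of continuous
#' mismatches. Passes iff mismatches <= 6, bulged/asymmetric nucleotides
#' <= 2 and the longest mismatch run <= 3.
#'
#' @param candidate a [hairpin_candidate()] with `mature_span` set.
#' @param max_mm,max_asym,max_run the three bounds.
#' @return the candidate with `verdicts$mircheck` and the three counts set.
#' @export
mircheck_filter <- function(candidate, max_mm = 6L, max_asym = 2L,
                            max_run = 3L) {
  if (is.null(candidate$mature_span)) {
    stop("mircheck_filter needs a candidate with mature_span set")
  }
  cts <- mircheck_counts(candidate$partner, candidate$mature_span)
  candidate$mircheck <- cts
  candidate$verdicts$mircheck <- cts$mismatches <= max_mm &&
    cts$asym <= max_asym && cts$max_run <= max_run
  candidate
}

#' Call a novel miRNA from star-strand evidence
#'
#' A novel mature is called iff tags from the library map to both arms of
#' the candidate hairpin and the dominant tag of each arm forms a duplex
#' with ~2-nt 3' overhangs (tolerance +/- `overhang_tol` nt) under the
#' candidate's structure. The more abundant tag becomes the mature, the
#' other the star.
#'
#' @param candidate a [hairpin_candidate()] that passed [hairpin_filter()].
#' @param lib a [tag_library()].
#' @param overhang_tol accepted deviation from the canonical 2-nt overhang.
#' @return one-row data.frame (`name`, `family`, `sequence`, `arm`,
#'   `source`, `precursor_id`, `star_sequence`, `count`) or `NULL`.
#' @export
call_novel <- function(candidate, lib, overhang_tol = 1L) {
  cand_set <- transcript_set(setNames(candidate$sequence, "cand"))
  hits <- map_tags(lib, cand_set, strands = "+")
  if (!nrow(hits)) return(NULL)
  hits$len <- nchar(hits$tag)
  hits <- hits[hits$len >= 20 & hits$len <= 24, , drop = FALSE]
  if (nrow(hits) < 2) return(NULL)
  p <- candidate$partner
  overhang <- function(a, b, c, d) {
    # 3' overhang of tag2 [c,d) relative to tag1 [a,b): for every tag1
    # position paired into [c,d) the implied overhang is constant along a
    # clean duplex, so take the modal value (robust to 1-2 shifted pairs
    # at the duplex ends in co-optimal folds)
    offs <- integer(0)
    for (i in a:(b - 1L)) {
      pi <- p[i + 1L]
      if (pi >= c && pi < d) offs <- c(offs, (d - 1L) - pi - (i - a))
    }
    if (!length(offs)) return(NA_integer_)
    tab <- table(offs)
    as.integer(names(tab)[which.max(tab)])
  }
  best <- NULL
  for (i in seq_len(nrow(hits) - 1L)) {
    for (j in seq(i + 1L, nrow(hits))) {
      h1 <- hits[i, ]; h2 <- hits[j, ]
      if (h1$pos > h2$pos) { tmp <- h1; h1 <- h2; h2 <- tmp }
      a <- h1$pos; b <- h1$pos + h1$len
      c <- h2$pos; d <- h2$pos + h2$len
      if (b > c) next  # overlapping spans cannot be a duplex
      o1 <- overhang(a, b, c, d)       # star-side 3' overhang
      o2 <- overhang(c, d, a, b)       # mature-side 3' overhang
      if (is.na(o1) || is.na(o2)) next
      if (abs(o1 - 2L) > overhang_tol || abs(o2 - 2L) > overhang_tol) next
      score <- min(h1$count, h2$count)
      if (is.null(best) || score > best$score) {
        best <- list(h5 = h1, h3 = h2, score = score)
      }
    }
  }
  if (is.null(best)) return(NULL)
  mature_first <- best$h5$count >= best$h3$count
  mat <- if (mature_first) best$h5 else best$h3
  star <- if (mature_first) best$h3 else best$h5
  data.frame(
    name = paste0(candidate$transcript_id, "_", candidate$window_start, "-novel"),
    family = NA_character_,
    sequence = mat$tag,
    arm = if (mature_first) "5p" else "3p",
    source = "novel",
    precursor_id = paste0(candidate$transcript_id, ":",
                          candidate$window_start),
    star_sequence = star$tag,
    count = mat$count)
}

# TRUE when two mature sequences differ only by <= max_end_diff terminal
# nucleotides in total (trimmed/extended at either end, no internal changes)
same_member_seq <- function(s, t, max_end_diff = 2L) {
  ns <- nchar(s); nt <- nchar(t)
  for (shift in seq.int(-max_end_diff, max_end_diff)) {
    lo <- max(0L, shift); hi <- min(ns, nt + shift)
    if (hi - lo < 1) next
    overlap <- hi - lo
    if ((ns - overlap) + (nt - overlap) > max_end_diff) next
    if (substr(s, lo + 1L, hi) == substr(t, lo + 1L - shift, hi - shift)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Merge isomiR-style mature calls into family members
#'
#' Two calls are the same member when their sequences differ by at most two
#' terminal nucleotides in total at the 5' or 3' ends (no internal changes)
#' and they do not carry two distinct precursors. Calls with distinct
#' recorded precursors always stay separate members.
#'
#' @param calls data.frame with at least `name`, `family`, `sequence`, and
#'   optionally `precursor_id` (NA when no precursor is available).
#' @param max_end_diff maximum total differing terminal nucleotides.
#' @return `calls` with a `member_key` column; the attribute
#'   `"member_counts"` holds members per family.
#' @export
merge_members <- function(calls, max_end_diff = 2L) {
  n <- nrow(calls)
  if (!n) {
    calls$member_key <- character(0)
    return(calls)
  }
  if (is.null(calls$precursor_id)) calls$precursor_id <- NA_character_
  if (is.null(calls$family)) calls$family <- NA_character_
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # precursors recorded per merged component: a member may never span two
  # distinct precursors, including transitively through precursor-free calls
  comp_prec <- lapply(calls$precursor_id,
                      function(p) if (is.na(p)) character(0) else p)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (!identical(calls$family[i], calls$family[j])) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      merged_prec <- union(comp_prec[[ri]], comp_prec[[rj]])
      if (length(merged_prec) > 1) next
      if (same_member_seq(calls$sequence[i], calls$sequence[j],
                          max_end_diff)) {
        parent[rj] <- ri
        comp_prec[[ri]] <- merged_prec
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  calls$member_key <- paste0(ifelse(is.na(calls$family), "fam", calls$family),
                             "_m", match(roots, unique(roots)))
  fam <- ifelse(is.na(calls$family), "<novel>", calls$family)
  attr(calls, "member_counts") <-
    tapply(calls$member_key, fam, function(k) length(unique(k)))
  calls
}

#' Conserved miRNA locus discovery pipeline
#'
#' Chains [find_homolog_loci()], [extract_flanks()], [fold()],
#' [hairpin_filter()] and [mircheck_filter()], recording the per-stage
#' funnel.
#'
#' @param known known mature miRNAs (named sequences).
#' @param transcripts a [transcript_set()].
#' @param cfg a [run_config()].
#' @param verbose emit per-stage funnel messages.
#' @return data.frame of candidate loci with filter verdicts; the
#'   `"funnel"` attribute counts survivors per stage, the `"candidates"`
#'   attribute keeps the [hairpin_candidate()] objects.
#' @export
discover_conserved <- function(known, transcripts, cfg = run_config(),
                               verbose = FALSE) {
  hits <- find_homolog_loci(known, transcripts, cfg$max_homolog_mm)
  funnel <- c(homolog_hits = nrow(hits))
  cands <- list()
  rows <- list()
  seqs <- unclass(transcripts)
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    win <- extract_flanks(seqs[[h$transcript_id]], c(h$start, h$end),
                          cfg$flank_len)
    fr <- fold(win$sequence)
    cand <- hairpin_candidate(h$transcript_id, win$start, win$sequence, fr,
                              c(win$mature_offset,
                                win$mature_offset + (h$end - h$start)))
    cand <- hairpin_filter(cand, cfg$min_paired, cfg$max_energy)
    cand <- mircheck_filter(cand)
    cands[[r]] <- cand
    rows[[r]] <- data.frame(
      mirna_id = h$mirna_id, transcript_id = h$transcript_id,
      start = h$start, end = h$end, strand = h$strand,
      mismatches = h$mismatches,
      window_start = win$start, window_end = win$end,
      energy = cand$energy, paired_in_mature = cand$paired_in_mature,
      hairpin_ok = cand$verdicts$hairpin,
      mircheck_ok = cand$verdicts$mircheck,
      pass = cand$verdicts$hairpin && cand$verdicts$mircheck)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), window_start = integer(0),
               window_end = integer(0), energy = numeric(0),
               paired_in_mature = integer(0), hairpin_ok = logical(0),
               mircheck_ok = logical(0), pass = logical(0))
  funnel["hairpin_pass"] <- sum(res$hairpin_ok)
  funnel["mircheck_pass"] <- sum(res$pass)
  if (verbose) {
    message("stage=homolog_search hits=", funnel["homolog_hits"])
    message("stage=hairpin_filter pass=", funnel["hairpin_pass"])
    message("stage=mircheck_filter pass=", funnel["mircheck_pass"])
  }
  attr(res, "funnel") <- funnel
  attr(res, "candidates") <- cands
  res
}
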