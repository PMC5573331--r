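#' Effective 5'-end positions with the 2-nt antisense offset
#'
#' Phased siRNA duplexes carry 2-nt 3' overhangs, so an antisense siRNA of a
#' phased duplex aligns two nucleotides 5' of its sense partner. Sense reads
#' keep their raw 5' position; antisense reads get `raw + 2`. Only 21-nt
#' tags are considered; other lengths are dropped and counted.
#'
#' @param reads data.frame with `tag`, `strand`, `pos` (0-based leftmost
#'   alignment coordinate) and `count`.
#' @param phase_len required tag length (default 21).
#' @return the 21-nt reads with an added `effective` column; the attribute
#'   `"n_excluded"` counts dropped non-21-nt entries.
#' @export
map_effective_positions <- function(reads, phase_len = 21L) {
  keep <- nchar(reads$tag) == phase_len
  out <- reads[keep, , drop = FALSE]
  out$effective <- out$pos + ifelse(out$strand == "-", 2L, 0L)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Hypergeometric window P-value for phased siRNAs
#'
#' Probability of observing at least `k` of `n` occupied positions on the
#' phased register when the `n` distinct 21-nt sRNA positions of a window
#' are placed at random among its `21 m` positions, of which `m` are in
#' register:
#' \deqn{P = \sum_{X=k}^{\min(n,m)} \frac{\binom{m}{X} \binom{20m}{n-X}}{\binom{21m}{n}}}
#' Evaluated in log space; exact to ~1e-12 relative error up to n = 210.
#'
#' @param n unique 21-nt sRNA positions in the window.
#' @param k occupied in-register positions.
#' @param m number of phases (default 10).
#' @return the upper-tail P-value.
#' @export
window_pvalue <- function(n, k, m = 10L) {
  if (k > n || k > m) stop("k must satisfy k <= min(n, m)")
  if (n > 21L * m) stop("n cannot exceed the ", 21L * m, " window positions")
  if (n < 0 || k < 0) stop("n and k must be non-negative")
  if (k == 0L) return(1)
  xs <- k:min(n, m)
  terms <- lchoose(m, xs) + lchoose(20L * m, n - xs) - lchoose(21L * m, n)
  mx <- max(terms)
  min(1, exp(mx) * sum(exp(terms - mx)))
}

#' Phase score of a window
#'
#' For a window with `k >= 3` phased unique sRNAs,
#' \deqn{score = (k-2)\,\ln\!\left(1 + 10\,\frac{\sum_i P_i}{1 + \sum_i U_i}\right)}
#' where `P_i` and `U_i` are the phased and non-phased read counts of the
#' i-th phase; the score is 0 for `k <= 2`.
#'
#' @param P per-phase phased read counts (length m).
#' @param U per-phase non-phased read counts (length m).
#' @param k number of phased unique sRNAs in the window.
#' @param min_k gate below which the score is 0 (default 3).
#' @return the phase score (>= 0).
#' @export
phase_score <- function(P, U, k, min_k = 3L) {
  if (length(P) != length(U)) stop("P and U must have one entry per phase")
  if (any(P < 0) || any(U < 0) || k < 0) stop("counts must be non-negative")
  if (k < min_k) return(0)
  (k - 2) * log(1 + 10 * sum(P) / (1 + sum(U)))
}

#' Scan a transcript for phased siRNA windows
#'
#' Slides a `window_len` (default 210 nt, ten 21-nt phases) window one
#' nucleotide at a time from `start_from` to the transcript end; the
#' register of each window is defined by its start. `n` counts distinct
#' occupied effective positions, `k` distinct occupied phase cycles, and
#' `P_i`/`U_i` raw reads on and off register per cycle.
#'
#' @param reads effective reads (output of [map_effective_positions()],
#'   possibly restricted to one transcript).
#' @param transcript_len transcript length in nt.
#' @param start_from first candidate window start (0-based, default 0).
#' @param cfg a [run_config()].
#' @return data.frame with one row per window: `window_start`, `n`, `k`,
#'   `sum_P`, `sum_U`, `p_value`, `phase_score`.
#' @export
scan_transcript <- function(reads, transcript_len, start_from = 0L,
                            cfg = run_config()) {
  wl <- cfg$window_len
  pl <- cfg$phase_len
  m <- cfg$n_phases
  if (start_from >= transcript_len) stop("start_from beyond transcript end")
  last <- transcript_len - wl
  if (last < start_from) {
    return(data.frame(window_start = integer(0), n = integer(0),
                      k = integer(0), sum_P = numeric(0), sum_U = numeric(0),
                      p_value = numeric(0), phase_score = numeric(0)))
  }
  # aggregate raw reads by effective position
  if (nrow(reads)) {
    agg <- aggregate(count ~ effective, data = reads, sum)
    pos <- agg$effective
    cnt <- agg$count
  } else {
    pos <- integer(0)
    cnt <- numeric(0)
  }
  starts <- seq.int(start_from, last)
  out <- data.frame(window_start = starts, n = 0L, k = 0L,
                    sum_P = 0, sum_U = 0, p_value = 1, phase_score = 0)
  for (r in seq_along(starts)) {
    w <- starts[r]
    inw <- pos >= w & pos < w + wl
    if (!any(inw)) next
    rel <- pos[inw] - w
    cw <- cnt[inw]
    phased <- rel %% pl == 0L
    n <- length(rel)
    k <- length(unique(rel[phased] %/% pl))
    sum_P <- sum(cw[phased])
    sum_U <- sum(cw[!phased])
    out$n[r] <- n
    out$k[r] <- k
    out$sum_P[r] <- sum_P
    out$sum_U[r] <- sum_U
    out$p_value[r] <- window_pvalue(n, k, m)
    out$phase_score[r] <- phase_score_sums(sum_P, sum_U, k, cfg$min_k)
  }
  out
}

# phase_score on pre-summed P/U
phase_score_sums <- function(sum_P, sum_U, k, min_k = 3L) {
  if (k < min_k) return(0)
  (k - 2) * log(1 + 10 * sum_P / (1 + sum_U))
}

#' Call phasiRNA-producing loci from scanned windows
#'
#' A transcript is called when at least one window satisfies
#' `p_value <= p_max` and `phase_score >= score_min`; the best such window
#' (smallest P, ties by score) is retained per transcript.
#'
#' @param windows data.frame of windows with a `transcript_id` column (rbind
#'   of per-transcript [scan_transcript()] results).
#' @param p_max P-value threshold (default 0.001).
#' @param score_min phase-score threshold (default 5).
#' @return data.frame with the best qualifying window per transcript.
#' @export
call_phased_loci <- function(windows, p_max = 0.001, score_min = 5) {
  if (p_max <= 0 || score_min <= 0) stop("thresholds must be positive")
  if (is.null(windows) || !nrow(windows)) {
    return(data.frame(transcript_id = character(0),
                      window_start = integer(0), n = integer(0),
                      k = integer(0), p_value = numeric(0),
                      phase_score = numeric(0)))
  }
  ok <- windows[windows$p_value <= p_max & windows$phase_score >= score_min, ,
                drop = FALSE]
  if (!nrow(ok)) return(ok)
  ok <- ok[order(ok$transcript_id, ok$p_value, -ok$phase_score), ,
           drop = FALSE]
  best <- ok[!duplicated(ok$transcript_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Anchor a phasing scan to a validated trigger site
#'
#' Restricts the window scan to start at the trigger's cleavage position and
#' reports the offset between the cleavage position and the best window
#' start (0 or a multiple of the phase length when the locus is in register
#' with the trigger-guided cleavage).
#'
#' @param site one-row target-site data.frame (see [find_sites()]) with
#'   `cleavage_pos` and `transcript_id`.
#' @param reads effective reads of the site's transcript.
#' @param transcript_len transcript length.
#' @param cfg a [run_config()].
#' @return one-row data.frame with the best window, `trigger_id`, `offset`
#'   and `in_register`, or `NULL` when no window qualifies.
#' @export
anchor_to_trigger <- function(site, reads, transcript_len,
                              cfg = run_config()) {
  cleave <- site$cleavage_pos
  if (cleave >= transcript_len - cfg$window_len) return(NULL)
  win <- scan_transcript(reads, transcript_len, start_from = cleave, cfg = cfg)
  win$transcript_id <- site$transcript_id
  best <- call_phased_loci(win, cfg$p_max, cfg$score_min)
  if (!nrow(best)) return(NULL)
  best$trigger_id <- site$small_rna_id
  best$offset <- best$window_start - cleave
  best$in_register <- best$offset %% cfg$phase_len == 0L
  best
}
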