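test_that("homolog search honors the mismatch threshold on both strands", {
  set.seed(21)
  mature <- random_seq(21)
  mm2 <- mature
  substr(mm2, 4, 4) <- c(A = "C", C = "A", G = "A", U = "C")[substr(mm2, 4, 4)]
  substr(mm2, 15, 15) <- c(A = "C", C = "A", G = "A", U = "C")[substr(mm2, 15, 15)]
  mm3 <- mm2
  substr(mm3, 9, 9) <- c(A = "C", C = "A", G = "A", U = "C")[substr(mm3, 9, 9)]
  tx <- make_transcripts(
    t_exact = paste0(random_seq(50), mature, random_seq(50)),
    t_mm2 = paste0(random_seq(50), mm2, random_seq(50)),
    t_mm3 = paste0(random_seq(50), mm3, random_seq(50)),
    t_anti = paste0(random_seq(50), revcomp(mature), random_seq(50)))
  hits <- find_homolog_loci(c(mir = mature), tx, max_mm = 2)
  expect_setequal(unique(hits$transcript_id), c("t_exact", "t_mm2", "t_anti"))
  he <- hits[hits$transcript_id == "t_exact" & hits$strand == "+", ]
  expect_identical(he$start, 50L)
  expect_identical(he$end, 71L)
  expect_identical(he$mismatches, 0L)
  expect_identical(hits$mismatches[hits$transcript_id == "t_mm2"], 2L)
  expect_identical(hits$strand[hits$transcript_id == "t_anti"], "-")
})

test_that("flank extraction truncates at transcript ends and records it", {
  tx <- random_seq(600)
  w <- extract_flanks(tx, c(200L, 221L), 150L)
  expect_identical(c(w$start, w$end), c(50L, 371L))
  expect_false(w$left_truncated || w$right_truncated)
  expect_identical(w$mature_offset, 150L)

  w2 <- extract_flanks(tx, c(10L, 31L), 150L)
  expect_identical(c(w2$start, w2$end), c(0L, 181L))
  expect_true(w2$left_truncated)
  expect_identical(w2$mature_offset, 10L)

  w3 <- extract_flanks(tx, c(100L, 121L), 0L)
  expect_identical(c(w3$start, w3$end), c(100L, 121L))
})

make_candidate <- function(mm = 0L, loop_len = 8L, seed = 1) {
  set.seed(seed)
  mature <- random_seq(21)
  hp <- gen_hairpin(mature, mm, loop_len)
  cand <- hairpin_candidate("tx", 0L, hp$sequence, fold(hp$sequence),
                            c(0L, 21L))
  list(cand = cand, hp = hp, mature = mature)
}

test_that("hairpin filter applies both thresholds with strict energy inequality", {
  x <- make_candidate()
  c1 <- x$cand
  c1$paired_in_mature <- 19L; c1$energy <- -45
  expect_true(hairpin_filter(c1)$verdicts$hairpin)
  c2 <- x$cand
  c2$paired_in_mature <- 17L; c2$energy <- -60
  v2 <- hairpin_filter(c2)$verdicts
  expect_false(v2$hairpin); expect_false(v2$paired_ok); expect_true(v2$energy_ok)
  c3 <- x$cand
  c3$paired_in_mature <- 20L; c3$energy <- -40
  expect_false(hairpin_filter(c3)$verdicts$hairpin)  # "smaller than -40"
  c4 <- x$cand
  c4$mature_span <- NULL
  expect_error(hairpin_filter(c4), "mature_span")
})

# hand-built duplex structure: mature 1..21 at positions 0..20, partner arm
# downstream, with chosen mature positions left unpaired symmetrically
duplex_partner <- function(mm_at = integer(0), len = 60) {
  partner <- rep(-1L, len)
  star_hi <- 50L
  for (i in 1:19) {
    if (i %in% mm_at) next
    partner[i] <- star_hi - i
    partner[star_hi - i + 1L] <- i - 1L
  }
  partner
}

test_that("mircheck counts mismatches and the boundary sits at six", {
  cand <- list(partner = duplex_partner(), mature_span = c(0L, 21L))
  class(cand) <- "hairpin_candidate"
  v <- mircheck_filter(cand)
  expect_true(v$verdicts$mircheck)
  expect_identical(v$mircheck$mismatches, 0L)

  scatter6 <- c(3L, 5L, 8L, 11L, 14L, 17L)
  c6 <- list(partner = duplex_partner(scatter6), mature_span = c(0L, 21L))
  class(c6) <- "hairpin_candidate"
  v6 <- mircheck_filter(c6)
  expect_identical(v6$mircheck$mismatches, 6L)
  expect_true(v6$verdicts$mircheck)

  scatter7 <- c(scatter6, 12L)
  c7 <- list(partner = duplex_partner(scatter7), mature_span = c(0L, 21L))
  class(c7) <- "hairpin_candidate"
  v7 <- mircheck_filter(c7)
  expect_identical(v7$mircheck$mismatches, 7L)
  expect_false(v7$verdicts$mircheck)

  run4 <- c(8L, 9L, 10L, 11L)
  cr <- list(partner = duplex_partner(run4), mature_span = c(0L, 21L))
  class(cr) <- "hairpin_candidate"
  vr <- mircheck_filter(cr)
  expect_identical(vr$mircheck$max_run, 4L)
  expect_false(vr$verdicts$mircheck)
})

test_that("novel calls require star evidence with ~2-nt overhangs", {
  d <- sim_design(n_transcripts = 12L, n_planted_hairpins = 4L,
                  n_planted_phased_loci = 0L, n_decoy_loci = 0L, n_tas3 = 0L,
                  seed = 9)
  sim <- gen_transcriptome(d)
  lib <- gen_srna_library(sim, d)
  tr <- sim$truth$hairpins
  seqs <- unclass(sim$transcripts)
  for (i in seq_len(nrow(tr))) {
    win <- extract_flanks(seqs[[tr$transcript_id[i]]],
                          c(tr$mature_start[i], tr$mature_start[i] + 21L), 150L)
    cand <- hairpin_candidate(tr$transcript_id[i], win$start, win$sequence,
                              fold(win$sequence),
                              c(win$mature_offset, win$mature_offset + 21L))
    cand <- hairpin_filter(cand)
    nc <- call_novel(cand, lib)
    expect_false(is.null(nc))
    expect_identical(nc$sequence, tr$mature[i])
    expect_identical(nc$star_sequence, tr$star_tag[i])
    expect_identical(nc$source, "novel")

    # a library with tags on the mature arm only: no call without miRNA*
    lib_onearm <- tag_library(setNames(c(50L, 5L),
                                       c(tr$mature[i], random_seq(21))))
    expect_null(call_novel(cand, lib_onearm))
  }
})

test_that("duplexes with out-of-tolerance overhangs are rejected", {
  set.seed(31)
  mature <- random_seq(21)
  hp <- gen_hairpin(mature, 0L, 8L)
  seqs <- paste0(random_seq(30), hp$sequence, random_seq(30))
  cand <- hairpin_candidate("t", 0L, seqs, fold(seqs), c(30L, 51L))
  # a star-side tag shifted 3 nt off the true star start still maps to the
  # candidate but implies overhangs of -1 on both sides
  shifted_star <- substr(seqs, 57, 77)
  lib_bad <- tag_library(setNames(c(50L, 12L), c(mature, shifted_star)))
  expect_null(call_novel(cand, lib_bad))
  # the true star at the same abundance is accepted
  lib_ok <- tag_library(setNames(c(50L, 12L), c(mature, hp$star_tag)))
  expect_false(is.null(call_novel(cand, lib_ok)))
})

test_that("isomiR merging follows the terminal-difference rule", {
  x <- "ACGUACGUACGUACGUACGUA"
  calls <- data.frame(
    name = c("a", "b", "c", "d", "e"),
    family = "miR1",
    sequence = c(x,
                 substr(x, 1, 20),                     # 3' trim: same member
                 paste0("G", substr(x, 2, 21)),        # internal change? no:
                 x, x),                                # d/e same seq
    precursor_id = c(NA, NA, NA, "prec1", "prec2"),
    stringsAsFactors = FALSE)
  internal <- x
  substr(internal, 10, 10) <- "A"
  calls$sequence[3] <- internal                        # internal substitution
  merged <- merge_members(calls)
  expect_identical(merged$member_key[1], merged$member_key[2])
  expect_false(merged$member_key[3] == merged$member_key[1])
  # same sequence but two distinct precursors: two members
  expect_false(merged$member_key[4] == merged$member_key[5])
  # the same-sequence precursor-free call joins the first member
  expect_identical(merged$member_key[1], merged$member_key[4])
})

test_that("filters are monotone: tightening thresholds never adds loci", {
  d <- sim_design(n_transcripts = 15L, n_planted_hairpins = 6L,
                  n_planted_phased_loci = 0L, n_decoy_loci = 0L, n_tas3 = 0L,
                  seed = 10)
  sim <- gen_transcriptome(d)
  known <- setNames(sim$truth$hairpins$mature, sim$truth$hairpins$name)
  loose <- discover_conserved(known, sim$transcripts,
                              run_config(min_paired = 16, max_energy = -30))
  tight <- discover_conserved(known, sim$transcripts,
                              run_config(min_paired = 19, max_energy = -60))
  key <- function(x) paste(x$mirna_id, x$transcript_id, x$start, x$strand)
  expect_true(all(key(tight[tight$hairpin_ok, ]) %in%
                  key(loose[loose$hairpin_ok, ])))
})
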